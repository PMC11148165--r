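# feature_io: TSV readers/writers (strict, round-trip safe) and the packaged
# published Dysbiosis Index coefficient tables.
#
# All writers emit a format-version comment line ("# icudysbiosis <kind> v1")
# so files self-identify; readers skip leading '#' comment lines.

FORMAT_VERSION <- "v1"

format_header <- function(kind) sprintf("# icudysbiosis %s %s", kind, FORMAT_VERSION)

read_tsv_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(NULL)
  read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
             check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = "character")
}

#' Read and write genus-level count tables
#'
#' Canonical on-disk form: UTF-8 tab-delimited text, one comment header line,
#' then a header row whose first cell is `sample_id` followed by taxon ids,
#' and one row per sample. Counts are parsed strictly: any cell that is not a
#' non-negative integer is an error naming the offending sample and taxon.
#' A table whose first header cell is `taxon_id` is rejected as transposed
#' (taxa-in-rows input is never silently flipped).
#'
#' @param path File path.
#' @param compartment Compartment tag to attach (`"oral"`, `"lung"`, `"gut"`).
#' @return `read_count_table()` returns a [count_table()];
#'   `write_count_table()` invisibly returns `path`.
#' @export
read_count_table <- function(path, compartment) {
  df <- read_tsv_body(path)
  if (is.null(df) || nrow(df) == 0L) stop_("empty count table: ", path)
  first <- names(df)[1L]
  if (identical(first, "taxon_id"))
    stop_("table appears transposed (taxa in rows); expected samples in rows ",
          "with a leading `sample_id` column")
  if (!identical(first, "sample_id"))
    stop_("first column of a count table must be `sample_id`, found `", first, "`")
  sample_ids <- df[[1L]]
  taxa <- names(df)[-1L]
  if (length(taxa) == 0L) stop_("count table has no taxon columns: ", path)
  m <- matrix(NA_integer_, nrow(df), length(taxa),
              dimnames = list(sample_ids, taxa))
  for (j in seq_along(taxa)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != round(val))
    if (length(bad) > 0L)
      stop_(sprintf(
        "invalid count '%s' at sample '%s', taxon '%s': counts must be non-negative integers",
        raw[bad[1L]], sample_ids[bad[1L]], taxa[j]))
    m[, j] <- as.integer(val)
  }
  count_table(m, compartment)
}

#' @rdname read_count_table
#' @param table A [count_table()].
#' @export
write_count_table <- function(table, path) {
  m <- as_count_matrix(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header("count_table"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write taxon annotation tables
#'
#' Annotations mirror the clinical classification schemes applied to the
#' genus table: oxygen requirement (obligate/facultative anaerobes, aerobes,
#' microaerophiles, variable, unclassifiable), plausible respiratory
#' pathogenicity (respiratory pathogen / oral commensal / other) and
#' compartment of origin (oral / gut / either). Category strings outside the
#' closed sets are rejected, listing the allowed values.
#'
#' @param path File path of a TSV with columns `taxon_id`, `oxygen_class`,
#'   `pathogenicity_class`, `origin_compartment`.
#' @return A data.frame with the four columns, one row per taxon.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_body(path)
  if (is.null(df) || nrow(df) == 0L) {
    warn_("empty annotation table: ", path)
    return(data.frame(taxon_id = character(), oxygen_class = character(),
                      pathogenicity_class = character(),
                      origin_compartment = character()))
  }
  need <- c("taxon_id", "oxygen_class", "pathogenicity_class", "origin_compartment")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop_("annotation table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, need]
  check_cat <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad) > 0L)
      stop_(sprintf("unknown %s value(s) %s; allowed: %s", col,
                    paste(sQuote(bad), collapse = ", "),
                    paste(allowed, collapse = ", ")))
  }
  check_cat("oxygen_class", OXYGEN_CLASSES)
  check_cat("pathogenicity_class", PATHOGENICITY_CLASSES)
  check_cat("origin_compartment", ORIGIN_COMPARTMENTS)
  if (anyDuplicated(df$taxon_id))
    stop_("duplicate taxon_id in annotations: ",
          paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  df
}

#' @rdname read_annotations
#' @param annotations Data frame as returned by `read_annotations()`.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header("taxon_annotation"), con)
  write.table(annotations, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' One row per sample: subject, compartment, follow-up interval
#' (baseline/middle/late), day from intubation, specimen type, soiled flag
#' (gut specimens), 16S qPCR copies, plus any number of `biomarker_*`
#' columns.
#'
#' @param path File path.
#' @return Data frame of per-sample metadata.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_body(path)
  if (is.null(df) || nrow(df) == 0L) stop_("empty metadata table: ", path)
  need <- c("sample_id", "subject_id", "compartment", "interval")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop_("metadata missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$interval), INTERVALS)
  if (length(bad) > 0L)
    stop_("unknown interval value(s): ", paste(bad, collapse = ", "),
          "; allowed: ", paste(INTERVALS, collapse = ", "))
  for (col in c("day_from_intubation", "qpcr_copies",
                grep("^biomarker_", names(df), value = TRUE)))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("soiled_flag" %in% names(df))
    df$soiled_flag <- df$soiled_flag %in% c("TRUE", "true", "1")
  if ("qpcr_copies" %in% names(df) && any(df$qpcr_copies < 0, na.rm = TRUE))
    stop_("qpcr_copies must be non-negative")
  df
}

#' @rdname read_metadata
#' @param metadata Data frame of sample metadata.
#' @export
write_metadata <- function(metadata, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header("sample_metadata"), con)
  write.table(metadata, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a packaged published Dysbiosis Index model
#'
#' Returns the compartment-specific multinomial-logit Dysbiosis Index with
#' the published coefficient values, transcribed verbatim into
#' `inst/extdata/dysbiosis_index_<compartment>.tsv`. The oral model has an
#' Intercept plus 7 taxon terms; the lung model an Intercept, ShannonIndex
#' and 11 taxon terms; the gut model an Intercept, ShannonIndex and 5 taxon
#' terms. `b1` is the Intermediate-vs-High coefficient vector, `b2` the
#' Low-vs-High vector. Taxon names follow the published spellings exactly
#' (e.g. `Pasteurellaceae_uncl`); remapping user data onto them is the
#' caller's responsibility via an explicit alias map, never fuzzy matching.
#'
#' @param compartment `"oral"`, `"lung"` or `"gut"`.
#' @return A [dysbiosis_index_model] object.
#' @export
#' @examples
#' m <- load_paper_model("lung")
#' m$feature_names
load_paper_model <- function(compartment) {
  compartment <- assert_compartment(compartment)
  path <- system.file("extdata", sprintf("dysbiosis_index_%s.tsv", compartment),
                      package = "icudysbiosis", mustWork = TRUE)
  df <- read_tsv_body(path)
  b1 <- as.numeric(df$b1)
  b2 <- as.numeric(df$b2)
  names(b1) <- names(b2) <- df$term
  if (sum(df$term == "Intercept") != 1L)
    stop_("coefficient table must contain exactly one Intercept row")
  features <- df$term[df$term != "Intercept"]
  new_dysbiosis_index_model(
    compartment = compartment,
    feature_names = features,
    b1 = b1, b2 = b2,
    feature_space = list(
      clr_pseudocount = 0.5,
      shannon = "rarefied_1000x100",
      source = "published"
    ))
}

#' Serialize a Dysbiosis Index model to JSON and back
#'
#' @param model A [dysbiosis_index_model].
#' @param path File path for the JSON model file.
#' @return `read_dysbiosis_model()` returns the model;
#'   `write_dysbiosis_model()` invisibly returns `path`.
#' @export
write_dysbiosis_model <- function(model, path) {
  stopifnot(inherits(model, "dysbiosis_index_model"))
  out <- list(
    format = paste("icudysbiosis dysbiosis_index_model", FORMAT_VERSION),
    compartment = model$compartment,
    feature_names = model$feature_names,
    b1 = as.list(model$b1),
    b2 = as.list(model$b2),
    feature_space = model$feature_space
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dysbiosis_model
#' @export
read_dysbiosis_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_dysbiosis_index_model(
    compartment = x$compartment,
    feature_names = x$feature_names,
    b1 = unlist(x$b1), b2 = unlist(x$b2),
    feature_space = x$feature_space
  )
}
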