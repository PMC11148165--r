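# CountTable: the samples x taxa unit every analysis stage consumes.

#' Construct a count table
#'
#' A `count_table` is a non-negative integer matrix with samples in rows,
#' taxa in columns, unique row/column names, and a compartment tag
#' (`"oral"`, `"lung"` or `"gut"`). It is the unit every downstream stage
#' (QC, diversity, CLR, DMM clustering, the Dysbiosis Index) consumes.
#'
#' @param counts Numeric matrix of non-negative integers, samples x taxa,
#'   with row names (sample ids) and column names (taxon ids).
#' @param compartment One of `"oral"`, `"lung"`, `"gut"`.
#' @return An object of class `count_table`: the integer matrix with a
#'   `compartment` attribute.
#' @export
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
#' ct <- count_table(m, "lung")
#' compartment(ct)
count_table <- function(counts, compartment) {
  compartment <- assert_compartment(compartment)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_("`counts` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("`counts` must carry sample ids as rownames and taxon ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop_("duplicate sample ids: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_("duplicate taxon ids: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop_("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(counts, compartment = compartment, class = c("count_table", "matrix", "array"))
}

#' @rdname count_table
#' @param x A `count_table`.
#' @export
compartment <- function(x) attr(x, "compartment")

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa [%s compartment]\n",
              nrow(x), ncol(x), compartment(x)))
  cat(sprintf("  read depth: min %d, median %s, max %d\n",
              min(rowSums(x)), format(stats::median(rowSums(x))), max(rowSums(x))))
  invisible(x)
}

# Subset samples, preserving class and compartment tag.
subset_samples <- function(table, keep) {
  count_table(unclass(table)[keep, , drop = FALSE], compartment(table))
}

as_count_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "compartment") <- NULL
  m
}

#' Relative abundances of a count table
#'
#' @param table A `count_table` (or plain counts matrix).
#' @return Matrix of row-wise proportions.
#' @export
relative_abundance <- function(table) {
  m <- as_count_matrix(table)
  rs <- rowSums(m)
  if (any(rs == 0)) stop_("cannot form relative abundances: zero-read sample(s) ",
                          paste(rownames(m)[rs == 0], collapse = ", "))
  sweep(m, 1L, rs, "/")
}
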