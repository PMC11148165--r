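# composition: low-abundance filtering, clinically motivated class
# aggregation (oxygen requirement / pathogenicity), gut-origin enrichment and
# dominance flags, and taxa-biomarker correlations.

#' Filter singletons and low-abundance taxa
#'
#' Drops taxa whose total count across all samples is 1 (singletons) and
#' taxa that fail the prevalence-at-abundance rule: a taxon is KEPT only if
#' it reaches relative abundance of at least `rel_min` in at least
#' `prevalence_min` of the samples. The operation is idempotent.
#'
#' @param table A [count_table()].
#' @param rel_min Relative-abundance detection threshold (default 1e-4).
#' @param prevalence_min Minimum fraction of samples at or above `rel_min`
#'   (default 0.05).
#' @return The filtered [count_table()].
#' @export
filter_low_abundance <- function(table, rel_min = 1e-4, prevalence_min = 0.05) {
  assert_scalar_number(rel_min, "rel_min", lower = 0)
  assert_scalar_number(prevalence_min, "prevalence_min", lower = 0, upper = 1)
  rel <- relative_abundance(table)
  singleton <- colSums(table) == 1L
  prevalent <- colMeans(rel >= rel_min) >= prevalence_min
  keep <- !singleton & prevalent
  if (!any(keep)) stop_("all taxa removed by the low-abundance filter")
  count_table(unclass(table)[, keep, drop = FALSE], compartment(table))
}

#' Aggregate abundances by annotation class
#'
#' Sums each sample's relative abundances within the classes of a
#' classification scheme (`"oxygen"` requirement or `"pathogenicity"`), so
#' per-sample class shares partition to 1. CLR aggregates are computed by
#' applying the CLR transform to the class-summed composition (CLR is not
#' additive, so summing per-taxon CLR values would be wrong). Taxa without
#' an annotation fall into the `unclassifiable` / `other` bucket with a
#' warning.
#'
#' @param table A [count_table()].
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param scheme `"oxygen"` or `"pathogenicity"`.
#' @param clr_pseudocount Pseudocount for the class-level CLR (default 0.5).
#' @return List of two matrices (samples x classes): `relative` and `clr`.
#' @export
aggregate_class_abundance <- function(table, annotations,
                                      scheme = c("oxygen", "pathogenicity"),
                                      clr_pseudocount = 0.5) {
  scheme <- match.arg(scheme)
  col <- switch(scheme, oxygen = "oxygen_class", pathogenicity = "pathogenicity_class")
  classes <- switch(scheme, oxygen = OXYGEN_CLASSES,
                    pathogenicity = PATHOGENICITY_CLASSES)
  fallback <- switch(scheme, oxygen = "unclassifiable", pathogenicity = "other")
  cls <- annotations[[col]][match(colnames(table), annotations$taxon_id)]
  if (anyNA(cls)) {
    warn_(sum(is.na(cls)), " taxa lack a ", scheme,
          " annotation; assigned to '", fallback, "'")
    cls[is.na(cls)] <- fallback
  }
  counts <- as_count_matrix(table)
  agg_counts <- t(rowsum(t(counts), group = factor(cls, levels = classes)))
  agg_counts[is.na(agg_counts)] <- 0
  rel <- sweep(agg_counts, 1L, rowSums(agg_counts), "/")
  list(relative = rel,
       clr = clr_transform(agg_counts, pseudocount = clr_pseudocount))
}

#' Gut-origin enrichment flag
#'
#' `TRUE` for samples whose summed relative abundance of taxa annotated as
#' gut-origin strictly exceeds `threshold` (default 30%); used to flag
#' possible gut-to-lung translocation in oral/lung samples.
#'
#' @param rel Relative-abundance matrix or one sample's named vector.
#' @param annotations Annotation data frame with `origin_compartment`.
#' @param threshold Strict lower bound on the gut-origin share (default 0.30).
#' @return Logical vector, one flag per sample.
#' @export
gut_origin_enrichment <- function(rel, annotations, threshold = 0.30) {
  if (is.null(dim(rel))) rel <- t(as.matrix(rel))
  gut_taxa <- annotations$taxon_id[annotations$origin_compartment == "gut"]
  share <- rowSums(rel[, colnames(rel) %in% gut_taxa, drop = FALSE])
  share > threshold
}

#' Single-taxon dominance flag
#'
#' `TRUE` when `taxon_id`'s relative abundance strictly exceeds `threshold`
#' (default 50%) in a sample, the operational definition of community
#' dominance.
#'
#' @param rel Relative-abundance matrix or one sample's named vector.
#' @param taxon_id Taxon to test; must be present in the table.
#' @param threshold Strict dominance bound (default 0.50).
#' @return Logical vector, one flag per sample.
#' @export
dominance_flag <- function(rel, taxon_id, threshold = 0.50) {
  if (is.null(dim(rel))) rel <- t(as.matrix(rel))
  if (!taxon_id %in% colnames(rel))
    stop_("unknown taxon: ", taxon_id)
  rel[, taxon_id] > threshold
}

#' Taxa-biomarker Pearson correlations
#'
#' Pairwise complete-case Pearson correlations between each taxon's CLR
#' abundance (typically the top-20 taxa of a compartment) and each
#' biomarker, with Benjamini-Hochberg adjustment across all tested pairs.
#' Pairs with a constant biomarker (or fewer than 3 complete observations)
#' are reported with `NA` statistics and excluded from the adjustment.
#'
#' @param clr CLR matrix restricted to the taxa of interest (samples x taxa).
#' @param biomarkers Numeric matrix (samples x biomarkers), rows aligned.
#' @return Data frame: `taxon`, `biomarker`, `r`, `p`, `p_adj`, sorted by
#'   adjusted p.
#' @export
biomarker_correlations <- function(clr, biomarkers) {
  clr <- as.matrix(clr); biomarkers <- as.matrix(biomarkers)
  if (nrow(clr) != nrow(biomarkers))
    stop_("`clr` and `biomarkers` must have the same samples")
  grid <- expand.grid(taxon = colnames(clr), biomarker = colnames(biomarkers),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- clr[, grid$taxon[i]]; y <- biomarkers[, grid$biomarker[i]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || sd(y[ok]) == 0 || sd(x[ok]) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "BH")
  out[order(out$p_adj), ]
}
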