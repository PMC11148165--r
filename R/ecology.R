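# ecology: QC filtering, rarefaction-based Shannon diversity, CLR transform,
# Bray-Curtis distances, PCoA and PERMANOVA.

#' Quality-control filter for count tables
#'
#' Removes samples with fewer than `min_reads` total reads (the ">= 1000
#' high-quality reads" rule is inclusive: a sample with exactly `min_reads`
#' is retained). For the gut compartment, rectal swabs not visibly coated by
#' stool ("unsoiled") are additionally removed because they under-represent
#' gut microbiota; a gut sample is dropped when its metadata `soiled_flag`
#' is `FALSE`.
#'
#' @param table A [count_table()].
#' @param metadata Sample metadata data frame covering all samples of
#'   `table` (must have `sample_id`; `soiled_flag` is used for gut tables).
#' @param min_reads Minimum total read count per sample (default 1000).
#' @return A list with elements `table` (the filtered [count_table()]) and
#'   `report` (data frame of removed samples with a `reason` column).
#' @export
qc_filter <- function(table, metadata, min_reads = 1000) {
  assert_count(min_reads, "min_reads", lower = 1L)
  ids <- rownames(table)
  if (!all(ids %in% metadata$sample_id))
    stop_("metadata does not cover sample(s): ",
          paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), ]
  depth <- rowSums(table)
  reason <- rep(NA_character_, length(ids))
  reason[depth < min_reads] <- sprintf("low_reads(<%d)", min_reads)
  if (identical(compartment(table), "gut") && "soiled_flag" %in% names(md)) {
    unsoiled <- !is.na(md$soiled_flag) & !md$soiled_flag
    reason[is.na(reason) & unsoiled] <- "unsoiled"
  }
  drop <- !is.na(reason)
  report <- data.frame(sample_id = ids[drop], reads = depth[drop],
                       reason = reason[drop], row.names = NULL)
  if (all(drop))
    stop_("no samples passed QC (min_reads = ", min_reads, ")")
  list(table = subset_samples(table, !drop), report = report)
}

#' Average Shannon index under rarefaction
#'
#' Computes the Shannon diversity (natural log) of a sample after repeated
#' random subsampling of reads without replacement to a fixed depth, and
#' returns the average over repetitions. Subsampling is multivariate
#' hypergeometric (drawing reads, not resampling proportions), the standard
#' device for making diversity comparable across uneven sequencing depths.
#' When the sample's total equals `depth` the subsample is the sample itself
#' and the result is its plug-in Shannon index exactly.
#'
#' @param counts Integer vector of one sample's taxon counts.
#' @param depth Rarefaction depth (default 1000 reads).
#' @param reps Number of random subsamplings averaged (default 100).
#' @param seed Integer seed; identical seeds give identical results.
#' @param base Logarithm base; natural log by default.
#' @return A list: `mean_shannon`, `depth`, `n_subsamples`.
#' @export
#' @examples
#' rarefied_shannon(c(250, 250, 250, 250), depth = 1000, reps = 5, seed = 1)
rarefied_shannon <- function(counts, depth = 1000, reps = 100, seed = 1L,
                             base = exp(1)) {
  assert_count(depth, "depth", lower = 1L)
  assert_count(reps, "reps", lower = 1L)
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop_("counts must be non-negative")
  total <- sum(counts)
  if (total < depth)
    stop_("sample has ", total, " reads, fewer than rarefaction depth ",
          depth, "; run qc_filter() first")
  sub <- with_seed_(seed, rarefy_matrix(counts, depth, reps))
  p <- sub / depth
  h <- -rowSums(ifelse(p > 0, p * log(p, base = base), 0))
  list(mean_shannon = mean(h), depth = depth, n_subsamples = reps)
}

# reps x T matrix of multivariate hypergeometric subsamples of `counts` at
# `depth`, drawn by sequential conditional hypergeometric sampling
# (vectorised across reps).
rarefy_matrix <- function(counts, depth, reps) {
  T_ <- length(counts)
  out <- matrix(0L, reps, T_)
  remaining_draw <- rep.int(depth, reps)
  remaining_pop <- sum(counts)
  for (t in seq_len(T_)) {
    if (counts[t] == 0L) next
    x <- rhyper(reps, m = counts[t], n = remaining_pop - counts[t],
                k = remaining_draw)
    out[, t] <- x
    remaining_draw <- remaining_draw - x
    remaining_pop <- remaining_pop - counts[t]
    if (remaining_pop == 0L || all(remaining_draw == 0L)) break
  }
  out
}

#' Shannon diversity for every sample of a table
#'
#' Convenience wrapper applying [rarefied_shannon()] row-wise with child
#' seeds split from one root seed (see [split_seed()]).
#'
#' @inheritParams rarefied_shannon
#' @param table A [count_table()] whose samples all have at least `depth` reads.
#' @return Data frame: `sample_id`, `mean_shannon`, `depth`, `n_subsamples`.
#' @export
shannon_table <- function(table, depth = 1000, reps = 100, seed = 1L) {
  seeds <- split_seed(seed, nrow(table), stream = 3L)
  vals <- vapply(seq_len(nrow(table)), function(i)
    rarefied_shannon(table[i, ], depth, reps, seeds[i])$mean_shannon,
    numeric(1))
  data.frame(sample_id = rownames(table), mean_shannon = vals,
             depth = depth, n_subsamples = reps, row.names = NULL)
}

#' Centered log-ratio transform
#'
#' Maps each sample's counts to `log(x + pseudocount)` centered by the
#' sample's mean log value, so each transformed row sums to zero. The
#' additive pseudocount (default 0.5, applied to every cell) handles zeros;
#' exact scale invariance holds only in the no-pseudocount limit, i.e.
#' approximately at large counts.
#'
#' @param table A [count_table()] or non-negative matrix (samples x taxa).
#' @param pseudocount Positive offset added to all counts (default 0.5).
#' @return Real matrix, same dimnames, rows summing to zero.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop_("`pseudocount` must be > 0")
  m <- if (inherits(table, "count_table")) as_count_matrix(table) else as.matrix(table)
  if (any(m < 0)) stop_("counts must be non-negative")
  lx <- log(m + pseudocount)
  lx - rowMeans(lx)
}

#' Bray-Curtis distance matrix
#'
#' `d(i, j) = sum|x_i - x_j| / sum(x_i + x_j)` over taxa. In `"relative"`
#' mode rows must be non-negative compositions and distances lie in
#' `[0, 1]`. `"clr_shifted"` mode accepts a CLR matrix and first subtracts
#' its global minimum so all entries are non-negative; this follows the
#' literal "Bray-Curtis on CLR abundances" recipe but the resulting
#' dissimilarities depend on the shift and are not true Bray-Curtis
#' fractions (see the methods vignette).
#'
#' @param x Abundance matrix, samples in rows.
#' @param mode `"relative"` (default) or `"clr_shifted"`.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(x, mode = c("relative", "clr_shifted")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "relative") {
    if (any(x < 0)) stop_("negative entries are not allowed in relative mode")
  } else {
    x <- x - min(x)
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  # vegdist returns NaN for pairs of all-zero rows; such rows are degenerate
  d[is.nan(d)] <- 0
  diag(d) <- 0
  d
}

#' Principal coordinates analysis
#'
#' Classical (metric) multidimensional scaling: Gower double-centering of
#' `-d^2/2` followed by eigen-decomposition. Coordinates are returned for
#' positive eigenvalues only, sorted in decreasing order; negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported untouched, never corrected.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return A list: `coordinates` (samples x positive axes) and
#'   `eigenvalues` (all, decreasing).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-12)
    stop_("`d` must be a symmetric distance matrix")
  n <- nrow(dm)
  fit <- cmdscale(as.dist(dm), k = n - 1L, eig = TRUE)
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(dm)
  list(coordinates = coords, eigenvalues = eig)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational analysis of variance: the pseudo-F statistic from the
#' distance-based sums-of-squares decomposition for a single grouping
#' factor, with a permutation p-value using the add-one convention
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, which guarantees
#' `p in (0, 1]`. Computation is delegated to `vegan::adonis2`.
#'
#' @param d Symmetric distance matrix (samples x samples).
#' @param labels Grouping vector, one label per sample; at least two groups
#'   with at least two samples each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A list: `pseudo_F`, `R2`, `p`, `n_permutations`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  dm <- as.matrix(d)
  labels <- as.factor(labels)
  if (length(labels) != nrow(dm))
    stop_("`labels` length must match the distance matrix")
  tab <- table(labels)
  if (length(tab) < 2L) stop_("PERMANOVA needs at least two groups")
  if (any(tab < 2L)) stop_("each group needs at least two samples")
  df <- data.frame(g = labels)
  fit <- with_seed_(seed,
    vegan::adonis2(as.dist(dm) ~ g, data = df, permutations = n_perm))
  list(pseudo_F = fit$F[1L], R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L],
       n_permutations = n_perm)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value; `m` defaults to the number of tests.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Write a distance matrix as square TSV
#'
#' @param d Symmetric matrix with sample-id dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  dm <- as.matrix(d)
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header("distance_matrix"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
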