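# Dysbiosis Index: feature selection on top-50 CLR taxa plus Shannon,
# multinomial logit with the High-Diversity cluster as reference, closed-form
# probability computation, and held-out accuracy evaluation.

#' Dysbiosis Index model object
#'
#' A compartment-specific multinomial-logit classifier mapping a sample's
#' features (CLR taxa abundances, optionally the Shannon index) to
#' probabilities of the High- / Intermediate- / Low-Diversity cluster.
#' `b1` holds the Intercept and per-feature coefficients of the
#' Intermediate-vs-High logit, `b2` those of the Low-vs-High logit. The
#' `feature_space` descriptor records how prediction-time features must be
#' constructed (CLR pseudocount, Shannon variant), so a serialized model
#' states its assumptions explicitly.
#'
#' @param compartment `"oral"`, `"lung"` or `"gut"`.
#' @param feature_names Ordered feature terms (taxon names, optionally
#'   `"ShannonIndex"`), excluding the Intercept.
#' @param b1,b2 Named numeric vectors over `c("Intercept", feature_names)`.
#' @param feature_space List describing the feature construction.
#' @return An object of class `dysbiosis_index_model`.
#' @export
new_dysbiosis_index_model <- function(compartment, feature_names, b1, b2,
                                      feature_space = list()) {
  compartment <- assert_compartment(compartment)
  need <- c("Intercept", feature_names)
  for (nm in c("b1", "b2")) {
    b <- get(nm)
    if (!all(need %in% names(b)))
      stop_(sprintf("`%s` missing coefficient(s): %s", nm,
                    paste(setdiff(need, names(b)), collapse = ", ")))
    if (any(!is.finite(b[need])))
      stop_(sprintf("`%s` has non-finite coefficients", nm))
  }
  structure(list(compartment = compartment,
                 feature_names = as.character(feature_names),
                 b1 = b1[need], b2 = b2[need],
                 feature_space = feature_space),
            class = "dysbiosis_index_model")
}

#' @export
print.dysbiosis_index_model <- function(x, ...) {
  cat(sprintf("Dysbiosis Index model [%s]: Intercept + %d feature(s)\n",
              x$compartment, length(x$feature_names)))
  print(data.frame(term = names(x$b1), b1 = unname(x$b1), b2 = unname(x$b2)),
        row.names = FALSE)
  invisible(x)
}

#' Top taxa of a compartment by mean abundance
#'
#' Ranks taxa by mean relative abundance across samples (the default,
#' order-stable choice; `rank_by = "clr"` ranks by mean CLR value instead)
#' and returns the top `n` taxon ids.
#'
#' @param table A [count_table()].
#' @param n Number of taxa to keep (50 for index derivation, 20 for
#'   biomarker correlation screens).
#' @param rank_by `"relative"` (default) or `"clr"`.
#' @return Character vector of taxon ids, by decreasing mean abundance.
#' @export
top_taxa <- function(table, n = 50, rank_by = c("relative", "clr")) {
  rank_by <- match.arg(rank_by)
  score <- switch(rank_by,
    relative = colMeans(relative_abundance(table)),
    clr = colMeans(clr_transform(table)))
  names(sort(score, decreasing = TRUE))[seq_len(min(n, ncol(table)))]
}

#' Feature selection for the Dysbiosis Index
#'
#' Selects, from the top-50 CLR taxa plus the Shannon index, the features
#' informative for the 3-class cluster label. The default
#' `"mb_surrogate"` method is stability selection over L1-penalised
#' multinomial fits: the penalty is fixed once on the full data by
#' cross-validation, then the model is refitted on `n_subsamples` random
#' half-subsamples and a feature is kept when it receives a non-zero
#' coefficient (any class) in at least `threshold` of the fits. This stands
#' in for a Markov-blanket search around the cluster variable: stable
#' L1-selected features approximate the label's Markov blanket in the
#' feature set. The `"ci_screen"` alternative keeps features whose
#' class-association likelihood-ratio test rejects at level `alpha`.
#'
#' @param features Numeric matrix (samples x candidate features), typically
#'   CLR values of the top-50 taxa with a `ShannonIndex` column appended.
#' @param labels 3-class factor/character vector of cluster labels.
#' @param alpha Test level for `"ci_screen"` (default 0.1).
#' @param method `"mb_surrogate"` (default) or `"ci_screen"`.
#' @param seed Integer seed; a fixed seed gives a deterministic subset.
#' @param n_subsamples Number of stability subsamples (default 50).
#' @param threshold Selection-frequency cutoff (default 0.7).
#' @return Character vector of selected feature names, with a
#'   `selection_frequency` attribute for the default method.
#' @export
select_features <- function(features, labels, alpha = 0.1,
                            method = c("mb_surrogate", "ci_screen"),
                            seed = 1L, n_subsamples = 50, threshold = 0.7) {
  method <- match.arg(method)
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 3L)
    stop_("`labels` must have exactly 3 classes, found ", nlevels(labels))
  if (any(table(labels) < 10L))
    stop_("each class needs at least 10 samples for feature selection")
  if (is.null(colnames(features))) stop_("`features` must have column names")

  if (method == "ci_screen") {
    p <- vapply(seq_len(ncol(features)), function(j) {
      f0 <- nnet::multinom(labels ~ 1, trace = FALSE)
      f1 <- nnet::multinom(labels ~ features[, j], trace = FALSE)
      lr <- 2 * (stats::logLik(f1) - stats::logLik(f0))
      pchisq(as.numeric(lr), df = 2, lower.tail = FALSE)
    }, numeric(1))
    return(structure(colnames(features)[p < alpha], p_values = p))
  }

  n <- nrow(features)
  # penalty fixed once on the full data, then held through the subsamples
  lam <- with_seed_(split_seed(seed, 1L, stream = 21L), {
    cv <- glmnet::cv.glmnet(features, labels, family = "multinomial",
                            nfolds = 5, type.measure = "class")
    cv$lambda.1se
  })
  seeds <- split_seed(seed, n_subsamples, stream = 22L)
  hits <- setNames(numeric(ncol(features)), colnames(features))
  kept_fits <- 0L
  for (b in seq_len(n_subsamples)) {
    idx <- with_seed_(seeds[b], {
      # stratified half-subsample so every class stays represented
      unlist(lapply(levels(labels), function(l) {
        rows <- which(labels == l)
        sample(rows, max(2L, floor(length(rows) / 2)))
      }))
    })
    fit <- tryCatch(
      glmnet::glmnet(features[idx, , drop = FALSE], labels[idx],
                     family = "multinomial", lambda = lam),
      error = function(e) NULL)
    if (is.null(fit)) next
    kept_fits <- kept_fits + 1L
    nz <- Reduce(`|`, lapply(coef(fit), function(cm) as.matrix(cm)[-1L, 1L] != 0))
    hits <- hits + as.numeric(nz)
  }
  if (kept_fits == 0L) stop_("all stability-selection fits failed")
  freq <- hits / kept_fits
  structure(names(freq)[freq >= threshold], selection_frequency = freq)
}

#' Fit the multinomial-logit Dysbiosis Index
#'
#' Maximum-likelihood multinomial logistic regression of the 3-class
#' cluster label on the selected features, with the High-Diversity class as
#' the reference category. If quasi-separation is detected (any coefficient
#' magnitude above 15 at convergence), the model is refitted with a small
#' ridge penalty (weight decay 1e-4) and flagged.
#'
#' @param features Numeric matrix (samples x features) with column names.
#' @param labels Labels with the three classes High / Intermediate / Low
#'   (or any 3 labels; `reference` names the reference class).
#' @param compartment Compartment tag stored on the model.
#' @param reference Reference class (default `"High"`).
#' @param feature_space Descriptor list stored on the model.
#' @return A [new_dysbiosis_index_model()] object; attribute `"ridged"`
#'   is `TRUE` when the separation fallback was used.
#' @export
fit_mlr <- function(features, labels, compartment = "lung",
                    reference = "High", feature_space = list()) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 3L)
    stop_("need exactly 3 classes, found: ",
          paste(levels(labels), collapse = ", "))
  if (!reference %in% levels(labels))
    stop_("reference class '", reference, "' not present in labels")
  if (nrow(features) <= ncol(features) + 1L)
    stop_("need more samples than features + 1")
  qr_x <- qr(cbind(1, features))
  if (qr_x$rank < ncol(features) + 1L) {
    dropped <- colnames(features)[qr_x$pivot[-seq_len(qr_x$rank)] - 1L]
    stop_("rank-deficient design; collinear column(s): ",
          paste(dropped, collapse = ", "))
  }
  labels <- stats::relevel(labels, ref = reference)
  safe <- make.names(colnames(features), unique = TRUE)
  df <- data.frame(features, check.names = FALSE)
  names(df) <- safe
  df$.label <- labels
  form <- stats::as.formula(paste(".label ~", paste(safe, collapse = " + ")))
  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 1000)
  ridged <- FALSE
  if (max(abs(coef(fit))) > 15) {
    fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = 1000,
                          decay = 1e-4)
    ridged <- TRUE
  }
  cm <- coef(fit)   # rows: non-reference classes; columns: (Intercept), features
  rename <- function(v) {
    names(v) <- c("Intercept", colnames(features))
    v
  }
  non_ref <- rownames(cm)
  # row order: Intermediate-vs-reference is b1, Low-vs-reference is b2 when
  # labels are the canonical High/Intermediate/Low; otherwise first/second
  # non-reference level in factor order.
  b1_row <- if ("Intermediate" %in% non_ref) "Intermediate" else non_ref[1L]
  b2_row <- if ("Low" %in% non_ref) "Low" else non_ref[2L]
  model <- new_dysbiosis_index_model(
    compartment = compartment,
    feature_names = colnames(features),
    b1 = rename(cm[b1_row, ]),
    b2 = rename(cm[b2_row, ]),
    feature_space = c(feature_space,
                      list(classes = c(reference, b1_row, b2_row))))
  attr(model, "ridged") <- ridged
  model
}

#' Predict cluster probabilities from a Dysbiosis Index model
#'
#' Closed-form evaluation of the two logits against the High-Diversity
#' reference: with `X = exp(b1 . [1, f])` and `Y = exp(b2 . [1, f])`,
#' `P(High) = 1 / (1 + X + Y)`, `P(Intermediate) = X / (1 + X + Y)`,
#' `P(Low) = Y / (1 + X + Y)`; the predicted cluster is the most probable
#' one. Computation is done on the log scale (log-sum-exp), so extreme
#' logits cannot overflow; the three probabilities sum to one exactly up to
#' machine rounding. Ties in the argmax are broken conservatively in the
#' order Low, Intermediate, High.
#'
#' Features are matched to `model$feature_names` by name: every model
#' feature must be present (no silent zero-fill unless
#' `fill_missing = TRUE`), `NaN`s are rejected, and extra columns are
#' ignored.
#'
#' @param object A `dysbiosis_index_model`.
#' @param features Named numeric vector (one sample) or matrix/data frame
#'   (samples x features).
#' @param fill_missing If `TRUE`, absent model features are taken as 0
#'   (CLR-scale "at the geometric mean"); off by default.
#' @param ... Unused.
#' @return Data frame: `P_high`, `P_intermediate`, `P_low`, `label`.
#' @export
predict.dysbiosis_index_model <- function(object, features,
                                          fill_missing = FALSE, ...) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.matrix(features)
  missing <- setdiff(object$feature_names, colnames(features))
  if (length(missing) > 0L) {
    if (!fill_missing)
      stop_("missing model feature(s): ", paste(missing, collapse = ", "),
            " (set fill_missing = TRUE to treat them as 0)")
    features <- cbind(features,
                      matrix(0, nrow(features), length(missing),
                             dimnames = list(NULL, missing)))
  }
  F_ <- features[, object$feature_names, drop = FALSE]
  if (any(is.na(F_)) || any(is.nan(F_)))
    stop_("feature matrix contains NA/NaN values")
  lx <- object$b1[["Intercept"]] + drop(F_ %*% object$b1[object$feature_names])
  ly <- object$b2[["Intercept"]] + drop(F_ %*% object$b2[object$feature_names])
  L <- cbind(High = 0, Intermediate = lx, Low = ly)
  P <- exp(L - row_logsumexp(L))
  # conservative tie-break: Low > Intermediate > High
  pref <- c("Low", "Intermediate", "High")
  lab <- apply(P, 1L, function(p) pref[which.max(p[pref])])
  out <- data.frame(P_high = P[, "High"], P_intermediate = P[, "Intermediate"],
                    P_low = P[, "Low"], label = lab, row.names = rownames(features))
  out
}

#' Stratified train/test split
#'
#' Splits samples into train and test sets with `test_frac` of each label
#' class (rounded, at least one per class) assigned to the test set;
#' seed-reproducible.
#'
#' @param labels Vector of class labels.
#' @param test_frac Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List of integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_frac = 0.2, seed = 1L) {
  assert_scalar_number(test_frac, "test_frac", lower = 0, upper = 1)
  labels <- factor(labels)
  test <- with_seed_(split_seed(seed, 1L, stream = 23L), {
    unlist(lapply(levels(labels), function(l) {
      rows <- which(labels == l)
      sample(rows, max(1L, round(length(rows) * test_frac)))
    }))
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Held-out accuracy of a Dysbiosis Index model
#'
#' Fraction of argmax predictions equal to the reference (DMM) labels, with
#' an exact Clopper-Pearson 95% binomial confidence interval and the full
#' confusion matrix.
#'
#' @param model A `dysbiosis_index_model`.
#' @param features Test-set feature matrix (samples x features).
#' @param labels Test-set reference labels (High/Intermediate/Low).
#' @return List: `accuracy`, `ci` (length 2), `confusion` (table),
#'   `n`.
#' @export
evaluate_accuracy <- function(model, features, labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop_("empty test set")
  pred <- predict(model, features)
  correct <- sum(pred$label == labels)
  bt <- binom.test(correct, length(labels))
  list(accuracy = correct / length(labels),
       ci = as.numeric(bt$conf.int),
       confusion = table(predicted = pred$label, reference = labels),
       n = length(labels))
}

#' Derive a compartment Dysbiosis Index from a clustered cohort
#'
#' End-to-end derivation mirroring the published procedure: DMM cluster
#' labels on QC-passed counts, CLR abundances of the top-50 taxa plus the
#' rarefied Shannon index as candidate features, a stratified 80/20
#' train/test split, Markov-blanket-surrogate feature selection on the
#' training set, a multinomial logit with High-Diversity reference, and
#' held-out accuracy on the test set.
#'
#' @param table A QC-passed [count_table()].
#' @param sample_labels Per-sample High/Intermediate/Low cluster labels
#'   (e.g. `label_clusters()$sample_labels`).
#' @param shannon Named per-sample Shannon index vector.
#' @param n_top Number of top taxa considered (default 50).
#' @param test_frac Held-out fraction (default 0.2).
#' @param seed Integer seed driving split and selection.
#' @param clr_pseudocount CLR pseudocount recorded in the feature space.
#' @return List: `model`, `selected_features`, `evaluation`
#'   (from [evaluate_accuracy()]), `split`.
#' @export
derive_dysbiosis_index <- function(table, sample_labels, shannon,
                                   n_top = 50, test_frac = 0.2, seed = 1L,
                                   clr_pseudocount = 0.5) {
  samples <- rownames(table)
  sample_labels <- sample_labels[samples]
  shannon <- shannon[samples]
  top <- top_taxa(table, n = n_top)
  feats <- cbind(clr_transform(table, clr_pseudocount)[, top, drop = FALSE],
                 ShannonIndex = shannon)
  split <- split_train_test(sample_labels, test_frac, seed)
  sel <- select_features(feats[split$train, , drop = FALSE],
                         sample_labels[split$train], seed = seed)
  if (length(sel) == 0L)
    stop_("no features survived stability selection")
  model <- fit_mlr(feats[split$train, sel, drop = FALSE],
                   sample_labels[split$train],
                   compartment = compartment(table),
                   feature_space = list(clr_pseudocount = clr_pseudocount,
                                        shannon = "rarefied",
                                        n_top = n_top,
                                        source = "derived"))
  evaluation <- evaluate_accuracy(model, feats[split$test, , drop = FALSE],
                                  sample_labels[split$test])
  list(model = model, selected_features = sel, evaluation = evaluation,
       split = split)
}

#' Write Dysbiosis Index predictions as TSV
#'
#' @param predictions Data frame from [predict.dysbiosis_index_model()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  df <- data.frame(sample_id = rownames(predictions), predictions,
                   row.names = NULL)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header("predictions"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
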