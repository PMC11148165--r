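# Dirichlet-multinomial mixture (DMM) community typing: EM fitting, Laplace
# model evidence, K selection under a cluster-prevalence rule, and labeling
# of components by diversity (High / Intermediate / Low).

ALPHA_FLOOR <- 1e-10

# n x K matrix of per-sample log Dirichlet-multinomial likelihoods, omitting
# the multinomial coefficient (constant in the parameters, so it cancels in
# responsibilities and in evidence comparisons across K).
dirmult_loglik_matrix <- function(X, alpha) {
  n_i <- rowSums(X)
  K <- nrow(alpha)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    a <- alpha[k, ]
    A <- sum(a)
    out[, k] <- lgamma(A) - lgamma(A + n_i) +
      rowSums(lgamma(sweep(X, 2L, a, "+"))) - sum(lgamma(a))
  }
  out
}

# One responsibility-weighted fixed-point update of a component's alpha
# (Minka's bound-based iteration, which cannot decrease the weighted
# likelihood), floored for numerical safety.
update_alpha_fp <- function(alpha_k, X, r, n_i, inner = 3L) {
  for (it in seq_len(inner)) {
    A <- sum(alpha_k)
    denom <- sum(r * (digamma(n_i + A) - digamma(A)))
    if (denom <= 0) break
    num <- colSums(r * (digamma(sweep(X, 2L, alpha_k, "+")))) -
      sum(r) * digamma(alpha_k)
    alpha_k <- alpha_k * num / denom
    alpha_k[!is.finite(alpha_k) | alpha_k < ALPHA_FLOOR] <- ALPHA_FLOOR
  }
  alpha_k
}

# Moment-style initial alphas from a hard assignment.
init_alpha <- function(X, assign, K, precision = 20) {
  P <- sweep(X + 0.5, 1L, rowSums(X + 0.5), "/")
  t(vapply(seq_len(K), function(k) {
    rows <- which(assign == k)
    p <- if (length(rows) > 0L) colMeans(P[rows, , drop = FALSE]) else colMeans(P)
    pmax(p * precision, 1e-3)
  }, numeric(ncol(X))))
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Each mixture component is a Dirichlet prior over multinomial
#' proportions; a sample's marginal likelihood under component `k` is
#' Dirichlet-multinomial with parameter vector `alpha[k, ]`. The E-step
#' computes responsibilities proportional to `weights[k] *
#' DirMult(x | alpha[k, ])`; the M-step sets the weights to mean
#' responsibilities and updates each `alpha[k, ]` by responsibility-weighted
#' fixed-point iterations. The best of `n_init` restarts (first: k-means on
#' CLR-transformed counts; rest: random assignments) by final log-likelihood
#' is returned. The EM log-likelihood is checked to be non-decreasing at
#' every iteration.
#'
#' @param table A [count_table()] (or counts matrix) that has passed QC.
#' @param K Number of components, `1 <= K <=` number of samples.
#' @param n_init Number of restarts (default 5).
#' @param tol Convergence tolerance: EM stops when the mean per-sample
#'   log-likelihood changes by less than `tol` between iterations
#'   (default 1e-6) - a per-sample criterion, so the stopping rule does
#'   not loosen as read depths or cohort sizes grow.
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param seed Integer seed controlling initialisation.
#' @param verbose Print per-restart log-likelihoods.
#' @return A `dmm_model`: `K`, `alpha` (K x taxa), `weights`,
#'   `responsibilities` (samples x K), `log_lik`, `fit_info`.
#' @export
fit_dmm <- function(table, K, n_init = 5, tol = 1e-6, max_iter = 500,
                    seed = 1L, verbose = FALSE) {
  X <- if (inherits(table, "count_table")) as_count_matrix(table) else as.matrix(table)
  K <- assert_count(K, "K", lower = 1L)
  if (K > nrow(X)) stop_("K (", K, ") exceeds the number of samples (", nrow(X), ")")
  n_init <- assert_count(n_init, "n_init", lower = 1L)
  storage.mode(X) <- "double"
  n <- nrow(X); T_ <- ncol(X)
  n_i <- rowSums(X)

  seeds <- split_seed(seed, n_init, stream = 11L)
  best <- NULL
  for (init in seq_len(n_init)) {
    assign0 <- with_seed_(seeds[init], {
      if (init == 1L && K > 1L) {
        km <- tryCatch(
          stats::kmeans(clr_transform(X), centers = K, nstart = 5),
          error = function(e) NULL)
        if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
      } else if (K == 1L) rep(1L, n) else sample.int(K, n, replace = TRUE)
    })
    alpha <- init_alpha(X, assign0, K)
    weights <- as.numeric(table(factor(assign0, levels = seq_len(K)))) / n
    weights <- pmax(weights, 1e-6); weights <- weights / sum(weights)

    ll_prev <- -Inf; converged <- FALSE; iter <- 0L
    R <- NULL
    repeat {
      iter <- iter + 1L
      lmat <- dirmult_loglik_matrix(X, alpha)
      la <- sweep(lmat, 2L, log(weights), "+")
      lse <- row_logsumexp(la)
      ll <- sum(lse)
      if (ll + 1e-8 * max(1, abs(ll)) < ll_prev)
        warn_("EM log-likelihood decreased at iteration ", iter,
              " (", format(ll_prev), " -> ", format(ll), ")")
      R <- exp(la - lse)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * n) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_prev <- ll
      # M-step
      weights <- pmax(colMeans(R), 1e-12)
      weights <- weights / sum(weights)
      for (k in seq_len(K))
        alpha[k, ] <- update_alpha_fp(alpha[k, ], X, R[, k], n_i)
    }
    if (verbose)
      message(sprintf("init %d: logLik %.3f (%d iters, converged=%s)",
                      init, ll, iter, converged))
    if (is.null(best) || ll > best$log_lik)
      best <- list(alpha = alpha, weights = weights, R = R, log_lik = ll,
                   iterations = iter, converged = converged)
  }
  if (!best$converged)
    warn_("EM did not converge within ", max_iter,
          " iterations; returning best fit with converged = FALSE")
  dimnames(best$alpha) <- list(paste0("component", seq_len(K)), colnames(X))
  dimnames(best$R) <- list(rownames(X), paste0("component", seq_len(K)))
  structure(list(
    K = K,
    alpha = best$alpha,
    weights = best$weights,
    responsibilities = best$R,
    log_lik = best$log_lik,
    laplace_log_evidence = NULL,
    fit_info = list(iterations = best$iterations, converged = best$converged,
                    n_init = n_init, seed = seed, tol = tol,
                    max_iter = max_iter)
  ), class = "dmm_model")
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial mixture: K = %d, %d taxa, %d samples\n",
              x$K, ncol(x$alpha), nrow(x$responsibilities)))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat(sprintf("  logLik %.2f (%d EM iterations, converged = %s)\n",
              x$log_lik, x$fit_info$iterations, x$fit_info$converged))
  if (!is.null(x$laplace_log_evidence))
    cat(sprintf("  Laplace log evidence %.2f\n", x$laplace_log_evidence))
  invisible(x)
}

#' Hard cluster assignments of a DMM model
#'
#' Argmax responsibilities; ties broken towards the lowest component index.
#'
#' @param model A `dmm_model`.
#' @return Integer vector of component indices, named by sample.
#' @export
dmm_assignments <- function(model) {
  a <- apply(model$responsibilities, 1L, which.max)
  setNames(as.integer(a), rownames(model$responsibilities))
}

# Analytic gradient and Hessian blocks of the mixture log-likelihood in
# eta = log(alpha) space, responsibility-weighted per component. Exact for
# K = 1; for K > 1 the cross-component curvature is neglected
# (block-diagonal approximation, see vignette).
component_hessian_eta <- function(alpha_k, X, r, n_i) {
  A <- sum(alpha_k)
  c_i <- trigamma(A) - trigamma(A + n_i)        # shared curvature term
  g_alpha <- sum(r * (digamma(A) - digamma(A + n_i))) +
    colSums(r * digamma(sweep(X, 2L, alpha_k, "+"))) -
    sum(r) * digamma(alpha_k)
  s <- sum(r * c_i)
  diag_term <- colSums(r * trigamma(sweep(X, 2L, alpha_k, "+"))) -
    sum(r) * trigamma(alpha_k)
  H_alpha <- matrix(s, length(alpha_k), length(alpha_k))
  diag(H_alpha) <- diag(H_alpha) + diag_term
  # chain rule to eta = log alpha
  H_eta <- (alpha_k %o% alpha_k) * H_alpha + diag(alpha_k * g_alpha,
                                                  length(alpha_k))
  H_eta
}

# Hessian (finite differences) of the mixture log-likelihood with respect to
# the mixing-weight logits (K-1 free parameters), alphas held fixed. Cheap:
# the per-component likelihood matrix is precomputed.
weights_hessian_logit <- function(lmat, weights, h = 1e-4) {
  K <- length(weights)
  if (K == 1L) return(matrix(0, 0, 0))
  u0 <- log(weights[-K] / weights[K])
  f <- function(u) {
    w <- c(exp(u), 1); w <- w / sum(w)
    sum(row_logsumexp(sweep(lmat, 2L, log(w), "+")))
  }
  d <- K - 1L
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in i:d) {
    ei <- ej <- rep(0, d); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(u0 + ei + ej) - f(u0 + ei - ej) - f(u0 - ei + ej) + f(u0 - ei - ej)) /
      (4 * h^2)
  }
  H
}

#' Laplace approximation to the DMM log model evidence
#'
#' Approximates the log marginal likelihood at the fitted mode:
#' `log evidence ~ log posterior(theta_hat) + (d/2) log(2*pi) -
#' log det(H) / 2`, where `H` is the Hessian of the negative log posterior
#' in an unconstrained parameterisation (log-alpha per component;
#' mixing-weight logits) and `d = K * T + (K - 1)` free parameters. The
#' posterior combines the mixture likelihood with weakly informative
#' normal priors on the unconstrained parameters (`log alpha ~ N(0, 3^2)`,
#' weight logits `~ N(0, 1.5^2)`); a proper prior is what supplies the
#' Occam factor that lets the evidence penalise superfluous components.
#' Alpha blocks use the analytic responsibility-weighted Hessian (exact at
#' `K = 1`); the small mixing-weight block is differentiated numerically.
#' The value is invariant to component relabeling.
#'
#' @param model A converged `dmm_model`.
#' @param table The [count_table()] the model was fitted to.
#' @param prior_sd_log_alpha,prior_sd_logit Prior standard deviations on
#'   the log-alpha and weight-logit scales (defaults 3 and 1.5).
#' @return Log evidence (finite scalar).
#' @export
laplace_log_evidence <- function(model, table, prior_sd_log_alpha = 3,
                                 prior_sd_logit = 1.5) {
  stopifnot(inherits(model, "dmm_model"))
  if (!model$fit_info$converged)
    stop_("Laplace evidence requires a converged model")
  X <- if (inherits(table, "count_table")) as_count_matrix(table) else as.matrix(table)
  storage.mode(X) <- "double"
  n_i <- rowSums(X)
  K <- model$K; T_ <- ncol(X)
  d <- K * T_ + (K - 1L)
  eta <- log(model$alpha)
  log_prior <- sum(dnorm(eta, 0, prior_sd_log_alpha, log = TRUE))
  logdet <- 0
  for (k in seq_len(K)) {
    Hk <- -component_hessian_eta(model$alpha[k, ], X,
                                 model$responsibilities[, k], n_i)
    diag(Hk) <- diag(Hk) + 1 / prior_sd_log_alpha^2
    ev <- tryCatch(determinant(Hk, logarithm = TRUE),
                   error = function(e) NULL)
    if (is.null(ev) || ev$sign <= 0)
      stop_("singular or indefinite Hessian for component ", k,
            "; the model is over-parameterised - consider reducing K")
    logdet <- logdet + as.numeric(ev$modulus)
  }
  if (K > 1L) {
    u <- log(model$weights[-K] / model$weights[K])
    log_prior <- log_prior + sum(dnorm(u, 0, prior_sd_logit, log = TRUE))
    lmat <- dirmult_loglik_matrix(X, model$alpha)
    Hw <- -weights_hessian_logit(lmat, model$weights)
    diag(Hw) <- diag(Hw) + 1 / prior_sd_logit^2
    ev <- tryCatch(determinant(Hw, logarithm = TRUE), error = function(e) NULL)
    if (is.null(ev) || ev$sign <= 0)
      stop_("singular mixing-weight Hessian; consider reducing K")
    logdet <- logdet + as.numeric(ev$modulus)
  }
  out <- model$log_lik + log_prior + (d / 2) * log(2 * pi) - logdet / 2
  if (!is.finite(out)) stop_("Laplace evidence is not finite")
  out
}

# BIC-style evidence fallback: logLik - (d/2) log n.
bic_log_evidence <- function(model, table) {
  n <- nrow(model$responsibilities)
  d <- model$K * ncol(model$alpha) + (model$K - 1L)
  model$log_lik - (d / 2) * log(n)
}

#' Select the number of DMM components
#'
#' Fits `K = 1..K_max`, discards any `K` whose smallest hard-assigned
#' cluster holds fewer than `prevalence_min` of the samples (clusters must
#' contain at least 10% of observations by default to merit inclusion), and
#' returns the surviving model with the highest Laplace log evidence. If
#' every `K` is discarded the `K = 1` model is returned with a warning.
#'
#' @inheritParams fit_dmm
#' @param K_max Largest number of components tried (default 5).
#' @param prevalence_min Minimum fraction of samples in the smallest
#'   cluster (default 0.10).
#' @param method `"laplace"` (default) or `"bic"` evidence.
#' @return The selected `dmm_model`, with `laplace_log_evidence` filled in
#'   and an `selection` element recording the per-K evidence table.
#' @export
select_k <- function(table, K_max = 5, prevalence_min = 0.10, seed = 1L,
                     n_init = 5, method = c("laplace", "bic"), ...) {
  method <- match.arg(method)
  K_max <- assert_count(K_max, "K_max", lower = 1L)
  seeds <- split_seed(seed, K_max, stream = 12L)
  fits <- vector("list", K_max)
  tab <- data.frame(K = seq_len(K_max), log_evidence = NA_real_,
                    min_prevalence = NA_real_, admissible = FALSE,
                    converged = NA)
  n <- nrow(table)
  for (K in seq_len(K_max)) {
    fit <- fit_dmm(table, K, n_init = n_init, seed = seeds[K], ...)
    hard <- dmm_assignments(fit)
    prev <- min(tabulate(hard, nbins = K)) / n
    ev <- tryCatch(
      if (method == "laplace") laplace_log_evidence(fit, table)
      else bic_log_evidence(fit, table),
      error = function(e) { warn_("evidence failed at K = ", K, ": ",
                                  conditionMessage(e)); NA_real_ })
    fit$laplace_log_evidence <- ev
    fits[[K]] <- fit
    tab$log_evidence[K] <- ev
    tab$min_prevalence[K] <- prev
    tab$converged[K] <- fit$fit_info$converged
    tab$admissible[K] <- is.finite(ev) && prev >= prevalence_min
  }
  if (!any(tab$admissible)) {
    warn_("no K satisfied the prevalence/evidence criteria; falling back to K = 1")
    best <- fits[[1L]]
  } else {
    best <- fits[[which.max(ifelse(tab$admissible, tab$log_evidence, -Inf))]]
  }
  best$selection <- tab
  best
}

#' Label DMM components by diversity
#'
#' Orders components by the mean Shannon index of their (hard-assigned)
#' member samples, descending, and names them High / Intermediate / Low
#' (for `K = 3`; other `K` get `High`, `Intermediate-i`, ..., `Low` by
#' rank). Ties in mean Shannon are broken by component index with a
#' warning. The sample labeling is invariant to permuting component
#' indices.
#'
#' @param model A `dmm_model`.
#' @param shannon Numeric vector of per-sample Shannon indices, aligned
#'   with (or named by) the model's samples.
#' @return A list: `component_labels` (component -> label),
#'   `mean_shannon` (per component), `sample_labels` (per sample).
#' @export
label_clusters <- function(model, shannon) {
  stopifnot(inherits(model, "dmm_model"))
  samples <- rownames(model$responsibilities)
  if (!is.null(names(shannon))) {
    if (!all(samples %in% names(shannon)))
      stop_("`shannon` is missing sample(s): ",
            paste(setdiff(samples, names(shannon)), collapse = ", "))
    shannon <- shannon[samples]
  } else if (length(shannon) != length(samples)) {
    stop_("`shannon` must have one value per sample")
  }
  hard <- dmm_assignments(model)
  means <- vapply(seq_len(model$K), function(k) {
    members <- which(hard == k)
    if (length(members) == 0L) -Inf else mean(shannon[members])
  }, numeric(1))
  if (anyDuplicated(means[is.finite(means)]))
    warn_("tie in component mean Shannon; breaking by component index")
  ord <- order(means, -seq_along(means), decreasing = TRUE)
  labels <- cluster_rank_labels(model$K)
  component_labels <- character(model$K)
  component_labels[ord] <- labels
  names(component_labels) <- paste0("component", seq_len(model$K))
  list(component_labels = component_labels,
       mean_shannon = setNames(means, names(component_labels)),
       sample_labels = setNames(component_labels[hard], samples))
}

#' Write DMM assignments as TSV
#'
#' @param model A `dmm_model`.
#' @param labeling Output of [label_clusters()] (optional).
#' @param path Output path.
#' @export
write_dmm_assignments <- function(model, path, labeling = NULL) {
  hard <- dmm_assignments(model)
  df <- data.frame(
    sample_id = names(hard),
    component = hard,
    label = if (is.null(labeling)) NA_character_
            else unname(labeling$sample_labels[names(hard)]),
    max_responsibility = apply(model$responsibilities, 1L, max),
    row.names = NULL)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header("dmm_assignments"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a DMM model to JSON
#'
#' @param model A `dmm_model`.
#' @param path Output path.
#' @export
write_dmm_model <- function(model, path) {
  out <- list(
    format = paste("icudysbiosis dmm_model", FORMAT_VERSION),
    K = model$K,
    taxa = colnames(model$alpha),
    alpha = apply(model$alpha, 1L, identity, simplify = FALSE),
    weights = model$weights,
    log_lik = model$log_lik,
    laplace_log_evidence = model$laplace_log_evidence,
    fit_info = model$fit_info)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
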