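# synthetic_cohort: generators with the statistical structure the analysis
# assumes (K-component Dirichlet-multinomial counts per compartment, three
# visit intervals with outcome-informative dropout, cluster-dependent
# 60-day hazards, biomarkers coupled to pathogen abundance), so every
# downstream stage is testable without external sequencing data.

#' Block-structured Dirichlet parameter matrix
#'
#' Builds a K x n_taxa Dirichlet parameter matrix in which component `k`
#' concentrates `block_mass[k]` of its total mass on its own disjoint block
#' of `block_size` taxa, the rest spread evenly over all other taxa. Equal
#' block masses of 0.7 give the well-separated fixture used for cluster
#' recovery; a graded vector (increasing mass, decreasing evenness) makes
#' component Shannon diversity strictly decrease with `k`, emulating
#' High / Intermediate / Low-Diversity community types.
#'
#' @param K Number of components.
#' @param n_taxa Number of taxa (at least `K * block_size`).
#' @param block_size Taxa per dominant block (default 5).
#' @param block_mass Fraction of mass on the block, recycled to `K`
#'   (default 0.7).
#' @param precision Total Dirichlet concentration per component
#'   (default 50).
#' @return K x n_taxa matrix with taxa named `taxon_01`, ...
#' @export
separated_alpha_matrix <- function(K = 3, n_taxa = 50, block_size = 5,
                                   block_mass = 0.7, precision = 50) {
  K <- assert_count(K, "K", lower = 1L)
  if (n_taxa < K * block_size)
    stop_("need n_taxa >= K * block_size")
  block_mass <- rep_len(block_mass, K)
  if (any(block_mass <= 0 | block_mass >= 1))
    stop_("block_mass must lie in (0, 1)")
  alpha <- matrix(0, K, n_taxa,
                  dimnames = list(paste0("component", seq_len(K)),
                                  sprintf("taxon_%02d", seq_len(n_taxa))))
  for (k in seq_len(K)) {
    block <- ((k - 1L) * block_size + 1L):(k * block_size)
    alpha[k, ] <- precision * (1 - block_mass[k]) / (n_taxa - block_size)
    alpha[k, block] <- precision * block_mass[k] / block_size
  }
  alpha
}

#' Simulate Dirichlet-multinomial mixture counts
#'
#' The generative process the DMM fitting assumes: for each sample,
#' (i) a component `z` is drawn from `mixing_weights`, (ii) a composition
#' `p ~ Dirichlet(alpha[z, ])`, (iii) a read depth uniform on
#' `depth_range`, (iv) counts `~ Multinomial(depth, p)`. Identical seeds
#' give identical tables.
#'
#' @param alpha_matrix K x T matrix of positive Dirichlet parameters.
#' @param mixing_weights Length-K simplex (sums to 1 within 1e-12).
#' @param n_samples Number of samples to draw.
#' @param depth_range Integer `c(min, max)` read depth, min >= 1.
#' @param seed Integer seed.
#' @param compartment Compartment tag for the returned table.
#' @param sample_prefix Prefix for generated sample ids.
#' @param labels Optional integer vector of fixed component memberships
#'   (length `n_samples`); when supplied, step (i) is skipped and counts
#'   are drawn conditional on these labels.
#' @return List: `table` (a [count_table()]) and `labels` (integer vector
#'   of generating components).
#' @export
simulate_dmm_counts <- function(alpha_matrix, mixing_weights, n_samples,
                                depth_range, seed = 1L,
                                compartment = "lung",
                                sample_prefix = "sample", labels = NULL) {
  alpha_matrix <- as.matrix(alpha_matrix)
  K <- nrow(alpha_matrix)
  if (K == 0L) stop_("alpha_matrix must have at least one component row")
  if (any(!is.finite(alpha_matrix)) || any(alpha_matrix <= 0))
    stop_("all Dirichlet parameters must be positive")
  if (length(mixing_weights) != K)
    stop_("mixing_weights must have one entry per component")
  if (any(mixing_weights < 0) || abs(sum(mixing_weights) - 1) > 1e-12)
    stop_("mixing_weights must be a simplex summing to 1 (within 1e-12)")
  n_samples <- assert_count(n_samples, "n_samples", lower = 1L)
  depth_range <- as.integer(round(depth_range))
  if (length(depth_range) != 2L || depth_range[1L] < 1L ||
      depth_range[2L] < depth_range[1L])
    stop_("depth_range must be c(min, max) with 1 <= min <= max")
  T_ <- ncol(alpha_matrix)
  taxa <- colnames(alpha_matrix) %||% sprintf("taxon_%02d", seq_len(T_))

  if (!is.null(labels)) {
    if (length(labels) != n_samples || any(!labels %in% seq_len(K)))
      stop_("`labels` must be length n_samples with values in 1..K")
  }
  out <- with_seed_(seed, {
    z <- if (is.null(labels))
      sample.int(K, n_samples, replace = TRUE, prob = mixing_weights)
    else as.integer(labels)
    depths <- if (depth_range[1L] == depth_range[2L])
      rep.int(depth_range[1L], n_samples)
    else depth_range[1L] + sample.int(depth_range[2L] - depth_range[1L] + 1L,
                                      n_samples, replace = TRUE) - 1L
    counts <- matrix(0L, n_samples, T_)
    for (i in seq_len(n_samples)) {
      g <- rgamma(T_, shape = alpha_matrix[z[i], ], rate = 1)
      if (sum(g) == 0) g <- rep(1, T_)   # guard against underflow at tiny alpha
      counts[i, ] <- as.integer(rmultinom(1L, depths[i], g / sum(g)))
    }
    list(z = z, counts = counts)
  })
  dimnames(out$counts) <- list(sprintf("%s_%04d", sample_prefix,
                                       seq_len(n_samples)), taxa)
  list(table = count_table(out$counts, compartment), labels = out$z)
}

#' Simulate 60-day outcomes and informative follow-up dropout
#'
#' Event times are exponential with hazard `baseline_hazard *
#' hazard_multipliers[cluster]`, administratively censored at `censor_day`.
#' Follow-up visits are missed with probability
#' `plogis(intercept + cluster[z] + latent_time * (1 - min(T*, censor) /
#' censor))` where `T*` is the latent event time — so subjects heading for
#' an early event are more likely to lose follow-up (informative
#' censoring), on top of the structural loss of visits scheduled after
#' death.
#'
#' @param true_labels Integer vector: per-subject cluster (1..K).
#' @param baseline_hazard Events per day (>= 0).
#' @param hazard_multipliers Positive per-cluster relative hazards.
#' @param censor_day Administrative censoring day (default 60).
#' @param dropout_logit List with `intercept`, `cluster` (length-K
#'   additive terms) and `latent_time` coefficients; `NULL` disables
#'   dropout.
#' @param visit_days Days of the baseline/middle/late visits.
#' @param seed Integer seed.
#' @return Data frame: `subject_id`, `cluster`, `time`, `event`, and
#'   logical `attend_baseline` / `attend_middle` / `attend_late`.
#' @export
simulate_outcomes <- function(true_labels, baseline_hazard,
                              hazard_multipliers, censor_day = 60,
                              dropout_logit = NULL,
                              visit_days = c(1, 5, 9), seed = 1L) {
  if (baseline_hazard < 0) stop_("baseline_hazard must be non-negative")
  if (any(hazard_multipliers <= 0)) stop_("hazard_multipliers must be positive")
  if (censor_day <= 0) stop_("censor_day must be positive")
  n <- length(true_labels)
  K <- max(true_labels)
  if (length(hazard_multipliers) < K)
    stop_("need one hazard multiplier per cluster")
  with_seed_(seed, {
    h <- baseline_hazard * hazard_multipliers[true_labels]
    latent <- ifelse(h > 0, rexp(n, rate = pmax(h, 1e-300)), Inf)
    time <- pmin(latent, censor_day)
    event <- as.integer(latent <= censor_day)
    attend <- matrix(TRUE, n, 3L,
                     dimnames = list(NULL, paste0("attend_", INTERVALS)))
    for (v in 2:3) {
      alive <- latent > visit_days[v]
      miss <- rep(FALSE, n)
      if (!is.null(dropout_logit)) {
        lp <- dropout_logit$intercept +
          dropout_logit$cluster[true_labels] +
          dropout_logit$latent_time * (1 - pmin(latent, censor_day) / censor_day)
        miss <- runif(n) < stats::plogis(lp)
      }
      attend[, v] <- alive & !miss
    }
    data.frame(subject_id = sprintf("subj_%04d", seq_len(n)),
               cluster = as.integer(true_labels),
               time = time, event = event, attend,
               row.names = NULL)
  })
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort. Defaults
#' emulate the structure of a mixed-ICU acute-respiratory-failure cohort:
#' three community types per compartment with graded diversity (the
#' low-diversity type dominated by a pathogen block), three visit
#' intervals (days 1 / 5 / 9 from intubation), roughly 27% 60-day
#' mortality concentrated in the low-diversity cluster (relative hazards
#' 0.6 / 1 / 2.2), within-subject cluster persistence of 0.8 across
#' visits, outcome-informative follow-up dropout, and inflammation
#' biomarkers loading on pathogen-class abundance.
#'
#' @param seed Root seed; all cohort randomness derives from it.
#' @param n_subjects Subjects per compartment (default 100).
#' @param n_taxa Taxa in each table (default 50).
#' @param K_true Number of community types (default 3).
#' @param alpha_matrix K x T Dirichlet parameters; default graded
#'   [separated_alpha_matrix()] with block masses 0.5 / 0.7 / 0.9.
#' @param mixing_weights Baseline cluster probabilities
#'   (default 0.40 / 0.35 / 0.25).
#' @param depth_range Read-depth range (default 2000-10000).
#' @param visit_days Baseline / middle / late sampling days (default
#'   1, 5, 9).
#' @param persistence Probability a subject keeps its cluster at the next
#'   visit (off-cluster moves split evenly; default 0.8).
#' @param compartment_coupling Probability that a compartment's baseline
#'   cluster equals the subject's shared latent cluster rather than an
#'   independent draw (default 0.75) - this is what makes oral and lung
#'   Low-Diversity membership strongly associated, as observed in ICU
#'   cohorts.
#' @param translocation_rate Fraction of oral/lung samples whose
#'   composition is redrawn with boosted gut-origin taxa (expected
#'   gut-origin share ~45%), emulating gut-to-lung translocation
#'   (default 0.05).
#' @param dropout_logit Informative-dropout coefficients (see
#'   [simulate_outcomes()]).
#' @param baseline_hazard Events/day (default 0.0052, ~27% by day 60).
#' @param hazard_multipliers Per-cluster relative hazards.
#' @param censor_day Administrative censoring (default 60).
#' @param biomarker_loadings Named coefficients on pathogen-class CLR
#'   abundance.
#' @param noise_sd Biomarker Gaussian noise SD (default 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 100,
                       n_taxa = 50,
                       K_true = 3,
                       alpha_matrix = NULL,
                       mixing_weights = c(0.40, 0.35, 0.25),
                       depth_range = c(2000, 10000),
                       visit_days = c(1, 5, 9),
                       persistence = 0.8,
                       compartment_coupling = 0.75,
                       translocation_rate = 0.05,
                       dropout_logit = list(intercept = -1.5,
                                            cluster = c(0, 0.3, 0.6),
                                            latent_time = 1),
                       baseline_hazard = 0.0052,
                       hazard_multipliers = c(0.6, 1, 2.2),
                       censor_day = 60,
                       biomarker_loadings = c(sTNFR1 = 2, Ang2 = 1.5,
                                              IL6 = 1, procalcitonin = 1.2),
                       noise_sd = 1) {
  K_true <- assert_count(K_true, "K_true", lower = 1L)
  n_subjects <- assert_count(n_subjects, "n_subjects", lower = 1L)
  n_taxa <- assert_count(n_taxa, "n_taxa", lower = 2L)
  if (is.null(alpha_matrix))
    alpha_matrix <- separated_alpha_matrix(
      K_true, n_taxa, block_mass = seq(0.5, 0.9, length.out = K_true))
  if (nrow(alpha_matrix) != K_true || ncol(alpha_matrix) != n_taxa)
    stop_("alpha_matrix must be K_true x n_taxa")
  if (any(alpha_matrix <= 0)) stop_("all alpha entries must be > 0")
  if (length(mixing_weights) != K_true ||
      abs(sum(mixing_weights) - 1) > 1e-12)
    stop_("mixing_weights must be a length-K_true simplex (sum 1 within 1e-12)")
  if (depth_range[1L] < 1) stop_("depth_range min must be >= 1")
  if (censor_day <= 0) stop_("censor_day must be > 0")
  if (length(visit_days) != 3L || is.unsorted(visit_days))
    stop_("visit_days must be three increasing integers")
  assert_scalar_number(persistence, "persistence", lower = 0, upper = 1)
  assert_scalar_number(compartment_coupling, "compartment_coupling",
                       lower = 0, upper = 1)
  assert_scalar_number(translocation_rate, "translocation_rate",
                       lower = 0, upper = 1)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_taxa = n_taxa, K_true = K_true,
                 alpha_matrix = alpha_matrix,
                 mixing_weights = mixing_weights,
                 depth_range = depth_range, visit_days = visit_days,
                 persistence = persistence,
                 compartment_coupling = compartment_coupling,
                 translocation_rate = translocation_rate,
                 dropout_logit = dropout_logit,
                 baseline_hazard = baseline_hazard,
                 hazard_multipliers = hazard_multipliers,
                 censor_day = censor_day,
                 biomarker_loadings = biomarker_loadings,
                 noise_sd = noise_sd),
            class = "sim_config")
}

# Default taxon annotations for the synthetic taxa: the last component's
# dominant block is the respiratory-pathogen block (aerobes / facultative
# anaerobes), the first component's block is obligate-anaerobe oral
# commensals, and the top decile of taxon indices is marked gut-origin so
# translocation flags are exercisable.
default_annotations <- function(n_taxa, K_true, block_size = 5) {
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  oxy <- rep("variable", n_taxa)
  path <- rep("other", n_taxa)
  origin <- rep("oral", n_taxa)
  low_block <- ((K_true - 1L) * block_size + 1L):(K_true * block_size)
  high_block <- 1:block_size
  oxy[high_block] <- "obligate_anaerobe"
  path[high_block] <- "oral_commensal"
  oxy[low_block] <- rep(c("aerobe", "facultative_anaerobe"),
                        length.out = block_size)
  path[low_block] <- "respiratory_pathogen"
  mid <- setdiff(seq_len(n_taxa), c(high_block, low_block))
  oxy[mid[seq_len(floor(length(mid) / 3))]] <- "facultative_anaerobe"
  gut_taxa <- tail(seq_len(n_taxa), max(1L, round(n_taxa * 0.1)))
  origin[gut_taxa] <- "gut"
  data.frame(taxon_id = taxa, oxygen_class = oxy,
             pathogenicity_class = path, origin_compartment = origin)
}

#' Simulate a full multicompartment cohort
#'
#' Orchestrates the count and outcome generators per compartment: baseline
#' cluster per subject from the mixing weights; cluster transitions across
#' the three visits via the persistence parameter; counts per attended
#' visit from the subject's current cluster; 60-day outcomes driven by the
#' baseline cluster; biomarkers as `loading * pathogen-class CLR abundance
#' + noise` at baseline. All randomness derives from `config$seed` via
#' [split_seed()].
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort`: `tables` (per-compartment
#'   [count_table()] stacking all attended visits), `metadata` (one row
#'   per sample), `annotations`, `outcomes` (per compartment x subject),
#'   `biomarkers` (subjects x markers, baseline), `true_labels` (named
#'   per-sample generating components), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects; K <- config$K_true
  tables <- list(); metadata <- list(); outcomes <- list(); true_labels <- c()
  biomarkers <- NULL
  annotations <- default_annotations(config$n_taxa, K)
  pathogens <- annotations$taxon_id[annotations$pathogenicity_class ==
                                      "respiratory_pathogen"]
  gut_taxa <- annotations$taxon_id[annotations$origin_compartment == "gut"]
  # shared latent cluster: couples baseline membership across compartments
  z_latent <- with_seed_(split_seed(config$seed, 1L, stream = 39L),
    sample.int(K, n, replace = TRUE, prob = config$mixing_weights))
  for (ci in seq_along(COMPARTMENTS)) {
    comp <- COMPARTMENTS[ci]
    seeds <- split_seed(config$seed, 9L, stream = 40L + ci)
    z_base <- with_seed_(seeds[1L], {
      keep_latent <- runif(n) < config$compartment_coupling
      z <- sample.int(K, n, replace = TRUE, prob = config$mixing_weights)
      z[keep_latent] <- z_latent[keep_latent]
      z
    })
    # cluster path across visits: stay with prob `persistence`
    z_visits <- matrix(z_base, n, 3L)
    z_visits[, 2L] <- transition_step(z_base, config$persistence, K, seeds[2L])
    z_visits[, 3L] <- transition_step(z_visits[, 2L], config$persistence, K,
                                      seeds[3L])
    out <- simulate_outcomes(z_base, config$baseline_hazard,
                             config$hazard_multipliers, config$censor_day,
                             config$dropout_logit, config$visit_days,
                             seed = seeds[4L])
    attend <- as.matrix(out[, paste0("attend_", INTERVALS)])
    rows <- which(attend, arr.ind = TRUE)
    rows <- rows[order(rows[, "row"], rows[, "col"]), , drop = FALSE]
    z_sample <- z_visits[rows]
    sim <- simulate_dmm_counts(config$alpha_matrix, config$mixing_weights,
                               n_samples = nrow(rows),
                               depth_range = config$depth_range,
                               seed = seeds[5L], compartment = comp,
                               labels = z_sample)
    ids <- sprintf("%s_%s_%s", comp, out$subject_id[rows[, "row"]],
                   INTERVALS[rows[, "col"]])
    counts <- as_count_matrix(sim$table)
    rownames(counts) <- ids
    if (comp != "gut" && config$translocation_rate > 0) {
      # redraw a small fraction of samples with gut-origin taxa boosted to
      # an expected ~45% share (gut-to-lung/oral translocation events)
      counts <- with_seed_(seeds[9L], {
        trans <- which(runif(nrow(counts)) < config$translocation_rate)
        for (i in trans) {
          a <- config$alpha_matrix[z_sample[i], ]
          gi <- colnames(counts) %in% gut_taxa
          a[gi] <- a[gi] + 0.8 * sum(a) / sum(gi)
          g <- rgamma(length(a), shape = a, rate = 1)
          counts[i, ] <- as.integer(rmultinom(1L, sum(counts[i, ]), g / sum(g)))
        }
        counts
      })
    }
    tab <- count_table(counts, comp)
    tables[[comp]] <- tab
    specimen <- switch(comp, oral = "oral_swab", lung = "ETA",
                       gut = "rectal_swab")
    md <- data.frame(
      sample_id = ids,
      subject_id = out$subject_id[rows[, "row"]],
      compartment = comp,
      interval = INTERVALS[rows[, "col"]],
      day_from_intubation = config$visit_days[rows[, "col"]],
      specimen_type = specimen,
      soiled_flag = TRUE,
      qpcr_copies = with_seed_(seeds[7L],
        round(exp(rnorm(nrow(rows), mean = 10 + 2 * (comp != "lung"), sd = 1)))),
      row.names = NULL)
    metadata[[comp]] <- md
    out$compartment <- comp
    outcomes[[comp]] <- out
    true_labels <- c(true_labels, setNames(z_sample, ids))
    if (comp == "lung") {
      base_rows <- which(rows[, "col"] == 1L)
      clr_path <- clr_class_pathogen(counts[base_rows, , drop = FALSE], pathogens)
      bm <- with_seed_(seeds[8L], {
        sapply(names(config$biomarker_loadings), function(bmk)
          config$biomarker_loadings[[bmk]] * clr_path +
            rnorm(length(clr_path), sd = config$noise_sd))
      })
      rownames(bm) <- out$subject_id[rows[base_rows, "row"]]
      biomarkers <- bm
    }
  }
  structure(list(tables = tables,
                 metadata = do.call(rbind, metadata),
                 annotations = annotations,
                 outcomes = outcomes,
                 biomarkers = biomarkers,
                 true_labels = true_labels,
                 config = config),
            class = "synthetic_cohort")
}

transition_step <- function(z, persistence, K, seed) {
  if (K == 1L) return(z)
  with_seed_(seed, {
    move <- runif(length(z)) > persistence
    z_new <- z
    if (any(move)) {
      z_new[move] <- vapply(z[move], function(zk)
        sample(setdiff(seq_len(K), zk), 1L), integer(1))
    }
    z_new
  })
}

# pathogen-class CLR abundance of each sample (class-summed composition)
clr_class_pathogen <- function(counts, pathogens) {
  path_sum <- rowSums(counts[, colnames(counts) %in% pathogens, drop = FALSE])
  other_sum <- rowSums(counts) - path_sum
  m <- cbind(pathogen = path_sum, other = other_sum)
  clr_transform(m)[, "pathogen"]
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits the standard pipeline input files: per-compartment count tables,
#' one metadata table, the annotation table, per-compartment outcome
#' tables and the baseline biomarker matrix.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (comp in names(cohort$tables)) {
    p <- file.path(dir, sprintf("counts_%s.tsv", comp))
    write_count_table(cohort$tables[[comp]], p)
    paths <- c(paths, p)
    po <- file.path(dir, sprintf("outcomes_%s.tsv", comp))
    con <- file(po, "w", encoding = "UTF-8")
    writeLines(format_header("outcomes"), con)
    write.table(cohort$outcomes[[comp]], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    paths <- c(paths, po)
  }
  pm <- file.path(dir, "metadata.tsv")
  write_metadata(cohort$metadata, pm)
  pa <- file.path(dir, "annotations.tsv")
  write_annotations(cohort$annotations, pa)
  pb <- file.path(dir, "biomarkers.tsv")
  con <- file(pb, "w", encoding = "UTF-8")
  writeLines(format_header("biomarkers"), con)
  write.table(data.frame(subject_id = rownames(cohort$biomarkers),
                         cohort$biomarkers, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(paths, pm, pa, pb))
}
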