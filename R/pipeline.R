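# pipeline: simulate/ingest -> QC -> diversity -> DMM -> dysbiosis index ->
# composition -> differential abundance -> survival, with all stage outputs
# written to disk and a machine-readable report.

#' Run the full multicompartment analysis pipeline
#'
#' Executes every stage on a synthetic cohort (or pre-written cohort
#' directory): per compartment, QC filtering (read-count and unsoiled-swab
#' rules), rarefied Shannon diversity, low-abundance taxon filtering, DMM
#' fitting with Laplace K selection, diversity labeling, Dysbiosis Index
#' derivation with held-out accuracy, class-abundance summaries by
#' interval, Low-vs-High differential abundance, Kaplan-Meier / adjusted
#' Cox / persister survival analyses, a joint model for the longitudinal
#' Shannon index, and the oral-lung Low-cluster co-membership odds ratio.
#' Identical config and seed give identical reports.
#'
#' @param config A [sim_config()] (its `seed` drives everything), or a
#'   path to a JSON file of `sim_config()` arguments.
#' @param output_dir Directory for stage outputs and `report.json`.
#' @param min_reads QC threshold (default 1000).
#' @param rarefy_depth,rarefy_reps Rarefaction depth / repetitions
#'   (defaults 1000 / 100).
#' @param k_max,prevalence_min DMM selection controls (defaults 5 / 0.10).
#' @param n_init EM restarts per K (default 3 at pipeline scale).
#' @param n_boot Joint-model bootstrap resamples (default 100).
#' @param compartments Compartments to analyse (default all three).
#' @return The report list (invisibly written as `report.json`).
#' @export
run_pipeline <- function(config = sim_config(), output_dir = tempfile("pipeline"),
                         min_reads = 1000, rarefy_depth = 1000,
                         rarefy_reps = 100, k_max = 5, prevalence_min = 0.10,
                         n_init = 3, n_boot = 100,
                         compartments = COMPARTMENTS) {
  if (is.character(config)) {
    args <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(seed = seed, config = config[setdiff(names(config),
                                                      "alpha_matrix")],
                 compartments = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(output_dir, "FAILED"))
      stop_("pipeline failed at stage '", name, "': ", conditionMessage(e))
    })
  }

  cohort <- stage("simulate", simulate_cohort(config))
  write_cohort(cohort, file.path(output_dir, "cohort"))

  labels_by_comp <- list()
  fitted_labels <- list()
  for (comp in compartments) {
    message("== compartment: ", comp)
    tab <- cohort$tables[[comp]]
    qc <- stage("qc", qc_filter(tab, cohort$metadata, min_reads))
    tab_qc <- qc$table
    shannon <- stage("diversity", {
      s <- shannon_table(tab_qc, depth = rarefy_depth, reps = rarefy_reps,
                         seed = split_seed(seed, 1L, stream = 51L))
      setNames(s$mean_shannon, s$sample_id)
    })
    tab_f <- stage("filter", filter_low_abundance(tab_qc))
    model <- stage("dmm", select_k(tab_f, K_max = k_max,
                                   prevalence_min = prevalence_min,
                                   seed = split_seed(seed, 1L, stream = 52L),
                                   n_init = n_init))
    # the Dysbiosis Index is a three-class (High/Intermediate/Low) model;
    # when evidence selects another K, keep it in the report but label and
    # classify with a K = 3 fit
    model3 <- if (model$K == 3L) model else
      stage("dmm3", fit_dmm(tab_f, 3L, n_init = n_init,
                            seed = split_seed(seed, 1L, stream = 56L)))
    labeling <- stage("labels", label_clusters(model3, shannon))
    write_dmm_assignments(model3,
                          file.path(output_dir, paste0("dmm_", comp, ".tsv")),
                          labeling)
    di <- stage("dysbiosis_index", derive_dysbiosis_index(
      tab_f, labeling$sample_labels, shannon,
      seed = split_seed(seed, 1L, stream = 53L)))
    write_dysbiosis_model(di$model,
                          file.path(output_dir, paste0("index_", comp, ".json")))
    comp_rel <- relative_abundance(tab_f)
    agg_oxy <- stage("composition",
                     aggregate_class_abundance(tab_f, cohort$annotations, "oxygen"))
    agg_path <- aggregate_class_abundance(tab_f, cohort$annotations,
                                          "pathogenicity")
    gut_flags <- gut_origin_enrichment(comp_rel, cohort$annotations)
    lab <- labeling$sample_labels[rownames(tab_f)]
    da <- stage("diffab", {
      keep <- lab %in% c("High", "Low")
      moderated_t_test(clr_transform(tab_f)[keep, , drop = FALSE], lab[keep])
    })
    utils::write.table(da, file.path(output_dir, paste0("diffab_", comp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    md <- cohort$metadata[match(rownames(tab_f), cohort$metadata$sample_id), ]
    baseline_label <- lab[md$interval == "baseline"]
    names(baseline_label) <- md$subject_id[md$interval == "baseline"]
    labels_by_comp[[comp]] <- baseline_label
    fitted_labels[[comp]] <- labeling$sample_labels
    outc <- cohort$outcomes[[comp]]
    surv <- stage("survival", {
      idx <- match(outc$subject_id, names(baseline_label))
      grp <- unname(baseline_label[idx])
      keep <- !is.na(grp)
      rec <- data.frame(time = outc$time[keep], event = outc$event[keep],
                        low = as.integer(grp[keep] == "Low"))
      km <- kaplan_meier(rec, grp[keep])
      cx <- if (sum(rec$event) > 0 && sd(rec$low) > 0)
        fit_cox(rec, "low") else NULL
      list(logrank_p = km$logrank_p,
           low_hr = if (!is.null(cx)) cx$coefficients$HR[1L] else NA_real_)
    })
    report$compartments[[comp]] <- list(
      n_samples = nrow(tab),
      n_qc_removed = nrow(qc$report),
      selected_K = model$K,
      log_evidence = model$laplace_log_evidence,
      cluster_sizes = as.list(table(labeling$sample_labels)),
      index_accuracy = di$evaluation$accuracy,
      index_accuracy_ci = di$evaluation$ci,
      selected_features = di$selected_features,
      mean_shannon_by_label = lapply(split(shannon, labeling$sample_labels), mean),
      anaerobe_share_by_interval =
        lapply(split(agg_oxy$relative[, "obligate_anaerobe"], md$interval), mean),
      pathogen_share_by_interval =
        lapply(split(agg_path$relative[, "respiratory_pathogen"], md$interval), mean),
      gut_origin_rate = mean(gut_flags),
      n_diffab_significant = sum(da$significant, na.rm = TRUE),
      survival = surv)
  }

  if (all(c("oral", "lung") %in% names(labels_by_comp))) {
    report$oral_lung_low_comembership <- stage("comembership", {
      common <- intersect(names(labels_by_comp$oral), names(labels_by_comp$lung))
      tab2 <- table(oral_low = labels_by_comp$oral[common] == "Low",
                    lung_low = labels_by_comp$lung[common] == "Low")
      if (all(dim(tab2) == c(2L, 2L))) fisher_association(tab2[2:1, 2:1])
      else list(odds_ratio = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_)
    })
  }
  if ("lung" %in% names(labels_by_comp)) {
    report$lung_persister <- stage("persister", {
      outc <- cohort$outcomes$lung
      get_lab <- function(interval) {
        ids <- sprintf("lung_%s_%s", outc$subject_id, interval)
        unname(fitted_labels$lung[ids])
      }
      rec <- data.frame(subject_id = outc$subject_id, time = outc$time,
                        event = outc$event,
                        label_baseline = get_lab("baseline"),
                        label_middle = get_lab("middle"))
      keep <- !is.na(rec$label_middle) & !is.na(rec$label_baseline)
      df <- rec[keep, , drop = FALSE]
      df$persister <- as.integer(df$label_baseline == "Low" &
                                   df$label_middle == "Low")
      if (sum(df$event) > 0 && sd(df$persister) > 0) {
        cx <- fit_cox(df, "persister")
        list(hr = cx$coefficients$HR[1L], p = cx$coefficients$p[1L])
      } else list(hr = NA_real_, p = NA_real_)
    })
  }
  if ("lung" %in% compartments) {
    report$lung_joint_shannon <- stage("joint", {
      md <- cohort$metadata[cohort$metadata$compartment == "lung", ]
      tab <- cohort$tables$lung
      keep_ids <- md$sample_id[rowSums(tab)[md$sample_id] >= rarefy_depth]
      sh <- shannon_table(subset_samples(tab, rownames(tab) %in% keep_ids),
                          depth = rarefy_depth, reps = 25,
                          seed = split_seed(seed, 1L, stream = 54L))
      long <- data.frame(subject_id = md$subject_id[match(sh$sample_id, md$sample_id)],
                         day = md$day_from_intubation[match(sh$sample_id, md$sample_id)],
                         shannon = sh$mean_shannon)
      outc <- cohort$outcomes$lung
      jf <- fit_joint(long, outc, response = "shannon", fixed = "day",
                      subject = "subject_id", n_boot = n_boot,
                      seed = split_seed(seed, 1L, stream = 55L))
      list(slope_day = unname(jf$beta[["day"]]), nu = jf$nu,
           nu_ci = jf$nu_ci, n_boot_failed = jf$n_boot_failed)
    })
  }

  report$provenance <- list(package_version = as.character(
    utils::packageVersion("icudysbiosis")), seed = seed)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
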