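#' One-command discovery analysis
#'
#' Runs the discovery workflow in fixed order on a cohort: QC (conversion
#' efficiency, detection filtering, replicate-outlier removal, probe
#' exclusions, SVD confounder scan, replicate averaging), moderated-t MVP
#' calling on CpH probes, group delta with permutation and Monte Carlo CpG
#' nulls, panel selection and CI-midpoint threshold derivation, hierarchical
#' clustering, donor epigenetic-memory deltas, and (when a corridor table is
#' supplied) the Reference-Corridor comparison. Each stochastic stage draws
#' from its own seed substream, so toggling stages does not shift other
#' stages' results.
#'
#' @param cohort A `cph_cohort` or equivalent list (beta, detp, annotation,
#'   sheet, controls).
#' @param variants Optional variant tibble for probe exclusion.
#' @param corridor Optional corridor tibble.
#' @param fdr FDR level for MVP calling.
#' @param permutation_B,mc_B Resampling draw counts.
#' @param mc_beta_min Pool restriction for the methylated-CpG Monte Carlo
#'   variant (default 0.80).
#' @param panel_k,panel_top Panel size and candidate-pool size.
#' @param k_clusters Clusters for the dendrogram cut.
#' @param stages Character vector of stages to run; `qc` and `mvp` are
#'   prerequisites of the later stages.
#' @param seed Master seed for the run.
#' @return List of class `discovery_report`.
#' @export
run_discovery <- function(cohort, variants = NULL, corridor = NULL,
                          fdr = 0.05, permutation_B = 20000, mc_B = 10000,
                          mc_beta_min = 0.80, panel_k = 9, panel_top = 200,
                          k_clusters = 3,
                          stages = c("qc", "mvp", "resampling", "classifier",
                                     "clustering", "memory", "corridor"),
                          seed = 1L) {
  report <- list(seed = seed,
                 parameters = list(fdr = fdr, permutation_B = permutation_B,
                                   mc_B = mc_B, mc_beta_min = mc_beta_min,
                                   panel_k = panel_k, panel_top = panel_top,
                                   k_clusters = k_clusters),
                 version = as.character(utils::packageVersion("cphcap")))
  if (!"qc" %in% stages)
    abort("the qc stage is required", class = "cphcap_config_error")

  qc <- run_qc(cohort, variants = variants)
  report$qc <- qc$report

  ann <- cohort$annotation
  cph_ids <- ann$probe_id[ann$context == "CpH"]
  cpg_ids <- ann$probe_id[ann$context == "CpG"]
  line_beta <- qc$line_beta
  groups <- line_groups(cohort$sheet, beta_sample_ids(line_beta))
  hipsc <- names(groups)[groups %in% c("HDC", "LDC")]
  donors <- names(groups)[groups == "donor"]
  cph_line <- line_beta %>% filter(.data$probe_id %in% cph_ids)
  cph_hipsc <- cph_line[, c("probe_id", hipsc)]
  report$line_beta <- line_beta
  report$groups <- groups

  if (!"mvp" %in% stages) {
    class(report) <- "discovery_report"
    return(report)
  }

  fit <- fit_moderated_t(cph_hipsc, groups) %>% call_mvps(fdr = fdr)
  delta <- group_delta(cph_hipsc, groups)
  report$fit <- fit
  report$delta <- delta
  if (length(donors) > 0) {
    dmeans <- colMeans(beta_as_matrix(cph_line[, c("probe_id", donors)]),
                       na.rm = TRUE)
    n <- length(dmeans)
    half <- if (n >= 2) qt(0.975, n - 1) * sd(dmeans) / sqrt(n) else NA_real_
    report$donor_summary <- tibble(n = n, mean = mean(dmeans),
                                   ci_lower = mean(dmeans) - half,
                                   ci_upper = mean(dmeans) + half)
  }
  report$motifs <- motif_effect_summary(fit, ann)

  if ("resampling" %in% stages) {
    report$permutation <- permutation_test_delta(
      cph_hipsc, groups, B = permutation_B, seed = derive_seed(seed, 1L))
    cpg_hipsc <- line_beta %>% filter(.data$probe_id %in% cpg_ids)
    cpg_hipsc <- cpg_hipsc[, c("probe_id", hipsc)]
    n_draw <- min(nrow(cph_hipsc), nrow(cpg_hipsc))
    report$montecarlo <- montecarlo_cpg_null(
      cpg_hipsc, groups, n_probes = n_draw, B = mc_B,
      seed = derive_seed(seed, 2L), observed = delta$delta)
    pool_meth <- sum(rowMeans(beta_as_matrix(cpg_hipsc), na.rm = TRUE) > mc_beta_min)
    report$montecarlo_methylated <- montecarlo_cpg_null(
      cpg_hipsc, groups, n_probes = min(n_draw, pool_meth), B = mc_B,
      seed = derive_seed(seed, 3L), beta_min = mc_beta_min,
      observed = delta$delta)
  }

  if ("classifier" %in% stages) {
    panel <- select_panel(fit, k = panel_k, top = panel_top,
                          seed = derive_seed(seed, 4L))
    model <- derive_threshold(cph_hipsc, panel, groups,
                              provenance = list(cohort = "discovery",
                                                fdr = fdr, rule = "top_p"))
    preds <- predict_capacity(cph_hipsc, model, truth = groups[hipsc])
    report$model <- model
    report$discovery_predictions <- preds
    report$discovery_evaluation <- evaluate_predictions(preds)
  }

  if ("clustering" %in% stages) {
    sig <- fit$table$probe_id[fit$table$significant]
    if (length(sig) >= 2) {
      cl <- cluster_lines(cph_line, probe_subset = sig)
      report$clustering <- cl
      report$purity <- clade_purity(cl, groups, k = k_clusters)
    }
  }

  if ("memory" %in% stages && length(donors) > 0) {
    donor_map <- cohort$sheet %>%
      distinct(.data$line_id, .data$group, donor_line_id = .data$donor_line_id)
    report$memory <- memory_delta(cph_line, donor_map)
  }

  if ("corridor" %in% stages && !is.null(corridor)) {
    pmap <- map_promoters(ann, corridor)
    if (nrow(pmap) > 0) {
      med <- promoter_medians(line_beta[, c("probe_id", hipsc)], pmap)
      report$corridor <- corridor_capture(med, corridor)
      report$corridor_cv <- promoter_cv(med)
    } else inform("corridor supplied but no probe overlaps a promoter; stage skipped")
  }

  structure(report, class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("<discovery_report>\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$delta)) print(x$delta)
  if (!is.null(x$permutation)) print(x$permutation)
  if (!is.null(x$montecarlo)) print(x$montecarlo)
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$discovery_evaluation))
    cat(sprintf("  discovery threshold accuracy: %d/%d = %.2f\n",
                sum(x$discovery_evaluation$per_line$correct),
                x$discovery_evaluation$n, x$discovery_evaluation$accuracy))
  if (!is.null(x$purity))
    cat(sprintf("  clustering agreement at k = %d: %.2f (ARI %.2f)\n",
                x$purity$k, x$purity$agreement, x$purity$ari))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.discovery_report <- function(x, ...) {
  tibble(
    delta_beta_mean = if (!is.null(x$delta)) x$delta$delta else NA_real_,
    delta_p = if (!is.null(x$delta)) x$delta$p else NA_real_,
    permutation_p = if (!is.null(x$permutation)) x$permutation$p else NA_real_,
    mc_max_abs_delta = if (!is.null(x$montecarlo)) x$montecarlo$max_abs_null else NA_real_,
    n_significant = if (!is.null(x$fit)) sum(x$fit$table$significant) else NA_integer_,
    threshold = if (!is.null(x$model)) x$model$threshold else NA_real_,
    discovery_accuracy = if (!is.null(x$discovery_evaluation))
      x$discovery_evaluation$accuracy else NA_real_,
    cluster_agreement = if (!is.null(x$purity)) x$purity$agreement else NA_real_,
    seed = x$seed)
}

#' Predict a replication cohort with a frozen model
#'
#' Applies a discovery-derived `capacity_model` to an independent cohort
#' without any retraining: detection filtering and replicate averaging only,
#' then panel-mean prediction and (when labels are available) evaluation.
#'
#' @param model A `capacity_model` (or path to its JSON serialisation).
#' @param cohort A `cph_cohort`, or a list with `beta`, `detp`, `sheet` (and
#'   optionally `annotation`, `controls`).
#' @param alpha Detection threshold.
#' @return List of class `replication_report`: `predictions`, `evaluation`.
#' @export
run_replication <- function(model, cohort, alpha = 0.01) {
  if (is.character(model)) model <- read_capacity_model(model)
  stopifnot(inherits(model, "capacity_model"))
  beta <- cohort$beta
  if (!is.null(cohort$detp)) {
    det <- filter_detection(beta, cohort$detp, alpha = alpha)
    # never drop a panel probe for detection in a replication run: a missing
    # probe aborts prediction, so report it instead
    lost <- intersect(det$excluded$probe_id, model$panel)
    beta <- det$beta
    if (length(lost)) {
      warn(sprintf("panel probe(s) failed detection in replication: %s",
                   paste(lost, collapse = ", ")))
      beta <- cohort$beta %>%
        filter(.data$probe_id %in% c(det$beta$probe_id, lost))
    }
  }
  line_beta <- average_replicates(beta, cohort$sheet)
  groups <- line_groups(cohort$sheet, beta_sample_ids(line_beta))
  known <- groups[groups %in% c("HDC", "LDC")]
  preds <- predict_capacity(line_beta, model,
                            truth = if (length(known)) groups else NULL)
  structure(list(predictions = preds,
                 evaluation = if (length(known)) evaluate_predictions(preds),
                 model = model),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> %d lines predicted\n", nrow(x$predictions)))
  if (!is.null(x$evaluation))
    cat(sprintf("  accuracy %d/%d = %.2f\n",
                sum(x$evaluation$per_line$correct), x$evaluation$n,
                x$evaluation$accuracy))
  invisible(x)
}

#' Write a report bundle as JSON
#'
#' Serialises the scalar summaries of a discovery report (and optionally a
#' replication report) into a JSON bundle following the schema shipped at
#' `inst/schema/report.schema.json`.
#'
#' @param report A `discovery_report`.
#' @param path Output JSON path.
#' @param replication Optional `replication_report`.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, replication = NULL) {
  stopifnot(inherits(report, "discovery_report"))
  g <- glance(report)
  x <- list(
    version = report$version, seed = report$seed,
    parameters = report$parameters,
    qc = list(n_excluded_probes = nrow(report$qc$excluded_probes),
              n_flagged_extracts = nrow(report$qc$flagged_extracts),
              mean_efficiency = mean(report$qc$efficiency$efficiency, na.rm = TRUE)),
    mvp = if (!is.null(report$fit)) as.list(glance(report$fit)),
    delta = if (!is.null(report$delta)) as.list(glance(report$delta)),
    resampling = list(
      permutation = if (!is.null(report$permutation)) as.list(glance(report$permutation)),
      montecarlo = if (!is.null(report$montecarlo)) as.list(glance(report$montecarlo))),
    classifier = if (!is.null(report$model)) as.list(glance(report$model)),
    clustering = if (!is.null(report$purity)) as.list(glance(report$purity)),
    corridor = if (!is.null(report$corridor)) as.list(glance(report$corridor)),
    replication = if (!is.null(replication))
      list(n = nrow(replication$predictions),
           accuracy = if (!is.null(replication$evaluation))
             replication$evaluation$accuracy))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
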