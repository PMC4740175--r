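#' Select a probe panel from the top MVPs
#'
#' Ranks significant MVPs by p-value, takes the top-`top` pool and selects
#' `k` probes. The default rule takes the `k` smallest p-values; the
#' `"spread"` rule greedily picks probes maximising the minimum pairwise
#' distance in `delta_beta` (deterministic given `seed`, which only breaks
#' ties in the greedy start).
#'
#' @param fit A `moderated_fit` after [call_mvps()], or its `tidy()` table
#'   with `p`, `significant`, `delta_beta` columns.
#' @param k Panel size (default 9).
#' @param top Size of the candidate pool (default 200; reduced with a notice
#'   when fewer MVPs are significant).
#' @param rule "top_p" or "spread".
#' @param seed Seed for the spread rule.
#' @return Character vector of `k` probe ids.
#' @export
select_panel <- function(fit, k = 9, top = 200, rule = c("top_p", "spread"),
                         seed = 1L) {
  rule <- match.arg(rule)
  tab <- if (inherits(fit, "moderated_fit")) tidy(fit) else fit
  if (!"significant" %in% names(tab))
    abort("call_mvps() must be applied before panel selection",
          class = "cphcap_config_error")
  sig <- tab %>% filter(.data$significant) %>% arrange(.data$p, .data$probe_id)
  if (nrow(sig) < top) {
    inform(sprintf("only %d significant MVPs; reducing pool from %d", nrow(sig), top))
    top <- nrow(sig)
  }
  if (k > top)
    abort(sprintf("panel size k = %d exceeds candidate pool of %d", k, top),
          class = "cphcap_selection_error")
  pool <- head(sig, top)
  if (rule == "top_p") return(pool$probe_id[seq_len(k)])
  with_seed(seed, {
    chosen <- sample(which(pool$delta_beta == max(pool$delta_beta)), 1)
    while (length(chosen) < k) {
      cand <- setdiff(seq_len(nrow(pool)), chosen)
      score <- vapply(cand, function(i)
        min(abs(pool$delta_beta[i] - pool$delta_beta[chosen])), numeric(1))
      chosen <- c(chosen, cand[which.max(score)])
    }
    pool$probe_id[sort(chosen)]
  })
}

#' Derive the CI-midpoint capacity threshold
#'
#' Computes each line's mean beta over the panel probes, each group's mean
#' and t-based confidence interval over its lines, and sets the decision
#' threshold at the midpoint between the LDC upper and HDC lower CI bounds.
#' Overlapping CIs are flagged prominently but still yield a model.
#'
#' @param line_beta Line-level beta tibble (discovery cohort).
#' @param panel Character vector of panel probe ids.
#' @param groups Group labels (named by line id or aligned with columns).
#' @param conf Confidence level for the group CIs (default 0.95).
#' @param provenance Optional named list recorded in the model (cohort id,
#'   fdr, selection rule).
#' @return Object of class `capacity_model` with fields `panel`, `hdc_ci`,
#'   `ldc_ci`, `threshold`, `ci_overlap`, `line_means`.
#' @export
derive_threshold <- function(line_beta, panel, groups, conf = 0.95,
                             provenance = list()) {
  missing <- setdiff(panel, line_beta$probe_id)
  if (length(missing))
    abort(sprintf("panel probe(s) missing from matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "cphcap_validation_error")
  b <- beta_as_matrix(line_beta %>% filter(.data$probe_id %in% panel))
  if (!is.null(names(groups))) groups <- groups[colnames(b)]
  pm <- colMeans(b, na.rm = TRUE)
  ci_of <- function(v) {
    n <- length(v)
    if (n < 2) abort("both groups need >= 2 lines for the threshold CI",
                     class = "cphcap_config_error")
    half <- qt(1 - (1 - conf) / 2, n - 1) * sd(v) / sqrt(n)
    c(mean = mean(v), lower = mean(v) - half, upper = mean(v) + half)
  }
  hdc <- ci_of(pm[groups == "HDC"])
  ldc <- ci_of(pm[groups == "LDC"])
  threshold <- unname((ldc["upper"] + hdc["lower"]) / 2)
  overlap <- ldc["upper"] > hdc["lower"]
  if (overlap)
    warn(sprintf("group CIs overlap (LDC upper %.3f > HDC lower %.3f): threshold unreliable",
                 ldc["upper"], hdc["lower"]))
  structure(list(panel = panel, hdc_ci = hdc, ldc_ci = ldc,
                 threshold = threshold, ci_overlap = unname(overlap),
                 conf = conf,
                 line_means = tibble(line_id = names(pm), group = unname(groups),
                                     panel_mean = unname(pm)),
                 provenance = provenance),
            class = "capacity_model")
}

#' @export
print.capacity_model <- function(x, ...) {
  cat(sprintf("<capacity_model> %d-probe panel; threshold beta_mean = %.1f%%\n",
              length(x$panel), 100 * x$threshold))
  cat(sprintf("  LDC mean %.1f%% (CI %.1f-%.1f%%), HDC mean %.1f%% (CI %.1f-%.1f%%)%s\n",
              100 * x$ldc_ci["mean"], 100 * x$ldc_ci["lower"], 100 * x$ldc_ci["upper"],
              100 * x$hdc_ci["mean"], 100 * x$hdc_ci["lower"], 100 * x$hdc_ci["upper"],
              if (x$ci_overlap) "  [CI OVERLAP]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.capacity_model <- function(x, ...) x$line_means

#' @exportS3Method generics::glance
glance.capacity_model <- function(x, ...) {
  tibble(threshold = x$threshold, ldc_upper = unname(x$ldc_ci["upper"]),
         hdc_lower = unname(x$hdc_ci["lower"]), ci_overlap = x$ci_overlap,
         panel_size = length(x$panel), conf = x$conf)
}

#' Serialise / restore a capacity model
#'
#' @param model A `capacity_model`.
#' @param path JSON file path.
#' @return `write_capacity_model` returns `path` invisibly;
#'   `read_capacity_model` returns the model.
#' @export
write_capacity_model <- function(model, path) {
  stopifnot(inherits(model, "capacity_model"))
  x <- list(panel = model$panel,
            hdc_ci = as.list(model$hdc_ci), ldc_ci = as.list(model$ldc_ci),
            threshold = model$threshold, ci_overlap = model$ci_overlap,
            conf = model$conf, provenance = model$provenance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_capacity_model
#' @export
read_capacity_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(panel = x$panel,
                 hdc_ci = unlist(x$hdc_ci), ldc_ci = unlist(x$ldc_ci),
                 threshold = x$threshold, ci_overlap = x$ci_overlap,
                 conf = x$conf, line_means = NULL,
                 provenance = as.list(x$provenance)),
            class = "capacity_model")
}

#' Predict differentiation capacity for new lines
#'
#' Computes each line's mean beta over the model's panel probes
#' (pairwise-complete) and predicts HDC when the mean is at or above the
#' threshold (ties go to HDC), LDC otherwise. A line missing more than a
#' third of the panel probes is marked unpredictable.
#'
#' @param line_beta Line-level beta tibble containing the panel probes (an
#'   error lists any that are absent).
#' @param model A `capacity_model`.
#' @param truth Optional named vector or tibble (`line_id`, `group`) of true
#'   labels to carry into the table.
#' @return Tibble: `line_id`, `panel_mean`, `deviation`, `predicted`, `true`.
#' @export
predict_capacity <- function(line_beta, model, truth = NULL) {
  stopifnot(inherits(model, "capacity_model"))
  missing <- setdiff(model$panel, line_beta$probe_id)
  if (length(missing))
    abort(sprintf("panel probe(s) missing from matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "cphcap_validation_error")
  b <- beta_as_matrix(line_beta %>% filter(.data$probe_id %in% model$panel))
  n_missing <- colSums(is.na(b))
  unpredictable <- n_missing > length(model$panel) / 3
  pm <- colMeans(b, na.rm = TRUE)
  pred <- tibble(line_id = colnames(b),
                 panel_mean = unname(pm),
                 deviation = unname(pm) - model$threshold,
                 predicted = unname(ifelse(unpredictable, NA_character_,
                                    ifelse(pm >= model$threshold, "HDC", "LDC"))))
  if (!is.null(truth)) {
    if (is.data.frame(truth)) {
      truth_v <- setNames(truth$group, truth$line_id)
    } else truth_v <- truth
    pred$true <- unname(truth_v[pred$line_id])
  }
  pred
}

#' Evaluate capacity predictions against known labels
#'
#' @param predictions Output of [predict_capacity()] with a `true` column.
#' @return List: `confusion` (2x2 tibble), `accuracy`, `n`, `per_line`.
#' @export
evaluate_predictions <- function(predictions) {
  labelled <- predictions %>%
    filter(!is.na(.data$true), !is.na(.data$predicted),
           .data$true %in% c("HDC", "LDC"))
  if (nrow(labelled) == 0) {
    inform("no labelled lines: evaluation skipped")
    return(NULL)
  }
  per_line <- labelled %>% mutate(correct = .data$predicted == .data$true)
  confusion <- labelled %>%
    count(true = factor(.data$true, c("HDC", "LDC")),
          predicted = factor(.data$predicted, c("HDC", "LDC")),
          .drop = FALSE)
  list(confusion = confusion,
       accuracy = mean(per_line$correct),
       n = nrow(labelled),
       per_line = per_line %>% select("line_id", "true", "predicted", "correct"))
}
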