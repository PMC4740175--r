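#' Convert beta fractions to M-values
#'
#' `M = log2(beta / (1 - beta))` after clamping beta to
#' `[epsilon, 1 - epsilon]`; the logit scale reduces the heteroscedasticity
#' of beta values near 0 and 1 before linear-model testing.
#'
#' @param beta Beta tibble.
#' @param epsilon Clamp bound keeping M finite (default 1e-6).
#' @return An M-value tibble with the same shape.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  m <- beta_as_matrix(beta)
  m <- pmin(pmax(m, epsilon), 1 - epsilon)
  matrix_as_beta(log2(m / (1 - m)))
}

#' Convert M-values back to beta fractions
#' @param m M-value tibble.
#' @return Beta tibble.
#' @export
m_to_beta <- function(m) {
  x <- beta_as_matrix(m)
  matrix_as_beta(2^x / (1 + 2^x))
}

# Newton solve of trigamma(x) = y, vectorised; used by the empirical-Bayes
# prior estimation. Monotone decreasing trigamma => unique root for y > 0.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6; out[lo] <- 1 / sqrt(y[lo])
  hi <- y > 1e7; out[hi] <- 1 / y[hi]
  mid <- !(lo | hi)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-12) break
    }
    out[mid] <- x
  }
  out
}

# Moment-matching of a scaled-F marginal for per-probe sample variances s2
# with df degrees of freedom: on log s2 the model gives
# E[e] = log s0^2 and Var[e] = trigamma(df/2) + trigamma(d0/2),
# where e = log s2 - digamma(df/2) + log(df/2). Solving the second equation
# with the trigamma inverse yields the prior df d0; the first yields s0^2.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok))
    abort("cannot estimate the variance prior: no probe has positive residual variance",
          class = "cphcap_estimation_error")
  z <- log(s2[ok]); d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d / 2))
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0_sq = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderated t-test for differential methylation
#'
#' Two-group comparison on M-values at the cell-line level. Per probe, the
#' pooled residual variance `s2` with `df = n1 + n2 - 2` is shrunk towards a
#' prior `(d0, s0^2)` estimated by moment matching the scaled-F marginal of
#' the variances (digamma/trigamma method on log variances); the posterior
#' variance `(d0*s0^2 + df*s2) / (d0 + df)` replaces `s2` in the t statistic,
#' which gains `d0` degrees of freedom. Group beta means and their
#' difference (`delta_beta = mean(HDC) - mean(LDC)`) are reported on the
#' original beta scale.
#'
#' @param line_beta Line-level beta tibble (replicates already averaged).
#' @param groups Character vector of group labels, either named by line id or
#'   aligned with the matrix columns; only the two `levels` enter the test.
#' @param levels The two group labels compared, difference = first - second.
#' @param epsilon Clamp for the M-value transform.
#' @param prior Optional list(d0, s0_sq) forcing the prior instead of
#'   estimating it (d0 = 0 reduces to the ordinary t-test; d0 = Inf tests
#'   against the common prior variance).
#' @return An object of class `moderated_fit`; `tidy()` returns the
#'   per-probe table, `glance()` the prior and fit summary.
#' @export
fit_moderated_t <- function(line_beta, groups, levels = c("HDC", "LDC"),
                            epsilon = 1e-6, prior = NULL) {
  b <- beta_as_matrix(line_beta)
  if (!is.null(names(groups))) groups <- groups[colnames(b)]
  if (length(groups) != ncol(b))
    abort("groups must align with the matrix columns", class = "cphcap_config_error")
  i1 <- which(groups == levels[1]); i2 <- which(groups == levels[2])
  if (length(i1) < 2 || length(i2) < 2)
    abort(sprintf("need >= 2 lines per group (got %d '%s', %d '%s')",
                  length(i1), levels[1], length(i2), levels[2]),
          class = "cphcap_config_error")

  mm <- beta_as_matrix(beta_to_m(line_beta, epsilon))
  x1 <- mm[, i1, drop = FALSE]; x2 <- mm[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1, var, na.rm = TRUE); v2 <- apply(x2, 1, var, na.rm = TRUE)
  v1[n1 < 2] <- 0; v2[n2 < 2] <- 0
  df <- pmax(n1 + n2 - 2, 0)
  s2 <- ifelse(df > 0, ((n1 - 1) * v1 + (n2 - 1) * v2) / df, NA_real_)

  pr <- prior %||% estimate_variance_prior(s2, df)
  d0 <- pr$d0; s0_sq <- pr$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df_total <- pmin(d0 + df, sum(df, na.rm = TRUE))
  p <- 2 * pt(-abs(tstat), df_total)

  bm1 <- rowMeans(b[, i1, drop = FALSE], na.rm = TRUE)
  bm2 <- rowMeans(b[, i2, drop = FALSE], na.rm = TRUE)
  table <- tibble(probe_id = rownames(b),
                  mean_hdc = unname(bm1), mean_ldc = unname(bm2),
                  delta_beta = unname(bm1 - bm2), delta_m = unname(m1 - m2),
                  s2 = unname(s2), df = unname(df),
                  s2_post = unname(s2_post), t = unname(tstat),
                  df_total = unname(df_total), p = unname(p))
  structure(list(table = table, d0 = d0, s0_sq = s0_sq,
                 n1 = length(i1), n2 = length(i2), levels = levels,
                 fdr = NA_real_),
            class = "moderated_fit")
}

#' Call methylation variable positions at a given FDR
#'
#' Adds Benjamini-Hochberg q-values to a moderated fit and marks probes with
#' `q <= fdr` as significant MVPs; `direction` is hyper when
#' `delta_beta > 0` (higher methylation in the first group) and hypo
#' otherwise.
#'
#' @param fit A `moderated_fit`.
#' @param fdr False discovery rate (default 0.05).
#' @return The fit with `q`, `significant`, `direction` columns added.
#' @export
call_mvps <- function(fit, fdr = 0.05) {
  stopifnot(inherits(fit, "moderated_fit"))
  fit$table <- fit$table %>%
    mutate(q = p.adjust(.data$p, method = "BH"),
           significant = .data$q <= fdr,
           direction = ifelse(.data$delta_beta > 0, "hyper", "hypo"))
  fit$fdr <- fdr
  fit
}

#' @exportS3Method generics::tidy
tidy.moderated_fit <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.moderated_fit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, n_probes = nrow(x$table),
         n_hdc = x$n1, n_ldc = x$n2, fdr = x$fdr,
         n_significant = if ("significant" %in% names(x$table))
           sum(x$table$significant, na.rm = TRUE) else NA_integer_,
         n_hyper = if ("direction" %in% names(x$table))
           sum(x$table$significant & x$table$direction == "hyper", na.rm = TRUE)
         else NA_integer_)
}

#' @export
print.moderated_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<moderated_fit> %d probes, %d vs %d lines; d0 = %.3g, s0^2 = %.3g\n",
              g$n_probes, g$n_hdc, g$n_ldc, g$d0, g$s0_sq))
  if (!is.na(g$fdr))
    cat(sprintf("  %d significant at FDR %.2g (%d hyper)\n",
                g$n_significant, g$fdr, g$n_hyper))
  invisible(x)
}

#' Between-group difference in mean methylation
#'
#' Averages beta over probes within each line, then compares the line-level
#' means of two groups with a Welch two-sample t-test. Returns the difference
#' `delta = mean(first) - mean(second)` with its 95% CI, plus each group's
#' own mean and t-based CI (the ingredients of the classifier threshold).
#'
#' @param line_beta Line-level beta tibble.
#' @param groups Group labels (named by line id or aligned with columns).
#' @param levels The two groups compared.
#' @param conf Confidence level.
#' @return Object of class `group_delta`; `glance()` gives the one-row
#'   summary, `tidy()` the per-line means.
#' @export
group_delta <- function(line_beta, groups, levels = c("HDC", "LDC"),
                        conf = 0.95) {
  b <- beta_as_matrix(line_beta)
  if (!is.null(names(groups))) groups <- groups[colnames(b)]
  line_means <- tibble(line_id = colnames(b),
                       group = unname(groups),
                       mean_beta = colMeans(b, na.rm = TRUE))
  x <- line_means$mean_beta[line_means$group == levels[1]]
  y <- line_means$mean_beta[line_means$group == levels[2]]
  assert_two_groups(groups, levels)

  group_summary <- purrr::map_dfr(list(levels[1], levels[2]), function(g) {
    v <- line_means$mean_beta[line_means$group == g]
    n <- length(v)
    half <- if (n >= 2) qt(1 - (1 - conf) / 2, n - 1) * sd(v) / sqrt(n) else NA_real_
    tibble(group = g, n = n, mean = mean(v),
           ci_lower = mean(v) - half, ci_upper = mean(v) + half)
  })

  if (length(x) >= 2 && length(y) >= 2) {
    d <- mean(x) - mean(y)
    res <- tryCatch({
      ht <- t.test(x, y, conf.level = conf)
      list(delta = d, ci = as.numeric(ht$conf.int), t = unname(ht$statistic),
           df = unname(ht$parameter), p = ht$p.value)
    }, error = function(e) {
      # essentially-constant groups: the difference is exact, the test degenerate
      tiny <- abs(d) < sqrt(.Machine$double.eps)
      list(delta = d, ci = c(d, d), t = if (tiny) 0 else sign(d) * Inf,
           df = length(x) + length(y) - 2, p = if (tiny) 1 else 0)
    })
  } else {
    res <- list(delta = mean(x) - mean(y), ci = c(NA_real_, NA_real_),
                t = NA_real_, df = NA_real_, p = NA_real_)
    warn("a group has < 2 lines: CI and test undefined")
  }
  structure(c(res, list(conf = conf, levels = levels,
                        line_means = line_means,
                        group_summary = group_summary)),
            class = "group_delta")
}

#' @exportS3Method generics::tidy
tidy.group_delta <- function(x, ...) x$line_means

#' @exportS3Method generics::glance
glance.group_delta <- function(x, ...) {
  tibble(delta_beta_mean = x$delta, ci_lower = x$ci[1], ci_upper = x$ci[2],
         t = x$t, df = x$df, p = x$p, conf = x$conf)
}

#' @export
print.group_delta <- function(x, ...) {
  cat(sprintf("<group_delta> %s - %s: delta beta_mean = %.1f%% (%.0f%% CI %.1f-%.1f%%), t = %.2f, p = %.3g\n",
              x$levels[1], x$levels[2], 100 * x$delta, 100 * x$conf,
              100 * x$ci[1], 100 * x$ci[2], x$t, x$p))
  invisible(x)
}

#' Epigenetic-memory deltas between derived lines and their donors
#'
#' For each derived line with a matched donor, computes the difference in
#' mean beta over the supplied probes (line minus donor), summarises the
#' per-pair deltas by phenotype group, and compares donors of HDC-derived
#' versus LDC-derived lines with [group_delta()] (expected non-significant:
#' donor non-CG methylation is uniformly low).
#'
#' @param line_beta Line-level beta tibble containing both derived and donor
#'   line columns (typically restricted to CpH probes).
#' @param donor_map Tibble with `line_id`, `donor_line_id`, `group`; lines
#'   without a donor in the matrix are skipped with a notice.
#' @return List of class `memory_delta`: `pairs`, `group_summary`,
#'   `donor_delta` (a `group_delta` or NULL).
#' @export
memory_delta <- function(line_beta, donor_map) {
  b <- beta_as_matrix(line_beta)
  cm <- colMeans(b, na.rm = TRUE)
  dm <- donor_map %>%
    filter(!is.na(.data$donor_line_id), .data$group %in% c("HDC", "LDC"))
  ok <- dm$line_id %in% colnames(b) & dm$donor_line_id %in% colnames(b)
  if (any(!ok))
    inform(sprintf("%d line(s) skipped: line or donor absent from matrix", sum(!ok)))
  dm <- dm[ok, , drop = FALSE]
  pairs <- tibble(line_id = dm$line_id, donor_line_id = dm$donor_line_id,
                  group = dm$group,
                  delta = unname(cm[dm$line_id] - cm[dm$donor_line_id]))
  group_summary <- pairs %>%
    group_by(.data$group) %>%
    summarise(n_pairs = n(), mean_delta = mean(.data$delta), .groups = "drop")

  donor_groups <- setNames(dm$group, paste(dm$donor_line_id, dm$group))
  donors <- distinct(dm, .data$donor_line_id, .data$group)
  donor_delta <- NULL
  if (all(table(factor(donors$group, c("HDC", "LDC"))) >= 2)) {
    db <- b[, donors$donor_line_id, drop = FALSE]
    colnames(db) <- paste0(donors$donor_line_id, ".", donors$group)
    donor_delta <- group_delta(matrix_as_beta(db),
                               setNames(donors$group, colnames(db)))
  }
  structure(list(pairs = pairs, group_summary = group_summary,
                 donor_delta = donor_delta),
            class = "memory_delta")
}

#' @exportS3Method generics::tidy
tidy.memory_delta <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.memory_delta <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$group_summary, names_from = "group",
                             values_from = c("n_pairs", "mean_delta"))
  if (!is.null(x$donor_delta)) {
    g <- glance(x$donor_delta)
    wide$donor_delta <- g$delta_beta_mean
    wide$donor_p <- g$p
  }
  wide
}

#' Per-motif summary of the differential-methylation effect
#'
#' Groups CpH probes by the 6-base sequence flanking the non-CG locus and
#' reports, per motif, the probe count, mean delta beta and the fraction of
#' hypermethylated calls — a check that the effect is independent of local
#' sequence context. Motifs with fewer than `min_n` probes are pooled as
#' "other".
#'
#' @param fit A `moderated_fit` (after [call_mvps()]) or its `tidy()` table.
#' @param annotation Probe annotation providing `flank6`.
#' @param min_n Minimum probes per reported motif.
#' @return Tibble: `motif`, `n`, `mean_delta_beta`, `frac_hyper`.
#' @export
motif_effect_summary <- function(fit, annotation, min_n = 5) {
  tab <- if (inherits(fit, "moderated_fit")) tidy(fit) else fit
  tab <- tab %>%
    inner_join(annotation %>% select("probe_id", "flank6"), by = "probe_id")
  if (all(tab$flank6 == "" | is.na(tab$flank6)))
    abort("no probe has a flank6 motif; cannot summarise by motif",
          class = "cphcap_validation_error")
  tab %>%
    filter(.data$flank6 != "", !is.na(.data$flank6)) %>%
    group_by(motif = .data$flank6) %>%
    mutate(motif = if (dplyr::n() < min_n) "other" else .data$motif[1]) %>%
    ungroup() %>%
    group_by(.data$motif) %>%
    summarise(n = n(), mean_delta_beta = mean(.data$delta_beta),
              frac_hyper = mean(.data$delta_beta > 0), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n))
}

#' Join a precomputed DNA-methylation-age table onto a report
#'
#' Epigenetic-clock coefficients are external to this package; this hook
#' merely merges a user-supplied table of precomputed DNAm ages (per sample
#' or per line) into a result tibble by its identifier column.
#'
#' @param x A tibble with a `sample_id` or `line_id` column.
#' @param age_table Tibble with the matching identifier column and `dnam_age`.
#' @return `x` with `dnam_age` joined.
#' @export
attach_dnam_age <- function(x, age_table) {
  key <- intersect(c("sample_id", "line_id"), intersect(names(x), names(age_table)))
  if (!length(key))
    abort("no shared sample_id/line_id column to join DNAm age on",
          class = "cphcap_format_error")
  left_join(x, age_table, by = key[1])
}
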