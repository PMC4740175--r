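new_resample_result <- function(kind, observed, null_draws, B, p, seed,
                                extra = list()) {
  structure(c(list(kind = kind, observed = observed, null = null_draws,
                   B = B, p = p, seed = seed,
                   max_abs_null = if (length(null_draws)) max(abs(null_draws)) else NA_real_,
                   quantiles = if (length(null_draws))
                     quantile(null_draws, c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1))
                   else NULL),
              extra),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("<resample_result:%s> observed = %.4g, B = %d, empirical p = %.3g, max |null| = %.4g\n",
              x$kind, x$observed, x$B, x$p, x$max_abs_null))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.resample_result <- function(x, ...) {
  tibble(kind = x$kind, observed = x$observed, B = x$B, p = x$p,
         max_abs_null = x$max_abs_null, seed = x$seed %||% NA_integer_,
         exhaustive = isTRUE(x$exhaustive))
}

#' @exportS3Method generics::tidy
tidy.resample_result <- function(x, ...) tibble(null_delta = x$null)

#' Label-permutation test for the group mean-methylation difference
#'
#' Permutes the group labels over cell lines uniformly at random (without
#' replacement) and recomputes the between-group difference in mean beta
#' each draw. The two-sided empirical p-value uses the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (B + 1)`. When `B` meets or exceeds
#' the number of distinct label assignments, the test switches to exhaustive
#' enumeration (exact p over all assignments, which include the observed
#' labelling).
#'
#' @param line_beta Line-level beta tibble.
#' @param groups Group labels (named by line id or aligned with columns).
#' @param B Number of random permutations.
#' @param seed Seed for the permutation stream.
#' @param levels The two groups compared.
#' @return A `resample_result`.
#' @export
permutation_test_delta <- function(line_beta, groups, B = 20000, seed = 1L,
                                   levels = c("HDC", "LDC")) {
  if (B < 1) abort("B must be >= 1", class = "cphcap_config_error")
  b <- beta_as_matrix(line_beta)
  if (!is.null(names(groups))) groups <- groups[colnames(b)]
  keep <- groups %in% levels
  means <- colMeans(b[, keep, drop = FALSE], na.rm = TRUE)
  g <- groups[keep]
  n <- length(means); n1 <- sum(g == levels[1])
  assert_two_groups(g, levels)
  obs <- mean(means[g == levels[1]]) - mean(means[g == levels[2]])
  # permute labels of the smaller group: the |delta| null is identical either
  # way, which makes the p-value invariant to relabelling the two groups
  k <- min(n1, n - n1)
  stat <- function(lab) mean(means[lab]) - mean(means[-lab])

  n_assign <- choose(n, k)
  if (B >= n_assign) {
    inform(sprintf("B = %d >= %s distinct assignments: enumerating exhaustively",
                   B, format(n_assign)))
    nulls <- apply(combn(n, k), 2, stat)
    p <- mean(abs(nulls) >= abs(obs) - 1e-12)
    return(new_resample_result("permutation", obs, nulls, length(nulls), p,
                               seed, list(exhaustive = TRUE)))
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(B), function(i) stat(sample.int(n, k)), numeric(1))
  })
  p <- (1 + sum(abs(nulls) >= abs(obs) - 1e-12)) / (B + 1)
  new_resample_result("permutation", obs, nulls, B, p, seed,
                      list(exhaustive = FALSE))
}

#' Monte Carlo CpG-subsampling null for the group difference
#'
#' Repeatedly samples `n_probes` CpG probes without replacement and computes
#' the between-group difference in mean beta on each subset — an empirical
#' null for whether a CpH-sized probe panel could show the observed group
#' difference by chance in the (group-stable) CpG compartment. Optionally
#' restricts the pool to methylated probes (pooled mean beta > `beta_min`,
#' e.g. 0.80), reflecting the genomic distribution of CpG methylation.
#'
#' @param cpg_line_beta Line-level beta tibble of CpG probes.
#' @param groups Group labels.
#' @param n_probes Probes per draw (default 2676, the CpH panel size).
#' @param B Number of draws.
#' @param seed Seed.
#' @param beta_min Optional pool restriction: keep probes whose mean beta
#'   over the compared lines exceeds this value.
#' @param observed Optional observed statistic (e.g. the CpH delta) used for
#'   the add-one empirical p-value.
#' @param levels The two groups compared.
#' @return A `resample_result`; `max_abs_null` is the largest |delta| seen.
#' @export
montecarlo_cpg_null <- function(cpg_line_beta, groups, n_probes = 2676,
                                B = 10000, seed = 1L, beta_min = NULL,
                                observed = NA_real_,
                                levels = c("HDC", "LDC")) {
  if (B < 1) abort("B must be >= 1", class = "cphcap_config_error")
  b <- beta_as_matrix(cpg_line_beta)
  if (!is.null(names(groups))) groups <- groups[colnames(b)]
  keep <- groups %in% levels
  b <- b[, keep, drop = FALSE]; g <- groups[keep]
  assert_two_groups(g, levels)
  if (!is.null(beta_min)) b <- b[rowMeans(b, na.rm = TRUE) > beta_min, , drop = FALSE]
  if (nrow(b) < n_probes)
    abort(sprintf("CpG pool has %d probes after restriction but %d are required per draw",
                  nrow(b), n_probes), class = "cphcap_size_error")
  # per-probe group difference; a subset's delta is the mean over its probes
  d <- rowMeans(b[, g == levels[1], drop = FALSE], na.rm = TRUE) -
    rowMeans(b[, g == levels[2], drop = FALSE], na.rm = TRUE)
  nulls <- with_seed(seed, {
    vapply(seq_len(B), function(i) mean(d[sample.int(length(d), n_probes)]),
           numeric(1))
  })
  p <- if (is.na(observed)) NA_real_
  else (1 + sum(abs(nulls) >= abs(observed) - 1e-12)) / (B + 1)
  new_resample_result("montecarlo_cpg", observed, nulls, B, p, seed,
                      list(pool_size = length(d), n_probes = n_probes,
                           beta_min = beta_min %||% NA_real_))
}
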