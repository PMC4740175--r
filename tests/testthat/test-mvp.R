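test_that("the beta to M transform matches known points and inverts", {
  beta <- as_beta_tbl(cbind(s1 = c(0.5, 0.8, 0.2)))
  m <- beta_to_m(beta)
  expect_equal(m$s1, c(0, 2, -2))
  set.seed(1)
  b <- as_beta_tbl(matrix(runif(200, 0.01, 0.99), 20, 10))
  expect_equal(beta_mat(m_to_beta(beta_to_m(b))), beta_mat(b),
               tolerance = 1e-9)
})

test_that("moderated t matches an independent implementation of the estimator", {
  skip_if_not_installed("limma")
  set.seed(42)
  n <- 20; n1 <- 4; n2 <- 3
  mv <- matrix(rnorm(n * (n1 + n2), 0, rep(sqrt(exp(rnorm(n, 0, 1))), n1 + n2)),
               n, n1 + n2)
  mv[, 1:n1] <- mv[, 1:n1] + rep(rnorm(n, 0, 2), n1)
  beta <- as_beta_tbl(2^mv / (1 + 2^mv),
                      samples = c(paste0("H", 1:n1), paste0("L", 1:n2)))
  groups <- setNames(c(rep("HDC", n1), rep("LDC", n2)),
                     setdiff(names(beta), "probe_id"))
  fit <- fit_moderated_t(beta, groups)

  ref <- limma::eBayes(limma::lmFit(beta_mat(beta_to_m(beta)),
                                    cbind(1, c(rep(1, n1), rep(0, n2)))))
  expect_equal(fit$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_sq, ref$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(ref$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p, unname(ref$p.value[, 2]), tolerance = 1e-6)
})

test_that("forced priors recover the ordinary t and the common-variance limits", {
  set.seed(3)
  beta <- as_beta_tbl(matrix(runif(20 * 8, 0.2, 0.8), 20, 8),
                      samples = c(paste0("H", 1:4), paste0("L", 1:4)))
  groups <- setNames(rep(c("HDC", "LDC"), each = 4),
                     setdiff(names(beta), "probe_id"))
  m <- beta_mat(beta_to_m(beta))
  # d0 = 0: per-probe pooled-variance two-sample t with equal variances
  fit0 <- fit_moderated_t(beta, groups, prior = list(d0 = 0, s0_sq = 1))
  ordinary <- apply(m, 1, function(r)
    t.test(r[1:4], r[5:8], var.equal = TRUE)$statistic)
  expect_equal(fit0$table$t, unname(ordinary), tolerance = 1e-10)
  # d0 = Inf: z-like statistic against the fixed prior variance
  s0 <- 0.7
  fitI <- fit_moderated_t(beta, groups, prior = list(d0 = Inf, s0_sq = s0))
  delta_m <- rowMeans(m[, 1:4]) - rowMeans(m[, 5:8])
  expect_equal(fitI$table$t, unname(delta_m / sqrt(s0 * (1 / 4 + 1 / 4))),
               tolerance = 1e-10)
})

test_that("a zero-variance probe still yields a finite moderated t", {
  m <- matrix(c(rep(c(0.6, 0.4), each = 4),
                runif(5 * 8, 0.2, 0.8)), 6, 8, byrow = TRUE)
  beta <- as_beta_tbl(m, samples = c(paste0("H", 1:4), paste0("L", 1:4)))
  groups <- setNames(rep(c("HDC", "LDC"), each = 4),
                     setdiff(names(beta), "probe_id"))
  fit <- fit_moderated_t(beta, groups)
  expect_true(all(is.finite(fit$table$t)))
})

test_that("BH q-values match hand computation and bound significance", {
  fit <- structure(list(table = tibble::tibble(
    probe_id = c("a", "b", "c"), delta_beta = c(0.1, -0.2, 0.3),
    p = c(0.01, 0.02, 0.03))), class = "moderated_fit")
  out <- call_mvps(fit, fdr = 0.05)
  expect_equal(out$table$q, c(0.03, 0.03, 0.03))
  expect_equal(out$table$direction, c("hyper", "hypo", "hyper"))
  expect_true(all(out$table$q >= out$table$p))

  fit$table$p <- c(1, 1, 1)
  out <- call_mvps(fit, fdr = 0.05)
  expect_false(any(out$table$significant))

  set.seed(2)
  fit$table <- tibble::tibble(probe_id = sprintf("p%03d", 1:100),
                              delta_beta = rnorm(100), p = runif(100))
  q <- call_mvps(fit)$table$q
  expect_true(all(q[order(fit$table$p)] == cummax(q[order(fit$table$p)])))
  expect_true(all(q <= 1))
})

test_that("nearly all CpH probes are hyper-MVPs on the default cohort", {
  fit <- default_fit()
  tab <- fit$table
  expect_gte(mean(tab$significant), 0.90)
  expect_true(all(tab$direction[tab$significant] == "hyper"))
})

test_that("group delta matches closed-form Welch formulas on a toy case", {
  beta <- as_beta_tbl(cbind(h1 = 0.52, h2 = 0.48, l1 = 0.38, l2 = 0.36))
  groups <- c(h1 = "HDC", h2 = "HDC", l1 = "LDC", l2 = "LDC")
  d <- group_delta(beta, groups)
  expect_equal(d$delta, 0.13)
  x <- c(0.52, 0.48); y <- c(0.38, 0.36)
  se <- sqrt(var(x) / 2 + var(y) / 2)
  tt <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 2)^2 / 1 + (var(y) / 2)^2 / 1)
  expect_equal(d$t, tt)
  expect_equal(d$df, df)
  expect_equal(d$ci, 0.13 + c(-1, 1) * qt(0.975, df) * se,
               ignore_attr = TRUE)
  expect_equal(d$p, 2 * pt(-abs(tt), df))
})

test_that("group delta is antisymmetric and null for identical groups", {
  set.seed(4)
  beta <- as_beta_tbl(matrix(runif(40, 0.3, 0.7), 10, 4),
                      samples = c("h1", "h2", "l1", "l2"))
  g1 <- c(h1 = "HDC", h2 = "HDC", l1 = "LDC", l2 = "LDC")
  g2 <- c(h1 = "LDC", h2 = "LDC", l1 = "HDC", l2 = "HDC")
  expect_equal(group_delta(beta, g1)$delta, -group_delta(beta, g2)$delta)
  expect_equal(group_delta(beta, g1)$p, group_delta(beta, g2)$p)

  same <- as_beta_tbl(cbind(h1 = c(0.4, 0.5), h2 = c(0.6, 0.3),
                            l1 = c(0.4, 0.5), l2 = c(0.6, 0.3)))
  d <- group_delta(same, g1)
  expect_equal(d$delta, 0)
  expect_equal(d$p, 1)
})

test_that("the default cohort recovers the calibrated group difference", {
  d <- group_delta(cph_line_beta(), default_groups())
  expect_equal(d$delta, 0.13, tolerance = 0.02 / 0.13)
  expect_lt(d$p, 7.4e-4)
  g <- d$group_summary
  expect_equal(g$mean[g$group == "HDC"], 0.50, tolerance = 0.04)
  expect_equal(g$mean[g$group == "LDC"], 0.37, tolerance = 0.06)
})

test_that("mean recovered delta over many seeds matches the configured gap", {
  deltas <- vapply(1:20, function(s) {
    co <- simulate_cohort(generator_config(seed = s))
    cph <- co$annotation$probe_id[co$annotation$context == "CpH"]
    lb <- average_replicates(co$beta[co$beta$probe_id %in% cph, ], co$sheet)
    g <- line_groups(co$sheet, setdiff(names(lb), "probe_id"))
    hip <- names(g)[g %in% c("HDC", "LDC")]
    group_delta(lb[, c("probe_id", hip)], g)$delta
  }, numeric(1))
  expect_equal(mean(deltas), 0.13, tolerance = 0.02 / 0.13)
})

test_that("memory deltas separate HDC- and LDC-derived lines from shared donors", {
  co <- default_cohort()
  lb <- cph_line_beta(hipsc_only = FALSE)
  donor_map <- dplyr::distinct(co$sheet, line_id, group, donor_line_id)
  md <- memory_delta(lb, donor_map)
  gs <- md$group_summary
  expect_equal(gs$mean_delta[gs$group == "HDC"], 0.42, tolerance = 0.10)
  expect_equal(gs$mean_delta[gs$group == "LDC"], 0.29, tolerance = 0.12)
  expect_gt(gs$mean_delta[gs$group == "HDC"], gs$mean_delta[gs$group == "LDC"])
  # donors derive lines of both phenotypes, so donor-vs-donor delta is null
  expect_equal(glance(md$donor_delta)$delta_beta_mean, 0, tolerance = 0.02)

  # a line identical to its donor has delta 0
  two <- as_beta_tbl(cbind(L1 = c(0.3, 0.5), D1 = c(0.3, 0.5)))
  md0 <- memory_delta(two, tibble::tibble(line_id = "L1", donor_line_id = "D1",
                                          group = "HDC"))
  expect_equal(md0$pairs$delta, 0)
})

test_that("motif summaries pool small motifs and reflect a motif-free effect", {
  tab <- tibble::tibble(probe_id = paste0("p", 1:10),
                        delta_beta = rep(0.2, 10))
  ann <- tibble::tibble(probe_id = paste0("p", 1:10), flank6 = "AACAGT")
  out <- motif_effect_summary(tab, ann)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_delta_beta, 0.2)
  expect_equal(out$frac_hyper, 1)

  ann$flank6 <- ""
  expect_error(motif_effect_summary(tab, ann), class = "cphcap_validation_error")

  # generator draws motifs independently of the effect: across motifs the
  # per-probe delta distribution is exchangeable and every motif is all-hyper
  fit <- default_fit()
  ann7 <- default_cohort()$annotation
  ms <- motif_effect_summary(fit, ann7)
  expect_true(all(ms$frac_hyper == 1))
  joined <- dplyr::inner_join(tidy(fit), ann7[, c("probe_id", "flank6")],
                              by = "probe_id")
  joined <- joined[joined$flank6 != "", ]
  kw <- kruskal.test(joined$delta_beta, factor(joined$flank6))
  expect_gt(kw$p.value, 0.01)
})

test_that("DNAm age tables join onto line-level results", {
  res <- tibble::tibble(line_id = c("A", "B"), mean_beta = c(0.4, 0.5))
  age <- tibble::tibble(line_id = c("A", "B"), dnam_age = c(-0.4, 22))
  expect_equal(attach_dnam_age(res, age)$dnam_age, c(-0.4, 22))
  expect_error(attach_dnam_age(res, tibble::tibble(id = "A", dnam_age = 1)),
               class = "cphcap_format_error")
})
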