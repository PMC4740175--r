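make_controls <- function(bic, biu, negs) {
  tibble::tibble(sample_id = "s1",
                 bic1 = bic[1], bic2 = bic[2], bic3 = bic[3],
                 biu1 = biu[1], biu2 = biu[2], biu3 = biu[3],
                 neg1 = negs[1], neg2 = negs[2])
}

test_that("conversion efficiency matches closed-form cases", {
  # background equals the unconverted signal -> 100%
  eff <- conversion_efficiency(make_controls(c(5150, 5150, 5150),
                                             c(150, 150, 150), c(150, 150)))
  expect_equal(eff$efficiency, 100)
  # symmetric converted/unconverted signal -> 50%
  eff <- conversion_efficiency(make_controls(c(2650, 2650, 2650),
                                             c(2650, 2650, 2650), c(150, 150)))
  expect_equal(eff$efficiency, 50)
})

test_that("conversion efficiency is scale invariant and flags degenerate controls", {
  base <- make_controls(c(4000, 4200, 3900), c(400, 380, 410), c(150, 160))
  scaled <- base
  scaled[, -1] <- scaled[, -1] * 3.7
  expect_equal(conversion_efficiency(base)$efficiency,
               conversion_efficiency(scaled)$efficiency)
  degen <- make_controls(c(100, 100, 100), c(100, 100, 100), c(150, 150))
  out <- conversion_efficiency(degen)
  expect_true(out$degenerate)
  expect_true(is.na(out$efficiency))
})

test_that("generator round-trip recovers the configured conversion rate within 1 point", {
  ci <- simulate_control_intensities(sprintf("s%02d", 1:20), 0.8, seed = 3)
  expect_equal(mean(conversion_efficiency(ci)$efficiency), 80, tolerance = 0.0125)
})

test_that("detection filtering excludes exactly the probes failing in >= 1 extract", {
  beta <- as_beta_tbl(matrix(0.5, 3, 2))
  detp <- as_beta_tbl(matrix(0.001, 3, 2))
  out <- filter_detection(beta, detp)
  expect_equal(nrow(out$beta), 3)
  expect_equal(nrow(out$excluded), 0)

  detp$s001[2] <- 0.5
  out <- filter_detection(beta, detp)
  expect_equal(out$excluded$probe_id, "p002")
  expect_equal(setdiff(beta$probe_id, out$beta$probe_id), "p002")
  expect_identical(names(out$beta), names(beta))

  expect_error(filter_detection(beta, detp, alpha = 1.5),
               class = "cphcap_config_error")
})

test_that("detection exclusions match the injected failure registry", {
  co <- inject_artifacts(simulate_cohort(small_config(seed = 21)),
                         n_failed_probes = 10, seed = 3)
  out <- filter_detection(co$beta, co$detp)
  planted <- co$truth$artifacts$probe_id[co$truth$artifacts$kind == "failed_probe"]
  expect_setequal(out$excluded$probe_id, planted)
})

test_that("detection exclusions are monotone in alpha", {
  co <- inject_artifacts(simulate_cohort(small_config(seed = 22)),
                         n_failed_probes = 20, seed = 4)
  alphas <- c(0.5, 0.1, 0.05, 0.01, 0.001)
  n_excl <- vapply(alphas, function(a)
    nrow(filter_detection(co$beta, co$detp, alpha = a)$excluded), numeric(1))
  expect_true(all(diff(n_excl) >= 0))
})

test_that("perfectly separated genotypes yield no outlier flags", {
  rs <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1))
  beta <- as_beta_tbl(rs, probes = paste0("rs", 1:3),
                      samples = c("a1", "a2", "b1", "b2"))
  sheet <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                          line_id = c("A", "A", "B", "B"),
                          group = "HDC")
  out <- flag_replicate_outliers(beta, sheet)
  expect_equal(nrow(out$flagged), 0)
})

test_that("a swapped-in extract is flagged and its source line is not", {
  rs <- cbind(A1 = c(0, 0, 1), A2 = c(0, 0, 1), A3 = c(1, 0.5, 0.01),
              B1 = c(1, 0.5, 0), B2 = c(0.99, 0.5, 0.01), B3 = c(1, 0.49, 0))
  # A3 carries B's genotype: a planted sample swap
  beta <- as_beta_tbl(rs, probes = paste0("rs", 1:3))
  sheet <- tibble::tibble(sample_id = colnames(rs),
                          line_id = rep(c("A", "B"), each = 3),
                          group = "HDC")
  out <- flag_replicate_outliers(beta, sheet)
  expect_equal(out$flagged$sample_id, "A3")
})

test_that("planted outlier extracts are recovered exactly on a seeded cohort", {
  co <- inject_artifacts(simulate_cohort(generator_config(seed = 11)),
                         n_outlier_extracts = 2, seed = 12)
  out <- flag_replicate_outliers(co$beta, co$sheet, co$annotation)
  planted <- co$truth$artifacts$sample_id[co$truth$artifacts$kind == "outlier_extract"]
  expect_setequal(out$flagged$sample_id, planted)
})

test_that("replicate averaging matches a brute-force mean and handles singletons", {
  beta <- as_beta_tbl(cbind(a1 = c(0.4, 0.1), a2 = c(0.6, NA), b1 = c(0.2, 0.3)))
  sheet <- tibble::tibble(sample_id = c("a1", "a2", "b1"),
                          line_id = c("A", "A", "B"), group = "HDC")
  lb <- average_replicates(beta, sheet)
  expect_equal(lb$A, c(0.5, 0.1))   # pairwise-complete mean
  expect_equal(lb$B, c(0.2, 0.3))   # singleton line = identity

  co <- simulate_cohort(small_config(seed = 13))
  lb <- average_replicates(co$beta, co$sheet)
  m <- beta_mat(co$beta)
  for (l in c("HDC01", "LDC03", "DON02")) {
    cols <- co$sheet$sample_id[co$sheet$line_id == l]
    expect_equal(lb[[l]], unname(rowMeans(m[, cols])))
  }
})

test_that("replicate averaging commutes with probe subsetting", {
  co <- simulate_cohort(small_config(seed = 14))
  sub <- co$beta$probe_id[seq(1, nrow(co$beta), by = 7)]
  a <- average_replicates(co$beta[co$beta$probe_id %in% sub, ], co$sheet)
  b <- average_replicates(co$beta, co$sheet)
  expect_equal(a, b[b$probe_id %in% sub, ])
})

test_that("probe exclusion assigns one primary reason per probe", {
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:5),
    context = "CpH",
    chromosome = c("chrX", "chr1", "chr1", "chr1", "chr1"),
    position = c(50L, 100L, 200L, 300L, 400L),
    strand = c("+", "+", "+", "+", "-"),
    flank6 = "AACAGT")
  variants <- tibble::tibble(chromosome = "chr1",
                             position = c(101L, 208L, 312L, 390L),
                             ref = "A", alt = "G")
  out <- filter_probes(ann, variants)
  expect_equal(out$reason[out$probe_id == "p1"], "sex_chromosome")
  # variant at position+1 overlaps the target dinucleotide
  expect_equal(out$reason[out$probe_id == "p2"], "variant_at_target")
  # variant 8 bases 3' of the target on a + strand probe
  expect_equal(out$reason[out$probe_id == "p3"], "variant_3prime_10bp")
  # variant one base past the 10-base extension window, none closer -> not flagged
  expect_false("p4" %in% out$probe_id)
  # on the - strand the extension window lies below the target
  expect_equal(out$reason[out$probe_id == "p5"], "variant_3prime_10bp")

  expect_equal(filter_probes(ann, NULL)$probe_id, "p1")
})

test_that("svd scan returns missing p for constant covariates and detects planted structure", {
  # probe patterns anticorrelate between the sample pairs so that after
  # column centring the leading component separates {1,2} from {3,4}
  m <- rbind(c(0.80, 0.79, 0.20, 0.21),
             c(0.20, 0.21, 0.80, 0.79),
             c(0.50, 0.50, 0.50, 0.50))
  beta <- as_beta_tbl(m)
  sheet <- tibble::tibble(sample_id = colnames(beta)[-1],
                          line_id = colnames(beta)[-1],
                          group = "HDC",
                          batch = c("b1", "b1", "b2", "b2"),
                          sex = "F")
  out <- svd_confounder_scan(beta, sheet, k = 2,
                             covariates = c("batch", "sex", "group"))
  expect_true(all(is.na(out$p[out$covariate %in% c("sex", "group")])))
  # perfect rank separation of 2 vs 2: H = 12/(4*5) * (2*(1.5-2.5)^2 + 2*(3.5-2.5)^2)
  h <- 12 / 20 * (2 * (1.5 - 2.5)^2 + 2 * (3.5 - 2.5)^2)
  expect_equal(out$p[out$component == 1 & out$covariate == "batch"],
               1 - pchisq(h, df = 1))
})

test_that("no technical covariate associates with the leading components on null data", {
  svd_tab <- default_qc()$report$svd
  tech <- svd_tab[svd_tab$covariate == "batch" & svd_tab$component <= 3, ]
  expect_true(all(tech$p > 0.01))
  # the leading component reflects biology (group), not batch
  grp <- svd_tab[svd_tab$covariate == "group" & svd_tab$component == 1, ]
  expect_lt(grp$p, 1e-6)
})
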