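#' Generator settings for a synthetic 450K-like cohort
#'
#' Bundles the parameters of the synthetic-data model. Defaults emulate the
#' discovery study design: 25 pluripotent lines in two endodermal
#' differentiation capacity groups (15 HDC, 10 LDC), 6 matched donor lines,
#' 6 DNA extracts per line, ~2,676 autosomal CpH probes, a 20,000-probe CpG
#' pool and 59 rs genotype probes. Group levels of mean CpH methylation are
#' 50% (HDC), 37% (LDC) and 8% (donor).
#'
#' @param n_hdc_lines,n_ldc_lines,n_donor_lines Numbers of cell lines per
#'   group (donors may be 0, e.g. for a replication cohort).
#' @param extracts_per_line Replicate DNA extracts per line.
#' @param n_cph,n_cpg,n_rs Probe counts by context.
#' @param mu_hdc,mu_ldc,mu_donor Target grand-mean CpH beta per group.
#' @param probe_sd_logit SD of per-probe baseline on the natural-logit scale.
#' @param line_sd_logit SD of the per-line shift applied to CpH probes
#'   (between-line biological variation in global non-CG methylation).
#' @param extract_sd_logit SD of per-probe, per-extract technical noise.
#' @param cpg_meth_frac Fraction of CpG probes drawn around beta ~ 0.85
#'   (the rest sit around 0.10); CpG probes carry no group effect.
#' @param conversion_rate Bisulfite conversion rate used for the Infinium-I
#'   control-probe intensities.
#' @param seed Integer seed; a fixed seed makes the cohort fully reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_hdc_lines = 15, n_ldc_lines = 10,
                             n_donor_lines = 6, extracts_per_line = 6,
                             n_cph = 2676, n_cpg = 20000, n_rs = 59,
                             mu_hdc = 0.50, mu_ldc = 0.37, mu_donor = 0.08,
                             probe_sd_logit = 0.8, line_sd_logit = 0.15,
                             extract_sd_logit = 0.10, cpg_meth_frac = 0.70,
                             conversion_rate = 0.995, seed = 1L) {
  cfg <- list(n_hdc_lines = n_hdc_lines, n_ldc_lines = n_ldc_lines,
              n_donor_lines = n_donor_lines, extracts_per_line = extracts_per_line,
              n_cph = n_cph, n_cpg = n_cpg, n_rs = n_rs,
              mu_hdc = mu_hdc, mu_ldc = mu_ldc, mu_donor = mu_donor,
              probe_sd_logit = probe_sd_logit, line_sd_logit = line_sd_logit,
              extract_sd_logit = extract_sd_logit, cpg_meth_frac = cpg_meth_frac,
              conversion_rate = conversion_rate, seed = as.integer(seed))
  fr <- c("mu_hdc", "mu_ldc", "mu_donor", "cpg_meth_frac", "conversion_rate")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    abort(sprintf("generator_config: %s must be in [0, 1]", f),
          class = "cphcap_config_error")
  for (f in c("n_hdc_lines", "n_ldc_lines", "extracts_per_line", "n_cph", "n_cpg"))
    if (cfg[[f]] < 1)
      abort(sprintf("generator_config: %s must be >= 1", f),
            class = "cphcap_config_error")
  for (f in c("n_donor_lines", "n_rs"))
    if (cfg[[f]] < 0)
      abort(sprintf("generator_config: %s must be >= 0", f),
            class = "cphcap_config_error")
  for (f in c("probe_sd_logit", "line_sd_logit", "extract_sd_logit"))
    if (cfg[[f]] < 0)
      abort(sprintf("generator_config: %s must be >= 0", f),
            class = "cphcap_config_error")
  structure(cfg, class = "generator_config")
}

# shift d such that mean(plogis(theta + d)) == mu, to within 1e-6
solve_group_shift <- function(theta, mu) {
  uniroot(function(d) mean(plogis(theta + d)) - mu,
          interval = c(-40, 40), tol = 1e-8)$root
}

clip01 <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)

rand_flank6 <- function(n, central) {
  bases <- c("A", "C", "G", "T")
  paste0(sample(bases, n, TRUE), sample(bases, n, TRUE),
         sample(central, n, TRUE),
         sample(bases, n, TRUE), sample(bases, n, TRUE))
}

#' Simulate Infinium-I bisulfite-conversion control intensities
#'
#' Negative-control intensities are drawn around 150 units (SD 15); converted
#' controls (BIC) around `150 + 5000 * conversion_rate` and unconverted
#' controls (BIU) around `150 + 5000 * (1 - conversion_rate)` (SD 100), all
#' floored at 0, so that the background-adjusted efficiency statistic
#' recovers `conversion_rate` in expectation.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param conversion_rate Bisulfite conversion rate in \[0, 1\].
#' @param seed Optional seed; NULL continues the caller's RNG stream.
#' @param n_negatives Number of negative-control probes per sample (a small
#'   stand-in for the array's 613; only their mean enters the statistic).
#' @return A control-intensity tibble (`sample_id`, `bic1..3`, `biu1..3`,
#'   `neg1..n`).
#' @export
simulate_control_intensities <- function(sample_ids, conversion_rate,
                                         seed = NULL, n_negatives = 25) {
  if (conversion_rate < 0 || conversion_rate > 1)
    abort("conversion_rate must be in [0, 1]", class = "cphcap_config_error")
  n <- length(sample_ids)
  with_seed(seed, {
    draw <- function(mu, sd, k) pmax(matrix(rnorm(n * k, mu, sd), n, k), 0)
    bic <- draw(150 + 5000 * conversion_rate, 100, 3)
    biu <- draw(150 + 5000 * (1 - conversion_rate), 100, 3)
    neg <- draw(150, 15, n_negatives)
    colnames(bic) <- paste0("bic", 1:3)
    colnames(biu) <- paste0("biu", 1:3)
    colnames(neg) <- paste0("neg", seq_len(n_negatives))
    bind_cols(tibble(sample_id = sample_ids),
              as_tibble(bic), as_tibble(biu), as_tibble(neg))
  })
}

#' Simulate a 450K-like methylation cohort
#'
#' Draws a probe-by-sample beta matrix with the hierarchical structure the
#' downstream analysis assumes. Each CpH probe has a baseline
#' `theta_p ~ N(0, probe_sd_logit)` on the natural-logit scale; a group shift
#' `delta_g` is solved by root finding so that the grand mean of
#' `plogis(theta_p + delta_g)` equals the target group mean; each line adds a
#' scalar shift `N(0, line_sd_logit)` to its CpH probes (lines differ in
#' global non-CG level, which is what the biomarker exploits) and each
#' extract adds per-probe noise `N(0, extract_sd_logit)`. CpG probes are
#' bimodal (around 0.85 and 0.10) with no group or line effect, so the CpG
#' compartment is a true null for group comparisons. rs probes carry a
#' per-line genotype in \{0, 0.5, 1\} shared by all extracts of that line.
#' Detection p-values are Uniform(0, 0.005) unless failures are injected via
#' [inject_artifacts()].
#'
#' @param config A [generator_config()].
#' @param template Optional `cph_cohort` whose probe-level parameters
#'   (baselines, annotation) are reused, emulating a new cohort measured on
#'   the same array: cell lines and extracts are drawn fresh but every probe
#'   keeps its identity, so panels selected in one cohort transfer to the
#'   other. Probe counts in `config` are overridden by the template's.
#' @return A list of class `cph_cohort`: `beta`, `detp` (beta tibbles),
#'   `annotation`, `sheet`, `controls`, and `truth` (line groups, per-probe
#'   true group means, artifact registry).
#' @export
simulate_cohort <- function(config = generator_config(), template = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  if (!is.null(template)) {
    stopifnot(inherits(template, "cph_cohort"))
    pp <- template$truth$probe_params
    cfg$n_cph <- length(pp$theta_cph)
    cfg$n_cpg <- length(pp$theta_cpg)
    cfg$n_rs <- sum(template$annotation$context == "rs")
  }
  with_seed(cfg$seed, {
    lines <- tibble(
      line_id = c(sprintf("HDC%02d", seq_len(cfg$n_hdc_lines)),
                  sprintf("LDC%02d", seq_len(cfg$n_ldc_lines)),
                  if (cfg$n_donor_lines > 0)
                    sprintf("DON%02d", seq_len(cfg$n_donor_lines))),
      group = c(rep("HDC", cfg$n_hdc_lines), rep("LDC", cfg$n_ldc_lines),
                rep("donor", cfg$n_donor_lines)))
    n_hipsc <- cfg$n_hdc_lines + cfg$n_ldc_lines
    lines$cell_class <- ifelse(lines$group == "donor", "donor", "hiPSC")
    lines$donor_line_id <- NA_character_
    if (cfg$n_donor_lines > 0)
      lines$donor_line_id[seq_len(n_hipsc)] <-
        sprintf("DON%02d", ((seq_len(n_hipsc) - 1L) %% cfg$n_donor_lines) + 1L)
    lines$sex <- sample(c("F", "M"), nrow(lines), TRUE)
    lines$passage <- ifelse(lines$group == "donor", NA_integer_,
                            sample(10:40, nrow(lines), TRUE))
    lines$line_effect <- rnorm(nrow(lines), 0, cfg$line_sd_logit)

    sheet <- tidyr::crossing(lines, extract = seq_len(cfg$extracts_per_line)) %>%
      arrange(match(.data$line_id, lines$line_id), .data$extract) %>%
      mutate(sample_id = sprintf("%s_e%d", .data$line_id, .data$extract))
    n_samp <- nrow(sheet)
    sheet$slide <- sprintf("S%02d", sample(rep(seq_len(ceiling(n_samp / 12)),
                                               each = 12)[seq_len(n_samp)]))
    sheet$batch <- sprintf("B%d", (as.integer(sub("S", "", sheet$slide)) - 1L) %/% 4L + 1L)
    sheet$array_position <- sprintf("R%02d", sample(1:12, n_samp, TRUE))

    # CpH compartment
    theta_cph <- if (is.null(template)) rnorm(cfg$n_cph, 0, cfg$probe_sd_logit)
                 else template$truth$probe_params$theta_cph
    mu <- c(HDC = cfg$mu_hdc, LDC = cfg$mu_ldc, donor = cfg$mu_donor)
    delta <- vapply(mu, function(m) solve_group_shift(theta_cph, m), numeric(1))
    base_cph <- outer(theta_cph, delta[sheet$group] + sheet$line_effect, "+")
    beta_cph <- clip01(plogis(base_cph +
      rnorm(cfg$n_cph * n_samp, 0, cfg$extract_sd_logit)))

    # CpG compartment: bimodal, no group/line structure
    n_meth <- round(cfg$cpg_meth_frac * cfg$n_cpg)
    theta_cpg <- if (is.null(template))
      c(rnorm(n_meth, qlogis(0.85), 0.5),
        rnorm(cfg$n_cpg - n_meth, qlogis(0.10), 0.5))
    else template$truth$probe_params$theta_cpg
    beta_cpg <- clip01(plogis(matrix(theta_cpg, cfg$n_cpg, n_samp) +
      rnorm(cfg$n_cpg * n_samp, 0, cfg$extract_sd_logit)))

    # rs genotype probes: per-line genotype shared by that line's extracts
    if (cfg$n_rs > 0) {
      geno <- matrix(sample(c(0, 0.5, 1), cfg$n_rs * nrow(lines), TRUE,
                            prob = c(0.25, 0.5, 0.25)), cfg$n_rs, nrow(lines),
                     dimnames = list(NULL, lines$line_id))
      beta_rs <- geno[, sheet$line_id, drop = FALSE] +
        matrix(rnorm(cfg$n_rs * n_samp, 0, 0.01), cfg$n_rs, n_samp)
      beta_rs <- pmin(pmax(beta_rs, 1e-3), 1 - 1e-3)
    } else beta_rs <- matrix(numeric(0), 0, n_samp)

    probe_ids <- c(sprintf("cph%05d", seq_len(cfg$n_cph)),
                   sprintf("cpg%05d", seq_len(cfg$n_cpg)),
                   if (cfg$n_rs > 0) sprintf("rs%03d", seq_len(cfg$n_rs)))
    beta <- rbind(beta_cph, beta_cpg, beta_rs)
    dimnames(beta) <- list(probe_ids, sheet$sample_id)

    detp <- matrix(runif(length(beta), 0, 0.005), nrow(beta), ncol(beta),
                   dimnames = dimnames(beta))

    annotation <- if (is.null(template)) tibble(
      probe_id = probe_ids,
      context = c(rep("CpH", cfg$n_cph), rep("CpG", cfg$n_cpg),
                  rep("rs", cfg$n_rs)),
      chromosome = paste0("chr", sample(1:22, length(probe_ids), TRUE)),
      position = sample.int(2.4e8, length(probe_ids)),
      strand = sample(c("+", "-"), length(probe_ids), TRUE),
      flank6 = c(rand_flank6(cfg$n_cph, c("CA", "CT", "CC")),
                 rand_flank6(cfg$n_cpg, "CG"), rep("", cfg$n_rs)))
    else template$annotation

    controls <- simulate_control_intensities(sheet$sample_id,
                                             cfg$conversion_rate)

    truth <- list(
      line_groups = lines %>% select("line_id", "group", "donor_line_id"),
      probe_means = tibble(probe_id = probe_ids[seq_len(cfg$n_cph)],
                           mean_hdc = plogis(theta_cph + delta["HDC"]),
                           mean_ldc = plogis(theta_cph + delta["LDC"]),
                           mean_donor = plogis(theta_cph + delta["donor"])),
      artifacts = tibble(kind = character(), probe_id = character(),
                         sample_id = character(), value = numeric()),
      probe_params = list(theta_cph = theta_cph, theta_cpg = theta_cpg))

    sheet_out <- sheet %>%
      select("sample_id", "line_id", "group", "cell_class", "passage",
             "batch", "slide", "array_position", "sex", "donor_line_id")

    structure(list(beta = matrix_as_beta(beta), detp = matrix_as_beta(detp),
                   annotation = annotation, sheet = sheet_out,
                   controls = controls, truth = truth, config = cfg),
              class = "cph_cohort")
  })
}

#' Inject QC artifacts into a synthetic cohort
#'
#' Plants known defects so QC stages can be tested against a truth registry:
#' failed probes receive detection p ~ Uniform(0.05, 1) in one extract;
#' outlier extracts have their rs-probe profile replaced by another line's
#' genotypes (a sample swap); under-converted samples have every beta
#' replaced by `1 - c * (1 - beta)` (unconverted cytosines read as
#' methylated) and their control intensities regenerated at rate `c`.
#'
#' @param cohort A `cph_cohort`.
#' @param n_failed_probes,n_outlier_extracts,n_underconverted Counts of each
#'   artifact to plant.
#' @param underconversion_rate Conversion rate `c` of under-converted samples.
#' @param seed Seed for the artifact placement.
#' @return The modified cohort; `truth$artifacts` lists every planted defect.
#' @export
inject_artifacts <- function(cohort, n_failed_probes = 0,
                             n_outlier_extracts = 0, n_underconverted = 0,
                             underconversion_rate = 0.9, seed = 1L) {
  stopifnot(inherits(cohort, "cph_cohort"))
  beta <- beta_as_matrix(cohort$beta)
  detp <- beta_as_matrix(cohort$detp)
  sheet <- cohort$sheet
  reg <- cohort$truth$artifacts
  if (n_failed_probes > nrow(beta))
    abort(sprintf("requested %d failed probes but only %d probes exist",
                  n_failed_probes, nrow(beta)), class = "cphcap_config_error")
  if (n_underconverted > ncol(beta) || n_outlier_extracts > ncol(beta))
    abort(sprintf("requested more artifact samples than the %d available",
                  ncol(beta)), class = "cphcap_config_error")

  with_seed(seed, {
    if (n_failed_probes > 0) {
      probes <- sample(rownames(beta), n_failed_probes)
      cols <- sample.int(ncol(beta), n_failed_probes, replace = TRUE)
      detp[cbind(match(probes, rownames(beta)), cols)] <- runif(n_failed_probes, 0.05, 1)
      reg <- bind_rows(reg, tibble(kind = "failed_probe", probe_id = probes,
                                   sample_id = colnames(beta)[cols], value = NA_real_))
    }
    if (n_outlier_extracts > 0) {
      rs_ids <- cohort$annotation$probe_id[cohort$annotation$context == "rs"]
      if (length(rs_ids) == 0)
        abort("cannot plant outlier extracts without rs probes",
              class = "cphcap_config_error")
      multi <- sheet %>% count(.data$line_id) %>% filter(n >= 2) %>% pull("line_id")
      pool <- sheet$sample_id[sheet$line_id %in% multi]
      if (n_outlier_extracts > length(pool))
        abort("not enough multi-extract samples for requested outliers",
              class = "cphcap_config_error")
      victims <- sample(pool, n_outlier_extracts)
      for (v in victims) {
        own <- sheet$line_id[sheet$sample_id == v]
        other <- sample(setdiff(sheet$line_id, own), 1)
        src <- sheet$sample_id[sheet$line_id == other][1]
        beta[rs_ids, v] <- pmin(pmax(beta[rs_ids, src] +
          rnorm(length(rs_ids), 0, 0.01), 1e-3), 1 - 1e-3)
      }
      reg <- bind_rows(reg, tibble(kind = "outlier_extract",
                                   probe_id = NA_character_,
                                   sample_id = victims, value = NA_real_))
    }
    if (n_underconverted > 0) {
      taken <- reg$sample_id[reg$kind == "outlier_extract"]
      pool <- setdiff(colnames(beta), taken)
      victims <- sample(pool, n_underconverted)
      c_rate <- underconversion_rate
      beta[, victims] <- 1 - c_rate * (1 - beta[, victims])
      new_ci <- simulate_control_intensities(victims, c_rate)
      keep <- intersect(names(cohort$controls), names(new_ci))
      cohort$controls[match(victims, cohort$controls$sample_id), keep] <-
        new_ci[, keep]
      reg <- bind_rows(reg, tibble(kind = "underconverted",
                                   probe_id = NA_character_,
                                   sample_id = victims, value = c_rate))
    }
  })
  cohort$beta <- matrix_as_beta(beta)
  cohort$detp <- matrix_as_beta(detp)
  cohort$truth$artifacts <- reg
  cohort
}

#' Generator settings for a replication-style cohort
#'
#' Convenience wrapper around [generator_config()] for an independent
#' 10-line replication cohort (5 HDC, 5 LDC, no donors, 2 extracts per
#' line). Pass the discovery cohort as `template` to [simulate_cohort()] so
#' both cohorts share probe identities.
#'
#' @param n_hdc_lines,n_ldc_lines,extracts_per_line Replication design.
#' @param seed Integer seed.
#' @param ... Further arguments to [generator_config()].
#' @return A `generator_config`.
#' @export
replication_config <- function(n_hdc_lines = 5, n_ldc_lines = 5,
                               extracts_per_line = 2, seed = 2L, ...) {
  generator_config(n_hdc_lines = n_hdc_lines, n_ldc_lines = n_ldc_lines,
                   n_donor_lines = 0, extracts_per_line = extracts_per_line,
                   seed = seed, ...)
}

#' @export
print.cph_cohort <- function(x, ...) {
  cat(sprintf("<cph_cohort> %d probes x %d extracts (%d lines)\n",
              nrow(x$beta), ncol(x$beta) - 1L, nrow(x$truth$line_groups)))
  print(count(x$truth$line_groups, .data$group))
  invisible(x)
}
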