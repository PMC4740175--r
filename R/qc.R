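#' Bisulfite conversion efficiency from Infinium-I control probes
#'
#' Background-adjusts the three converted (BIC) and three unconverted (BIU)
#' control-probe intensities by subtracting the mean negative-control
#' intensity (floored at zero) and reports
#' `100 * sum(adj BIC) / (sum(adj BIC) + sum(adj BIU))` per sample. An
#' efficiency of 100% means no unconverted signal above background. When both
#' adjusted sums are zero the statistic is undefined and the sample is
#' flagged rather than erroring.
#'
#' @param controls Control-intensity tibble (see
#'   [read_control_intensities()]).
#' @return Tibble: `sample_id`, `efficiency` (percent, NA when degenerate),
#'   `degenerate` flag.
#' @export
conversion_efficiency <- function(controls) {
  bic <- as.matrix(controls[, paste0("bic", 1:3)])
  biu <- as.matrix(controls[, paste0("biu", 1:3)])
  neg <- as.matrix(controls[, grepl("^neg", names(controls)), drop = FALSE])
  nbar <- rowMeans(neg)
  adj_c <- rowSums(pmax(bic - nbar, 0))
  adj_u <- rowSums(pmax(biu - nbar, 0))
  degen <- adj_c == 0 & adj_u == 0
  eff <- ifelse(degen, NA_real_, 100 * adj_c / (adj_c + adj_u))
  tibble(sample_id = controls$sample_id, efficiency = eff, degenerate = degen)
}

#' Exclude probes failing detection in any extract
#'
#' A probe is excluded when its detection p-value exceeds `alpha` (i.e. the
#' signal is not confidently above background) in at least one extract.
#'
#' @param beta Beta tibble.
#' @param detp Detection p-value tibble of the same shape.
#' @param alpha Detection threshold (default 0.01).
#' @return List: `beta` (surviving probes, all samples retained) and
#'   `excluded` tibble (`probe_id`, `n_failed`).
#' @export
filter_detection <- function(beta, detp, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1)
    abort("alpha must be in (0, 1)", class = "cphcap_config_error")
  dm <- beta_as_matrix(detp)
  if (!identical(rownames(dm), beta$probe_id))
    dm <- dm[match(beta$probe_id, rownames(dm)), , drop = FALSE]
  n_failed <- rowSums(dm > alpha, na.rm = TRUE)
  bad <- n_failed >= 1
  list(beta = beta[!bad, , drop = FALSE],
       excluded = tibble(probe_id = beta$probe_id[bad],
                         reason = "detection_fail",
                         n_failed = n_failed[bad]))
}

#' Flag replicate extracts whose genotype profile misclusters
#'
#' Computes Euclidean distances between extracts over the rs (genotype)
#' probes and flags an extract when the majority of its k nearest neighbours
#' belong to a different cell line, with k equal to the number of other
#' extracts of its own line — the deterministic analogue of spotting sample
#' swaps in a distance plot. (With k = 1 this is the nearest-neighbour rule;
#' the majority vote keeps genuine members of a line from being flagged when
#' a swapped-in extract carries their genotype.) Lines with a single extract
#' cannot be checked and are reported as skipped.
#'
#' @param beta Beta tibble containing rs probes (other probes are ignored
#'   when `annotation` is supplied).
#' @param sheet Sample sheet.
#' @param annotation Optional probe annotation used to restrict to
#'   `context == "rs"`; if NULL, all rows of `beta` are used.
#' @return List: `flagged` tibble (`sample_id`, `line_id`,
#'   `nearest_sample_id`, `nearest_line_id`), `skipped_lines`.
#' @export
flag_replicate_outliers <- function(beta, sheet, annotation = NULL) {
  if (!is.null(annotation)) {
    rs_ids <- annotation$probe_id[annotation$context == "rs"]
    beta <- beta %>% filter(.data$probe_id %in% rs_ids)
  }
  if (nrow(beta) == 0)
    abort("no rs probes available for outlier flagging",
          class = "cphcap_validation_error")
  m <- beta_as_matrix(beta)
  ids <- colnames(m)
  line_of <- setNames(sheet$line_id, sheet$sample_id)[ids]
  counts <- table(line_of)
  skipped <- names(counts)[counts < 2]
  d <- as.matrix(dist(t(m)))
  diag(d) <- Inf
  checkable <- ids[line_of %in% names(counts)[counts >= 2]]
  res <- purrr::map_dfr(checkable, function(s) {
    k <- max(1L, sum(line_of == line_of[s]) - 1L)
    nb <- ids[order(d[s, ])][seq_len(k)]
    foreign <- mean(line_of[nb] != line_of[s])
    tibble(sample_id = s, line_id = unname(line_of[s]),
           nearest_sample_id = nb[1],
           nearest_line_id = unname(line_of[nb[1]]),
           flag = foreign > 0.5)
  })
  list(flagged = res %>% filter(.data$flag) %>% select(-"flag"),
       skipped_lines = skipped)
}

#' Average replicate extracts to line level
#'
#' Collapses the extract columns of a beta tibble to one column per cell
#' line by the arithmetic mean, excluding missing values pairwise. Outlying
#' extracts should be removed beforehand.
#'
#' @param beta Beta tibble (one column per extract).
#' @param sheet Sample sheet mapping `sample_id` to `line_id`.
#' @return A line-level beta tibble (one column per `line_id`, in
#'   sample-sheet order).
#' @export
average_replicates <- function(beta, sheet) {
  m <- beta_as_matrix(beta)
  samples <- colnames(m)
  line_of <- setNames(sheet$line_id, sheet$sample_id)[samples]
  if (anyNA(line_of))
    abort(sprintf("sample '%s' absent from sample sheet",
                  samples[which(is.na(line_of))[1]]),
          class = "cphcap_validation_error")
  line_ids <- unique(sheet$line_id[sheet$sample_id %in% samples])
  out <- vapply(line_ids, function(l) {
    cols <- m[, line_of == l, drop = FALSE]
    rowMeans(cols, na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(m), line_ids)
  matrix_as_beta(out)
}

#' Probe exclusions: sex chromosomes and polymorphisms
#'
#' Excludes probes mapping to sex chromosomes and flags probes whose target
#' dinucleotide (positions p, p+1 on the probe strand) overlaps a variant,
#' or with a variant within the 10 bases adjacent to the target on the
#' single-base-extension side. Each probe receives one primary reason code
#' (sex_chromosome > variant_at_target > variant_3prime_10bp).
#'
#' @param annotation Probe annotation tibble.
#' @param variants Optional variant tibble (`chromosome`, `position`); NULL
#'   means only sex-chromosome exclusions.
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return Tibble: `probe_id`, `reason`.
#' @export
filter_probes <- function(annotation, variants = NULL,
                          sex_chroms = c("chrX", "chrY", "X", "Y")) {
  sex <- annotation$chromosome %in% sex_chroms
  at_target <- three_prime <- rep(FALSE, nrow(annotation))
  if (!is.null(variants) && nrow(variants) > 0) {
    for (i in seq_len(nrow(annotation))) {
      v <- variants$position[variants$chromosome == annotation$chromosome[i]]
      if (!length(v)) next
      p <- annotation$position[i]
      target <- c(p, p + 1L)
      window <- if (identical(annotation$strand[i], "-"))
        (p - 10L):(p - 1L) else (p + 2L):(p + 11L)
      at_target[i] <- any(v %in% target)
      three_prime[i] <- !at_target[i] && any(v %in% window)
    }
  }
  reason <- dplyr::case_when(sex ~ "sex_chromosome",
                             at_target ~ "variant_at_target",
                             three_prime ~ "variant_3prime_10bp",
                             TRUE ~ NA_character_)
  tibble(probe_id = annotation$probe_id, reason = reason) %>%
    filter(!is.na(.data$reason))
}

#' SVD confounder scan
#'
#' Performs singular value decomposition of the column-centred beta matrix
#' and tests each of the top `k` right-singular vectors (sample-space
#' components) for association with sample-sheet covariates:
#' Kruskal-Wallis for categorical covariates, Pearson correlation test for
#' numeric ones. Constant covariates yield missing p-values.
#'
#' @param beta Beta tibble (extract- or line-level).
#' @param sheet Sample sheet; tested covariates default to group, cell_class,
#'   batch, slide, array_position, sex (categorical) and passage (numeric).
#' @param k Number of components to test.
#' @param covariates Optional character vector restricting the covariates.
#' @return Tibble: `component`, `covariate`, `p`, `variance_explained`.
#' @export
svd_confounder_scan <- function(beta, sheet, k = 6, covariates = NULL) {
  m <- beta_as_matrix(beta)
  m <- m[complete.cases(m), , drop = FALSE]
  if (ncol(m) < k)
    abort(sprintf("need >= k samples for k = %d components", k),
          class = "cphcap_config_error")
  cen <- sweep(m, 2, colMeans(m))
  # right-singular vectors via the small-side eigendecomposition
  xtx <- crossprod(cen)
  eig <- eigen(xtx, symmetric = TRUE)
  v <- eig$vectors[, seq_len(k), drop = FALSE]
  ve <- eig$values[seq_len(k)] / sum(pmax(eig$values, 0))

  covs <- covariates %||% intersect(
    c("group", "cell_class", "batch", "slide", "array_position", "sex", "passage"),
    names(sheet))
  meta <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    meta <- sheet[match(colnames(m), sheet$line_id), , drop = FALSE]

  purrr::map_dfr(seq_len(k), function(j) {
    purrr::map_dfr(covs, function(cv) {
      x <- meta[[cv]]
      ok <- !is.na(x)
      p <- if (length(unique(x[ok])) < 2) NA_real_
      else if (is.numeric(x)) cor.test(v[ok, j], x[ok])$p.value
      else kruskal.test(v[ok, j], factor(x[ok]))$p.value
      tibble(component = j, covariate = cv, p = p, variance_explained = ve[j])
    })
  })
}

#' Run the full sample/probe QC stage
#'
#' Chains conversion-efficiency scoring, detection filtering, rs-probe
#' replicate-outlier removal, probe exclusions (sex chromosomes, variants)
#' and replicate averaging, and returns the cleaned line-level matrix
#' together with a QC report.
#'
#' @param cohort A `cph_cohort` or a list with elements beta, detp,
#'   annotation, sheet, controls.
#' @param variants Optional variant tibble.
#' @param alpha Detection threshold.
#' @param min_efficiency Samples below this conversion efficiency (percent)
#'   are reported (not removed by default).
#' @param svd_k Components for the confounder scan (0 skips it).
#' @return List of class `qc_result`: `line_beta`, `beta` (extract level,
#'   filtered), `report` (efficiency, excluded probes with reason codes,
#'   flagged extracts, SVD table).
#' @export
run_qc <- function(cohort, variants = NULL, alpha = 0.01,
                   min_efficiency = 90, svd_k = 6) {
  eff <- if (!is.null(cohort$controls)) conversion_efficiency(cohort$controls)
         else tibble(sample_id = character(), efficiency = numeric(),
                     degenerate = logical())
  det <- if (!is.null(cohort$detp))
    filter_detection(cohort$beta, cohort$detp, alpha = alpha)
  else list(beta = cohort$beta,
            excluded = tibble(probe_id = character(), reason = character()))
  has_rs <- !is.null(cohort$annotation) &&
    any(cohort$annotation$context == "rs")
  out <- if (has_rs)
    flag_replicate_outliers(det$beta, cohort$sheet, cohort$annotation)
  else list(flagged = tibble(sample_id = character(), line_id = character()),
            skipped_lines = character())
  beta <- det$beta %>% select(-any_of(out$flagged$sample_id))
  probe_excl <- filter_probes(cohort$annotation, variants)
  beta <- beta %>% filter(!.data$probe_id %in%
                            probe_excl$probe_id[probe_excl$reason == "sex_chromosome"])
  excluded <- bind_rows(det$excluded %>% select("probe_id", "reason"),
                        probe_excl)
  svd_tab <- if (svd_k > 0) svd_confounder_scan(beta, cohort$sheet, k = svd_k)
             else tibble()
  line_beta <- average_replicates(beta, cohort$sheet)
  structure(list(
    line_beta = line_beta, beta = beta,
    report = list(efficiency = eff,
                  low_efficiency = eff$sample_id[!is.na(eff$efficiency) &
                                                   eff$efficiency < min_efficiency],
                  excluded_probes = excluded,
                  flagged_extracts = out$flagged,
                  skipped_lines = out$skipped_lines,
                  svd = svd_tab)),
    class = "qc_result")
}
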