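#' Map probes to promoter intervals
#'
#' Assigns a probe to every promoter whose interval contains its position
#' (1-based inclusive on both ends, same genome build assumed). Only
#' promoters with at least one probe are retained.
#'
#' @param annotation Probe annotation tibble.
#' @param corridor Corridor tibble (`promoter_id`, `chromosome`, `start`,
#'   `end`, ...).
#' @param contexts Probe contexts considered (default CpG, matching the
#'   corridor's RRBS-derived CpG estimates).
#' @return Tibble: `promoter_id`, `probe_id`.
#' @export
map_promoters <- function(annotation, corridor, contexts = "CpG") {
  ann <- annotation %>% filter(.data$context %in% contexts)
  if (nrow(ann) == 0 || nrow(corridor) == 0) {
    inform("empty probe set or corridor: promoter map is empty")
    return(tibble(promoter_id = character(), probe_id = character()))
  }
  purrr::map_dfr(intersect(unique(corridor$chromosome), unique(ann$chromosome)),
                 function(chr) {
    a <- ann %>% filter(.data$chromosome == chr)
    cr <- corridor %>% filter(.data$chromosome == chr)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = a$position, width = 1L),
      IRanges::IRanges(start = cr$start, end = cr$end))
    h <- as.data.frame(hits)
    tibble(promoter_id = cr$promoter_id[h$subjectHits],
           probe_id = a$probe_id[h$queryHits])
  }) %>% arrange(.data$promoter_id, .data$probe_id)
}

#' Promoter-level methylation as the median of member probes
#'
#' The median is preferred over the mean because promoters carry few array
#' probes and the median resists outlying probes. Missing probe values are
#' excluded; a promoter with no non-missing member in a sample is missing.
#'
#' @param beta Beta tibble (sample- or line-level).
#' @param map Promoter map from [map_promoters()].
#' @return Tibble: `promoter_id` plus one column per sample.
#' @export
promoter_medians <- function(beta, map) {
  if (nrow(map) == 0)
    abort("promoter map is empty", class = "cphcap_validation_error")
  samples <- beta_sample_ids(beta)
  long <- map %>%
    inner_join(beta, by = "probe_id") %>%
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "beta") %>%
    group_by(.data$promoter_id, .data$sample_id) %>%
    summarise(median_beta = if (all(is.na(.data$beta))) NA_real_
              else median(.data$beta, na.rm = TRUE), .groups = "drop")
  long %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "median_beta") %>%
    select(all_of(c("promoter_id", intersect(samples, unique(long$sample_id)))))
}

#' Reference-Corridor capture of promoter methylation estimates
#'
#' An estimate (one promoter in one sample) is captured when it lies within
#' the promoter's published `[lower, upper]` corridor, bounds inclusive. For
#' missed estimates the distance to the nearest bound is reported in
#' absolute beta units, with the fractions of missed estimates within `near`
#' of a bound (defaults 0.10 and 0.20).
#'
#' @param medians Promoter-by-sample median tibble from
#'   [promoter_medians()].
#' @param corridor Corridor tibble with `promoter_id`, `lower`, `upper`.
#' @param near Near-miss distances (absolute beta).
#' @param relative If TRUE, near-miss distances are relative to the corridor
#'   width instead of absolute.
#' @return List of class `corridor_capture`: `capture_fraction`,
#'   `n_estimates`, `per_promoter` (capture counts, zero-capture flag),
#'   `near_fractions`, `n_skipped_promoters`, `estimates` (long tibble).
#' @export
corridor_capture <- function(medians, corridor, near = c(0.10, 0.20),
                             relative = FALSE) {
  samples <- setdiff(names(medians), "promoter_id")
  skipped <- setdiff(medians$promoter_id, corridor$promoter_id)
  long <- medians %>%
    filter(.data$promoter_id %in% corridor$promoter_id) %>%
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "median_beta") %>%
    filter(!is.na(.data$median_beta)) %>%
    inner_join(corridor %>% select("promoter_id", "lower", "upper"),
               by = "promoter_id") %>%
    mutate(captured = .data$median_beta >= .data$lower &
             .data$median_beta <= .data$upper,
           miss_distance = ifelse(.data$captured, 0,
                                  pmax(.data$lower - .data$median_beta,
                                       .data$median_beta - .data$upper)),
           miss_distance = if (relative)
             .data$miss_distance / pmax(.data$upper - .data$lower, 1e-12)
           else .data$miss_distance)

  per_promoter <- long %>%
    group_by(.data$promoter_id) %>%
    summarise(n_estimates = n(), n_captured = sum(.data$captured),
              .groups = "drop") %>%
    mutate(zero_capture = .data$n_captured == 0)
  missed <- long %>% filter(!.data$captured)
  near_fractions <- setNames(
    vapply(near, function(d) if (nrow(missed)) mean(missed$miss_distance <= d)
           else NA_real_, numeric(1)),
    paste0("within_", near))
  structure(list(capture_fraction = mean(long$captured),
                 n_estimates = nrow(long),
                 per_promoter = per_promoter,
                 zero_capture_promoters = per_promoter$promoter_id[per_promoter$zero_capture],
                 near_fractions = near_fractions,
                 n_skipped_promoters = length(skipped),
                 estimates = long),
            class = "corridor_capture")
}

#' @export
print.corridor_capture <- function(x, ...) {
  cat(sprintf("<corridor_capture> %.1f%% of %d estimates captured; %d promoters capture none\n",
              100 * x$capture_fraction, x$n_estimates,
              length(x$zero_capture_promoters)))
  nf <- x$near_fractions
  cat(sprintf("  of missed estimates: %s\n",
              paste(sprintf("%.0f%% %s a bound", 100 * nf,
                            gsub("_", " ", names(nf))), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.corridor_capture <- function(x, ...) {
  bind_cols(tibble(capture_fraction = x$capture_fraction,
                   n_estimates = x$n_estimates,
                   n_zero_capture_promoters = length(x$zero_capture_promoters),
                   n_skipped_promoters = x$n_skipped_promoters),
            as_tibble(as.list(x$near_fractions)))
}

#' Coefficient of variation of promoter methylation across samples
#'
#' CV = sample standard deviation / mean of a promoter's median estimates
#' across samples; promoters with fewer than two non-missing samples, or a
#' zero mean, yield a missing CV and are flagged.
#'
#' @param medians Promoter-by-sample median tibble.
#' @return Tibble: `promoter_id`, `n`, `mean`, `sd`, `cv`, `flag`.
#' @export
promoter_cv <- function(medians) {
  samples <- setdiff(names(medians), "promoter_id")
  m <- as.matrix(medians[, samples, drop = FALSE])
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  cv <- ifelse(n < 2, NA_real_, ifelse(mu == 0, NA_real_, s / mu))
  tibble(promoter_id = medians$promoter_id, n = n, mean = mu, sd = s, cv = cv,
         flag = dplyr::case_when(n < 2 ~ "too_few_samples",
                                 mu == 0 ~ "zero_mean",
                                 TRUE ~ NA_character_))
}
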