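# Internal helpers shared across modules. A "beta tibble" is a tibble whose
# first column is `probe_id` and whose remaining columns are numeric sample
# (or line) columns of beta fractions in [0, 1].

beta_sample_ids <- function(beta) setdiff(names(beta), "probe_id")

# beta tibble -> numeric matrix with probe_id rownames
beta_as_matrix <- function(beta) {
  stopifnot(is.data.frame(beta), names(beta)[1] == "probe_id")
  m <- as.matrix(beta[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- beta$probe_id
  m
}

matrix_as_beta <- function(m) {
  out <- as_tibble(m)
  tibble::add_column(out, probe_id = rownames(m), .before = 1)
}

check_beta_values <- function(beta, what = "beta", lo = 0, hi = 1) {
  m <- beta_as_matrix(beta)
  bad <- which(!is.na(m) & (m < lo | m > hi | !is.finite(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    abort(sprintf(
      "%s value %.6g outside [%g, %g] at probe '%s', sample '%s' (%d offending cell(s))",
      what, m[i[1], i[2]], lo, hi, rownames(m)[i[1]], colnames(m)[i[2]], nrow(bad)
    ), class = "cphcap_validation_error")
  }
  invisible(beta)
}

#' Group labels for the columns of a (line-level) beta tibble
#'
#' Looks each identifier up in the sample sheet (by `line_id` when present,
#' else `sample_id`) and returns its phenotype group, named by identifier and
#' in column order — the `groups` argument expected by the testing,
#' resampling and classifier functions.
#'
#' @param sheet Sample sheet tibble.
#' @param ids Character vector of line or sample identifiers.
#' @return Named character vector of group labels.
#' @export
line_groups <- function(sheet, ids) {
  key <- if ("line_id" %in% names(sheet)) "line_id" else "sample_id"
  map <- sheet %>%
    distinct(.data[[key]], .data$group) %>%
    filter(.data[[key]] %in% ids)
  setNames(map$group, map[[key]])[ids]
}

assert_two_groups <- function(groups, levels = c("HDC", "LDC")) {
  groups <- groups[!is.na(groups)]
  n1 <- sum(groups == levels[1]); n2 <- sum(groups == levels[2])
  if (n1 < 1 || n2 < 1) {
    abort(sprintf("need members of both groups '%s' and '%s' (got %d and %d)",
                  levels[1], levels[2], n1, n2),
          class = "cphcap_config_error")
  }
  invisible(c(n1, n2))
}

# seeded RNG scope: evaluate expr with a fresh seed, restoring the caller's
# RNG state afterwards so stages do not perturb each other's streams
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# derive a per-stage substream seed below 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1103L + stage * 7919L) %% 2147483629L
}
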