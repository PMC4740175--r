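# Shared fixtures. The default discovery cohort (seed 7) and derived objects
# are expensive enough to build once and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

default_cohort <- function() {
  fixture("cohort7", function() simulate_cohort(generator_config(seed = 7)))
}

default_qc <- function() {
  fixture("qc7", function() run_qc(default_cohort(), svd_k = 6))
}

default_groups <- function() {
  lb <- default_qc()$line_beta
  line_groups(default_cohort()$sheet, setdiff(names(lb), "probe_id"))
}

cph_line_beta <- function(hipsc_only = TRUE) {
  co <- default_cohort(); qc <- default_qc()
  ids <- co$annotation$probe_id[co$annotation$context == "CpH"]
  lb <- qc$line_beta[qc$line_beta$probe_id %in% ids, ]
  if (hipsc_only) {
    g <- default_groups()
    lb <- lb[, c("probe_id", names(g)[g %in% c("HDC", "LDC")])]
  }
  lb
}

cpg_line_beta <- function() {
  co <- default_cohort(); qc <- default_qc()
  ids <- co$annotation$probe_id[co$annotation$context == "CpG"]
  g <- default_groups()
  qc$line_beta[qc$line_beta$probe_id %in% ids,
               c("probe_id", names(g)[g %in% c("HDC", "LDC")])]
}

default_fit <- function() {
  fixture("fit7", function()
    call_mvps(fit_moderated_t(cph_line_beta(), default_groups()), fdr = 0.05))
}

default_model <- function() {
  fixture("model7", function() {
    panel <- select_panel(default_fit(), k = 9, top = 200)
    derive_threshold(cph_line_beta(), panel, default_groups())
  })
}

# a small cohort for fast property loops
small_config <- function(seed, mu_hdc = 0.50, mu_ldc = 0.37, ...) {
  generator_config(n_hdc_lines = 5, n_ldc_lines = 5, n_donor_lines = 2,
                   extracts_per_line = 2, n_cph = 150, n_cpg = 80, n_rs = 20,
                   mu_hdc = mu_hdc, mu_ldc = mu_ldc, seed = seed, ...)
}

# beta tibble from a plain matrix (rows auto-named when needed)
as_beta_tbl <- function(m, probes = NULL, samples = NULL) {
  if (!is.null(probes)) rownames(m) <- probes
  if (!is.null(samples)) colnames(m) <- samples
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  tibble::add_column(out, probe_id = rownames(m), .before = 1)
}

# line-level values with an exact group mean and t-CI half-width
lines_with_ci <- function(mean, half, n = 4, prefix = "x") {
  s <- half * sqrt(n) / qt(0.975, n - 1)       # target sd
  d <- s * sqrt(3) / 2                          # sd of c(-d,-d,d,d) is 2d/sqrt(3)
  vals <- mean + c(-d, -d, d, d)
  setNames(vals, sprintf("%s%d", prefix, seq_len(n)))
}

beta_mat <- function(beta) {
  m <- as.matrix(beta[, -1])
  rownames(m) <- beta$probe_id
  m
}
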