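#' Read a probe-by-sample beta matrix
#'
#' Reads a TSV whose first column is `probe_id` and whose remaining columns
#' are per-sample methylated fractions (beta values) in \[0, 1\]. Missing
#' values are encoded as the literal `NA`.
#'
#' @param path Path to a TSV file.
#' @param what Label used in validation messages ("beta" or "detection p").
#' @return A beta tibble (`probe_id` plus one numeric column per sample).
#' @export
read_beta_matrix <- function(path, what = "beta") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "probe_id") {
    abort(sprintf("'%s': first column must be 'probe_id', got '%s'",
                  path, names(x)[1]), class = "cphcap_format_error")
  }
  if (anyDuplicated(x$probe_id))
    abort(sprintf("'%s': duplicated probe_id values", path),
          class = "cphcap_validation_error")
  check_beta_values(x, what = what)
  x
}

#' Read probe annotation
#'
#' TSV with columns `probe_id, context, chromosome, position, strand, flank6`.
#' `context` is one of CpH/CpG/rs/control; `flank6` is empty or a 6-base
#' string giving the sequence flanking the interrogated cytosine.
#'
#' @param path Path to a TSV file.
#' @return A tibble of probe annotation.
#' @export
read_probe_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         probe_id = "c", context = "c", chromosome = "c",
                         position = "i", strand = "c", flank6 = "c"))
  need <- c("probe_id", "context", "chromosome", "position", "strand", "flank6")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(sprintf("annotation missing column(s): %s", paste(miss, collapse = ", ")),
          class = "cphcap_format_error")
  x$flank6[is.na(x$flank6)] <- ""
  validate_annotation(x)
  x
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$probe_id))
    abort("annotation: duplicated probe_id", class = "cphcap_validation_error")
  bad <- ann$probe_id[!ann$context %in% c("CpH", "CpG", "rs", "control")]
  if (length(bad))
    abort(sprintf("annotation: unknown context for probe '%s'", bad[1]),
          class = "cphcap_validation_error")
  if (any(ann$position < 1, na.rm = TRUE))
    abort("annotation: position must be >= 1", class = "cphcap_validation_error")
  nb <- nchar(ann$flank6)
  bad <- ann$probe_id[!(nb == 0 | nb == 6)]
  if (length(bad))
    abort(sprintf("annotation: flank6 must be empty or 6 bases (probe '%s')", bad[1]),
          class = "cphcap_validation_error")
  invisible(ann)
}

#' Read a sample sheet
#'
#' CSV with one row per DNA extract: `sample_id, line_id, group, cell_class,
#' passage, batch, slide, array_position, sex`. `group` is LDC/HDC/donor/
#' unknown. An optional `donor_line_id` column links a derived line to its
#' donor line for epigenetic-memory analyses.
#'
#' @param path Path to a CSV file.
#' @return A tibble of per-extract metadata.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "line_id", "group")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")),
          class = "cphcap_format_error")
  if (anyDuplicated(x$sample_id))
    abort("sample sheet: duplicated sample_id", class = "cphcap_validation_error")
  bad <- unique(x$group[!x$group %in% c("LDC", "HDC", "donor", "unknown")])
  if (length(bad))
    abort(sprintf("sample sheet: unknown group '%s'", bad[1]),
          class = "cphcap_validation_error")
  x
}

#' Read Infinium-I bisulfite-conversion control intensities
#'
#' TSV with columns `sample_id, bic1..bic3, biu1..biu3` plus one or more
#' `neg*` columns of negative-control intensities (arbitrary fluorescence
#' units, green channel).
#'
#' @param path Path to a TSV file.
#' @return A tibble of control intensities.
#' @export
read_control_intensities <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", paste0("bic", 1:3), paste0("biu", 1:3))
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(sprintf("control intensities missing column(s): %s",
                  paste(miss, collapse = ", ")), class = "cphcap_format_error")
  if (!any(grepl("^neg", names(x))))
    abort("control intensities need at least one negative-control column (neg*)",
          class = "cphcap_format_error")
  if (any(as.matrix(x[, -1]) < 0, na.rm = TRUE))
    abort("control intensities must be non-negative", class = "cphcap_validation_error")
  x
}

#' Read a Reference-Corridor table
#'
#' TSV with columns `promoter_id, chromosome, start, end, lower, upper`;
#' coordinates are 1-based inclusive, bounds are beta fractions.
#'
#' @param path Path to a TSV file.
#' @param zero_based Set TRUE for BED-style half-open inputs; starts are
#'   shifted to 1-based inclusive on read.
#' @return A tibble with one row per promoter.
#' @export
read_corridor_table <- function(path, zero_based = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("promoter_id", "chromosome", "start", "end", "lower", "upper")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(sprintf("corridor table missing column(s): %s", paste(miss, collapse = ", ")),
          class = "cphcap_format_error")
  if (zero_based) x$start <- x$start + 1L
  if (any(x$start > x$end))
    abort("corridor table: start > end", class = "cphcap_validation_error")
  if (any(x$lower > x$upper | x$lower < 0 | x$upper > 1))
    abort("corridor table: require 0 <= lower <= upper <= 1",
          class = "cphcap_validation_error")
  x
}

#' Read a variant table
#'
#' Accepts either a TSV with header `chromosome, position, ref, alt` or a
#' VCF 4.x body (first five columns used; `#` lines skipped).
#'
#' @param path Path to a TSV or VCF file.
#' @return A tibble with columns chromosome, position, ref, alt.
#' @export
read_variant_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##") || startsWith(first, "#CHROM")) {
    x <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         show_col_types = FALSE, progress = FALSE)
    x <- tibble(chromosome = as.character(x[[1]]), position = as.integer(x[[2]]),
                ref = as.character(x[[4]]), alt = as.character(x[[5]]))
  } else {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("chromosome", "position", "ref", "alt")
    miss <- setdiff(need, names(x))
    if (length(miss))
      abort(sprintf("variant table missing column(s): %s", paste(miss, collapse = ", ")),
            class = "cphcap_format_error")
  }
  if (any(x$position < 1, na.rm = TRUE))
    abort("variant table: position must be >= 1", class = "cphcap_validation_error")
  x
}

#' Read and cross-validate a beta dataset
#'
#' Reads a beta matrix, probe annotation and sample sheet, checks their
#' identifiers against one another, and reorders the matrix to canonical
#' order (annotation file order for probes, sample-sheet order for samples).
#'
#' @param beta_path,annotation_path,sheet_path File paths (TSV/TSV/CSV).
#' @return A list with elements `beta`, `annotation`, `sheet` and a
#'   `validation` tibble listing dropped or mismatched records (empty when
#'   the files agree exactly).
#' @export
read_beta_dataset <- function(beta_path, annotation_path, sheet_path) {
  beta <- read_beta_matrix(beta_path)
  ann <- read_probe_annotation(annotation_path)
  sheet <- read_sample_sheet(sheet_path)

  samples <- beta_sample_ids(beta)
  missing_sheet <- setdiff(samples, sheet$sample_id)
  if (length(missing_sheet))
    abort(sprintf("sample '%s' in beta matrix absent from sample sheet",
                  missing_sheet[1]), class = "cphcap_validation_error")

  report <- tibble(record = character(), issue = character())
  extra_ann <- setdiff(ann$probe_id, beta$probe_id)
  extra_beta <- setdiff(beta$probe_id, ann$probe_id)
  extra_sheet <- setdiff(sheet$sample_id, samples)
  if (length(extra_beta))
    report <- bind_rows(report, tibble(record = extra_beta,
                                       issue = "probe in matrix but not annotation (dropped)"))
  if (length(extra_ann))
    report <- bind_rows(report, tibble(record = extra_ann,
                                       issue = "probe annotated but absent from matrix (dropped)"))
  if (length(extra_sheet))
    report <- bind_rows(report, tibble(record = extra_sheet,
                                       issue = "sample in sheet but not in matrix (kept in sheet)"))

  keep <- intersect(ann$probe_id, beta$probe_id)
  ann <- ann %>% filter(.data$probe_id %in% keep)
  beta <- beta[match(ann$probe_id, beta$probe_id),
               c("probe_id", intersect(sheet$sample_id, samples))]
  list(beta = beta, annotation = ann, sheet = sheet, validation = report)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 6))
}

#' Write dataset tables with deterministic formatting
#'
#' Writes each named object (beta tibbles, annotation, sample sheet, control
#' intensities, result tables) to `out_dir` with a fixed column order and
#' 6-decimal float formatting, so repeated writes of the same object are
#' byte-identical.
#'
#' @param objects Named list of tibbles. Names become file stems; sample
#'   sheets (`sheet`) are written as CSV, everything else as TSV.
#' @param out_dir Output directory (created if needed).
#' @return A manifest tibble: file, rows, columns.
#' @export
write_tables <- function(objects, out_dir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("cannot create output directory '%s'", out_dir),
          class = "cphcap_io_error")
  manifest <- purrr::imap(objects, function(obj, name) {
    obj <- as_tibble(obj)
    csv <- identical(name, "sheet")
    file <- file.path(out_dir, paste0(name, if (csv) ".csv" else ".tsv"))
    out <- obj %>% mutate(across(dplyr::where(is.double), fmt_num))
    if (csv) readr::write_csv(out, file, na = "NA", progress = FALSE)
    else readr::write_tsv(out, file, na = "NA", progress = FALSE)
    tibble(file = file, rows = nrow(obj), columns = ncol(obj))
  })
  bind_rows(manifest)
}
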