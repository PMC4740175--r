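#' Hierarchical clustering of cell lines on methylation profiles
#'
#' Agglomerative clustering of the line columns over a probe subset
#' (typically the significant MVPs). Columns are ordered lexicographically by
#' line id before clustering so ties in the merge sequence resolve
#' deterministically.
#'
#' @param line_beta Line-level beta tibble.
#' @param probe_subset Optional character vector of probe ids (NULL = all).
#' @param distance "euclidean" or "manhattan".
#' @param linkage "average", "complete", "single" or "ward.D2".
#' @return Object of class `cluster_result`: the `hclust` tree, `leaf_order`
#'   and the inputs used.
#' @export
cluster_lines <- function(line_beta, probe_subset = NULL,
                          distance = c("euclidean", "manhattan"),
                          linkage = c("average", "complete", "single", "ward.D2")) {
  distance <- tryCatch(match.arg(distance),
                       error = function(e) abort("unsupported distance",
                                                 class = "cphcap_config_error"))
  linkage <- tryCatch(match.arg(linkage),
                      error = function(e) abort("unsupported linkage",
                                                class = "cphcap_config_error"))
  if (!is.null(probe_subset))
    line_beta <- line_beta %>% filter(.data$probe_id %in% probe_subset)
  if (nrow(line_beta) == 0)
    abort("probe subset is empty", class = "cphcap_validation_error")
  m <- beta_as_matrix(line_beta)
  if (ncol(m) < 3)
    abort("need >= 3 lines to cluster", class = "cphcap_config_error")
  m <- m[, order(colnames(m)), drop = FALSE]
  tree <- hclust(dist(t(m), method = distance), method = linkage)
  structure(list(tree = tree, leaf_order = tree$labels[tree$order],
                 distance = distance, linkage = linkage,
                 n_probes = nrow(m)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d lines on %d probes (%s distance, %s linkage)\n",
              length(x$leaf_order), x$n_probes, x$distance, x$linkage))
  invisible(x)
}

#' Clade purity and adjusted Rand index at a k-cluster cut
#'
#' Cuts the dendrogram into `k` clusters and evaluates agreement with known
#' labels: per class, the fraction of members falling in that class's
#' majority cluster; overall, the fraction of lines in their cluster's
#' majority class (agreement) and the adjusted Rand index.
#'
#' @param result A `cluster_result`.
#' @param labels Named character vector of class labels per line id.
#' @param k Number of clusters to cut.
#' @return List of class `clade_purity`: `assignments` tibble, `per_class`
#'   purity, `agreement`, `ari`, `k`.
#' @export
clade_purity <- function(result, labels, k = 3) {
  stopifnot(inherits(result, "cluster_result"))
  if (k > length(result$tree$labels))
    abort("k exceeds the number of lines", class = "cphcap_config_error")
  cl <- cutree(result$tree, k = k)
  lab <- labels[names(cl)]
  if (length(unique(lab[!is.na(lab)])) < 2)
    abort("need labels for >= 2 classes", class = "cphcap_config_error")
  assignments <- tibble(line_id = names(cl), cluster = unname(cl),
                        label = unname(lab))
  per_class <- assignments %>%
    filter(!is.na(.data$label)) %>%
    group_by(.data$label) %>%
    summarise(n = n(),
              purity = max(table(.data$cluster)) / n(), .groups = "drop")
  agreement <- assignments %>%
    filter(!is.na(.data$label)) %>%
    group_by(.data$cluster) %>%
    summarise(hits = max(table(.data$label)), n = n(), .groups = "drop")
  ok <- !is.na(lab)
  list(assignments = assignments,
       per_class = per_class,
       agreement = sum(agreement$hits) / sum(agreement$n),
       ari = mclust::adjustedRandIndex(cl[ok], lab[ok]),
       k = k) -> out
  structure(out, class = "clade_purity")
}

#' @exportS3Method generics::glance
glance.clade_purity <- function(x, ...) {
  tibble(k = x$k, agreement = x$agreement, ari = x$ari)
}

#' @exportS3Method generics::tidy
tidy.clade_purity <- function(x, ...) x$assignments
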