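#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene cluster
#' and an annotated gene set: the probability of drawing at least the
#' observed number of annotated genes when `n = |cluster|` genes are drawn
#' without replacement from a universe of `M` genes of which `K_set` are
#' annotated. The tail sum is exact.
#'
#' @param cluster Character vector of gene ids (the cluster).
#' @param annotated Character vector of gene ids (the gene set).
#' @param universe Character vector of all analyzed gene ids.
#' @return The p-value `P(X >= x)`.
#' @export
hypergeom_enrichment <- function(cluster, annotated, universe) {
  cluster <- unique(cluster); annotated <- unique(annotated)
  universe <- unique(universe)
  abort_if(!all(cluster %in% universe) || !all(annotated %in% universe),
           "cluster and annotated sets must be subsets of the universe")
  M <- length(universe)
  x <- length(intersect(cluster, annotated))
  phyper(x - 1, length(annotated), M - length(annotated), length(cluster),
         lower.tail = FALSE)
}

#' Pearson chi-square gene-set enrichment
#'
#' Tests independence between cluster membership and target-set membership
#' on the 2x2 contingency table (in/out of cluster x target/non-target)
#' with the Pearson statistic, no continuity correction, against the
#' 1-df chi-square upper tail. Used for transcription-factor target sets.
#'
#' @param targets Character vector of target gene ids.
#' @param cluster Character vector of cluster gene ids.
#' @param universe Character vector of all analyzed gene ids.
#' @return Tibble with `statistic`, `p_value`, and `flagged` (TRUE when an
#'   expected cell count is zero and the test is skipped).
#' @export
chisq_enrichment <- function(targets, cluster, universe) {
  targets <- unique(targets); cluster <- unique(cluster)
  universe <- unique(universe)
  abort_if(!all(targets %in% universe) || !all(cluster %in% universe),
           "targets and cluster must be subsets of the universe")
  in_c <- universe %in% cluster
  in_t <- universe %in% targets
  tab <- table(factor(in_c, c(TRUE, FALSE)), factor(in_t, c(TRUE, FALSE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          flagged = TRUE))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value), flagged = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up or Bonferroni correction, preserving input
#' order; adjusted values are clipped to `[0, 1]`.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(pvalues, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  abort_if(any(pvalues < 0 | pvalues > 1, na.rm = TRUE),
           "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
}

#' Cluster-by-set enrichment matrix
#'
#' Tests every factor cluster against every gene set, adjusts the p-values
#' jointly across all cells, and reports the significant cells.
#'
#' The universe is the set of genes in the cluster assignment (the
#' analyzed corpus), and gene sets are intersected with it on entry.
#'
#' @param clusters Either the tibble from [assign_clusters()] or a named
#'   list of gene-id vectors (e.g. top-gene lists per factor).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param test `"hypergeom"` or `"chisq"`.
#' @param alpha Significance level applied to adjusted p-values.
#' @param adjust Correction method passed to [adjust_pvalues()].
#' @param universe Optional explicit universe; defaults to all genes in
#'   `clusters`.
#' @return Tibble with one row per (set, cluster): `set`, `cluster`,
#'   `overlap`, `p_value`, `p_adjusted`, `significant`; rows ordered by
#'   set name then cluster. The applied test/adjustment/alpha are attached
#'   as attributes.
#' @export
enrichment_matrix <- function(clusters, sets, test = c("hypergeom", "chisq"),
                              alpha = 0.05, adjust = c("bh", "bonferroni"),
                              universe = NULL) {
  test <- match.arg(test); adjust <- match.arg(adjust)
  abort_if(length(sets) == 0, "need at least one gene set")
  if (is.data.frame(clusters)) {
    cl <- clusters[!is.na(clusters$factor), ]
    cluster_list <- split(cl$gene_id, cl$factor)
    if (is.null(universe)) universe <- unique(clusters$gene_id)
  } else {
    cluster_list <- clusters
    if (is.null(universe)) universe <- unique(unlist(clusters))
  }
  abort_if(length(cluster_list) == 0, "no non-empty clusters")
  sets <- lapply(sets, intersect, y = universe)
  grid <- tidyr::expand_grid(set = names(sets),
                             cluster = names(cluster_list))
  res <- purrr::pmap_dfr(grid, function(set, cluster) {
    cl_genes <- intersect(cluster_list[[cluster]], universe)
    ov <- length(intersect(cl_genes, sets[[set]]))
    if (test == "hypergeom") {
      p <- hypergeom_enrichment(cl_genes, sets[[set]], universe)
      tibble::tibble(set = set, cluster = cluster, overlap = ov,
                     statistic = NA_real_, p_value = p)
    } else {
      ct <- chisq_enrichment(sets[[set]], cl_genes, universe)
      tibble::tibble(set = set, cluster = cluster, overlap = ov,
                     statistic = ct$statistic, p_value = ct$p_value)
    }
  })
  res$p_adjusted <- adjust_pvalues(res$p_value, adjust)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res <- dplyr::arrange(res, .data$set, .data$cluster)
  attr(res, "test") <- test
  attr(res, "adjust") <- adjust
  attr(res, "alpha") <- alpha
  res
}

#' Read / write gene sets in GMT format
#'
#' GMT is one set per line: set name, description, then tab-separated gene
#' ids.
#'
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "spexfa") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
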