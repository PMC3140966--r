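#' Pool image-level loadings to gene level
#'
#' A gene is usually represented by several images; downstream cluster and
#' enrichment analyses work at gene level, so the image rows of the
#' loading matrix are reduced per gene. The default reducer is the
#' element-wise mean; `"maxabs"` keeps, per factor, the signed value of
#' largest magnitude across the gene's images.
#'
#' @param fit A `sbfa_fit` carrying image metadata, or a loading matrix
#'   (then supply `meta`).
#' @param reducer `"mean"` or `"maxabs"`.
#' @param meta Tibble with `image_id`, `gene_id` when `fit` is a matrix.
#' @return `G x K` matrix with gene ids as rownames.
#' @export
gene_loadings <- function(fit, reducer = c("mean", "maxabs"), meta = NULL) {
  reducer <- match.arg(reducer)
  if (inherits(fit, "sbfa_fit")) {
    meta <- fit$meta
    Lambda <- fit$Lambda
  } else Lambda <- as.matrix(fit)
  abort_if(is.null(meta), "need image metadata (gene_id per image row)")
  abort_if(nrow(Lambda) != nrow(meta), "loading rows must match metadata")
  genes <- unique(meta$gene_id)
  out <- t(vapply(genes, function(g) {
    rows <- Lambda[meta$gene_id == g, , drop = FALSE]
    if (reducer == "mean") colMeans(rows)
    else rows[cbind(max.col(t(abs(rows)), ties.method = "first"),
                    seq_len(ncol(rows)))]
  }, numeric(ncol(Lambda))))
  rownames(out) <- genes
  out
}

#' Assign genes to factor clusters by dominant loading
#'
#' Each gene is assigned to the factor on which it has the largest
#' absolute loading — the factors act as cluster centroids. Ties go to the
#' lowest factor index; all-zero rows are left unassigned.
#'
#' @param Lambda_gene `G x K` gene-level loading matrix (see
#'   [gene_loadings()]).
#' @return Tibble with `gene_id`, `factor` (NA when unassigned) and
#'   `loading` (the winning signed loading).
#' @export
assign_clusters <- function(Lambda_gene) {
  abort_if(nrow(Lambda_gene) < 1, "need at least one gene")
  genes <- rownames(Lambda_gene)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(Lambda_gene)))
  winner <- max.col(abs(Lambda_gene), ties.method = "first")
  win_val <- unname(Lambda_gene[cbind(seq_len(nrow(Lambda_gene)), winner)])
  all_zero <- unname(rowSums(abs(Lambda_gene)) == 0)
  tibble::tibble(
    gene_id = genes,
    factor = ifelse(all_zero, NA_integer_, winner),
    loading = ifelse(all_zero, NA_real_, win_val)
  )
}

#' Informative factor set of a loading row
#'
#' Under the model's sparsity assumption, a gene's pattern is driven by the
#' few factors whose loadings come close to its largest one: all entries
#' with `|loading| >= (1 - tau) * max |loading|` are called informative.
#'
#' @param loading_row Numeric length-K vector.
#' @param tau Fraction in `[0, 1)`; `tau = 0` keeps only the argmax set.
#' @return Integer vector of informative factor indices (empty for an
#'   all-zero row).
#' @export
informative_entries <- function(loading_row, tau = 0.1) {
  abort_if(tau < 0 || tau >= 1, "tau must be in [0, 1)")
  m <- max(abs(loading_row))
  if (m == 0) return(integer(0))
  which(abs(loading_row) >= (1 - tau) * m)
}

#' Cluster link graph from shared informative genes
#'
#' Two factor clusters are linked when genes carry informative loadings on
#' both factors; the edge weight counts those shared genes.
#'
#' @param Lambda_gene `G x K` gene-level loading matrix.
#' @param tau Informative-entry fraction (see [informative_entries()]).
#' @return Tibble of edges: `factor_a < factor_b`, `n_shared > 0`.
#' @export
cluster_links <- function(Lambda_gene, tau = 0.1) {
  K <- ncol(Lambda_gene)
  counts <- matrix(0L, K, K)
  for (g in seq_len(nrow(Lambda_gene))) {
    inf <- informative_entries(Lambda_gene[g, ], tau)
    if (length(inf) > 1) {
      pairs <- utils::combn(inf, 2)
      for (q in seq_len(ncol(pairs)))
        counts[pairs[1, q], pairs[2, q]] <- counts[pairs[1, q], pairs[2, q]] + 1L
    }
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  tibble::tibble(
    factor_a = unname(idx[, 1]), factor_b = unname(idx[, 2]),
    n_shared = counts[idx]
  ) |> dplyr::arrange(.data$factor_a, .data$factor_b)
}

#' Top-loading genes of a factor
#'
#' @param Lambda_gene `G x K` gene-level loading matrix.
#' @param factor Factor index (1-based).
#' @param q Number of genes to return (`1 <= q <= G`).
#' @return Character vector of `q` gene ids, by descending absolute
#'   loading; ties broken lexicographically by gene id.
#' @export
top_genes <- function(Lambda_gene, factor, q = 50) {
  G <- nrow(Lambda_gene)
  abort_if(q < 1 || q > G, "q must be between 1 and the number of genes")
  genes <- rownames(Lambda_gene)
  if (is.null(genes)) genes <- as.character(seq_len(G))
  ord <- order(-abs(Lambda_gene[, factor]), genes)
  genes[ord][seq_len(q)]
}

#' Filter non-informative images by loading-row norm
#'
#' Images whose whole loading row sits near the null vector use no factor
#' appreciably — in real corpora these are mostly failed stainings or
#' ubiquitous (maternal) expression. The Euclidean norm of each image's
#' loading row is compared against a threshold; rows at exactly the
#' threshold are kept.
#'
#' @param fit A `sbfa_fit`, or an `N x K` loading matrix.
#' @param threshold Non-negative norm cutoff; see [valley_threshold()] for
#'   a data-driven choice.
#' @return Tibble with `image_id`, `norm`, `kept`.
#' @export
filter_images <- function(fit, threshold) {
  abort_if(threshold < 0, "threshold must be >= 0")
  Lambda <- if (inherits(fit, "sbfa_fit")) fit$Lambda else as.matrix(fit)
  ids <- rownames(Lambda)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Lambda)))
  norms <- unname(sqrt(rowSums(Lambda^2)))
  tibble::tibble(image_id = ids, norm = norms, kept = norms >= threshold)
}

#' Histogram-valley threshold for the image filter
#'
#' Picks the separating norm value between the non-informative mode (norms
#' near zero) and the informative mode: the minimum of a kernel density
#' estimate between the two largest modes.
#'
#' @param norms Numeric vector of loading-row norms.
#' @return A single threshold value.
#' @export
valley_threshold <- function(norms) {
  abort_if(length(norms) < 2 || max(norms) <= 0,
           "need at least two norms with a positive maximum")
  # non-informative rows sit orders of magnitude below informative ones,
  # so the histogram is bimodal on the log scale; take the density
  # minimum between the two highest log-scale modes
  eps <- max(norms) * 1e-6
  z <- log10(norms + eps)
  dens <- density(z, n = 512)
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2) return(unname(10^quantile(z, 0.2)))
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  10^dens$x[valley] - eps
}
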