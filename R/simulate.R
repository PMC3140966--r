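#' Spatial factor templates
#'
#' Builds prototype spatial expression templates on a grid, mimicking the
#' canonical lateral-view pattern classes of the early embryo: anterior or
#' posterior half-domains, dorsal/ventral bands, pair-rule-like stripes
#' along the anterior-posterior axis, and a shape template (the embryo
#' outline itself, standing in for the non-expression factors a factor
#' model discovers in real corpora). All templates live inside an
#' elliptical embryo mask and are returned as unit-L2-norm row-major image
#' vectors.
#'
#' @param kinds Character vector drawn from `"anterior"`, `"posterior"`,
#'   `"dorsal_band"`, `"ventral_band"`, `"ap_stripes"`, `"shape_artifact"`.
#'   Repeats are allowed (stripes get an increasing number of periods).
#' @param n_rows,n_cols Grid dimensions (at least 4 x 4).
#' @return A `length(kinds) x (n_rows * n_cols)` matrix; each row has unit
#'   L2 norm.
#' @export
spatial_templates <- function(kinds, n_rows = 20, n_cols = 40) {
  abort_if(n_rows < 4 || n_cols < 4, "grid must be at least 4 x 4")
  known <- c("anterior", "posterior", "dorsal_band", "ventral_band",
             "ap_stripes", "shape_artifact")
  bad <- setdiff(kinds, known)
  abort_if(length(bad) > 0,
           paste0("unknown template kind(s): ", paste(bad, collapse = ", ")))
  # elliptical embryo mask; row = dorsal-ventral axis, col = A-P axis
  rc <- (seq_len(n_rows) - (n_rows + 1) / 2) / (n_rows / 2)
  cc <- (seq_len(n_cols) - (n_cols + 1) / 2) / (n_cols / 2)
  mask <- outer(rc, cc, function(y, x) (x^2 + y^2 <= 1) * 1)
  n_stripe_seen <- 0L
  templates <- lapply(kinds, function(kind) {
    img <- switch(kind,
      anterior  = mask * outer(rep(1, n_rows), cc <= 0),
      posterior = mask * outer(rep(1, n_rows), cc > 0),
      dorsal_band  = mask * outer(rc <= -0.25, rep(1, n_cols)),
      ventral_band = mask * outer(rc >= 0.25, rep(1, n_cols)),
      ap_stripes = {
        n_stripe_seen <<- n_stripe_seen + 1L
        periods <- 3 + n_stripe_seen
        mask * outer(rep(1, n_rows), (sin(pi * periods * cc) > 0) * 1)
      },
      shape_artifact = mask
    )
    v <- as.vector(t(img))                 # row-major
    v / sqrt(sum(v^2))
  })
  out <- do.call(rbind, templates)
  rownames(out) <- make.unique(kinds)
  out
}

#' Sparse loading matrix with planted zeros
#'
#' Each entry is exactly zero with probability `sparsity` and otherwise a
#' zero-mean normal draw, emulating the sparse mixing-weight structure the
#' Student-t prior induces.
#'
#' @param n_images,k Matrix dimensions.
#' @param sparsity Probability of an exact zero, in `[0, 1)`.
#' @param scale Standard deviation of the nonzero entries.
#' @param seed Integer seed; the draw is reproducible.
#' @return `n_images x k` numeric matrix.
#' @export
sample_sparse_loadings <- function(n_images, k, sparsity = 0.8, scale = 1,
                                   seed = 1) {
  abort_if(sparsity < 0 || sparsity >= 1, "sparsity must be in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- matrix(rnorm(n_images * k, sd = scale), n_images, k)
  z * (matrix(runif(n_images * k), n_images, k) >= sparsity)
}

# save/restore global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an image corpus with known factor structure
#'
#' Generates a corpus with exactly the statistical structure the factor
#' model assumes: `X = Lambda F + E`, where `F` holds spatial templates,
#' `Lambda` is sparse, and `E` is Gaussian with precision set so that the
#' signal-to-noise ratio `var(Lambda F) * psi` equals `snr`. Every gene is
#' represented by `images_per_gene` replicate images sharing the gene's
#' loading row; optionally a fraction of images is made non-informative
#' (loading row zeroed — pure noise, emulating failed stainings).
#'
#' @param n_genes Number of genes.
#' @param images_per_gene Replicate images per gene.
#' @param k Number of factors; templates are recycled from the six stock
#'   kinds if `k > 6`.
#' @param n_rows,n_cols Feature grid (default 20 x 40, P = 800).
#' @param sparsity Fraction of exact zeros in the gene loading matrix.
#' @param snr Signal-to-noise ratio `var(signal) / var(noise)`; the implied
#'   reconstruction R-squared is `snr / (1 + snr)`.
#' @param loading_scale Standard deviation of nonzero loadings.
#' @param prop_noninformative Fraction of images whose loading row is
#'   zeroed (drawn at random across images).
#' @param seed Integer seed; the corpus is bit-reproducible.
#' @return A `spexfa_corpus`: list with `fm` (centered `spexfa_features`),
#'   `truth` (list: `Lambda_true` N x k image-level loadings, `Lambda_gene`
#'   G x k, `F_true`, `psi_true`, `noninformative` image ids, `sparsity`,
#'   `snr`, `seed`), plus `meta`.
#' @export
simulate_corpus <- function(n_genes = 100, images_per_gene = 2, k = 6,
                            n_rows = 20, n_cols = 40, sparsity = 0.8,
                            snr = 10, loading_scale = 1,
                            prop_noninformative = 0, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  # default template set is linearly independent after row-centering
  # (anterior + posterior = shape_artifact, so the shape template is
  # replaced by a second stripe factor to keep the truth identifiable)
  kinds <- rep_len(c("anterior", "posterior", "dorsal_band", "ventral_band",
                     "ap_stripes", "ap_stripes"), k)
  F_true <- spatial_templates(kinds, n_rows, n_cols)
  # nonzero loadings are half-normal (positive): stain accumulates, so an
  # image uses a template additively or not at all; this also keeps
  # planted |loading|-threshold terms one-sided and hence learnable by a
  # linear classifier
  Lambda_gene <- abs(sample_sparse_loadings(n_genes, k, sparsity,
                                            loading_scale, seed = seed))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  rownames(Lambda_gene) <- gene_ids
  N <- n_genes * images_per_gene
  gene_col <- rep(gene_ids, each = images_per_gene)
  meta <- tibble::tibble(
    image_id = sprintf("%s_im%d", gene_col,
                       rep(seq_len(images_per_gene), n_genes)),
    gene_id  = gene_col
  )
  Lambda_true <- Lambda_gene[meta$gene_id, , drop = FALSE]
  rownames(Lambda_true) <- meta$image_id

  set.seed(seed + 1L)
  noninformative <- character(0)
  if (prop_noninformative > 0) {
    n_drop <- round(prop_noninformative * N)
    idx <- sample.int(N, n_drop)
    Lambda_true[idx, ] <- 0
    noninformative <- meta$image_id[idx]
  }
  signal <- Lambda_true %*% F_true
  # SNR is defined on the centered signal — what the model actually sees —
  # so the implied reconstruction R2 is snr / (1 + snr)
  psi <- snr / stats::var(as.vector(signal - rowMeans(signal)))
  P <- n_rows * n_cols
  E <- matrix(rnorm(N * P, sd = 1 / sqrt(psi)), N, P)
  X <- signal + E
  fm <- new_spexfa_features(X, meta, c(n_rows, n_cols), centered = FALSE)
  fm <- center_patterns(fm)
  structure(
    list(
      fm = fm, meta = meta,
      truth = list(Lambda_true = Lambda_true, Lambda_gene = Lambda_gene,
                   F_true = F_true, psi_true = rep(psi, P),
                   noninformative = noninformative, sparsity = sparsity,
                   snr = snr, seed = seed)
    ),
    class = "spexfa_corpus"
  )
}

#' @export
print.spexfa_corpus <- function(x, ...) {
  cat(sprintf(
    "<spexfa_corpus: %d images, %d genes, %d factors, grid %d x %d, snr %.3g>\n",
    nrow(x$fm$X), nrow(x$truth$Lambda_gene), nrow(x$truth$F_true),
    x$fm$grid[1], x$fm$grid[2], x$truth$snr))
  invisible(x)
}

#' Materialize corpus rows as raster images
#'
#' Un-flattens each feature row to its grid shape and maps intensities
#' affinely to `[0, 1]` with one corpus-wide range (so relative intensity
#' between images survives the mapping). With a one-pixel-per-patch grid,
#' [grid_features()] on these images recovers the mapped feature rows
#' exactly.
#'
#' @param corpus A `spexfa_corpus`.
#' @return List of `spexfa_image` objects.
#' @export
corpus_images <- function(corpus) {
  rng <- range(corpus$fm$X)
  grid <- corpus$fm$grid
  purrr::map2(seq_len(nrow(corpus$fm$X)), corpus$meta$image_id, function(i, id) {
    img <- matrix(corpus$fm$X[i, ], grid[1], grid[2], byrow = TRUE)
    img <- (img - rng[1]) / (rng[2] - rng[1])
    new_spexfa_image(img, id, corpus$meta$gene_id[i])
  })
}

#' Derive annotation labels from ground-truth loadings
#'
#' Plants gene-level annotation terms from the true loading matrix: a gene
#' carries a term when the absolute loading on the term's factor exceeds
#' the threshold. All images of a gene inherit its terms.
#'
#' @param truth The `truth` element of a [simulate_corpus()] result.
#' @param term_rules Named list mapping term name to `c(factor, threshold)`
#'   (1-based factor index).
#' @return Tibble with columns `gene_id`, `term`.
#' @export
derive_labels <- function(truth, term_rules) {
  K <- ncol(truth$Lambda_gene)
  rows <- purrr::imap(term_rules, function(rule, term) {
    kf <- as.integer(rule[1]); thr <- as.numeric(rule[2])
    abort_if(kf < 1 || kf > K, "term rule factor index out of range")
    pos <- rownames(truth$Lambda_gene)[abs(truth$Lambda_gene[, kf]) > thr]
    if (length(pos)) tibble::tibble(gene_id = pos, term = term) else NULL
  })
  dplyr::bind_rows(rows)
}

#' Plant enriched gene sets from ground-truth loadings
#'
#' For every factor, builds a gene set containing a fraction of that
#' factor's top-loading genes plus random background genes, giving each
#' factor's cluster a known most-enriched set for testing enrichment
#' analyses.
#'
#' @param truth The `truth` element of a [simulate_corpus()] result.
#' @param per_factor_overlap Fraction in `(0, 1]` of each factor's top
#'   genes included in its set.
#' @param background_size Number of random background genes added per set.
#' @param top_q How many top-loading genes define a factor's gene group.
#' @param seed Integer seed for the background draws.
#' @return Named list of character vectors (sets `set_f1`, `set_f2`, ...).
#' @export
plant_gene_sets <- function(truth, per_factor_overlap = 1,
                            background_size = 10, top_q = 20, seed = 1) {
  abort_if(per_factor_overlap <= 0 || per_factor_overlap > 1,
           "per_factor_overlap must be in (0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- rownames(truth$Lambda_gene)
  K <- ncol(truth$Lambda_gene)
  sets <- lapply(seq_len(K), function(kf) {
    top <- genes[order(-abs(truth$Lambda_gene[, kf]), genes)][seq_len(top_q)]
    core <- top[seq_len(max(1L, round(per_factor_overlap * top_q)))]
    bg <- sample(setdiff(genes, core), min(background_size,
                                           length(genes) - length(core)))
    sort(unique(c(core, bg)))
  })
  names(sets) <- sprintf("set_f%d", seq_len(K))
  sets
}

#' Write a synthetic corpus to disk
#'
#' Writes the feature matrix (TSV via [write_features()]), truth arrays
#' (TSV), labels (TSV) and, optionally, per-image PNG renderings. Raster
#' intensities are mapped affinely to `[0, 1]` using one corpus-wide range
#' so relative intensities between images are preserved.
#'
#' @param corpus A `spexfa_corpus`.
#' @param dir Output directory (created if missing).
#' @param labels Optional tibble from [derive_labels()].
#' @param gene_sets Optional named list from [plant_gene_sets()].
#' @param png Logical; also write one PNG per image.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, labels = NULL, gene_sets = NULL,
                         png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_features(corpus$fm, file.path(dir, "X.tsv"))
  wt <- function(m, f) write.table(m, file.path(dir, f), sep = "\t",
                                   quote = FALSE, col.names = NA)
  wt(corpus$truth$Lambda_true, "Lambda_true.tsv")
  wt(corpus$truth$F_true, "F_true.tsv")
  if (!is.null(labels))
    write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(gene_sets))
    write_gmt(gene_sets, file.path(dir, "sets.gmt"))
  if (png) {
    rng <- range(corpus$fm$X)
    grid <- corpus$fm$grid
    for (i in seq_len(nrow(corpus$fm$X))) {
      img <- matrix(corpus$fm$X[i, ], grid[1], grid[2], byrow = TRUE)
      img <- (img - rng[1]) / (rng[2] - rng[1])
      png::writePNG(img, file.path(dir, paste0(corpus$meta$image_id[i], ".png")))
    }
  }
  invisible(dir)
}
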