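#' Sparse Bayesian factor analysis by Gibbs sampling
#'
#' Fits the factor model `X = Lambda F + E` to a centered image-by-feature
#' matrix. Rows of `F` (K x P) are latent spatial templates with standard
#' normal entries a priori; entries of `Lambda` (N x K) are the mixing
#' weights, each with a normal prior whose precision `alpha_nk` carries a
#' Gamma(a, rate b) hyperprior — marginally a Student-t, which shrinks most
#' weights towards zero. The noise is Gaussian with per-feature precision
#' `psi_p ~ Gamma(c, rate d)` (or one pooled precision with
#' `psi_mode = "scalar"`). All four conditionals are conjugate and the
#' sampler cycles them in the fixed order F, Lambda, alpha, psi.
#'
#' Posterior summaries are plain arithmetic means of the post-burn-in
#' sweeps. The per-sweep reconstruction mean squared error is recorded as
#' a convergence trace.
#'
#' @param fm A centered `spexfa_features` object (see [feature_matrix()]),
#'   or a plain centered numeric matrix.
#' @param k Number of factors.
#' @param a,b Shape and rate of the Gamma hyperprior on loading precisions.
#'   The defaults make the marginal Student-t sharply discriminate zero
#'   from nonzero loadings: the prior's discrimination scale `sqrt(2b)`
#'   must sit well below the magnitude of a typical nonzero loading, or
#'   the posterior cannot break the rotational invariance of the
#'   likelihood and factors come out mixed.
#' @param c,d Shape and rate of the Gamma prior on noise precisions.
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before averaging (`burn_in < n_iter`).
#' @param seed Integer seed; runs are bit-reproducible.
#' @param psi_mode `"feature"` for a per-feature noise precision vector,
#'   `"scalar"` for one pooled precision.
#' @param normalize_factors Report factor rows with unit L2 norm, moving
#'   the (arbitrary) scale split into the loadings. `FALSE` returns the
#'   raw arithmetic means of the retained samples.
#' @return A `sbfa_fit` object: list with posterior means `Lambda` (N x K,
#'   rownames = image ids) and `F` (k x P), the final `state`, `trace`
#'   tibble (iteration, mse), dimensions, hyperparameters, `grid`, `meta`
#'   and `seed`.
#' @export
sbfa <- function(fm, k, a = 0.5, b = 1e-10, c = 1e-3, d = 1e-3,
                 n_iter = 1000, burn_in = 300, seed = 1,
                 psi_mode = c("feature", "scalar"), normalize_factors = TRUE) {
  psi_mode <- match.arg(psi_mode)
  abort_if(burn_in >= n_iter, "burn_in must be smaller than n_iter")
  abort_if(k < 1, "k must be >= 1")
  meta <- NULL; grid <- NULL
  if (inherits(fm, "spexfa_features")) {
    abort_if(!fm$centered, "feature matrix must be centered (see center_patterns)")
    meta <- fm$meta; grid <- fm$grid
    X <- fm$X
  } else {
    X <- as.matrix(fm)
    abort_if(max(abs(rowMeans(X))) > 1e-8,
             "feature matrix must be centered (row means ~ 0)")
  }
  hp <- list(k = as.integer(k), a = a, b = b, c = c, d = d)
  abort_if(any(unlist(hp[c("a", "b", "c", "d")]) <= 0),
           "hyperparameters must be strictly positive")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  state <- init_state(X, hp)
  N <- nrow(X); P <- ncol(X)
  Lambda_sum <- matrix(0, N, k)
  F_sum <- matrix(0, k, P)
  mse <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    state$F <- sample_factor_columns(state, X)
    state$Lambda <- sample_loading_rows(state, X)
    state$alpha <- sample_loading_precisions(state, hp)
    state$psi <- sample_noise_precisions(state, X, hp, psi_mode)
    resid <- X - state$Lambda %*% state$F
    mse[it] <- mean(resid^2)
    if (!is.finite(mse[it]) || !all(is.finite(state$psi)))
      stop("sampler diverged (non-finite state) at iteration ", it,
           call. = FALSE)
    if (it > burn_in) {
      Lambda_sum <- Lambda_sum + state$Lambda
      F_sum <- F_sum + state$F
    }
  }
  n_keep <- n_iter - burn_in
  Lambda_mean <- Lambda_sum / n_keep
  F_mean <- F_sum / n_keep
  if (normalize_factors) {
    # move the arbitrary scale split into the loadings: factor rows are
    # reported unit-L2-norm so loadings are comparable across factors and
    # runs; the reconstruction Lambda F is unchanged
    nrm <- sqrt(rowSums(F_mean^2))
    nrm[nrm == 0] <- 1
    F_mean <- F_mean / nrm
    Lambda_mean <- Lambda_mean * rep(nrm, each = N)
  }
  if (!is.null(meta)) rownames(Lambda_mean) <- meta$image_id
  structure(
    list(Lambda = Lambda_mean, F = F_mean, state = state,
         trace = tibble::tibble(iteration = seq_len(n_iter), mse = mse),
         n_iter = n_iter, burn_in = burn_in, seed = seed,
         hyperparams = hp, psi_mode = psi_mode, grid = grid, meta = meta),
    class = "sbfa_fit"
  )
}

# Initial state: F ~ N(0,1), Lambda ~ N(0, 0.01); precisions at their
# prior means a/b and c/d. Draws come from the current RNG stream.
init_state <- function(X, hp) {
  N <- nrow(X); P <- ncol(X); k <- hp$k
  list(
    Lambda = matrix(rnorm(N * k, sd = 0.1), N, k),
    F = matrix(rnorm(k * P), k, P),
    alpha = matrix(hp$a / hp$b, N, k),
    psi = rep(hp$c / hp$d, P)
  )
}

# Gaussian conditional for the factor matrix: column p of F has
# covariance (I_K + psi_p Lambda'Lambda)^-1 and mean
# psi_p Sigma_p Lambda' x_p. All P columns are drawn at once through the
# eigendecomposition Lambda'Lambda = Q D Q'.
sample_factor_columns <- function(state, X) {
  k <- ncol(state$Lambda); P <- ncol(X)
  S <- crossprod(state$Lambda)
  eg <- eigen(S, symmetric = TRUE)
  Q <- eg$vectors
  dvals <- pmax(eg$values, 0)
  W <- 1 / (1 + outer(dvals, state$psi))          # k x P: 1/(1 + psi_p d_i)
  M <- crossprod(Q, crossprod(state$Lambda, X))    # Q' Lambda' X
  mu <- Q %*% (W * M * rep(state$psi, each = k))
  Z <- matrix(rnorm(k * P), k, P)
  mu + Q %*% (sqrt(W) * Z)
}

# Gaussian conditional for the loading rows: row n of Lambda has
# covariance (diag(alpha_n) + F Psi F')^-1 and mean Sigma_n F Psi x_n.
sample_loading_rows <- function(state, X) {
  N <- nrow(X); k <- nrow(state$F)
  Fp <- state$F * rep(state$psi, each = k)         # F Psi
  G <- tcrossprod(Fp, state$F)                     # F Psi F'
  B <- tcrossprod(Fp, X)                           # k x N, col n = F Psi x_n
  Z <- matrix(rnorm(N * k), k, N)
  Lambda <- matrix(0, N, k)
  for (n in seq_len(N)) {
    A <- G
    diag(A) <- diag(A) + state$alpha[n, ]
    R <- tryCatch(chol(A), error = function(e) {
      message("jittering singular conditional precision (row ", n, ")")
      chol(A + diag(1e-10, k))
    })
    mu <- backsolve(R, forwardsolve(t(R), B[, n]))
    Lambda[n, ] <- mu + backsolve(R, Z[, n])
  }
  Lambda
}

# Conjugate Gamma update for the loading precisions:
# alpha_nk ~ Gamma(a + 1/2, rate b + lambda_nk^2 / 2).
sample_loading_precisions <- function(state, hp) {
  L <- state$Lambda
  matrix(rgamma(length(L), shape = hp$a + 0.5, rate = hp$b + L^2 / 2),
         nrow(L), ncol(L))
}

# Conjugate Gamma update for the noise precisions:
# psi_p ~ Gamma(c + N/2, rate d + RSS_p / 2); the scalar mode pools all
# features into one precision.
sample_noise_precisions <- function(state, X, hp, psi_mode = "feature") {
  N <- nrow(X); P <- ncol(X)
  rss <- colSums((X - state$Lambda %*% state$F)^2)
  if (psi_mode == "scalar") {
    rep(rgamma(1, shape = hp$c + N * P / 2, rate = hp$d + sum(rss) / 2), P)
  } else {
    rgamma(P, shape = hp$c + N / 2, rate = hp$d + rss / 2)
  }
}

# Closed-form conditional moments, used by the moment-matching tests.
factor_conditional_moments <- function(state, X, p) {
  k <- ncol(state$Lambda)
  Sigma <- solve(diag(k) + state$psi[p] * crossprod(state$Lambda))
  list(mean = as.vector(state$psi[p] * Sigma %*% crossprod(state$Lambda, X[, p])),
       cov = Sigma)
}

loading_conditional_moments <- function(state, X, n) {
  k <- nrow(state$F)
  Fp <- state$F * rep(state$psi, each = k)
  Sigma <- solve(diag(state$alpha[n, ], k) + tcrossprod(Fp, state$F))
  list(mean = as.vector(Sigma %*% (Fp %*% X[n, ])), cov = Sigma)
}

#' Reconstruct the expression matrix from a fit
#'
#' Returns the posterior-mean reconstruction `Lambda F`, the model's
#' denoised version of the centered feature matrix (the factor-based
#' images).
#'
#' @param fit A `sbfa_fit`.
#' @return `N x P` numeric matrix.
#' @export
reconstruct <- function(fit) {
  abort_if(!inherits(fit, "sbfa_fit"), "fit must be a sbfa_fit")
  fit$Lambda %*% fit$F
}

#' Align estimated factors with a reference
#'
#' Factor models are identified only up to row permutation and sign.
#' Greedily matches estimated factor rows to reference rows by largest
#' absolute Pearson correlation, one-to-one, and picks signs making the
#' matched correlations positive.
#'
#' @param estimated,reference `K x P` matrices with equal shapes.
#' @return List with `perm` (for each reference row, the matched estimated
#'   row), `sign` (+1/-1 per match), and `cor` (the signed correlations,
#'   all non-negative). Zero-variance rows match with correlation 0.
#' @export
align_factors <- function(estimated, reference) {
  abort_if(!all(dim(estimated) == dim(reference)),
           "estimated and reference must have equal shapes")
  K <- nrow(reference)
  cmat <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (sd(reference[i, ]) > 0 && sd(estimated[j, ]) > 0)
      cmat[i, j] <- cor(reference[i, ], estimated[j, ])
  }
  perm <- integer(K); sgn <- integer(K); rho <- numeric(K)
  absc <- abs(cmat)
  for (step in seq_len(K)) {
    best <- arrayInd(which.max(absc), dim(absc))
    i <- best[1]; j <- best[2]
    perm[i] <- j
    sgn[i] <- if (cmat[i, j] >= 0) 1L else -1L
    rho[i] <- abs(cmat[i, j])
    absc[i, ] <- -Inf; absc[, j] <- -Inf
  }
  list(perm = perm, sign = sgn, cor = rho)
}

#' @export
print.sbfa_fit <- function(x, ...) {
  cat(sprintf(
    "<sbfa_fit: %d images x %d features, %d factors; %d sweeps (burn-in %d), final mse %.4g>\n",
    nrow(x$Lambda), ncol(x$F), ncol(x$Lambda), x$n_iter, x$burn_in,
    x$trace$mse[x$n_iter]))
  invisible(x)
}

#' Tidy the posterior-mean loadings of a fit
#'
#' @param x A `sbfa_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (image, factor): `image_id`, `gene_id`
#'   (when metadata is available), `factor`, `loading`.
#' @method tidy sbfa_fit
#' @export
tidy.sbfa_fit <- function(x, ...) {
  k <- ncol(x$Lambda)
  ids <- rownames(x$Lambda)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x$Lambda)))
  out <- tibble::tibble(
    image_id = rep(ids, times = k),
    factor = rep(seq_len(k), each = nrow(x$Lambda)),
    loading = as.vector(x$Lambda)
  )
  if (!is.null(x$meta))
    out <- dplyr::left_join(out, x$meta, by = "image_id") |>
      dplyr::select("image_id", "gene_id", "factor", "loading")
  out
}

#' One-row summary of a fit
#'
#' @param x A `sbfa_fit`.
#' @param ... Unused.
#' @return Tibble with dimensions, sweep counts and the final
#'   reconstruction MSE.
#' @method glance sbfa_fit
#' @export
glance.sbfa_fit <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$Lambda), n_features = ncol(x$F),
    k = ncol(x$Lambda), n_iter = x$n_iter, burn_in = x$burn_in,
    final_mse = x$trace$mse[x$n_iter], seed = x$seed
  )
}

#' Plot the estimated spatial factors
#'
#' Renders each posterior-mean factor row as its grid image, faceted by
#' factor. Requires the fit to carry a grid (fitted from a
#' `spexfa_features`); otherwise supply `grid`.
#'
#' @param object A `sbfa_fit`.
#' @param grid Optional `c(n_rows, n_cols)` overriding the stored grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sbfa_fit
#' @export
autoplot.sbfa_fit <- function(object, grid = object$grid, ...) {
  abort_if(is.null(grid), "no grid stored in fit; supply grid = c(rows, cols)")
  k <- nrow(object$F)
  df <- tidyr::expand_grid(factor = seq_len(k), row = seq_len(grid[1]),
                           col = seq_len(grid[2]))
  df$value <- as.vector(t(object$F))   # row-major per factor
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::facet_wrap(~factor, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Estimated spatial factors")
}

#' Plot the reconstruction-error trace
#'
#' @param fit A `sbfa_fit`.
#' @return A ggplot object showing per-sweep reconstruction MSE with the
#'   burn-in boundary marked.
#' @export
plot_trace <- function(fit) {
  ggplot2::ggplot(fit$trace, ggplot2::aes(x = .data$iteration, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = fit$burn_in, linetype = "dashed") +
    ggplot2::labs(x = "Gibbs sweep", y = "reconstruction MSE")
}
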