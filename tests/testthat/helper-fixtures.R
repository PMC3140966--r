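# Shared fixtures, computed lazily once per test session. Problem sizes
# follow the generator defaults (100 genes x 2 images, K = 6, grid 20 x 40);
# Gibbs runs use 800/600 sweeps, enough for the chain to settle on these
# corpora while keeping the suite fast.

.fixtures <- new.env(parent = emptyenv())

default_corpus <- function() {
  if (is.null(.fixtures$corpus))
    .fixtures$corpus <- simulate_corpus(seed = 7)
  .fixtures$corpus
}

default_fit <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- sbfa(default_corpus()$fm, k = 6, n_iter = 800,
                          burn_in = 400, seed = 7)
  .fixtures$fit
}

noise_corpus <- function() {
  if (is.null(.fixtures$noise_corpus))
    .fixtures$noise_corpus <- simulate_corpus(seed = 11,
                                              prop_noninformative = 0.2)
  .fixtures$noise_corpus
}

noise_fit <- function() {
  if (is.null(.fixtures$noise_fit))
    .fixtures$noise_fit <- sbfa(noise_corpus()$fm, k = 6, n_iter = 600,
                                burn_in = 300, seed = 11)
  .fixtures$noise_fit
}

# Quadrature oracle: posterior mean/variance of a scalar parameter with
# unnormalized log-density logf, integrated on a fine grid.
quadrature_moments <- function(logf, lower, upper, n = 20001) {
  x <- seq(lower, upper, length.out = n)
  lw <- logf(x)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  m <- sum(w * x)
  list(mean = m, var = sum(w * (x - m)^2))
}

# Per-gene summary of a gene_loocv result: gene score, truth, votes.
summarise_loocv <- function(cv) {
  cv |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      score = gene_score(decision),
      truth = truth[1],
      majority = vote_majority(predicted),
      minority_correct = vote_minority(predicted, truth[1]),
      .groups = "drop"
    )
}
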