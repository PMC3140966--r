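test_that("SMLR matches a dense objective-grid oracle on a toy problem", {
  x <- matrix(c(-2, -1.5, -0.5, 0.5, 1.2, 2.2,
                 1.0, -0.5, 0.8, -1.0, 0.3, -0.2), ncol = 2)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- train_smlr(x, y, reg_lambda = 0.5, intercept = FALSE)
  grid <- seq(-5, 5, by = 0.01)
  W <- as.matrix(expand.grid(w1 = grid, w2 = grid))   # dense grid, 1e6 points
  eta <- W %*% t(x)                                   # candidates x samples
  vals <- eta %*% y - rowSums(log1p(exp(eta))) - 0.5 * rowSums(abs(W))
  w_grid <- unname(W[which.max(vals), ])
  obj <- function(w) {
    e <- drop(x %*% w)
    sum(y * e - log1p(exp(e))) - 0.5 * sum(abs(w))
  }
  expect_lt(abs(fit$objective - obj(w_grid)), 1e-4)
  expect_equal(fit$weights, w_grid, tolerance = 0.011)
  expect_true(fit$converged)
})

test_that("SMLR agrees with an independent penalized-likelihood solver", {
  set.seed(55)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(plogis(x %*% c(1.5, -1, 0, 0)) > runif(n))
  lam <- 3
  fit <- train_smlr(x, y, reg_lambda = lam)
  # glmnet minimizes -loglik/n + lambda * ||w||_1
  gn <- glmnet::glmnet(x, y, family = "binomial", lambda = lam / n,
                       standardize = FALSE, thresh = 1e-12)
  expect_equal(fit$weights, as.vector(gn$beta), tolerance = 1e-3)
  expect_equal(fit$intercept, as.numeric(gn$a0), tolerance = 1e-3)
})

test_that("extreme L1 strength zeroes all weights; duplicates split one weight", {
  set.seed(57)
  x <- matrix(rnorm(80), 40, 2)
  y <- as.integer(x[, 1] + rnorm(40, sd = 0.4) > 0)
  big <- train_smlr(x, y, reg_lambda = 1e6)
  expect_equal(big$weights, c(0, 0))
  expect_equal(big$n_nonzero, 0)
  # intercept alone drives predictions
  expect_equal(predict(big, x, type = "prob"),
               rep(plogis(big$intercept), 40), tolerance = 1e-10)
  # duplicated feature column: objective must match the single-column one
  x1 <- x[, 1, drop = FALSE]
  f1 <- train_smlr(x1, y, reg_lambda = 0.7)
  f2 <- train_smlr(cbind(x1, x1), y, reg_lambda = 0.7)
  expect_lt(abs(f1$objective - f2$objective), 1e-6)
  expect_equal(sum(f2$weights), f1$weights[1], tolerance = 1e-3)
})

test_that("SMLR predictions are proper probabilities", {
  set.seed(59)
  x <- matrix(rnorm(30), 15, 2)
  m <- list(weights = c(0, 0), intercept = 0, reg_lambda = 0)
  class(m) <- "smlr"
  expect_equal(predict(m, x, type = "prob"), rep(0.5, 15))
  m$weights <- c(1.3, -0.4); m$intercept <- 0.2
  pr <- predict(m, x, type = "response")
  expect_equal(rowSums(pr), rep(1, 15), tolerance = 1e-12)
  expect_true(all(pr > 0))
  expect_equal(as.integer(predict(m, x, type = "link") > 0),
               predict(m, x, type = "class"))
  expect_error(predict(m, x[, 1, drop = FALSE]), "dimension")
})

test_that("SMLR sparsity grows along the regularization path", {
  # the attained penalty norm ||w||_1 is non-increasing in reg_lambda (a
  # theorem for penalized M-estimators); the nonzero COUNT is only a
  # trend — the active set can genuinely gain a coordinate locally (KKT
  # boundary effects), so the count is checked at the path ends and as a
  # monotone trend rather than pointwise
  lams <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 10, 20, 50)
  for (s in 1:3) {
    set.seed(60 + s)
    x <- matrix(rnorm(60 * 6), 60, 6)
    y <- as.integer(x %*% c(2, -1, 0.5, 0, 0, 0) + rnorm(60, sd = 0.5) > 0)
    fits <- lapply(lams, function(l) train_smlr(x, y, reg_lambda = l))
    l1 <- vapply(fits, function(f) sum(abs(f$weights)), numeric(1))
    expect_true(all(diff(l1) <= 1e-8))
    nz <- vapply(fits, `[[`, integer(1), "n_nonzero")
    expect_equal(nz[length(nz)], 0L)
    expect_gte(nz[1], max(nz) - 1L)
    expect_lte(cor(nz, seq_along(lams), method = "spearman"), 0)
  }
})

test_that("polynomial SVM adapter separates what its kernel can", {
  x <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  y_lin <- c(0, 0, 1, 1)
  m <- train_svm_poly(x, y_lin)
  expect_equal(predict(m, x, type = "class"), y_lin)
  dv <- predict(m, x, type = "link")
  expect_true(all(is.finite(dv)))
  expect_equal(as.integer(dv > 0), y_lin)
  # label flip flips decision values
  m2 <- train_svm_poly(x, 1 - y_lin)
  expect_equal(sign(predict(m2, x, type = "link")), -sign(dv))
  # XOR needs the degree-2 kernel
  y_xor <- c(0, 1, 1, 0)
  mx <- train_svm_poly(x, y_xor, degree = 2)
  expect_equal(predict(mx, x, type = "class"), y_xor)
  expect_error(train_svm_poly(x, c(1, 1, 1, 1)), "classes")
})

test_that("gene-level LOO-CV never trains on the held-out gene", {
  set.seed(61)
  meta <- tibble::tibble(image_id = sprintf("i%02d", 1:12),
                         gene_id = rep(sprintf("g%d", 1:6), each = 2))
  labels <- tibble::tibble(gene_id = c("g1", "g2", "g3"), term = "t")
  feats <- matrix(rnorm(24), 12, 2)
  feats[meta$gene_id %in% labels$gene_id, 1] <-
    feats[meta$gene_id %in% labels$gene_id, 1] + 3
  cv <- gene_loocv(feats, labels, "t", meta = meta, reg_lambda = 0.05)
  expect_equal(nrow(cv), 12)
  expect_setequal(names(attr(cv, "models")), unique(meta$gene_id))
  expect_equal(cv$truth, as.integer(meta$gene_id %in% labels$gene_id))
  # every image scored exactly once, and folds are per gene
  expect_equal(length(unique(cv$image_id)), 12)
  # determinism
  cv2 <- gene_loocv(feats, labels, "t", meta = meta, reg_lambda = 0.05)
  expect_equal(cv$decision, cv2$decision)
  expect_error(gene_loocv(feats, labels[1, ], "t", meta = meta),
               "at least 2 genes")
})

test_that("gene-level CV AUC tracks a held-out-split AUC", {
  set.seed(63)
  G <- 120
  feats <- abs(sample_sparse_loadings(G, 4, sparsity = 0.6, seed = 63)) +
    matrix(rnorm(G * 4, sd = 0.1), G, 4)
  meta <- tibble::tibble(image_id = sprintf("i%03d", 1:G),
                         gene_id = sprintf("g%03d", 1:G))
  pos <- meta$gene_id[feats[, 2] > 0.6]
  labels <- tibble::tibble(gene_id = pos, term = "t")
  cv <- gene_loocv(feats, labels, "t", meta = meta, reg_lambda = 0.1)
  auc_cv <- compute_auc(cv$decision, cv$truth)
  # held-out half-split at the same n
  idx <- seq_len(G) %% 2 == 0
  m <- train_smlr(feats[idx, ], cv$truth[idx], reg_lambda = 0.1)
  auc_split <- compute_auc(predict(m, feats[!idx, ], type = "link"),
                           cv$truth[!idx])
  expect_lt(abs(auc_cv - auc_split), 0.05)
})

test_that("voting rules behave as stated and minority dominates majority", {
  expect_equal(vote_majority(c(1, 1, 0)), 1L)
  expect_equal(vote_majority(c(1, 0)), 0L)    # tie -> negative class
  expect_equal(vote_majority(c(0, 0, 0)), 0L)
  expect_true(vote_minority(c(0, 0, 1), 1))
  expect_false(vote_minority(c(0, 0), 1))
  # exhaustive: minority-correct implied by majority-correct, <= 4 images
  for (n in 1:4) {
    pats <- expand.grid(rep(list(0:1), n))
    for (truth in 0:1) for (i in seq_len(nrow(pats))) {
      preds <- as.integer(pats[i, ])
      maj_ok <- vote_majority(preds) == truth
      min_ok <- vote_minority(preds, truth)
      expect_true(!maj_ok || min_ok)
    }
  }
})

test_that("gene score thresholds reproduce the voting rules", {
  expect_equal(gene_score(c(1, 1, -1)), 2 / 3)
  expect_equal(gene_score(c(-2, -0.1)), 0)
  for (n in 1:5) {
    pats <- expand.grid(rep(list(c(-1, 1)), n))
    for (i in seq_len(nrow(pats))) {
      dv <- as.numeric(pats[i, ])
      expect_equal(as.integer(gene_score(dv) > 0.5),
                   vote_majority(as.integer(dv > 0)))
      expect_equal(gene_score(dv) > 0, any(dv > 0))
    }
  }
})

test_that("AUC equals the all-pairs enumeration oracle", {
  expect_equal(compute_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(compute_auc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(compute_auc(rep(0.7, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(65)
  for (rep in 1:20) {
    scores <- round(rnorm(20), 1)      # rounding forces ties
    labels <- sample(0:1, 20, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(compute_auc(scores, labels), mean(pairs))
  }
  # invariance under strictly monotone transforms
  s <- rnorm(30); l <- rep(0:1, 15)
  expect_equal(compute_auc(exp(s), l), compute_auc(s, l))
  expect_warning(a <- compute_auc(1:3, c(1, 1, 1)), "one class")
  expect_true(is.na(a))
})

test_that("recognition rate is the plain fraction correct, with its caveat", {
  expect_equal(compute_arr(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(compute_arr(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.75)
  # trivial larger-class predictor on a 90/10 split: ARR 0.9, AUC 0.5
  truth <- rep(c(0, 1), c(90, 10))
  pred <- rep(0, 100)
  expect_equal(compute_arr(pred, truth), 0.9)
  expect_equal(compute_auc(pred, truth), 0.5)
  expect_error(compute_arr(numeric(0), numeric(0)), "at least one")
})

test_that("balanced splits are reproducible gene-disjoint partitions", {
  labels <- tibble::tibble(gene_id = sprintf("g%02d", 1:12), term = "t")
  genes <- sprintf("g%02d", 1:40)
  sp <- balanced_splits(labels, "t", genes, n_per_class = 5, repeats = 100,
                        seed = 9)
  expect_length(sp, 100)
  for (s in sp) {
    expect_equal(sum(s$train$y == 1), 5)
    expect_equal(sum(s$train$y == 0), 5)
    expect_length(intersect(s$train$gene_id, s$test$gene_id), 0)
    expect_setequal(c(s$train$gene_id, s$test$gene_id), genes)
  }
  sp2 <- balanced_splits(labels, "t", genes, n_per_class = 5, repeats = 100,
                         seed = 9)
  expect_identical(sp, sp2)
  expect_error(balanced_splits(labels, "t", genes, n_per_class = 30),
               "not enough genes")
})

test_that("term filtering keeps well-populated terms in stable order", {
  labels <- tibble::tibble(
    gene_id = c(sprintf("g%02d", 1:50), sprintf("g%02d", 1:5)),
    term = rep(c("big", "small"), c(50, 5)))
  kept <- filter_terms(labels, min_genes = 10)
  expect_equal(kept$term, "big")
  expect_equal(kept$n_genes, 50)
  expect_equal(nrow(filter_terms(labels, min_genes = 60)), 0)
  expect_identical(filter_terms(labels, 3), filter_terms(labels, 3))
})

test_that("multi-resolution concatenation aligns on image ids", {
  ids <- sprintf("i%02d", 1:8)
  m1 <- matrix(rnorm(16), 8, 2, dimnames = list(ids, NULL))
  m2 <- matrix(rnorm(32), 8, 4, dimnames = list(rev(ids), NULL))
  m3 <- matrix(rnorm(48), 8, 6, dimnames = list(ids, NULL))
  out <- concat_multires(list(lo = m1, mid = m2, hi = m3))
  expect_equal(ncol(out), 12)
  expect_equal(rownames(out), ids)
  expect_equal(out[3, 3:6], m2["i03", ], ignore_attr = TRUE)
  prov <- attr(out, "provenance")
  expect_equal(nrow(prov), 12)
  expect_equal(prov$resolution, rep(c("lo", "mid", "hi"), c(2, 4, 6)))
  # provenance survives serialization
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(out, path)
  expect_equal(attr(readRDS(path), "provenance"), prov)
  expect_identical(concat_multires(list(a = m1)), {
    x <- m1; attr(x, "provenance") <-
      tibble::tibble(resolution = "a", factor = 1:2); x
  })
  m4 <- m1[1:6, ]
  expect_error(concat_multires(list(m1, m4)), "mismatch")
})

test_that("relevance counts reflect per-fold support", {
  zero <- list(weights = c(0, 0, 0))
  mid <- list(weights = c(0.5, 0, 1e-12))
  full <- list(weights = c(-2, 0.1, 0))
  counts <- relevance_counts(list(zero, mid, full))
  expect_equal(counts$n_selected, c(2L, 1L, 0L))
  expect_true(all(counts$n_selected <= 3))
  expect_equal(attr(counts, "never_selected"), 3L)
  all_zero <- relevance_counts(list(zero, zero))
  expect_equal(all_zero$n_selected, rep(0L, 3))
  expect_equal(attr(relevance_counts(list(full, full)), "always_selected"),
               c(1L, 2L))
})

test_that("evaluation reports average per-term metrics", {
  r <- evaluation_report(tibble::tibble(term = "only", auc = 0.83))
  expect_equal(unname(r$means["auc"]), 0.83)
  expect_equal(glance(r)$n_terms, 1)
  expect_equal(tidy(r)$term, "only")
  expect_error(evaluation_report(tibble::tibble(term = character(0))),
               "at least one")
})
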