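#' Sparse multinomial logistic regression (L1-MAP)
#'
#' Trains the binary special case of sparse multinomial logistic
#' regression: weights maximize the penalized log-likelihood
#' `l(w) - reg_lambda * sum(|w_j|)`, where `l` is the logistic
#' log-likelihood (softmax with the reference-class weights pinned at
#' zero, which for two classes is the ordinary logit link) and the L1 term
#' is the log of a Laplacian prior — a MAP estimate that sets irrelevant
#' feature weights exactly to zero. The intercept is unpenalized.
#'
#' Optimization is by accelerated proximal gradient (soft-thresholding)
#' on the exact objective, run to an objective change below `tol`.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary labels (0/1, logical, or two-level factor).
#' @param reg_lambda Non-negative L1 regularization strength (total, not
#'   per-sample).
#' @param intercept Include an unpenalized intercept.
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap; exceeding it returns
#'   `converged = FALSE` with a warning.
#' @return An object of class `smlr`: `weights`, `intercept`,
#'   `reg_lambda`, `objective` (the attained penalized log-likelihood),
#'   `converged`, `n_nonzero` (weights with `|w| > 1e-8`).
#' @export
train_smlr <- function(x, y, reg_lambda = 0.1, intercept = TRUE,
                       tol = 1e-10, max_iter = 20000) {
  x <- as.matrix(x)
  y <- as_binary01(y)
  abort_if(length(unique(y)) < 2, "need at least one sample in each class")
  abort_if(reg_lambda < 0, "reg_lambda must be non-negative")
  n <- nrow(x); p <- ncol(x)

  # Lipschitz bound on the negative log-likelihood gradient
  Xa <- if (intercept) cbind(1, x) else x
  L <- norm(Xa, "2")^2 / 4
  if (L == 0) L <- 1

  log1pexp <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  obj <- function(w0, w) {
    eta <- drop(x %*% w) + w0
    sum(y * eta - log1pexp(eta)) - reg_lambda * sum(abs(w))
  }
  grad <- function(w0, w) {
    eta <- drop(x %*% w) + w0
    r <- y - plogis(eta)
    list(g0 = if (intercept) sum(r) else 0, g = drop(crossprod(x, r)))
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  w <- numeric(p); w0 <- 0
  vw <- w; vw0 <- w0          # momentum point (FISTA)
  tmom <- 1
  f_old <- obj(w0, w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- grad(vw0, vw)
    w_new <- soft(vw + gr$g / L, reg_lambda / L)
    w0_new <- if (intercept) vw0 + gr$g0 / L else 0
    t_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    vw <- w_new + ((tmom - 1) / t_new) * (w_new - w)
    vw0 <- w0_new + ((tmom - 1) / t_new) * (w0_new - w0)
    w <- w_new; w0 <- w0_new; tmom <- t_new
    f_new <- obj(w0, w)
    if (is.finite(f_new) && abs(f_new - f_old) < tol && it > 10) {
      converged <- TRUE
      break
    }
    # restart momentum if the objective worsens (monotone FISTA)
    if (f_new < f_old) { vw <- w; vw0 <- w0; tmom <- 1 }
    f_old <- f_new
  }
  if (!converged)
    warning("SMLR did not converge within ", max_iter, " iterations")
  # polish with plain proximal steps: these set truly inactive
  # coordinates exactly to zero instead of leaving numerical dust
  for (it in seq_len(5000)) {
    gr <- grad(w0, w)
    w_new <- soft(w + gr$g / L, reg_lambda / L)
    w0_new <- if (intercept) w0 + gr$g0 / L else 0
    delta <- max(abs(w_new - w), abs(w0_new - w0))
    w <- w_new; w0 <- w0_new
    if (delta < 1e-12) break
  }
  structure(
    list(weights = w, intercept = w0, reg_lambda = reg_lambda,
         objective = obj(w0, w), converged = converged,
         n_nonzero = sum(abs(w) > 1e-8)),
    class = "smlr"
  )
}

as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  abort_if(!all(y %in% c(0, 1)), "labels must be binary (0/1)")
  as.numeric(y)
}

#' @export
print.smlr <- function(x, ...) {
  cat(sprintf(
    "<smlr: %d/%d nonzero weights, reg_lambda %.3g, objective %.6g%s>\n",
    x$n_nonzero, length(x$weights), x$reg_lambda, x$objective,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from an SMLR model
#'
#' @param object An `smlr` model.
#' @param newdata Feature matrix with the training feature dimension.
#' @param type `"prob"` for class-1 probabilities, `"response"` for both
#'   class probabilities (columns `p0`, `p1`, rows sum to 1), `"link"`
#'   for the linear decision value, `"class"` for 0/1 labels
#'   (threshold 0.5).
#' @param ... Unused.
#' @export
predict.smlr <- function(object, newdata,
                         type = c("prob", "response", "link", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  abort_if(ncol(newdata) != length(object$weights),
           "feature dimension does not match the trained model")
  eta <- drop(newdata %*% object$weights) + object$intercept
  p1 <- plogis(eta)
  switch(type,
         prob = p1,
         response = cbind(p0 = 1 - p1, p1 = p1),
         link = eta,
         class = as.integer(eta > 0))
}

#' Polynomial-kernel SVM adapter
#'
#' Thin adapter around a polynomial-kernel support vector machine with
#' unit cost (trade-off between training error and functional margin).
#' Decision values are oriented so that positive values predict class 1.
#'
#' @param x Feature matrix.
#' @param y Binary labels (0/1, logical, or two-level factor).
#' @param degree Polynomial degree.
#' @param coef0 Kernel offset.
#' @return An object of class `svm_poly` wrapping the fitted model.
#' @export
train_svm_poly <- function(x, y, degree = 3, coef0 = 1) {
  x <- as.matrix(x)
  y <- as_binary01(y)
  abort_if(length(unique(y)) < 2, "need both classes present")
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "polynomial",
                    degree = degree, coef0 = coef0, cost = 1, scale = FALSE)
  # orient decision values: positive decision value <-> class 1
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  flip <- mean(dv[y == 1]) < mean(dv[y == 0])
  structure(list(fit = fit, flip = flip), class = "svm_poly")
}

#' @export
predict.svm_poly <- function(object, newdata,
                             type = c("link", "class"), ...) {
  type <- match.arg(type)
  dv <- attr(predict(object$fit, as.matrix(newdata),
                     decision.values = TRUE), "decision.values")
  dv <- drop(dv) * if (object$flip) -1 else 1
  if (type == "link") dv else as.integer(dv > 0)
}
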