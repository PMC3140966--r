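#' Gene-level leave-one-out cross-validation
#'
#' Scores every image under the protocol in which all images of one gene
#' are left out per fold and the classifier is trained on the images of
#' all remaining genes — so a gene's replicate images can never leak into
#' their own training set.
#'
#' @param features Numeric matrix of per-image features (e.g. the loading
#'   matrix of a [sbfa()] fit), rows named by image id, or a `sbfa_fit`.
#' @param meta Tibble with `image_id`, `gene_id` (taken from the fit when
#'   `features` is a `sbfa_fit`).
#' @param labels Tibble with `gene_id`, `term` (gene-level annotations).
#' @param term The annotation term to classify.
#' @param classifier `"smlr"` or `"svm"`.
#' @param reg_lambda L1 strength for the SMLR classifier.
#' @param ... Passed to the classifier's training function.
#' @return Tibble with one row per image: `image_id`, `gene_id`,
#'   `decision` (signed decision value), `predicted` (0/1), `truth`
#'   (0/1). The fold models are attached as attribute `"models"` (named
#'   by held-out gene).
#' @export
gene_loocv <- function(features, labels, term, meta = NULL,
                       classifier = c("smlr", "svm"), reg_lambda = 0.1, ...) {
  classifier <- match.arg(classifier)
  if (inherits(features, "sbfa_fit")) {
    meta <- features$meta
    features <- features$Lambda
  }
  abort_if(is.null(meta), "need image metadata (image_id, gene_id)")
  features <- as.matrix(features)
  abort_if(nrow(features) != nrow(meta),
           "feature rows must match metadata rows")
  pos_genes <- unique(labels$gene_id[labels$term == term])
  y_gene <- meta$gene_id %in% pos_genes
  abort_if(length(unique(meta$gene_id[y_gene])) < 2 ||
             length(unique(meta$gene_id[!y_gene])) < 2,
           "need at least 2 genes in each class for gene-level LOO-CV")
  genes <- unique(meta$gene_id)
  y <- as.integer(y_gene)
  decision <- numeric(nrow(features))
  models <- vector("list", length(genes))
  names(models) <- genes
  for (g in genes) {
    hold <- meta$gene_id == g
    model <- if (classifier == "smlr") {
      train_smlr(features[!hold, , drop = FALSE], y[!hold],
                 reg_lambda = reg_lambda, ...)
    } else {
      train_svm_poly(features[!hold, , drop = FALSE], y[!hold], ...)
    }
    decision[hold] <- predict(model, features[hold, , drop = FALSE],
                              type = "link")
    models[[g]] <- model
  }
  out <- tibble::tibble(
    image_id = meta$image_id, gene_id = meta$gene_id,
    decision = decision, predicted = as.integer(decision > 0), truth = y
  )
  attr(out, "models") <- models
  attr(out, "term") <- term
  out
}

#' Voting rules over a gene's image predictions
#'
#' Majority voting labels a gene 1 only when strictly more than half of
#' its images are predicted 1 (exact ties go to 0, the conservative
#' choice). Minority voting calls a gene correct when at least one image
#' is predicted with the true label.
#'
#' @param predictions Binary vector of per-image predicted labels.
#' @return `vote_majority`: the gene label (0/1).
#' @export
vote_majority <- function(predictions) {
  abort_if(length(predictions) == 0, "need at least one prediction")
  as.integer(mean(predictions) > 0.5)
}

#' @rdname vote_majority
#' @param truth The gene's true label.
#' @return `vote_minority`: logical, whether the gene counts as correct.
#' @export
vote_minority <- function(predictions, truth) {
  abort_if(length(predictions) == 0, "need at least one prediction")
  any(predictions == truth)
}

#' Gene score from per-image decision values
#'
#' Default reducer for building gene-level ROC curves: the fraction of a
#' gene's images with positive decision value. Thresholding this score at
#' 1/2 reproduces majority voting; at 0, minority voting for the positive
#' class.
#'
#' @param decisions Numeric per-image decision values of one gene.
#' @param reducer `"vote_fraction"` (default) or `"mean_decision"`.
#' @return Scalar gene score.
#' @export
gene_score <- function(decisions, reducer = c("vote_fraction",
                                              "mean_decision")) {
  reducer <- match.arg(reducer)
  abort_if(length(decisions) == 0, "need at least one decision value")
  if (reducer == "vote_fraction") mean(decisions > 0) else mean(decisions)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic:
#' the probability that a random positive outscores a random negative,
#' ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`; `NA` (with a warning) if a class is absent.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as_binary01(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Absolute recognition rate
#'
#' Fraction of samples whose predicted label equals the true label. On
#' unbalanced data this is inflated: predicting only the larger class on
#' a 90/10 split already scores 0.9.
#'
#' @param predicted,truth Equal-length binary label vectors.
#' @return Fraction correct in `[0, 1]`.
#' @export
compute_arr <- function(predicted, truth) {
  abort_if(length(predicted) == 0, "need at least one prediction")
  abort_if(length(predicted) != length(truth), "length mismatch")
  mean(predicted == truth)
}

#' Balanced gene-level train/test splits
#'
#' For each repeat, samples `n_per_class` positive and `n_per_class`
#' negative genes (without replacement) for training; all remaining genes
#' form the test set. Splitting is at gene level so no gene ever appears
#' on both sides of a repeat.
#'
#' @param labels Tibble with `gene_id`, `term`.
#' @param term The annotation term defining the positive class.
#' @param genes Character vector of all gene ids under study.
#' @param n_per_class Training genes sampled per class.
#' @param repeats Number of random splits.
#' @param seed Integer seed.
#' @return List of length `repeats`; each element has `train` and `test`
#'   tibbles with columns `gene_id`, `y`.
#' @export
balanced_splits <- function(labels, term, genes, n_per_class, repeats = 10,
                            seed = 1) {
  pos <- intersect(genes, unique(labels$gene_id[labels$term == term]))
  neg <- setdiff(genes, pos)
  abort_if(length(pos) <= n_per_class || length(neg) <= n_per_class,
           "not enough genes per class for the requested split size")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  purrr::map(seq_len(repeats), function(r) {
    tr_pos <- sample(pos, n_per_class)
    tr_neg <- sample(neg, n_per_class)
    train <- tibble::tibble(gene_id = c(tr_pos, tr_neg),
                            y = rep(1:0, each = n_per_class))
    test_genes <- setdiff(genes, train$gene_id)
    test <- tibble::tibble(gene_id = test_genes,
                           y = as.integer(test_genes %in% pos))
    list(train = train, test = test)
  })
}

#' Retain terms with enough annotated genes
#'
#' Terms carried by too few genes are statistically too weak to learn and
#' evaluate; only terms annotated to strictly more than `min_genes` genes
#' are kept, ordered by descending gene count then term name.
#'
#' @param labels Tibble with `gene_id`, `term`.
#' @param min_genes Threshold (strict).
#' @return Tibble with `term`, `n_genes`.
#' @export
filter_terms <- function(labels, min_genes = 10) {
  abort_if(min_genes < 1, "min_genes must be >= 1")
  labels |>
    dplyr::distinct(.data$gene_id, .data$term) |>
    dplyr::count(.data$term, name = "n_genes") |>
    dplyr::filter(.data$n_genes > min_genes) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$term)
}

#' Concatenate multi-resolution loading features
#'
#' Joins loading matrices inferred at different grid resolutions into one
#' wide feature matrix, aligned on image id, with per-column provenance.
#'
#' @param loading_matrices Named list of matrices with identical rowname
#'   (image id) sets.
#' @return Matrix of horizontally concatenated features (rows aligned on
#'   the first matrix's image order) with attribute `"provenance"`, a
#'   tibble of (`resolution`, `factor`) per column.
#' @export
concat_multires <- function(loading_matrices) {
  abort_if(length(loading_matrices) == 0, "need at least one matrix")
  if (is.null(names(loading_matrices)))
    names(loading_matrices) <- paste0("res", seq_along(loading_matrices))
  ids <- rownames(loading_matrices[[1]])
  abort_if(is.null(ids), "matrices must have image ids as rownames")
  for (nm in names(loading_matrices)) {
    other <- rownames(loading_matrices[[nm]])
    missing <- setdiff(ids, other)
    extra <- setdiff(other, ids)
    abort_if(length(missing) > 0 || length(extra) > 0,
             paste0("image id mismatch in '", nm, "': missing [",
                    paste(head(missing, 5), collapse = ", "),
                    "], extra [", paste(head(extra, 5), collapse = ", "), "]"))
  }
  aligned <- lapply(loading_matrices, function(m) m[ids, , drop = FALSE])
  out <- do.call(cbind, aligned)
  prov <- purrr::imap_dfr(loading_matrices, function(m, nm) {
    tibble::tibble(resolution = nm, factor = seq_len(ncol(m)))
  })
  attr(out, "provenance") <- prov
  out
}

#' Feature-relevance counts across CV folds
#'
#' Counts, for every feature, in how many cross-validation fold models its
#' SMLR weight exceeded the tolerance in magnitude — a stability histogram
#' of feature selection.
#'
#' @param models List of `smlr` models sharing one feature space (e.g. the
#'   `"models"` attribute of [gene_loocv()]).
#' @param tolerance Magnitude below which a weight counts as zero.
#' @return Tibble with `feature`, `n_selected`, plus attributes
#'   `"always_selected"` and `"never_selected"` (feature index vectors).
#' @export
relevance_counts <- function(models, tolerance = 1e-8) {
  p <- length(models[[1]]$weights)
  counts <- Reduce(`+`, lapply(models, function(m) {
    abort_if(length(m$weights) != p, "models do not share a feature space")
    as.integer(abs(m$weights) > tolerance)
  }))
  out <- tibble::tibble(feature = seq_len(p), n_selected = counts)
  attr(out, "always_selected") <- which(counts == length(models))
  attr(out, "never_selected") <- which(counts == 0)
  out
}

#' Per-term evaluation report
#'
#' Collects per-term classification metrics into a report with the
#' arithmetic mean over terms, plus the scheme metadata (voting rule,
#' classifier, CV scheme, seeds) that a results table must never leave
#' implicit.
#'
#' @param metrics Tibble with a `term` column and one or more numeric
#'   metric columns (e.g. `auc`, `arr`).
#' @param voting,classifier,cv_scheme,level Free-text scheme descriptors.
#' @param seed Seed(s) used by the evaluation.
#' @return An object of class `spexfa_eval`: `table` (the per-term
#'   tibble), `means` (named numeric, one per metric column), `scheme`
#'   (metadata list).
#' @export
evaluation_report <- function(metrics, voting = NA_character_,
                              classifier = NA_character_,
                              cv_scheme = NA_character_,
                              level = c("gene", "image"), seed = NA_integer_) {
  metrics <- tibble::as_tibble(metrics)
  abort_if(nrow(metrics) < 1, "need at least one term")
  abort_if(!"term" %in% names(metrics), "metrics must have a 'term' column")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  abort_if(length(num_cols) == 0, "metrics must have a numeric column")
  means <- vapply(metrics[num_cols], mean, numeric(1))
  structure(
    list(table = metrics, means = means,
         scheme = list(voting = voting, classifier = classifier,
                       cv_scheme = cv_scheme,
                       level = match.arg(level), seed = seed)),
    class = "spexfa_eval"
  )
}

#' @export
print.spexfa_eval <- function(x, ...) {
  cat("<spexfa_eval>\n")
  print(x$table)
  cat("mean over terms:",
      paste(sprintf("%s = %.4g", names(x$means), x$means), collapse = ", "),
      "\n")
  sch <- x$scheme
  cat(sprintf("scheme: voting=%s classifier=%s cv=%s level=%s\n",
              sch$voting, sch$classifier, sch$cv_scheme, sch$level))
  invisible(x)
}

#' @method tidy spexfa_eval
#' @export
tidy.spexfa_eval <- function(x, ...) x$table

#' @method glance spexfa_eval
#' @export
glance.spexfa_eval <- function(x, ...) {
  tibble::as_tibble(as.list(x$means)) |>
    dplyr::mutate(n_terms = nrow(x$table), voting = x$scheme$voting,
                  classifier = x$scheme$classifier, level = x$scheme$level)
}

#' Plot per-term evaluation metrics
#'
#' @param object A `spexfa_eval` report.
#' @param ... Unused.
#' @return A ggplot bar chart of the first metric column by term, with
#'   the mean drawn as a dashed line.
#' @method autoplot spexfa_eval
#' @export
autoplot.spexfa_eval <- function(object, ...) {
  metric <- names(object$means)[1]
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term,
                                                      -.data[[metric]]),
                                   y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$means[[metric]],
                        linetype = "dashed") +
    ggplot2::labs(x = "annotation term", y = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
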