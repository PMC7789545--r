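#' Collapse seven topics to the four-topic granularity
#'
#' Information, Evaluation, Order and Insurance merge into Information; the
#' result topics Positive, Negative and VUS are unchanged.
#'
#' @param labels character or factor of seven-topic labels
#' @return character vector of four-topic labels
#' @export
coarse_labels <- function(labels) {
  l <- as.character(labels)
  l[l %in% c("Information", "Evaluation", "Order", "Insurance")] <- "Information"
  l
}

#' Bag-of-words vectorization of normalized sentences
#'
#' Fits a vocabulary (sorted unique tokens) on the given sentences and
#' returns a sparse token-count matrix. When \code{vocab} is supplied the
#' matrix is built over that fixed vocabulary and unseen tokens are ignored —
#' the prediction-time contract used inside cross-validation, where the
#' vocabulary is fitted on training folds only.
#'
#' @param sentences normalized sentence data.frame with a \code{tokens} list
#'   column (or a bare list of token vectors)
#' @param vocab optional fixed vocabulary
#' @return list with \code{x} (dgCMatrix, rows = sentences) and \code{vocab}
#' @export
vectorize <- function(sentences, vocab = NULL) {
  toks <- if (is.data.frame(sentences)) sentences$tokens else sentences
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(toks, use.names = FALSE)))
    if (!length(vocab)) stop("empty vocabulary")
  }
  i <- rep(seq_along(toks), lengths(toks))
  j <- match(unlist(toks, use.names = FALSE), vocab)
  keep <- !is.na(j)
  x <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(toks), length(vocab)),
                            dimnames = list(NULL, vocab))
  list(x = x, vocab = vocab)
}

stratified_folds <- function(labels, n_folds, classes = unique(labels)) {
  fold <- integer(length(labels))
  small <- character()
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) small <- c(small, cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(n_folds), length(idx))
  }
  if (length(small))
    warning("class(es) with fewer members than folds (non-stratified coverage): ",
            paste(small, collapse = ", "))
  fold
}

#' Cross-validated tree-ensemble topic classification
#'
#' Stratified k-fold cross-validation (default ten-fold) of the bagged
#' randomized-tree classifier at either topic granularity. Within each fold
#' the vocabulary is fitted on the training sentences only; tokens unseen in
#' training contribute nothing at prediction time. The report aggregates
#' out-of-fold predictions: per-class precision/recall/F with supports, and
#' overall metrics computed two ways (micro and support-weighted macro).
#' Feature importance comes from a final ensemble fitted on the full data.
#' Deterministic given \code{seed}.
#'
#' @param sentences normalized sentence data.frame with \code{tokens}
#' @param labels seven-topic gold labels, one per sentence
#' @param granularity "seven" or "four" (coarse) classification task
#' @param n_folds number of folds (default 10)
#' @param seed integer seed governing folds, bootstraps and feature sampling
#' @param n_trees,mtry,min_node,max_depth passed to \code{rf_fit()}
#' @return object of class \code{rwe_cv}: list with \code{per_class},
#'   \code{overall}, \code{predictions} (out-of-fold), \code{folds},
#'   \code{feature_importance}, \code{granularity}, \code{seed}
#' @export
crossvalidate <- function(sentences, labels, granularity = c("seven", "four"),
                          n_folds = 10, seed = 13L, n_trees = 500,
                          mtry = NULL, min_node = 1L, max_depth = Inf) {
  granularity <- match.arg(granularity)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(sentences), nrow(sentences) >= n_folds)
  if (granularity == "four") labels <- coarse_labels(labels)
  y <- factor(labels)
  stopifnot(nlevels(y) >= 2)
  with_seed(seed, {
    fold <- stratified_folds(labels, n_folds, levels(y))
    pred <- character(length(labels))
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (!length(te)) next
      vt <- vectorize(sentences$tokens[tr])
      m <- if (is.null(mtry)) max(1L, floor(sqrt(length(vt$vocab)))) else mtry
      fit <- rf_fit(vt$x, droplevels(y[tr]), n_trees = n_trees, mtry = m,
                    min_node = min_node, max_depth = max_depth)
      xte <- vectorize(sentences$tokens[te], vocab = vt$vocab)$x
      pred[te] <- as.character(predict(fit, xte))
    }
    vfull <- vectorize(sentences$tokens)
    m <- if (is.null(mtry)) max(1L, floor(sqrt(length(vfull$vocab)))) else mtry
    final <- rf_fit(vfull$x, y, n_trees = n_trees, mtry = m,
                    min_node = min_node, max_depth = max_depth)
  })
  tab <- prf_table(labels, pred, classes = levels(y))
  structure(list(per_class = tab$per_class, overall = tab$overall,
                 predictions = pred, gold = labels, folds = fold,
                 feature_importance = rf_importance(final),
                 model = final, granularity = granularity,
                 n_folds = n_folds, seed = seed),
            class = "rwe_cv")
}

#' @export
print.rwe_cv <- function(x, ...) {
  cat(sprintf("%s-fold cross-validation, %s-topic task (seed %d)\n",
              x$n_folds, x$granularity, x$seed))
  print(x$per_class, row.names = FALSE)
  cat("overall:\n")
  print(round(x$overall, 3))
  cat("top features:",
      paste(head(x$feature_importance$token, 8), collapse = ", "), "\n")
  invisible(x)
}
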