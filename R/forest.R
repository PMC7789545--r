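## Bagged ensemble of randomized CART-style classification trees, written
## in-package because no tree learner ships with this environment. Features
## are token counts, which in sentence classification are near-binary, so
## splits are presence splits (x > 0): this keeps split search a single
## matrix crossproduct per node and changes nothing for 0/1 data.

gini_from_counts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  1 - sum((cnt / n)^2)
}

grow_tree <- function(xb, y, k, mtry, min_node, max_depth) {
  # xb: dense 0/1 matrix (n x p); y: integer class codes 1..k
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  # stack of (row index set, depth, slot to fill)
  grow <- function(idx, depth) {
    id <- new_node()
    nodes[id] <<- list(NULL)  # reserve the slot (keeps child ids stable)
    cnt <- tabulate(y[idx], k)
    g <- gini_from_counts(cnt)
    leafify <- function() {
      nodes[[id]] <<- list(leaf = TRUE, pred = which.max(cnt), n = length(idx))
      id
    }
    if (g == 0 || length(idx) < 2 * min_node || depth >= max_depth) return(leafify())
    feats <- sample.int(ncol(xb), min(mtry, ncol(xb)))
    feats <- sort(feats)
    xs <- xb[idx, feats, drop = FALSE]
    yind <- matrix(0, length(idx), k)
    yind[cbind(seq_along(idx), y[idx])] <- 1
    right_cnt <- crossprod(xs, yind)           # |feats| x k
    nR <- rowSums(right_cnt)
    left_cnt <- matrix(cnt, nrow(right_cnt), k, byrow = TRUE) - right_cnt
    nL <- length(idx) - nR
    pR <- right_cnt / pmax(nR, 1)
    pL <- left_cnt / pmax(nL, 1)
    child_imp <- (nL * (1 - rowSums(pL^2)) + nR * (1 - rowSums(pR^2))) / length(idx)
    gain <- g - child_imp
    gain[nL == 0 | nR == 0] <- -Inf
    best <- which.max(gain)
    if (!is.finite(gain[best]) || gain[best] <= 1e-12) return(leafify())
    f <- feats[best]
    go_right <- xb[idx, f] > 0
    nodes[[id]] <<- list(leaf = FALSE, feature = f, n = length(idx),
                         decrease = gain[best] * length(idx))
    left_id <- grow(idx[!go_right], depth + 1L)
    right_id <- grow(idx[go_right], depth + 1L)
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  grow(seq_len(nrow(xb)), 0L)
  nodes
}

#' Fit a bagged randomized-tree classifier
#'
#' An ensemble of CART-style trees, each grown on a bootstrap sample with a
#' fresh random feature subset of size \code{mtry} evaluated at every node
#' (Gini impurity criterion, presence splits on token counts). Prediction is
#' by majority vote. Feature importance is the mean decrease in Gini impurity
#' (weighted by node size) together with the number of nodes splitting on
#' each feature.
#'
#' @param x numeric matrix or \code{Matrix::dgCMatrix} of token counts
#'   (rows = sentences, columns = vocabulary)
#' @param y factor of class labels
#' @param n_trees number of trees (default 500)
#' @param mtry features sampled per node (default \code{floor(sqrt(ncol(x)))})
#' @param min_node minimum node size to attempt a split (default 1)
#' @param max_depth depth cap (default unlimited)
#' @return object of class \code{rwe_forest}
#' @export
rf_fit <- function(x, y, n_trees = 500, mtry = max(1L, floor(sqrt(ncol(x)))),
                   min_node = 1L, max_depth = Inf) {
  y <- droplevels(as.factor(y))
  stopifnot(nrow(x) == length(y), ncol(x) >= 1)
  xb <- as.matrix(x)
  xb[xb > 0] <- 1
  k <- nlevels(y)
  yi <- as.integer(y)
  n <- nrow(xb)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(xb[boot, , drop = FALSE], yi[boot], k, mtry,
                            min_node, max_depth)
    oob[[b]] <- setdiff(seq_len(n), unique(boot))
  }
  structure(list(trees = trees, levels = levels(y), vocab = colnames(x),
                 n_trees = n_trees, mtry = mtry, n_train = n, oob = oob),
            class = "rwe_forest")
}

predict_tree <- function(nodes, xb) {
  out <- integer(nrow(xb))
  route <- function(id, idx) {
    nd <- nodes[[id]]
    if (isTRUE(nd$leaf)) { out[idx] <<- nd$pred; return(invisible()) }
    go_right <- xb[idx, nd$feature] > 0
    if (any(!go_right)) route(nd$left, idx[!go_right])
    if (any(go_right)) route(nd$right, idx[go_right])
  }
  if (nrow(xb)) route(1L, seq_len(nrow(xb)))
  out
}

#' Predict topics with a fitted tree ensemble
#' @param object an \code{rwe_forest}
#' @param newdata matrix with the same columns as the training matrix (or a
#'   superset/reordering carrying matching column names)
#' @param type "class" (majority vote) or "votes" (vote count matrix)
#' @param ... unused
#' @export
predict.rwe_forest <- function(object, newdata, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  xb <- as.matrix(newdata)
  if (!is.null(object$vocab) && !is.null(colnames(xb))) {
    m <- matrix(0, nrow(xb), length(object$vocab),
                dimnames = list(NULL, object$vocab))
    common <- intersect(colnames(xb), object$vocab)
    m[, common] <- xb[, common, drop = FALSE]
    xb <- m
  }
  xb[xb > 0] <- 1
  k <- length(object$levels)
  votes <- matrix(0L, nrow(xb), k, dimnames = list(NULL, object$levels))
  for (tr in object$trees) {
    p <- predict_tree(tr, xb)
    votes[cbind(seq_len(nrow(xb)), p)] <- votes[cbind(seq_len(nrow(xb)), p)] + 1L
  }
  if (type == "votes") return(votes)
  factor(object$levels[max.col(votes, ties.method = "first")], levels = object$levels)
}

#' Impurity-based feature importance of a fitted ensemble
#'
#' Tokens ranked by mean decrease in Gini impurity (per-tree decreases are
#' size-weighted and normalized by the root size, then averaged over trees);
#' the node-usage count reports in how many internal nodes each token was the
#' splitting feature.
#'
#' @param object an \code{rwe_forest}
#' @return data.frame (token, importance, n_nodes) sorted by decreasing
#'   importance
#' @export
rf_importance <- function(object) {
  p <- length(object$vocab %||% integer())
  if (!p) stop("model was fitted without column names")
  imp <- numeric(p)
  nn <- integer(p)
  for (tr in object$trees) {
    root_n <- tr[[1]]$n
    for (nd in tr) {
      if (!isTRUE(nd$leaf)) {
        imp[nd$feature] <- imp[nd$feature] + nd$decrease / root_n
        nn[nd$feature] <- nn[nd$feature] + 1L
      }
    }
  }
  out <- data.frame(token = object$vocab, importance = imp / object$n_trees,
                    n_nodes = nn, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$token), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.rwe_forest <- function(x, ...) {
  cat("Bagged randomized-tree classifier:", x$n_trees, "trees, mtry =", x$mtry,
      "\n  classes:", paste(x$levels, collapse = ", "),
      "\n  vocabulary:", length(x$vocab %||% integer()), "tokens\n")
  invisible(x)
}
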