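#' Sentence universality scores (sf-ipf)
#'
#' For each unique normalized sentence s, computes
#' \deqn{sf(s) = \frac{\#s}{\mathrm{total\ \#\ sentences}}, \quad
#'       ipf(s) = \frac{\log N}{\#\ \mathrm{patients\ with}\ s}, \quad
#'       \mathrm{sfipf}(s) = sf(s)\,ipf(s)}
#' where N is the cohort size. Boilerplate sentences shared by many patients
#' score high; patient-specific result sentences score low. The log is
#' natural by default (configurable base).
#'
#' @param sentences normalized sentence data.frame (needs \code{patient_id},
#'   \code{norm_text}; \code{raw_text} used for display)
#' @param n_patients cohort size N; defaults to the number of distinct
#'   patient ids present in \code{sentences}
#' @param log_base base of the ipf logarithm (default natural)
#' @return data.frame with one row per unique sentence: \code{sentence_key}
#'   (the normalized text), \code{text}, \code{count}, \code{n_patients_with},
#'   \code{sf}, \code{ipf}, \code{score}, sorted by increasing score
#' @export
sf_ipf <- function(sentences, n_patients = length(unique(sentences$patient_id)),
                   log_base = exp(1)) {
  if (!nrow(sentences)) stop("empty corpus")
  stopifnot(n_patients >= 1)
  key <- sentences$norm_text
  total <- length(key)
  cnt <- table(key)
  npat <- tapply(sentences$patient_id, key, function(p) length(unique(p)))
  keys <- names(cnt)
  first_idx <- match(keys, key)
  out <- data.frame(
    sentence_key = keys,
    text = (sentences$raw_text %||% sentences$norm_text)[first_idx],
    count = as.integer(cnt),
    n_patients_with = as.integer(npat[keys]),
    stringsAsFactors = FALSE
  )
  out$sf <- out$count / total
  out$ipf <- log(n_patients, base = log_base) / out$n_patients_with
  out$score <- out$sf * out$ipf
  out <- out[order(out$score, out$sentence_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select low-universality sentences plus a random sample of the rest
#'
#' Splits scored sentences into the below-threshold set (candidate
#' patient-specific sentences for manual review) and a seeded random sample
#' without replacement from the remainder, mirroring a stratified review
#' set-up (e.g. all sentences with score < 0.5 plus 50 random others).
#'
#' @param scores output of \code{sf_ipf()}
#' @param threshold score cut-off (default 0.5)
#' @param n_random size of the random sample from the remainder (default 50);
#'   if the remainder is smaller, all of it is returned
#' @param seed integer seed; the same seed always yields the same sample
#' @return list with data.frames \code{below} and \code{sampled}
#' @export
select_universal <- function(scores, threshold = 0.5, n_random = 50, seed = 1L) {
  stopifnot(threshold > 0, n_random >= 0)
  below <- scores[scores$score < threshold, , drop = FALSE]
  rest <- scores[scores$score >= threshold, , drop = FALSE]
  n <- min(n_random, nrow(rest))
  idx <- if (n > 0) with_seed(seed, sample.int(nrow(rest), n)) else integer()
  list(below = below, sampled = rest[sort(idx), , drop = FALSE])
}

#' Word-topic pointwise mutual information table
#'
#' Ranks words as topic indicators by
#' \deqn{\mathrm{pmi}(w,t) = \log \frac{P(w,t)}{P(w)P(t)}}
#' with probabilities estimated from token counts over the word-by-topic grid
#' under add-k smoothing (each word counted once per sentence occurrence).
#' With k = 0, entries with zero joint count are omitted with a warning (their
#' PMI is undefined).
#'
#' @param sentences normalized sentence data.frame with a \code{tokens} list
#'   column
#' @param labels topic label per sentence (character or factor, recycled
#'   against rows of \code{sentences})
#' @param smoothing_k add-k smoothing constant (default 0.5)
#' @param positive_only when TRUE (default) only word-topic pairs actually
#'   observed are returned; set FALSE to get the full smoothed grid
#' @return data.frame (word, topic, pmi, count_wt, count_w, count_t), sorted
#'   within topic by decreasing pmi
#' @export
pmi_table <- function(sentences, labels, smoothing_k = 0.5, positive_only = TRUE) {
  stopifnot(smoothing_k >= 0)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(sentences), !anyNA(labels))
  toks <- lapply(sentences$tokens, unique)
  n_tok <- lengths(toks)
  w <- unlist(toks, use.names = FALSE)
  t_rep <- rep(labels, n_tok)
  if (!length(w)) stop("no tokens in corpus")
  tab <- table(word = w, topic = t_rep)
  W <- nrow(tab); K <- ncol(tab); C <- sum(tab)
  k <- smoothing_k
  cw <- rowSums(tab); ct <- colSums(tab)
  denom_total <- C + k * W * K
  pmi <- log(sweep(sweep((tab + k) * denom_total, 1, cw + K * k, "/"), 2, ct + W * k, "/"))
  out <- data.frame(
    word = rep(rownames(tab), K),
    topic = rep(colnames(tab), each = W),
    pmi = as.vector(pmi),
    count_wt = as.vector(tab),
    count_w = rep(as.vector(cw), K),
    count_t = rep(as.vector(ct), each = W),
    stringsAsFactors = FALSE
  )
  if (k == 0) {
    zero <- out$count_wt == 0
    if (any(zero)) {
      warning(sum(zero), " word-topic pair(s) omitted: zero joint count with k = 0")
      out <- out[!zero, , drop = FALSE]
    }
  } else if (positive_only) {
    out <- out[out$count_wt > 0, , drop = FALSE]
  }
  out <- out[order(out$topic, -out$pmi, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}
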