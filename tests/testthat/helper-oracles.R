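# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive each quantity from first
# principles with different code paths.

# sf-ipf by naive two-pass counting
sfipf_oracle <- function(patient_id, norm_text, n_patients) {
  total <- length(norm_text)
  out <- list()
  for (s in unique(norm_text)) {
    idx <- which(norm_text == s)
    sf <- length(idx) / total
    np <- length(unique(patient_id[idx]))
    ipf <- log(n_patients) / np
    out[[s]] <- c(sf = sf, ipf = ipf, score = sf * ipf)
  }
  out
}

# PMI by direct probability arithmetic over the smoothed grid
pmi_oracle <- function(tokens_list, labels, k) {
  words <- sort(unique(unlist(lapply(tokens_list, unique))))
  topics <- sort(unique(labels))
  cwt <- matrix(0, length(words), length(topics), dimnames = list(words, topics))
  for (i in seq_along(tokens_list))
    for (w in unique(tokens_list[[i]]))
      cwt[w, labels[i]] <- cwt[w, labels[i]] + 1
  C <- sum(cwt); W <- length(words); K <- length(topics)
  tot <- C + k * W * K
  res <- list()
  for (w in words) for (t in topics) {
    pwt <- (cwt[w, t] + k) / tot
    pw <- (sum(cwt[w, ]) + K * k) / tot
    pt <- (sum(cwt[, t]) + W * k) / tot
    res[[paste(w, t)]] <- log(pwt / (pw * pt))
  }
  res
}

# exhaustive indicator-gene pairing with nearest + window rules
positivity_oracle <- function(tokens, gene_pos, gene_sym, ind_pos, ind_status, window) {
  out <- list()
  for (i in seq_along(ind_pos)) {
    d <- abs(gene_pos - ind_pos[i]) - 1L
    d[d < 0] <- 0L
    best <- which(d == min(d))[1]
    if (d[best] <= window)
      out[[length(out) + 1L]] <- list(gene = gene_sym[best], status = ind_status[i],
                                      distance = d[best])
  }
  out
}

# two-sided Fisher p for a 2x2 table by direct hypergeometric summation
fisher_2x2_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, rs[1], rs[2], cs[1])
  p_obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# number of nonnegative integer matrices with fixed margins (memoized DP,
# counting only -- no probabilities)
count_tables_oracle <- function(rs, cs) {
  memo <- new.env()
  rec <- function(i, rem) {
    if (i > length(rs)) return(as.numeric(all(rem == 0)))
    key <- paste(i, paste(rem, collapse = ","))
    if (!is.null(memo[[key]])) return(memo[[key]])
    # enumerate compositions of rs[i] bounded by rem
    comp <- function(j, left, rem2) {
      if (j == length(rem2)) {
        if (left <= rem2[j]) { rem2[j] <- rem2[j] - left; return(rec(i + 1, rem2)) }
        return(0)
      }
      tot <- 0
      for (v in 0:min(left, rem2[j])) {
        r3 <- rem2; r3[j] <- r3[j] - v
        tot <- tot + comp(j + 1, left - v, r3)
      }
      tot
    }
    memo[[key]] <- comp(1, rs[i], rem)
    memo[[key]]
  }
  rec(1, cs)
}

# precision/recall/F by a second direct implementation
prf_oracle <- function(tp, fp, fn) {
  c(precision = tp / (tp + fp), recall = tp / (tp + fn),
    f = 2 * tp / (2 * tp + fp + fn))
}

# Cohen's kappa from the full contingency table
kappa_oracle <- function(a, b) {
  lv <- union(a, b)
  tab <- table(factor(a, lv), factor(b, lv))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# canonical key for a gene-switch discrepancy (unordered gene pair)
switch_key <- function(p, a, b) paste(p, pmin(a, b), pmax(a, b))

# quick sentence-corpus constructor
mk_sentences <- function(text, patient_id = "p1", note_id = NULL, date = "2020-01-01") {
  n <- length(text)
  data.frame(patient_id = rep_len(patient_id, n),
             note_id = note_id %||% sprintf("n%03d", seq_len(n)),
             date = rep_len(date, n), text = text, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
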