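#' The seven clinical-context topics
#' @return character vector of topic labels, in rule priority order for
#'   result topics first
#' @export
topic_labels <- function() {
  c("Information", "Evaluation", "Insurance", "Order", "Negative", "Positive", "VUS")
}

# split configured indicator entries (possibly multi-word phrases) into
# lemmatized token vectors
lemmatize_phrases <- function(phrases, stopwords = character()) {
  lapply(phrases, function(p) {
    t <- stringi::stri_split_regex(tolower(p), "[^a-z0-9]+")[[1]]
    t <- t[nzchar(t) & !t %in% stopwords]
    lemmatize_tokens(t)
  })
}

#' Construct a rule set for topic classification
#'
#' Indicator words are given in natural form and lemmatized with the same
#' suffix rules the normalizer applies, so rules match normalized tokens.
#' Multi-word entries are matched as consecutive token phrases. Conditional
#' indicators fire only when a primary indicator of the same topic is also
#' present (they never decide a topic on their own). The shipped defaults are
#' seeded from high-PMI topic-indicating words (family/history/hereditary for
#' Evaluation, insurance, order, risk, vus, negative, pathogenic, ...) and are
#' a faithful skeleton, not a full converged clinical rule set; extend them
#' via YAML (\code{read_ruleset()}).
#'
#' @param indicator_words named list (topic -> character vector) of primary
#'   context indicators for Information/Evaluation/Insurance/Order
#' @param conditional_indicators named list of conditional context indicators
#' @param positivity_indicators words asserting a pathogenic/positive result
#' @param negativity_indicators words asserting a negative/wildtype result
#' @param vus_indicators words/phrases asserting a VUS result
#' @param proximity_window maximum intervening tokens between a result
#'   indicator and the gene it binds to (default 5; bindings farther apart
#'   are rejected)
#' @param negation_cues tokens that flip a positivity indicator to
#'   negativity when within \code{negation_window} tokens before it
#' @param negation_window token window for negation flips (default 3)
#' @param priority_order tie-breaking topic order, most specific first
#' @return object of class \code{rwe_ruleset}
#' @export
ruleset <- function(indicator_words = NULL, conditional_indicators = NULL,
                    positivity_indicators = c("positive", "pathogenic",
                                              "deleterious", "actionable", "mutated"),
                    negativity_indicators = c("negative", "wildtype",
                                              "unremarkable", "no mutation"),
                    vus_indicators = c("vus", "unknown significance",
                                       "uncertain significance"),
                    proximity_window = 5L,
                    negation_cues = c("no", "not", "without", "never"),
                    negation_window = 3L,
                    priority_order = c("VUS", "Positive", "Negative", "Insurance",
                                       "Order", "Evaluation", "Information")) {
  if (is.null(indicator_words)) indicator_words <- list(
    Insurance = c("insurance", "coverage", "copay", "preauthorization",
                  "authorization", "payer"),
    Order = c("order", "ordered", "pending", "awaiting", "specimen",
              "requisition", "submitted"),
    Evaluation = c("risk", "family", "history", "hereditary", "carrier",
                   "counseling", "probability"),
    Information = c("guideline", "panel", "pathway", "education",
                    "information", "brochure", "criteria")
  )
  if (is.null(conditional_indicators)) conditional_indicators <- list(
    Insurance = c("denied", "approved", "company"),
    Order = c("results", "waiting", "sample"),
    Evaluation = c("benefit", "relative", "estimate"),
    Information = c("discussed", "reviewed", "implication")
  )
  stopifnot(proximity_window >= 1, negation_window >= 0)
  sw <- default_stopwords()
  rs <- list(
    indicator_words = lapply(indicator_words, lemmatize_phrases, stopwords = sw),
    conditional_indicators = lapply(conditional_indicators, lemmatize_phrases, stopwords = sw),
    positivity = lemmatize_phrases(positivity_indicators, sw),
    negativity = lemmatize_phrases(negativity_indicators, sw),
    vus = lemmatize_phrases(vus_indicators, sw),
    proximity_window = as.integer(proximity_window),
    negation_cues = lemmatize_tokens(tolower(negation_cues)),
    negation_window = as.integer(negation_window),
    priority_order = priority_order
  )
  # collapse lemma-identical entries within a topic, then require pairwise
  # disjointness across topics within each granularity
  dedupe <- function(ps) ps[!duplicated(vapply(ps, paste, character(1), collapse = " "))]
  rs$indicator_words <- lapply(rs$indicator_words, dedupe)
  rs$conditional_indicators <- lapply(rs$conditional_indicators, dedupe)
  rs$positivity <- dedupe(rs$positivity)
  rs$negativity <- dedupe(rs$negativity)
  rs$vus <- dedupe(rs$vus)
  ctx <- lapply(rs$indicator_words, function(ps) vapply(ps, paste, character(1), collapse = " "))
  if (anyDuplicated(unlist(ctx)))
    stop("context indicator sets are not pairwise disjoint")
  res <- lapply(rs[c("positivity", "negativity", "vus")],
                function(ps) vapply(ps, paste, character(1), collapse = " "))
  if (anyDuplicated(unlist(res)))
    stop("result indicator sets are not pairwise disjoint")
  class(rs) <- "rwe_ruleset"
  rs
}

#' Read a rule set from a YAML file
#'
#' The YAML may define any of the arguments of \code{ruleset()} (per-topic
#' word lists under \code{indicator_words} / \code{conditional_indicators},
#' the result indicator vectors, and the window sizes); omitted entries fall
#' back to the shipped defaults.
#'
#' @param path YAML file path
#' @return \code{rwe_ruleset}
#' @export
read_ruleset <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("indicator_words", "conditional_indicators", "positivity_indicators",
               "negativity_indicators", "vus_indicators", "proximity_window",
               "negation_cues", "negation_window", "priority_order")
  cfg <- cfg[intersect(names(cfg), allowed)]
  do.call(ruleset, cfg)
}

#' @export
print.rwe_ruleset <- function(x, ...) {
  cat("Rule set for seven-topic sentence classification\n")
  for (tp in names(x$indicator_words))
    cat(sprintf("  %-12s %s\n", tp,
                paste(vapply(x$indicator_words[[tp]], paste, character(1), collapse = " "),
                      collapse = ", ")))
  cat("  result indicators: +", length(x$positivity), " / -", length(x$negativity),
      " / vus ", length(x$vus), "; window ", x$proximity_window, " tokens\n", sep = "")
  invisible(x)
}

# locate phrase occurrences in a token vector; returns data.frame(first, last)
locate_phrases <- function(tokens, phrases) {
  hits <- list()
  for (ph in phrases) {
    L <- length(ph)
    if (L == 0 || length(tokens) < L) next
    if (L == 1) {
      idx <- which(tokens == ph)
      if (length(idx)) hits[[length(hits) + 1L]] <-
          data.frame(first = idx, last = idx, phrase = ph)
    } else {
      starts <- which(tokens == ph[1])
      ok <- starts[vapply(starts, function(s) {
        s + L - 1 <= length(tokens) && all(tokens[s:(s + L - 1)] == ph)
      }, logical(1))]
      if (length(ok)) hits[[length(hits) + 1L]] <-
          data.frame(first = ok, last = ok + L - 1L,
                     phrase = paste(ph, collapse = " "))
    }
  }
  if (!length(hits)) return(data.frame(first = integer(), last = integer(),
                                       phrase = character()))
  out <- do.call(rbind, hits)
  out[order(out$first), , drop = FALSE]
}

# token positions of gene mentions, with resolved symbols. Target genes keep
# their symbol as a token; masked non-target genes appear as "gene" tokens and
# are mapped, in order, back to the record's non-target mentions.
gene_token_positions <- function(tokens, gene_mentions, targets = c("BRCA1", "BRCA2")) {
  tgt <- tolower(targets)
  pos <- which(tokens %in% c(tgt, "gene"))
  if (!length(pos)) return(data.frame(pos = integer(), symbol = character()))
  nt <- gene_mentions[!gene_mentions$is_target, , drop = FALSE]
  k <- 0L
  sym <- vapply(pos, function(i) {
    if (tokens[i] == "gene") {
      k <<- k + 1L
      if (k <= nrow(nt)) nt$symbol[k] else "GENE"
    } else toupper(tokens[i])
  }, character(1))
  data.frame(pos = pos, symbol = sym, stringsAsFactors = FALSE)
}

#' Bind result indicators to their nearest gene mention
#'
#' Scans the normalized token sequence for positivity, negativity and VUS
#' indicators. A negation cue within \code{negation_window} tokens before a
#' positivity indicator flips it to negativity. Each indicator then binds to
#' the nearest gene mention by token distance (number of tokens strictly
#' between; ties broken toward the leftmost gene) and the binding is rejected
#' when the distance exceeds the proximity window (default: more than five
#' intervening tokens).
#'
#' @param tokens normalized token vector of one sentence
#' @param gene_mentions the sentence's gene-mention data.frame (from
#'   \code{recognize_mentions()})
#' @param rules an \code{rwe_ruleset}
#' @param targets target gene symbols
#' @return data.frame of assertions: gene, status (pathogenic/wildtype/vus),
#'   indicator_token, distance, gene_pos, indicator_pos
#' @export
assign_positivity <- function(tokens, gene_mentions, rules = ruleset(),
                              targets = c("BRCA1", "BRCA2")) {
  empty <- data.frame(gene = character(), status = character(),
                      indicator_token = character(), distance = integer(),
                      gene_pos = integer(), indicator_pos = integer(),
                      stringsAsFactors = FALSE)
  genes <- gene_token_positions(tokens, gene_mentions, targets)
  if (!nrow(genes)) return(empty)
  tag <- function(hits, status) {
    hits$status <- rep_len(status, nrow(hits))
    hits
  }
  ind <- rbind(
    tag(locate_phrases(tokens, rules$positivity), "pathogenic"),
    tag(locate_phrases(tokens, rules$negativity), "wildtype"),
    tag(locate_phrases(tokens, rules$vus), "vus")
  )
  if (!nrow(ind)) return(empty)
  # negation flip: cue within negation_window tokens before a positivity hit
  if (rules$negation_window > 0) {
    for (i in which(ind$status == "pathogenic")) {
      lo <- max(1L, ind$first[i] - rules$negation_window)
      if (ind$first[i] > 1 && any(tokens[lo:(ind$first[i] - 1L)] %in% rules$negation_cues))
        ind$status[i] <- "wildtype"
    }
  }
  rows <- lapply(seq_len(nrow(ind)), function(i) {
    # distance from the indicator phrase edge to each gene token
    d <- ifelse(genes$pos < ind$first[i], ind$first[i] - genes$pos - 1L,
                ifelse(genes$pos > ind$last[i], genes$pos - ind$last[i] - 1L, 0L))
    j <- which(d == min(d))[1]  # nearest; ties -> leftmost gene
    if (d[j] > rules$proximity_window) return(NULL)
    data.frame(gene = genes$symbol[j], status = ind$status[i],
               indicator_token = ind$phrase[i], distance = as.integer(d[j]),
               gene_pos = genes$pos[j], indicator_pos = ind$first[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

status_to_topic <- c(pathogenic = "Positive", wildtype = "Negative", vus = "VUS")

classify_one <- function(tokens, gene_mentions, rules, targets) {
  ass <- assign_positivity(tokens, gene_mentions, rules, targets)
  if (nrow(ass)) {
    present <- unique(status_to_topic[ass$status])
    for (tp in rules$priority_order) if (tp %in% present) return(tp)
  }
  for (tp in rules$priority_order) {
    prim <- rules$indicator_words[[tp]]
    if (is.null(prim)) next
    if (nrow(locate_phrases(tokens, prim))) return(tp)
  }
  "Information"
}

#' Rule-based seven-topic classification
#'
#' Result topics (Positive/Negative/VUS) take precedence over context topics
#' whenever a gene-bound result assertion is found; otherwise the
#' highest-priority context topic with a matching primary indicator wins, and
#' sentences matching nothing fall back to Information. Deterministic and
#' order-independent; every sentence receives exactly one label.
#'
#' @param sentences normalized, annotated sentence data.frame
#' @param rules an \code{rwe_ruleset}
#' @param targets target gene symbols
#' @return character vector of topic labels, one per sentence
#' @export
classify_rule <- function(sentences, rules = ruleset(), targets = c("BRCA1", "BRCA2")) {
  vapply(seq_len(nrow(sentences)), function(i) {
    classify_one(sentences$tokens[[i]], sentences$gene_mentions[[i]], rules, targets)
  }, character(1))
}

empty_variant_record <- function() {
  data.frame(Hugo_Symbol = "", Variant_Type = "", Variant_Source = "",
             Variant_Pathogenicity = "", Variant_Classification = "",
             HGVS_Short = "", De_sample_ID = "", Pathogeneity_Report_Date = "",
             Chromosome = "", Start_Position = NA_integer_,
             End_Position = NA_integer_, Strand = "",
             Variant_Allele_Freq = NA_real_, BP_Coverage = NA_real_,
             negative_flag = FALSE, patient_id = "", note_id = "",
             date = as.Date(NA), topic = "", stringsAsFactors = FALSE)
}

infer_variant_type <- function(kind, raw) {
  switch(kind,
         cdna = if (grepl(">", raw)) "SNP" else "INDEL",
         protein_3letter = if (grepl("fs|del|dup|ins", raw)) "INDEL" else "SNP",
         protein_shorthand = if (grepl("fs", raw)) "INDEL" else "SNP",
         cnv_term = "CNV",
         rearrangement_term = "Rearrangement",
         "")
}

classification_keywords <- list(
  Missense_Mutation = list(c("missense")),
  Nonsense_Mutation = list(c("nonsense")),
  Splice_Site = list(c("splice", "site"), c("splice_site")),
  Silent = list(c("silent")),
  Intron = list(c("intron"), c("intronic")),
  Frame_Shift_Del = list(c("frameshift"))
)

#' Curate a clinical-genomics variant record from a result assertion
#'
#' Populates the Table-style clinical-genomics data model row for one
#' gene-bound result assertion in one sentence. HGVS_Short is the nearest
#' syntactic variant mention (whitespace around ">" normalized away);
#' Variant_Type is inferred from the mention syntax (substitution -> SNP,
#' ins/del/dup/frameshift -> INDEL, amplification/deletion terms -> CNV,
#' rearrangement/truncation terms -> Rearrangement); Variant_Source is filled
#' only when "germline" or "somatic" occurs in the sentence;
#' Variant_Pathogenicity only on explicit wording (pathogenic / actionable /
#' vus as a token); Variant_Classification only when a classification keyword
#' (missense, nonsense, splice site, ...) appears. Absent fields are left
#' empty — the expected, not exceptional, outcome in clinical notes. Wildtype
#' assertions set \code{negative_flag} and leave pathogenicity empty.
#'
#' @param sentence one row of an annotated, normalized sentence data.frame
#' @param assertion one row of \code{assign_positivity()} output
#' @return one-row data.frame in the data-model layout
#' @export
extract_variant_record <- function(sentence, assertion) {
  rec <- empty_variant_record()
  rec$Hugo_Symbol <- assertion$gene
  rec$patient_id <- as.character(sentence$patient_id)
  rec$note_id <- as.character(sentence$note_id)
  rec$date <- sentence$date
  rec$topic <- status_to_topic[[assertion$status]]
  tokens <- sentence$tokens[[1]]
  vm <- sentence$variant_mentions[[1]]
  gm <- sentence$gene_mentions[[1]]
  if (assertion$status == "wildtype") rec$negative_flag <- TRUE

  if (nrow(vm)) {
    # anchor = char span of the asserted gene (match by symbol when possible)
    anchor <- gm[toupper(gm$symbol) == toupper(assertion$gene), , drop = FALSE]
    if (!nrow(anchor)) anchor <- gm
    amid <- if (nrow(anchor)) (anchor$start[1] + anchor$end[1]) / 2 else 0
    vmid <- (vm$start + vm$end) / 2
    v <- vm[order(abs(vmid - amid)), , drop = FALSE][1, ]
    syntactic <- !v$syntax_kind %in% c("cnv_term", "rearrangement_term")
    if (syntactic) rec$HGVS_Short <- gsub("\\s+", "", v$raw)
    rec$Variant_Type <- infer_variant_type(v$syntax_kind, v$raw)
  }
  if ("germline" %in% tokens) rec$Variant_Source <- "germline"
  else if ("somatic" %in% tokens) rec$Variant_Source <- "somatic"
  if (assertion$status == "vus") {
    if ("vus" %in% tokens) rec$Variant_Pathogenicity <- "VUS"
  } else if (assertion$status == "pathogenic") {
    if ("pathogenic" %in% tokens) rec$Variant_Pathogenicity <- "pathogenic"
    else if ("actionable" %in% tokens) rec$Variant_Pathogenicity <- "actionable"
  }
  for (cl in names(classification_keywords)) {
    if (nrow(locate_phrases(tokens, classification_keywords[[cl]]))) {
      rec$Variant_Classification <- cl
      if (cl == "Frame_Shift_Del" && nzchar(rec$HGVS_Short) &&
          grepl("ins|dup", rec$HGVS_Short))
        rec$Variant_Classification <- "Frame_Shift_Ins"
      break
    }
  }
  rec
}

#' Extract all variant records from a classified corpus
#'
#' Runs \code{assign_positivity()} on every sentence and curates one variant
#' record per gene-bound result assertion (deduplicated per sentence and
#' gene).
#'
#' @param sentences annotated, normalized sentence data.frame
#' @param rules an \code{rwe_ruleset}
#' @param targets target gene symbols
#' @return data.frame of variant records with provenance columns
#' @export
extract_variant_records <- function(sentences, rules = ruleset(),
                                    targets = c("BRCA1", "BRCA2")) {
  out <- list()
  for (i in seq_len(nrow(sentences))) {
    ass <- assign_positivity(sentences$tokens[[i]], sentences$gene_mentions[[i]],
                             rules, targets)
    if (!nrow(ass)) next
    ass <- ass[!duplicated(paste(ass$gene, ass$status)), , drop = FALSE]
    # one record per asserted gene; VUS > pathogenic > wildtype if conflicting
    for (g in unique(ass$gene)) {
      sub <- ass[ass$gene == g, , drop = FALSE]
      pick <- sub[order(match(sub$status, c("vus", "pathogenic", "wildtype"))), , drop = FALSE][1, ]
      out[[length(out) + 1L]] <- extract_variant_record(sentences[i, , drop = FALSE], pick)
    }
  }
  if (!length(out)) return(empty_variant_record()[0, ])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
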