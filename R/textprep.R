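#' Default English stopword list
#'
#' A compact English stopword list shipped with the package. Negation cues
#' (\code{no}, \code{not}, \code{nor}, \code{without}) are deliberately absent
#' so that downstream negation handling can see them in the normalized token
#' stream.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_en.txt", package = "rwegm"))
}

#' Default gene-symbol dictionary
#'
#' Small editable dictionary of HUGO gene symbols used for gene-mention
#' recognition. A full HUGO list can be supplied instead via
#' \code{read_gene_dict()} or any character vector.
#'
#' @return Character vector of uppercase HUGO symbols.
#' @export
default_gene_dict <- function() {
  readLines(system.file("extdata", "gene_symbols.txt", package = "rwegm"))
}

#' Read a gene dictionary from a plain-text file (one symbol per line)
#' @param path file path
#' @return character vector of symbols
#' @export
read_gene_dict <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read patient-linked sentence records
#'
#' Reads a sentence corpus with columns \code{patient_id}, \code{note_id},
#' \code{date} (ISO-8601) and \code{text}, from JSONL (one JSON object per
#' line) or CSV.
#'
#' @param path input file
#' @param format "auto" (by extension), "jsonl" or "csv"
#' @return data.frame with character ids, \code{Date} dates and \code{text}
#' @export
read_sentences <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
  }
  need <- c("patient_id", "note_id", "date", "text")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  df$date_raw <- as.character(df$date)
  df$date <- as.Date(df$date_raw, format = "%Y-%m-%d")
  df
}

#' Write enriched sentence records as JSONL
#' @param sentences a sentence data.frame (list columns are serialized)
#' @param path output path
#' @return invisibly, the path
#' @export
write_sentences <- function(sentences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    row <- lapply(sentences[i, , drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col
      if (inherits(v, "Date")) v <- format(v)
      v
    })
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Extract sentences mentioning target genes
#'
#' Keeps exactly the records whose raw text contains one of the target gene
#' symbols as a whole word, case-insensitively; input order is preserved.
#' Records with unparseable dates are dropped with a warning rather than
#' aborting the run.
#'
#' @param sentences data.frame with \code{patient_id}, \code{note_id},
#'   \code{date}, \code{text}
#' @param targets character vector of target gene symbols
#' @return the retained subset, with a \code{raw_text} column
#' @export
extract_target_sentences <- function(sentences, targets = c("BRCA1", "BRCA2")) {
  stopifnot(nrow(sentences) >= 0, length(targets) >= 1)
  if (!inherits(sentences$date, "Date")) {
    sentences$date <- as.Date(as.character(sentences$date), format = "%Y-%m-%d")
  }
  bad <- is.na(sentences$date)
  if (any(bad)) {
    warning(sum(bad), " record(s) dropped: unparseable date")
    sentences <- sentences[!bad, , drop = FALSE]
  }
  txt <- if ("raw_text" %in% names(sentences)) sentences$raw_text else sentences$text
  keep <- stringi::stri_detect_regex(txt, word_regex(targets))
  out <- sentences[keep, , drop = FALSE]
  out$raw_text <- if ("raw_text" %in% names(out)) out$raw_text else out$text
  rownames(out) <- NULL
  out
}

## --- mention recognition ------------------------------------------------

aa3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile","Leu",
         "Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val","Ter")

variant_patterns <- function() {
  aa <- paste(aa3, collapse = "|")
  list(
    cdna = paste0("\\bc\\.[0-9][0-9_+*?-]*(?:",
                  "\\s*[ACGTacgt]+\\s*>\\s*[ACGTacgt]+",
                  "|del(?:ins)?[ACGTacgt]*",
                  "|ins[ACGTacgt]*",
                  "|dup[ACGTacgt]*)"),
    protein_3letter = paste0("\\bp\\.\\(?(?:", aa, ")[0-9]+",
                             "(?:(?:", aa, ")|fs(?:\\*?[0-9]+)?|del|dup|ins|\\*|=)\\)?"),
    protein_shorthand = "\\b[ACDEFGHIKLMNPQRSTVWY][0-9]{1,5}(?:[ACDEFGHIKLMNPQRSTVWY*]|fs)\\b",
    cnv_term = "(?i)\\b(?:amplifications?|amplified|deletions?|deleted)\\b",
    rearrangement_term = "(?i)\\b(?:rearrangements?|rearranged|truncations?|truncating|truncated)\\b"
  )
}

# whitespace-word distance between two character spans: number of words
# strictly between end_a (0-based exclusive end) and start_b (1-based start)
word_distance <- function(text, end_a, start_b) {
  if (start_b - 1L <= end_a) return(0L)
  between <- substr(text, end_a + 1L, start_b - 1L)
  sum(nzchar(stringi::stri_split_regex(trimws(between), "\\s+")[[1]]))
}

#' Recognize gene and variant mentions in one sentence
#'
#' Gene mentions are whole-word, case-insensitive matches against a HUGO-style
#' dictionary. Variant mentions cover c.-prefixed cDNA changes (spaces around
#' ">" tolerated), p.-prefixed three-letter protein changes, shorthand protein
#' changes (e.g. S34F), and copy-number / rearrangement terms
#' ("amplification", "deletion", "rearrangement", "truncation") when they fall
#' within \code{term_window} words of a gene mention. Spans are 0-based,
#' half-open character offsets into \code{text}; mentions never overlap.
#'
#' @param text a single sentence
#' @param gene_dict character vector of gene symbols
#' @param targets symbols treated as targets (never masked)
#' @param term_window word-distance window for CNV/rearrangement terms
#' @return list with data.frames \code{genes} (symbol, start, end, is_target)
#'   and \code{variants} (raw, syntax_kind, start, end)
#' @export
recognize_mentions <- function(text, gene_dict = default_gene_dict(),
                               targets = c("BRCA1", "BRCA2"), term_window = 5L) {
  stopifnot(length(gene_dict) >= 1)
  genes <- data.frame(symbol = character(), start = integer(), end = integer(),
                      is_target = logical(), stringsAsFactors = FALSE)
  variants <- data.frame(raw = character(), syntax_kind = character(),
                         start = integer(), end = integer(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(list(genes = genes, variants = variants))

  loc <- stringi::stri_locate_all_regex(text, word_regex(gene_dict))[[1]]
  if (!all(is.na(loc))) {
    sym <- toupper(stringi::stri_sub(text, loc[, 1], loc[, 2]))
    genes <- data.frame(symbol = sym, start = loc[, 1] - 1L, end = loc[, 2],
                        is_target = sym %in% toupper(targets), stringsAsFactors = FALSE)
    rownames(genes) <- NULL
  }

  pats <- variant_patterns()
  vl <- list()
  for (kind in names(pats)) {
    loc <- stringi::stri_locate_all_regex(text, pats[[kind]])[[1]]
    if (all(is.na(loc))) next
    vl[[kind]] <- data.frame(raw = stringi::stri_sub(text, loc[, 1], loc[, 2]),
                             syntax_kind = kind, start = loc[, 1] - 1L,
                             end = loc[, 2], stringsAsFactors = FALSE)
  }
  if (length(vl)) {
    v <- do.call(rbind, vl)
    # syntactic kinds take precedence over term kinds, then longer matches
    kind_rank <- match(v$syntax_kind, names(pats))
    v <- v[order(kind_rank, v$start, -(v$end - v$start)), , drop = FALSE]
    keep <- rep(TRUE, nrow(v))
    taken <- genes[, c("start", "end"), drop = FALSE]
    for (i in seq_len(nrow(v))) {
      ov_gene <- nrow(taken) && any(v$start[i] < taken$end & v$end[i] > taken$start)
      ov_var <- FALSE
      if (any(keep[seq_len(i - 1L)])) {
        prev <- v[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], , drop = FALSE]
        ov_var <- any(v$start[i] < prev$end & v$end[i] > prev$start)
      }
      keep[i] <- !(ov_gene || ov_var)
    }
    v <- v[keep, , drop = FALSE]
    # term mentions only count near a gene mention
    is_term <- v$syntax_kind %in% c("cnv_term", "rearrangement_term")
    if (any(is_term)) {
      near <- vapply(which(is_term), function(i) {
        if (!nrow(genes)) return(FALSE)
        any(vapply(seq_len(nrow(genes)), function(g) {
          if (genes$end[g] <= v$start[i])
            word_distance(text, genes$end[g], v$start[i] + 1L) <= term_window
          else if (v$end[i] <= genes$start[g])
            word_distance(text, v$end[i], genes$start[g] + 1L) <= term_window
          else TRUE
        }, logical(1)))
      }, logical(1))
      drop <- which(is_term)[!near]
      if (length(drop)) v <- v[-drop, , drop = FALSE]
    }
    v <- v[order(v$start), , drop = FALSE]
    rownames(v) <- NULL
    variants <- v
  }
  list(genes = genes, variants = variants)
}

#' Annotate a sentence corpus with gene and variant mentions
#'
#' @param sentences data.frame with a \code{raw_text} (or \code{text}) column
#' @inheritParams recognize_mentions
#' @return \code{sentences} with list-columns \code{gene_mentions} and
#'   \code{variant_mentions}
#' @export
annotate_sentences <- function(sentences, gene_dict = default_gene_dict(),
                               targets = c("BRCA1", "BRCA2"), term_window = 5L) {
  txt <- sentences$raw_text %||% sentences$text
  men <- lapply(txt, recognize_mentions, gene_dict = gene_dict,
                targets = targets, term_window = term_window)
  sentences$raw_text <- txt
  sentences$gene_mentions <- I(lapply(men, `[[`, "genes"))
  sentences$variant_mentions <- I(lapply(men, `[[`, "variants"))
  sentences
}

## --- normalization ------------------------------------------------------

lemma_exceptions <- c(
  analyses = "analysis", diagnoses = "diagnosis", metastases = "metastasis",
  women = "woman", men = "man", children = "child", data = "data",
  criteria = "criterion", species = "species", ordering = "order",
  counseling = "counseling", screening = "screening", testing = "test",
  pending = "pending", during = "during", nothing = "nothing",
  something = "something", anything = "anything", everything = "everything",
  morning = "morning", evening = "evening", findings = "finding"
)

undouble <- function(w) {
  n <- nchar(w)
  if (n >= 3 && substr(w, n, n) == substr(w, n - 1, n - 1) &&
      !substr(w, n, n) %in% c("s", "l"))
    substr(w, 1, n - 1) else w
}

#' Deterministic suffix-rule lemmatizer
#'
#' Maps plural nouns to singular and strips -ing/-ed verb suffixes with a
#' small exception list. Purely rule-based: no model download, byte-for-byte
#' reproducible. Masked tokens and gene symbols pass through unchanged.
#'
#' @param tokens character vector of lowercase tokens
#' @return character vector of lemmas
#' @export
lemmatize_tokens <- function(tokens) {
  vapply(tokens, function(w) {
    if (w %in% names(lemma_exceptions)) return(unname(lemma_exceptions[[w]]))
    n <- nchar(w)
    if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 4 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
    if (n > 4 && (endsWith(w, "ches") || endsWith(w, "shes") ||
                  endsWith(w, "xes") || endsWith(w, "zes")))
      return(substr(w, 1, n - 2))
    if (n > 3 && endsWith(w, "s") && !endsWith(w, "ss") &&
        !endsWith(w, "us") && !endsWith(w, "is"))
      return(substr(w, 1, n - 1))
    if (n >= 6 && endsWith(w, "ing")) return(undouble(substr(w, 1, n - 3)))
    if (n > 4 && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n >= 5 && endsWith(w, "ed")) return(undouble(substr(w, 1, n - 2)))
    w
  }, character(1), USE.NAMES = FALSE)
}

mask_text <- function(raw_text, genes, variants) {
  pieces <- list()
  if (nrow(genes)) {
    ng <- genes[!genes$is_target, , drop = FALSE]
    if (nrow(ng)) pieces[[length(pieces) + 1L]] <-
      data.frame(start = ng$start, end = ng$end, repl = "GENE")
  }
  if (nrow(variants)) {
    sv <- variants[!variants$syntax_kind %in% c("cnv_term", "rearrangement_term"), , drop = FALSE]
    if (nrow(sv)) pieces[[length(pieces) + 1L]] <-
      data.frame(start = sv$start, end = sv$end, repl = "MUTATION")
  }
  if (!length(pieces)) return(raw_text)
  spans <- do.call(rbind, pieces)
  spans <- spans[order(-spans$start), , drop = FALSE]
  out <- raw_text
  for (i in seq_len(nrow(spans))) {
    out <- paste0(substr(out, 1, spans$start[i]), spans$repl[i],
                  substr(out, spans$end[i] + 1L, nchar(out)))
  }
  out
}

#' Normalize and mask annotated sentences
#'
#' Produces \code{masked_text} (non-target gene mentions replaced by "GENE",
#' syntactic variant mentions by "MUTATION"; target genes preserved) and a
#' normalized token sequence: lowercased, punctuation- and digit-only tokens
#' removed, stopwords removed, suffix-rule lemmatized, and optionally
#' restricted to a plain vocabulary filter (a stand-in for licensed concept
#' dictionaries; default none). Masked tokens and target gene symbols always
#' survive the vocabulary filter. \code{norm_text} is the space-joined token
#' sequence and defines sentence identity for deduplication. The operation is
#' idempotent: re-normalizing an already-normalized record is a no-op.
#'
#' @param sentences output of \code{annotate_sentences()}
#' @param stopwords character vector of stopwords
#' @param vocab_filter optional character vector; when given, tokens outside
#'   it (after lemmatization) are dropped
#' @param targets target gene symbols
#' @return \code{sentences} with \code{masked_text}, \code{tokens} (list
#'   column) and \code{norm_text} columns
#' @export
normalize_sentences <- function(sentences, stopwords = default_stopwords(),
                                vocab_filter = NULL, targets = c("BRCA1", "BRCA2")) {
  stopifnot(all(c("gene_mentions", "variant_mentions") %in% names(sentences)))
  keep_always <- c("gene", "mutation", tolower(targets))
  masked <- vapply(seq_len(nrow(sentences)), function(i) {
    mask_text(sentences$raw_text[i], sentences$gene_mentions[[i]],
              sentences$variant_mentions[[i]])
  }, character(1))
  toks <- lapply(masked, function(m) {
    t <- stringi::stri_split_regex(tolower(m), "[^a-z0-9_']+")[[1]]
    t <- gsub("'", "", t, fixed = TRUE)
    t <- t[nzchar(t)]
    t <- t[!grepl("^[0-9_]+$", t)]
    t <- t[!t %in% stopwords]
    t <- lemmatize_tokens(t)
    t <- t[nzchar(t)]
    if (!is.null(vocab_filter)) t <- t[t %in% c(vocab_filter, keep_always)]
    t
  })
  sentences$masked_text <- masked
  sentences$tokens <- I(toks)
  sentences$norm_text <- vapply(toks, paste, character(1), collapse = " ")
  sentences
}

#' Deduplicate sentences within each patient
#'
#' Within a patient, records with identical normalized text collapse to the
#' earliest-dated instance (date ties broken by lexicographically smallest
#' note_id). Identical sentences in different patients are all retained.
#' The result is invariant to input order; output is sorted by patient, date,
#' note_id.
#'
#' @param sentences normalized sentence data.frame (needs \code{patient_id},
#'   \code{date}, \code{note_id}, \code{norm_text})
#' @return the deduplicated subset
#' @export
deduplicate_per_patient <- function(sentences) {
  stopifnot("norm_text" %in% names(sentences))
  if (!nrow(sentences)) return(sentences)
  ord <- order(sentences$patient_id, sentences$norm_text, sentences$date,
               as.character(sentences$note_id))
  s <- sentences[ord, , drop = FALSE]
  key <- paste(s$patient_id, s$norm_text, sep = "\r")
  s <- s[!duplicated(key), , drop = FALSE]
  s <- s[order(s$patient_id, s$date, as.character(s$note_id)), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Split free-text notes into sentences
#'
#' Rule-based splitter on sentence-final punctuation and newlines, with a
#' guard list of common clinical abbreviations so "Dr." or "e.g." do not end a
#' sentence.
#'
#' @param text a character vector of note texts
#' @return list of character vectors of sentences (one element per note)
#' @export
split_sentences <- function(text) {
  guards <- c("dr", "mr", "mrs", "ms", "st", "vs", "e\\.g", "i\\.e", "etc", "approx", "no")
  protected <- stringi::stri_replace_all_regex(
    text, paste0("(?i)\\b(", paste(guards, collapse = "|"), ")\\."), "$1․")
  lapply(stringi::stri_split_regex(protected, "(?<=[.;!?])\\s+|\\n+"), function(ss) {
    ss <- gsub("․", ".", ss, fixed = TRUE)
    trimws(ss[nzchar(trimws(ss))])
  })
}

#' One-call corpus preparation pipeline
#'
#' Convenience wrapper: target-sentence extraction, mention recognition,
#' normalization/masking and per-patient deduplication.
#'
#' @inheritParams extract_target_sentences
#' @inheritParams annotate_sentences
#' @inheritParams normalize_sentences
#' @param dedup collapse within-patient duplicates (default TRUE)
#' @return enriched, deduplicated sentence data.frame
#' @export
prepare_corpus <- function(sentences, targets = c("BRCA1", "BRCA2"),
                           gene_dict = default_gene_dict(),
                           stopwords = default_stopwords(),
                           vocab_filter = NULL, dedup = TRUE) {
  s <- extract_target_sentences(sentences, targets)
  s <- annotate_sentences(s, gene_dict = gene_dict, targets = targets)
  s <- normalize_sentences(s, stopwords = stopwords,
                           vocab_filter = vocab_filter, targets = targets)
  if (dedup) s <- deduplicate_per_patient(s)
  s
}
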