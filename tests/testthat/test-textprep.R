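test_that("target-sentence extraction keeps exactly whole-word matches, case-insensitively", {
  df <- mk_sentences(c("Patient tested positive for BRCA1 mutation.",
                       "Family history of colon cancer.",
                       "brca2 VUS reported",
                       "the ABRCA1X protein"))  # embedded, no word boundary
  out <- extract_target_sentences(df)
  expect_identical(out$text, df$text[c(1, 3)])

  # brute-force boundary oracle on generated sentences
  set.seed(91)
  words <- c("brca1", "BRCA2", "breast", "cancer", "xbrca1", "brca2y", "tp53")
  txts <- replicate(50, paste(sample(words, sample(3:7, 1), replace = TRUE), collapse = " "))
  got <- extract_target_sentences(mk_sentences(txts))$text
  oracle <- vapply(txts, function(s) {
    any(tolower(strsplit(s, " ")[[1]]) %in% c("brca1", "brca2"))
  }, logical(1))
  expect_identical(got, txts[oracle])
})

test_that("unparseable dates reject the record with a warning, not a crash", {
  df <- mk_sentences(c("BRCA1 a", "BRCA1 b"), date = c("2020-01-01", "not-a-date"))
  expect_warning(out <- extract_target_sentences(df), "unparseable date")
  expect_identical(out$text, "BRCA1 a")
})

test_that("mention recognition covers HGVS syntaxes and proximity-gated terms", {
  m <- recognize_mentions("pathogenic BRCA2 p.Arg149Trp")
  expect_identical(m$genes$symbol, "BRCA2")
  expect_true(m$genes$is_target)
  expect_identical(m$variants$raw, "p.Arg149Trp")
  expect_identical(m$variants$syntax_kind, "protein_3letter")

  m <- recognize_mentions("c.7759C > T detected")
  expect_identical(m$variants$syntax_kind, "cdna")
  expect_identical(gsub("\\s", "", m$variants$raw), "c.7759C>T")

  expect_identical(recognize_mentions("")$genes, recognize_mentions("no match here")$genes)

  # term mentions require a gene within the window
  near <- recognize_mentions("BRCA1 amplification was seen")
  far <- recognize_mentions("amplification of one two three four five six BRCA1")
  expect_identical(near$variants$syntax_kind, "cnv_term")
  expect_identical(nrow(far$variants), 0L)

  # spans are 0-based half-open into the raw text
  s <- "BRCA2 S34F found"
  m <- recognize_mentions(s)
  expect_identical(substr(s, m$genes$start + 1, m$genes$end), "BRCA2")
  expect_identical(substr(s, m$variants$start + 1, m$variants$end), "S34F")
})

test_that("mention recognition agrees with a brute-force regex-scan oracle", {
  set.seed(7)
  frags <- c("BRCA1", "BRCA2", "EGFR", "TP53", "c.7759C>T", "c.68_69delAG",
             "p.Arg149Trp", "S34F", "testing", "was", "negative", "panel",
             "c.5266dupC", "history")
  txts <- replicate(100, paste(sample(frags, sample(3:8, 1), replace = TRUE), collapse = " "))
  dict <- default_gene_dict()
  for (s in txts) {
    m <- recognize_mentions(s, dict)
    # oracle: every dictionary symbol occurrence (word-boundary) must be found
    for (g in c("BRCA1", "BRCA2", "EGFR", "TP53")) {
      hits <- gregexpr(paste0("\\b", g, "\\b"), s)[[1]]
      n_exp <- if (hits[1] == -1) 0L else length(hits)
      expect_identical(sum(m$genes$symbol == g), n_exp)
    }
    # no overlapping mentions
    spans <- rbind(m$genes[, c("start", "end")], m$variants[, c("start", "end")])
    if (nrow(spans) > 1) {
      spans <- spans[order(spans$start), ]
      expect_true(all(diff_ok <- spans$start[-1] >= spans$end[-nrow(spans)]))
    }
  }
})

test_that("normalization masks non-target genes and variants and tokenizes deterministically", {
  df <- mk_sentences(c("EGFR L858R was negative",
                       "BRCA1 c.68_69delAG pathogenic",
                       "She was tested for BRCA2 mutations."))
  s <- normalize_sentences(annotate_sentences(df))
  expect_identical(s$masked_text[1], "GENE MUTATION was negative")
  expect_identical(s$masked_text[2], "BRCA1 MUTATION pathogenic")
  expect_identical(s$tokens[[3]], c("test", "brca2", "mutation"))
})

test_that("normalize/mask is idempotent", {
  fix <- table1_fixture()
  s <- prepare_corpus(fix$notes, dedup = FALSE)
  again <- prepare_corpus(mk_sentences(s$masked_text, patient_id = s$patient_id,
                                       note_id = s$note_id),
                          dedup = FALSE)
  expect_identical(again$masked_text, s$masked_text)
  expect_identical(unclass(again$tokens), unclass(s$tokens))
})

test_that("vocabulary filter restricts tokens but keeps masks and targets", {
  df <- mk_sentences("EGFR L858R and BRCA1 testing of hereditary cancer")
  s <- normalize_sentences(annotate_sentences(df), vocab_filter = c("hereditary"))
  expect_setequal(s$tokens[[1]], c("gene", "mutation", "brca1", "hereditary"))
})

test_that("per-patient deduplication keeps the earliest instance and is order-invariant", {
  df <- rbind(
    mk_sentences("BRCA1 testing was negative.", "A", "n2", "2017-06-01"),
    mk_sentences("BRCA1 testing was negative.", "A", "n1", "2017-01-01"),
    mk_sentences("BRCA1 testing was negative.", "B", "n3", "2017-03-01"))
  s <- prepare_corpus(df)
  expect_identical(nrow(s), 2L)
  expect_identical(s$note_id[s$patient_id == "A"], "n1")

  # date tie -> lexicographically smallest note_id
  df2 <- rbind(mk_sentences("BRCA2 ordered.", "A", "nb", "2017-01-01"),
               mk_sentences("BRCA2 ordered.", "A", "na", "2017-01-01"))
  expect_identical(prepare_corpus(df2)$note_id, "na")

  # 12 records with 3 within-patient duplicate pairs -> 9 survive
  base <- c("BRCA1 testing was negative.", "BRCA2 ordered.", "BRCA1 panel discussed.")
  df3 <- rbind(
    mk_sentences(base, "A", c("a1", "a2", "a3"), "2018-01-01"),
    mk_sentences(base, "A", c("a4", "a5", "a6"), "2018-02-01"),  # 3 dup pairs
    mk_sentences(base, "B", c("b1", "b2", "b3"), "2018-01-01"),
    mk_sentences(c("BRCA1 results pending.", "BRCA2 coverage denied.",
                   "BRCA1 risk assessed."), "C", c("c1", "c2", "c3"), "2018-01-01"))
  s3 <- prepare_corpus(df3)
  expect_identical(nrow(s3), 9L)

  # invariance to input order, never increases count
  set.seed(5)
  perm <- df3[sample.int(nrow(df3)), ]
  s3p <- prepare_corpus(perm)
  expect_identical(s3p[order(s3p$note_id), "note_id"], s3[order(s3$note_id), "note_id"])
  expect_lte(nrow(s3), nrow(df3))
})

test_that("sentence splitter honours abbreviation guards", {
  out <- split_sentences("Seen by Dr. Smith today. BRCA1 test ordered; results pending.")[[1]]
  expect_identical(out, c("Seen by Dr. Smith today.",
                          "BRCA1 test ordered;", "results pending."))
})

test_that("JSONL and CSV round-trips preserve sentence records", {
  fix <- table1_fixture()
  tmp <- tempfile(fileext = ".jsonl")
  con <- file(tmp, "w")
  for (i in seq_len(nrow(fix$notes)))
    writeLines(jsonlite::toJSON(as.list(fix$notes[i, ]), auto_unbox = TRUE), con)
  close(con)
  rt <- read_sentences(tmp)
  expect_identical(rt$text, fix$notes$text)
  expect_s3_class(rt$date, "Date")

  tmpc <- tempfile(fileext = ".csv")
  write.csv(fix$notes, tmpc, row.names = FALSE)
  rtc <- read_sentences(tmpc)
  expect_identical(rtc$patient_id, fix$notes$patient_id)
})
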