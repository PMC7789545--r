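mk_records <- function(n, topic, type = "", src = "", path = "", cls = "", hgvs = "") {
  df <- empty <- data.frame(Hugo_Symbol = rep("BRCA1", n), Variant_Type = rep_len(type, n),
                            Variant_Source = rep_len(src, n),
                            Variant_Pathogenicity = rep_len(path, n),
                            Variant_Classification = rep_len(cls, n),
                            HGVS_Short = rep_len(hgvs, n),
                            negative_flag = topic == "Negative",
                            topic = rep_len(topic, n), stringsAsFactors = FALSE)
  df
}

test_that("completeness audits the right scopes and rounds half-up to one decimal", {
  recs <- rbind(mk_records(8, "Positive", type = "SNP"),
                mk_records(8, "VUS"),
                mk_records(24, "Negative", src = "germline"),
                mk_records(51, "Negative"))
  cr <- completeness(recs)
  expect_equal(cr$percent[cr$field == "Variant_Type"], 50.0)
  expect_equal(cr$denominator[cr$field == "Variant_Source"], 91)
  expect_equal(cr$percent[cr$field == "Variant_Source"], 26.4)  # 24/91 = 26.37

  all_full <- mk_records(4, "Positive", "SNP", "germline", "pathogenic",
                         "Missense_Mutation", "c.1A>G")
  expect_true(all(completeness(all_full)$percent == 100))

  none <- mk_records(3, "Negative")
  cn <- completeness(none)
  expect_true(is.na(cn$percent[cn$field == "Variant_Type"]))  # zero denominator

  # randomized missingness against direct counting
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    r <- mk_records(n, sample(c("Positive", "VUS"), n, replace = TRUE),
                    type = ifelse(runif(n) < 0.4, "SNP", ""),
                    hgvs = ifelse(runif(n) < 0.3, "c.1A>G", ""))
    cr <- completeness(r)
    expect_equal(cr$numerator[cr$field == "Variant_Type"], sum(nzchar(r$Variant_Type)))
    expect_equal(cr$percent[cr$field == "HGVS_Short"],
                 floor(1000 * sum(nzchar(r$HGVS_Short)) / n + 0.5) / 10)
  }
})

test_that("capture rate matches reference patients by gene and compatible status", {
  ref <- data.frame(patient_id = c("a", "b", "c"), gene = c("BRCA1", "BRCA2", "BRCA1"),
                    status = "positive", variant = c("c.1A>G", "", ""))
  recs <- rbind(mk_records(1, "Positive", hgvs = "c.9T>C"), mk_records(1, "Positive"))
  recs$patient_id <- c("a", "b")
  recs$Hugo_Symbol <- c("BRCA1", "BRCA1")  # wrong gene for b
  cp <- capture_rate(ref, recs, "positive")
  expect_equal(cp$n_matched, 1L)
  expect_equal(cp$percent, 33.3)
  # strict mode additionally requires the HGVS string to match
  expect_equal(capture_rate(ref, recs, "positive", strict = TRUE)$n_matched, 0L)
  # empty extraction -> zero
  expect_equal(capture_rate(ref, recs[0, ], "positive")$fraction, 0)
})

test_that("discrepancy detection flags gene switches and status flips symmetrically", {
  tl <- data.frame(patient_id = c("p", "p", "q", "q"),
                   gene = c("BRCA2", "BRCA1", "BRCA1", "BRCA1"),
                   status = c("pathogenic", "pathogenic", "pathogenic", "pathogenic"),
                   date = as.Date(c("2017-08-30", "2017-10-01", "2018-01-01", "2018-02-01")),
                   note_id = c("n1", "n2", "n3", "n4"))
  fl <- detect_discrepancies(tl)
  expect_identical(fl$type, "gene_switch")
  expect_identical(fl$patient_id, "p")
  # consistent repetition is not a discrepancy; reversal in time changes nothing
  rev_fl <- detect_discrepancies(tl[rev(seq_len(nrow(tl))), ])
  expect_identical(switch_key(fl$patient_id, fl$gene_a, fl$gene_b),
                   switch_key(rev_fl$patient_id, rev_fl$gene_a, rev_fl$gene_b))

  flip <- data.frame(patient_id = "r", gene = "BRCA1",
                     status = c("pathogenic", "wildtype"),
                     date = as.Date(c("2019-01-01", "2019-03-01")),
                     note_id = c("m1", "m2"))
  expect_identical(detect_discrepancies(flip)$type, "status_flip")
})

test_that("topic-rank matrix rows are percentage-normalized occurrence ranks", {
  ev <- data.frame(patient_id = "p1", note_id = c("n1", "n2", "n3"),
                   date = as.Date(c("2017-01-01", "2017-02-01", "2017-03-01")),
                   topic = c("Evaluation", "Order", "Positive"))
  m <- topic_rank_matrix(ev)
  expect_equal(m["Evaluation", "1"], 100)
  expect_equal(m["Order", "2"], 100)
  rs <- rowSums(m)
  expect_true(all(abs(rs[rs > 0] - 100) <= 0.1))

  # multi-patient: every nonzero row still sums to 100 within rounding
  set.seed(6)
  ev2 <- do.call(rbind, lapply(1:20, function(i) {
    k <- sample(2:6, 1)
    data.frame(patient_id = paste0("p", i), note_id = paste0("x", seq_len(k)),
               date = as.Date("2017-01-01") + cumsum(sample(1:20, k, TRUE)),
               topic = sample(topic_labels(), k, replace = TRUE))
  }))
  m2 <- topic_rank_matrix(ev2)
  rs2 <- rowSums(m2)
  expect_true(all(abs(rs2[rs2 > 0] - 100) <= 0.1))
})
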