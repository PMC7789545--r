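prep1 <- function(text) prepare_corpus(mk_sentences(text), dedup = FALSE)

test_that("rule classification resolves the seven clinical contexts", {
  s <- prep1(c("insurance coverage for brca1 testing was denied",
               "estimated risk of carrying a brca2 mutation given family history",
               "brca1 variant of unknown significance identified",
               "BRCA1 genetic test order was placed today.",
               "Provided education material about the BRCA1 testing guideline.",
               "Genetic testing revealed a pathogenic BRCA2 mutation.",
               "BRCA1 testing was negative.",
               "BRCA1 alpha beta gamma delta epsilon zeta positive"))
  labs <- classify_rule(s)
  expect_identical(labs, c("Insurance", "Evaluation", "VUS", "Order",
                           "Information", "Positive", "Negative",
                           "Information"))  # last: indicator beyond the window
})

test_that("classification is deterministic, order-independent and total", {
  fix <- table1_fixture()
  s <- prepare_corpus(fix$notes)
  l1 <- classify_rule(s)
  set.seed(3)
  perm <- sample.int(nrow(s))
  l2 <- classify_rule(s[perm, ])
  expect_identical(l2, l1[perm])
  expect_true(all(l1 %in% topic_labels()))
})

test_that("positivity indicators bind to the nearest gene within five tokens", {
  s <- prep1("positive mutation in BRCA2")
  a <- assign_positivity(s$tokens[[1]], s$gene_mentions[[1]])
  expect_identical(a$gene, "BRCA2")
  expect_identical(a$status, "pathogenic")

  s <- prep1("BRCA1 alpha beta gamma delta epsilon zeta positive")
  a <- assign_positivity(s$tokens[[1]], s$gene_mentions[[1]])
  expect_identical(nrow(a), 0L)  # six intervening tokens -> rejected

  s <- prep1("BRCA1 negative but BRCA2 positive")
  a <- assign_positivity(s$tokens[[1]], s$gene_mentions[[1]])
  a <- a[order(a$gene), ]
  expect_identical(a$gene, c("BRCA1", "BRCA2"))
  expect_identical(a$status[a$gene == "BRCA1"], "wildtype")
  expect_identical(a$status[a$gene == "BRCA2"], "pathogenic")
})

test_that("negation cues flip positivity to a negative assertion", {
  s <- prep1("No pathogenic mutation was detected in BRCA1.")
  a <- assign_positivity(s$tokens[[1]], s$gene_mentions[[1]])
  expect_identical(a$status, "wildtype")
  expect_identical(classify_rule(s), "Negative")
})

test_that("gene binding matches the exhaustive-pairing oracle on random fixtures", {
  rules <- ruleset()
  set.seed(101)
  filler <- c("alpha", "beta", "gamma", "delta", "case", "note", "clinic",
              "review", "tumor", "assay")
  inds <- c(positive = "pathogenic", negative = "wildtype", vus = "vus",
            pathogenic = "pathogenic", wildtype = "wildtype")
  n_cases <- 1000
  for (case in seq_len(n_cases)) {
    n <- sample(4:20, 1)
    tokens <- sample(filler, n, replace = TRUE)
    g_at <- sample(n, sample(1:2, 1))
    tokens[g_at] <- sample(c("brca1", "brca2"), length(g_at), replace = TRUE)
    i_at <- setdiff(sample(n, sample(1:2, 1)), g_at)
    tokens[i_at] <- sample(names(inds), length(i_at), replace = TRUE)
    g_at <- which(tokens %in% c("brca1", "brca2"))
    i_at <- which(tokens %in% names(inds))
    gm <- data.frame(symbol = toupper(tokens[g_at]), start = 0, end = 1,
                     is_target = TRUE)
    got <- assign_positivity(tokens, gm, rules)
    got <- got[order(got$indicator_pos), , drop = FALSE]  # oracle is position-ordered
    orc <- positivity_oracle(tokens, g_at, toupper(tokens[g_at]),
                             i_at, unname(inds[tokens[i_at]]),
                             rules$proximity_window)
    expect_identical(nrow(got), length(orc))
    if (length(orc)) {
      expect_identical(got$gene, vapply(orc, `[[`, "", "gene"))
      expect_identical(got$status, vapply(orc, `[[`, "", "status"))
      expect_identical(got$distance, vapply(orc, function(e) as.integer(e$distance), 1L))
    }
    expect_true(all(got$distance <= rules$proximity_window))
  }
})

test_that("variant records curate type, source, pathogenicity and classification", {
  s <- prep1(c("Genetic testing revealed a pathogenic germline BRCA1 c.7759C>T mutation.",
               "Foundation report showed a pathogenic BRCA2 amplification.",
               "A pathogenic splice site variant was found in BRCA1.",
               "BRCA1 S34F was reported as a somatic VUS.",
               "Testing confirmed a pathogenic BRCA1 c.68_69delAG mutation."))
  recs <- extract_variant_records(s)
  expect_identical(recs$Variant_Type, c("SNP", "CNV", "", "SNP", "INDEL"))
  expect_identical(recs$HGVS_Short, c("c.7759C>T", "", "", "S34F", "c.68_69delAG"))
  expect_identical(recs$Variant_Source, c("germline", "", "", "somatic", ""))
  expect_identical(recs$Variant_Pathogenicity,
                   c("pathogenic", "pathogenic", "pathogenic", "VUS", "pathogenic"))
  expect_identical(recs$Variant_Classification, c("", "", "Splice_Site", "", ""))
  expect_identical(recs$topic, c("Positive", "Positive", "Positive", "VUS", "Positive"))
})

test_that("wildtype assertions set the negative flag and leave pathogenicity empty", {
  s <- prep1("BRCA2 was negative on the Foundation panel.")
  recs <- extract_variant_records(s)
  expect_true(recs$negative_flag)
  expect_identical(recs$Variant_Pathogenicity, "")
  expect_identical(recs$topic, "Negative")
})

test_that("rule configuration round-trips through YAML", {
  cfg <- list(positivity_indicators = c("positive", "confirmed"),
              proximity_window = 3)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  rs <- read_ruleset(tmp)
  expect_identical(rs$proximity_window, 3L)
  s <- prep1("confirmed mutation in BRCA1")
  a <- assign_positivity(s$tokens[[1]], s$gene_mentions[[1]], rs)
  expect_identical(a$status, "pathogenic")
})
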