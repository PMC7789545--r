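#' Specification of a synthetic clinical cohort
#'
#' Defines the statistical world the generator emulates: cohort size and
#' mutation prevalence of a genetically tested women-cancer cohort (defaults:
#' 196 patients of whom 12 carry a pathogenic BRCA1/2 mutation and 24 a VUS
#' on the reference report), the temporal grammar of the medical journey
#' (Evaluation and Information encounters, then Order, optionally Insurance,
#' then repeated result mentions), boilerplate duplication of sentences
#' across notes, per-field dropout of variant details at clinical-notes
#' completeness rates, injected gene-switch documentation discrepancies, and
#' the conditional probabilities of targeted-therapy discussion and
#' prescription given mutation status.
#'
#' @param n_patients cohort size (default 196)
#' @param mutation_prevalence named probabilities for Mutated/VUS/Negative
#'   (default 12/196, 24/196, 160/196)
#' @param p_documented probability that a patient's genetic journey appears
#'   in notes at all (default 122/196, the fraction of a cohort with any
#'   target-gene sentence)
#' @param stage_range named list of min/max encounter counts per stage
#' @param p_order,p_insurance probabilities of Order / Insurance stages
#' @param duplication_rate probability each sentence is repeated in a later
#'   note (default 0.42, reproducing roughly 1179 instances per 682 uniques)
#' @param field_missingness named dropout probabilities for Variant_Type,
#'   Variant_Source, Variant_Pathogenicity, Variant_Classification,
#'   HGVS_Short (defaults are one minus the completeness rates observed in
#'   clinical notes: 0.50, 0.736, 0.562, 0.937, 0.75)
#' @param discrepancy_rate probability a documented mutated patient gets an
#'   injected gene-switch discrepancy (default 0.03)
#' @param therapy_effect data.frame-able list: per mutation status, the
#'   probability of therapy discussion and of prescription given discussion
#' @param seed integer seed; all generator randomness flows from it
#' @return object of class \code{rwe_cohort_spec}
#' @export
cohort_spec <- function(n_patients = 196,
                        mutation_prevalence = c(Mutated = 12, VUS = 24, Negative = 160) / 196,
                        p_documented = 122 / 196,
                        stage_range = list(Evaluation = c(1, 2), Information = c(1, 2),
                                           Order = c(1, 1), Insurance = c(1, 2),
                                           Result = c(1, 4)),
                        p_order = 1, p_insurance = 0.3,
                        duplication_rate = 0.42,
                        field_missingness = c(Variant_Type = 0.5, Variant_Source = 0.736,
                                              Variant_Pathogenicity = 0.562,
                                              Variant_Classification = 0.937,
                                              HGVS_Short = 0.75),
                        discrepancy_rate = 0.03,
                        therapy_effect = list(
                          Mutated = c(discussion = 0.9, prescription = 0.65),
                          VUS = c(discussion = 0.55, prescription = 0.10),
                          Negative = c(discussion = 0.45, prescription = 0.03)),
                        seed = 20200331L) {
  probs <- c(mutation_prevalence, p_documented, p_order, p_insurance,
             duplication_rate, field_missingness, discrepancy_rate,
             unlist(therapy_effect))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(mutation_prevalence) - 1) > 1e-8)
    stop("mutation_prevalence must sum to 1")
  need <- c("Evaluation", "Information", "Order", "Insurance", "Result")
  if (!all(need %in% names(stage_range))) stop("stage_range must name all five stages")
  ord <- match(need, names(stage_range))
  if (ord[3] <= max(ord[1:2]) || ord[5] <= ord[3])
    stop("temporal grammar must place Evaluation/Information before Order before results")
  stopifnot(is_count(n_patients), n_patients >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 mutation_prevalence = mutation_prevalence,
                 p_documented = p_documented, stage_range = stage_range,
                 p_order = p_order, p_insurance = p_insurance,
                 duplication_rate = duplication_rate,
                 field_missingness = field_missingness,
                 discrepancy_rate = discrepancy_rate,
                 therapy_effect = therapy_effect, seed = as.integer(seed)),
            class = "rwe_cohort_spec")
}

## sentence template banks; {G} = gene, {DRUG} = therapy term. Slot
## vocabularies are disjoint across topics so the rule lexicons can recover
## the gold labels exactly on a noise-free cohort.
templates_context <- list(
  Evaluation = c(
    "Discussed family history of breast cancer and the risk of carrying a {G} mutation.",
    "Patient has a strong family history; hereditary risk assessment for {G} recommended.",
    "Genetic counseling regarding {G} carrier probability was provided."),
  Information = c(
    "Provided education material about the {G} testing guideline.",
    "General information regarding the {G} panel was reviewed.",
    "NCCN guideline criteria for {G} testing were discussed with the patient."),
  Order = c(
    "{G} genetic test order was placed today.",
    "Awaiting {G} test results; specimen submitted to the lab.",
    "Ordered {G} sequencing; results pending."),
  Insurance = c(
    "Insurance preauthorization for {G} testing was requested.",
    "Coverage for the {G} test was denied by the insurance company.",
    "Insurance approved coverage for {G} testing.")
)
template_parp <- "Provided information about {DRUG} therapy options related to {G} per guideline."

hgvs_pool <- data.frame(
  hgvs = c("c.7759C>T", "p.Arg149Trp", "c.68_69delAG", "S34F", "c.5266dupC", "p.Gln563Ter"),
  type = c("SNP", "SNP", "INDEL", "SNP", "INDEL", "SNP"),
  stringsAsFactors = FALSE)
cnv_terms <- c(amplification = "CNV", deletion = "CNV",
               rearrangement = "Rearrangement", truncation = "Rearrangement")

# build one result sentence plus its gold field record
build_result_sentence <- function(topic, gene, fm) {
  gold <- list(Variant_Type = "", Variant_Source = "", Variant_Pathogenicity = "",
               Variant_Classification = "", HGVS_Short = "")
  p_hgvs <- 1 - fm[["HGVS_Short"]]
  p_type <- 1 - fm[["Variant_Type"]]
  src <- if (runif(1) < 1 - fm[["Variant_Source"]])
    sample(c("germline", "somatic"), 1) else ""
  if (nzchar(src)) gold$Variant_Source <- src
  srcw <- if (nzchar(src)) paste0(src, " ") else ""

  if (topic == "Negative") {
    text <- sprintf("%s%s testing was negative.",
                    if (nzchar(srcw)) paste0(toupper(substr(srcw, 1, 1)), substr(srcw, 2, nchar(srcw))) else "",
                    gene)
    if (!nzchar(srcw) && runif(1) < 0.5)
      text <- sprintf("No pathogenic mutation was detected in %s.", gene)
    return(list(text = text, gold = gold))
  }

  has_hgvs <- runif(1) < p_hgvs
  term <- ""
  if (has_hgvs) {
    v <- hgvs_pool[sample.int(nrow(hgvs_pool), 1), ]
    gold$HGVS_Short <- v$hgvs
    gold$Variant_Type <- v$type
  } else {
    p_term <- max(0, min(1, (p_type - p_hgvs) / (1 - p_hgvs)))
    if (runif(1) < p_term) {
      term <- sample(names(cnv_terms), 1)
      gold$Variant_Type <- unname(cnv_terms[term])
    }
  }
  detail <- if (has_hgvs) paste0(" ", gold$HGVS_Short) else ""

  if (topic == "Positive") {
    worded <- runif(1) < 1 - fm[["Variant_Pathogenicity"]]
    cls <- ""
    if (runif(1) < 1 - fm[["Variant_Classification"]]) {
      cls <- sample(c("missense", "nonsense", "splice site"), 1)
      gold$Variant_Classification <- c(missense = "Missense_Mutation",
                                       nonsense = "Nonsense_Mutation",
                                       `splice site` = "Splice_Site")[[cls]]
      cls <- paste0(cls, " ")
    }
    if (worded) {
      gold$Variant_Pathogenicity <- "pathogenic"
      text <- if (nzchar(term))
        sprintf("Genetic testing revealed a pathogenic %s%s%s %s.", cls, srcw, gene, term)
      else sprintf("Genetic testing revealed a pathogenic %s%s%s%s mutation.", cls, srcw, gene, detail)
    } else {
      text <- if (nzchar(term))
        sprintf("%s%s was positive with a %s%sidentified.", srcw, gene, cls, paste0(term, " "))
      else sprintf("%s%s test returned positive%s.", srcw, gene,
                   if (nzchar(detail)) paste0(" for", detail) else "")
      text <- paste0(toupper(substr(text, 1, 1)), substr(text, 2, nchar(text)))
    }
  } else { # VUS
    worded <- runif(1) < 1 - fm[["Variant_Pathogenicity"]]
    cls <- ""
    if (runif(1) < 1 - fm[["Variant_Classification"]]) {
      cls <- sample(c("missense", "nonsense", "splice site"), 1)
      gold$Variant_Classification <- c(missense = "Missense_Mutation",
                                       nonsense = "Nonsense_Mutation",
                                       `splice site` = "Splice_Site")[[cls]]
      cls <- paste0(cls, " ")
    }
    if (worded) {
      gold$Variant_Pathogenicity <- "VUS"
      text <- if (nzchar(term))
        sprintf("%s %s%s was reported as a %sVUS.", gene, srcw, term, cls)
      else sprintf("%s%s was reported as a %sVUS in %s.",
                   if (nzchar(detail)) paste0(trimws(detail), " ") else "A variant ",
                   srcw, cls, gene)
    } else {
      text <- if (nzchar(term))
        sprintf("A %s%svariant of unknown significance with a %s was found in %s.",
                srcw, cls, term, gene)
      else sprintf("A %s%svariant of unknown significance%s was found in %s.",
                   srcw, cls, detail, gene)
    }
  }
  list(text = text, gold = gold)
}

#' Generate a synthetic labeled cohort
#'
#' Produces notes (one sentence per note record), gold topic labels,
#' reference genetic reports, medication and CDM prescription sources, gold
#' variant-field records and the injected discrepancy list, all deterministic
#' given \code{spec$seed}. Every sentence carries a hidden gold topic;
#' result sentences embed gene, status and (per the missingness spec) HGVS,
#' variant-type, source and classification tokens; duplicated sentences
#' reappear verbatim in later notes; gene-switch discrepancies are injected
#' into documented mutated patients and recorded as ground truth.
#'
#' @param spec an \code{rwe_cohort_spec}
#' @return object of class \code{rwe_cohort}: list with \code{notes},
#'   \code{gold_labels}, \code{reference}, \code{meds}, \code{cdm},
#'   \code{gold_records}, \code{gold_discrepancies}, \code{mutation},
#'   \code{spec}
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "rwe_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    pid <- sprintf("P%04d", seq_len(n))
    status <- sample(names(spec$mutation_prevalence), n, replace = TRUE,
                     prob = spec$mutation_prevalence)
    gene <- ifelse(status == "Negative", "",
                   sample(c("BRCA1", "BRCA2"), n, replace = TRUE))
    documented <- runif(n) < spec$p_documented

    notes <- list(); gold <- list(); recs <- list(); disc <- list()
    meds <- list(); cdm <- list()
    note_ctr <- 0L
    new_note <- function() { note_ctr <<- note_ctr + 1L; sprintf("N%06d", note_ctr) }

    ref <- data.frame(patient_id = pid, gene = gene,
                      status = c(Mutated = "positive", VUS = "vus",
                                 Negative = "negative")[status],
                      variant = ifelse(status == "Mutated",
                                       hgvs_pool$hgvs[sample.int(nrow(hgvs_pool), n, replace = TRUE)], ""),
                      report_date = format(as.Date("2017-06-01") + sample.int(600, n, replace = TRUE)),
                      stringsAsFactors = FALSE)

    rng_range <- function(r) if (r[1] >= r[2]) r[1] else sample(seq(r[1], r[2]), 1)

    for (i in seq_len(n)) {
      if (!documented[i]) next
      # therapy evidence requires a documented journey: discussion lives in
      # notes, and prescription never occurs without discussion
      te <- spec$therapy_effect[[status[i]]]
      discussion <- runif(1) < te[["discussion"]]
      prescription <- discussion && runif(1) < te[["prescription"]]
      if (prescription) {
        drug <- sample(c("Olaparib", "Rucaparib", "Niraparib"), 1)
        if (runif(1) < 0.5)
          meds[[length(meds) + 1L]] <- data.frame(patient_id = pid[i], drug = drug,
                                                  date = format(as.Date("2019-01-01") + sample.int(300, 1)),
                                                  stringsAsFactors = FALSE)
        else
          cdm[[length(cdm) + 1L]] <- data.frame(patient_id = pid[i],
                                                line = sprintf("Trial drug administered: %s 300 mg BID", drug),
                                                stringsAsFactors = FALSE)
      }

      g <- if (nzchar(gene[i])) gene[i] else sample(c("BRCA1", "BRCA2"), 1)
      seq_topics <- character()
      for (st in c("Evaluation", "Information")) {
        k <- rng_range(spec$stage_range[[st]])
        seq_topics <- c(seq_topics, rep(st, k))
      }
      if (runif(1) < spec$p_order)
        seq_topics <- c(seq_topics, rep("Order", rng_range(spec$stage_range$Order)))
      if (runif(1) < spec$p_insurance)
        seq_topics <- c(seq_topics, rep("Insurance", rng_range(spec$stage_range$Insurance)))
      res_topic <- c(Mutated = "Positive", VUS = "VUS", Negative = "Negative")[status[i]]
      n_res <- rng_range(spec$stage_range$Result)
      seq_topics <- c(seq_topics, rep(res_topic, n_res))
      if (discussion) {
        # therapy information sentence lands with the information block
        pos <- max(which(seq_topics == "Information"))
        seq_topics <- append(seq_topics, "Information_PARP", after = pos)
      }

      date <- as.Date("2016-01-01") + sample.int(1200, 1)
      used <- character()
      for (tp in seq_topics) {
        date <- date + sample(5:45, 1)
        nid <- new_note()
        if (tp == "Information_PARP") {
          drugterm <- sample(c("olaparib", "rucaparib", "niraparib", "Lynparza", "PARP inhibitor"), 1)
          text <- sub("{DRUG}", drugterm, sub("{G}", g, template_parp, fixed = TRUE), fixed = TRUE)
          gold_tp <- "Information"
        } else if (tp %in% names(templates_context)) {
          bank <- templates_context[[tp]]
          avail <- setdiff(bank, used)
          if (!length(avail)) avail <- bank
          text <- sub("{G}", g, sample(avail, 1), fixed = TRUE)
          used <- c(used, text)
          gold_tp <- tp
        } else {
          built <- build_result_sentence(tp, g, spec$field_missingness)
          text <- built$text
          gold_tp <- tp
          recs[[length(recs) + 1L]] <- data.frame(
            note_id = nid, patient_id = pid[i], topic = tp, gene = g,
            as.data.frame(built$gold, stringsAsFactors = FALSE),
            stringsAsFactors = FALSE)
        }
        notes[[length(notes) + 1L]] <- data.frame(
          patient_id = pid[i], note_id = nid, date = format(date), text = text,
          stringsAsFactors = FALSE)
        gold[[length(gold) + 1L]] <- data.frame(note_id = nid, patient_id = pid[i],
                                                topic = gold_tp, stringsAsFactors = FALSE)
        # boilerplate duplication into a later note
        if (runif(1) < spec$duplication_rate) {
          nid2 <- new_note()
          d2 <- date + sample(10:200, 1)
          notes[[length(notes) + 1L]] <- data.frame(
            patient_id = pid[i], note_id = nid2, date = format(d2), text = text,
            stringsAsFactors = FALSE)
          gold[[length(gold) + 1L]] <- data.frame(note_id = nid2, patient_id = pid[i],
                                                  topic = gold_tp, stringsAsFactors = FALSE)
        }
      }
      # injected gene-switch discrepancy
      if (status[i] == "Mutated" && runif(1) < spec$discrepancy_rate) {
        other <- setdiff(c("BRCA1", "BRCA2"), g)
        date <- date + sample(10:60, 1)
        nid <- new_note()
        text <- sprintf("%s test returned positive.", other)
        notes[[length(notes) + 1L]] <- data.frame(
          patient_id = pid[i], note_id = nid, date = format(date), text = text,
          stringsAsFactors = FALSE)
        gold[[length(gold) + 1L]] <- data.frame(note_id = nid, patient_id = pid[i],
                                                topic = "Positive", stringsAsFactors = FALSE)
        disc[[length(disc) + 1L]] <- data.frame(
          patient_id = pid[i], status = "pathogenic",
          gene_a = min(g, other), gene_b = max(g, other), stringsAsFactors = FALSE)
      }
    }

    bind <- function(l, proto) if (length(l)) {
      x <- do.call(rbind, l); rownames(x) <- NULL; x
    } else proto
    structure(list(
      notes = bind(notes, data.frame(patient_id = character(), note_id = character(),
                                     date = character(), text = character())),
      gold_labels = bind(gold, data.frame(note_id = character(), patient_id = character(),
                                          topic = character())),
      reference = ref,
      meds = bind(meds, data.frame(patient_id = character(), drug = character(),
                                   date = character())),
      cdm = bind(cdm, data.frame(patient_id = character(), line = character())),
      gold_records = bind(recs, NULL),
      gold_discrepancies = bind(disc, data.frame(patient_id = character(),
                                                 status = character(), gene_a = character(),
                                                 gene_b = character())),
      mutation = data.frame(patient_id = pid, status = status, stringsAsFactors = FALSE),
      spec = spec), class = "rwe_cohort")
  })
}

#' @export
print.rwe_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$spec$n_patients, "patients,",
      nrow(x$notes), "note sentences,",
      nrow(x$gold_records %||% data.frame()), "gold result records,",
      nrow(x$gold_discrepancies), "injected discrepancies\n")
  invisible(x)
}

#' Write a generated cohort to a directory
#'
#' Emits notes.jsonl, gold_labels.csv, reports.csv, meds.csv, cdm.txt and
#' gold_discrepancies.csv.
#'
#' @param cohort an \code{rwe_cohort}
#' @param dir output directory (created if missing)
#' @return invisibly, the directory
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "notes.jsonl"), "w")
  for (i in seq_len(nrow(cohort$notes)))
    writeLines(jsonlite::toJSON(as.list(cohort$notes[i, ]), auto_unbox = TRUE), con)
  close(con)
  write.csv(cohort$gold_labels, file.path(dir, "gold_labels.csv"), row.names = FALSE)
  write.csv(cohort$reference, file.path(dir, "reports.csv"), row.names = FALSE)
  write.csv(cohort$meds, file.path(dir, "meds.csv"), row.names = FALSE)
  writeLines(paste(cohort$cdm$patient_id, cohort$cdm$line, sep = "\t"),
             file.path(dir, "cdm.txt"))
  write.csv(cohort$gold_discrepancies, file.path(dir, "gold_discrepancies.csv"),
            row.names = FALSE)
  invisible(dir)
}
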