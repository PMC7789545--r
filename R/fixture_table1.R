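#' Fixed worked-example cohort reproducing the data-model completeness rates
#'
#' A small deterministic cohort engineered so that running the full pipeline
#' (sentence extraction, normalization, rule classification, variant-record
#' curation, completeness audit and capture-rate comparison) reproduces the
#' printed clinical-notes completeness fractions of the internal genomics
#' data model: Variant_Type 8/16 (50.0%), Variant_Pathogenicity 7/16
#' (43.8%), Variant_Classification 1/16 (6.3%), HGVS_Short 4/16 (25.0%),
#' Variant_Source 24/91 (26.4%); and the patient-level capture rates against
#' the reference reports: 9/12 positive patients (75.0%) and 5/24 VUS
#' patients (20.8%). The cohort is synthetic: it mirrors the printed
#' numerators and denominators, not any real patient text.
#'
#' Composition: 91 result sentences (11 Positive, 5 VUS, 75 Negative), three
#' Evaluation-only patients whose positive reference result never reached the
#' notes, two extra EHR-only positives (prior germline panel results, absent
#' from the reference reports), and a reference table of 12 positive and 24
#' VUS patients.
#'
#' @return list with \code{notes} (patient_id, note_id, date, text) and
#'   \code{reference} (patient_id, gene, status, variant, report_date)
#' @export
table1_fixture <- function() {
  pp <- sprintf("PP%02d", 1:12)
  pv <- sprintf("PV%02d", 1:24)
  pgene <- ifelse(seq_len(12) %% 2 == 1, "BRCA1", "BRCA2")
  vgene <- ifelse(seq_len(24) %% 2 == 1, "BRCA1", "BRCA2")

  sent <- list()
  add <- function(patient, text) {
    sent[[length(sent) + 1L]] <<- data.frame(patient_id = patient, text = text,
                                             stringsAsFactors = FALSE)
  }

  # 11 positive result sentences: 9 matching reference patients + 2 EHR-only
  add(pp[1], "Genetic testing revealed a pathogenic germline BRCA1 c.7759C>T mutation.")
  add(pp[2], "Genetic testing revealed a pathogenic BRCA2 p.Arg149Trp mutation.")
  add(pp[3], "Testing confirmed a pathogenic BRCA1 c.68_69delAG mutation.")
  add(pp[4], "Foundation report showed a pathogenic BRCA2 amplification.")
  add(pp[5], "A pathogenic splice site variant was found in BRCA1.")
  add(pp[6], "BRCA2 was positive with a deletion identified.")
  add(pp[7], "BRCA1 testing was positive showing a rearrangement.")
  add(pp[8], "BRCA2 test returned positive.")
  add(pp[9], "BRCA1 test result was positive.")
  add("PN01", "Prior testing was positive for BRCA2.")
  add("PN02", "Previous testing was positive for BRCA1.")
  # 5 VUS result sentences matching reference patients PV01..PV05
  add(pv[1], "BRCA1 S34F was reported as a somatic VUS.")
  add(pv[2], "BRCA2 VUS with a truncation was reported.")
  add(pv[3], "A variant of unknown significance was found in BRCA1.")
  add(pv[4], "A variant of unknown significance was identified in BRCA2.")
  add(pv[5], "BRCA1 variant of unknown significance reported by outside lab.")
  # 3 reference-positive patients whose result never reached the notes
  add(pp[10], "Discussed family history and the risk of a BRCA2 mutation.")
  add(pp[11], "Discussed family history and the risk of a BRCA1 mutation.")
  add(pp[12], "Genetic counseling regarding BRCA2 carrier probability was provided.")

  # 75 negative result sentences across 58 patients (first 17 carry two)
  neg_src <- c("Germline %s testing was negative.",
               "%s somatic testing was negative.")
  neg_plain <- c("%s testing was negative.",
                 "%s was negative on the Foundation panel.",
                 "No pathogenic mutation was detected in %s.",
                 "%s results were negative for mutations.",
                 "Genetic test was negative for %s mutations.",
                 "%s sequencing was negative.")
  npat <- sprintf("PN%02d", 3:60)
  for (j in seq_len(75)) {
    patient <- npat[((j - 1) %% 58) + 1]
    g <- if (j %% 2 == 1) "BRCA1" else "BRCA2"
    tmpl <- if (j <= 22) neg_src[((j - 1) %% 2) + 1]
            else neg_plain[((j - 23) %% 6) + 1]
    add(patient, sprintf(tmpl, g))
  }

  notes <- do.call(rbind, sent)
  notes$note_id <- sprintf("N%03d", seq_len(nrow(notes)))
  notes$date <- format(as.Date("2018-01-01") + seq_len(nrow(notes)))
  notes <- notes[, c("patient_id", "note_id", "date", "text")]

  reference <- rbind(
    data.frame(patient_id = pp, gene = pgene, status = "positive",
               variant = c("c.7759C>T", "p.Arg149Trp", "c.68_69delAG", "", "",
                           "", "", "", "", "c.5266dupC", "p.Gln563Ter", ""),
               stringsAsFactors = FALSE),
    data.frame(patient_id = pv, gene = vgene, status = "vus",
               variant = c("S34F", "", "", "", "", rep("", 19)),
               stringsAsFactors = FALSE))
  reference$report_date <- format(as.Date("2017-12-01"))
  list(notes = notes, reference = reference)
}
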