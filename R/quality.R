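#' Field-completeness audit of curated variant records
#'
#' Audits the five key data-model fields over the scopes in which they are
#' expected: Variant_Type, Variant_Pathogenicity, Variant_Classification and
#' HGVS_Short over Positive + VUS records; Variant_Source over Positive +
#' VUS + Negative records (panel type, hence source, is knowable for negative
#' results too). Percentages are exact fractions rounded half-up to one
#' decimal.
#'
#' @param records variant-record data.frame from
#'   \code{extract_variant_records()} (needs a \code{topic} provenance column)
#' @return data.frame (field, numerator, denominator, percent); a zero
#'   denominator reports NA percent (not applicable)
#' @export
completeness <- function(records) {
  stopifnot("topic" %in% names(records))
  pvus <- records[records$topic %in% c("Positive", "VUS"), , drop = FALSE]
  allr <- records[records$topic %in% c("Positive", "VUS", "Negative"), , drop = FALSE]
  audit <- list(
    Variant_Type = pvus, Variant_Source = allr, Variant_Pathogenicity = pvus,
    Variant_Classification = pvus, HGVS_Short = pvus
  )
  rows <- lapply(names(audit), function(f) {
    scope <- audit[[f]]
    den <- nrow(scope)
    num <- sum(nzchar(scope[[f]]))
    data.frame(field = f, numerator = num, denominator = den,
               percent = if (den == 0) NA_real_ else round_half_up(100 * num / den, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Patient-level capture rate against reference genetic reports
#'
#' Fraction of reference-report patients of a given mutation status whose
#' result is also documented in the notes: a patient counts as captured when
#' at least one extracted record matches the reference gene and has a
#' compatible status (Positive topic for reference-positive, VUS topic for
#' reference-VUS). Strict mode additionally requires the extracted HGVS_Short
#' to match the reference variant string.
#'
#' @param reference data.frame with one row per reference mutation:
#'   \code{patient_id}, \code{gene}, \code{status}
#'   ("positive"/"vus"/"negative"), optional \code{variant}
#' @param records extracted variant-record data.frame
#' @param status which reference status to audit ("positive" or "vus")
#' @param strict also require an HGVS match (default FALSE)
#' @return list: \code{fraction}, \code{percent} (half-up, 1 decimal),
#'   \code{n_matched}, \code{n_reference}, \code{matched_patients}
#' @export
capture_rate <- function(reference, records, status = c("positive", "vus"),
                         strict = FALSE) {
  status <- match.arg(status)
  ref <- reference[tolower(reference$status) == status, , drop = FALSE]
  want_topic <- if (status == "positive") "Positive" else "VUS"
  hits <- records[records$topic == want_topic & !records$negative_flag, , drop = FALSE]
  matched <- vapply(seq_len(nrow(ref)), function(i) {
    m <- hits$patient_id == ref$patient_id[i] &
      toupper(hits$Hugo_Symbol) == toupper(ref$gene[i])
    if (strict && !is.null(ref$variant))
      m <- m & gsub("\\s+", "", hits$HGVS_Short) == gsub("\\s+", "", ref$variant[i])
    any(m)
  }, logical(1))
  n_ref <- nrow(ref); n_hit <- sum(matched)
  list(fraction = if (n_ref) n_hit / n_ref else 0,
       percent = if (n_ref) round_half_up(100 * n_hit / n_ref, 1) else 0,
       n_matched = n_hit, n_reference = n_ref,
       matched_patients = unique(ref$patient_id[matched]))
}

#' Detect documentation discrepancies in patient result timelines
#'
#' Flags two kinds of conflicts among dated, gene-bound result assertions:
#' \emph{gene-switch} — the same patient asserted with the same status for
#' different target genes on different records (e.g. first documented as a
#' positive mutation in BRCA2, later revised to BRCA1); and
#' \emph{status-flip} — pathogenic and wildtype assertions for the same
#' patient and gene. Each flag carries the provenance of both sides and is
#' invariant to processing the timeline in reverse.
#'
#' @param assertions data.frame with \code{patient_id}, \code{gene},
#'   \code{status} ("pathogenic"/"wildtype"/"vus"), \code{date},
#'   \code{note_id}
#' @return data.frame of flags: type, patient_id, status (gene-switch) or
#'   gene (status-flip), gene_a/gene_b, date_a/date_b, note_a/note_b
#' @export
detect_discrepancies <- function(assertions) {
  flags <- list()
  a <- assertions[order(assertions$patient_id, assertions$date,
                        as.character(assertions$note_id)), , drop = FALSE]
  for (p in unique(a$patient_id)) {
    ap <- a[a$patient_id == p, , drop = FALSE]
    # gene-switch: same status, different gene
    for (st in unique(ap$status)) {
      sub <- ap[ap$status == st, , drop = FALSE]
      genes <- unique(sub$gene)
      if (length(genes) < 2) next
      for (i in seq_len(length(genes) - 1)) for (j in seq(i + 1, length(genes))) {
        ga <- sub[sub$gene == genes[i], , drop = FALSE][1, ]
        gb <- sub[sub$gene == genes[j], , drop = FALSE][1, ]
        flags[[length(flags) + 1L]] <- data.frame(
          type = "gene_switch", patient_id = p, status = st,
          gene_a = genes[i], gene_b = genes[j],
          date_a = ga$date, date_b = gb$date,
          note_a = as.character(ga$note_id), note_b = as.character(gb$note_id),
          stringsAsFactors = FALSE)
      }
    }
    # status-flip: pathogenic vs wildtype for one gene
    for (g in unique(ap$gene)) {
      sub <- ap[ap$gene == g, , drop = FALSE]
      if (all(c("pathogenic", "wildtype") %in% sub$status)) {
        sa <- sub[sub$status == "pathogenic", , drop = FALSE][1, ]
        sb <- sub[sub$status == "wildtype", , drop = FALSE][1, ]
        flags[[length(flags) + 1L]] <- data.frame(
          type = "status_flip", patient_id = p, status = "pathogenic/wildtype",
          gene_a = g, gene_b = g, date_a = sa$date, date_b = sb$date,
          note_a = as.character(sa$note_id), note_b = as.character(sb$note_id),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(flags))
    return(data.frame(type = character(), patient_id = character(),
                      status = character(), gene_a = character(),
                      gene_b = character(), date_a = as.Date(character()),
                      date_b = as.Date(character()), note_a = character(),
                      note_b = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Topic-by-rank temporal matrix of patient timelines
#'
#' Orders each patient's labeled events by date (ties broken by note id) and
#' assigns occurrence ranks 1, 2, ... to every encounter. Counts of each
#' topic at each rank are row-normalized so every topic row sums to 100
#' percent — the summarized timeline heatmap view of where in the medical
#' journey each topic tends to occur.
#'
#' @param events data.frame with \code{patient_id}, \code{date},
#'   \code{note_id}, \code{topic}
#' @param topics row universe (default the seven topics)
#' @param max_rank optional cap on the number of rank columns
#' @return matrix of percentages (rows = topics, columns = ranks) with a
#'   \code{counts} attribute holding the raw count matrix
#' @export
topic_rank_matrix <- function(events, topics = topic_labels(), max_rank = NULL) {
  ev <- events[order(events$patient_id, events$date,
                     as.character(events$note_id)), , drop = FALSE]
  rk <- ave(seq_len(nrow(ev)), ev$patient_id, FUN = seq_along)
  R <- if (is.null(max_rank)) max(rk) else min(max_rank, max(rk))
  keep <- rk <= R
  cnt <- table(factor(ev$topic[keep], topics), factor(rk[keep], seq_len(R)))
  cnt <- matrix(as.integer(cnt), nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  pct <- cnt * 0
  rs <- rowSums(cnt)
  nz <- rs > 0
  # full precision, so each nonzero row sums to exactly 100
  pct[nz, ] <- 100 * cnt[nz, , drop = FALSE] / rs[nz]
  attr(pct, "counts") <- cnt
  pct
}
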