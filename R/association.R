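#' Default PARP-inhibitor term lexicon
#'
#' Generic names searched in structured medication tables and clinical-trial
#' (CDM) report lines; the full term set — class terms, generic and brand
#' names (including the "Lyparza" spelling seen in clinical text alongside
#' the usual "Lynparza") — searched in notes.
#'
#' @return list with \code{generic}, \code{brand} and \code{class_terms}
#' @export
parp_lexicon <- function() {
  list(generic = c("Olaparib", "Rucaparib", "Niraparib"),
       brand = c("Lyparza", "Lynparza", "Rubraca", "Zejula"),
       class_terms = c("PARP", "PARPi", "PARP inhibitor"))
}

#' Read a therapy-term lexicon from YAML
#' @param path YAML file with keys generic/brand/class_terms
#' @return lexicon list
#' @export
read_lexicon <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(generic = as.character(cfg$generic %||% character()),
       brand = as.character(cfg$brand %||% character()),
       class_terms = as.character(cfg$class_terms %||% character()))
}

#' Per-patient targeted-therapy status from heterogeneous sources
#'
#' \emph{Discussion} evidence: any Information-labeled sentence whose raw
#' text contains a lexicon term (case-insensitive, word-boundary match).
#' \emph{Prescription} evidence: a generic-name hit in the structured
#' medication table or in CDM report lines, or any lexicon term inside a
#' "Current Medication" note section (located by a case-insensitive header
#' regex, or an explicit \code{section == "current_medication"} column).
#' Each patient is classified as \code{none}, \code{discussion_only} or
#' \code{discussion_plus_prescription}; prescription evidence implies the
#' combined class. A prescription without any discussion evidence is
#' unexpected and triggers a validation warning.
#'
#' @param sentences labeled sentence data.frame (needs \code{patient_id},
#'   \code{raw_text}, \code{topic}; optional \code{section})
#' @param meds optional structured medication table (\code{patient_id},
#'   \code{drug})
#' @param cdm optional CDM report lines (\code{patient_id}, \code{line})
#' @param lexicon term lexicon (default \code{parp_lexicon()})
#' @param patients patient universe for the output (default: everyone seen in
#'   any source)
#' @param section_regex header regex marking current-medication content
#' @return data.frame (patient_id, discussion, prescription, status)
#' @export
extract_therapy_status <- function(sentences, meds = NULL, cdm = NULL,
                                   lexicon = parp_lexicon(), patients = NULL,
                                   section_regex = "(?i)current\\s+medications?") {
  all_terms <- unlist(lexicon, use.names = FALSE)
  stopifnot(length(all_terms) > 0)
  if (is.null(sentences$topic))
    stop("sentences must carry a 'topic' column (run classify_rule() first)")
  term_rx <- word_regex(all_terms)
  generic_rx <- word_regex(lexicon$generic)

  hit <- stringi::stri_detect_regex(sentences$raw_text, term_rx)
  disc_pat <- unique(sentences$patient_id[hit & sentences$topic == "Information"])

  in_medsec <- stringi::stri_detect_regex(sentences$raw_text, section_regex)
  if (!is.null(sentences$section))
    in_medsec <- in_medsec | (!is.na(sentences$section) &
                                sentences$section == "current_medication")
  rx_pat <- unique(sentences$patient_id[hit & in_medsec])
  if (!is.null(meds) && nrow(meds))
    rx_pat <- union(rx_pat, meds$patient_id[stringi::stri_detect_regex(meds$drug, generic_rx)])
  if (!is.null(cdm) && nrow(cdm))
    rx_pat <- union(rx_pat, cdm$patient_id[stringi::stri_detect_regex(cdm$line, generic_rx)])

  if (is.null(patients))
    patients <- unique(c(sentences$patient_id, meds$patient_id, cdm$patient_id))
  orphan <- setdiff(rx_pat, disc_pat)
  if (length(orphan))
    warning(length(orphan), " patient(s) with prescription but no discussion evidence")
  out <- data.frame(patient_id = patients,
                    discussion = patients %in% disc_pat | patients %in% rx_pat,
                    prescription = patients %in% rx_pat,
                    stringsAsFactors = FALSE)
  out$status <- ifelse(out$prescription, "discussion_plus_prescription",
                       ifelse(out$discussion, "discussion_only", "none"))
  out
}

#' Mutation-status by therapy-status contingency table
#'
#' @param mutation data.frame (patient_id, status in Mutated/VUS/Negative) —
#'   typically derived from validated reference reports
#' @param therapy output of \code{extract_therapy_status()}
#' @return integer matrix, rows Mutated/VUS/Negative, columns
#'   discussion_only / discussion_plus_prescription / none; each patient in
#'   \code{mutation} counted exactly once (patients without therapy rows
#'   count as none)
#' @export
contingency_table <- function(mutation, therapy) {
  stopifnot(!anyDuplicated(mutation$patient_id))
  st <- therapy$status[match(mutation$patient_id, therapy$patient_id)]
  st[is.na(st)] <- "none"
  tab <- table(factor(mutation$status, c("Mutated", "VUS", "Negative")),
               factor(st, c("discussion_only", "discussion_plus_prescription", "none")))
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

log_table_prob <- function(cells, lr, lc, ln) {
  # log P(T | margins) under independence: prod r_i! prod c_j! / (n! prod t_ij!)
  lr + lc - ln - sum(lgamma(cells + 1))
}

# enumerate all r x c tables with the given margins, calling visit(cells, logp)
enumerate_tables <- function(row_sums, col_sums, visit, max_tables = Inf) {
  r <- length(row_sums); cc <- length(col_sums)
  lr <- sum(lgamma(row_sums + 1)); lc <- sum(lgamma(col_sums + 1))
  ln <- lgamma(sum(row_sums) + 1)
  count <- 0L
  cells <- matrix(0L, r, cc)
  rec_row <- function(i, rem_cols) {
    if (count < 0) return()
    if (i == r) {
      cells[r, ] <<- rem_cols
      count <<- count + 1L
      if (count > max_tables) { count <<- -1L; return() }
      visit(cells, log_table_prob(cells, lr, lc, ln))
      return()
    }
    rec_cell <- function(j, left, rem_cols) {
      if (count < 0) return()
      if (j == cc) {
        if (left <= rem_cols[cc]) {
          cells[i, cc] <<- left
          rc <- rem_cols; rc[cc] <- rc[cc] - left
          rec_row(i + 1L, rc)
        }
        return()
      }
      hi <- min(left, rem_cols[j])
      for (v in 0:hi) {
        cells[i, j] <<- v
        rc <- rem_cols; rc[j] <- rc[j] - v
        rec_cell(j + 1L, left - v, rc)
      }
    }
    rec_cell(1L, row_sums[i], rem_cols)
  }
  rec_row(1L, col_sums)
  count  # -1 signals the cap was hit
}

#' Exact conditional test for an r x c contingency table
#'
#' Two-sided exact test by the probability-ordering criterion (the standard
#' generalization of Fisher's exact test to r x c tables): conditional on the
#' observed margins, the p-value is the total hypergeometric probability of
#' all tables whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7). Tables are enumerated recursively; when
#' the enumeration would exceed \code{max_tables}, a seeded Monte-Carlo
#' estimate over margin-preserving random tables (Patefield sampler) is used
#' instead, with the standard (1 + hits) / (1 + draws) estimator.
#'
#' @param table integer matrix of counts (zero rows/columns are dropped with
#'   a warning)
#' @param max_tables enumeration bound before falling back to Monte Carlo
#' @param mc_draws Monte-Carlo sample size (default 1e6)
#' @param seed seed for the Monte-Carlo fallback
#' @return list: \code{p.value}, \code{method} ("exact enumeration" or
#'   "Monte Carlo"), \code{tables} (number enumerated, NA for MC)
#' @export
fisher_exact <- function(table, max_tables = 2e6, mc_draws = 1e6, seed = 1L) {
  x <- as.matrix(table)
  stopifnot(all(x >= 0), sum(x) > 0, all(x == floor(x)))
  zr <- rowSums(x) == 0; zc <- colSums(x) == 0
  if (any(zr) || any(zc)) {
    warning("degenerate margins: dropping ", sum(zr), " zero row(s) and ",
            sum(zc), " zero column(s)")
    x <- x[!zr, !zc, drop = FALSE]
  }
  if (nrow(x) < 2 || ncol(x) < 2)
    return(list(p.value = 1, method = "degenerate", tables = 1L))
  rs <- rowSums(x); cs <- colSums(x)
  lr <- sum(lgamma(rs + 1)); lc <- sum(lgamma(cs + 1)); ln <- lgamma(sum(x) + 1)
  lp_obs <- log_table_prob(x, lr, lc, ln)
  tol <- 1e-7

  psum <- 0
  cnt <- enumerate_tables(rs, cs, function(cells, lp) {
    if (lp <= lp_obs + tol) psum <<- psum + exp(lp)
  }, max_tables = max_tables)
  if (cnt >= 0)
    return(list(p.value = min(1, psum), method = "exact enumeration", tables = cnt))

  # Monte-Carlo fallback
  hits <- 0
  done <- 0
  with_seed(seed, while (done < mc_draws) {
    b <- min(50000L, mc_draws - done)
    draws <- r2dtable(b, rs, cs)
    lps <- vapply(draws, function(d) log_table_prob(d, lr, lc, ln), numeric(1))
    hits <- hits + sum(lps <= lp_obs + tol)
    done <- done + b
  })
  list(p.value = (1 + hits) / (1 + mc_draws), method = "Monte Carlo", tables = NA_integer_)
}
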