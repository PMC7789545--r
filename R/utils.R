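#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict runif r2dtable ave
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Half-up decimal rounding (base round() is banker's); matches printed
# clinical-report percentages such as 43.8 and 20.8.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Case-insensitive whole-word regex for a set of literal terms.
word_regex <- function(terms) {
  esc <- stringi::stri_replace_all_regex(terms, "([\\W])", "\\\\$1")
  paste0("(?i)\\b(?:", paste(esc, collapse = "|"), ")\\b")
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
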