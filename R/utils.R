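# Internal condition helpers: every user-facing failure is a classed
# condition so callers (and the pipeline driver) can distinguish format
# problems from empty repertoires.

stop_format <- function(msg) {
  rlang::abort(msg, class = "tcrtrack_format_error")
}

stop_empty <- function(msg) {
  rlang::abort(msg, class = "tcrtrack_empty_error")
}

GROUPS <- c("LC", "OB-ND", "OB-Dys")
COMPARTMENTS <- c("PB", "VAT")
SUBSETS <- c("PD1pos", "PD1neg")
CLONE_KEYS <- c("aa", "aa+V", "aa+V+J")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Strip an IMGT allele suffix ("*01") and any trailing score annotation,
# keeping the first hit of a comma-separated list: "TRBV19*01(932)" -> "TRBV19".
normalize_gene <- function(x) {
  x <- vapply(strsplit(as.character(x), ",", fixed = TRUE),
              function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  x <- sub("\\(.*$", "", x)
  x <- sub("\\*.*$", "", x)
  trimws(x)
}

# AIRR convention: a junction is non-productive if it carries a stop ('*'),
# an out-of-frame marker ('_'), or is empty.
infer_productive <- function(cdr3_aa) {
  !is.na(cdr3_aa) & nzchar(cdr3_aa) &
    !grepl("*", cdr3_aa, fixed = TRUE) &
    !grepl("_", cdr3_aa, fixed = TRUE)
}
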