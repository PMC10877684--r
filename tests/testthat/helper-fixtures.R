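# Compact fixture builders used across the suite.

make_clonotypes <- function(counts,
                            cdr3 = NULL,
                            v = NULL, j = NULL) {
  n <- length(counts)
  if (is.null(cdr3)) {
    cdr3 <- sprintf("CASS%sTEAFF", strrep(LETTERS[seq_len(n) %% 20 + 1], 3))
  }
  tibble::tibble(cdr3_aa = cdr3,
                 v_gene = v %||% rep("TRBV19", n),
                 j_gene = j %||% rep("TRBJ2-1", n),
                 count = as.integer(counts))
}

make_rep <- function(counts, cdr3 = NULL, v = NULL, j = NULL,
                     individual_id = "P1", group = "LC",
                     compartment = "VAT", subset = "PD1pos") {
  repertoire(make_clonotypes(counts, cdr3, v, j),
             individual_id, group, compartment, subset)
}

# A distinct, valid CDR3 per index: length 12, productive.
seq_pool <- function(n, prefix = "CASS") {
  stopifnot(n <= 26^2)
  idx <- seq_len(n) - 1
  paste0(prefix, LETTERS[idx %/% 26 + 1], LETTERS[idx %% 26 + 1], "GGTEQYF")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
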