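#' Central-region k-mers of a CDR3
#'
#' Returns the contiguous amino-acid k-mers of the central region of a CDR3
#' junction — positions 4 to L-3 (1-based), trimming the three conserved
#' residues at each flank, as in GLIPH-family local-motif analyses.
#'
#' @param cdr3_aa A single CDR3 amino-acid string.
#' @param k Motif length, 3 or 4.
#' @return Character vector of unique k-mers (empty if the sequence is
#'   shorter than `k + 6`).
#' @export
extract_motifs <- function(cdr3_aa, k = 3) {
  stopifnot(length(cdr3_aa) == 1, k %in% c(3, 4))
  core <- central_region(cdr3_aa)
  n <- nchar(core)
  if (is.na(n) || n < k) return(character(0))
  unique(vapply(seq_len(n - k + 1),
                function(i) substr(core, i, i + k - 1), character(1)))
}

central_region <- function(cdr3_aa) {
  L <- nchar(cdr3_aa)
  ifelse(L >= 7, substr(cdr3_aa, 4, L - 3), "")
}

has_central_motif <- function(cdr3_aa, motif) {
  grepl(motif, central_region(cdr3_aa), fixed = TRUE)
}

#' Motif over-representation against a reference repertoire
#'
#' For every central-region motif observed in the sample sequences, builds
#' the 2x2 table of sequences containing vs not containing the motif in
#' sample vs reference, and computes a one-sided (over-representation)
#' Fisher's exact p — the motif's "Fisher score" — together with the rate
#' fold change.
#'
#' @param sample_seqs Character vector of sample CDR3 amino-acid sequences
#'   (deduplicated internally).
#' @param reference_seqs Character vector of reference CDR3 sequences.
#' @param k Motif length (3 or 4).
#' @param min_sample Smallest number of sample sequences carrying a motif for
#'   it to be scored (default 1).
#' @return A tibble: `motif`, `n_sample`, `n_reference`, `fold`
#'   (`Inf` when absent from the reference), `fisher_score`.
#' @export
motif_enrichment <- function(sample_seqs, reference_seqs, k = 3,
                             min_sample = 1) {
  sample_seqs <- unique(sample_seqs)
  reference_seqs <- unique(reference_seqs)
  if (!length(reference_seqs)) stop_empty("reference repertoire is empty")
  motifs <- sort(unique(unlist(lapply(sample_seqs, extract_motifs, k = k))))
  if (!length(motifs)) {
    return(tibble::tibble(motif = character(), n_sample = integer(),
                          n_reference = integer(), fold = numeric(),
                          fisher_score = numeric()))
  }
  ns <- length(sample_seqs)
  nr <- length(reference_seqs)
  samp_core <- central_region(sample_seqs)
  ref_core <- central_region(reference_seqs)
  rows <- lapply(motifs, function(m) {
    a <- sum(grepl(m, samp_core, fixed = TRUE))
    c_ <- sum(grepl(m, ref_core, fixed = TRUE))
    if (a < min_sample) return(NULL)
    p <- stats::fisher.test(matrix(c(a, ns - a, c_, nr - c_), nrow = 2),
                            alternative = "greater")$p.value
    tibble::tibble(motif = m, n_sample = a, n_reference = c_,
                   fold = (a / ns) / if (c_ > 0) (c_ / nr) else NA_real_,
                   fisher_score = p)
  })
  out <- dplyr::bind_rows(rows)
  out$fold[is.na(out$fold) & out$n_reference == 0] <- Inf
  dplyr::arrange(out, .data$fisher_score)
}

#' Build motif patterns over a set of repertoires
#'
#' A pattern is a motif-defined cluster of CDR3 sequences: all scoped
#' sequences carrying the motif in their central region. Each pattern gets
#' the three statistics of the standard retention filter:
#' * `fisher_score` — one-sided motif over-representation vs the reference
#'   ([motif_enrichment()]);
#' * `v_enrichment_p` — one-sided Fisher's exact p for enrichment of the
#'   members' modal V gene against the scoped background;
#' * `length_p` — Mann-Whitney p for a CDR3-length bias of members vs
#'   background (exact for group sizes up to 20, normal approximation above).
#'
#' @param repertoires A list of `tcr_repertoire` objects (the scope).
#' @param reference Character vector of reference CDR3 sequences (a naive /
#'   unselected background).
#' @param k Motif lengths to scan (subset of `c(3, 4)`).
#' @param min_members Minimum number of distinct member CDR3s for a motif to
#'   be scored (default 2).
#' @return A `tcr_patterns` tibble: `motif`, `k`, `n_unique_cdr3`, `top_v`,
#'   `fold`, `fisher_score`, `v_enrichment_p`, `length_p`, and a `members`
#'   list-column of tibbles (`cdr3_aa`, `v_gene`, `individual_id`,
#'   `compartment`).
#' @export
build_patterns <- function(repertoires, reference, k = c(3, 4),
                           min_members = 2) {
  stopifnot(all(k %in% c(3, 4)),
            all(vapply(repertoires, inherits, logical(1), "tcr_repertoire")))
  scope <- purrr::map_dfr(repertoires, function(r) {
    cl <- filter_functional(r)$clonotypes
    tibble::tibble(cdr3_aa = cl$cdr3_aa, v_gene = cl$v_gene,
                   individual_id = r$individual_id,
                   compartment = r$compartment)
  })
  scope <- dplyr::distinct(scope)
  uniq <- dplyr::distinct(scope, .data$cdr3_aa, .keep_all = TRUE)
  out <- list()
  for (kk in k) {
    enr <- motif_enrichment(uniq$cdr3_aa, reference, k = kk,
                            min_sample = min_members)
    for (i in seq_len(nrow(enr))) {
      m <- enr$motif[[i]]
      member_mask <- has_central_motif(uniq$cdr3_aa, m)
      members <- scope[has_central_motif(scope$cdr3_aa, m), , drop = FALSE]
      out[[length(out) + 1]] <- tibble::tibble(
        motif = m, k = kk,
        n_unique_cdr3 = sum(member_mask),
        top_v = modal_value(uniq$v_gene[member_mask]),
        fold = enr$fold[[i]],
        fisher_score = enr$fisher_score[[i]],
        v_enrichment_p = v_enrichment_p(uniq, member_mask),
        length_p = length_bias_p(nchar(uniq$cdr3_aa[member_mask]),
                                 nchar(uniq$cdr3_aa[!member_mask])),
        members = list(members))
    }
  }
  pat <- dplyr::bind_rows(out)
  if (nrow(pat)) pat <- dplyr::arrange(pat, .data$fisher_score)
  structure(pat, class = c("tcr_patterns", class(tibble::tibble())))
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[[1]]
}

v_enrichment_p <- function(uniq, member_mask) {
  top_v <- modal_value(uniq$v_gene[member_mask])
  if (is.na(top_v)) return(NA_real_)
  a <- sum(uniq$v_gene[member_mask] == top_v, na.rm = TRUE)
  b <- sum(member_mask) - a
  c_ <- sum(uniq$v_gene[!member_mask] == top_v, na.rm = TRUE)
  d <- sum(!member_mask) - c_
  stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                     alternative = "greater")$p.value
}

length_bias_p <- function(member_lengths, background_lengths) {
  if (!length(member_lengths) || !length(background_lengths)) return(NA_real_)
  exact <- length(member_lengths) <= 20 && length(background_lengths) <= 20
  suppressWarnings(
    stats::wilcox.test(member_lengths, background_lengths,
                       exact = exact)$p.value)
}

#' Retention filter for motif patterns
#'
#' Keeps exactly the patterns satisfying all four inclusive criteria:
#' at least `min_unique_cdr3` distinct member CDR3s, Fisher score at most
#' `max_fisher`, V-gene enrichment p at most `max_v_p`, and CDR3-length bias
#' p at most `max_length_p`. Accepts either [build_patterns()] output or an
#' imported GLIPH2-format table ([read_gliph2()]). The filter is idempotent.
#'
#' @param patterns A pattern table with columns `n_unique_cdr3`,
#'   `fisher_score`, `v_enrichment_p`, `length_p`.
#' @param min_unique_cdr3,max_fisher,max_v_p,max_length_p Inclusive
#'   thresholds; defaults 3, 0.05, 0.05, 0.05.
#' @return The retained rows of `patterns`.
#' @export
filter_patterns <- function(patterns, min_unique_cdr3 = 3, max_fisher = 0.05,
                            max_v_p = 0.05, max_length_p = 0.05) {
  required <- c("n_unique_cdr3", "fisher_score", "v_enrichment_p", "length_p")
  missing <- setdiff(required, names(patterns))
  if (length(missing)) {
    stop_format(paste0("pattern table lacks statistic column(s): ",
                       paste(missing, collapse = ", ")))
  }
  for (col in required) {
    if (any(is.na(patterns[[col]]))) {
      bad <- if ("motif" %in% names(patterns))
        paste(patterns$motif[is.na(patterns[[col]])], collapse = ", ")
      else "<unnamed>"
      stop_format(paste0("missing ", col, " for pattern(s): ", bad))
    }
  }
  keep <- patterns$n_unique_cdr3 >= min_unique_cdr3 &
    patterns$fisher_score <= max_fisher &
    patterns$v_enrichment_p <= max_v_p &
    patterns$length_p <= max_length_p
  patterns[keep, , drop = FALSE]
}

#' Read a GLIPH2 output table
#'
#' Imports a GLIPH2 cluster CSV so the retention filter can be applied to an
#' externally computed clustering. Recognized columns: `pattern`,
#' `number_unique_cdr3`, `Fisher_score`, `vb_score`, `length_score`.
#'
#' @param path Path to the CSV.
#' @return A tibble with the internal pattern-statistic column names.
#' @export
read_gliph2 <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("pattern", "number_unique_cdr3", "Fisher_score", "vb_score",
            "length_score")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_format(paste0("GLIPH2 table ", path, " lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  tibble::tibble(motif = as.character(tab$pattern),
                 n_unique_cdr3 = as.integer(tab$number_unique_cdr3),
                 fisher_score = as.numeric(tab$Fisher_score),
                 v_enrichment_p = as.numeric(tab$vb_score),
                 length_p = as.numeric(tab$length_score))
}

#' Pattern-level recirculation
#'
#' A pattern is recirculating for an individual when it has at least one
#' member sequence in each of that individual's compartments (PB and VAT).
#'
#' @param patterns [build_patterns()] output (with a `members` list-column
#'   carrying `individual_id` and `compartment`).
#' @return A list: `per_individual` (tibble `individual_id`, `n_patterns`,
#'   `n_recirculating`, `frac_recirculating`) and `overall_frac` (fraction of
#'   patterns recirculating in at least one individual).
#' @export
pattern_recirculation <- function(patterns) {
  if (!nrow(patterns)) {
    return(list(per_individual = tibble::tibble(
      individual_id = character(), n_patterns = integer(),
      n_recirculating = integer(), frac_recirculating = numeric()),
      overall_frac = NA_real_))
  }
  long <- purrr::map_dfr(seq_len(nrow(patterns)), function(i) {
    mem <- patterns$members[[i]]
    dplyr::distinct(tibble::tibble(pattern = patterns$motif[[i]],
                                   individual_id = mem$individual_id,
                                   compartment = mem$compartment))
  })
  status <- long |>
    dplyr::group_by(.data$pattern, .data$individual_id) |>
    dplyr::summarise(recirc = all(c("PB", "VAT") %in% .data$compartment),
                     .groups = "drop")
  per_ind <- status |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(n_patterns = dplyr::n(),
                     n_recirculating = sum(.data$recirc),
                     frac_recirculating = mean(.data$recirc),
                     .groups = "drop")
  by_pattern <- status |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(any_recirc = any(.data$recirc), .groups = "drop")
  list(per_individual = per_ind,
       overall_frac = mean(by_pattern$any_recirc))
}
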