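#' Read a VDJdb-style antigen annotation table
#'
#' Expects a TSV with columns `cdr3`, `antigen.epitope`, `antigen.species`,
#' `mhc.class` (`MHCI`/`MHCII`), `gene` (chain, e.g. `TRB`), `vdjdb.score`,
#' and optionally `compartment` (`CD4`/`CD8`). Rows missing a CDR3 or a
#' parseable score are skipped (a message reports how many).
#'
#' @param path Path to the TSV.
#' @return A tibble of annotation records.
#' @export
read_vdjdb <- function(path) {
  tab <- read_tsv_quiet(path)
  need <- c("cdr3", "antigen.species", "mhc.class", "vdjdb.score")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_format(paste0("annotation table ", path, " lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  db <- tibble::tibble(
    cdr3_aa = as.character(tab$cdr3),
    epitope = if ("antigen.epitope" %in% names(tab))
      as.character(tab$antigen.epitope) else NA_character_,
    antigen_species = as.character(tab$antigen.species),
    mhc_class = as.character(tab$mhc.class),
    compartment_label = if ("compartment" %in% names(tab))
      as.character(tab$compartment) else NA_character_,
    score = suppressWarnings(as.integer(tab$vdjdb.score)))
  bad <- is.na(db$cdr3_aa) | !nzchar(db$cdr3_aa) | is.na(db$score)
  if (any(bad)) {
    message(sum(bad), " malformed annotation rows skipped")
  }
  db[!bad, , drop = FALSE]
}

#' Annotate clonotypes against an antigen database
#'
#' Matches CDR3 amino-acid sequences exactly against the database records
#' that survive the confidence filters: score at least `min_score` (records
#' with score below 1 are unreliable and dropped by default), MHC class II,
#' and CD4 compartment (records labelled CD8 are dropped; records without a
#' compartment label pass). Sequences matching records of more than one
#' antigen species are flagged as having multiple antigen specificities.
#'
#' @param x CDR3 sequences to annotate: a character vector, a clonotype data
#'   frame with a `cdr3_aa` column, or a `tcr_repertoire`.
#' @param db Annotation tibble from [read_vdjdb()] (columns `cdr3_aa`,
#'   `antigen_species`, `mhc_class`, `score`, optionally
#'   `compartment_label`, `epitope`).
#' @param min_score Minimum database confidence score (default 1).
#' @param mhc_class Required MHC restriction (default `"MHCII"`).
#' @param compartment_label Excluded T-cell compartment records are those
#'   not matching this label (default `"CD4"`; unlabeled records pass).
#' @return A tibble with one row per matched sequence: `cdr3_aa`, `species`
#'   (list-column of antigen species), `n_species`, `multiple_specificities`,
#'   `n_records`.
#' @export
annotate <- function(x, db, min_score = 1, mhc_class = "MHCII",
                     compartment_label = "CD4") {
  seqs <- if (inherits(x, "tcr_repertoire")) {
    unique(x$clonotypes$cdr3_aa[x$clonotypes$productive])
  } else if (is.data.frame(x)) {
    unique(x$cdr3_aa)
  } else {
    unique(as.character(x))
  }
  keep <- db$score >= min_score & db$mhc_class == mhc_class
  if ("compartment_label" %in% names(db)) {
    keep <- keep & (is.na(db$compartment_label) |
                      db$compartment_label == compartment_label)
  }
  db <- db[keep, , drop = FALSE]
  hits <- db[db$cdr3_aa %in% seqs, , drop = FALSE]
  if (!nrow(hits)) {
    return(tibble::tibble(cdr3_aa = character(), species = list(),
                          n_species = integer(),
                          multiple_specificities = logical(),
                          n_records = integer()))
  }
  hits |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(species = list(sort(unique(.data$antigen_species))),
                     n_species = dplyr::n_distinct(.data$antigen_species),
                     n_records = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(multiple_specificities = .data$n_species > 1) |>
    dplyr::select("cdr3_aa", "species", "n_species",
                  "multiple_specificities", "n_records")
}

#' Annotate motif patterns
#'
#' Matches every member sequence of each pattern against the filtered
#' annotation database and summarises antigen species at the pattern level.
#'
#' @param patterns [build_patterns()] output.
#' @inheritParams annotate
#' @return A tibble per pattern: `motif`, `n_matched_seqs`, `species`
#'   (list-column), `multiple_specificities`.
#' @export
annotate_patterns <- function(patterns, db, min_score = 1,
                              mhc_class = "MHCII", compartment_label = "CD4") {
  purrr::map_dfr(seq_len(nrow(patterns)), function(i) {
    mem <- unique(patterns$members[[i]]$cdr3_aa)
    ann <- annotate(mem, db, min_score = min_score, mhc_class = mhc_class,
                    compartment_label = compartment_label)
    pooled <- sort(unique(unlist(ann$species)))
    tibble::tibble(motif = patterns$motif[[i]],
                   n_matched_seqs = nrow(ann),
                   species = list(pooled),
                   multiple_specificities = length(pooled) > 1)
  })
}
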