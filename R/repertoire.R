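#' Construct a TCR repertoire
#'
#' A repertoire holds all clonotypes called for one individual in one
#' compartment (peripheral blood `PB` or visceral adipose tissue `VAT`) and
#' one sorted cell subset (`PD1pos` or `PD1neg` CD4 Tconv), together with the
#' cohort group of the individual (`LC` lean control, `OB-ND` obese
#' normoglycemic, `OB-Dys` obese dysglycemic).
#'
#' Clonotype frequencies ("relative sequence counts") are always computed
#' over the productive clonotypes of the repertoire: non-productive rows get
#' `NA` frequency and do not enter the denominator.
#'
#' @param clonotypes A data frame with columns `cdr3_aa`, `v_gene`, `j_gene`,
#'   `count`, and optionally `cdr3_nt` and `productive`. Missing `productive`
#'   is inferred from `cdr3_aa` (non-productive iff it contains `*` or `_` or
#'   is empty).
#' @param individual_id Individual identifier.
#' @param group One of `"LC"`, `"OB-ND"`, `"OB-Dys"`.
#' @param compartment One of `"PB"`, `"VAT"`.
#' @param subset One of `"PD1pos"`, `"PD1neg"`.
#' @param key Clone-identity key the clonotypes are collapsed by; one of
#'   `"aa"`, `"aa+V"`, `"aa+V+J"`, or `NA` if not yet collapsed.
#' @return An object of class `tcr_repertoire`: a list with elements
#'   `clonotypes` (a tibble), `individual_id`, `group`, `compartment`,
#'   `subset`, `key`.
#' @export
repertoire <- function(clonotypes, individual_id, group, compartment, subset,
                       key = NA_character_) {
  stopifnot(is.data.frame(clonotypes))
  group <- match.arg(group, GROUPS)
  compartment <- match.arg(compartment, COMPARTMENTS)
  subset <- match.arg(subset, SUBSETS)

  cl <- tibble::as_tibble(clonotypes)
  for (col in c("cdr3_nt")) {
    if (!col %in% names(cl)) cl[[col]] <- NA_character_
  }
  required <- c("cdr3_aa", "v_gene", "j_gene", "count")
  missing <- setdiff(required, names(cl))
  if (length(missing)) {
    stop_format(paste0("clonotype table lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (!"productive" %in% names(cl)) {
    cl$productive <- infer_productive(cl$cdr3_aa)
  }
  cl$count <- as.integer(cl$count)
  if (any(is.na(cl$count)) || any(cl$count < 0)) {
    stop_format("clonotype counts must be non-negative integers")
  }
  if (any(cl$productive & (!nzchar(cl$cdr3_aa) | is.na(cl$cdr3_aa)))) {
    stop_format("productive clonotypes must have a non-empty cdr3_aa")
  }
  cl <- recompute_frequencies(cl)

  structure(
    list(clonotypes = cl[, c("cdr3_aa", "cdr3_nt", "v_gene", "j_gene",
                             "count", "frequency", "productive")],
         individual_id = as.character(individual_id),
         group = group, compartment = compartment, subset = subset,
         key = key),
    class = "tcr_repertoire")
}

recompute_frequencies <- function(cl) {
  tot <- sum(cl$count[cl$productive])
  cl$frequency <- ifelse(cl$productive & tot > 0, cl$count / tot, NA_real_)
  cl
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> %s | %s | %s | %s: %d clonotypes (%d productive), key=%s\n",
    x$individual_id, x$group, x$compartment, x$subset,
    nrow(x$clonotypes), sum(x$clonotypes$productive), x$key))
  print(x$clonotypes, n = 5)
  invisible(x)
}

#' Remove non-functional clonotypes
#'
#' Drops non-productive (non-coding) clonotypes — those whose CDR3 amino-acid
#' junction carries a stop codon `*`, a frameshift `_`, or is empty — and
#' renormalizes frequencies over the retained clones.
#'
#' @param rep A [repertoire()].
#' @return A `tcr_repertoire` containing only productive clonotypes, with
#'   frequencies summing to 1.
#' @export
filter_functional <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes[rep$clonotypes$productive, , drop = FALSE]
  if (nrow(cl) == 0) {
    stop_empty(sprintf("repertoire %s/%s/%s has no productive clonotypes",
                       rep$individual_id, rep$compartment, rep$subset))
  }
  rep$clonotypes <- recompute_frequencies(cl)
  rep
}

#' Clone-identity key strings
#'
#' @param clonotypes A clonotype tibble.
#' @param key `"aa"` (CDR3 amino-acid sequence alone, the default identity
#'   used for sharing analyses), `"aa+V"`, or `"aa+V+J"`.
#' @return A character vector of key strings, one per row.
#' @export
clone_key <- function(clonotypes, key = c("aa", "aa+V", "aa+V+J")) {
  key <- match.arg(key)
  switch(key,
         "aa" = clonotypes$cdr3_aa,
         "aa+V" = paste(clonotypes$cdr3_aa, clonotypes$v_gene, sep = "|"),
         "aa+V+J" = paste(clonotypes$cdr3_aa, clonotypes$v_gene,
                          clonotypes$j_gene, sep = "|"))
}

#' Collapse clonotypes that share an identity key
#'
#' Merges clonotypes with equal identity key (counts summed, frequencies
#' recomputed). Productive and non-productive clonotypes are never merged
#' together. The key is recorded on the repertoire and propagated to
#' downstream sharing/tracking analyses.
#'
#' @inheritParams clone_key
#' @param rep A [repertoire()].
#' @return A `tcr_repertoire` with one clonotype per (key, productive) pair.
#' @export
collapse_by_key <- function(rep, key = c("aa", "aa+V", "aa+V+J")) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  key <- match.arg(key)
  cl <- rep$clonotypes
  cl$.key <- clone_key(cl, key)
  cl <- cl |>
    dplyr::group_by(.data$.key, .data$productive) |>
    dplyr::summarise(
      cdr3_aa = dplyr::first(.data$cdr3_aa),
      cdr3_nt = dplyr::first(.data$cdr3_nt),
      v_gene = dplyr::first(.data$v_gene),
      j_gene = dplyr::first(.data$j_gene),
      count = sum(.data$count),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count))
  cl$.key <- NULL
  rep$clonotypes <- recompute_frequencies(
    cl[, c("cdr3_aa", "cdr3_nt", "v_gene", "j_gene", "count", "productive")])
  rep$key <- key
  rep
}

#' Assemble a cohort of repertoires
#'
#' @param repertoires A list of [repertoire()] objects. Each
#'   (individual, compartment, subset) triple may appear at most once.
#' @param clinical Optional tibble of clinical records (see
#'   [clinical_record()]).
#' @return An object of class `tcr_cohort`.
#' @export
cohort <- function(repertoires, clinical = NULL) {
  stopifnot(is.list(repertoires),
            all(vapply(repertoires, inherits, logical(1), "tcr_repertoire")))
  ids <- vapply(repertoires, function(r)
    paste(r$individual_id, r$compartment, r$subset, sep = "/"), character(1))
  if (anyDuplicated(ids)) {
    stop_format(paste0("duplicate (individual, compartment, subset): ",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(repertoires) <- ids
  structure(list(repertoires = repertoires, clinical = clinical),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  meta <- cohort_metadata(x)
  cat(sprintf("<tcr_cohort> %d repertoires, %d individuals (%s)\n",
              nrow(meta), dplyr::n_distinct(meta$individual_id),
              paste(sort(unique(meta$group)), collapse = ", ")))
  invisible(x)
}

#' Metadata table of a cohort
#'
#' @param ch A [cohort()].
#' @return A tibble with one row per repertoire: `individual_id`, `group`,
#'   `compartment`, `subset`, `n_clonotypes`.
#' @export
cohort_metadata <- function(ch) {
  stopifnot(inherits(ch, "tcr_cohort"))
  purrr::map_dfr(ch$repertoires, function(r)
    tibble::tibble(individual_id = r$individual_id, group = r$group,
                   compartment = r$compartment, subset = r$subset,
                   n_clonotypes = nrow(r$clonotypes)))
}

#' Select repertoires from a cohort
#'
#' @param ch A [cohort()].
#' @param compartment,subset,group,individual_id Optional filters; `NULL`
#'   keeps all.
#' @return A list of `tcr_repertoire` objects.
#' @export
cohort_select <- function(ch, compartment = NULL, subset = NULL, group = NULL,
                          individual_id = NULL) {
  stopifnot(inherits(ch, "tcr_cohort"))
  keep <- vapply(ch$repertoires, function(r) {
    (is.null(compartment) || r$compartment %in% compartment) &&
      (is.null(subset) || r$subset %in% subset) &&
      (is.null(group) || r$group %in% group) &&
      (is.null(individual_id) || r$individual_id %in% individual_id)
  }, logical(1))
  ch$repertoires[keep]
}
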