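#' Read an AIRR Rearrangement clonotype table
#'
#' Reads a tab-separated AIRR Rearrangement file with at least columns
#' `junction_aa`, `v_call`, `j_call` and one of `duplicate_count` /
#' `consensus_count`. A `productive` column (`T`/`F` or logical) is honoured
#' when present and otherwise inferred from the junction content. V/J calls
#' are normalized to gene level (allele suffix `*NN` stripped, first hit of a
#' comma-separated list kept).
#'
#' @param path Path to the TSV file.
#' @param individual_id,group,compartment,subset Sample metadata (see
#'   [repertoire()]).
#' @return A `tcr_repertoire` with frequencies computed over productive
#'   clonotypes.
#' @export
read_airr_table <- function(path, individual_id, group, compartment, subset) {
  tab <- read_tsv_quiet(path)
  if (nrow(tab) == 0) {
    stop_empty(paste0("no clonotype rows in ", path))
  }
  required <- c("junction_aa", "v_call", "j_call")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop_format(paste0("AIRR table ", path, " lacks mandatory column(s): ",
                       paste(missing, collapse = ", ")))
  }
  count_col <- intersect(c("duplicate_count", "consensus_count"), names(tab))
  if (!length(count_col)) {
    stop_format(paste0("AIRR table ", path,
                       " lacks mandatory column: duplicate_count (or consensus_count)"))
  }
  cl <- tibble::tibble(
    cdr3_aa = as.character(tab$junction_aa),
    cdr3_nt = if ("junction" %in% names(tab)) as.character(tab$junction)
              else NA_character_,
    v_gene = normalize_gene(tab$v_call),
    j_gene = normalize_gene(tab$j_call),
    count = as.integer(tab[[count_col[[1]]]]))
  if ("productive" %in% names(tab)) {
    cl$productive <- parse_airr_logical(tab$productive)
  }
  rep <- repertoire(cl, individual_id, group, compartment, subset)
  if (!any(rep$clonotypes$productive)) {
    stop_empty(paste0("no productive clonotypes in ", path))
  }
  rep
}

parse_airr_logical <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("T", "TRUE", "1")
}

# MiXCR export header dialects we accept, mapped to internal fields.
MIXCR_COLS <- list(
  count = c("cloneCount", "clone count", "Clone count", "readCount"),
  cdr3_aa = c("aaSeqCDR3", "AA. Seq. CDR3", "aaSeqImputedCDR3"),
  cdr3_nt = c("nSeqCDR3", "N. Seq. CDR3"),
  v = c("bestVHit", "allVHitsWithScore", "Best V hit", "bestVGene"),
  j = c("bestJHit", "allJHitsWithScore", "Best J hit", "bestJGene"))

#' Read a MiXCR-style clonotype export
#'
#' Accepts the common MiXCR export header dialects (`cloneCount`,
#' `aaSeqCDR3`, `bestVHit` / `allVHitsWithScore`, ...). Same contract as
#' [read_airr_table()]: V/J hits are truncated to gene level (allele and
#' score annotations stripped) and productivity is inferred from the CDR3
#' amino-acid sequence.
#'
#' @inheritParams read_airr_table
#' @return A `tcr_repertoire`.
#' @export
read_mixcr_table <- function(path, individual_id, group, compartment, subset) {
  tab <- read_tsv_quiet(path)
  if (nrow(tab) == 0) {
    stop_empty(paste0("no clonotype rows in ", path))
  }
  pick <- function(field) {
    hit <- intersect(MIXCR_COLS[[field]], names(tab))
    if (length(hit)) hit[[1]] else NA_character_
  }
  cols <- vapply(names(MIXCR_COLS), pick, character(1))
  if (any(is.na(cols[c("count", "cdr3_aa", "v", "j")]))) {
    stop_format(paste0(
      "unrecognized MiXCR header set in ", path, "; detected columns: ",
      paste(names(tab), collapse = ", ")))
  }
  cl <- tibble::tibble(
    cdr3_aa = as.character(tab[[cols[["cdr3_aa"]]]]),
    cdr3_nt = if (!is.na(cols[["cdr3_nt"]]))
                as.character(tab[[cols[["cdr3_nt"]]]]) else NA_character_,
    v_gene = normalize_gene(tab[[cols[["v"]]]]),
    j_gene = normalize_gene(tab[[cols[["j"]]]]),
    count = as.integer(round(as.numeric(tab[[cols[["count"]]]]))))
  rep <- repertoire(cl, individual_id, group, compartment, subset)
  if (!any(rep$clonotypes$productive)) {
    stop_empty(paste0("no productive clonotypes in ", path))
  }
  rep
}

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  if (file.size(path) == 0) stop_empty(paste0("empty file: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' @param rep A [repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr_table <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  out <- tibble::tibble(
    junction_aa = cl$cdr3_aa,
    v_call = cl$v_gene,
    j_call = cl$j_gene,
    duplicate_count = cl$count,
    productive = ifelse(cl$productive, "T", "F"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort from a sample manifest
#'
#' The manifest is a YAML file with a `samples` list; each entry has fields
#' `file` (path to an AIRR or MiXCR TSV, relative to the manifest),
#' `individual_id`, `group`, `compartment`, `subset`, and optional `format`
#' (`"airr"`, the default, or `"mixcr"`). An optional top-level `clinical`
#' field names a CSV of clinical records (see [read_clinical()]).
#'
#' @param path Path to the manifest YAML.
#' @return A `tcr_cohort`.
#' @export
read_cohort <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$samples) || !length(man$samples)) {
    stop_format(paste0("manifest ", path, " has no samples"))
  }
  base <- dirname(path)
  reps <- purrr::map(man$samples, function(s) {
    f <- file.path(base, s$file)
    reader <- if (identical(s$format, "mixcr")) read_mixcr_table
              else read_airr_table
    reader(f, s$individual_id, s$group, s$compartment, s$subset)
  })
  clinical <- NULL
  if (!is.null(man$clinical)) {
    clinical <- read_clinical(file.path(base, man$clinical))
  }
  cohort(reps, clinical = clinical)
}
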