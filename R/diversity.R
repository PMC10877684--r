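#' Shannon diversity of a repertoire
#'
#' Plug-in Shannon entropy `H = -sum(p_i * log(p_i))` in nats over the
#' productive clonotype frequencies. `H` is 0 for a monoclonal repertoire and
#' `log(richness)` for a perfectly even one.
#'
#' @param rep A [repertoire()].
#' @return Non-negative numeric scalar (nats).
#' @export
shannon_diversity <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  p <- rep$clonotypes$frequency[rep$clonotypes$productive]
  p <- p[!is.na(p) & p > 0]
  if (!length(p)) stop_empty("cannot compute diversity of an empty repertoire")
  -sum(p * log(p))
}

#' Repertoire richness
#'
#' Number of unique clone keys among productive clonotypes.
#'
#' @inheritParams clone_key
#' @param rep A [repertoire()].
#' @return Non-negative integer.
#' @export
richness <- function(rep, key = c("aa", "aa+V", "aa+V+J")) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  key <- match.arg(key)
  cl <- rep$clonotypes[rep$clonotypes$productive, , drop = FALSE]
  length(unique(clone_key(cl, key)))
}

#' V-gene usage distribution
#'
#' Proportion of the repertoire attributed to each V gene (or V family, where
#' `TRBVnn-k` collapses to `TRBVnn`), weighted by clone frequency (default)
#' or counting unique clones equally.
#'
#' @param rep A [repertoire()].
#' @param level `"gene"` or `"family"`.
#' @param weight `"frequency"` (default) or `"clones"`.
#' @return A tibble with columns `label` and `proportion` (sums to 1),
#'   sorted by decreasing proportion. Clones with a missing V call are pooled
#'   under `"unresolved"` with a warning.
#' @export
vgene_usage <- function(rep, level = c("gene", "family"),
                        weight = c("frequency", "clones")) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  level <- match.arg(level)
  weight <- match.arg(weight)
  cl <- rep$clonotypes[rep$clonotypes$productive, , drop = FALSE]
  if (nrow(cl) == 0) stop_empty("empty repertoire")
  v <- cl$v_gene
  unresolved <- is.na(v) | !nzchar(v)
  if (any(unresolved)) {
    rlang::warn(sprintf("%d clones with missing v_gene pooled as 'unresolved'",
                        sum(unresolved)))
    v[unresolved] <- "unresolved"
  }
  if (level == "family") {
    v <- ifelse(v == "unresolved", v, sub("-.*$", "", v))
  }
  w <- if (weight == "frequency") cl$frequency else rep(1, nrow(cl))
  out <- tibble::tibble(label = v, w = w) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(proportion = sum(.data$w), .groups = "drop")
  out$proportion <- out$proportion / sum(out$proportion)
  dplyr::arrange(out, dplyr::desc(.data$proportion))
}

#' Per-sample diversity summary of a cohort
#'
#' @param ch A [cohort()].
#' @param key Clone-identity key for richness.
#' @return A tibble with one row per repertoire: metadata, `richness`,
#'   `shannon`.
#' @export
diversity_table <- function(ch, key = "aa") {
  stopifnot(inherits(ch, "tcr_cohort"))
  purrr::map_dfr(ch$repertoires, function(r) {
    r <- filter_functional(r)
    tibble::tibble(individual_id = r$individual_id, group = r$group,
                   compartment = r$compartment, subset = r$subset,
                   richness = richness(r, key = key),
                   shannon = shannon_diversity(r))
  })
}
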