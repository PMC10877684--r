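#' Recirculating clones of one individual
#'
#' "Recirculating clones" are clonotypes observed in both the peripheral
#' blood (PB) and visceral adipose tissue (VAT) repertoires of the same
#' individual and subset. Matching is exact on the configured clone key.
#' Each shared clone carries its relative sequence count (normalized clone
#' frequency) in each compartment and a directionality call: `VAT` if it is
#' more expanded in VAT, `PB` if more expanded in blood, `TIED` if equal.
#'
#' @param pb,vat `tcr_repertoire` objects for the PB and VAT compartments of
#'   one individual and subset.
#' @param key Clone-identity key (see [clone_key()]).
#' @return A list of class `tcr_recirc`: `individual_id`, `group`, `subset`,
#'   `shared_keys`, `frac_recirc_vat` (fraction of unique VAT clones also in
#'   PB), `frac_recirc_pb`, and `per_clone` (tibble `key`, `freq_vat`,
#'   `freq_pb`, `direction`).
#' @export
recirculating_clones <- function(pb, vat, key = "aa") {
  stopifnot(inherits(pb, "tcr_repertoire"), inherits(vat, "tcr_repertoire"))
  if (pb$compartment != "PB" || vat$compartment != "VAT") {
    rlang::abort("arguments must be the PB and VAT repertoires, in that order",
                 class = "tcrtrack_scope_error")
  }
  if (pb$individual_id != vat$individual_id || pb$subset != vat$subset) {
    rlang::abort("PB and VAT repertoires must share individual_id and subset",
                 class = "tcrtrack_scope_error")
  }
  pb <- collapse_by_key(filter_functional(pb), key)
  vat <- collapse_by_key(filter_functional(vat), key)
  pbk <- clone_key(pb$clonotypes, key)
  vatk <- clone_key(vat$clonotypes, key)
  shared <- intersect(pbk, vatk)
  per_clone <- tibble::tibble(
    key = shared,
    freq_vat = vat$clonotypes$frequency[match(shared, vatk)],
    freq_pb = pb$clonotypes$frequency[match(shared, pbk)])
  per_clone$direction <- classify_direction(per_clone$freq_vat,
                                            per_clone$freq_pb)
  structure(list(individual_id = pb$individual_id, group = vat$group,
                 subset = pb$subset, shared_keys = shared,
                 frac_recirc_vat = length(shared) / length(vatk),
                 frac_recirc_pb = length(shared) / length(pbk),
                 per_clone = per_clone),
            class = "tcr_recirc")
}

#' @export
print.tcr_recirc <- function(x, ...) {
  cat(sprintf(
    "<tcr_recirc> %s (%s, %s): %d recirculating clones (%.1f%% of VAT, %.1f%% of PB)\n",
    x$individual_id, x$group, x$subset, length(x$shared_keys),
    100 * x$frac_recirc_vat, 100 * x$frac_recirc_pb))
  invisible(x)
}

#' Classify the expansion direction of a recirculating clone
#'
#' @param freq_vat,freq_pb Clone frequencies in VAT and PB (vectors recycle).
#' @return `"VAT"` where `freq_vat > freq_pb`, `"PB"` where
#'   `freq_pb > freq_vat`, `"TIED"` where equal.
#' @export
classify_direction <- function(freq_vat, freq_pb) {
  stopifnot(all(freq_vat >= 0 & freq_vat <= 1),
            all(freq_pb >= 0 & freq_pb <= 1))
  dplyr::case_when(freq_vat > freq_pb ~ "VAT",
                   freq_pb > freq_vat ~ "PB",
                   TRUE ~ "TIED")
}

#' Group-level recirculation summary
#'
#' Summarises per-individual recirculation reports of one cohort group: the
#' median recirculating-clone fraction and the pooled directionality split of
#' all recirculating clones in the group (the stacked-bar quantities). The
#' VAT-expanded, PB-expanded and tied fractions are computed over all
#' recirculating clones of the group and sum to 1.
#'
#' @param reports List of [recirculating_clones()] reports from one group.
#' @param group Group label (defaults to the reports' common group).
#' @return A list of class `tcr_recirc_summary`: `group`, `subset`,
#'   `median_frac_recirc` (VAT-denominated), `median_frac_recirc_pb`,
#'   `frac_clones_vat_expanded`, `frac_clones_pb_expanded`,
#'   `frac_clones_tied`, `n_recirc_clones`, `reports`.
#' @export
group_summary <- function(reports, group = NULL) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "tcr_recirc")))
  group <- group %||% unique(vapply(reports, `[[`, character(1), "group"))
  stopifnot(length(group) == 1)
  dirs <- unlist(lapply(reports, function(r) r$per_clone$direction))
  n <- length(dirs)
  structure(list(
    group = group,
    subset = unique(vapply(reports, `[[`, character(1), "subset")),
    median_frac_recirc = median(vapply(reports, `[[`, numeric(1),
                                       "frac_recirc_vat")),
    median_frac_recirc_pb = median(vapply(reports, `[[`, numeric(1),
                                          "frac_recirc_pb")),
    frac_clones_vat_expanded = if (n) sum(dirs == "VAT") / n else NA_real_,
    frac_clones_pb_expanded = if (n) sum(dirs == "PB") / n else NA_real_,
    frac_clones_tied = if (n) sum(dirs == "TIED") / n else NA_real_,
    n_recirc_clones = n,
    reports = reports),
    class = "tcr_recirc_summary")
}

#' @export
print.tcr_recirc_summary <- function(x, ...) {
  cat(sprintf(
    "<tcr_recirc_summary> %s (%s): median recirc %.2f%% of VAT; %d clones: %.0f%% VAT- / %.0f%% PB-expanded\n",
    x$group, x$subset, 100 * x$median_frac_recirc, x$n_recirc_clones,
    100 * x$frac_clones_vat_expanded, 100 * x$frac_clones_pb_expanded))
  invisible(x)
}

#' Track recirculation across a whole cohort
#'
#' Pairs each individual's PB and VAT repertoires of the given subset and
#' returns per-individual reports plus per-group summaries.
#'
#' @param ch A [cohort()].
#' @param subset Subset scope (default `"PD1pos"`).
#' @param key Clone-identity key.
#' @return A list with `reports` (per individual), `summaries` (per group,
#'   named), and `table` (tidy per-individual tibble).
#' @export
track_cohort <- function(ch, subset = "PD1pos", key = "aa") {
  meta <- cohort_metadata(ch)
  meta <- meta[meta$subset == subset, , drop = FALSE]
  ids <- unique(meta$individual_id)
  reports <- list()
  for (id in ids) {
    pb <- cohort_select(ch, "PB", subset, individual_id = id)
    vat <- cohort_select(ch, "VAT", subset, individual_id = id)
    if (length(pb) == 1 && length(vat) == 1) {
      reports[[id]] <- recirculating_clones(pb[[1]], vat[[1]], key = key)
    }
  }
  if (!length(reports)) stop_empty("no paired PB/VAT repertoires in scope")
  groups <- vapply(reports, `[[`, character(1), "group")
  summaries <- lapply(split(reports, groups), group_summary)
  tab <- purrr::map_dfr(reports, function(r)
    tibble::tibble(individual_id = r$individual_id, group = r$group,
                   subset = r$subset, n_shared = length(r$shared_keys),
                   frac_recirc_vat = r$frac_recirc_vat,
                   frac_recirc_pb = r$frac_recirc_pb))
  list(reports = reports, summaries = summaries, table = tab)
}

#' Group comparison statistics for recirculation
#'
#' Kruskal-Wallis test of per-individual recirculating-clone fractions
#' across groups, and per-group Wilcoxon matched-pairs signed-rank tests of
#' the paired PB vs VAT relative sequence counts of recirculating clones.
#'
#' @param tracking Result of [track_cohort()].
#' @param denominator `"vat"` (default) or `"pb"`: which recirculation
#'   fraction enters the Kruskal-Wallis test.
#' @param alternative Alternative hypothesis for the Wilcoxon tests
#'   (`freq_pb` vs `freq_vat`); default two-sided.
#' @return A list with `kruskal` (list `statistic`, `p_value`, `df`) and
#'   `wilcoxon` (tibble per group: `group`, `n_pairs`, `p_value`).
#' @export
compare_recirculation <- function(tracking, denominator = c("vat", "pb"),
                                  alternative = "two.sided") {
  denominator <- match.arg(denominator)
  tab <- tracking$table
  col <- if (denominator == "vat") "frac_recirc_vat" else "frac_recirc_pb"
  if (dplyr::n_distinct(tab$group) < 2) {
    rlang::abort("Kruskal-Wallis needs at least 2 groups",
                 class = "tcrtrack_scope_error")
  }
  if (any(table(tab$group) < 2)) {
    rlang::abort("each group needs at least 2 individuals",
                 class = "tcrtrack_scope_error")
  }
  kw <- stats::kruskal.test(tab[[col]], factor(tab$group))
  wil <- purrr::map_dfr(tracking$summaries, function(s) {
    pc <- dplyr::bind_rows(lapply(s$reports, `[[`, "per_clone"))
    p <- if (nrow(pc) >= 1 && any(pc$freq_pb != pc$freq_vat)) {
      d <- pc$freq_pb - pc$freq_vat
      # exact signed-rank distribution is only defined without zeros/ties
      exact_ok <- nrow(pc) <= 50 && all(d != 0) && !any(duplicated(abs(d)))
      stats::wilcox.test(pc$freq_pb, pc$freq_vat, paired = TRUE,
                         alternative = alternative, exact = exact_ok)$p.value
    } else NA_real_
    tibble::tibble(group = s$group, n_pairs = nrow(pc), p_value = p)
  })
  list(kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value,
                      df = unname(kw$parameter)),
       wilcoxon = wil)
}
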