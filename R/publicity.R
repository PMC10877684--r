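#' Build a cross-individual clone sharing table
#'
#' Records, for every clone key observed in the scoped repertoires, which
#' individuals (and hence which cohort groups) carry it. Individuals — not
#' samples — are the sharing unit: a clone found in both compartments of one
#' individual counts once.
#'
#' @param ch A [cohort()].
#' @param compartment Compartment scope (default `"VAT"`); `NULL` pools both.
#' @param subset Subset scope (default `"PD1pos"`); `NULL` pools both.
#' @param key Clone-identity key (see [clone_key()]).
#' @return A `tcr_sharing` tibble with one row per (key, individual): columns
#'   `key`, `individual_id`, `group`; scope stored in attributes.
#' @export
build_sharing_table <- function(ch, compartment = "VAT", subset = "PD1pos",
                                key = "aa") {
  reps <- cohort_select(ch, compartment = compartment, subset = subset)
  if (!length(reps)) stop_empty("no repertoires in the requested scope")
  tab <- purrr::map_dfr(reps, function(r) {
    r <- collapse_by_key(filter_functional(r), key)
    tibble::tibble(key = clone_key(r$clonotypes, key),
                   individual_id = r$individual_id, group = r$group)
  })
  tab <- dplyr::distinct(tab)
  structure(tab, class = c("tcr_sharing", class(tab)),
            compartment = compartment, subset = subset, clone_key = key)
}

#' Public clonotypes
#'
#' Clonotypes carried by at least `min_individuals` distinct individuals;
#' clones below the threshold are private and excluded.
#'
#' @param table A sharing table from [build_sharing_table()].
#' @param min_individuals Minimum number of distinct carriers (default 2).
#' @return Character vector of public clone keys.
#' @export
public_clones <- function(table, min_individuals = 2) {
  stopifnot(min_individuals >= 2)
  counts <- table |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_ind = dplyr::n_distinct(.data$individual_id),
                     .groups = "drop")
  counts$key[counts$n_ind >= min_individuals]
}

#' Venn region counts of clone sharing across groups
#'
#' For each non-empty combination of cohort groups, the number of clone keys
#' observed in exactly that set of groups. Region counts partition the
#' distinct keys of the sharing table.
#'
#' @param table A sharing table from [build_sharing_table()].
#' @return A tibble with columns `region` (group names joined by `+`, in
#'   LC / OB-ND / OB-Dys order) and `n_clones`.
#' @export
venn_counts <- function(table) {
  regions <- table |>
    dplyr::distinct(.data$key, .data$group) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      region = paste(GROUPS[GROUPS %in% .data$group], collapse = "+"),
      .groups = "drop")
  regions |>
    dplyr::count(.data$region, name = "n_clones") |>
    dplyr::arrange(dplyr::desc(.data$n_clones))
}

#' Group divergence of shared clonotypes (Fisher's exact test)
#'
#' Tests whether clones shared among individuals tend to stay within a group
#' rather than cross between two groups. Restricting to clones carried by at
#' least two individuals of the pair's scope (private clones excluded), each
#' clone carried by group `g` is classified as shared *within* `g` only or
#' shared *across* the two groups; the 2x2 table (rows intra/cross, columns
#' the two groups — a cross-group clone contributes to both columns) goes
#' into a two-sided Fisher's exact test. An odds ratio below 1 means the two
#' repertoires rarely converge on the same shared clones.
#'
#' The contingency construction is pluggable via `strategy`, a function
#' `(table, group_a, group_b) -> 2x2 integer matrix` with rows
#' (intra, cross) and columns (group_a, group_b).
#'
#' @param table A sharing table from [build_sharing_table()].
#' @param group_a,group_b Group labels to compare.
#' @param strategy Optional replacement contingency builder.
#' @return A list of class `tcr_divergence`: `group_a`, `group_b`, `table`
#'   (2x2 matrix), `odds_ratio` (cross-product ratio `ad/bc`; `NA` with
#'   `or_defined = FALSE` when a margin is zero), `p_value` (two-sided
#'   exact).
#' @export
group_divergence_fisher <- function(table, group_a, group_b,
                                    strategy = NULL) {
  stopifnot(group_a %in% table$group, group_b %in% table$group)
  for (g in c(group_a, group_b)) {
    if (dplyr::n_distinct(table$individual_id[table$group == g]) < 2) {
      rlang::abort(sprintf("group %s has fewer than 2 individuals", g),
                   class = "tcrtrack_scope_error")
    }
  }
  build <- strategy %||% divergence_table_default
  m <- build(table, group_a, group_b)
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)), all(m >= 0))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  or_defined <- (b * c) > 0 || (a * d) > 0
  odds_ratio <- if ((b * c) == 0 && (a * d) == 0) NA_real_ else (a * d) / (b * c)
  p <- stats::fisher.test(m)$p.value
  structure(list(group_a = group_a, group_b = group_b, table = m,
                 odds_ratio = odds_ratio, or_defined = or_defined,
                 p_value = p),
            class = "tcr_divergence")
}

# Default construction: scope = clones shared by >=2 individuals within
# {group_a, group_b}; per group, count clones shared only within that group
# (intra) vs shared across the pair (cross).
divergence_table_default <- function(table, group_a, group_b) {
  sub <- table[table$group %in% c(group_a, group_b), , drop = FALSE]
  per_key <- sub |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_ind = dplyr::n_distinct(.data$individual_id),
                     in_a = group_a %in% .data$group,
                     in_b = group_b %in% .data$group,
                     .groups = "drop")
  shared <- per_key[per_key$n_ind >= 2, , drop = FALSE]
  cross <- shared$in_a & shared$in_b
  m <- matrix(c(sum(shared$in_a & !cross), sum(shared$in_b & !cross),
                sum(cross), sum(cross)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("intra", "cross"), c(group_a, group_b)))
  m
}

#' @export
print.tcr_divergence <- function(x, ...) {
  cat(sprintf("<tcr_divergence> %s vs %s: OR = %.4g, p = %.4g\n",
              x$group_a, x$group_b, x$odds_ratio, x$p_value))
  print(x$table)
  invisible(x)
}
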