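#' Pipeline run configuration
#'
#' Collects every tunable of the analysis chain with its standard default:
#' clone identity key `"aa"`, VAT-denominated recirculation fractions,
#' motif lengths 3 and 4, pattern retention thresholds (>= 3 unique CDR3s,
#' all three p-like scores <= 0.05), annotation confidence filters
#' (score >= 1, MHC class II, CD4), publicity threshold (>= 2 individuals),
#' and the HOMA-IR screen cuts (r > 0.8, p < 0.05).
#'
#' @param manifest Path to a cohort manifest YAML (see [read_cohort()]), or
#'   `NULL` when a cohort object is passed to [run_pipeline()] directly.
#' @param key Clone-identity key.
#' @param subset Cell subset analysed (default `"PD1pos"`).
#' @param denominator Recirculation-fraction denominator, `"vat"` or `"pb"`.
#' @param k Motif lengths.
#' @param min_unique_cdr3,max_fisher,max_v_p,max_length_p Pattern filter.
#' @param min_individuals Publicity threshold.
#' @param min_score,mhc_class,compartment_label Annotation filters.
#' @param r_min,p_max HOMA-IR screen thresholds.
#' @param out_dir Output directory.
#' @param seed Seed echoed into the run log.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest = NULL, key = "aa", subset = "PD1pos",
                       denominator = "vat", k = c(3, 4),
                       min_unique_cdr3 = 3, max_fisher = 0.05,
                       max_v_p = 0.05, max_length_p = 0.05,
                       min_individuals = 2, min_score = 1,
                       mhc_class = "MHCII", compartment_label = "CD4",
                       r_min = 0.8, p_max = 0.05,
                       out_dir = "tcrtrack_results", seed = 1) {
  stopifnot(key %in% CLONE_KEYS, denominator %in% c("vat", "pb"),
            min_unique_cdr3 >= 1, max_fisher >= 0, max_fisher <= 1,
            min_individuals >= 2, r_min >= -1, r_min <= 1,
            p_max > 0, p_max <= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Chains the analysis stages over a cohort: functional filtering and
#' diversity/usage tables; cross-individual sharing, Venn partitioning and
#' pairwise Fisher divergence; PB/VAT clonal tracking with group summaries
#' and comparison statistics; motif patterns with the retention filter and
#' (optionally) antigen annotation; and the HOMA-IR correlation screen when
#' clinical and expression data are available. All tables are written as TSV
#' under `config$out_dir` together with a `run_log.json` echoing the
#' configuration.
#'
#' @param config A [run_config()].
#' @param ch Optional [cohort()] (otherwise read from `config$manifest`).
#' @param reference Optional reference CDR3 vector for motif enrichment;
#'   when `NULL` the pattern stage is skipped.
#' @param annotation_db Optional annotation tibble (see [read_vdjdb()]).
#' @param expr Optional expression matrix for the metabolic screen.
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(config, ch = NULL, reference = NULL,
                         annotation_db = NULL, expr = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = config[setdiff(names(config), "out_dir")],
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = list())
  stage <- function(name, fun) {
    tryCatch(fun, error = function(e) {
      log$stages[[name]] <<- paste("error:", conditionMessage(e))
      write_log()
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  write_log <- function() {
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out <- list()

  if (is.null(ch)) {
    ch <- stage("read", read_cohort(config$manifest))
  }
  log$stages$read <- "ok"

  out$diversity <- stage("diversity", diversity_table(ch, key = config$key))
  readr::write_tsv(out$diversity, file.path(config$out_dir, "diversity.tsv"),
                   progress = FALSE)
  log$stages$diversity <- "ok"

  out$sharing <- stage("share", build_sharing_table(
    ch, compartment = "VAT", subset = config$subset, key = config$key))
  out$public <- public_clones(out$sharing,
                              min_individuals = config$min_individuals)
  out$venn <- venn_counts(out$sharing)
  readr::write_tsv(out$venn, file.path(config$out_dir, "venn_counts.tsv"),
                   progress = FALSE)
  groups <- unique(out$sharing$group)
  pairs <- if (length(groups) >= 2) utils::combn(sort(groups), 2,
                                                 simplify = FALSE) else list()
  out$divergence <- purrr::map_dfr(pairs, function(pr) {
    dv <- tryCatch(group_divergence_fisher(out$sharing, pr[1], pr[2]),
                   tcrtrack_scope_error = function(e) NULL)
    if (is.null(dv)) return(tibble::tibble())
    tibble::tibble(group_a = dv$group_a, group_b = dv$group_b,
                   odds_ratio = dv$odds_ratio, p_value = dv$p_value)
  })
  if (nrow(out$divergence)) {
    readr::write_tsv(out$divergence,
                     file.path(config$out_dir, "divergence.tsv"),
                     progress = FALSE)
  }
  log$stages$share <- "ok"

  out$tracking <- stage("track", track_cohort(ch, subset = config$subset,
                                              key = config$key))
  readr::write_tsv(out$tracking$table,
                   file.path(config$out_dir, "recirculation.tsv"),
                   progress = FALSE)
  out$group_summaries <- purrr::map_dfr(out$tracking$summaries, function(s)
    tibble::tibble(group = s$group,
                   median_frac_recirc = s$median_frac_recirc,
                   frac_clones_vat_expanded = s$frac_clones_vat_expanded,
                   frac_clones_pb_expanded = s$frac_clones_pb_expanded,
                   frac_clones_tied = s$frac_clones_tied,
                   n_recirc_clones = s$n_recirc_clones))
  readr::write_tsv(out$group_summaries,
                   file.path(config$out_dir, "group_summaries.tsv"),
                   progress = FALSE)
  out$stats <- tryCatch(
    compare_recirculation(out$tracking, denominator = config$denominator),
    tcrtrack_scope_error = function(e) NULL)
  log$stages$track <- "ok"

  if (!is.null(reference)) {
    scope <- cohort_select(ch, subset = config$subset)
    out$patterns <- stage("motifs", build_patterns(scope, reference,
                                                   k = config$k))
    out$patterns_retained <- filter_patterns(
      out$patterns, min_unique_cdr3 = config$min_unique_cdr3,
      max_fisher = config$max_fisher, max_v_p = config$max_v_p,
      max_length_p = config$max_length_p)
    flat <- out$patterns_retained[, setdiff(names(out$patterns_retained),
                                            "members")]
    readr::write_tsv(flat, file.path(config$out_dir, "patterns.tsv"),
                     progress = FALSE)
    log$stages$motifs <- "ok"
  }

  if (!is.null(annotation_db)) {
    seqs <- unique(unlist(lapply(cohort_select(ch, subset = config$subset),
                                 function(r)
                                   r$clonotypes$cdr3_aa[r$clonotypes$productive])))
    out$annotation <- stage("annotate", annotate(
      seqs, annotation_db, min_score = config$min_score,
      mhc_class = config$mhc_class,
      compartment_label = config$compartment_label))
    flat <- out$annotation
    flat$species <- vapply(flat$species, paste, character(1), collapse = ";")
    readr::write_tsv(flat, file.path(config$out_dir, "annotation.tsv"),
                     progress = FALSE)
    log$stages$annotate <- "ok"
  }

  if (!is.null(expr) && !is.null(ch$clinical)) {
    out$metabolic <- stage("metabolic",
                           correlate_with_homa(expr, ch$clinical,
                                               r_min = config$r_min,
                                               p_max = config$p_max))
    readr::write_tsv(out$metabolic,
                     file.path(config$out_dir, "homa_correlation.tsv"),
                     progress = FALSE)
    log$stages$metabolic <- "ok"
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_log()
  invisible(out)
}

#' Stacked-bar plot of recirculating-clone directionality
#'
#' Mirrors the group-level stacked bars: per group, the percentage of
#' recirculating clones more expanded in VAT vs in PB (ties excluded).
#' Requires ggplot2.
#'
#' @param summaries A list of [group_summary()] objects (or the `summaries`
#'   element of [track_cohort()]).
#' @return A ggplot object.
#' @export
plot_direction_bars <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("ggplot2 is required for plotting")
  }
  df <- purrr::map_dfr(summaries, function(s) {
    non_tied <- s$frac_clones_vat_expanded + s$frac_clones_pb_expanded
    tibble::tibble(group = s$group,
                   direction = c("VAT", "PB"),
                   pct = 100 * c(s$frac_clones_vat_expanded,
                                 s$frac_clones_pb_expanded) / non_tied)
  })
  df$group <- factor(df$group, levels = GROUPS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pct,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of recirculating clones",
                  fill = "Expanded in") +
    ggplot2::theme_minimal()
}
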