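#' Homeostasis Model Assessment of Insulin Resistance
#'
#' `HOMA-IR = fasting glucose (mg/dL) x fasting insulin (mU/L) / 405`.
#'
#' @param glucose Fasting glucose in mg/dL (must be positive).
#' @param insulin Fasting insulin in mU/L (non-negative).
#' @return Numeric HOMA-IR value(s).
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(is.na(glucose)) || any(glucose <= 0)) {
    rlang::abort("fasting glucose must be positive",
                 class = "tcrtrack_value_error")
  }
  if (any(is.na(insulin)) || any(insulin < 0)) {
    rlang::abort("fasting insulin must be non-negative",
                 class = "tcrtrack_value_error")
  }
  glucose * insulin / 405
}

#' Construct clinical records
#'
#' @param individual_id Individual identifiers.
#' @param glucose Fasting glucose, mg/dL.
#' @param insulin Fasting insulin, mU/L.
#' @param hba1c HbA1c, percent.
#' @param on_meds Logical: on antidiabetic medication.
#' @return A tibble with a derived `homa_ir` column.
#' @export
clinical_record <- function(individual_id, glucose, insulin, hba1c,
                            on_meds = FALSE) {
  tibble::tibble(individual_id = as.character(individual_id),
                 glucose = as.numeric(glucose),
                 insulin = as.numeric(insulin),
                 hba1c = as.numeric(hba1c),
                 on_meds = as.logical(on_meds),
                 homa_ir = homa_ir(glucose, insulin))
}

#' Read clinical records from CSV
#'
#' Expects columns `individual_id`, `glucose`, `insulin`, `hba1c`,
#' `on_meds`.
#'
#' @param path Path to the CSV.
#' @return A clinical tibble (see [clinical_record()]).
#' @export
read_clinical <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("individual_id", "glucose", "insulin", "hba1c", "on_meds")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_format(paste0("clinical table ", path, " lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  clinical_record(tab$individual_id, tab$glucose, tab$insulin, tab$hba1c,
                  as.logical(tab$on_meds))
}

#' ADA glycemia classification
#'
#' Classifies each record as diabetic (`D`: glucose >= 126 mg/dL, or HbA1c >=
#' 6.5 percent, or on antidiabetic medication), prediabetic (`PreD`: glucose
#' 100-125 mg/dL or HbA1c 5.7-6.4 percent), or normoglycemic (`ND`)
#' otherwise. The diagnostic criteria are evaluated with precedence
#' `D > PreD > ND`, so any analyte in a diagnostic range escalates the
#' class. Dysglycemia is `PreD` or `D`.
#'
#' @param glucose Fasting glucose, mg/dL. May also be a clinical tibble (see
#'   [clinical_record()]), in which case the other arguments are ignored.
#' @param hba1c HbA1c, percent.
#' @param on_meds Logical, antidiabetic medication.
#' @return Character vector in `c("ND", "PreD", "D")`.
#' @export
classify_glycemia <- function(glucose, hba1c = NULL, on_meds = FALSE) {
  if (is.data.frame(glucose)) {
    rec <- glucose
    glucose <- rec$glucose
    hba1c <- rec$hba1c
    on_meds <- rec$on_meds
  }
  if (is.null(hba1c)) rlang::abort("hba1c is required",
                                   class = "tcrtrack_value_error")
  n <- max(length(glucose), length(hba1c), length(on_meds))
  glucose <- rep_len(glucose, n)
  hba1c <- rep_len(hba1c, n)
  on_meds <- rep_len(on_meds, n)
  if (any(is.na(glucose) & is.na(hba1c))) {
    rlang::abort("both glucose and hba1c missing for at least one record",
                 class = "tcrtrack_value_error")
  }
  d <- (!is.na(glucose) & glucose >= 126) | (!is.na(hba1c) & hba1c >= 6.5) |
    (!is.na(on_meds) & on_meds)
  pred <- (!is.na(glucose) & glucose >= 100 & glucose <= 125) |
    (!is.na(hba1c) & hba1c >= 5.7 & hba1c <= 6.4)
  ifelse(d, "D", ifelse(pred, "PreD", "ND"))
}

#' Is a record dysglycemic?
#'
#' @inheritParams classify_glycemia
#' @return Logical: `TRUE` for `PreD` or `D`.
#' @export
is_dysglycemic <- function(glucose, hba1c = NULL, on_meds = FALSE) {
  classify_glycemia(glucose, hba1c, on_meds) %in% c("PreD", "D")
}

#' Screen gene expression for correlation with HOMA-IR
#'
#' Pearson correlation of each gene's log2 RPKM values with the samples'
#' HOMA-IR, retaining positively correlated genes with `r > r_min` and
#' nominal `p < p_max` (strict inequalities, defaults 0.8 and 0.05).
#' Zero-variance genes cannot be correlated and are skipped (reported via a
#' message).
#'
#' @param expr Numeric matrix, genes x samples, with row names (genes) and
#'   column names matching `clinical$individual_id`.
#' @param clinical Clinical tibble with `individual_id` and `homa_ir` (see
#'   [clinical_record()]).
#' @param r_min,p_max Retention thresholds (strict).
#' @return A tibble per testable gene: `gene`, `r`, `p`, `retained`, sorted
#'   by decreasing `r`. At least 3 overlapping samples are required.
#' @export
correlate_with_homa <- function(expr, clinical, r_min = 0.8, p_max = 0.05) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  common <- intersect(colnames(expr), clinical$individual_id)
  if (length(common) < 3) {
    rlang::abort("need at least 3 samples with both expression and HOMA-IR",
                 class = "tcrtrack_scope_error")
  }
  h <- clinical$homa_ir[match(common, clinical$individual_id)]
  x <- expr[, common, drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  skipped <- sum(sds == 0 | is.na(sds))
  if (skipped > 0) {
    message(skipped, " zero-variance genes skipped")
  }
  x <- x[sds > 0 & !is.na(sds), , drop = FALSE]
  res <- purrr::map_dfr(rownames(x), function(g) {
    ct <- stats::cor.test(x[g, ], h, method = "pearson")
    tibble::tibble(gene = g, r = unname(ct$estimate), p = ct$p.value)
  })
  res$retained <- res$r > r_min & res$p < p_max
  dplyr::arrange(res, dplyr::desc(.data$r))
}
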