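## Fold-error metric, within-k-fold accuracy, class summaries, scatter export.

#' Symmetric fold error between predicted and clinical dose
#'
#' `max(predicted/clinical, clinical/predicted)`: dimensionless, >= 1,
#' symmetric in its arguments, scale invariant, and equal to 1 exactly when
#' the prediction is on the nose. "Within k-fold" means this ratio is <= k.
#'
#' @param predicted predicted human dose in mg/kg; positive, vectorized.
#' @param clinical recommended clinical dose in mg/kg; positive, vectorized.
#' @return Numeric vector of fold errors.
#' @examples
#' fold_error(9, 3)  # 3
#' fold_error(3, 9)  # 3
#' @export
fold_error <- function(predicted, clinical) {
  if (!is.numeric(predicted) || !is.numeric(clinical) ||
      anyNA(predicted) || anyNA(clinical)) {
    stop("doses must be numeric and non-missing", call. = FALSE)
  }
  if (any(predicted <= 0) || any(clinical <= 0)) {
    stop("fold error requires strictly positive doses (log-scale metric)",
         call. = FALSE)
  }
  pmax(predicted / clinical, clinical / predicted)
}

#' Percentage of predictions within k-fold
#'
#' 100 x (number of fold errors <= k) / n. The boundary counts as within
#' (fold error exactly k is a hit). The unrounded percentage is returned;
#' use [format_pct()] for the one-decimal display convention.
#'
#' @param x evaluation data frame with a `fold_error` column, or a numeric
#'   vector of fold errors.
#' @param k fold threshold, `>= 1`.
#' @return Unrounded percentage in `[0, 100]`.
#' @examples
#' pct_within(c(1.5, 2.5, 4), 3)  # 66.66667
#' @export
pct_within <- function(x, k) {
  fe <- if (is.data.frame(x)) x$fold_error else x
  if (is.null(fe) || !is.numeric(fe)) {
    stop("x must be a numeric fold-error vector or a data frame with a fold_error column",
         call. = FALSE)
  }
  if (length(fe) == 0L) stop("empty row set: percentage undefined", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("k must be a single number >= 1", call. = FALSE)
  }
  100 * sum(fe <= k) / length(fe)
}

#' One-decimal display of a percentage
#'
#' Display convention for summary tables: one decimal place (e.g. `16.7` for
#' 5 of 30). Raw unrounded percentages are kept everywhere internally.
#'
#' @param pct numeric percentage(s).
#' @return Numeric rounded to one decimal.
#' @export
format_pct <- function(pct) {
  round(pct, 1)
}

#' Evaluate dose predictions for a record table
#'
#' Builds one evaluation row per drug: the mouse Day-1 dose (per-administration
#' value normalized to mg/kg times the number of Day-1 administrations) is
#' translated to a predicted human dose by the BSA route (x3/37), the direct
#' body-weight route, or per-drug selection on molecular weight
#' (`method = "auto"`: BW above 100 kDa, BSA otherwise); the recommended
#' clinical dose is reduced to mg/kg via [recommended_clinical_dose()]; and
#' the symmetric fold error with within-2x / within-3x indicators is attached.
#'
#' @param records validated drug-record data frame ([drug_record_columns()]).
#' @param method `"bsa"`, `"bw"`, or `"auto"`.
#' @return Data frame with columns `drug_name`, `modality_class`, `method`,
#'   `predicted_dose`, `clinical_dose`, `fold_error`, `within_2x`,
#'   `within_3x`.
#' @export
evaluate_records <- function(records, method = c("bsa", "bw", "auto")) {
  method <- match.arg(method)
  validate_drug_records(records)
  if (nrow(records) == 0L) stop("no records to evaluate", call. = FALSE)

  n_admin <- if ("nonclin_n_admin_day1" %in% names(records))
    ifelse(is.na(records$nonclin_n_admin_day1), 1, records$nonclin_n_admin_day1)
  else rep(1, nrow(records))
  day1 <- normalize_to_mgkg(records$nonclin_dose_value,
                            records$nonclin_dose_unit,
                            tolower(records$nonclin_species)) * n_admin

  per_drug_method <- switch(method,
    bsa = rep("BSA", nrow(records)),
    bw  = rep("BW", nrow(records)),
    auto = {
      mw <- records$molecular_weight_kda
      if (anyNA(mw)) {
        stop("method = 'auto' requires molecular_weight_kda for every record; missing for ",
             paste(records$drug_name[is.na(mw)], collapse = ", "), call. = FALSE)
      }
      select_method(mw)
    })

  predicted <- ifelse(per_drug_method == "BSA",
                      bsa_predict_human_dose(day1),
                      bw_predict_human_dose(day1))
  clin_high <- if ("clin_dose_high" %in% names(records)) records$clin_dose_high
               else rep(NA_real_, nrow(records))
  clinical <- tryCatch(
    recommended_clinical_dose(records$clin_dose_low, clin_high,
                              records$clin_dose_unit),
    error = function(e) {
      stop("clinical dose normalization failed (drugs: ",
           paste(utils::head(records$drug_name, 3), collapse = ", "), ", ...): ",
           conditionMessage(e), call. = FALSE)
    })
  bad <- predicted <= 0 | clinical <= 0
  if (any(bad)) {
    stop("nonpositive dose for drug(s): ",
         paste(records$drug_name[bad], collapse = ", "),
         "; fold error is undefined", call. = FALSE)
  }
  fe <- fold_error(predicted, clinical)
  data.frame(
    drug_name = records$drug_name,
    modality_class = records$modality_class,
    method = per_drug_method,
    predicted_dose = predicted,
    clinical_dose = clinical,
    fold_error = fe,
    within_2x = fe <= 2,
    within_3x = fe <= 3,
    stringsAsFactors = FALSE
  )
}

#' Class groupings for the summary table
#'
#' The groupings used in the published-style summary: small molecules by
#' route (IV, PO, their union) and the immune/hormone-targeted subgroup; large
#' molecules as the antibody + ADC pool and its ADC, antibody (including
#' checkpoint inhibitors and bispecifics) and checkpoint-inhibitor subsets.
#' Body-weight columns are reported only for the large-molecule groups.
#'
#' @return List of group definitions (`class_label`, `subclass_label`,
#'   `classes`, `methods`).
#' @export
table1_grouping <- function() {
  sm <- "BSA"
  lm <- c("BSA", "BW")
  list(
    list(class_label = "Small Molecule", subclass_label = "IV",
         classes = "SM_IV", methods = sm),
    list(class_label = "Small Molecule", subclass_label = "PO",
         classes = "SM_PO", methods = sm),
    list(class_label = "Small Molecule", subclass_label = "IV + PO",
         classes = c("SM_IV", "SM_PO"), methods = sm),
    list(class_label = "Small Molecule", subclass_label = "IO/HT",
         classes = "SM_IO_HT", methods = sm),
    list(class_label = "Large molecule", subclass_label = "mAb + ADC",
         classes = c("mAb", "checkpoint", "bispecific", "ADC"), methods = lm),
    list(class_label = "Large molecule", subclass_label = "ADC",
         classes = "ADC", methods = lm),
    list(class_label = "Large molecule", subclass_label = "mAb",
         classes = c("mAb", "checkpoint", "bispecific"), methods = lm),
    list(class_label = "Large molecule", subclass_label = "Checkpoint Inhibitor",
         classes = "checkpoint", methods = lm)
  )
}

#' Class-level within-fold summary table
#'
#' One row per group: number of drugs and the percentage of predictions
#' within 2x and 3x of the recommended clinical dose for each applicable
#' method (unrounded; apply [format_pct()] for display). Groups with no
#' contributing rows are omitted with a warning rather than reported as zero.
#'
#' @param rows evaluation rows for one or both methods (as produced by
#'   [evaluate_records()], possibly row-bound across methods); the `method`
#'   column distinguishes BSA from BW rows.
#' @param grouping list of group definitions; defaults to [table1_grouping()].
#' @param k fold thresholds to tabulate.
#' @return Data frame with columns `class_label`, `subclass_label`, `n`, and
#'   `pct_within_<k>x_<method>` for each threshold and method.
#' @export
summarize_translation <- function(rows, grouping = table1_grouping(),
                                  k = c(2, 3)) {
  stopifnot(is.data.frame(rows), all(k >= 1))
  out <- list()
  for (g in grouping) {
    res <- list(class_label = g$class_label, subclass_label = g$subclass_label)
    in_group <- rows$modality_class %in% g$classes
    n_drugs <- length(unique(rows$drug_name[in_group]))
    if (n_drugs == 0L) {
      warning("group '", g$class_label, " / ", g$subclass_label,
              "' has no records; omitted", call. = FALSE)
      next
    }
    res$n <- n_drugs
    for (kk in k) for (m in c("BSA", "BW")) {
      col <- sprintf("pct_within_%gx_%s", kk, tolower(m))
      sel <- in_group & rows$method == m
      res[[col]] <- if (m %in% g$methods && any(sel))
        pct_within(rows$fold_error[sel], kk) else NA_real_
    }
    out[[length(out) + 1L]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no non-empty groups to summarize", call. = FALSE)
  do.call(rbind, out)
}

#' Bootstrap confidence interval for a within-fold percentage
#'
#' Percentile 95% interval of [pct_within()] over resamples of the rows with
#' replacement. This interval is an addition beyond the published point
#' percentages and is labelled as such in report output.
#'
#' @param x evaluation rows or fold-error vector (see [pct_within()]).
#' @param k fold threshold.
#' @param n_boot number of resamples, `>= 100`.
#' @param seed RNG seed for reproducibility.
#' @param conf confidence level.
#' @return Named numeric `c(low, high)` in percentage points.
#' @export
bootstrap_ci <- function(x, k, n_boot = 1000, seed = 1, conf = 0.95) {
  fe <- if (is.data.frame(x)) x$fold_error else x
  if (length(fe) == 0L) stop("empty row set", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(i) {
    pct_within(fe[sample.int(length(fe), replace = TRUE)], k)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Export predicted-vs-clinical scatter data
#'
#' Writes the (predicted, clinical) dose pairs underlying the log-log scatter
#' to CSV, and optionally draws the figure (log-log axes, identity line, and
#' solid lines at plus and minus 3-fold from precise prediction) to a PNG.
#' Rows whose doses cannot be log-plotted (nonpositive) are excluded with a
#' warning.
#'
#' @param rows evaluation rows ([evaluate_records()]).
#' @param csv_path output CSV path.
#' @param png_path optional output PNG path; `NULL` skips the figure.
#' @param fold_band reference band in folds (default 3).
#' @return Invisibly, the exported data frame.
#' @export
export_scatter <- function(rows, csv_path, png_path = NULL, fold_band = 3) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  ok <- rows$predicted_dose > 0 & rows$clinical_dose > 0
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with nonpositive dose excluded from scatter",
            call. = FALSE)
  }
  rows <- rows[ok, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no plottable rows after exclusions", call. = FALSE)
  out <- rows[, c("drug_name", "modality_class", "method",
                  "predicted_dose", "clinical_dose", "fold_error")]
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 900, res = 130)
    on.exit(grDevices::dev.off(), add = TRUE)
    .plot_scatter(rows, fold_band = fold_band)
  }
  invisible(out)
}

.plot_scatter <- function(rows, fold_band = 3,
                          main = "Predicted vs recommended clinical dose") {
  rng <- range(c(rows$predicted_dose, rows$clinical_dose))
  lim <- c(rng[1] / fold_band, rng[2] * fold_band)
  graphics::plot(rows$predicted_dose, rows$clinical_dose, log = "xy",
                 xlim = lim, ylim = lim,
                 xlab = "Predicted human dose (mg/kg)",
                 ylab = "Recommended clinical dose (mg/kg)",
                 pch = 19, col = "#00000088", main = main)
  xs <- exp(seq(log(lim[1]), log(lim[2]), length.out = 200))
  graphics::lines(xs, xs, lty = 2)
  graphics::lines(xs, xs * fold_band, lty = 1)
  graphics::lines(xs, xs / fold_band, lty = 1)
  invisible(NULL)
}
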