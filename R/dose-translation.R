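## The fitted-object interface: dose_translation() runs the whole
## retrospective analysis on a record table and returns a classed object with
## the usual modelling verbs.

#' Fit the dose-translation analysis to a drug-record table
#'
#' Runs the retrospective dose-translation analysis end to end: validates the
#' records, partitions out curation exclusions (MTD-only efficacy, syngeneic
#' models), evaluates every retained drug under both the BSA route and the
#' direct body-weight route, selects a per-drug prediction according to
#' `method`, and fits the log10-normal fold-deviation model
#' `log10(clinical/predicted) ~ Normal(mu, sigma)` to each route. The object
#' supports `print`, `summary` (class-level within-2x/3x table), `coef`
#' (fitted mu/sigma per route), `residuals` (log10 fold deviations),
#' `predict` (predicted human doses for new records), `plot` (log-log scatter
#' with the 3-fold band) and `simulate` (synthetic cohorts from the fitted
#' error model).
#'
#' @param records drug-record data frame in the [drug_record_columns()]
#'   schema, or a path to such a CSV.
#' @param method prediction route used for the headline per-drug evaluation:
#'   `"bsa"`, `"bw"`, or `"auto"` (per-drug selection on the 100 kDa
#'   molecular-weight rule).
#' @param grouping class grouping for [summary()]; default [table1_grouping()].
#' @param exclude apply the curation exclusions before evaluating (default).
#' @return An object of class `dose_translation`.
#' @examples
#' m <- calibrate_error_model(0.633, 0.856)
#' rec <- simulate_drug_records(30, m, seed = 42)
#' fit <- dose_translation(rec, method = "bsa")
#' print(fit)
#' coef(fit)
#' @export
dose_translation <- function(records, method = c("auto", "bsa", "bw"),
                             grouping = table1_grouping(), exclude = TRUE) {
  method <- match.arg(method)
  cl <- match.call()
  if (is.character(records) && length(records) == 1L) {
    records <- read_drug_records(records)
  }
  validate_drug_records(records)
  part <- if (exclude) apply_exclusions(records)
          else list(kept = records,
                    excluded = cbind(records[0, , drop = FALSE],
                                     exclusion_reason = character(0)))
  kept <- part$kept
  if (nrow(kept) == 0L) stop("no records left after exclusions", call. = FALSE)

  rows_bsa <- evaluate_records(kept, "bsa")
  rows_bw <- evaluate_records(kept, "bw")
  selected <- switch(method,
    bsa = rows_bsa,
    bw = rows_bw,
    auto = evaluate_records(kept, "auto"))

  fits <- list(
    bsa = if (nrow(rows_bsa) >= 2) fit_error_model(rows_bsa) else NULL,
    bw = if (nrow(rows_bw) >= 2) fit_error_model(rows_bw) else NULL
  )

  structure(
    list(call = cl, method = method, records = kept, excluded = part$excluded,
         rows = rbind(rows_bsa, rows_bw), selected = selected,
         fits = fits, grouping = grouping),
    class = "dose_translation"
  )
}

#' @export
print.dose_translation <- function(x, ...) {
  cat("Preclinical-to-clinical dose translation\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  drugs analyzed: %d (excluded by curation flags: %d)\n",
              nrow(x$records), nrow(x$excluded)))
  cat(sprintf("  prediction route: %s\n", x$method))
  cat(sprintf("  within 2x: %.1f%%   within 3x: %.1f%%\n",
              format_pct(pct_within(x$selected, 2)),
              format_pct(pct_within(x$selected, 3))))
  invisible(x)
}

#' @rdname dose_translation
#' @param object,x a `dose_translation` fit.
#' @param ... unused.
#' @export
summary.dose_translation <- function(object, ...) {
  tab <- withCallingHandlers(
    summarize_translation(object$rows, object$grouping),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(table = tab, method = object$method,
         n = nrow(object$records), n_excluded = nrow(object$excluded),
         overall = c(within_2x = pct_within(object$selected, 2),
                     within_3x = pct_within(object$selected, 3)),
         coef = stats::coef(object)),
    class = "summary.dose_translation"
  )
}

#' @export
print.summary.dose_translation <- function(x, ...) {
  cat(sprintf("Dose translation: %d drugs (%d excluded), route = %s\n",
              x$n, x$n_excluded, x$method))
  cat(sprintf("Overall: %.1f%% within 2x, %.1f%% within 3x\n\n",
              format_pct(x$overall["within_2x"]),
              format_pct(x$overall["within_3x"])))
  disp <- x$table
  pct_cols <- grep("^pct_", names(disp))
  disp[pct_cols] <- lapply(disp[pct_cols], format_pct)
  print(disp, row.names = FALSE)
  cat("\nFitted log10 fold-deviation model (per route):\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @rdname dose_translation
#' @export
coef.dose_translation <- function(object, ...) {
  out <- sapply(object$fits, function(f) {
    if (is.null(f)) c(mu = NA_real_, sigma = NA_real_)
    else c(mu = f$mu, sigma = f$sigma)
  })
  colnames(out) <- toupper(colnames(out))
  out
}

#' @rdname dose_translation
#' @param route which prediction route's rows to use; defaults to the fit's
#'   headline route (`"selected"`).
#' @export
residuals.dose_translation <- function(object,
                                       route = c("selected", "bsa", "bw"), ...) {
  route <- match.arg(route)
  rows <- switch(route,
    selected = object$selected,
    bsa = object$rows[object$rows$method == "BSA", , drop = FALSE],
    bw = object$rows[object$rows$method == "BW", , drop = FALSE])
  stats::setNames(log10(rows$clinical_dose / rows$predicted_dose),
                  rows$drug_name)
}

#' @rdname dose_translation
#' @param newdata drug-record data frame to predict for.
#' @export
predict.dose_translation <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::setNames(object$selected$predicted_dose,
                                               object$selected$drug_name))
  rows <- evaluate_records(newdata, object$method)
  stats::setNames(rows$predicted_dose, rows$drug_name)
}

#' @rdname dose_translation
#' @export
plot.dose_translation <- function(x, route = c("selected", "bsa", "bw"), ...) {
  route <- match.arg(route)
  rows <- switch(route,
    selected = x$selected,
    bsa = x$rows[x$rows$method == "BSA", , drop = FALSE],
    bw = x$rows[x$rows$method == "BW", , drop = FALSE])
  .plot_scatter(rows, main = sprintf(
    "Predicted (%s) vs recommended clinical dose", route))
  invisible(x)
}

#' @rdname dose_translation
#' @param nsim number of synthetic cohorts to generate.
#' @param seed RNG seed.
#' @param n cohort size; defaults to the fitted cohort's size.
#' @export
simulate.dose_translation <- function(object, nsim = 1, seed = NULL,
                                      route = c("bsa", "bw"), n = NULL, ...) {
  route <- match.arg(route)
  fit <- object$fits[[route]]
  if (is.null(fit)) stop("no fitted error model for route '", route, "'",
                         call. = FALSE)
  if (is.null(n)) n <- nrow(object$records)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i) {
    simulate_drug_records(n, fit, method = route,
                          name_prefix = sprintf("sim%02d", i))
  })
  if (nsim == 1L) out[[1]] else out
}
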