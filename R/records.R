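## Drug-record schema, validation, CSV I/O, and the computable curation rules.
## One row per drug (one indication per drug per analysis set); doses are plain
## decimals with a separate unit column.

.modality_classes <- c("SM_IV", "SM_PO", "SM_IO_HT", "mAb", "ADC",
                       "checkpoint", "bispecific")
.large_molecule_classes <- c("mAb", "ADC", "checkpoint", "bispecific")
.routes <- c("IV", "PO", "SC", "IP", "other")
.response_metrics <- c("TGI_percent", "T_over_C", "survival", "regression", "stasis")
.curation_flags <- c("mtd_only", "syngeneic_model", "combination_mismatch",
                     "cns_mismatch", "heme_to_solid_mismatch")
.excluding_flags <- c("mtd_only", "syngeneic_model")

#' Drug-record CSV schema
#'
#' Column names of the curated drug-record table, mirroring a
#' supplemental-table layout: identity and class, the mouse xenograft dose
#' with unit/species/route/schedule and efficacy readout, the recommended
#' clinical dose (possibly a range) with unit and route, indication, curation
#' flags (semicolon-separated) and the literature reference. `flags` carries
#' the curation judgments that are made while reading the literature and are
#' recorded rather than recomputed (MTD-only efficacy, syngeneic model,
#' regimen/CNS/heme-to-solid mismatches).
#'
#' @return Character vector of mandatory-first column names.
#' @export
drug_record_columns <- function() {
  c("drug_name", "modality_class", "molecular_weight_kda",
    "nonclin_dose_value", "nonclin_dose_unit", "nonclin_n_admin_day1",
    "nonclin_species", "nonclin_route", "nonclin_model",
    "nonclin_response_metric", "nonclin_response_value",
    "clin_dose_low", "clin_dose_high", "clin_dose_unit", "clin_route",
    "indication", "flags", "reference")
}

.mandatory_columns <- c("drug_name", "modality_class", "nonclin_dose_value",
                        "nonclin_dose_unit", "nonclin_species",
                        "clin_dose_low", "clin_dose_unit")

.parse_flags <- function(flags) {
  lapply(flags, function(f) {
    if (is.na(f) || !nzchar(trimws(f))) return(character(0))
    trimws(strsplit(f, ";", fixed = TRUE)[[1]])
  })
}

#' Validate a drug-record table
#'
#' Checks a record table against the schema invariants: known modality class,
#' parseable nonnegative doses and units, molecular weight present for
#' large-molecule classes (mAb, ADC, checkpoint, bispecific), clinical range
#' ordered low <= high after unit normalization, known curation flags, and one
#' row per drug. Issues name the offending row and column.
#'
#' @param records data frame in the [drug_record_columns()] schema.
#' @param stop_on_error raise an error if any issue of severity `"error"` is
#'   found (default); otherwise return the issue table.
#' @return Data frame of issues (`row`, `column`, `severity`, `message`),
#'   zero rows when the table is clean, invisibly when `stop_on_error`.
#' @export
validate_drug_records <- function(records, stop_on_error = TRUE) {
  stopifnot(is.data.frame(records))
  issues <- list()
  add <- function(row, column, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, column = column, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }

  missing_cols <- setdiff(.mandatory_columns, names(records))
  for (col in missing_cols) add(NA_integer_, col, "error", "mandatory column missing")
  if (length(missing_cols) == 0L) {
    n <- nrow(records)
    mw <- if ("molecular_weight_kda" %in% names(records))
      suppressWarnings(as.numeric(records$molecular_weight_kda)) else rep(NA_real_, n)
    n_admin <- if ("nonclin_n_admin_day1" %in% names(records))
      suppressWarnings(as.numeric(records$nonclin_n_admin_day1)) else rep(1, n)
    for (i in seq_len(n)) {
      cls <- records$modality_class[i]
      if (!cls %in% .modality_classes) {
        add(i, "modality_class", "error",
            paste0("unknown modality_class '", cls, "'"))
      } else if (cls %in% .large_molecule_classes && !is.finite(mw[i])) {
        add(i, "molecular_weight_kda", "error",
            "molecular weight (kDa) required for large-molecule classes")
      }
      nd <- suppressWarnings(as.numeric(records$nonclin_dose_value[i]))
      if (!is.finite(nd) || nd < 0) {
        add(i, "nonclin_dose_value", "error", "unparseable or negative dose value")
      }
      if (!records$nonclin_dose_unit[i] %in% .dose_units) {
        add(i, "nonclin_dose_unit", "error",
            paste0("unknown unit '", records$nonclin_dose_unit[i], "'"))
      }
      if (is.finite(n_admin[i]) && (n_admin[i] < 1 || n_admin[i] != round(n_admin[i]))) {
        add(i, "nonclin_n_admin_day1", "error",
            "number of Day-1 administrations must be a positive integer")
      }
      sp <- tolower(trimws(records$nonclin_species[i]))
      if (!sp %in% list_species()) {
        add(i, "nonclin_species", "error", paste0("unknown species '", sp, "'"))
      }
      lo <- suppressWarnings(as.numeric(records$clin_dose_low[i]))
      if (!is.finite(lo) || lo < 0) {
        add(i, "clin_dose_low", "error", "missing, unparseable or negative clinical dose")
      }
      if (!records$clin_dose_unit[i] %in% .dose_units) {
        add(i, "clin_dose_unit", "error",
            paste0("unknown unit '", records$clin_dose_unit[i], "'"))
      }
      if ("clin_dose_high" %in% names(records)) {
        hi <- suppressWarnings(as.numeric(records$clin_dose_high[i]))
        if (is.finite(hi) && is.finite(lo) && hi < lo) {
          add(i, "clin_dose_high", "error", "clinical range has high < low")
        }
      }
      if ("flags" %in% names(records)) {
        fl <- .parse_flags(records$flags[i])[[1]]
        unknown <- setdiff(fl, .curation_flags)
        if (length(unknown)) {
          add(i, "flags", "error",
              paste0("unknown curation flag(s): ", paste(unknown, collapse = ", ")))
        }
      }
      if ("nonclin_response_metric" %in% names(records)) {
        m <- records$nonclin_response_metric[i]
        if (!is.na(m) && nzchar(m) && !m %in% .response_metrics) {
          add(i, "nonclin_response_metric", "error",
              paste0("unknown response metric '", m, "'"))
        }
        v <- if ("nonclin_response_value" %in% names(records))
          suppressWarnings(as.numeric(records$nonclin_response_value[i])) else NA_real_
        if (!is.na(m) && identical(m, "TGI_percent") && is.finite(v) &&
            (v < 0 || v > 100)) {
          add(i, "nonclin_response_value", "warning",
              "TGI outside [0, 100] (regressions are sometimes reported as >100% TGI)")
        }
      }
    }
    dup <- records$drug_name[duplicated(records$drug_name)]
    for (d in unique(dup)) {
      add(which(records$drug_name == d)[2], "drug_name", "error",
          "duplicate drug: one indication per drug per analysis set")
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(0), column = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  if (stop_on_error && any(issues$severity == "error")) {
    err <- issues[issues$severity == "error", , drop = FALSE]
    stop("invalid drug records:\n",
         paste(sprintf("  row %s, %s: %s", err$row, err$column, err$message),
               collapse = "\n"), call. = FALSE)
  }
  if (stop_on_error) invisible(issues) else issues
}

#' Read and write drug-record tables
#'
#' `read_drug_records()` loads a CSV in the [drug_record_columns()] schema,
#' coerces the numeric columns, validates every row (load fails naming the
#' offending row and column) and returns the table. Unknown columns are
#' preserved untouched. `write_drug_records()` writes the table back; the two
#' are round-trip stable. Lines starting with `#` are treated as comments.
#'
#' @param path CSV file path.
#' @param records validated record data frame.
#' @return `read_drug_records()`: the record data frame;
#'   `write_drug_records()`: `path`, invisibly.
#' @export
read_drug_records <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(.mandatory_columns, names(df))
  if (length(missing_cols)) {
    stop("drug-record CSV ", path, ": missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("molecular_weight_kda", "nonclin_dose_value",
                          "nonclin_n_admin_day1", "nonclin_response_value",
                          "clin_dose_low", "clin_dose_high"), names(df))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (!"nonclin_n_admin_day1" %in% names(df)) df$nonclin_n_admin_day1 <- 1
  df$nonclin_n_admin_day1[is.na(df$nonclin_n_admin_day1)] <- 1
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  validate_drug_records(df)
  df
}

#' @rdname read_drug_records
#' @export
write_drug_records <- function(records, path) {
  validate_drug_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Recommended clinical dose in mg/kg
#'
#' Reduces a recommended clinical dose, possibly given as a range, to one
#' mg/kg number: each endpoint is normalized to mg/kg first (absolute mg
#' divided by the 70 kg default human body weight, mg/m^2 divided by the
#' human BSA factor 37) and a range is collapsed to the arithmetic mean of
#' the normalized endpoints. The result is invariant to the order of the
#' endpoints.
#'
#' @param low lower (or only) dose value; vectorized.
#' @param high upper dose value, `NA` when the label gives a single dose.
#' @param unit unit of `low` (and of `high` unless `unit_high` is given).
#' @param unit_high unit of `high` when the endpoints use different units.
#' @param species species of the recipient; `"human"` for clinical labels.
#' @return Dose(s) in mg/kg.
#' @examples
#' recommended_clinical_dose(100, 200, unit = "mg")  # mean(100, 200)/70
#' recommended_clinical_dose(5)                      # 5
#' @export
recommended_clinical_dose <- function(low, high = NA, unit = "mg_per_kg",
                                      unit_high = unit, species = "human") {
  if (length(low) == 0L || all(is.na(low))) {
    stop("clinical dose missing: at least the low endpoint is required", call. = FALSE)
  }
  if (anyNA(low)) {
    stop("clinical dose missing for ", sum(is.na(low)), " record(s)", call. = FALSE)
  }
  n <- length(low)
  high <- rep_len(high, n)
  unit <- rep_len(unit, n)
  unit_high <- rep_len(unit_high, n)
  lo <- normalize_to_mgkg(low, unit, species)
  out <- lo
  has_hi <- !is.na(high)
  if (any(has_hi)) {
    hi <- normalize_to_mgkg(high[has_hi], unit_high[has_hi], species)
    out[has_hi] <- (lo[has_hi] + hi) / 2
  }
  out
}

#' Is a reported xenograft response efficacious?
#'
#' Applies the efficacy floor used in curation: tumor stasis or regression
#' always qualifies; percent tumor growth inhibition qualifies at >= 60
#' (boundary inclusive); TGI below 60 does not; other metrics (T/C, survival)
#' qualify only when the curator recorded that the reference authors declared
#' the response significant. TGI values outside [0, 100] trigger a warning,
#' not rejection, since regressions are sometimes reported as >100% TGI.
#'
#' @param metric response metric; one of `TGI_percent`, `T_over_C`,
#'   `survival`, `regression`, `stasis`. Vectorized.
#' @param value numeric readout (used for `TGI_percent`).
#' @param author_significant logical; curator-recorded author-declared
#'   significance, used for metrics without a numeric threshold.
#' @return Logical vector.
#' @examples
#' is_efficacious_response("TGI_percent", 60)    # TRUE (inclusive boundary)
#' is_efficacious_response("TGI_percent", 59.9)  # FALSE
#' is_efficacious_response("stasis")             # TRUE
#' @export
is_efficacious_response <- function(metric, value = NA_real_,
                                    author_significant = FALSE) {
  n <- max(length(metric), length(value))
  metric <- rep_len(as.character(metric), n)
  value <- rep_len(as.numeric(value), n)
  author_significant <- rep_len(as.logical(author_significant), n)
  bad <- !metric %in% .response_metrics
  if (any(bad)) {
    stop("unknown response metric '", metric[which(bad)[1]], "'", call. = FALSE)
  }
  tgi <- metric == "TGI_percent"
  if (any(tgi & is.finite(value) & (value < 0 | value > 100))) {
    warning("TGI value outside [0, 100]; accepted (regressions can exceed 100% TGI)",
            call. = FALSE)
  }
  if (any(tgi & !is.finite(value))) {
    stop("TGI_percent response requires a numeric value", call. = FALSE)
  }
  ifelse(metric %in% c("regression", "stasis"), TRUE,
         ifelse(tgi, value >= 60, author_significant))
}

#' Partition records into analyzed and excluded sets
#'
#' Records flagged `mtd_only` (efficacy observed only at a maximum tolerated
#' dose, where the response may be saturated) or `syngeneic_model` (mouse
#' tumor in a mouse, excluded for potential human-vs-mouse disconnects) are
#' moved to the excluded set with the triggering flag as the reason. All
#' other curation flags are annotations and do not exclude. The partition is
#' exhaustive and disjoint and no retained record is modified.
#'
#' @param records validated drug-record data frame.
#' @return List with elements `kept` (record data frame) and `excluded`
#'   (record data frame with an extra `exclusion_reason` column).
#' @export
apply_exclusions <- function(records) {
  stopifnot(is.data.frame(records))
  flags <- .parse_flags(if ("flags" %in% names(records)) records$flags
                        else rep("", nrow(records)))
  reason <- vapply(flags, function(f) {
    hit <- intersect(.excluding_flags, f)
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}
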