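## Unit-safe interspecies dose conversion. All internal arithmetic uses mg/kg
## as the canonical unit; mg/m2 and absolute mg are converted at the boundary.

.check_nonneg_dose <- function(dose, what = "dose") {
  if (!is.numeric(dose) || anyNA(dose)) {
    stop(what, " must be numeric and non-missing", call. = FALSE)
  }
  if (any(dose < 0)) {
    stop(what, " must be >= 0 (got ", min(dose), ")", call. = FALSE)
  }
  invisible(dose)
}

#' Convert a dose from mg/kg to mg/m^2
#'
#' Multiplies a weight-normalized dose by the species BSA factor
#' (mouse dose in mg/kg x 3 = mouse dose in mg/m^2).
#'
#' @param dose dose in mg/kg; nonnegative, vectorized.
#' @param species species name or [species_profile()].
#' @return Dose in mg/m^2.
#' @examples
#' mgkg_to_mgm2(1, "mouse")  # 3
#' @export
mgkg_to_mgm2 <- function(dose, species) {
  .check_nonneg_dose(dose)
  dose * species_profile(species)$bsa_factor
}

#' Convert a dose from mg/m^2 to mg/kg
#'
#' Divides a surface-area-normalized dose by the species BSA factor
#' (dose in mg/m^2 / 37 = human dose in mg/kg).
#'
#' @inheritParams mgkg_to_mgm2
#' @param dose dose in mg/m^2; nonnegative, vectorized.
#' @return Dose in mg/kg.
#' @examples
#' mgm2_to_mgkg(37, "human")  # 1
#' @export
mgm2_to_mgkg <- function(dose, species) {
  .check_nonneg_dose(dose)
  dose / species_profile(species)$bsa_factor
}

#' Predict a human dose from a mouse efficacious dose
#'
#' `bsa_predict_human_dose()` is the body-surface-area route: the mouse mg/kg
#' dose is converted to mg/m^2 (x3) and back to human mg/kg (/37), i.e.
#' multiplied by 3/37. `bw_predict_human_dose()` is the direct body-weight
#' route recommended for large proteins: the mg/kg dose carries over
#' unchanged (2 mg/kg in mouse = 2 mg/kg in human).
#'
#' @param mouse_dose,animal_dose dose in mg/kg; nonnegative, vectorized.
#' @return Predicted human dose in mg/kg.
#' @examples
#' bsa_predict_human_dose(37)  # 3
#' bw_predict_human_dose(2)    # 2
#' @export
bsa_predict_human_dose <- function(mouse_dose) {
  mgm2_to_mgkg(mgkg_to_mgm2(mouse_dose, "mouse"), "human")
}

#' @rdname bsa_predict_human_dose
#' @export
bw_predict_human_dose <- function(animal_dose) {
  .check_nonneg_dose(animal_dose)
  animal_dose
}

.dose_units <- c("mg_per_kg", "mg", "mg_per_m2")

#' Normalize a dose to mg/kg
#'
#' Converts a dose expressed in any supported unit to the canonical mg/kg
#' basis for its species: mg/kg passes through, absolute mg divides by the
#' species default body weight (70 kg for human, 25 g for mouse), and mg/m^2
#' divides by the species BSA factor.
#'
#' @param amount dose value(s); nonnegative.
#' @param unit one of `"mg_per_kg"`, `"mg"`, `"mg_per_m2"`; recycled against
#'   `amount`.
#' @param species species name(s) or a single [species_profile()]; recycled.
#' @return Dose(s) in mg/kg.
#' @examples
#' normalize_to_mgkg(140, "mg", "human")        # 2
#' normalize_to_mgkg(0.5, "mg", "mouse")        # 20
#' normalize_to_mgkg(74, "mg_per_m2", "human")  # 2
#' @export
normalize_to_mgkg <- function(amount, unit = "mg_per_kg", species = "mouse") {
  .check_nonneg_dose(amount)
  n <- length(amount)
  unit <- rep_len(as.character(unit), n)
  bad <- !(unit %in% .dose_units)
  if (any(bad)) {
    stop("unknown dose unit '", unit[which(bad)[1]], "'; expected one of ",
         paste(.dose_units, collapse = ", "), call. = FALSE)
  }
  if (inherits(species, "species_profile")) {
    profs <- rep(list(species), n)
  } else {
    profs <- lapply(rep_len(as.character(species), n), species_profile)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- switch(unit[i],
      mg_per_kg = amount[i],
      mg        = amount[i] / profs[[i]]$default_body_weight_kg,
      mg_per_m2 = amount[i] / profs[[i]]$bsa_factor
    )
  }
  out
}

#' Construct a dose specification
#'
#' A `dose_spec` bundles a dose with its unit basis, species, route, and the
#' per-administration amounts given within the first 24 h of dosing, so that
#' it can be reduced to a Day-1 total in mg/kg (intermittent-schedule
#' differences beyond Day 1 are deliberately not modelled).
#'
#' @param amount per-administration dose value; nonnegative.
#' @param unit dose unit basis (`"mg_per_kg"`, `"mg"`, `"mg_per_m2"`).
#' @param species species name or profile.
#' @param route route of administration; one of IV, PO, SC, IP, other.
#' @param administrations_day1 numeric vector of per-administration amounts
#'   within the first 24 h; defaults to a single administration of `amount`.
#' @return An object of class `dose_spec`.
#' @examples
#' d <- dose_spec(5, "mg_per_kg", "mouse", administrations_day1 = c(5, 5))
#' day1_total(d)  # 10
#' @export
dose_spec <- function(amount, unit = "mg_per_kg", species = "mouse",
                      route = c("IV", "PO", "SC", "IP", "other"),
                      administrations_day1 = amount) {
  route <- match.arg(route)
  .check_nonneg_dose(amount, "amount")
  stopifnot(length(amount) == 1L)
  .check_nonneg_dose(administrations_day1, "administrations_day1")
  if (length(administrations_day1) == 0L) {
    stop("administrations_day1 must be non-empty", call. = FALSE)
  }
  unit <- match.arg(unit, .dose_units)
  structure(
    list(amount = amount, unit = unit,
         species = species_profile(species)$species_name,
         route = route, administrations_day1 = administrations_day1),
    class = "dose_spec"
  )
}

#' Total Day-1 dose in mg/kg
#'
#' Sums the administrations given within the first 24 h of dosing, each
#' normalized to mg/kg. A dose given once every 4 days still counts only its
#' single Day-1 administration: intermittent-schedule differences are not
#' factored in.
#'
#' @param dose a [dose_spec()].
#' @return Total Day-1 dose in mg/kg.
#' @export
day1_total <- function(dose) {
  stopifnot(inherits(dose, "dose_spec"))
  sum(normalize_to_mgkg(dose$administrations_day1, dose$unit, dose$species))
}

#' @export
print.dose_spec <- function(x, ...) {
  cat(sprintf("Dose: %g %s (%s, %s); Day-1 administrations: %s => %g mg/kg total\n",
              x$amount, x$unit, x$species, x$route,
              paste(x$administrations_day1, collapse = " + "), day1_total(x)))
  invisible(x)
}

#' Choose the prediction method from molecular weight
#'
#' Implements the molecular-weight rule for intravascular proteins: above
#' 100 kDa the direct body-weight (mg/kg) carryover is used, at or below
#' 100 kDa the BSA conversion is used. The boundary is a strict inequality,
#' so exactly 100 kDa selects BSA; blinatumomab at 54.1 kDa falls on the BSA
#' side.
#'
#' @param molecular_weight molecular weight in kDa; positive, vectorized.
#' @return Character vector of `"BSA"` or `"BW"`.
#' @examples
#' select_method(54.1)  # "BSA"
#' select_method(150)   # "BW"
#' @export
select_method <- function(molecular_weight) {
  if (!is.numeric(molecular_weight) || anyNA(molecular_weight)) {
    stop("molecular_weight must be numeric and non-missing", call. = FALSE)
  }
  if (any(molecular_weight <= 0)) {
    stop("molecular_weight must be > 0 kDa", call. = FALSE)
  }
  ifelse(molecular_weight > 100, "BW", "BSA")
}

#' Maximum recommended starting dose from a human equivalent dose
#'
#' Divides a human equivalent dose by a safety factor (10 by default, the
#' factor used to bring a BSA-converted dose into a likely-safe range). This
#' is a labelled convenience for starting-dose context; it plays no part in
#' the efficacy-prediction analysis.
#'
#' @param hed human equivalent dose in mg/kg; nonnegative.
#' @param safety_factor dimensionless divisor, `>= 1`.
#' @return Starting dose in mg/kg.
#' @examples
#' mrsd_from_hed(3)  # 0.3
#' @export
mrsd_from_hed <- function(hed, safety_factor = 10) {
  .check_nonneg_dose(hed, "hed")
  if (!is.numeric(safety_factor) || length(safety_factor) != 1L ||
      is.na(safety_factor) || safety_factor < 1) {
    stop("safety_factor must be a single number >= 1", call. = FALSE)
  }
  hed / safety_factor
}
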