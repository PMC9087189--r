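# Builders for valid in-memory drug-record tables.

make_record <- function(drug_name = "drug-1", modality_class = "SM_PO",
                        molecular_weight_kda = 0.5,
                        nonclin_dose_value = 10, nonclin_dose_unit = "mg_per_kg",
                        nonclin_n_admin_day1 = 1, nonclin_species = "mouse",
                        nonclin_route = "PO", nonclin_model = "xenograft",
                        nonclin_response_metric = "TGI_percent",
                        nonclin_response_value = 75,
                        clin_dose_low = 1, clin_dose_high = NA_real_,
                        clin_dose_unit = "mg_per_kg", clin_route = "PO",
                        indication = "solid tumor", flags = "",
                        reference = "test") {
  data.frame(drug_name = drug_name, modality_class = modality_class,
             molecular_weight_kda = molecular_weight_kda,
             nonclin_dose_value = nonclin_dose_value,
             nonclin_dose_unit = nonclin_dose_unit,
             nonclin_n_admin_day1 = nonclin_n_admin_day1,
             nonclin_species = nonclin_species, nonclin_route = nonclin_route,
             nonclin_model = nonclin_model,
             nonclin_response_metric = nonclin_response_metric,
             nonclin_response_value = nonclin_response_value,
             clin_dose_low = clin_dose_low, clin_dose_high = clin_dose_high,
             clin_dose_unit = clin_dose_unit, clin_route = clin_route,
             indication = indication, flags = flags, reference = reference,
             stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, rows)
  if (any(duplicated(df$drug_name))) {
    df$drug_name <- make.unique(df$drug_name, sep = "-")
  }
  df
}

# A record engineered to a chosen BSA fold error: with mouse dose d the BSA
# prediction is d*3/37, so a clinical dose of (d*3/37)/fold over-predicts by
# exactly `fold`.
record_with_bsa_fold <- function(fold, mouse_dose = 10, drug_name = "eng",
                                 modality_class = "SM_PO") {
  make_record(drug_name = drug_name, modality_class = modality_class,
              nonclin_dose_value = mouse_dose,
              clin_dose_low = (mouse_dose * 3 / 37) / fold)
}

fixture_csv <- function() {
  system.file("extdata", "synthetic_oncology_records.csv",
              package = "dosetrans", mustWork = TRUE)
}
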