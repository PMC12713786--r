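# Shared fixture builders. Everything is generated in code; no stored data.

# One valid toxicity row with overridable fields.
tox_row <- function(entry_id = "e001", study_id = "s01",
                    species_label = "Eisenia fetida",
                    taxon_group = "invertebrate",
                    endpoint_name = "reproduction", endpoint_category = "B",
                    descriptor_kind = "NOEC", noec_value = 100,
                    loec_value = 500, honec_value = NA_real_,
                    exposure_days = 56,
                    concentration_unit = "nb_per_kg_dw",
                    particle_shape = NA_character_,
                    particle_diameter_um = NA_real_,
                    particle_length_um = NA_real_,
                    particle_thickness_um = NA_real_,
                    particle_density_g_cm3 = NA_real_,
                    particle_polymer = NA_character_,
                    particle_size_basis = NA_character_) {
  data.frame(entry_id = entry_id, study_id = study_id,
             species_label = species_label, taxon_group = taxon_group,
             endpoint_name = endpoint_name,
             endpoint_category = endpoint_category,
             descriptor_kind = descriptor_kind, noec_value = noec_value,
             loec_value = loec_value, honec_value = honec_value,
             exposure_days = exposure_days,
             concentration_unit = concentration_unit,
             particle_shape = particle_shape,
             particle_diameter_um = particle_diameter_um,
             particle_length_um = particle_length_um,
             particle_thickness_um = particle_thickness_um,
             particle_density_g_cm3 = particle_density_g_cm3,
             particle_polymer = particle_polymer,
             particle_size_basis = particle_size_basis,
             stringsAsFactors = FALSE)
}

write_tox_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write_toxicity_table(df, path)
  path
}

write_exp_csv <- function(conc, path = tempfile(fileext = ".csv"),
                          study_id = NULL, site_id = NULL) {
  n <- length(conc)
  df <- data.frame(sample_id = sprintf("x%03d", seq_len(n)),
                   study_id = study_id %||% sprintf("st%02d", seq_len(n)),
                   site_id = site_id %||% sprintf("site%03d", seq_len(n)),
                   concentration_nb_per_kg_dw = conc)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Single-row bootstrap ensemble from fixed parameters (collapses the
# uncertainty dimension for oracle comparisons).
fixed_ensemble <- function(family, params) {
  structure(list(family = family,
                 param_draws = matrix(params, nrow = 1,
                                      dimnames = list(NULL, names(params))),
                 B = 1L, n = NA_integer_, n_refit_failures = 0L),
            class = "mp_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
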