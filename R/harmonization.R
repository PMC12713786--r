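#' Descriptor classification
#'
#' Classifies a toxicity entry's raw descriptor into one of four precision
#' classes used to assign the descriptor uncertainty factor:
#'
#' * `NOEC_a`: NOEC with a tight bracketing LOEC (LOEC/NOEC ratio < 10) —
#'   the precise case from dense dose-response designs.
#' * `NOEC_b`: NOEC with a loose bracket (ratio >= 10), a NOEC with no LOEC
#'   reported, or a HONEC-only study (no effect at any tested
#'   concentration; the value is right-censored).
#' * `LOEC_a`: LOEC with a NOEC at ratio < 10 (only relevant when the NOEC
#'   is deliberately ignored — whenever a NOEC exists it is preferred).
#' * `LOEC_b`: LOEC with no usable NOEC (censored somewhere to the left).
#'
#' @param entry one toxicity entry (list or one-row data.frame with the
#'   toxicity schema fields).
#' @return list with `label`, `selected_value` (in the entry's unit) and
#'   `censoring` (`"none"`, `"right"`, `"left"`).
#' @export
classify_descriptor <- function(entry) {
  entry <- as.list(entry)
  noec <- entry$noec_value %||% NA_real_
  loec <- entry$loec_value %||% NA_real_
  honec <- entry$honec_value %||% NA_real_
  if (all(is.na(c(noec, loec, honec)))) {
    stop_mp("entry '%s': no descriptor value present",
            entry$entry_id %||% "?", class = "mp_validation_error")
  }
  if (!is.na(noec)) {
    if (!is.na(loec)) {
      if (loec <= noec) stop_mp("entry '%s': NOEC must be < LOEC",
                                entry$entry_id %||% "?",
                                class = "mp_validation_error")
      ratio <- loec / noec
      label <- if (ratio < 10) "NOEC_a" else "NOEC_b"
    } else {
      # NOEC reported without a bracketing LOEC: precision unknowable, treat
      # as the loose class.
      label <- "NOEC_b"
    }
    return(list(label = label, selected_value = noec, censoring = "none"))
  }
  if (!is.na(honec)) {
    # No effect at any tested concentration: true threshold lies to the
    # right of the highest tested concentration.
    return(list(label = "NOEC_b", selected_value = honec, censoring = "right"))
  }
  # LOEC only: the unobserved NOEC lies somewhere to the left.
  list(label = "LOEC_b", selected_value = loec, censoring = "left")
}

#' Resolve endpoint ties within a study x species x particle group
#'
#' When one study reports several endpoints for the same species and
#' particle, a single governing descriptor is retained. NOEC-bearing entries
#' (NOEC or HONEC) are preferred over LOEC-only entries. The governing value
#' is the minimum across endpoints; on exact value ties, a NOEC keeps the
#' *least* severe endpoint category (A < B < C, avoiding an overly
#' conservative category factor, since "no effect" on a mild endpoint at a
#' concentration that also leaves survival untouched is the informative
#' statement) while a LOEC keeps the *most* severe category (an effect on
#' survival must dominate an equal-concentration effect on enzymes).
#'
#' @param entries data.frame of toxicity entries sharing the grouping key.
#' @return the winning entry (one-row data.frame).
#' @export
resolve_endpoint_ties <- function(entries) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0L) {
    stop_mp("resolve_endpoint_ties(): empty group", class = "mp_precondition_error")
  }
  if (nrow(entries) == 1L) return(entries)
  has_noec <- !is.na(entries$noec_value) | !is.na(entries$honec_value)
  pool <- if (any(has_noec)) entries[has_noec, , drop = FALSE] else entries
  use_noec <- any(has_noec)
  value <- if (use_noec) {
    ifelse(!is.na(pool$noec_value), pool$noec_value, pool$honec_value)
  } else {
    pool$loec_value
  }
  lowest <- which(value == min(value))
  if (length(lowest) > 1L) {
    sev <- match(pool$endpoint_category[lowest], ENDPOINT_CATEGORIES)
    pick <- if (use_noec) lowest[which.min(sev)] else lowest[which.max(sev)]
  } else {
    pick <- lowest
  }
  pool[pick, , drop = FALSE]
}

#' Uncertainty-factor table and lookup
#'
#' Three multiplicative uncertainty factors, each on the geometric ladder
#' \{1, 2, 4\}, penalize (i) short exposure (`uf_time`: fully chronic >= 42
#' days -> 1; 14-41 days -> 2; >5 and < 14 days -> 4), (ii) descriptor
#' imprecision (`uf_descriptor`: NOEC_a 1, NOEC_b 2, LOEC_a 2, LOEC_b 4)
#' and (iii) endpoint severity (`uf_category`: A 1, B 2, C 4). All three
#' maps are config-overridable.
#'
#' @return `default_uf_table()`: list with `uf_time` (data.frame `min_days`,
#'   `factor`, bands closed on the left, evaluated from the longest band
#'   down), `uf_descriptor`, `uf_category` (named numeric vectors).
#' @export
default_uf_table <- function() {
  list(
    uf_time = data.frame(min_days = c(42, 14, 5 + 1e-9),
                         factor = c(1, 2, 4)),
    uf_descriptor = c(NOEC_a = 1, NOEC_b = 2, LOEC_a = 2, LOEC_b = 4),
    uf_category = c(A = 1, B = 2, C = 4)
  )
}

#' @rdname default_uf_table
#' @param exposure_days exposure duration in days (> 5; shorter studies are
#'   acute and out of scope).
#' @param dclass descriptor class label (or the list from
#'   [classify_descriptor()]).
#' @param category endpoint category `"A"`, `"B"` or `"C"`.
#' @param table a UF table as from [default_uf_table()].
#' @return `lookup_ufs()`: named numeric vector `c(uf_t, uf_d, uf_c)`.
#' @export
lookup_ufs <- function(exposure_days, dclass, category,
                       table = default_uf_table()) {
  if (!is.finite(exposure_days) || exposure_days <= 5) {
    stop_mp("exposure of %s days is acute (<= 5 d) and out of scope",
            format(exposure_days), class = "mp_scope_error")
  }
  if (is.list(dclass)) dclass <- dclass$label
  tt <- table$uf_time[order(-table$uf_time$min_days), , drop = FALSE]
  band <- which(exposure_days >= tt$min_days)
  if (!length(band)) {
    stop_mp("no uf_time band covers %s days", format(exposure_days),
            class = "mp_config_error")
  }
  uf_t <- tt$factor[band[1L]]
  if (!dclass %in% names(table$uf_descriptor)) {
    stop_mp("descriptor class '%s' missing from uf_descriptor map", dclass,
            class = "mp_config_error")
  }
  if (!category %in% names(table$uf_category)) {
    stop_mp("endpoint category '%s' missing from uf_category map", category,
            class = "mp_config_error")
  }
  c(uf_t = uf_t, uf_d = unname(table$uf_descriptor[[dclass]]),
    uf_c = unname(table$uf_category[[category]]))
}

#' Chronic no-effect equivalent
#'
#' `NOEC_equivalent = descriptor / (UF_T * UF_D * UF_C)`; never larger than
#' the raw descriptor, equal only when all three factors are 1.
#'
#' @param value_nb_per_kg descriptor value in particles per kg dry weight.
#' @param ufs numeric vector of the three factors.
#' @return the harmonized value, same unit.
#' @export
derive_noec_equivalent <- function(value_nb_per_kg, ufs) {
  if (any(!is.finite(value_nb_per_kg)) || any(value_nb_per_kg <= 0)) {
    stop_mp("descriptor value must be positive", class = "mp_precondition_error")
  }
  stopifnot(length(ufs) == 3L, all(ufs %in% c(1, 2, 4)))
  value_nb_per_kg / prod(ufs)
}

#' Harmonize a toxicity table into chronic NOEC equivalents
#'
#' The full harmonization pass: converts mg/kg entries to particle numbers
#' (via particle geometry and polymer density), resolves endpoint ties
#' within each study x species x particle group, classifies the governing
#' descriptor, looks up the three uncertainty factors and divides. One
#' output row per group.
#'
#' @param entries validated toxicity table ([load_toxicity_table()]).
#' @param uf_table UF table, default [default_uf_table()].
#' @param densities polymer density table, default shipped table.
#' @param default_fiber_diameter_um fallback fiber diameter when a study
#'   reports none (config constant, default 20 um).
#' @return data.frame (class `mp_harmonized`): `entry_id`, `study_id`,
#'   `species_label`, `taxon_group`, `descriptor_class`, `censoring`,
#'   `selected_value_nb_per_kg`, `uf_t`, `uf_d`, `uf_c`,
#'   `noec_equivalent_nb_per_kg_dw`.
#' @export
harmonize_toxicity <- function(entries, uf_table = default_uf_table(),
                               densities = default_density_table(),
                               default_fiber_diameter_um = 20) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0L) {
    stop_mp("harmonize_toxicity(): no entries", class = "mp_precondition_error")
  }
  # Convert mass-based entries to particle numbers (all descriptor columns
  # scale by the same per-particle mass, so ordering is preserved).
  for (i in seq_len(nrow(entries))) {
    if (identical(entries$concentration_unit[i], "mg_per_kg_dw")) {
      spec <- particle_spec_from_row(as.list(entries[i, ]), densities,
                                     default_fiber_diameter_um)
      for (cl in c("noec_value", "loec_value", "honec_value")) {
        if (!is.na(entries[[cl]][i])) {
          entries[[cl]][i] <- mass_to_number(entries[[cl]][i], spec)
        }
      }
      entries$concentration_unit[i] <- "nb_per_kg_dw"
    }
  }
  key <- paste(entries$study_id, entries$species_label,
               particle_signature(entries), sep = "\r")
  groups <- split(seq_len(nrow(entries)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    win <- resolve_endpoint_ties(entries[idx, , drop = FALSE])
    dc <- classify_descriptor(as.list(win))
    ufs <- lookup_ufs(win$exposure_days, dc, win$endpoint_category, uf_table)
    data.frame(entry_id = win$entry_id, study_id = win$study_id,
               species_label = win$species_label,
               taxon_group = win$taxon_group,
               descriptor_class = dc$label, censoring = dc$censoring,
               selected_value_nb_per_kg = dc$selected_value,
               uf_t = ufs[["uf_t"]], uf_d = ufs[["uf_d"]], uf_c = ufs[["uf_c"]],
               noec_equivalent_nb_per_kg_dw =
                 derive_noec_equivalent(dc$selected_value, ufs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mp_harmonized", "data.frame")
  out
}

particle_signature <- function(df) {
  cols <- c("particle_shape", "particle_polymer", "particle_diameter_um",
            "particle_length_um", "particle_thickness_um")
  sig <- rep("", nrow(df))
  for (cl in cols) {
    if (cl %in% names(df)) {
      v <- df[[cl]]
      sig <- paste(sig, ifelse(is.na(v), "", as.character(v)), sep = "|")
    }
  }
  sig
}

#' Aggregate harmonized records to one sensitivity per species
#'
#' Computes the geometric mean NOEC equivalent per species. With
#' `collapse_microbes = TRUE` (the default) all soil-bacteria records
#' collapse into one pseudo-species `"bacteria"` and all fungi into
#' `"fungi"`, preventing a handful of community studies from flooding the
#' species list. Microbial endpoints measured inside an animal host should
#' already be curated as endpoints of the host species (taxon_group
#' invertebrate), so they are unaffected.
#'
#' @param records harmonized records ([harmonize_toxicity()]).
#' @param collapse_microbes logical, see above.
#' @return data.frame (class `mp_species_sens`): `species_label`,
#'   `geomean_noec_equivalent`, `n_entries`.
#' @export
aggregate_species <- function(records, collapse_microbes = TRUE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    stop_mp("aggregate_species(): no records", class = "mp_precondition_error")
  }
  label <- records$species_label
  if (collapse_microbes) {
    label[records$taxon_group == "bacteria"] <- "bacteria"
    label[records$taxon_group == "fungi"] <- "fungi"
  }
  sp <- split(records$noec_equivalent_nb_per_kg_dw,
              factor(label, levels = unique(label)))
  out <- data.frame(species_label = names(sp),
                    geomean_noec_equivalent = vapply(sp, geomean, numeric(1)),
                    n_entries = vapply(sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mp_species_sens", "data.frame")
  out
}
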