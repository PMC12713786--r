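test_that("classify_descriptor follows the precision decision tree", {
  # tight bracket -> precise NOEC
  d <- classify_descriptor(tox_row(noec_value = 100, loec_value = 500))
  expect_equal(d, list(label = "NOEC_a", selected_value = 100,
                       censoring = "none"))
  # loose bracket (ratio >= 10, boundary included)
  expect_equal(classify_descriptor(tox_row(noec_value = 10,
                                           loec_value = 1000))$label, "NOEC_b")
  expect_equal(classify_descriptor(tox_row(noec_value = 10,
                                           loec_value = 100))$label, "NOEC_b")
  expect_equal(classify_descriptor(tox_row(noec_value = 10,
                                           loec_value = 99.9))$label, "NOEC_a")
  # HONEC only: right-censored NOEC_b
  d <- classify_descriptor(tox_row(descriptor_kind = "HONEC",
                                   noec_value = NA, loec_value = NA,
                                   honec_value = 2000))
  expect_equal(d, list(label = "NOEC_b", selected_value = 2000,
                       censoring = "right"))
  # LOEC only: left-censored LOEC_b
  d <- classify_descriptor(tox_row(descriptor_kind = "LOEC", noec_value = NA,
                                   loec_value = 300))
  expect_equal(d, list(label = "LOEC_b", selected_value = 300,
                       censoring = "left"))
  # NOEC without a bracketing LOEC: loose class, not censored
  expect_equal(classify_descriptor(tox_row(noec_value = 50,
                                           loec_value = NA))$label, "NOEC_b")
  expect_error(classify_descriptor(tox_row(noec_value = NA, loec_value = NA,
                                           honec_value = NA)),
               class = "mp_validation_error")
})

test_that("endpoint tie resolution prefers NOECs and applies severity rules", {
  # tied NOECs across categories -> least severe retained
  g <- rbind(tox_row("a", endpoint_name = "survival", endpoint_category = "C",
                     noec_value = 100, loec_value = 500),
             tox_row("b", endpoint_name = "enzyme_activity",
                     endpoint_category = "A", noec_value = 100,
                     loec_value = 500))
  expect_equal(resolve_endpoint_ties(g)$endpoint_category, "A")
  # tied LOECs (no NOECs) -> most severe retained
  g2 <- rbind(tox_row("a", descriptor_kind = "LOEC", noec_value = NA,
                      loec_value = 100, endpoint_category = "C"),
              tox_row("b", descriptor_kind = "LOEC", noec_value = NA,
                      loec_value = 100, endpoint_category = "A"))
  expect_equal(resolve_endpoint_ties(g2)$endpoint_category, "C")
  # lowest value governs before any severity tie-break
  g3 <- rbind(tox_row("a", noec_value = 50, loec_value = 200,
                      endpoint_category = "C"),
              tox_row("b", noec_value = 100, loec_value = 400,
                      endpoint_category = "A"))
  expect_equal(resolve_endpoint_ties(g3)$entry_id, "a")
  # NOEC-bearing entries beat LOEC-only entries
  g4 <- rbind(tox_row("a", descriptor_kind = "LOEC", noec_value = NA,
                      loec_value = 10),
              tox_row("b", noec_value = 500, loec_value = 900))
  expect_equal(resolve_endpoint_ties(g4)$entry_id, "b")
  # single entry is the identity
  expect_equal(resolve_endpoint_ties(tox_row("solo"))$entry_id, "solo")
  expect_error(resolve_endpoint_ties(tox_row()[0, ]),
               class = "mp_precondition_error")
})

test_that("UF lookup matches the default table over its bands", {
  expect_equal(lookup_ufs(60, "NOEC_a", "A"), c(uf_t = 1, uf_d = 1, uf_c = 1))
  expect_equal(lookup_ufs(60, "LOEC_b", "C"), c(uf_t = 1, uf_d = 4, uf_c = 4))
  expect_equal(lookup_ufs(7, "NOEC_a", "A"), c(uf_t = 4, uf_d = 1, uf_c = 1))
  # band boundaries: >= 42 chronic, 14-41 intermediate, >5-<14 short
  expect_equal(lookup_ufs(42, "NOEC_a", "A")[["uf_t"]], 1)
  expect_equal(lookup_ufs(41.9, "NOEC_a", "A")[["uf_t"]], 2)
  expect_equal(lookup_ufs(14, "NOEC_a", "A")[["uf_t"]], 2)
  expect_equal(lookup_ufs(13.9, "NOEC_a", "A")[["uf_t"]], 4)
  expect_equal(lookup_ufs(5.1, "NOEC_b", "B"), c(uf_t = 4, uf_d = 2, uf_c = 2))
  expect_error(lookup_ufs(5, "NOEC_a", "A"), "acute", class = "mp_scope_error")
  expect_error(lookup_ufs(3, "NOEC_a", "A"), class = "mp_scope_error")
})

test_that("NOEC equivalent is the descriptor over the UF product", {
  expect_equal(derive_noec_equivalent(1000, c(1, 1, 1)), 1000)
  expect_equal(derive_noec_equivalent(1000, c(2, 2, 1)), 250)
  expect_equal(derive_noec_equivalent(64, c(4, 4, 4)), 1)
  expect_error(derive_noec_equivalent(-5, c(1, 1, 1)),
               class = "mp_precondition_error")
})

test_that("harmonization never increases a value; divisor is a power of two", {
  bundle <- gen_toxicity_entries(synthetic_truth(), n_species = 12L,
                                 n_entries = 40L, seed = 99L)
  h <- harmonize_toxicity(bundle$table)
  expect_true(all(h$noec_equivalent_nb_per_kg_dw <=
                    h$selected_value_nb_per_kg + 1e-12))
  div <- h$selected_value_nb_per_kg / h$noec_equivalent_nb_per_kg_dw
  expect_true(all(abs(div - 2^round(log2(div))) < 1e-9))
  expect_true(all(round(log2(div)) %in% 0:6))
  # equality iff all UFs are 1
  all_one <- h$uf_t == 1 & h$uf_d == 1 & h$uf_c == 1
  expect_equal(abs(div - 1) < 1e-12, all_one)
})

test_that("mg/kg entries are converted before harmonization", {
  df <- tox_row(noec_value = 1, loec_value = 5,
                concentration_unit = "mg_per_kg_dw",
                particle_shape = "sphere", particle_diameter_um = 100,
                particle_density_g_cm3 = 0.95)
  h <- harmonize_toxicity(df)
  # oracle: one PE sphere d=100um weighs 0.95 * 5.23599e-7 g
  expect_equal(h$selected_value_nb_per_kg,
               1e-3 / (0.95 * (4 / 3) * pi * (50e-4)^3), tolerance = 1e-9)
  expect_equal(h$descriptor_class, "NOEC_a")
})

test_that("species aggregation: geomean, collapse, invariance properties", {
  rec <- function(sp, val, taxon = "invertebrate")
    data.frame(entry_id = paste0(sp, val), study_id = "s",
               species_label = sp, taxon_group = taxon,
               noec_equivalent_nb_per_kg_dw = val, stringsAsFactors = FALSE)
  r <- rbind(rec("worm", 1), rec("worm", 100), rec("plant", 7, "plant"))
  agg <- aggregate_species(r)
  expect_equal(agg$geomean_noec_equivalent[agg$species_label == "worm"], 10)
  expect_equal(agg$geomean_noec_equivalent[agg$species_label == "plant"], 7)
  # soil microbes collapse into pseudo-species
  r2 <- rbind(rec("Bacillus_sp", 10, "bacteria"),
              rec("Pseudomonas_sp", 1000, "bacteria"),
              rec("Aspergillus_sp", 5, "fungi"))
  agg2 <- aggregate_species(r2)
  expect_setequal(agg2$species_label, c("bacteria", "fungi"))
  expect_equal(agg2$geomean_noec_equivalent[agg2$species_label == "bacteria"],
               100)
  # permutation invariance and scale equivariance, property-style
  set.seed(5)
  for (i in 1:10) {
    vals <- rlnorm(12, 5, 2)
    sp <- sample(letters[1:4], 12, replace = TRUE)
    recs <- do.call(rbind, Map(rec, sp, vals))
    perm <- recs[sample(nrow(recs)), ]
    a1 <- aggregate_species(recs)
    a2 <- aggregate_species(perm)
    a2 <- a2[match(a1$species_label, a2$species_label), ]
    expect_equal(a1$geomean_noec_equivalent, a2$geomean_noec_equivalent)
    recs_k <- recs
    recs_k$noec_equivalent_nb_per_kg_dw <- recs_k$noec_equivalent_nb_per_kg_dw * 3.7
    a3 <- aggregate_species(recs_k)
    expect_equal(a3$geomean_noec_equivalent,
                 a1$geomean_noec_equivalent * 3.7, tolerance = 1e-12)
    # geomean bounded by min and max of the entries
    for (s in a1$species_label) {
      v <- vals[sp == s]
      g <- a1$geomean_noec_equivalent[a1$species_label == s]
      expect_true(g >= min(v) - 1e-12 && g <= max(v) + 1e-12)
    }
  }
})
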