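test_that("sphere geometry follows the closed-form formulas", {
  g <- derive_geometry(100, "sphere")
  expect_equal(g$surface_area, 31415.93, tolerance = 1e-6)
  expect_equal(g$volume, 523598.78, tolerance = 1e-6)
  expect_equal(g$sv_ratio, 0.06, tolerance = 1e-9)
  expect_equal(derive_geometry(6, "sphere")$sv_ratio, 1.0)
  # sv_ratio * d = 6 identity over a diameter grid
  for (d in c(0.5, 3, 10, 47, 120, 900))
    expect_equal(derive_geometry(d, "sphere")$sv_ratio * d, 6,
                 tolerance = 1e-12)
})

test_that("rod geometry uses closed cylinder formulas", {
  g <- derive_geometry(10, "rod", rod_length = 100)
  expect_equal(g$surface_area, 3298.67, tolerance = 1e-5)
  expect_equal(g$volume, pi * 25 * 100)
  expect_equal(g$sv_ratio, g$surface_area / g$volume)
})

test_that("geometry rejects bad dimensions and warns on shape 'other'", {
  expect_error(derive_geometry(-5, "sphere"), "diameter")
  expect_error(derive_geometry(0, "sphere"), "diameter")
  expect_error(derive_geometry(10, "rod"), "rod_length")
  expect_error(derive_geometry(10, "rod", -1), "rod_length")
  expect_warning(g <- derive_geometry(10, "other"), "sphere")
  expect_equal(g$volume, pi * 1000 / 6)
})

test_that("lipid weighting is a mass-fraction-weighted mean", {
  expect_equal(weighted_lipid_properties(
    data.frame(mass_percent = 100, lipophilicity = 5, polarity = 20)),
    list(lipid_lipophilicity = 5, lipid_polarity = 20))
  expect_equal(weighted_lipid_properties(
    data.frame(mass_percent = c(50, 50), lipophilicity = c(2, 4),
               polarity = c(10, 30))),
    list(lipid_lipophilicity = 3, lipid_polarity = 20))
  # three unequal components: direct weighted sum
  l <- data.frame(mass_percent = c(20, 30, 50),
                  lipophilicity = c(1, 2, 8), polarity = c(5, 50, 20))
  out <- weighted_lipid_properties(l)
  expect_equal(out$lipid_lipophilicity,
               sum(l$mass_percent * l$lipophilicity) / 100)
  expect_equal(out$lipid_polarity, sum(l$mass_percent * l$polarity) / 100)
})

test_that("lipid weighting is order- and rescale-invariant within tolerance", {
  l <- data.frame(mass_percent = c(20, 30, 50),
                  lipophilicity = c(1, 2, 8), polarity = c(5, 50, 20))
  expect_equal(weighted_lipid_properties(l),
               weighted_lipid_properties(l[c(3, 1, 2), ]))
  l2 <- l; l2$mass_percent <- l2$mass_percent * 0.96 # sum 96, renormalised
  expect_equal(weighted_lipid_properties(l), weighted_lipid_properties(l2))
  expect_error(weighted_lipid_properties(l[0, ]), "empty")
  l3 <- l; l3$mass_percent <- l3$mass_percent * 0.8
  expect_error(weighted_lipid_properties(l3), "tolerance")
})

test_that("encoding applies log10 before standardization and is deterministic", {
  rec <- penetration_records(tiny_records_df())
  fm <- encode_features(rec)
  p <- fm$transform_log$params
  # de-standardize the diameter column: log10(100) = 2
  raw <- fm$values[1, "core_diameter"] * p$scale[["core_diameter"]] +
    p$center[["core_diameter"]]
  expect_equal(unname(raw), 2)
  # identical records give identical rows
  rec2 <- penetration_records(rbind(tiny_records_df(),
                                    tiny_records_df()[1, ]))
  fm2 <- encode_features(rec2)
  expect_equal(fm2$values[1, ], fm2$values[4, ])
})

test_that("missing cells are flagged exactly where data are missing", {
  df <- tiny_records_df()
  df$hydrophobicity_value[2] <- NA
  fm <- encode_features(penetration_records(df))
  expect_true(fm$missing_mask[2, "hydrophobicity"])
  expect_equal(sum(fm$missing_mask[, "hydrophobicity"]), 1L)
  expect_false(any(fm$missing_mask[, "sc_thickness"]))
  # no NA outside the mask
  expect_identical(is.na(fm$values), fm$missing_mask)
})

test_that("one-hot groups sum to 1 and decode back to the original levels", {
  fx <- fixture_noiseless()
  fm <- fx$fm
  for (grp in c("medium", "species", "region", "shape", "np_class")) {
    cols <- fm$encoding_map[[grp]]
    expect_true(all(rowSums(fm$values[, cols]) == 1))
  }
  dec <- decode_categoricals(fm)
  df <- as.data.frame(fx$records)
  expect_equal(as.character(dec$medium), as.character(df$medium))
  expect_equal(as.character(dec$species), as.character(df$species))
  expect_equal(as.character(dec$shape), as.character(df$shape))
  expect_equal(as.character(dec$in_vivo), as.character(df$in_vivo))
})

test_that("a reference encoding is reused without refitting", {
  fx <- fixture_noiseless()
  sub <- fx$records[1:50, ]
  class(sub) <- class(fx$records)
  fm_sub <- encode_features(sub, reference = fx$fm)
  expect_equal(fm_sub$values[1:50, ], fx$fm$values[1:50, ])
})

test_that("CSV round trip is the identity and errors are located", {
  rec <- penetration_records(tiny_records_df())
  path <- tempfile(fileext = ".csv")
  write_dataset(rec, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)

  # empty body, header only
  empty <- rec[0, ]
  class(empty) <- class(rec)
  path2 <- tempfile(fileext = ".csv")
  write_dataset(empty, path2)
  expect_equal(nrow(read_dataset(path2)), 0L)

  # bad depth level names the offending row
  df <- tiny_records_df()
  df$depth[2] <- "Bloodstream"
  expect_error(penetration_records(df), "Bloodstream")
  expect_error(penetration_records(df), "row 2")

  df2 <- tiny_records_df()[, -3] # drop a mandatory column
  expect_error(penetration_records(df2), "shape")
})

test_that("record validation enforces physical plausibility bands", {
  df <- tiny_records_df(); df$temperature[1] <- 60
  expect_error(penetration_records(df), "temperature")
  df <- tiny_records_df(); df$hf_diameter[1] <- 800
  expect_error(penetration_records(df), "hf_diameter")
  df <- tiny_records_df(); df$sc_thickness[1] <- -2
  expect_error(penetration_records(df), "sc_thickness")
})

test_that("missing derived geometry is filled from diameter and shape", {
  df <- tiny_records_df()
  df$surface_area[1] <- NA; df$volume[1] <- NA; df$sv_ratio[1] <- NA
  rec <- penetration_records(df)
  expect_equal(rec$surface_area[1], pi * 100^2)
  expect_equal(rec$sv_ratio[1], 0.06)
})
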