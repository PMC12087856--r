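test_that("built-in reference table carries the published follicle means", {
  ref <- builtin_skin_reference()
  expect_equal(skin_reference_lookup(ref, "human", "back")$hf_diameter, 140.3)
  expect_equal(skin_reference_lookup(ref, "rat", "back")$hf_diameter, 14)
  expect_equal(skin_reference_lookup(ref, "pig", "abdomen")$hf_diameter, 185)
  expect_equal(skin_reference_lookup(ref, "human", "face")$hf_diameter, 71.3)
  expect_equal(skin_reference_lookup(ref, "human", "abdomen")$hf_diameter, 97)
  expect_equal(skin_reference_lookup(ref, "human", "arm")$hf_diameter, 103.2)
  expect_equal(skin_reference_lookup(ref, "human", "breast")$hf_diameter, 146.3)
  expect_true(all(ref$n_sources >= 3))
  expect_error(skin_reference_lookup(ref, "mouse", "ear"), "no entry")
})

test_that("generation is reproducible under the seed", {
  cfg <- generator_config(n_records = 100, seed = 5)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- generator_config(n_records = 100, seed = 6)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(generate_dataset(cfg2))))
})

test_that("with zero noise the label is a deterministic function of features", {
  fx <- fixture_noiseless()
  expect_equal(as.character(planted_depth(fx$cfg$rule, fx$records)),
               as.character(fx$records$depth))
})

test_that("planted rule validates dominance and threshold ordering", {
  expect_error(planted_rule(coefficients = c(hf_diameter = 1,
                                             hydrophobicity = 2,
                                             core_diameter = 0.5,
                                             sc_thickness = 0.1,
                                             temperature = 0.1)),
               "strictly largest")
  expect_error(planted_rule(thresholds = c(0, 1, 1, 2)), "increasing")
  expect_error(generator_config(n_records = 10), "n_records")
  expect_error(generator_config(species_mix = c(human = 0.5, pig = 0.2)),
               "sum to 1")
})

test_that("class proportions match a Monte-Carlo oracle of the latent law", {
  cfg <- generator_config(n_records = 5000, seed = 9)
  rec <- generate_dataset(cfg)
  got <- as.numeric(table(rec$depth)) / nrow(rec)

  # independent latent simulation at large n
  set.seed(901)
  n <- 3e5
  ref <- builtin_skin_reference()
  rule <- cfg$rule
  sp <- sample(names(cfg$species_mix), n, TRUE, cfg$species_mix)
  reg <- vapply(sp, function(s) {
    r <- ref$region[ref$species == s]
    if (length(r) == 1) r else sample(r, 1)
  }, character(1))
  key <- match(paste(sp, reg), paste(ref$species, ref$region))
  draw <- function(m, cv, lo = 0, hi = Inf)
    pmin(pmax(rnorm(n, m, cv * m), pmax(lo, 0.2 * m)), hi)
  hf <- draw(ref$hf_diameter[key], 0.15, lo = 5, hi = 500)
  sc <- draw(ref$sc_thickness[key], 0.15)
  d <- pmin(pmax(rlnorm(n, log(60), 0.8), 2), 2000)
  npc <- sample(c("inorganic", "polymeric", "other"), n, TRUE,
                c(0.5, 0.4, 0.1))
  hv <- ifelse(npc == "inorganic", runif(n, 15, 115), runif(n, -1.5, 7.5))
  hnorm <- ifelse(npc == "inorganic", (hv - 10) / 110, (hv + 2) / 10)
  iv <- runif(n) < 0.35
  temp <- pmin(pmax(ifelse(iv, rnorm(n, 37, 0.5), runif(n, 22, 37)), 15), 45)
  z <- function(x, f) (x - rule$centers[[f]]) / rule$scales[[f]]
  lat <- rule$coefficients[["hf_diameter"]] * z(hf, "hf_diameter") +
    rule$coefficients[["hydrophobicity"]] * z(hnorm, "hydrophobicity") +
    rule$coefficients[["core_diameter"]] * z(log10(d), "core_diameter") +
    rule$coefficients[["sc_thickness"]] * z(sc, "sc_thickness") +
    rule$coefficients[["temperature"]] * z(temp, "temperature") +
    rnorm(n, 0, rule$noise_sd)
  oracle <- as.numeric(table(cut(lat, c(-Inf, rule$thresholds, Inf),
                                 labels = depth_levels())) / n)
  expect_true(all(abs(got - oracle) <= 0.03))
})

test_that("injected missingness hits the target rates", {
  cfg <- generator_config(n_records = 1000, seed = 3, missingness = c())
  rec <- generate_dataset(cfg)
  expect_equal(sum(is.na(rec$hydrophobicity_value)), 0L)

  all_gone <- inject_missingness(rec, c(temperature = 1), seed = 1)
  expect_true(all(is.na(all_gone$temperature)))

  some <- inject_missingness(rec, c(hydrophobicity_value = 0.66), seed = 2)
  frac <- mean(is.na(some$hydrophobicity_value))
  expect_true(frac >= 0.61 && frac <= 0.71) # 3-sigma binomial band

  expect_error(inject_missingness(rec, c(nope = 0.5)), "unknown column")
  expect_error(inject_missingness(rec, c(temperature = 1.5)), "\\[0, 1\\]")
})

test_that("generated skin means track the reference table", {
  cfg <- generator_config(n_records = 3000, seed = 13, missingness = c())
  rec <- generate_dataset(cfg)
  ref <- builtin_skin_reference()
  df <- as.data.frame(rec)
  for (i in seq_len(nrow(ref))) {
    idx <- df$species == ref$species[i] & df$region == ref$region[i]
    if (sum(idx) < 30) next
    m <- mean(df$hf_diameter[idx])
    se <- sd(df$hf_diameter[idx]) / sqrt(sum(idx))
    expect_lt(abs(m - ref$hf_diameter[i]), 2.5 * se + 0.02 * ref$hf_diameter[i])
  }
})

test_that("species and medium mixes follow the configured compilation", {
  cfg <- generator_config(n_records = 4000, seed = 17)
  rec <- generate_dataset(cfg)
  expect_lt(abs(mean(rec$species == "human") - 0.24), 0.03)
  expect_gt(mean(rec$medium == "aqueous", na.rm = TRUE), 0.5)
  d <- rec$core_diameter
  expect_gt(mean(d <= 100), 0.5) # majority below the 100 nm bound
})
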