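# Synthetic literature-like penetration datasets. The generator emulates the
# statistical structure of a literature compilation -- species mix with ~24%
# human skin, media more than half aqueous, particle core diameters
# concentrated below 100 nm, per-species/region skin property means, and
# per-column missingness from partial reporting -- and plants an ordinal
# depth-labeling rule dominated by hair follicle diameter so that splitting,
# modeling, importance and scenario stages have a known ground truth.

#' Planted depth-labeling rule
#'
#' A linear latent score on fixed-reference z-scaled features, cut into the
#' five ordered depth classes by strictly increasing thresholds, plus
#' Gaussian noise. The hair follicle diameter coefficient must dominate in
#' absolute value; hydrophobicity, core diameter (log10), SC thickness and
#' temperature follow. The centers/scales are fixed constants of the rule
#' (not refit per dataset) so the label is a deterministic function of the
#' record when `noise_sd = 0`.
#'
#' @param coefficients Named coefficients on the z-scaled features.
#' @param thresholds Four strictly increasing latent cut points separating
#'   Surface/SC/Epidermis/Dermis/Distant.
#' @param noise_sd Latent noise standard deviation (0 = deterministic rule).
#' @return A `planted_rule` object.
#' @export
planted_rule <- function(coefficients = c(hf_diameter = 3.0,
                                          hydrophobicity = 0.9,
                                          core_diameter = -0.7,
                                          sc_thickness = -0.5,
                                          temperature = 0.35),
                         thresholds = c(-2.25, 0.4, 2.25, 4.25),
                         noise_sd = 0.6) {
  need <- c("hf_diameter", "hydrophobicity", "core_diameter",
            "sc_thickness", "temperature")
  if (!all(need %in% names(coefficients)))
    stop("planted_rule: coefficients must name ", paste(need, collapse = ", "))
  if (max(abs(coefficients[setdiff(need, "hf_diameter")])) >=
      abs(coefficients["hf_diameter"]))
    stop("planted_rule: |coef(hf_diameter)| must be strictly largest")
  if (any(diff(thresholds) <= 0))
    stop("planted_rule: thresholds must be strictly increasing")
  if (noise_sd < 0) stop("planted_rule: noise_sd must be >= 0")
  structure(list(
    coefficients = coefficients[need],
    thresholds = thresholds,
    noise_sd = noise_sd,
    # fixed reference location/scale per feature (rule constants)
    centers = c(hf_diameter = 100, hydrophobicity = 0.5,
                core_diameter = log10(60), sc_thickness = 20,
                temperature = 32),
    scales = c(hf_diameter = 50, hydrophobicity = 0.25,
               core_diameter = 0.35, sc_thickness = 6, temperature = 5),
    # fixed hydrophobicity normalisation ranges used by the rule
    hydro_range = list(logKow = c(-2, 8), contact_angle_deg = c(10, 120))
  ), class = "planted_rule")
}

# deterministic latent score of the rule (no noise)
planted_latent <- function(rule, records) {
  df <- as.data.frame(records)
  hr <- rule$hydro_range
  hnorm <- ifelse(df$hydrophobicity_scale == "contact_angle_deg",
                  (df$hydrophobicity_value - hr$contact_angle_deg[1]) /
                    diff(hr$contact_angle_deg),
                  (df$hydrophobicity_value - hr$logKow[1]) / diff(hr$logKow))
  feats <- cbind(hf_diameter = df$hf_diameter,
                 hydrophobicity = hnorm,
                 core_diameter = log10(df$core_diameter),
                 sc_thickness = df$sc_thickness,
                 temperature = df$temperature)
  z <- sweep(sweep(feats, 2, rule$centers[colnames(feats)]), 2,
             rule$scales[colnames(feats)], "/")
  drop(z %*% rule$coefficients[colnames(feats)])
}

#' Evaluate the planted rule on records
#'
#' Returns the depth class the rule assigns to each record (deterministic
#' part only; add latent noise before cutting to emulate label noise).
#'
#' @param rule A `planted_rule`.
#' @param records A `penetration_records` data.frame.
#' @param latent_noise Optional vector of latent noise to add before cutting.
#' @return Factor of depth classes.
#' @export
planted_depth <- function(rule, records, latent_noise = 0) {
  score <- planted_latent(rule, records) + latent_noise
  cut(score, breaks = c(-Inf, rule$thresholds, Inf),
      labels = depth_levels(), right = TRUE)
}

#' Synthetic dataset generator configuration
#'
#' Defaults encode the study conditions the generator emulates: 24% human
#' skin with a pig-dominant remainder, media more than half aqueous, a
#' log-normal core diameter law with median 60 nm (most particles below the
#' 100 nm ISO bound), per-column missingness reflecting partial literature
#' reporting, a 15% coefficient of variation around the reference skin
#' means, and the default planted rule.
#'
#' @param n_records Number of records (>= 20).
#' @param seed Integer seed.
#' @param species_mix,medium_mix Named probability vectors (sum to 1).
#' @param diameter_law c(meanlog, sdlog) of the core-diameter log-normal.
#' @param missingness Named per-column missing probabilities.
#' @param skin_cv Coefficient of variation around reference skin means.
#' @param rule A `planted_rule`.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_records = 500, seed = 1,
                             species_mix = c(human = 0.24, pig = 0.40,
                                             rat = 0.14, mouse = 0.14,
                                             rabbit = 0.08),
                             medium_mix = c(aqueous = 0.55, emulsion = 0.25,
                                            oil = 0.15, other = 0.05),
                             diameter_law = c(meanlog = log(60), sdlog = 0.8),
                             missingness = c(hydrophobicity_value = 0.30,
                                             concentration = 0.20,
                                             temperature = 0.10,
                                             contact_time = 0.05),
                             skin_cv = 0.15,
                             rule = planted_rule()) {
  if (n_records < 20) stop("generator_config: n_records must be >= 20")
  for (p in list(species_mix, medium_mix))
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("generator_config: probability vectors must be non-negative and sum to 1")
  if (any(missingness < 0 | missingness > 1))
    stop("generator_config: missingness probabilities must lie in [0, 1]")
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 species_mix = species_mix, medium_mix = medium_mix,
                 diameter_law = diameter_law, missingness = missingness,
                 skin_cv = skin_cv, rule = rule),
            class = "generator_config")
}

#' Generate a synthetic penetration dataset
#'
#' Draws skin descriptors from the built-in reference means with the
#' configured coefficient of variation, particle and condition descriptors
#' from the configured laws, labels each record with the planted rule (plus
#' latent noise), and finally masks fields per the missingness
#' probabilities. Fully reproducible under the config seed.
#'
#' @param config A `generator_config`.
#' @return A `penetration_records` data.frame with attribute `"latent"`
#'   (the noiseless latent scores, for oracle checks).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_records
  ref <- builtin_skin_reference()

  species <- sample(names(config$species_mix), n, replace = TRUE,
                    prob = config$species_mix)
  region <- vapply(species, function(sp) {
    regs <- ref$region[ref$species == sp]
    if (length(regs) == 1L) regs else sample(regs, 1L)
  }, character(1))

  jitter_pos <- function(mean, cv, lo = .Machine$double.eps, hi = Inf) {
    v <- stats::rnorm(length(mean), mean, cv * mean)
    pmin(pmax(v, pmax(lo, 0.2 * mean)), hi)
  }
  key <- match(paste(species, region), paste(ref$species, ref$region))
  skin <- ref[key, ]
  cv <- config$skin_cv
  sc_thickness   <- jitter_pos(skin$sc_thickness, cv)
  epi_thickness  <- jitter_pos(skin$epidermis_thickness, cv)
  derm_thickness <- jitter_pos(skin$dermis_thickness, cv)
  hf_density     <- jitter_pos(skin$hf_density, cv)
  hf_diameter    <- jitter_pos(skin$hf_diameter, cv, lo = 5, hi = 500)
  lip_lipo       <- jitter_pos(skin$lipid_lipophilicity, cv / 3)
  lip_polar      <- jitter_pos(skin$lipid_polarity, cv / 3)

  shape <- sample(np_shape_levels(), n, replace = TRUE,
                  prob = c(0.85, 0.10, 0.05))
  diameter <- pmin(pmax(stats::rlnorm(n, config$diameter_law[["meanlog"]],
                                      config$diameter_law[["sdlog"]]), 2), 2000)
  rod_length <- ifelse(shape == "rod", diameter * stats::runif(n, 2, 10),
                       NA_real_)
  geom <- mapply(function(d, s, l)
    unlist(suppressWarnings(derive_geometry(d, s, l))),
    diameter, shape, rod_length)
  concentration <- stats::rlnorm(n, log(100), 1.2)
  medium <- sample(names(config$medium_mix), n, replace = TRUE,
                   prob = config$medium_mix)
  np_class <- sample(np_class_levels(), n, replace = TRUE,
                     prob = c(0.50, 0.40, 0.10))
  hscale <- ifelse(np_class == "inorganic", "contact_angle_deg", "logKow")
  hvalue <- ifelse(hscale == "contact_angle_deg",
                   stats::runif(n, 15, 115), stats::runif(n, -1.5, 7.5))

  in_vivo <- stats::runif(n) < 0.35
  temperature <- ifelse(in_vivo, stats::rnorm(n, 37, 0.5),
                        stats::runif(n, 22, 37))
  temperature <- pmin(pmax(temperature, 15), 45)
  contact_time <- pmin(pmax(stats::rlnorm(n, log(24), 1.0), 0.25), 168)

  df <- data.frame(
    source_id = sprintf("synth-%05d", seq_len(n)),
    core_diameter = diameter, shape = shape, rod_length = rod_length,
    surface_area = geom["surface_area", ], volume = geom["volume", ],
    sv_ratio = geom["sv_ratio", ], concentration = concentration,
    medium = medium, np_class = np_class,
    hydrophobicity_value = hvalue, hydrophobicity_scale = hscale,
    species = species, region = region,
    sc_thickness = sc_thickness, epidermis_thickness = epi_thickness,
    dermis_thickness = derm_thickness, hf_density = hf_density,
    hf_diameter = hf_diameter, lipid_lipophilicity = lip_lipo,
    lipid_polarity = lip_polar,
    temperature = temperature, contact_time = contact_time,
    in_vivo = in_vivo, depth = NA_character_,
    stringsAsFactors = FALSE)

  rule <- config$rule
  latent <- planted_latent(rule, df)
  noise <- if (rule$noise_sd > 0) stats::rnorm(n, 0, rule$noise_sd) else 0
  df$depth <- as.character(cut(latent + noise,
                               breaks = c(-Inf, rule$thresholds, Inf),
                               labels = depth_levels(), right = TRUE))

  records <- penetration_records(df)
  if (length(config$missingness))
    records <- inject_missingness(records, config$missingness,
                                  seed = config$seed + 1L)
  attr(records, "latent") <- latent
  attr(records, "generator_config") <- config
  records
}

#' Mask fields at random to emulate partial literature reporting
#'
#' Each named column is masked independently with its probability
#' (missing completely at random).
#'
#' @param records A `penetration_records` data.frame.
#' @param missingness Named per-column missing probabilities in [0, 1].
#' @param seed Integer seed.
#' @return The records with masked cells set to NA.
#' @export
inject_missingness <- function(records, missingness, seed = 1) {
  stopifnot(inherits(records, "penetration_records"))
  if (any(missingness < 0 | missingness > 1))
    stop("inject_missingness: probabilities must lie in [0, 1]")
  bad <- setdiff(names(missingness), names(records))
  if (length(bad))
    stop("inject_missingness: unknown column(s) ", paste(bad, collapse = ", "))
  set.seed(seed)
  for (col in names(missingness)) {
    hit <- stats::runif(nrow(records)) < missingness[[col]]
    records[[col]][hit] <- NA
  }
  records
}
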