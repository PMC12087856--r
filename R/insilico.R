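# In-silico nanoparticle populations and per-layer descriptor analysis.
# Particle descriptors are sampled uniformly between the minimum and
# maximum observed in the source dataset (on the log scale for the
# log-transformed descriptors); categorical levels are drawn uniformly
# from the observed levels; the skin and condition context is fixed to a
# single (species, region) with stated temperature/contact time. The
# predicted layers are then profiled per descriptor with Kruskal-Wallis
# and a Dunn post hoc pairwise comparison.

#' Generate an in-silico nanoparticle population
#'
#' @param records Source `penetration_records` providing the descriptor
#'   bounds and observed categorical levels.
#' @param n Population size (default 100000).
#' @param species,region Fixed skin context (default human abdomen, a
#'   mid-range follicle diameter; the hf-dominated models keep layer
#'   contrasts there).
#' @param temperature,contact_time,in_vivo Fixed condition context
#'   (defaults 32 C, 24 h, ex vivo).
#' @param seed Integer seed.
#' @return An `insilico_population`: list with `records`
#'   (`penetration_records`, depth NA), `bounds`, `skin_context`, `seed`.
#' @export
generate_insilico <- function(records, n = 100000, species = "human",
                              region = "abdomen", temperature = 32,
                              contact_time = 24, in_vivo = FALSE, seed = 1) {
  stopifnot(inherits(records, "penetration_records"))
  df <- as.data.frame(records)
  set.seed(seed)

  rng <- function(col, log_scale = FALSE) {
    v <- df[[col]][is.finite(df[[col]])]
    if (!length(v)) stop("generate_insilico: unbounded descriptor '", col, "'")
    r <- range(v)
    if (log_scale && r[1] <= 0)
      stop("generate_insilico: non-positive values in log descriptor '",
           col, "'")
    r
  }
  runif_between <- function(r, log_scale = FALSE) {
    if (log_scale) 10^stats::runif(n, log10(r[1]), log10(r[2]))
    else stats::runif(n, r[1], r[2])
  }
  obs_levels <- function(col) {
    lv <- unique(as.character(df[[col]][!is.na(df[[col]])]))
    if (!length(lv)) stop("generate_insilico: no observed levels in '", col, "'")
    lv
  }
  sample_levels <- function(lv)
    if (length(lv) == 1L) rep(lv, n) else sample(lv, n, replace = TRUE)

  bounds <- list(core_diameter = rng("core_diameter", TRUE),
                 concentration = rng("concentration", TRUE))
  diameter <- runif_between(bounds$core_diameter, TRUE)
  concentration <- runif_between(bounds$concentration, TRUE)
  shape <- sample_levels(obs_levels("shape"))
  rod_length <- ifelse(shape == "rod", diameter * stats::runif(n, 2, 10),
                       NA_real_)
  geom <- mapply(function(d, s, l)
    unlist(suppressWarnings(derive_geometry(d, s, l))),
    diameter, shape, rod_length)
  medium <- sample_levels(obs_levels("medium"))
  np_class <- sample_levels(obs_levels("np_class"))
  hscale <- ifelse(np_class == "inorganic", "contact_angle_deg", "logKow")
  hv <- numeric(n)
  for (sc in unique(hscale)) {
    idx <- which(hscale == sc)
    v <- df$hydrophobicity_value[!is.na(df$hydrophobicity_scale) &
                                   df$hydrophobicity_scale == sc]
    v <- v[is.finite(v)]
    r <- if (length(v)) range(v) else c(0, 1)
    bounds[[paste0("hydrophobicity_", sc)]] <- r
    hv[idx] <- stats::runif(length(idx), r[1], r[2])
  }

  skin <- skin_reference_lookup(builtin_skin_reference(), species, region)
  pop <- data.frame(
    source_id = sprintf("insilico-%06d", seq_len(n)),
    core_diameter = diameter, shape = shape, rod_length = rod_length,
    surface_area = geom["surface_area", ], volume = geom["volume", ],
    sv_ratio = geom["sv_ratio", ], concentration = concentration,
    medium = medium, np_class = np_class,
    hydrophobicity_value = hv, hydrophobicity_scale = hscale,
    species = species, region = region,
    sc_thickness = skin$sc_thickness,
    epidermis_thickness = skin$epidermis_thickness,
    dermis_thickness = skin$dermis_thickness,
    hf_density = skin$hf_density, hf_diameter = skin$hf_diameter,
    lipid_lipophilicity = skin$lipid_lipophilicity,
    lipid_polarity = skin$lipid_polarity,
    temperature = temperature, contact_time = contact_time,
    in_vivo = in_vivo, depth = NA_character_,
    stringsAsFactors = FALSE)

  structure(list(records = penetration_records(pop), n = n, bounds = bounds,
                 skin_context = skin, seed = seed),
            class = "insilico_population")
}

#' @export
print.insilico_population <- function(x, ...) {
  cat("In-silico population:", x$n, "nanoparticles; skin context ",
      x$skin_context$species, "/", x$skin_context$region, "\n")
  invisible(x)
}

# ---- Kruskal-Wallis + Dunn -------------------------------------------------

#' Kruskal-Wallis test with Dunn post hoc pairwise comparison
#'
#' The omnibus test uses `stats::kruskal.test` (tie-corrected). Dunn's
#' pairwise z statistics compare mean ranks: z_ij = (Rbar_i - Rbar_j) /
#' sqrt((N(N+1)/12 - C) (1/n_i + 1/n_j)), with tie correction
#' C = sum(t^3 - t) / (12 (N - 1)); two-sided p-values are adjusted with
#' `adjust` (default Holm).
#'
#' @param x Numeric values.
#' @param g Grouping factor.
#' @param adjust p-value adjustment method (see `stats::p.adjust`).
#' @return List with `H`, `df`, `p`, and `pairs` (data.frame group1,
#'   group2, z, p, p_adj).
#' @export
kw_dunn <- function(x, g, adjust = "holm") {
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(factor(g[keep]))
  if (nlevels(g) < 2) stop("kw_dunn: need at least 2 groups")
  N <- length(x)
  r <- rank(x)
  if (length(unique(x)) == 1L) {
    # no rank variation: H = 0 by convention, all comparisons null
    cmb <- utils::combn(levels(g), 2)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1,
                pairs = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                                   z = 0, p = 1, p_adj = 1)))
  }
  kw <- stats::kruskal.test(x, g)
  ties <- table(x)
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  levs <- levels(g)
  cmb <- utils::combn(levs, 2)
  z <- apply(cmb, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    (rbar[[i]] - rbar[[j]]) /
      sqrt((N * (N + 1) / 12 - C) * (1 / ns[[i]] + 1 / ns[[j]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = z, p = p,
                      p_adj = stats::p.adjust(p, method = adjust))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairs = pairs)
}

#' Per-layer descriptor ranges of a predicted in-silico population
#'
#' Predicts the penetrated layer of every in-silico particle, then, for
#' each varying particle descriptor, tests whether its distribution
#' differs across predicted layers (Kruskal-Wallis + Dunn post hoc) and
#' summarises the per-layer descriptor range. Layers predicted for fewer
#' than `min_members` particles are excluded with a warning.
#'
#' @param population An `insilico_population`.
#' @param model A `qspr_model`.
#' @param reference The `feature_matrix` the model was trained against
#'   (its encoding is reused).
#' @param adjust p-value adjustment for the Dunn comparisons.
#' @param alpha Significance level for the `significant` flag.
#' @param min_members Minimum particles per layer (default 2).
#' @return A `layer_range_report`: list with `kw` (per-descriptor H, df,
#'   p, significant), `dunn` (pairwise table), `ranges` (per descriptor x
#'   layer summary), `layers` (predicted layer counts), `predicted`.
#' @export
layer_ranges <- function(population, model, reference, adjust = "holm",
                         alpha = 0.05, min_members = 2) {
  stopifnot(inherits(population, "insilico_population"))
  fm <- encode_features(population$records, reference = reference)
  pred <- stats::predict(model, fm$values)
  counts <- table(pred)
  small <- names(counts)[counts < min_members & counts > 0]
  if (length(small))
    warning("layer_ranges: excluding layer(s) with < ", min_members,
            " members: ", paste(small, collapse = ", "))
  keep_layers <- names(counts)[counts >= min_members]
  if (length(keep_layers) < 2)
    stop("layer_ranges: model predicts fewer than 2 usable layers")
  df <- as.data.frame(population$records)
  idx <- pred %in% keep_layers
  g <- droplevels(factor(pred[idx], levels = depth_levels()))

  descriptors <- c("core_diameter", "surface_area", "volume", "sv_ratio",
                   "concentration", "hydrophobicity_value")
  kw_rows <- list(); dunn_rows <- list(); range_rows <- list()
  for (dsc in descriptors) {
    v <- df[[dsc]][idx]
    if (length(unique(v[is.finite(v)])) < 2) next
    res <- kw_dunn(v, g, adjust = adjust)
    kw_rows[[dsc]] <- data.frame(descriptor = dsc, H = res$H, df = res$df,
                                 p = res$p, significant = res$p < alpha)
    dunn_rows[[dsc]] <- cbind(descriptor = dsc, res$pairs,
                              significant = res$pairs$p_adj < alpha)
    qs <- do.call(rbind, tapply(v, g, function(w)
      stats::quantile(w, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)))
    range_rows[[dsc]] <- data.frame(descriptor = dsc,
                                    layer = rownames(qs),
                                    min = qs[, 1], q25 = qs[, 2],
                                    median = qs[, 3], q75 = qs[, 4],
                                    max = qs[, 5], row.names = NULL)
  }
  structure(list(kw = do.call(rbind, c(kw_rows, list(make.row.names = FALSE))),
                 dunn = do.call(rbind, c(dunn_rows, list(make.row.names = FALSE))),
                 ranges = do.call(rbind, c(range_rows, list(make.row.names = FALSE))),
                 layers = counts, predicted = pred),
            class = "layer_range_report")
}

#' @export
print.layer_range_report <- function(x, ...) {
  cat("Per-layer descriptor analysis over predicted layers:\n")
  print(x$layers)
  print(x$kw, row.names = FALSE)
  invisible(x)
}
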