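# Core data model: penetration records, derived geometry, lipid weighting,
# CSV I/O. A dataset is a plain data.frame with one row per literature
# experiment, classed "penetration_records".

#' Ordered penetration depth classes
#'
#' The five theoretical layers used to categorise where most nanoparticles
#' accumulate: no penetration (Surface), the stratum corneum (SC), the viable
#' epidermis, the dermis, and Distant (beneath the dermis, potentially
#' systemic).
#'
#' @return Character vector of the five ordered depth class labels.
#' @export
depth_levels <- function() c("Surface", "SC", "Epidermis", "Dermis", "Distant")

np_shape_levels      <- function() c("sphere", "rod", "other")
np_medium_levels     <- function() c("aqueous", "oil", "emulsion", "other")
np_class_levels      <- function() c("inorganic", "polymeric", "other")
hydro_scale_levels   <- function() c("logKow", "contact_angle_deg")
skin_species_levels  <- function() c("human", "pig", "rat", "mouse", "rabbit")
skin_region_levels   <- function() c("face", "abdomen", "arm", "back", "breast", "ear", "other")

# Column dictionary of the flat CSV layout. Units are fixed per file:
# lengths in nm (particle) / um (skin), concentration in ug/mL (declared,
# never converted), temperature in degrees C, contact time in hours.
dataset_columns <- function() {
  c("source_id",
    # nanoparticle descriptors
    "core_diameter", "shape", "rod_length", "surface_area", "volume",
    "sv_ratio", "concentration", "medium", "np_class",
    "hydrophobicity_value", "hydrophobicity_scale",
    # skin descriptors
    "species", "region", "sc_thickness", "epidermis_thickness",
    "dermis_thickness", "hf_density", "hf_diameter",
    "lipid_lipophilicity", "lipid_polarity",
    # experimental conditions
    "temperature", "contact_time", "in_vivo",
    # outcome
    "depth")
}

#' Derive nanoparticle geometry from diameter and shape
#'
#' Computes surface area, volume and surface-to-volume ratio from the core
#' diameter. Spheres use the closed-form sphere formulas (pi d^2, pi d^3 / 6,
#' 6 / d); rods are modelled as closed cylinders of diameter `diameter` and
#' length `rod_length` (area 2 pi r^2 + 2 pi r L, volume pi r^2 L). Shapes
#' recorded as "other" fall back to the sphere formulas with a warning, the
#' convention used when the source study does not report a shape.
#'
#' @param diameter Core diameter in nm (> 0).
#' @param shape One of "sphere", "rod", "other".
#' @param rod_length Rod length in nm; required iff `shape == "rod"`.
#' @return List with `surface_area` (nm^2), `volume` (nm^3), `sv_ratio`
#'   (nm^-1).
#' @examples
#' derive_geometry(100, "sphere")
#' derive_geometry(10, "rod", rod_length = 100)
#' @export
derive_geometry <- function(diameter, shape = "sphere", rod_length = NA_real_) {
  shape <- match.arg(shape, np_shape_levels())
  if (!is.finite(diameter) || diameter <= 0)
    stop("derive_geometry: 'diameter' must be positive, got ", diameter)
  if (shape == "rod") {
    if (!is.finite(rod_length) || rod_length <= 0)
      stop("derive_geometry: 'rod_length' must be positive for shape = 'rod'")
    r <- diameter / 2
    sa <- 2 * pi * r^2 + 2 * pi * r * rod_length
    vol <- pi * r^2 * rod_length
  } else {
    if (shape == "other")
      warning("derive_geometry: shape 'other' treated as sphere")
    sa <- pi * diameter^2
    vol <- pi * diameter^3 / 6
  }
  list(surface_area = sa, volume = vol, sv_ratio = sa / vol)
}

#' Mass-weighted stratum corneum lipid properties
#'
#' Lipophilicity and polarity of the SC lipid matrix are summarised as the
#' mass-fraction-weighted means of the per-lipid values. Mass percentages
#' that sum to within [95, 105] are renormalised to 100; anything further
#' off is rejected as an inconsistent composition.
#'
#' @param lipids data.frame (or matrix) with columns `mass_percent`,
#'   `lipophilicity`, `polarity`.
#' @return List with `lipid_lipophilicity` and `lipid_polarity`.
#' @export
weighted_lipid_properties <- function(lipids) {
  lipids <- as.data.frame(lipids)
  if (nrow(lipids) == 0L)
    stop("weighted_lipid_properties: empty lipid list")
  need <- c("mass_percent", "lipophilicity", "polarity")
  if (!all(need %in% names(lipids)))
    stop("weighted_lipid_properties: need columns ",
         paste(need, collapse = ", "))
  w <- lipids$mass_percent
  if (any(!is.finite(w)) || any(w < 0))
    stop("weighted_lipid_properties: mass percents must be non-negative")
  s <- sum(w)
  if (s < 95 || s > 105)
    stop("weighted_lipid_properties: mass percents sum to ", round(s, 3),
         ", outside tolerance [95, 105]")
  w <- w / s
  list(lipid_lipophilicity = sum(w * lipids$lipophilicity),
       lipid_polarity      = sum(w * lipids$polarity))
}

#' Validate and class a penetration dataset
#'
#' Checks a data.frame against the column dictionary (see
#' `dataset_columns()`), coerces the categorical columns to their level sets,
#' fills derived geometry where absent, and returns the frame classed
#' `penetration_records`. Empty cells are missing values; `depth` must be one
#' of the five ordered classes wherever observed.
#'
#' @param df data.frame in the documented flat layout.
#' @param derive If TRUE (default) recompute surface area, volume and
#'   surface-to-volume ratio from diameter and shape where they are missing.
#' @return The validated data.frame, classed `penetration_records`.
#' @export
penetration_records <- function(df, derive = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dataset_columns(), names(df))
  if (length(missing_cols))
    stop("penetration_records: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[dataset_columns()]

  check_levels <- function(x, levels, col) {
    x <- as.character(x)
    x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      rows <- which(bad)
      stop("penetration_records: column '", col, "' has unknown level(s) ",
           paste(unique(x[bad]), collapse = ", "),
           " (row ", paste(utils::head(rows, 5), collapse = ", "), ")")
    }
    factor(x, levels = levels)
  }
  df$shape   <- check_levels(df$shape, np_shape_levels(), "shape")
  df$medium  <- check_levels(df$medium, np_medium_levels(), "medium")
  df$np_class <- check_levels(df$np_class, np_class_levels(), "np_class")
  df$hydrophobicity_scale <-
    check_levels(df$hydrophobicity_scale, hydro_scale_levels(),
                 "hydrophobicity_scale")
  df$species <- check_levels(df$species, skin_species_levels(), "species")
  df$region  <- check_levels(df$region, skin_region_levels(), "region")
  df$depth   <- check_levels(df$depth, depth_levels(), "depth")
  df$in_vivo <- as.logical(df$in_vivo)

  num_cols <- setdiff(dataset_columns(),
                      c("source_id", "shape", "medium", "np_class",
                        "hydrophobicity_scale", "species", "region",
                        "in_vivo", "depth"))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])

  pos_cols <- c("core_diameter", "sc_thickness", "epidermis_thickness",
                "dermis_thickness", "contact_time")
  for (col in pos_cols) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop("penetration_records: non-positive '", col, "' in row ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  bad_t <- which(!is.na(df$temperature) &
                   (df$temperature < 15 | df$temperature > 45))
  if (length(bad_t))
    stop("penetration_records: temperature outside [15, 45] C in row ",
         paste(utils::head(bad_t, 5), collapse = ", "))
  bad_hf <- which(!is.na(df$hf_diameter) &
                    (df$hf_diameter < 5 | df$hf_diameter > 500))
  if (length(bad_hf))
    stop("penetration_records: hf_diameter outside plausibility band ",
         "[5, 500] um in row ", paste(utils::head(bad_hf, 5), collapse = ", "))

  if (derive) {
    for (i in seq_len(nrow(df))) {
      if (is.na(df$core_diameter[i]) || is.na(df$shape[i])) next
      need <- is.na(df$surface_area[i]) || is.na(df$volume[i]) ||
        is.na(df$sv_ratio[i])
      if (!need) next
      g <- suppressWarnings(derive_geometry(
        df$core_diameter[i], as.character(df$shape[i]), df$rod_length[i]))
      if (is.na(df$surface_area[i])) df$surface_area[i] <- g$surface_area
      if (is.na(df$volume[i]))       df$volume[i] <- g$volume
      if (is.na(df$sv_ratio[i]))     df$sv_ratio[i] <- g$sv_ratio
    }
  }
  rownames(df) <- NULL
  class(df) <- c("penetration_records", "data.frame")
  df
}

#' Read a penetration dataset from CSV
#'
#' UTF-8, comma-separated, header row, empty cell = missing. Rows that fail
#' validation are reported with their line numbers by the validator.
#'
#' @param path Path to the CSV file.
#' @return A `penetration_records` data.frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("read_dataset: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  penetration_records(df)
}

#' Write a penetration dataset to CSV
#'
#' @param records A `penetration_records` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(records, path) {
  stopifnot(inherits(records, "penetration_records"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.penetration_records <- function(x, ...) {
  cat("Penetration dataset:", nrow(x), "records\n")
  if (nrow(x)) {
    cat("  depth classes:",
        paste(sprintf("%s=%d", depth_levels(),
                      as.integer(table(x$depth)[depth_levels()])),
              collapse = " "), "\n")
    cat("  species:",
        paste(names(which(table(x$species) > 0)), collapse = ", "), "\n")
    nmiss <- sum(is.na(as.data.frame(x)[setdiff(names(x), "rod_length")]))
    cat("  missing cells (excl. rod_length):", nmiss, "\n")
  }
  invisible(x)
}
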