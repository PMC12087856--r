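# Feature encoding: records -> standardized numeric design matrix with a
# missingness mask. Log10 is applied to the size-like particle descriptors
# so all variables live on a comparable order of magnitude; categoricals are
# one-hot encoded over their full level sets so encodings are stable across
# datasets; hydrophobicity, reported on two incompatible scales (logKow for
# organic particles, contact angle for inorganic), is min-max normalised
# within each scale group into a single [0, 1] column plus a binary scale
# indicator that retains provenance.

log_feature_cols <- function() c("core_diameter", "surface_area", "volume",
                                 "concentration")
linear_feature_cols <- function() c("sv_ratio", "sc_thickness",
                                    "epidermis_thickness", "dermis_thickness",
                                    "hf_density", "hf_diameter",
                                    "lipid_lipophilicity", "lipid_polarity",
                                    "temperature", "contact_time")
onehot_feature_cols <- function() {
  list(medium = np_medium_levels(), np_class = np_class_levels(),
       shape = np_shape_levels(), species = skin_species_levels(),
       region = skin_region_levels(), in_vivo = c("FALSE", "TRUE"))
}

#' Encode a penetration dataset as a standardized feature matrix
#'
#' Builds the numeric design matrix used by every downstream stage. Numeric
#' descriptors are z-standardized (after log10 for core diameter, surface
#' area, volume and concentration); categoricals are one-hot encoded;
#' hydrophobicity is min-max normalised within its scale group and paired
#' with a contact-angle indicator column. Missing entries are flagged in a
#' boolean mask and left as NA in the value grid.
#'
#' Standardization and min-max parameters are fitted on the records passed
#' in unless `reference` (a previously fitted feature matrix) is supplied,
#' in which case its parameters and level sets are reused. Fit the encoding
#' on the modeling set only and reuse it for hold-out and in-silico data so
#' no information leaks into the evaluation.
#'
#' @param records A `penetration_records` data.frame.
#' @param reference Optional `feature_matrix` whose fitted parameters are
#'   reused.
#' @return A `feature_matrix`: list with `values` (matrix), `feature_names`,
#'   `missing_mask`, `encoding_map` (descriptor -> columns), `transform_log`
#'   (fitted parameters), `record_ids`, `depth`.
#' @export
encode_features <- function(records, reference = NULL) {
  stopifnot(inherits(records, "penetration_records"))
  n <- nrow(records)
  if (n == 0L) stop("encode_features: empty dataset")
  df <- as.data.frame(records)

  if (is.null(reference)) {
    params <- list()
    # per-scale-group min-max for hydrophobicity
    params$hydro_range <- lapply(hydro_scale_levels(), function(sc) {
      v <- df$hydrophobicity_value[!is.na(df$hydrophobicity_scale) &
                                     df$hydrophobicity_scale == sc]
      v <- v[is.finite(v)]
      if (!length(v)) return(c(0, 1))
      r <- range(v)
      if (diff(r) == 0) r[2] <- r[1] + 1
      r
    })
    names(params$hydro_range) <- hydro_scale_levels()
  } else {
    stopifnot(inherits(reference, "feature_matrix"))
    params <- reference$transform_log$params
  }

  cols <- list()
  mask <- list()
  encoding_map <- list()

  add_col <- function(name, values, group) {
    cols[[name]] <<- values
    mask[[name]] <<- is.na(values)
    encoding_map[[group]] <<- c(encoding_map[[group]], name)
  }

  for (col in log_feature_cols()) {
    v <- df[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("encode_features: non-positive value in log column '", col, "'")
    add_col(col, log10(v), col)
  }
  for (col in linear_feature_cols()) add_col(col, df[[col]], col)

  # hydrophobicity: normalised value + scale indicator
  hv <- rep(NA_real_, n)
  for (sc in hydro_scale_levels()) {
    idx <- which(!is.na(df$hydrophobicity_scale) &
                   df$hydrophobicity_scale == sc &
                   !is.na(df$hydrophobicity_value))
    if (length(idx)) {
      r <- params$hydro_range[[sc]]
      hv[idx] <- (df$hydrophobicity_value[idx] - r[1]) / (r[2] - r[1])
    }
  }
  add_col("hydrophobicity", hv, "hydrophobicity")
  ind <- ifelse(is.na(df$hydrophobicity_scale), NA_real_,
                as.numeric(df$hydrophobicity_scale == "contact_angle_deg"))
  add_col("hydro_scale_contact_angle", ind, "hydrophobicity")

  for (grp in names(onehot_feature_cols())) {
    levs <- onehot_feature_cols()[[grp]]
    x <- if (grp == "in_vivo") factor(as.character(df$in_vivo), levels = levs)
         else df[[grp]]
    for (lv in levs) {
      nm <- paste0(grp, ".", make.names(lv))
      add_col(nm, ifelse(is.na(x), NA_real_, as.numeric(x == lv)), grp)
    }
  }

  values <- do.call(cbind, cols)
  missing_mask <- do.call(cbind, mask)
  feature_names <- colnames(values)

  # z-standardization of the continuous columns only
  std_cols <- c(log_feature_cols(), linear_feature_cols(), "hydrophobicity")
  if (is.null(reference)) {
    params$center <- vapply(std_cols, function(cl)
      mean(values[, cl], na.rm = TRUE), numeric(1))
    params$scale <- vapply(std_cols, function(cl) {
      s <- stats::sd(values[, cl], na.rm = TRUE)
      if (!is.finite(s) || s == 0) 1 else s
    }, numeric(1))
    params$center[!is.finite(params$center)] <- 0
  }
  for (cl in std_cols)
    values[, cl] <- (values[, cl] - params$center[[cl]]) / params$scale[[cl]]

  structure(list(
    values = values,
    feature_names = feature_names,
    missing_mask = missing_mask,
    encoding_map = encoding_map,
    transform_log = list(log_cols = log_feature_cols(),
                         standardized = std_cols, params = params),
    record_ids = seq_len(n),
    depth = df$depth
  ), class = "feature_matrix")
}

#' Recover categorical levels from a feature matrix
#'
#' Inverts the one-hot encoding back to factors (NA where the group was
#' missing). Used for imputation of categoricals and for round-trip checks.
#'
#' @param fm A `feature_matrix`.
#' @return data.frame of factor columns, one per one-hot group.
#' @export
decode_categoricals <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- list()
  for (grp in names(onehot_feature_cols())) {
    levs <- onehot_feature_cols()[[grp]]
    sub <- fm$values[, fm$encoding_map[[grp]], drop = FALSE]
    idx <- apply(sub, 1, function(r)
      if (anyNA(r)) NA_integer_ else which.max(r))
    out[[grp]] <- factor(levs[idx], levels = levs)
  }
  as.data.frame(out)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "records x",
      ncol(x$values), "encoded features\n")
  cat("  missing cells:", sum(x$missing_mask), "\n")
  invisible(x)
}
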