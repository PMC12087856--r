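# Skin-parameter perturbation scenarios for route attribution. Baseline
# occupancy of the five layers is compared with three perturbations applied
# multiplicatively at 5/10/15/20%: (1) reduced hair follicle density
# (transappendageal probe), (2) increased SC lipid lipophilicity with
# decreased polarity (intercellular probe), (3) the polar reverse
# (intracellular probe). Shifts indicate preferred pathways only; no route
# is exclusively used.

scenario_ids <- function() c("baseline", "reduced_follicles",
                             "lipophilic_shift", "polar_shift")

# multiplicative field effects per unit (1 + m/100) of magnitude
scenario_effects <- function(id) {
  switch(id,
    baseline = list(),
    reduced_follicles = list(hf_density = -1),
    lipophilic_shift = list(lipid_lipophilicity = +1, lipid_polarity = -1),
    polar_shift = list(lipid_lipophilicity = -1, lipid_polarity = +1))
}

#' Scenario specification
#'
#' @param id One of "baseline", "reduced_follicles", "lipophilic_shift",
#'   "polar_shift".
#' @param magnitude Percent perturbation in {0, 5, 10, 15, 20}; baseline
#'   must be 0.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(id = scenario_ids(), magnitude = 0) {
  id <- match.arg(id)
  if (!magnitude %in% c(0, 5, 10, 15, 20))
    stop("scenario_spec: magnitude must be one of 0, 5, 10, 15, 20")
  if (id == "baseline" && magnitude != 0)
    stop("scenario_spec: baseline has magnitude 0")
  if (id != "baseline" && magnitude == 0)
    stop("scenario_spec: perturbation scenarios need magnitude > 0")
  structure(list(id = id, magnitude = magnitude,
                 effects = scenario_effects(id)),
            class = "scenario_spec")
}

#' Apply a scenario to skin descriptors
#'
#' Multiplies only the scenario's fields by (1 +/- magnitude/100); all
#' other fields are untouched. `revert_scenario` divides by the same
#' factors, recovering the unperturbed skin exactly.
#'
#' @param skin data.frame (or one-row record) holding skin descriptor
#'   columns.
#' @param spec A `scenario_spec`.
#' @return The perturbed skin data.
#' @export
apply_scenario <- function(skin, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- skin
  for (field in names(spec$effects)) {
    fac <- 1 + spec$effects[[field]] * spec$magnitude / 100
    v <- out[[field]] * fac
    if (any(v <= 0, na.rm = TRUE))
      stop("apply_scenario: perturbation drives '", field, "' non-positive")
    out[[field]] <- v
  }
  out
}

#' @rdname apply_scenario
#' @export
revert_scenario <- function(skin, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- skin
  for (field in names(spec$effects))
    out[[field]] <- out[[field]] /
      (1 + spec$effects[[field]] * spec$magnitude / 100)
  out
}

#' Run the route-attribution perturbation experiment
#'
#' For every medium group (aqueous, emulsion, oil) and every scenario x
#' magnitude cell, perturbs the population's skin context, re-encodes it
#' with the reference encoding, predicts the penetrated layer of every
#' particle, and tabulates per-layer occupancy percentages and their
#' deltas versus baseline. Fully deterministic given model and population.
#'
#' @param model A `qspr_model`.
#' @param population An `insilico_population` whose records carry medium
#'   labels covering the three groups.
#' @param reference The `feature_matrix` whose encoding is reused.
#' @param magnitudes Perturbation magnitudes (default 5, 10, 15, 20).
#' @return A `scenario_result`: long data.frame (medium, scenario,
#'   magnitude, layer, occupancy, delta).
#' @export
run_route_experiment <- function(model, population, reference,
                                 magnitudes = c(5, 10, 15, 20)) {
  stopifnot(inherits(population, "insilico_population"))
  records <- population$records
  media <- c("aqueous", "emulsion", "oil")
  present <- media %in% unique(as.character(records$medium))
  if (!all(present))
    stop("run_route_experiment: empty medium group(s): ",
         paste(media[!present], collapse = ", "))

  specs <- list(scenario_spec("baseline", 0))
  for (id in setdiff(scenario_ids(), "baseline"))
    for (m in magnitudes) specs[[length(specs) + 1L]] <- scenario_spec(id, m)

  occupancy_rows <- list()
  for (spec in specs) {
    skin_cols <- names(spec$effects)
    pert <- records
    if (length(skin_cols)) pert <- apply_scenario(pert, spec)
    fm <- encode_features(pert, reference = reference)
    pred <- stats::predict(model, fm$values)
    for (med in media) {
      idx <- as.character(records$medium) == med
      tab <- table(factor(pred[idx], levels = depth_levels()))
      occ <- 100 * as.numeric(tab) / sum(idx)
      occupancy_rows[[length(occupancy_rows) + 1L]] <- data.frame(
        medium = med, scenario = spec$id, magnitude = spec$magnitude,
        layer = depth_levels(), occupancy = occ)
    }
  }
  out <- do.call(rbind, occupancy_rows)
  base <- out[out$scenario == "baseline",
              c("medium", "layer", "occupancy")]
  names(base)[3] <- "baseline_occupancy"
  out <- merge(out, base, by = c("medium", "layer"), sort = FALSE)
  out$delta <- out$occupancy - out$baseline_occupancy
  out <- out[order(match(out$scenario, scenario_ids()), out$magnitude,
                   match(out$medium, media),
                   match(out$layer, depth_levels())),
             c("medium", "scenario", "magnitude", "layer", "occupancy",
               "delta")]
  rownames(out) <- NULL
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' Qualitative route-preference attribution
#'
#' Rule-based reading of a `scenario_result`: per medium, sensitivity (max
#' absolute occupancy delta over magnitudes and layers) to the reduced-
#' follicle scenario indicates transappendageal reliance; sensitivity to
#' the lipophilic shift indicates intercellular preference; sensitivity to
#' the polar shift indicates intracellular preference. Deltas are always
#' reported alongside the labels -- shifts indicate preferred pathways, not
#' exclusive routes.
#'
#' @param result A `scenario_result`.
#' @param threshold Minimum max-|delta| (percentage points) for a route to
#'   be called (default 0.5).
#' @return A `route_attribution` data.frame: medium, route, scenario,
#'   max_abs_delta, inferred.
#' @export
route_attribution <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "scenario_result"))
  need <- setdiff(scenario_ids(), "baseline")
  have <- unique(result$scenario)
  if (!all(need %in% have))
    stop("route_attribution: result must cover scenarios ",
         paste(need, collapse = ", "))
  route_of <- c(reduced_follicles = "transappendageal",
                lipophilic_shift = "intercellular",
                polar_shift = "intracellular")
  rows <- list()
  for (med in unique(result$medium)) {
    for (sc in need) {
      sub <- result[result$medium == med & result$scenario == sc, ]
      mx <- max(abs(sub$delta))
      rows[[length(rows) + 1L]] <- data.frame(
        medium = med, route = route_of[[sc]], scenario = sc,
        max_abs_delta = mx, inferred = mx >= threshold)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("route_attribution", "data.frame")
  out
}

#' @export
print.route_attribution <- function(x, ...) {
  cat("Route preference attribution (shifts indicate preferred pathways,",
      "not exclusive use):\n")
  for (med in unique(x$medium)) {
    sub <- x[x$medium == med & x$inferred, ]
    lbl <- if (nrow(sub)) paste0(sub$route, " (max |delta| ",
                                 round(sub$max_abs_delta, 2), " pp)",
                                 collapse = ", ")
           else "no inferred preference"
    cat(" ", med, ": ", lbl, "\n", sep = "")
  }
  invisible(x)
}
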