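# Cross-species skin similarity: signed percent differences of each
# species' skin layers versus human, and a Euclidean-distance similarity
# matrix over z-standardized thickness vectors. Standardization before the
# distance is deliberate: raw-scale distances would be dominated by dermis
# thickness, which is two orders of magnitude larger than the SC.

#' Signed percent difference versus a reference value
#'
#' 100 * (other - reference) / reference.
#'
#' @param reference Reference value (> 0).
#' @param other Comparison value.
#' @return Signed percent difference.
#' @export
percent_difference <- function(reference, other) {
  if (any(reference == 0)) stop("percent_difference: zero reference")
  100 * (other - reference) / reference
}

#' Cross-species skin similarity for one body region
#'
#' Builds per-species vectors of SC, epidermis and dermis thickness for
#' the requested region, z-standardizes each layer across species, and
#' computes the pairwise Euclidean distance matrix plus each species'
#' ranking by distance to human. Percent differences versus human are
#' reported per layer and for hair follicle diameter. Species missing a
#' layer value are dropped with a warning.
#'
#' @param table A `skin_reference` data.frame (default: built-in).
#' @param region Body region (default "back").
#' @return A `similarity_report`: list with `percent_differences`,
#'   `distance` (symmetric matrix), `ranking` (species ordered by distance
#'   to human), `region`.
#' @export
species_similarity <- function(table = builtin_skin_reference(),
                               region = "back") {
  sub <- table[table$region == region, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("species_similarity: region '", region,
         "' present for fewer than 2 species")
  layers <- c("sc_thickness", "epidermis_thickness", "dermis_thickness")
  ok <- stats::complete.cases(sub[layers])
  if (any(!ok)) {
    warning("species_similarity: dropping species with missing layers: ",
            paste(sub$species[!ok], collapse = ", "))
    sub <- sub[ok, , drop = FALSE]
  }
  if (!"human" %in% sub$species)
    stop("species_similarity: human reference missing for region '",
         region, "'")
  M <- as.matrix(sub[layers])
  rownames(M) <- sub$species
  Z <- scale(M)
  # a layer constant across species carries no information; drop its NaNs
  Z[, !is.finite(colSums(Z))] <- 0
  D <- as.matrix(stats::dist(Z))

  href <- sub[sub$species == "human", ]
  pd <- data.frame(species = sub$species)
  for (l in c(layers, "hf_diameter"))
    pd[[l]] <- percent_difference(href[[l]], sub[[l]])
  ranking <- names(sort(D["human", ]))

  structure(list(percent_differences = pd, distance = D, ranking = ranking,
                 region = region), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Skin similarity (", x$region, " region), distance to human:\n",
      sep = "")
  d <- sort(x$distance["human", ])
  for (sp in names(d))
    cat(sprintf("  %-7s %.3f\n", sp, d[[sp]]))
  invisible(x)
}
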