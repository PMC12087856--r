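# Shared fixtures, built in code. Heavier objects are computed once per
# test run and reused.

# small complete noiseless dataset + encoding (separable planted rule)
fixture_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_records = 300, seed = 11,
                              missingness = c(),
                              rule = planted_rule(noise_sd = 0))
      rec <- generate_dataset(cfg)
      fm <- encode_features(rec)
      cache <<- list(cfg = cfg, records = rec, fm = fm)
    }
    cache
  }
})

# default-condition dataset (moderate label noise + missingness), imputed
fixture_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_records = 300, seed = 21)
      rec <- generate_dataset(cfg)
      fm <- encode_features(rec)
      fmc <- pool_completed(mice_impute(fm, m = 2, n_iterations = 5,
                                        seed = 1), "mean")
      cache <<- list(cfg = cfg, records = rec, fm = fm, fmc = fmc)
    }
    cache
  }
})

# minimal hand-written record rows for I/O tests
tiny_records_df <- function() {
  g1 <- derive_geometry(100, "sphere")
  g2 <- derive_geometry(20, "rod", 80)
  g3 <- derive_geometry(50, "sphere")
  data.frame(
    source_id = c("a", "b", "c"),
    core_diameter = c(100, 20, 50), shape = c("sphere", "rod", "sphere"),
    rod_length = c(NA, 80, NA),
    surface_area = c(g1$surface_area, g2$surface_area, g3$surface_area),
    volume = c(g1$volume, g2$volume, g3$volume),
    sv_ratio = c(g1$sv_ratio, g2$sv_ratio, g3$sv_ratio),
    concentration = c(10, 200, 50),
    medium = c("aqueous", "oil", "emulsion"),
    np_class = c("inorganic", "polymeric", "other"),
    hydrophobicity_value = c(45, 2.5, -0.5),
    hydrophobicity_scale = c("contact_angle_deg", "logKow", "logKow"),
    species = c("human", "pig", "rat"),
    region = c("back", "ear", "back"),
    sc_thickness = c(17, 21, 36), epidermis_thickness = c(85, 55, 29),
    dermis_thickness = c(2400, 1300, 370),
    hf_density = c(29, 15, 289), hf_diameter = c(140.3, 105, 14),
    lipid_lipophilicity = c(6.2, 6.0, 5.6),
    lipid_polarity = c(35, 38, 42),
    temperature = c(32, 37, 25), contact_time = c(24, 6, 48),
    in_vivo = c(FALSE, TRUE, FALSE),
    depth = c("Surface", "Dermis", "SC"),
    stringsAsFactors = FALSE)
}

# independent brute-force Kennard-Stone: explicit max-min scan with
# lowest-index tie-break, no shared code with the implementation
brute_kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  ed <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- NULL; bestd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- ed(i, j)
    if (d > bestd + 1e-12) { bestd <- d; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_select) {
    cand <- setdiff(1:n, sel)
    score <- sapply(cand, function(p) min(sapply(sel, function(s) ed(p, s))))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# independent tie-corrected Kruskal-Wallis H (textbook formula)
brute_kw_h <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# independent Cohen's kappa via observed/expected agreement
brute_kappa <- function(cm) {
  N <- sum(cm)
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

# exhaustive convex-hull membership in 3-D: a point is inside iff it lies
# on the inner side of every supporting plane through a point triplet
brute_hull3d_contains <- function(P, q, tol = 1e-9) {
  P <- as.matrix(P)
  n <- nrow(P)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- P[j, ] - P[i, ]; v <- P[k, ] - P[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    nrm <- nrm / nn
    s <- drop(P %*% nrm) - sum(nrm * P[i, ])
    if (all(s <= tol)) { # supporting plane, inner side is <=
      if (sum(nrm * q) - sum(nrm * P[i, ]) > tol) return(FALSE)
    } else if (all(s >= -tol)) {
      if (sum(nrm * q) - sum(nrm * P[i, ]) < -tol) return(FALSE)
    }
  }
  TRUE
}

# a minimal model whose predictions deepen with hair-follicle density:
# constructed oracle for the perturbation engine
monotone_hf_model <- function() {
  structure(list(), class = "hfdepth_model")
}
predict.hfdepth_model <- function(object, newdata, ...) {
  s <- 3 * newdata[, "hf_density"] + 0.5 * newdata[, "core_diameter"]
  cut(s, breaks = c(-Inf, -1, 0, 1, 2, Inf), labels = depth_levels())
}
registerS3method("predict", "hfdepth_model", predict.hfdepth_model)
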