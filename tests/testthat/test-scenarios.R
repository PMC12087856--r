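test_that("scenario specs validate their magnitude grammar", {
  expect_error(scenario_spec("baseline", 10), "magnitude 0")
  expect_error(scenario_spec("reduced_follicles", 0), "magnitude > 0")
  expect_error(scenario_spec("reduced_follicles", 7), "one of")
  expect_silent(scenario_spec("polar_shift", 15))
})

test_that("scenarios perturb exactly their stated fields, multiplicatively", {
  skin <- data.frame(sc_thickness = 17, hf_density = 29, hf_diameter = 140.3,
                     lipid_lipophilicity = 6.2, lipid_polarity = 35)
  base <- apply_scenario(skin, scenario_spec("baseline", 0))
  expect_identical(base, skin)

  lip <- apply_scenario(skin, scenario_spec("lipophilic_shift", 10))
  expect_equal(lip$lipid_lipophilicity, 6.2 * 1.10)
  expect_equal(lip$lipid_polarity, 35 * 0.90)
  expect_equal(lip$hf_density, skin$hf_density)

  rf <- apply_scenario(skin, scenario_spec("reduced_follicles", 20))
  expect_equal(rf$hf_density, 29 * 0.8)
  expect_equal(rf[setdiff(names(rf), "hf_density")],
               skin[setdiff(names(skin), "hf_density")])

  pol <- apply_scenario(skin, scenario_spec("polar_shift", 5))
  expect_equal(pol$lipid_lipophilicity, 6.2 * 0.95)
  expect_equal(pol$lipid_polarity, 35 * 1.05)

  skin0 <- skin; skin0$hf_density <- 0
  expect_error(apply_scenario(skin0, scenario_spec("reduced_follicles", 5)),
               "non-positive")
})

test_that("applying then reverting a scenario recovers the baseline exactly", {
  skin <- data.frame(hf_density = 29.37, lipid_lipophilicity = 6.2345,
                     lipid_polarity = 35.71)
  for (id in c("reduced_follicles", "lipophilic_shift", "polar_shift"))
    for (m in c(5, 10, 15, 20)) {
      sp <- scenario_spec(id, m)
      back <- revert_scenario(apply_scenario(skin, sp), sp)
      expect_equal(back, skin, tolerance = 1e-12)
    }
})

test_that("occupancies close to 100% and baseline deltas vanish", {
  fx <- fixture_noiseless()
  fm <- fx$fm
  m <- train_classifier(classifier_spec("decision_tree", seed = 1),
                        fm$values, fm$depth)
  pop <- generate_insilico(fx$records, n = 600, seed = 3)
  res <- run_route_experiment(m, pop, fm, magnitudes = c(10, 20))
  sums <- tapply(res$occupancy,
                 paste(res$medium, res$scenario, res$magnitude), sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_true(all(res$delta[res$scenario == "baseline"] == 0))
  expect_setequal(unique(res$scenario), scenario_ids())
})

test_that("a monotone model shifts occupancy shallower as follicles shrink", {
  fx <- fixture_noiseless()
  fm <- fx$fm
  pop <- generate_insilico(fx$records, n = 800, seed = 4)
  res <- run_route_experiment(monotone_hf_model(), pop, fm)
  # weighted mean depth decreases monotonically with magnitude
  depth_rank <- stats::setNames(seq_along(depth_levels()), depth_levels())
  for (med in c("aqueous", "emulsion", "oil")) {
    md <- sapply(c(0, 5, 10, 15, 20), function(mag) {
      sub <- res[res$medium == med & res$magnitude == mag &
                   res$scenario %in% c("baseline", "reduced_follicles"), ]
      sum(sub$occupancy * depth_rank[sub$layer]) / 100
    })
    expect_true(all(diff(md) <= 1e-9), info = med)
  }
})

test_that("scenario results are invariant to population row order", {
  fx <- fixture_noiseless()
  fm <- fx$fm
  m <- train_classifier(classifier_spec("decision_tree", seed = 1),
                        fm$values, fm$depth)
  pop <- generate_insilico(fx$records, n = 300, seed = 5)
  set.seed(6)
  perm <- sample(300)
  pop2 <- pop
  pop2$records <- pop$records[perm, ]
  class(pop2$records) <- class(pop$records)
  r1 <- run_route_experiment(m, pop, fm, magnitudes = 10)
  r2 <- run_route_experiment(m, pop2, fm, magnitudes = 10)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("route attribution fires rules on constructed patterns", {
  mk <- function(deltas) {
    rows <- expand.grid(medium = c("aqueous", "emulsion", "oil"),
                        scenario = scenario_ids(),
                        magnitude = c(0, 10), layer = depth_levels(),
                        stringsAsFactors = FALSE)
    rows <- rows[(rows$scenario == "baseline") == (rows$magnitude == 0), ]
    rows$occupancy <- 20
    rows$delta <- 0
    for (i in seq_len(nrow(deltas)))
      rows$delta[rows$medium == deltas$medium[i] &
                   rows$scenario == deltas$scenario[i] &
                   rows$layer == "SC" & rows$magnitude > 0] <-
        deltas$delta[i]
    class(rows) <- c("scenario_result", "data.frame")
    rows
  }
  # zero deltas everywhere: nothing inferred
  att0 <- route_attribution(mk(data.frame(medium = character(0),
                                          scenario = character(0),
                                          delta = numeric(0))))
  expect_false(any(att0$inferred))

  # large SC accumulation under reduced follicles only
  att1 <- route_attribution(mk(data.frame(medium = "oil",
                                          scenario = "reduced_follicles",
                                          delta = 5)))
  expect_true(att1$inferred[att1$medium == "oil" &
                              att1$route == "transappendageal"])
  expect_false(any(att1$inferred[att1$route != "transappendageal"]))

  # published pattern: emulsion/oil sensitive to scenarios 1-2,
  # aqueous to scenario 3
  pat <- data.frame(
    medium = c("emulsion", "oil", "emulsion", "oil", "aqueous"),
    scenario = c("reduced_follicles", "reduced_follicles",
                 "lipophilic_shift", "lipophilic_shift", "polar_shift"),
    delta = c(4, 4, 5, 5, 3))
  att2 <- route_attribution(mk(pat))
  inferred <- att2[att2$inferred, ]
  expect_setequal(
    paste(inferred$medium, inferred$route),
    c("emulsion transappendageal", "oil transappendageal",
      "emulsion intercellular", "oil intercellular",
      "aqueous intracellular"))
})
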