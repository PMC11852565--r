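scenario_fix <- campaign_scenario()

score_sim <- function(epitope_map, affinities = NULL, noise_sd = 0, seed = 1,
                      eps_block = 0.05) {
  if (is.null(affinities)) {
    affinities <- stats::setNames(rep(5, length(epitope_map)), names(epitope_map))
  }
  sim <- gen_competition(epitope_map, affinities, noise_sd = noise_sd,
                         eps_block = eps_block, seed = seed)
  lapply(plates_to_experiments(sim$plates), score_competition)
}

test_that("self-competition scores exactly zero and classifies same-epitope", {
  scores <- score_sim(c(a = "e1", b = "e2"), noise_sd = 0.02, seed = 3)
  for (s in scores) {
    self <- s[s$analyte == s$capture, ]
    expect_equal(self$corrected_auc, 0)
    expect_equal(self$percent_binding, 0)
    expect_equal(self$classification, "same_epitope")
  }
})

test_that("percent binding is invariant under uniform absorbance rescaling", {
  sim <- gen_competition(scenario_fix$epitope_map, scenario_fix$affinities,
                         capture_set = "F9", noise_sd = 0.02, seed = 11)
  p1 <- sim$plates
  p2 <- p1
  p2$a450 <- p1$a450 * 2.7
  p2$blank <- p1$blank * 2.7
  s1 <- score_competition(plates_to_experiments(p1)[[1]])
  s2 <- score_competition(plates_to_experiments(p2)[[1]])
  expect_equal(s2$percent_binding, s1$percent_binding, tolerance = 1e-10)
})

test_that("higher analyte occupancy never lowers percent binding (noiseless)", {
  map <- c(cap = "e1", probe = "e2", strong = "e2")
  # increasing occupancy: tighter EC50 raises the probe's curve everywhere
  pct2 <- vapply(c(50, 20, 8, 2), function(e50) {
    aff <- c(cap = 5, probe = e50, strong = 2)
    sim <- gen_competition(map, aff, capture_set = "cap", noise_sd = 0, seed = 1)
    s <- score_competition(plates_to_experiments(sim$plates)[[1]])
    s$percent_binding[s$analyte == "probe"]
  }, numeric(1))
  expect_true(all(diff(pct2) >= -1e-9))
})

test_that("the published qualitative pattern yields the three reported bins", {
  ba <- infer_bins(campaign_competition_calls())
  expect_equal(length(unique(ba$bins)), 3)
  expect_setequal(partition_of(ba$bins),
                  c("C1", "C7,F9", "D9,E6,F1,F8,G10,G7"))
  expect_equal(nrow(ba$conflicts), 0)
})

test_that("noiseless synthetic plates recover the planted nine-clone partition", {
  scores <- score_sim(scenario_fix$epitope_map, scenario_fix$affinities,
                      noise_sd = 0, seed = 2)
  ba <- infer_bins(scores)
  expect_setequal(partition_of(ba$bins), partition_of(scenario_fix$epitope_map))
})

test_that("bins equal the transitive closure over all small epitope maps", {
  # exhaustive: every partition of 3 and 4 clones, complete capture coverage.
  # The denominator is the tightest binder's direct-ELISA area (the global
  # normalization option): with the in-plate maximum, a map where every
  # clone shares one epitope has no unblocked analyte to normalize against.
  for (clones in list(c("a", "b", "c"), c("a", "b", "c", "d"))) {
    aff <- stats::setNames(seq(2, 10, length.out = length(clones)), clones)
    ref <- max(vapply(clones, function(cl) {
      auc_logdose(dose_response_curve(cl, "direct", default_dose_grid(),
                                      fourpl(default_dose_grid(), 0, 1.8,
                                             aff[[cl]], 1) + 0.05,
                                      blank = 0.05))
    }, numeric(1)))
    for (map in all_epitope_maps(clones)) {
      sim <- gen_competition(map, aff, noise_sd = 0, seed = 1)
      scores <- lapply(plates_to_experiments(sim$plates), score_competition,
                       reference_auc = ref)
      ba <- infer_bins(scores)
      expect_setequal(partition_of(ba$bins), partition_of(map))
    }
  }
})

test_that("no same-epitope evidence leaves every clone in its own bin", {
  calls <- data.frame(capture = "a", analyte = c("a", "b", "c"),
                      classification = c("same_epitope", "different_epitope",
                                         "different_epitope"))
  ba <- infer_bins(calls)
  expect_equal(partition_of(ba$bins), c("a", "b", "c"))

  # eps_block = 1 (no blocking at all): singletons, including self-noise case
  scores <- score_sim(c(x = "e1", y = "e1", z = "e2"), eps_block = 1, seed = 4)
  ba2 <- infer_bins(scores)
  expect_equal(length(unique(ba2$bins)), 3)
})

test_that("conflicting same/different evidence keeps the edge but is flagged", {
  calls <- rbind(
    data.frame(capture = "a", analyte = c("a", "b"),
               classification = c("same_epitope", "same_epitope")),
    data.frame(capture = "b", analyte = c("b", "a"),
               classification = c("same_epitope", "different_epitope")))
  ba <- infer_bins(calls)
  expect_equal(unname(ba$bins["a"]), unname(ba$bins["b"]))
  expect_equal(nrow(ba$conflicts), 1)
})

test_that("indeterminate zone calls are reported, not forced into bins", {
  expect_error(binning_thresholds(60, 25))
  # constant-signal analytes put percent binding exactly where we want it:
  # self at blank (0%), mid at 40% of far, far at 100%
  doses <- c(1, 10, 100, 1000)
  curves <- list(
    self = dose_response_curve("self", "cap", doses, rep(0.05, 4), blank = 0.05),
    mid = dose_response_curve("mid", "cap", doses, rep(0.45, 4), blank = 0.05),
    far = dose_response_curve("far", "cap", doses, rep(1.05, 4), blank = 0.05))
  s <- score_competition(competition_experiment("self", curves))
  expect_equal(s$percent_binding[s$analyte == "mid"], 40, tolerance = 1e-10)
  expect_equal(s$classification[s$analyte == "mid"], "indeterminate")
  expect_equal(s$classification[s$analyte == "far"], "different_epitope")
  ba <- infer_bins(list(s))
  expect_equal(length(unique(ba$bins)), 3)   # mid not merged into self's bin
  expect_equal(nrow(ba$indeterminate), 1)
})

test_that("transitivity-only pairs are surfaced", {
  calls <- data.frame(capture = c("a", "b"), analyte = c("b", "c"),
                      classification = "same_epitope")
  ba <- infer_bins(calls)
  expect_equal(length(unique(ba$bins)), 1)
  expect_equal(nrow(ba$transitive_pairs), 1)
  expect_setequal(unlist(ba$transitive_pairs[1, ]), c("a", "c"))
})

test_that("an experiment where nothing binds is flagged unusable", {
  flat <- lapply(c(a = "a", b = "b"), function(cl) {
    dose_response_curve(cl, "cap_a", c(1, 10, 100, 1000), rep(0.05, 4), blank = 0.05)
  })
  ex <- competition_experiment("a", flat)
  s <- score_competition(ex)
  expect_true(all(!s$usable))
  expect_true(all(is.na(s$percent_binding[s$analyte != "a"])))
  expect_equal(s$percent_binding[s$analyte == "a"], 0)
})

test_that("binning report lays out captures by analytes with zero self cells", {
  scores <- score_sim(scenario_fix$epitope_map, scenario_fix$affinities,
                      noise_sd = 0, seed = 6)
  rep3 <- binning_report(scores[c("C1", "E6", "F9")])
  expect_equal(dim(rep3$matrix), c(3, 9))
  for (cap in rownames(rep3$matrix)) expect_equal(rep3$matrix[cap, cap], 0)
  expect_setequal(rep3$bin_table$clone, names(scenario_fix$epitope_map))

  solo <- competition_experiment("a", list(
    a = dose_response_curve("a", "cap_a", c(1, 10, 100, 1000),
                            c(0.1, 0.3, 0.8, 1.2), blank = 0.05)))
  rep1 <- binning_report(list(score_competition(solo)))
  expect_equal(dim(rep1$matrix), c(1, 1))
  expect_equal(rep1$matrix[1, 1], 0)
})
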