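test_that("build_design lays out the full factorial spot grid", {
  spec <- design_spec(n_mice_per_group = 8, regions = "hippocampus",
                      fractions = "nuclear", proteins = c("A", "B"))
  des <- build_design(spec, seed = 3)
  expect_equal(nrow(des$mice), 64) # 8 groups x 8 mice
  expect_equal(sort(unique(des$mice$label)), sort(rppa_groups()$label))
  expect_equal(as.integer(table(des$mice$label)), rep(8L, 8))
  # 2 proteins x 1 region x 1 fraction x 64 mice x 5 dilutions x 3 replicates
  expect_equal(nrow(des$spots), 2 * 64 * 15)
  per_mouse <- table(des$spots$mouse_id, des$spots$protein)
  expect_true(all(per_mouse == 15))
})

test_that("design construction is deterministic given the seed", {
  spec <- design_spec(n_mice_per_group = c(7, 10), regions = "hippocampus",
                      fractions = "nuclear", proteins = "A")
  d1 <- build_design(spec, seed = 11)
  d2 <- build_design(spec, seed = 11)
  d3 <- build_design(spec, seed = 12)
  expect_identical(d1$mice, d2$mice)
  expect_identical(d1$spots, d2$spots)
  expect_false(identical(d1$mice, d3$mice)) # unbalanced draw uses the seed
  sizes <- table(d1$mice$label)
  expect_true(all(sizes >= 7 & sizes <= 10))
})

test_that("invalid design parameters are rejected", {
  expect_error(design_spec(n_mice_per_group = 0), "n_mice_per_group")
  expect_error(design_spec(n_proteins = 0), "n_proteins")
  expect_error(design_spec(n_dilution_steps = 0), "dilution steps")
  expect_error(design_spec(dilution_factor = -1), "dilution_factor")
})

test_that("archetype group means reproduce the planted contrasts exactly", {
  cases <- list(
    list("FL_EQ_NL", 20, 0,  c(NL = 20, FL = 20, B = 0, RL = 20, `B-tm` = 0)),
    list("B_COMP", 20, 20,   c(NL = 20, FL = 0, B = 20, RL = 0, `B-tm` = 0)),
    list("STABLE", 0, 0,     c(NL = 0, FL = 0, B = 0, RL = 0, `B-tm` = 0)),
    list("B_PLUS_FL", 40, 15, c(NL = 40, FL = 25, B = 15, RL = 25, `B-tm` = 0)),
    list("BTM_PLUS_RL", 40, 15, c(NL = 40, FL = 0, B = 0, RL = 25, `B-tm` = 15)),
    list("B_ABN_COMP_FL", 0, 20, c(NL = 0, FL = -20, B = 20, RL = -20, `B-tm` = 0))
  )
  for (cs in cases) {
    means <- archetype_to_effects(cs[[1]], cs[[2]], cs[[3]])
    expect_true(all(means > 0))
    got <- contrasts_from_means(means)
    expect_equal(got[names(cs[[4]])], cs[[4]], tolerance = 1e-12,
                 info = cs[[1]])
  }
  # the worked FL_EQ_NL example: explicit mean values
  m <- archetype_to_effects("FL_EQ_NL", 20)
  expect_equal(unname(m[c("c-SC-sal", "c-CS-sal", "t-SC-sal", "t-CS-sal",
                          "t-SC-mem", "t-CS-mem")]),
               c(1, 1.2, 1, 1.2, 1, 1.2))
})

test_that("archetype contrasts honour the planted magnitudes", {
  nl_anchored <- c("FL_EQ_NL", "B_COMP", "B_PLUS_FL", "RL_EQ_NL", "BTM_COMP",
                   "BTM_PLUS_RL", "RL_PLUS_B", "RL_PLUS_B_PLUS_BTM")
  for (a in pattern_archetypes()) {
    ct <- contrasts_from_means(archetype_to_effects(a, 30, 12))
    expect_true(all(is.finite(ct)), info = a)
    expect_equal(unname(ct["B-cm"]), 0, info = a) # memantine inert in controls
    if (a %in% nl_anchored) {
      expect_equal(unname(ct["NL"]), 30, tolerance = 1e-12, info = a)
      # the classifier's additive identity: significant terms sum to NL
      terms <- ct[c("FL", "B", "RL", "B-tm")]
      if (a %in% c("FL_EQ_NL", "RL_EQ_NL")) {
        expect_equal(unname(ct[sub("_EQ_NL", "", sub("BTM", "B-tm", a))]), 30,
                     tolerance = 1e-12, info = a)
      }
      if (a == "B_PLUS_FL") {
        expect_equal(unname(ct["B"] + ct["FL"]), 30, tolerance = 1e-12)
      }
      if (a %in% c("BTM_PLUS_RL", "RL_PLUS_B", "RL_PLUS_B_PLUS_BTM",
                   "BTM_COMP")) {
        expect_equal(unname(ct["B"] + ct["B-tm"] + ct["RL"]), 30,
                     tolerance = 1e-12, info = a)
      }
    } else {
      expect_equal(unname(ct["NL"]), 0, tolerance = 1e-12, info = a)
    }
  }
  expect_error(archetype_to_effects("NOT_A_CODE", 10), "valid codes")
})

test_that("zero-noise simulation reproduces planted means spot-for-spot", {
  spec <- tiny_spec(proteins = c("A", "B"))
  asg <- plant(spec, "B_PLUS_FL", nl = 40, b = 15)
  meas <- simulate_planted(spec, asg, zero_noise(), seed = 5)
  norm <- normalize_to_total_protein(meas)
  eff <- effect_table(spec, asg)
  key_m <- paste(norm$protein, norm$region, norm$fraction,
                 group_label(norm$genotype, norm$paradigm, norm$drug))
  key_e <- paste(eff$protein, eff$region, eff$fraction, eff$label)
  expect_equal(norm$normalized_intensity, eff$true_mean[match(key_m, key_e)],
               tolerance = 1e-12)
  # independent of dilution step
  expect_equal(length(unique(round(norm$normalized_intensity[
    norm$protein == "A" & key_m == key_m[1]], 12))), 1)
})

test_that("simulation is byte-identical under the same seed", {
  spec <- tiny_spec(proteins = c("A", "B"))
  m1 <- simulate_planted(spec, NULL, noise_spec(), seed = 42)
  m2 <- simulate_planted(spec, NULL, noise_spec(), seed = 42)
  m3 <- simulate_planted(spec, NULL, noise_spec(), seed = 43)
  expect_identical(m1, m2)
  expect_false(identical(m1$raw_intensity, m3$raw_intensity))
})

test_that("missing effect entries are reported by instance", {
  spec <- tiny_spec(proteins = c("A", "B"))
  des <- build_design(spec, seed = 1)
  eff <- effect_table(spec)
  eff <- eff[eff$protein != "B", ]
  expect_error(simulate_measurements(des, eff, noise_spec(), seed = 1), "B")
})

test_that("a silenced protein instance falls below the reliability floor", {
  spec <- tiny_spec(proteins = "A")
  meas <- simulate_planted(spec, NULL,
                           noise_spec(low_signal_rate = 1), seed = 2)
  norm <- preprocess(meas)
  expect_true(all(norm$qc_low_signal))
  expect_equal(nrow(clean_spots(norm)), 0)
  res <- try(fit_all_comparisons(norm), silent = TRUE)
  expect_s3_class(res, "try-error") # nothing reaches the model
})

test_that("measurement tables round-trip through TSV", {
  spec <- tiny_spec(proteins = "A", n_mice = 2)
  meas <- simulate_planted(spec, NULL, noise_spec(), seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(meas, path)
  back <- read_measurements(path)
  expect_equal(back$raw_intensity, meas$raw_intensity, tolerance = 1e-12)
  expect_identical(back$mouse_id, meas$mouse_id)
})
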