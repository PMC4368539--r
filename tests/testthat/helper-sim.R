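# Small-design builders shared across test files, plus the independent
# nested means-of-means oracle used to cross-check the mixed-model estimator.

tiny_spec <- function(proteins = "A", n_mice = 3,
                      regions = "hippocampus", fractions = "nuclear") {
  design_spec(n_mice_per_group = n_mice, regions = regions,
              fractions = fractions, proteins = proteins)
}

# one-archetype assignment table for every protein of a spec
plant <- function(spec, archetype, nl = 0, b = 0) {
  expand.grid(protein = spec$proteins, region = spec$regions,
              fraction = spec$fractions, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE) |>
    transform(archetype = archetype, nl_magnitude = nl, baseline_magnitude = b)
}

simulate_planted <- function(spec, assignments = NULL, noise = noise_spec(),
                             seed = 1L) {
  des <- build_design(spec, seed = seed)
  simulate_measurements(des, effect_table(spec, assignments), noise,
                        seed = seed)
}

zero_noise <- function() noise_spec(0, 0, 0, outlier_rate = 0,
                                    low_signal_rate = 0)

# Independent oracle: mean over replicates within each dilution, then over
# dilutions within each mouse, then over mice; percent difference of the
# back-transformed group means. Deliberately written with explicit loops,
# separate from the package's own fallback estimator.
oracle_percent_difference <- function(x, group_a, group_b) {
  lab <- group_label(x$genotype, x$paradigm, x$drug)
  group_log_mean <- function(d) {
    mouse_means <- c()
    for (m in unique(d$mouse_id)) {
      dm <- d[d$mouse_id == m, ]
      dil_means <- c()
      for (s in unique(dm$dilution_step)) {
        dil_means <- c(dil_means,
                       mean(log(dm$normalized_intensity[dm$dilution_step == s])))
      }
      mouse_means <- c(mouse_means, mean(dil_means))
    }
    mean(mouse_means)
  }
  la <- group_log_mean(x[lab == group_a, , drop = FALSE])
  lb <- group_log_mean(x[lab == group_b, , drop = FALSE])
  100 * (exp(la - lb) - 1)
}

# normalize the print-variant protein names of the roster fixtures to the
# spellings used in the per-protein table
normalize_roster_name <- function(p) {
  map <- c(pPKCAB = "pPKCA", ubiquitin = "Ubiquitin",
           `pGSK3B-T216` = "pGSK3BT216")
  ifelse(p %in% names(map), map[p], p)
}

classifier_battery <- function() {
  bat <- comparison_battery()
  bat[bat$code %in% c("NL", "FL", "B", "RL", "B-tm"), , drop = FALSE]
}
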