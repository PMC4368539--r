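#' Specify a factorial RPPA design
#'
#' Describes the array layout the simulator emulates: eight experimental
#' groups, a fixed number of mice per group, brain regions and subcellular
#' fractions, a panel of proteins, and for every sample a dilution series
#' spotted in replicate.
#'
#' @param n_mice_per_group Mice per group. Either a single integer (default 8,
#'   the midpoint of the 7-10 animals per group the design assumes) or a
#'   length-2 range `c(lo, hi)` from which per-group sizes are drawn uniformly
#'   at simulation time (unbalanced design).
#' @param regions Character vector of brain regions.
#' @param fractions Character vector of subcellular fractions.
#' @param n_proteins Number of proteins/protein modifications on the panel.
#' @param proteins Optional explicit protein identifiers; overrides
#'   `n_proteins`.
#' @param n_dilution_steps Points in the dilution series per sample.
#' @param n_replicates Replicate spots per dilution point.
#' @param dilution_factor Fold-change in loaded protein between successive
#'   dilution steps (step 1 is the most concentrated).
#' @return An object of class `rppa_design_spec`.
#' @examples
#' design_spec(n_proteins = 4, regions = "hippocampus", fractions = "nuclear")
#' @export
design_spec <- function(n_mice_per_group = 8,
                        regions = c("hippocampus", "cortex"),
                        fractions = c("nuclear", "cytosolic", "membrane"),
                        n_proteins = 85,
                        proteins = NULL,
                        n_dilution_steps = 5,
                        n_replicates = 3,
                        dilution_factor = 2) {
  if (!length(n_mice_per_group) %in% 1:2 || any(n_mice_per_group < 1) ||
      any(n_mice_per_group != round(n_mice_per_group))) {
    stop("design_spec: n_mice_per_group must be a positive integer or range")
  }
  if (length(n_mice_per_group) == 2 && diff(n_mice_per_group) < 0) {
    stop("design_spec: n_mice_per_group range must be increasing")
  }
  if (is.null(proteins)) {
    if (n_proteins < 1) stop("design_spec: n_proteins must be >= 1")
    proteins <- sprintf("P%03d", seq_len(n_proteins))
  }
  if (anyDuplicated(proteins)) stop("design_spec: duplicated protein names")
  if (length(regions) < 1 || length(fractions) < 1) {
    stop("design_spec: need at least one region and one fraction")
  }
  if (n_dilution_steps < 1 || n_replicates < 1) {
    stop("design_spec: dilution steps and replicates must be >= 1")
  }
  if (dilution_factor <= 0) stop("design_spec: dilution_factor must be > 0")
  structure(
    list(
      n_mice_per_group = n_mice_per_group,
      regions = as.character(regions),
      fractions = as.character(fractions),
      proteins = as.character(proteins),
      n_dilution_steps = as.integer(n_dilution_steps),
      n_replicates = as.integer(n_replicates),
      dilution_factor = dilution_factor
    ),
    class = "rppa_design_spec"
  )
}

#' Specify the nested noise structure of simulated intensities
#'
#' Noise is multiplicative log-normal at the three nested levels the
#' statistical model accounts for: a mouse-level random intercept, a
#' dilution-series-within-mouse random intercept, and a spot-level residual
#' (all standard deviations on the natural-log scale). Technical outliers are
#' spots whose residual is inflated by `outlier_scale`; `low_signal_rate`
#' silences whole protein instances below the reliability floor.
#'
#' @param sd_mouse,sd_dilution,sd_replicate Nonnegative log-scale standard
#'   deviations of the three noise levels.
#' @param outlier_rate Probability that a spot is a technical outlier.
#' @param outlier_scale Multiplier applied to an outlier spot's residual.
#' @param low_signal_rate Probability that a protein instance is expressed
#'   below the low-signal reliability floor.
#' @return An object of class `rppa_noise_spec`.
#' @export
noise_spec <- function(sd_mouse = 0.05,
                       sd_dilution = 0.03,
                       sd_replicate = 0.05,
                       outlier_rate = 0.01,
                       outlier_scale = 10,
                       low_signal_rate = 0) {
  sds <- c(sd_mouse, sd_dilution, sd_replicate)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("noise_spec: standard deviations must be nonnegative")
  }
  for (p in c(outlier_rate, low_signal_rate)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("noise_spec: rates must be probabilities in [0, 1]")
    }
  }
  structure(
    list(sd_mouse = sd_mouse, sd_dilution = sd_dilution,
         sd_replicate = sd_replicate, outlier_rate = outlier_rate,
         outlier_scale = outlier_scale, low_signal_rate = low_signal_rate),
    class = "rppa_noise_spec"
  )
}

#' Build the mouse roster and spot grid for a design
#'
#' Assigns mice to the eight groups and lays out every spot of the array:
#' one row per protein x region x fraction x mouse x dilution step x
#' replicate. Deterministic given `seed` (the seed only matters when
#' `n_mice_per_group` is a range and group sizes are drawn).
#'
#' @param spec An [design_spec()] object.
#' @param seed Integer seed.
#' @return An object of class `rppa_design`: a list with elements `spec`,
#'   `mice` (mouse roster with group assignment) and `spots` (the spot grid,
#'   without intensities).
#' @export
build_design <- function(spec, seed = 1L) {
  if (!inherits(spec, "rppa_design_spec")) {
    stop("build_design: spec must be created by design_spec()")
  }
  groups <- rppa_groups()
  set.seed(seed)
  n_per <- if (length(spec$n_mice_per_group) == 2) {
    sample(seq(spec$n_mice_per_group[1], spec$n_mice_per_group[2]),
           nrow(groups), replace = TRUE)
  } else {
    rep(spec$n_mice_per_group, nrow(groups))
  }
  mice <- groups[rep(seq_len(nrow(groups)), n_per), , drop = FALSE]
  mice$mouse_id <- sprintf("m%03d", seq_len(nrow(mice)))
  rownames(mice) <- NULL
  mice <- mice[, c("mouse_id", "genotype", "paradigm", "drug", "label")]

  spots <- expand.grid(
    replicate = seq_len(spec$n_replicates),
    dilution_step = seq_len(spec$n_dilution_steps),
    mouse_id = mice$mouse_id,
    fraction = spec$fractions,
    region = spec$regions,
    protein = spec$proteins,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("protein", "region", "fraction", "mouse_id",
        "dilution_step", "replicate")]
  structure(list(spec = spec, mice = mice, spots = spots),
            class = "rppa_design")
}

#' Pattern archetypes understood by the effect generator
#'
#' @return Character vector of valid archetype codes.
#' @export
pattern_archetypes <- function() {
  c("STABLE", "FL_EQ_NL", "B_COMP", "B_PLUS_FL", "RL_EQ_NL", "BTM_COMP",
    "BTM_PLUS_RL", "RL_PLUS_B", "RL_PLUS_B_PLUS_BTM",
    "B_ABN_COMP_FL", "B_ABN_COMP_MEM", "B_ABN_UNCOMP", "SINGLE_RESPONDER")
}

# Planted percent contrasts (NL, FL, B, RL, B-tm) for one archetype.
archetype_contrasts <- function(archetype, nl_magnitude, baseline_magnitude) {
  n <- nl_magnitude
  b <- baseline_magnitude
  half <- (n - b) / 2
  switch(archetype,
    STABLE             = c(NL = 0, FL = 0,     B = 0, RL = 0,     `B-tm` = 0),
    FL_EQ_NL           = c(NL = n, FL = n,     B = 0, RL = n,     `B-tm` = 0),
    B_COMP             = c(NL = n, FL = 0,     B = b, RL = 0,     `B-tm` = 0),
    B_PLUS_FL          = c(NL = n, FL = n - b, B = b, RL = n - b, `B-tm` = 0),
    RL_EQ_NL           = c(NL = n, FL = 0,     B = 0, RL = n,     `B-tm` = 0),
    BTM_COMP           = c(NL = n, FL = 0,     B = b, RL = 0,     `B-tm` = n - b),
    BTM_PLUS_RL        = c(NL = n, FL = 0,     B = 0, RL = n - b, `B-tm` = b),
    RL_PLUS_B          = c(NL = n, FL = 0,     B = b, RL = n - b, `B-tm` = 0),
    RL_PLUS_B_PLUS_BTM = c(NL = n, FL = 0,     B = b, RL = half,  `B-tm` = half),
    B_ABN_COMP_FL      = c(NL = 0, FL = -b,    B = b, RL = -b,    `B-tm` = 0),
    B_ABN_COMP_MEM     = c(NL = 0, FL = 0,     B = b, RL = 0,     `B-tm` = -b),
    B_ABN_UNCOMP       = c(NL = 0, FL = 0,     B = b, RL = 0,     `B-tm` = 0),
    SINGLE_RESPONDER   = c(NL = 0, FL = n,     B = 0, RL = 0,     `B-tm` = 0),
    stop("unknown archetype '", archetype, "'; valid codes: ",
         paste(pattern_archetypes(), collapse = ", "))
  )
}

#' Group means implied by a planted compensation archetype
#'
#' Translates a pattern archetype plus planted magnitudes into the eight true
#' group means whose pairwise contrasts reproduce the archetype exactly. The
#' learning contrast (NL) carries `nl_magnitude`; archetypes that involve a
#' baseline abnormality or a direct drug response split the effect using
#' `baseline_magnitude` (for example `B_PLUS_FL` plants `B = baseline` and
#' `FL = RL = nl - baseline`, so that the classifier's sum `B + FL` equals
#' `NL`).
#'
#' @param archetype One of [pattern_archetypes()].
#' @param nl_magnitude Planted normal-learning percent difference (> -100).
#' @param baseline_magnitude Planted baseline percent difference (> -100).
#' @param base_mean Mean normalized abundance of the reference group
#'   (`c-SC-sal`), positive linear scale.
#' @return Named numeric vector of eight positive group means.
#' @examples
#' archetype_to_effects("FL_EQ_NL", 20)
#' contrasts_from_means(archetype_to_effects("B_COMP", 20, 20))
#' @export
archetype_to_effects <- function(archetype, nl_magnitude = 0,
                                 baseline_magnitude = 0, base_mean = 1) {
  if (nl_magnitude <= -100 || baseline_magnitude <= -100) {
    stop("archetype_to_effects: magnitudes must be > -100 percent")
  }
  if (base_mean <= 0) stop("archetype_to_effects: base_mean must be > 0")
  ct <- archetype_contrasts(archetype, nl_magnitude, baseline_magnitude)
  f <- 1 + ct / 100
  means <- c(
    "c-SC-sal" = 1,
    "c-CS-sal" = unname(f["NL"]),
    "c-SC-mem" = 1,
    "c-CS-mem" = unname(f["NL"]),
    "t-SC-sal" = unname(f["B"]),
    "t-CS-sal" = unname(f["B"] * f["FL"]),
    "t-SC-mem" = unname(f["B"] * f["B-tm"]),
    "t-CS-mem" = unname(f["B"] * f["B-tm"] * f["RL"])
  ) * base_mean
  means
}

#' Build a per-instance effect table for a whole design
#'
#' @param spec A [design_spec()] object.
#' @param assignments Data frame with one row per protein instance and columns
#'   `protein`, `region`, `fraction`, `archetype`, `nl_magnitude`,
#'   `baseline_magnitude` (the last two default to 0 if absent). Instances of
#'   the design not listed default to `STABLE`.
#' @return A data frame with columns `protein`, `region`, `fraction`,
#'   `label` (group) and `true_mean` — eight rows per instance.
#' @export
effect_table <- function(spec, assignments = NULL) {
  inst <- expand.grid(protein = spec$proteins, region = spec$regions,
                      fraction = spec$fractions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  inst$archetype <- "STABLE"
  inst$nl_magnitude <- 0
  inst$baseline_magnitude <- 0
  if (!is.null(assignments)) {
    if (!all(c("protein", "region", "fraction", "archetype") %in%
             names(assignments))) {
      stop("effect_table: assignments need protein, region, fraction, archetype")
    }
    if (is.null(assignments$nl_magnitude)) assignments$nl_magnitude <- 0
    if (is.null(assignments$baseline_magnitude)) {
      assignments$baseline_magnitude <- 0
    }
    key <- function(d) paste(d$protein, d$region, d$fraction, sep = "\r")
    idx <- match(key(assignments), key(inst))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop("effect_table: assignment for instance not in design: ",
           assignments$protein[bad], " / ", assignments$region[bad], " / ",
           assignments$fraction[bad])
    }
    inst$archetype[idx] <- assignments$archetype
    inst$nl_magnitude[idx] <- assignments$nl_magnitude
    inst$baseline_magnitude[idx] <- assignments$baseline_magnitude
  }
  labs <- rppa_groups()$label
  out <- inst[rep(seq_len(nrow(inst)), each = length(labs)),
              c("protein", "region", "fraction")]
  out$label <- rep(labs, nrow(inst))
  means <- mapply(function(a, n, b) archetype_to_effects(a, n, b)[labs],
                  inst$archetype, inst$nl_magnitude, inst$baseline_magnitude,
                  SIMPLIFY = TRUE)
  out$true_mean <- as.vector(means) # column-major: 8 means per instance
  rownames(out) <- NULL
  out
}

#' Simulate RPPA spot intensities for a design
#'
#' Each spot's SyproRuby (total-protein stain) intensity encodes the loaded
#' protein amount, `base_loading / dilution_factor^(step - 1)`; the raw
#' antibody intensity is the instance's true group mean times that loading
#' times multiplicative log-normal noise at the mouse, dilution-within-mouse
#' and spot levels. The ratio raw/sypro therefore has expectation equal to the
#' true mean regardless of dilution step, and with all noise at zero it equals
#' the planted mean exactly.
#'
#' @param design An [build_design()] result.
#' @param effects An [effect_table()] data frame covering every instance in
#'   the design.
#' @param noise A [noise_spec()] object.
#' @param seed Integer seed; output is byte-identical for identical inputs.
#' @param base_loading SyproRuby intensity at the most concentrated dilution
#'   step (arbitrary fluorescence units).
#' @return A data frame of measurements: the spot grid plus `genotype`,
#'   `paradigm`, `drug`, `raw_intensity` and `sypro_intensity`.
#' @export
simulate_measurements <- function(design, effects, noise = noise_spec(),
                                  seed = 1L, base_loading = 500) {
  if (!inherits(design, "rppa_design")) {
    stop("simulate_measurements: design must come from build_design()")
  }
  if (!inherits(noise, "rppa_noise_spec")) {
    stop("simulate_measurements: noise must come from noise_spec()")
  }
  x <- design$spots
  mi <- match(x$mouse_id, design$mice$mouse_id)
  x$genotype <- design$mice$genotype[mi]
  x$paradigm <- design$mice$paradigm[mi]
  x$drug <- design$mice$drug[mi]
  label <- design$mice$label[mi]

  ekey <- paste(effects$protein, effects$region, effects$fraction,
                effects$label, sep = "\r")
  xkey <- paste(x$protein, x$region, x$fraction, label, sep = "\r")
  ei <- match(xkey, ekey)
  if (anyNA(ei)) {
    bad <- which(is.na(ei))[1]
    stop("simulate_measurements: no effect entry for instance ",
         x$protein[bad], " / ", x$region[bad], " / ", x$fraction[bad],
         " group ", label[bad])
  }
  mu <- effects$true_mean[ei]

  ikey <- paste(x$protein, x$region, x$fraction, sep = "\r")
  inst <- unique(ikey)
  mkey <- paste(ikey, x$mouse_id, sep = "\r")
  dkey <- paste(mkey, x$dilution_step, sep = "\r")
  mlev <- unique(mkey)
  dlev <- unique(dkey)

  set.seed(seed)
  mouse_eff <- stats::rnorm(length(mlev), 0, noise$sd_mouse)
  dil_eff <- stats::rnorm(length(dlev), 0, noise$sd_dilution)
  rep_eff <- stats::rnorm(nrow(x), 0, noise$sd_replicate)
  is_outlier <- stats::runif(nrow(x)) < noise$outlier_rate
  rep_eff[is_outlier] <- rep_eff[is_outlier] * noise$outlier_scale
  low_inst <- inst[stats::runif(length(inst)) < noise$low_signal_rate]
  if (length(low_inst) > 0) {
    # silenced instances express at ~5% of the reference scale, far below the
    # 0.1 reliability floor for means on the unit scale
    mu[ikey %in% low_inst] <- mu[ikey %in% low_inst] * 0.05
  }

  loading <- base_loading / design$spec$dilution_factor^(x$dilution_step - 1)
  x$raw_intensity <- mu * loading *
    exp(mouse_eff[match(mkey, mlev)] + dil_eff[match(dkey, dlev)] + rep_eff)
  x$sypro_intensity <- loading
  x
}

#' Write / read measurement tables
#'
#' Long-format tab-delimited text with a header row; the on-disk interchange
#' format of the pipeline.
#'
#' @param x Measurement data frame.
#' @param path File path.
#' @return `read_measurements()` returns the data frame; `write_measurements()`
#'   returns `path` invisibly.
#' @export
write_measurements <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
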