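#' Count significant increases and decreases per comparison
#'
#' Builds the summary count matrix: for every region x fraction x comparison,
#' the number of proteins with a significant increase (`n_up`), a significant
#' decrease (`n_down`), and the number tested (`n_tested`). A significant
#' result with a percent difference of exactly zero is counted as neither and
#' triggers a warning.
#'
#' @param results Data frame with `protein`, `region`, `fraction`,
#'   `comparison`, `percent_difference` and `significant` columns (gated
#'   pipeline results or [fixture_profiles()] output).
#' @return A data frame of class `rppa_counts`.
#' @export
summarize_counts <- function(results) {
  need <- c("region", "fraction", "comparison", "percent_difference",
            "significant")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0) {
    stop("summarize_counts: missing column(s): ", paste(miss, collapse = ", "))
  }
  sig <- results$significant & !is.na(results$percent_difference)
  zero_sig <- sig & results$percent_difference == 0
  if (any(zero_sig)) {
    warning(sum(zero_sig),
            " significant result(s) with zero percent difference counted as",
            " neither increase nor decrease")
  }
  tested <- !is.na(results$percent_difference)
  if (!is.null(results$status)) tested <- tested & results$status == "ok"
  fam <- list(region = results$region, fraction = results$fraction,
              comparison = results$comparison)
  up <- aggregate(list(n_up = sig & results$percent_difference > 0), fam, sum)
  down <- aggregate(list(n_down = sig & results$percent_difference < 0), fam, sum)
  nt <- aggregate(list(n_tested = tested), fam, sum)
  out <- merge(merge(up, down, by = names(fam)), nt, by = names(fam))
  out$n_up <- as.integer(out$n_up)
  out$n_down <- as.integer(out$n_down)
  out$n_tested <- as.integer(out$n_tested)
  out <- out[order(out$region, out$fraction,
                   match(out$comparison, comparison_battery()$code)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rppa_counts", "data.frame")
  out
}

#' Aggregate counts or roster entries for one region
#'
#' For a count matrix ([summarize_counts()] output or the packaged printed
#' count fixture) sums increases and decreases for one comparison across the
#' region's fractions. For a pattern roster (one row per instance) counts the
#' region's instances, optionally restricted to a pattern family.
#'
#' @param x An `rppa_counts` data frame, an `rppa_roster` object, or a
#'   fixture roster data frame with one row per instance.
#' @param region Brain region to aggregate.
#' @param comparison Comparison code (count-matrix route only).
#' @param family Optional pattern family (`"no_memantine"`, `"memantine"`,
#'   ...) for the roster route.
#' @return Count-matrix route: list with `n_up`, `n_down`, `total`. Roster
#'   route: integer instance count.
#' @export
aggregate_totals <- function(x, region, comparison = NULL, family = NULL) {
  if (!is.null(x$n_up)) {
    if (!region %in% x$region) {
      stop("aggregate_totals: unknown region '", region, "'")
    }
    keep <- x$region == region
    if (!is.null(comparison)) {
      if (!comparison %in% x$comparison) {
        stop("aggregate_totals: unknown comparison '", comparison, "'")
      }
      keep <- keep & x$comparison == comparison
    }
    return(list(n_up = sum(x$n_up[keep]), n_down = sum(x$n_down[keep]),
                total = sum(x$n_up[keep]) + sum(x$n_down[keep])))
  }
  if (inherits(x, "rppa_roster")) x <- x$instances
  if (is.null(x$protein) || is.null(x$region)) {
    stop("aggregate_totals: x is neither a count matrix nor a roster")
  }
  if (nrow(x) > 0 && !region %in% x$region) {
    stop("aggregate_totals: unknown region '", region, "'")
  }
  keep <- x$region == region
  if (!is.null(family)) {
    code_col <- if (!is.null(x$code)) x$code else x$pattern
    keep <- keep & pattern_families()[code_col] == family
  }
  sum(keep)
}

#' Group pattern assignments into a roster
#'
#' @param assignments Output of [classify_all()].
#' @return An object of class `rppa_roster`: a list with `instances` (one row
#'   per instance: `code`, `region`, `fraction`, `band`, `protein`), `cells`
#'   (protein lists per code x region x fraction x band) and `totals`
#'   (instance counts per pattern family x region).
#' @export
build_roster <- function(assignments) {
  inst <- assignments[, c("code", "region", "fraction", "band", "protein")]
  inst$band[is.na(inst$band)] <- "none"
  key <- list(code = inst$code, region = inst$region,
              fraction = inst$fraction, band = inst$band)
  cells <- aggregate(list(proteins = inst$protein), key,
                     function(p) paste(sort(p), collapse = ","))
  fams <- pattern_families()[assignments$code]
  totals <- aggregate(list(n = assignments$protein),
                      list(family = fams, region = assignments$region),
                      length)
  totals$n <- as.integer(totals$n)
  structure(list(instances = inst, cells = cells, totals = totals),
            class = "rppa_roster")
}

#' @export
print.rppa_roster <- function(x, ...) {
  cat("RPPA pattern roster:", nrow(x$instances), "instances\n")
  print(x$totals, ...)
  invisible(x)
}

fixture_files <- c(
  table1 = "table1_comparisons.tsv",
  table2 = "table2_counts.tsv",
  table3 = "table3_hippocampus.tsv",
  table4 = "table4_roster.tsv",
  table5 = "table5_roster.tsv"
)

#' Load a packaged transcription of a printed summary table
#'
#' The package ships plain-text transcriptions of the five printed tables of
#' the source study: the comparison definitions (table1), the count matrix of
#' significant responses (table2), the per-protein hippocampal percent
#' differences with bold-print significance flags (table3), and the two
#' pattern rosters (table4, memantine not required; table5, memantine
#' required). Cells whose transcription is doubtful carry a `note`.
#'
#' @param id One of `"table1"` ... `"table5"`.
#' @return The fixture as a data frame (with class `rppa_counts` for
#'   table2).
#' @export
load_fixture <- function(id) {
  if (!id %in% names(fixture_files)) {
    stop("load_fixture: unknown table id '", id, "'; valid: ",
         paste(names(fixture_files), collapse = ", "))
  }
  path <- system.file("extdata", fixture_files[[id]], package = "rppacomp")
  if (path == "") stop("load_fixture: fixture file missing for ", id)
  out <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (id == "table2") class(out) <- c("rppa_counts", "data.frame")
  out
}

#' Long-format comparison profiles from the table3 fixture
#'
#' Converts the wide per-protein transcription (seven comparison columns with
#' paired significance flags) into the long format consumed by
#' [classify_all()] and [summarize_counts()].
#'
#' @param tbl3 The data frame returned by `load_fixture("table3")`.
#' @return Data frame with columns `protein`, `region`, `fraction`,
#'   `comparison`, `percent_difference`, `significant`.
#' @export
fixture_profiles <- function(tbl3) {
  cols <- c(NL = "NL", FL = "FL", B = "B", RL = "RL", B_tm = "B-tm",
            B_tm_cs = "B-tm-cs", RL_NL = "RL-NL")
  out <- do.call(rbind, lapply(names(cols), function(cn) {
    data.frame(protein = tbl3$protein, region = tbl3$region,
               fraction = tbl3$fraction, comparison = cols[[cn]],
               percent_difference = tbl3[[cn]],
               significant = as.logical(tbl3[[paste0(cn, "_sig")]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# flat yaml config -> validated pieces with defaults
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("run_pipeline: config must be a list or a path")
  get <- function(section, defaults) {
    vals <- config[[section]]
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), names(defaults))
    if (length(unknown) > 0) {
      stop("run_pipeline: unknown ", section, " config key(s): ",
           paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults, vals)
  }
  design_defaults <- list(
    n_mice_per_group = 8, regions = c("hippocampus", "cortex"),
    fractions = c("nuclear", "cytosolic", "membrane"), n_proteins = 85,
    proteins = NULL, n_dilution_steps = 5, n_replicates = 3,
    dilution_factor = 2)
  simplify <- function(args) lapply(args, function(v)
    if (is.list(v)) unlist(v) else v)
  list(
    design = do.call(design_spec, simplify(get("design", design_defaults))),
    effects = config$effects,
    noise = do.call(noise_spec, get("noise", list(
      sd_mouse = 0.05, sd_dilution = 0.03, sd_replicate = 0.05,
      outlier_rate = 0.01, outlier_scale = 10, low_signal_rate = 0))),
    preprocess = do.call(preprocess_config, get("preprocess", list(
      low_signal_floor = 0.1, sd_inclusion_k = 3, sd_scope = "pooled",
      replicate_outlier_rule = "none", mad_threshold = 3.5))),
    stats = do.call(stats_config, get("stats", list(
      family_alpha = 0.05, transform = "log", fallback = "nested_means"))),
    classifier = do.call(classifier_config, get("classifier", list(
      tolerance_pp = 10, band_threshold_pp = 10, ns_term_policy = "zero"))),
    classify_only = isTRUE(config$classify_only)
  )
}

log_line <- function(con, ...) {
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ..., "\n",
      sep = "", file = con, append = TRUE)
}

#' Run the full simulate / preprocess / compare / classify / report pipeline
#'
#' End-to-end orchestration, deterministic given `seed`. Every stage's output
#' is written as TSV under `out_dir` (`measurements.tsv`, `normalized.tsv`,
#' `comparisons.tsv`, `assignments.tsv`, `counts.tsv`, `roster_totals.tsv`)
#' together with a plain-text `log.txt` recording exclusions, convergence
#' fallbacks and Bonferroni family sizes. With `classify_only: true` in the
#' config, the packaged hippocampal transcription is classified instead of
#' simulating new data.
#'
#' @param config Path to a YAML config file or an equivalent nested list with
#'   sections `design`, `effects` (data frame / list of archetype
#'   assignments), `noise`, `preprocess`, `stats`, `classifier`, and an
#'   optional `classify_only` flag.
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = tempfile("rppa_")) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)

  if (cfg$classify_only) {
    log_line(logf, "stage classify_only: packaged hippocampal transcription")
    profiles <- fixture_profiles(load_fixture("table3"))
  } else {
    log_line(logf, "stage simulate: seed ", seed)
    design <- build_design(cfg$design, seed = seed)
    eff_assign <- if (is.null(cfg$effects)) {
      NULL
    } else if (is.data.frame(cfg$effects)) {
      cfg$effects
    } else {
      do.call(rbind, lapply(cfg$effects, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
    effects <- effect_table(cfg$design, eff_assign)
    meas <- simulate_measurements(design, effects, cfg$noise, seed = seed)
    write_measurements(meas, file.path(out_dir, "measurements.tsv"))

    log_line(logf, "stage preprocess")
    norm <- preprocess(meas, cfg$preprocess)
    for (flag in grep("^qc_", names(norm), value = TRUE)) {
      log_line(logf, "  ", flag, ": ", sum(norm[[flag]]), " spots")
    }
    write_measurements(norm, file.path(out_dir, "normalized.tsv"))

    log_line(logf, "stage compare")
    results <- fit_all_comparisons(norm, cfg$stats)
    results <- bonferroni_gate(results, cfg$stats)
    log_line(logf, "  fallback fits: ",
             sum(results$method == "nested_means", na.rm = TRUE), " of ",
             nrow(results))
    for (fam in unique(paste(results$region, results$fraction))) {
      m <- results$m_tests[paste(results$region, results$fraction) == fam][1]
      log_line(logf, "  family ", fam, ": m = ", m)
    }
    write_measurements(results, file.path(out_dir, "comparisons.tsv"))
    profiles <- results
  }

  log_line(logf, "stage classify")
  assignments <- classify_all(profiles, cfg$classifier)
  write_measurements(assignments, file.path(out_dir, "assignments.tsv"))

  log_line(logf, "stage report")
  counts <- summarize_counts(profiles)
  write_measurements(counts, file.path(out_dir, "counts.tsv"))
  roster <- build_roster(assignments)
  write_measurements(roster$totals, file.path(out_dir, "roster_totals.tsv"))
  write_measurements(roster$instances, file.path(out_dir, "roster.tsv"))
  log_line(logf, "done: ", nrow(assignments), " instances classified")

  invisible(list(profiles = profiles, assignments = assignments,
                 counts = counts, roster = roster, out_dir = out_dir))
}
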