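#' Preprocessing configuration
#'
#' @param low_signal_floor Instances whose median normalized intensity falls
#'   below this value (normalized units) are considered too low to be reliable
#'   and never reach the model. Default 0.1.
#' @param sd_inclusion_k A spot is retained only if it lies within `k`
#'   standard deviations of its instance mean (strictly "within": a value at
#'   exactly `k` SD is kept). Default 3.
#' @param sd_scope Whether the mean/SD of the inclusion rule pool all groups
#'   of an instance (`"pooled"`, default) or are computed per group.
#' @param replicate_outlier_rule Optional technical-outlier rule applied
#'   within replicate triplets before the SD rule: `"none"` (default) or
#'   `"mad"` (flag spots deviating from the triplet median by more than
#'   `mad_threshold` times the median absolute deviation).
#' @param mad_threshold Threshold for the `"mad"` rule.
#' @return An object of class `rppa_preprocess_config`.
#' @export
preprocess_config <- function(low_signal_floor = 0.1,
                              sd_inclusion_k = 3,
                              sd_scope = c("pooled", "per_group"),
                              replicate_outlier_rule = c("none", "mad"),
                              mad_threshold = 3.5) {
  if (low_signal_floor <= 0) stop("preprocess_config: floor must be > 0")
  if (sd_inclusion_k <= 0) stop("preprocess_config: sd_inclusion_k must be > 0")
  structure(
    list(low_signal_floor = low_signal_floor,
         sd_inclusion_k = sd_inclusion_k,
         sd_scope = match.arg(sd_scope),
         replicate_outlier_rule = match.arg(replicate_outlier_rule),
         mad_threshold = mad_threshold),
    class = "rppa_preprocess_config"
  )
}

instance_key <- function(x) paste(x$protein, x$region, x$fraction, sep = "\r")

#' Normalize raw intensities to the total-protein stain
#'
#' Divides each spot's raw antibody intensity by its SyproRuby total-protein
#' intensity, removing per-spot loading (and hence dilution-step) effects.
#' Spots with nonpositive or missing stain signal cannot be normalized and are
#' flagged invalid rather than divided.
#'
#' @param x Measurement data frame with `raw_intensity` and `sypro_intensity`.
#' @return `x` with columns `normalized_intensity` and `qc_invalid` added.
#' @export
normalize_to_total_protein <- function(x) {
  stopifnot(all(c("raw_intensity", "sypro_intensity") %in% names(x)))
  bad <- !is.finite(x$sypro_intensity) | x$sypro_intensity <= 0 |
    !is.finite(x$raw_intensity)
  x$normalized_intensity <- ifelse(bad, NA_real_,
                                   x$raw_intensity / x$sypro_intensity)
  x$qc_invalid <- bad
  x
}

#' Flag protein instances below the low-signal reliability floor
#'
#' The screening-level discard rule: a whole protein instance (protein x
#' region x fraction) is dropped when its median normalized intensity is below
#' the floor. Spots are flagged, not deleted.
#'
#' @param x Normalized measurement data frame.
#' @param config A [preprocess_config()] object.
#' @return `x` with logical column `qc_low_signal` added/updated.
#' @export
discard_low_signal <- function(x, config = preprocess_config()) {
  stopifnot("normalized_intensity" %in% names(x))
  key <- instance_key(x)
  med <- tapply(x$normalized_intensity[!x$qc_invalid], key[!x$qc_invalid],
                stats::median, na.rm = TRUE)
  low <- names(med)[!is.na(med) & med < config$low_signal_floor]
  x$qc_low_signal <- key %in% low
  x
}

# optional technical-outlier rule within replicate triplets
flag_replicate_outliers <- function(x, config) {
  x$qc_technical_outlier <- FALSE
  if (config$replicate_outlier_rule != "mad") return(x)
  usable <- !x$qc_invalid & !x$qc_low_signal
  key <- paste(instance_key(x), x$mouse_id, x$dilution_step, sep = "\r")
  v <- x$normalized_intensity
  med <- stats::ave(ifelse(usable, v, NA), key,
                    FUN = function(z) stats::median(z, na.rm = TRUE))
  madv <- stats::ave(ifelse(usable, v, NA), key,
                     FUN = function(z) stats::mad(z, na.rm = TRUE))
  out <- usable & is.finite(madv) & madv > 0 &
    abs(v - med) > config$mad_threshold * madv
  x$qc_technical_outlier <- out
  x
}

#' Apply the k-standard-deviation inclusion rule
#'
#' Per protein instance, the mean and SD of the normalized intensities are
#' computed over all spots not already flagged, in a single pass; spots whose
#' deviation from the mean exceeds `k` SD are flagged. A value at exactly `k`
#' SD is "within" and retained. Instances left with fewer than three usable
#' spots are flagged unestimable.
#'
#' @param x Normalized measurement data frame (after [discard_low_signal()]).
#' @param config A [preprocess_config()] object.
#' @return `x` with logical columns `qc_sd_excluded` and `qc_unestimable`.
#' @export
exclude_extreme_values <- function(x, config = preprocess_config()) {
  stopifnot("normalized_intensity" %in% names(x))
  if (is.null(x$qc_technical_outlier)) x$qc_technical_outlier <- FALSE
  usable <- !x$qc_invalid & !x$qc_low_signal & !x$qc_technical_outlier
  key <- instance_key(x)
  if (config$sd_scope == "per_group") {
    key <- paste(key, x$genotype, x$paradigm, x$drug, sep = "\r")
  }
  v <- ifelse(usable, x$normalized_intensity, NA)
  m <- stats::ave(v, key, FUN = function(z) mean(z, na.rm = TRUE))
  s <- stats::ave(v, key, FUN = function(z) stats::sd(z, na.rm = TRUE))
  x$qc_sd_excluded <- usable & is.finite(s) & s > 0 &
    abs(v - m) > config$sd_inclusion_k * s
  clean <- usable & !x$qc_sd_excluded
  n_clean <- stats::ave(as.numeric(clean), instance_key(x), FUN = sum)
  x$qc_unestimable <- n_clean < 3
  x
}

#' Run the full preprocessing chain
#'
#' Normalization to total protein, the low-signal instance discard, the
#' optional technical-outlier rule, and the k-SD inclusion rule, in that
#' order. Rows are only ever flagged, never removed.
#'
#' @param x Raw measurement data frame.
#' @param config A [preprocess_config()] object.
#' @return `x` with `normalized_intensity` and all `qc_*` flag columns.
#' @export
preprocess <- function(x, config = preprocess_config()) {
  x <- normalize_to_total_protein(x)
  x <- discard_low_signal(x, config)
  x <- flag_replicate_outliers(x, config)
  x <- exclude_extreme_values(x, config)
  x
}

#' Spots that survived every quality-control rule
#'
#' @param x Preprocessed measurement data frame.
#' @return The subset of rows carrying no QC flag.
#' @export
clean_spots <- function(x) {
  need <- c("qc_invalid", "qc_low_signal", "qc_technical_outlier",
            "qc_sd_excluded", "qc_unestimable")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("clean_spots: run preprocess() first (missing ",
         paste(miss, collapse = ", "), ")")
  }
  x[!(x$qc_invalid | x$qc_low_signal | x$qc_technical_outlier |
        x$qc_sd_excluded | x$qc_unestimable), , drop = FALSE]
}
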