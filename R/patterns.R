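#' Classifier configuration
#'
#' @param tolerance_pp Absolute tolerance, in percentage points, for a sum of
#'   responses to "match" the normal-learning response. Default 10.
#' @param band_threshold_pp Residual magnitude separating the `within` and
#'   `beyond` reporting bands. Default 10.
#' @param ns_term_policy How non-significant comparisons contribute to sums:
#'   `"zero"` (default; only significant effects count) or `"point_estimate"`
#'   (sensitivity analysis: raw point estimates are summed).
#' @return An object of class `rppa_classifier_config`.
#' @export
classifier_config <- function(tolerance_pp = 10,
                              band_threshold_pp = 10,
                              ns_term_policy = c("zero", "point_estimate")) {
  if (tolerance_pp <= 0) stop("classifier_config: tolerance_pp must be > 0")
  if (band_threshold_pp <= 0) {
    stop("classifier_config: band_threshold_pp must be > 0")
  }
  structure(
    list(tolerance_pp = tolerance_pp,
         band_threshold_pp = band_threshold_pp,
         ns_term_policy = match.arg(ns_term_policy)),
    class = "rppa_classifier_config"
  )
}

#' All pattern codes the classifier can assign
#'
#' @return Character vector of codes. The first three form the "memantine not
#'   required" family, the next five the "memantine required" family; the
#'   `B_ABN_*` codes cover baseline abnormalities without a normal-learning
#'   response.
#' @export
pattern_codes <- function() {
  c("FL_EQ_NL", "B_COMP", "B_PLUS_FL",
    "RL_EQ_NL", "BTM_COMP", "BTM_PLUS_RL", "RL_PLUS_B", "RL_PLUS_B_PLUS_BTM",
    "NL_UNRESOLVED",
    "B_ABN_COMP_FL", "B_ABN_COMP_MEM", "B_ABN_UNCOMP",
    "SINGLE_RESPONDER", "STABLE")
}

#' Pattern families used for roster totals
#'
#' @return Named character vector mapping each pattern code to its family:
#'   `no_memantine` (response adequate without drug), `memantine`
#'   (memantine-rescued), `baseline_abnormal`, or `other`.
#' @export
pattern_families <- function() {
  c(FL_EQ_NL = "no_memantine", B_COMP = "no_memantine",
    B_PLUS_FL = "no_memantine",
    RL_EQ_NL = "memantine", BTM_COMP = "memantine",
    BTM_PLUS_RL = "memantine", RL_PLUS_B = "memantine",
    RL_PLUS_B_PLUS_BTM = "memantine",
    NL_UNRESOLVED = "other",
    B_ABN_COMP_FL = "baseline_abnormal", B_ABN_COMP_MEM = "baseline_abnormal",
    B_ABN_UNCOMP = "baseline_abnormal",
    SINGLE_RESPONDER = "other", STABLE = "other")
}

classifier_comparisons <- c("NL", "FL", "B", "RL", "B-tm")

#' Classify one protein instance's comparison profile
#'
#' Deterministic rule evaluation of the compensation-pattern logic. Writing
#' `v[X]` for a comparison's percent difference and `e[X]` for its effective
#' value (the percent difference if significant, else 0 under the default
#' policy), and `match(x, t)` for `|x - t| <= tolerance_pp` with sign
#' agreement when `t != 0`:
#'
#' * NL significant — candidates tried in fixed simplest-first precedence,
#'   each requiring its listed dynamic terms to be significant:
#'   `FL_EQ_NL` (`match(FL, NL)`); `B_COMP` (FL ns, `match(B, NL)`);
#'   `B_PLUS_FL` (`match(B + FL, NL)`); `RL_EQ_NL` (B-tm ns,
#'   `match(RL, NL)`); `BTM_COMP` (RL ns, `match(B-tm, NL)` or
#'   `match(e[B] + B-tm, NL)`); `BTM_PLUS_RL` (`match(B-tm + RL, NL)`);
#'   `RL_PLUS_B` (B-tm ns, `match(B + RL, NL)`); `RL_PLUS_B_PLUS_BTM`
#'   (`match(e[B] + e[B-tm] + e[RL], NL)` with RL or B-tm significant);
#'   otherwise `NL_UNRESOLVED`, recording the candidate with minimal
#'   residual.
#' * NL not significant, B significant — `B_ABN_COMP_FL` (FL significant,
#'   opposite sign to B, `|B + FL| <= tol`), `B_ABN_COMP_MEM` (only RL and/or
#'   B-tm significant, `|B + e[B-tm] + e[RL]| <= tol`), else `B_ABN_UNCOMP`.
#' * Neither significant — `SINGLE_RESPONDER` if any of FL, RL, B-tm is
#'   significant, else `STABLE`.
#'
#' @param values Named numeric vector of percent differences; names must
#'   include `"NL"`, `"FL"`, `"B"`, `"RL"`, `"B-tm"`.
#' @param significant Named logical vector over the same comparisons.
#' @param config A [classifier_config()] object.
#' @return A list with `code`, `terms_used` (character vector of comparison
#'   codes), `residual_pp` (signed, sum minus target; `NA` where no target
#'   anchors the code) and `band` (`"within"`/`"beyond"`/`NA`).
#' @examples
#' classify_profile(
#'   c(NL = 16.7, FL = 19.7, B = 2.3, RL = 22.8, `B-tm` = 2.4),
#'   c(NL = TRUE, FL = TRUE, B = FALSE, RL = TRUE, `B-tm` = FALSE)
#' )
#' @export
classify_profile <- function(values, significant,
                             config = classifier_config()) {
  miss <- setdiff(classifier_comparisons, names(values))
  if (length(miss) > 0) {
    stop("classify_profile: missing comparison(s): ",
         paste(miss, collapse = ", "))
  }
  miss <- setdiff(classifier_comparisons, names(significant))
  if (length(miss) > 0) {
    stop("classify_profile: missing significance flag(s): ",
         paste(miss, collapse = ", "))
  }
  v <- values[classifier_comparisons]
  s <- significant[classifier_comparisons]
  if (any(!is.finite(v))) stop("classify_profile: percent values must be finite")
  e <- if (config$ns_term_policy == "zero") ifelse(s, v, 0) else v
  tol <- config$tolerance_pp
  matches <- function(x, target) {
    abs(x - target) <= tol && (target == 0 || sign(x) == sign(target))
  }
  band_of <- function(res) {
    if (is.na(res)) NA_character_
    else if (abs(res) <= config$band_threshold_pp) "within" else "beyond"
  }
  done <- function(code, terms, sum_terms, target) {
    res <- if (is.na(target)) NA_real_ else sum_terms - target
    list(code = code, terms_used = terms, residual_pp = res,
         band = band_of(res))
  }

  nl <- unname(v["NL"])
  if (s["NL"]) {
    # candidate list: (code, terms, sum, admissible)
    cand <- list(
      list("FL_EQ_NL", "FL", unname(v["FL"]), s["FL"]),
      list("B_COMP", "B", unname(v["B"]), !s["FL"] && s["B"]),
      list("B_PLUS_FL", c("B", "FL"), unname(v["B"] + v["FL"]),
           s["FL"] && s["B"]),
      list("RL_EQ_NL", "RL", unname(v["RL"]), !s["B-tm"] && s["RL"]),
      list("BTM_COMP", "B-tm", unname(v["B-tm"]), !s["RL"] && s["B-tm"]),
      list("BTM_COMP", c("B", "B-tm"), unname(e["B"] + v["B-tm"]),
           !s["RL"] && s["B-tm"]),
      list("BTM_PLUS_RL", c("B-tm", "RL"), unname(v["B-tm"] + v["RL"]),
           s["RL"] && s["B-tm"]),
      list("RL_PLUS_B", c("B", "RL"), unname(v["B"] + v["RL"]),
           s["RL"] && s["B"] && !s["B-tm"]),
      list("RL_PLUS_B_PLUS_BTM", c("B", "B-tm", "RL"),
           unname(e["B"] + e["B-tm"] + e["RL"]), s["RL"] || s["B-tm"])
    )
    for (cc in cand) {
      if (cc[[4]] && matches(cc[[3]], nl)) {
        return(done(cc[[1]], cc[[2]], cc[[3]], nl))
      }
    }
    # unresolved: report the nearest candidate among those whose significance
    # preconditions hold (fall back to the all-terms sum if none does)
    adm <- Filter(function(cc) cc[[4]], cand)
    if (length(adm) == 0) {
      adm <- list(list("NL_UNRESOLVED", character(0), 0, TRUE))
    }
    resids <- vapply(adm, function(cc) abs(cc[[3]] - nl), numeric(1))
    best <- adm[[which.min(resids)]]
    return(done("NL_UNRESOLVED", best[[2]], best[[3]], nl))
  }

  if (s["B"]) {
    b <- unname(v["B"])
    if (s["FL"] && sign(v["FL"]) == -sign(b) && abs(b + v["FL"]) <= tol) {
      return(done("B_ABN_COMP_FL", c("B", "FL"), b + unname(v["FL"]), 0))
    }
    mem_sum <- b + unname(e["B-tm"] + e["RL"])
    if (!s["FL"] && (s["RL"] || s["B-tm"]) && abs(mem_sum) <= tol) {
      terms <- c("B", c("B-tm", "RL")[c(s["B-tm"], s["RL"])])
      return(done("B_ABN_COMP_MEM", terms, mem_sum, 0))
    }
    terms <- c("B", classifier_comparisons[-c(1, 3)][s[-c(1, 3)]])
    return(done("B_ABN_UNCOMP", terms, b + sum(e[c("FL", "B-tm", "RL")]), 0))
  }

  responders <- c("FL", "RL", "B-tm")[s[c("FL", "RL", "B-tm")]]
  if (length(responders) > 0) {
    return(list(code = "SINGLE_RESPONDER", terms_used = responders,
                residual_pp = NA_real_, band = NA_character_))
  }
  list(code = "STABLE", terms_used = character(0),
       residual_pp = NA_real_, band = NA_character_)
}

#' Classify every protein instance in a comparison-result table
#'
#' @param profiles Long-format data frame with columns `protein`, `region`,
#'   `fraction`, `comparison`, `percent_difference`, `significant` — e.g. the
#'   gated output of [bonferroni_gate()] or the packaged printed-table
#'   transcription via [fixture_profiles()]. Every instance must carry all
#'   five classifier comparisons (NL, FL, B, RL, B-tm); duplicates are an
#'   error.
#' @param config A [classifier_config()] object.
#' @return A data frame with one row per instance: `protein`, `region`,
#'   `fraction`, `code`, `terms_used` (comma-separated), `residual_pp`,
#'   `band`, sorted by (region, fraction, protein) so the result is
#'   independent of input order.
#' @export
classify_all <- function(profiles, config = classifier_config()) {
  need <- c("protein", "region", "fraction", "comparison",
            "percent_difference", "significant")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    stop("classify_all: missing column(s): ", paste(miss, collapse = ", "))
  }
  profiles <- profiles[profiles$comparison %in% classifier_comparisons, ,
                       drop = FALSE]
  key <- paste(profiles$protein, profiles$region, profiles$fraction,
               profiles$comparison, sep = "\r")
  if (anyDuplicated(key)) {
    d <- profiles[duplicated(key), , drop = FALSE][1, ]
    stop("classify_all: duplicate profile entry for ", d$protein, " / ",
         d$region, " / ", d$fraction, " [", d$comparison, "]")
  }
  pieces <- split(profiles, paste(profiles$region, profiles$fraction,
                                  profiles$protein, sep = "\r"))
  rows <- lapply(pieces, function(p) {
    values <- stats::setNames(p$percent_difference, p$comparison)
    sig <- stats::setNames(as.logical(p$significant), p$comparison)
    cl <- classify_profile(values, sig, config)
    data.frame(protein = p$protein[1], region = p$region[1],
               fraction = p$fraction[1], code = cl$code,
               terms_used = paste(cl$terms_used, collapse = ","),
               residual_pp = cl$residual_pp, band = cl$band,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$fraction, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
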