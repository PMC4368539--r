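#' Experimental groups of the context-fear-conditioning design
#'
#' The study crosses genotype (control vs. trisomic Ts65Dn), conditioning
#' paradigm (SC, shock-context, which does not produce learning, vs. CS,
#' context-shock, which does) and drug (saline vs. memantine), giving eight
#' groups. Each group carries a stable compact label of the form
#' `"t-CS-mem"` used throughout the package.
#'
#' @return A data frame with one row per group and columns `genotype`,
#'   `paradigm`, `drug` and `label`.
#' @examples
#' rppa_groups()
#' @export
rppa_groups <- function() {
  g <- expand.grid(
    drug     = c("saline", "memantine"),
    paradigm = c("SC", "CS"),
    genotype = c("control", "trisomic"),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("genotype", "paradigm", "drug")]
  g$label <- group_label(g$genotype, g$paradigm, g$drug)
  g
}

#' Compact label for an experimental group
#'
#' @param genotype `"control"` or `"trisomic"` (vectorised).
#' @param paradigm `"SC"` or `"CS"`.
#' @param drug `"saline"` or `"memantine"`.
#' @return Character vector of labels such as `"c-SC-sal"` or `"t-CS-mem"`.
#' @export
group_label <- function(genotype, paradigm, drug) {
  geno <- c(control = "c", trisomic = "t")[genotype]
  drg  <- c(saline = "sal", memantine = "mem")[drug]
  if (anyNA(geno)) stop("unknown genotype; expected 'control' or 'trisomic'")
  if (!all(paradigm %in% c("SC", "CS"))) {
    stop("unknown paradigm; expected 'SC' or 'CS'")
  }
  if (anyNA(drg)) stop("unknown drug; expected 'saline' or 'memantine'")
  paste(geno, paradigm, drg, sep = "-")
}

#' The nine biologically relevant pairwise group comparisons
#'
#' Returns the fixed battery of pairwise comparisons used throughout the
#' analysis: baseline genotype differences (B), memantine effects on each
#' baseline (B-tm, B-cm, B-tm-cs), the three learning contrasts (NL, normal
#' learning in controls; FL, failed learning in trisomics; RL,
#' memantine-rescued learning in trisomics), and the two endpoint contrasts
#' (RL-FL, RL-NL). For each comparison the estimated effect is the percent
#' difference of `group_a` relative to `group_b`.
#'
#' @return A data frame with columns `code`, `group_a`, `group_b` and
#'   `description`, one row per comparison (nine rows).
#' @examples
#' comparison_battery()
#' @export
comparison_battery <- function() {
  data.frame(
    code = c("B", "B-tm", "B-cm", "B-tm-cs", "NL", "FL", "RL", "RL-FL", "RL-NL"),
    group_a = c("t-SC-sal", "t-SC-mem", "c-SC-mem", "t-SC-mem",
                "c-CS-sal", "t-CS-sal", "t-CS-mem", "t-CS-mem", "t-CS-mem"),
    group_b = c("c-SC-sal", "t-SC-sal", "c-SC-sal", "c-SC-sal",
                "c-SC-sal", "t-SC-sal", "t-SC-mem", "t-CS-sal", "c-CS-sal"),
    description = c(
      "initial genotype differences",
      "memantine effect on trisomic baseline",
      "memantine effect on control baseline",
      "memantine-treated trisomic baseline vs saline control baseline",
      "CFC training effect in saline-injected controls",
      "CFC training effect in saline-injected trisomics",
      "CFC training effect in memantine-injected trisomics",
      "endpoint: rescued vs failed learning",
      "endpoint: rescued vs normal learning"
    ),
    stringsAsFactors = FALSE
  )
}

#' Percent difference between two positive means
#'
#' @param mu_a,mu_b Group means on the positive linear scale; `mu_b` is the
#'   reference.
#' @return `100 * (mu_a - mu_b) / mu_b`, vectorised.
#' @examples
#' percent_difference(1.2, 1) # 20
#' @export
percent_difference <- function(mu_a, mu_b) {
  if (any(!is.finite(mu_b)) || any(mu_b <= 0)) {
    stop("percent_difference: reference mean mu_b must be positive and finite")
  }
  100 * (mu_a - mu_b) / mu_b
}

#' Recompute the nine comparison contrasts from eight group means
#'
#' Given the true (or estimated) mean normalized abundance of each of the
#' eight groups, computes the percent difference for every comparison in
#' [comparison_battery()].
#'
#' @param means Named numeric vector of positive means; names must be the
#'   eight group labels of [rppa_groups()].
#' @return Named numeric vector of percent differences, one per comparison
#'   code.
#' @export
contrasts_from_means <- function(means) {
  labs <- rppa_groups()$label
  missing <- setdiff(labs, names(means))
  if (length(missing) > 0) {
    stop("contrasts_from_means: missing group means for ",
         paste(missing, collapse = ", "))
  }
  bat <- comparison_battery()
  out <- percent_difference(unname(means[bat$group_a]), unname(means[bat$group_b]))
  names(out) <- bat$code
  out
}
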