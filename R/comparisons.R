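#' Statistical configuration for the pairwise comparisons
#'
#' @param family_alpha Family-wise significance level for the Bonferroni gate.
#' @param transform Scale on which the mixed model is fitted: `"log"`
#'   (default; percent differences are obtained by back-transformation, with
#'   the SEM propagated by the delta method) or `"linear"`.
#' @param fallback What to do when the REML fit fails or does not converge:
#'   `"nested_means"` (default; deterministic means-of-means estimator with a
#'   Welch test on mouse-level means, recorded in the result's `method`
#'   column) or `"error"`.
#' @return An object of class `rppa_stats_config`.
#' @export
stats_config <- function(family_alpha = 0.05,
                         transform = c("log", "linear"),
                         fallback = c("nested_means", "error")) {
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("stats_config: family_alpha must be in (0, 1)")
  }
  structure(
    list(family_alpha = family_alpha,
         transform = match.arg(transform),
         fallback = match.arg(fallback)),
    class = "rppa_stats_config"
  )
}

# mouse-level means by nesting: spot -> dilution mean -> mouse mean
nested_mouse_means <- function(y, mouse, dilution) {
  dkey <- paste(mouse, dilution, sep = "\r")
  dmean <- tapply(y, dkey, mean)
  dmouse <- sub("\r.*$", "", names(dmean))
  tapply(as.vector(dmean), dmouse, mean)
}

# deterministic fallback: nested means-of-means + Welch test on mouse means
fit_nested_means <- function(ya, yb, mouse_a, mouse_b, dil_a, dil_b) {
  ma <- nested_mouse_means(ya, mouse_a, dil_a)
  mb <- nested_mouse_means(yb, mouse_b, dil_b)
  beta <- mean(ma) - mean(mb)
  va <- stats::var(ma) / length(ma)
  vb <- stats::var(mb) / length(mb)
  se <- sqrt(va + vb)
  if (is.finite(se) && se > 0) {
    df <- (va + vb)^2 / (va^2 / (length(ma) - 1) + vb^2 / (length(mb) - 1))
    p <- 2 * stats::pt(-abs(beta / se), df)
  } else {
    # degenerate (zero between-mouse variance): exact data, exact verdict
    se <- 0
    p <- if (abs(beta) > 0) 0 else 1
  }
  list(beta = beta, se = se, p = p, mu_b = mean(mb), method = "nested_means")
}

fit_reml <- function(y, arm, mouse, dilution) {
  d <- data.frame(y = y, arm = arm,
                  mouse = factor(mouse),
                  series = factor(paste(mouse, dilution, sep = ":")))
  fit <- lme4::lmer(y ~ arm + (1 | mouse) + (1 | series), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  co <- summary(fit)$coefficients
  list(beta = co["arma", "Estimate"], se = co["arma", "Std. Error"],
       mu_b = co["(Intercept)", "Estimate"], method = "reml")
}

#' Fit one pairwise comparison for one protein instance
#'
#' Fits the three-level mixed-effects model for the two groups of a
#' comparison: transformed normalized intensity ~ fixed group effect +
#' random intercept per mouse + random intercept per dilution series within
#' mouse + spot residual, by REML. The fixed effect is reported as a percent
#' difference of group A relative to group B on the linear scale (for the log
#' transform, `100 * (exp(beta) - 1)`, SEM by the delta method), with a Wald
#' p-value referred to a t distribution on between-mouse degrees of freedom
#' (`n_a + n_b - 2`). Data with no spot-level variability, or fits that fail
#' to converge, use the documented deterministic fallback (nested
#' means-of-means with a Welch test on mouse-level means).
#'
#' @param x Clean normalized measurements for one protein instance (see
#'   [clean_spots()]); must contain both comparison groups.
#' @param def One row of [comparison_battery()] (or a list with `code`,
#'   `group_a`, `group_b`).
#' @param config A [stats_config()] object.
#' @return A one-row data frame: `protein`, `region`, `fraction`,
#'   `comparison`, `percent_difference`, `sem`, `p_value`, `n_a`, `n_b`,
#'   `method`, `status`.
#' @export
fit_pairwise <- function(x, def, config = stats_config()) {
  inst <- unique(x[, c("protein", "region", "fraction")])
  if (nrow(inst) != 1) {
    stop("fit_pairwise: x must hold exactly one protein instance")
  }
  lab <- group_label(x$genotype, x$paradigm, x$drug)
  res <- data.frame(protein = inst$protein, region = inst$region,
                    fraction = inst$fraction, comparison = def$code,
                    percent_difference = NA_real_, sem = NA_real_,
                    p_value = NA_real_, n_a = 0L, n_b = 0L,
                    method = NA_character_, status = "unestimable",
                    stringsAsFactors = FALSE)
  a <- x[lab == def$group_a, , drop = FALSE]
  b <- x[lab == def$group_b, , drop = FALSE]
  res$n_a <- length(unique(a$mouse_id))
  res$n_b <- length(unique(b$mouse_id))
  if (res$n_a < 2 || res$n_b < 2) return(res)

  trans <- function(v) if (config$transform == "log") log(v) else v
  ya <- trans(a$normalized_intensity)
  yb <- trans(b$normalized_intensity)
  if (any(!is.finite(c(ya, yb)))) return(res)

  y <- c(ya, yb)
  arm <- factor(rep(c("a", "b"), c(length(ya), length(yb))),
                levels = c("b", "a"))
  mouse <- c(a$mouse_id, b$mouse_id)
  dil <- c(a$dilution_step, b$dilution_step)

  # residual variation around group/mouse/dilution cell means; exactly-zero
  # data cannot support a REML fit and goes straight to the fallback
  cellm <- stats::ave(y, paste(arm, mouse, dil, sep = "\r"))
  degenerate <- max(abs(y - cellm)) < 1e-10

  fit <- NULL
  if (!degenerate) {
    not_converged <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        fit_reml(y, arm, mouse, dil),
        warning = function(w) {
          if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
            not_converged <<- TRUE
          }
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) NULL
    )
    if (not_converged) fit <- NULL
  }
  if (is.null(fit)) {
    if (config$fallback == "error" && !degenerate) {
      stop("fit_pairwise: REML fit failed for ", inst$protein, " / ",
           inst$region, " / ", inst$fraction, " [", def$code, "]")
    }
    fit <- fit_nested_means(ya, yb, a$mouse_id, b$mouse_id,
                            a$dilution_step, b$dilution_step)
    p <- fit$p
  } else {
    df <- res$n_a + res$n_b - 2
    p <- 2 * stats::pt(-abs(fit$beta / fit$se), df)
  }

  if (config$transform == "log") {
    res$percent_difference <- 100 * (exp(fit$beta) - 1)
    res$sem <- 100 * exp(fit$beta) * fit$se
  } else {
    if (fit$mu_b <= 0) return(res)
    res$percent_difference <- 100 * fit$beta / fit$mu_b
    res$sem <- 100 * fit$se / abs(fit$mu_b)
  }
  res$p_value <- p
  res$method <- fit$method
  res$status <- "ok"
  res
}

#' Fit the full comparison battery across all protein instances
#'
#' @param x Preprocessed measurement data frame (flags are honoured via
#'   [clean_spots()]).
#' @param config A [stats_config()] object.
#' @param battery Comparison definitions; defaults to the nine of
#'   [comparison_battery()]. Comparisons whose groups are absent from the
#'   design are skipped.
#' @return A data frame of [fit_pairwise()] rows, one per instance x
#'   comparison.
#' @export
fit_all_comparisons <- function(x, config = stats_config(),
                                battery = comparison_battery()) {
  if (!is.null(x$qc_invalid)) x <- clean_spots(x)
  if (nrow(x) == 0) stop("fit_all_comparisons: no clean spots to analyse")
  labs <- unique(group_label(x$genotype, x$paradigm, x$drug))
  battery <- battery[battery$group_a %in% labs & battery$group_b %in% labs, ,
                     drop = FALSE]
  if (nrow(battery) == 0) {
    stop("fit_all_comparisons: no comparison has both groups in the data")
  }
  pieces <- split(x, instance_key(x))
  out <- lapply(pieces, function(inst_x) {
    do.call(rbind, lapply(seq_len(nrow(battery)), function(i) {
      fit_pairwise(inst_x, battery[i, ], config)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$region, out$fraction, out$protein,
            match(out$comparison, comparison_battery()$code)), ,
      drop = FALSE]
}

#' Apply the Bonferroni family-wise gate
#'
#' The multiplicity family is the set of proteins analysed within one region
#' x fraction; each comparison's p-value is gated at
#' `family_alpha / m_tests`. With the 73 proteins detectable in the
#' hippocampal nuclear fraction and alpha 0.05 the per-test threshold is
#' 0.05 / 73 = 6.85e-4.
#'
#' @param results Data frame from [fit_all_comparisons()] (or any table with
#'   `protein`, `region`, `fraction`, `p_value`, `status`).
#' @param config A [stats_config()] object.
#' @return `results` with integer column `m_tests` and logical `significant`.
#' @export
bonferroni_gate <- function(results, config = stats_config()) {
  if (nrow(results) == 0) stop("bonferroni_gate: empty result family")
  fam <- paste(results$region, results$fraction, sep = "\r")
  ok <- results$status == "ok"
  m <- vapply(split(ifelse(ok, results$protein, NA_character_), fam),
              function(p) length(unique(p[!is.na(p)])), integer(1))
  results$m_tests <- pmax(m[fam], 1L)
  results$significant <- ok & !is.na(results$p_value) &
    results$p_value < config$family_alpha / results$m_tests
  results
}
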