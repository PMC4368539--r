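# profile helper: values + significance from two named vectors
prof <- function(...) {
  v <- c(...)
  list(values = v, sig = setNames(v != 0, names(v)))
}

test_that("published worked examples classify to their reported patterns", {
  t3 <- load_fixture("table3")
  asg <- classify_all(fixture_profiles(t3))
  pick <- function(p, f) asg[asg$protein == p & asg$fraction == f, ]

  cana <- pick("CaNA", "nuclear")
  expect_equal(cana$code, "FL_EQ_NL")
  expect_equal(cana$residual_pp, 19.7 - 16.7, tolerance = 1e-9)
  expect_equal(cana$band, "within")

  pjnk <- pick("pJNK", "nuclear")
  expect_equal(pjnk$code, "BTM_PLUS_RL")
  expect_equal(abs(pjnk$residual_pp), abs(31.0 - 36.3), tolerance = 1e-9)
  expect_equal(pjnk$band, "within")

  braf <- pick("BRAF", "nuclear")
  expect_equal(braf$code, "B_PLUS_FL")
  expect_equal(abs(braf$residual_pp), abs(55.7 - 59.4), tolerance = 1e-9)

  expect_equal(pick("pPKCA", "nuclear")$code, "B_COMP")
  expect_equal(pick("pELK", "nuclear")$code, "STABLE")
  expect_equal(pick("DYRK1A", "cytosolic")$code, "B_ABN_UNCOMP")
})

test_that("each rule branch is reachable on constructed profiles", {
  cases <- list(
    list(prof(NL = 20, FL = 18, B = 0, RL = 19, `B-tm` = 0), "FL_EQ_NL"),
    list(prof(NL = 20, FL = 0, B = 22, RL = 0, `B-tm` = 0), "B_COMP"),
    list(prof(NL = 40, FL = 22, B = 15, RL = 20, `B-tm` = 0), "B_PLUS_FL"),
    list(prof(NL = 30, FL = 0, B = 0, RL = 28, `B-tm` = 0), "RL_EQ_NL"),
    list(prof(NL = 30, FL = 0, B = 0, RL = 0, `B-tm` = 27), "BTM_COMP"),
    list(prof(NL = 40, FL = 0, B = 18, RL = 0, `B-tm` = 25), "BTM_COMP"),
    list(prof(NL = 40, FL = 0, B = 0, RL = 18, `B-tm` = 24), "BTM_PLUS_RL"),
    list(prof(NL = 40, FL = 0, B = 20, RL = 21, `B-tm` = 0), "RL_PLUS_B"),
    list(prof(NL = 45, FL = 0, B = 15, RL = 16, `B-tm` = 15),
         "RL_PLUS_B_PLUS_BTM"),
    list(prof(NL = 60, FL = 5, B = 0, RL = 0, `B-tm` = 0), "NL_UNRESOLVED"),
    list(prof(NL = 0, FL = -19, B = 21, RL = 0, `B-tm` = 0), "B_ABN_COMP_FL"),
    list(prof(NL = 0, FL = 0, B = 21, RL = 0, `B-tm` = -20), "B_ABN_COMP_MEM"),
    list(prof(NL = 0, FL = 0, B = 30, RL = 0, `B-tm` = 0), "B_ABN_UNCOMP"),
    list(prof(NL = 0, FL = 15, B = 0, RL = 0, `B-tm` = 0), "SINGLE_RESPONDER"),
    list(prof(NL = 0, FL = 0, B = 0, RL = 0, `B-tm` = 0), "STABLE")
  )
  for (cs in cases) {
    got <- classify_profile(cs[[1]]$values, cs[[1]]$sig)
    expect_equal(got$code, cs[[2]],
                 info = paste(names(cs[[1]]$values), cs[[1]]$values,
                              collapse = " "))
  }
})

test_that("sign gating blocks opposite-direction matches", {
  # a small FL decrease lies within 10 points of a small NL increase, but the
  # sign gate must still reject the match
  p <- prof(NL = 4, FL = -4, B = 0, RL = 0, `B-tm` = 0)
  got <- classify_profile(p$values, p$sig)
  expect_false(got$code == "FL_EQ_NL")
  # likewise a baseline decrease cannot compensate an NL increase
  p2 <- prof(NL = 5, FL = 0, B = -5, RL = 0, `B-tm` = 0)
  expect_false(classify_profile(p2$values, p2$sig)$code == "B_COMP")
})

test_that("non-significant terms contribute zero under the default policy", {
  v <- c(NL = 40, FL = 0, B = 25, RL = 16, `B-tm` = 30)
  s <- c(NL = TRUE, FL = FALSE, B = FALSE, RL = TRUE, `B-tm` = TRUE)
  # with B non-significant, B-tm + RL = 46 misses NL = 40 by 6 -> matches
  got <- classify_profile(v, s)
  expect_equal(got$code, "BTM_PLUS_RL")
  expect_equal(got$residual_pp, 6, tolerance = 1e-9)
  # point-estimate policy includes B in the grand sum candidate instead
  got2 <- classify_profile(v, s,
                           classifier_config(ns_term_policy = "point_estimate"))
  expect_equal(got2$code, "BTM_PLUS_RL") # precedence unchanged here
})

test_that("raising the tolerance never demotes a matched code to unresolved", {
  set.seed(7)
  for (i in 1:200) {
    v <- c(NL = round(runif(1, -60, 60), 1),
           FL = round(runif(1, -40, 40), 1),
           B = round(runif(1, -40, 40), 1),
           RL = round(runif(1, -40, 40), 1),
           `B-tm` = round(runif(1, -40, 40), 1))
    s <- setNames(runif(5) < 0.6, names(v))
    lo <- classify_profile(v, s, classifier_config(tolerance_pp = 8))
    hi <- classify_profile(v, s, classifier_config(tolerance_pp = 14))
    if (lo$code != "NL_UNRESOLVED") {
      expect_false(hi$code == "NL_UNRESOLVED",
                   info = paste(round(v, 1), collapse = "/"))
    }
  }
})

test_that("classification is total, deterministic and order-independent", {
  profs <- fixture_profiles(load_fixture("table3"))
  a1 <- classify_all(profs)
  a2 <- classify_all(profs[sample(nrow(profs)), ])
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 139) # 73 nuclear + 66 cytosolic instances
  expect_true(all(a1$code %in% pattern_codes()))
  expect_equal(anyDuplicated(a1[, c("protein", "region", "fraction")]), 0L)
  # empty input stays empty-safe via zero instances
  expect_error(classify_all(rbind(profs, profs[1, ])), "duplicate")
})

test_that("missing comparisons are named in the error", {
  profs <- fixture_profiles(load_fixture("table3"))
  broken <- profs[!(profs$protein == "AKT" & profs$fraction == "nuclear" &
                      profs$comparison == "RL"), ]
  expect_error(classify_all(broken), "RL")
})

test_that("hippocampal roster rows the rules can match stay in the published family", {
  # Instances the printed roster places in the "memantine not required"
  # patterns should classify into that family. Five instances cannot match
  # any rule within the 10-point tolerance (their nearest candidate misses
  # NL by 11-24 points) and land in NL_UNRESOLVED; they are pinned here as
  # known discordances with the printed roster rather than silently dropped.
  discordant <- c("nuclear.ELK", "nuclear.H3AcK18", "cytosolic.pERK",
                  "cytosolic.pNR2A", "cytosolic.pMEK")
  t4 <- load_fixture("table4")
  t4 <- t4[t4$region == "hippocampus" & t4$fraction != "membrane", ]
  t4$protein <- normalize_roster_name(t4$protein)
  asg <- classify_all(fixture_profiles(load_fixture("table3")))
  key <- paste(asg$fraction, asg$protein, sep = ".")
  roster_key <- paste(t4$fraction, t4$protein, sep = ".")
  expect_true(all(roster_key %in% key)) # every roster instance is classified
  codes <- setNames(asg$code, key)[roster_key]
  in_family <- codes %in% c("FL_EQ_NL", "B_COMP", "B_PLUS_FL")
  expect_identical(sort(roster_key[!in_family]), sort(discordant))
  expect_identical(unique(unname(codes[!in_family])), "NL_UNRESOLVED")
})
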