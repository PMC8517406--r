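fake_sites <- function(n, roi = "HGPM", hemisphere = "R") {
  data.frame(site = sprintf("e%02d", seq_len(n)), hemisphere = hemisphere,
             x_mni = 45, y_mni = -20, z_mni = 8, roi = roi,
             roi_group = roi_group(roi), excluded = FALSE,
             stringsAsFactors = FALSE)
}

fake_class <- function(sites, positive, negative = rep(FALSE, nrow(sites)),
                       state = "W") {
  data.frame(site = sites$site, state = state, positive = positive,
             negative = negative, stringsAsFactors = FALSE)
}

test_that("hemisphere flip negates left x once and only once", {
  el <- data.frame(site = c("l1", "r1"), hemisphere = c("L", "R"),
                   x_mni = c(-45, 45), y_mni = c(-20, -20), z_mni = c(5, 5),
                   roi = "HGPM", roi_group = "HGPM", excluded = FALSE)
  f <- flip_left_hemisphere(el)
  expect_equal(f$x_mni, c(45, 45))  # mirror-symmetric pair coincides
  expect_error(flip_left_hemisphere(f), "already flipped")
})

test_that("ROI subdivisions map onto the group scheme", {
  expect_equal(roi_group(c("HGPM", "PT", "Posterior STG", "MTG", "IFG",
                           "Precentral g.")),
               c("HGPM", "STP", "STG", "Auditory-related", "Prefrontal",
                 "Other"))
})

test_that("prevalence counts and percentages follow the definition", {
  sites <- fake_sites(44)
  pos <- rep(c(TRUE, FALSE), c(20, 24))
  prev <- prevalence(fake_class(sites, pos), sites)
  row <- prev[prev$sign == "positive", ]
  expect_equal(row$n_total, 44)
  expect_equal(row$n_significant, 20)
  expect_equal(row$percent, 100 * 20 / 44)
  expect_equal(format_percent_printed(row$percent), "45.5")
  # no significant sites -> all percents zero
  prev0 <- prevalence(fake_class(sites, rep(FALSE, 44)), sites)
  expect_true(all(prev0$percent == 0))
  # a site significant for both signs increments both rows
  both <- fake_class(sites, c(TRUE, rep(FALSE, 43)),
                     c(TRUE, rep(FALSE, 43)))
  prev2 <- prevalence(both, sites)
  expect_equal(prev2$n_significant[prev2$sign == "positive"], 1)
  expect_equal(prev2$n_significant[prev2$sign == "negative"], 1)
  # excluded sites never enter; unknown sites are a join error
  sites2 <- sites; sites2$excluded[1:4] <- TRUE
  prev3 <- prevalence(fake_class(sites, pos), sites2)
  expect_equal(prev3$n_total[1], 40)
  cl_bad <- fake_class(sites, pos); cl_bad$site[1] <- "nowhere"
  expect_error(prevalence(cl_bad, sites), "unknown site")
})

test_that("prevalence is monotone when alpha tightens", {
  # lowering alpha can only demote sites: recompute with a subset flagged
  sites <- fake_sites(30)
  loose <- rep(c(TRUE, FALSE), c(12, 18))
  tight <- loose & rep(c(TRUE, FALSE), 15)  # subset of the loose calls
  p_loose <- prevalence(fake_class(sites, loose), sites)
  p_tight <- prevalence(fake_class(sites, tight), sites)
  expect_lte(p_tight$percent[p_tight$sign == "positive"],
             p_loose$percent[p_loose$sign == "positive"])
})

test_that("reference coverage table sums to its printed totals", {
  tab <- reference_site_counts()
  expect_equal(sum(tab$hgpm), 44)
  expect_equal(sum(tab$stp), 64)
  expect_equal(sum(tab$stg), 109)
  expect_equal(sum(tab$auditory_related), 364)
  expect_equal(sum(tab$prefrontal), 251)
  expect_equal(sum(tab$other), 339)
  expect_equal(sum(tab$total), 1171)
  # per-subject row sums are internally consistent
  expect_equal(tab$hgpm + tab$stp + tab$stg + tab$auditory_related +
                 tab$prefrontal + tab$other, tab$total)
})

test_that("reference prevalence arithmetic reproduces printed percentages", {
  chk <- check_reference_prevalence()
  # every arithmetically consistent cell agrees at printed precision
  clean <- chk[!chk$flagged_inconsistent, ]
  expect_true(all(clean$agrees))
  # the flagged cells disagree with print but match correct arithmetic
  flagged <- chk[chk$flagged_inconsistent, ]
  expect_true(all(!flagged$agrees))
  expect_equal(nrow(flagged), 3)
})

test_that("latency comparisons run the three planned tests", {
  set.seed(77)
  mk <- function(g, st, sgn, n, mu) {
    data.frame(site = paste0(g, st, sgn, seq_len(n)), state = st,
               sign = sgn, roi_group = g,
               latency_ms = rnorm(n, mu, 15))
  }
  lat <- rbind(
    mk("HGPM", "W", "positive", 8, 115),
    mk("STP", "W", "positive", 8, 108),
    mk("STG", "W", "positive", 8, 128),
    mk("Auditory-related", "W", "positive", 8, 120),
    mk("HGPM", "S", "positive", 6, 160),
    mk("STG", "S", "positive", 6, 158),
    mk("Auditory-related", "W", "negative", 10, 441),
    mk("Prefrontal", "W", "negative", 10, 335))
  rep <- latency_comparisons(lat)
  expect_false(rep$kw_positive_w$skipped)
  expect_gt(rep$kw_positive_w$p, 0.001)
  # awake vs sedated shift of ~45 ms is detected
  expect_false(rep$ranksum_w_vs_s$skipped)
  expect_lt(rep$ranksum_w_vs_s$p, 0.01)
  expect_false(rep$ranksum_negative$skipped)
  # four identical latency groups: KW p ~ 1
  same <- rbind(mk("HGPM", "W", "positive", 5, 120),
                mk("STP", "W", "positive", 5, 120),
                mk("STG", "W", "positive", 5, 120),
                mk("Auditory-related", "W", "positive", 5, 120))
  same$latency_ms <- rep(c(100, 110, 120, 130, 140), 4)
  reps <- latency_comparisons(same)
  expect_gt(reps$kw_positive_w$p, 0.95)
  # single-group input: comparisons are skipped, not crashed
  solo <- mk("HGPM", "W", "positive", 5, 120)
  rep2 <- latency_comparisons(solo)
  expect_true(rep2$kw_positive_w$skipped)
  expect_true(rep2$ranksum_negative$skipped)
})

test_that("rank-sum detects a large constant latency shift", {
  set.seed(13)
  a <- rnorm(20, 120, 10)
  b <- rnorm(20, 420, 10)
  expect_lt(wilcox.test(a, b)$p.value, 0.001)
  lat <- rbind(
    data.frame(site = paste0("a", 1:20), state = "W", sign = "negative",
               roi_group = "Auditory-related", latency_ms = b),
    data.frame(site = paste0("p", 1:20), state = "W", sign = "negative",
               roi_group = "Prefrontal", latency_ms = a))
  rep <- latency_comparisons(lat)
  expect_lt(rep$ranksum_negative$p, 0.001)
})

test_that("time-course summaries average only significant sites", {
  ep1 <- simulate_null_epochs(5, seed = 1, site = "e01")
  ep2 <- simulate_null_epochs(5, seed = 2, site = "e02")
  cl1 <- permutation_test(ep1, n_perm = 200, seed = 3)
  cl2 <- permutation_test(ep2, n_perm = 200, seed = 3)
  cl1$positive <- TRUE                   # force classifications for the
  cl2$positive <- FALSE; cl2$negative <- TRUE  # aggregation logic test
  sites <- fake_sites(2)
  tc <- timecourse_summary(list(cl1, cl2), sites)
  pos <- tc$traces[["HGPM/W/positive"]]
  expect_equal(pos$mean_t, cl1$t)  # single site: trace equals its t series
  expect_equal(pos$n_sites, rep(1, length(cl1$t)))
  neg <- tc$traces[["HGPM/W/negative"]]
  expect_equal(neg$mean_t, cl2$t)  # opposite signs never cancel across traces
  expect_false("HGPM/S/positive" %in% names(tc$traces))
})

test_that("synthetic MNI-box assigner covers the canonical groups", {
  g <- synthetic_mni_box_roi(c(42, 60, 40, 45), c(-18, -20, -60, 40),
                             c(8, 5, -20, 10))
  expect_equal(g[1], "HGPM")
  expect_equal(g[4], "Prefrontal")
  expect_true(all(g %in% lgdint:::ROI_GROUP_LEVELS))
})
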