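tab <- msc_viability_table()

test_that("packaged dose-response table reproduces every knot exactly", {
  expect_equal(tab$concentrations, c(0, 0.01, 0.1, 0.5, 1))
  expect_equal(tab$exposure_times, c(24, 48))
  for (i in seq_along(tab$exposure_times)) {
    for (j in seq_along(tab$concentrations)) {
      expect_equal(
        interpolate_viability(tab, tab$concentrations[j],
                              tab$exposure_times[i]),
        tab$mean_viability[i, j]
      )
    }
  }
  # anchor values: 90% at 0.1 mM / 48 h, 43% at 1 mM / 24 h, control 100%
  expect_equal(interpolate_viability(tab, 0.1, 48), 90)
  expect_equal(interpolate_viability(tab, 1, 24), 43)
  expect_equal(interpolate_viability(tab, 0, 24), 100)
  expect_equal(interpolate_viability(tab, 0, 48), 100)
})

test_that("the ambiguous SEM cell is parsed but flagged as suspect", {
  expect_equal(unname(tab$mean_viability["48", "0.5"]), 62)
  sus <- tab$metadata$suspect_sem
  expect_equal(nrow(sus), 1L)
  expect_equal(unname(tab$exposure_times[sus[1, "row"]]), 48)
  expect_equal(unname(tab$concentrations[sus[1, "col"]]), 0.5)
  expect_equal(tab$metadata$verbatim[sus], "62 ± 35")
})

test_that("interpolation is log-linear between doses and bounded", {
  # geometric midpoint between the 0.1 and 0.5 mM knots at 24 h
  mid <- sqrt(0.1 * 0.5)
  expect_equal(interpolate_viability(tab, mid, 24), (70 + 64) / 2)
  # between the control and the smallest dose the segment is linear in dose
  expect_equal(interpolate_viability(tab, 0.005, 24), (100 + 86) / 2)
  expect_error(interpolate_viability(tab, 1.5, 24), "extrapolate")
  expect_error(interpolate_viability(tab, -0.1, 24), ">= 0")
})

test_that("interpolated viability is monotone on monotone table rows", {
  # the 24 h row decreases monotonically with dose (the 48 h row does not:
  # its 0.01 mM cell sits at 105%)
  doses <- seq(0, 1, length.out = 101)
  v <- vapply(doses, function(d) interpolate_viability(tab, d, 24), numeric(1))
  expect_true(all(diff(v) <= 1e-9))
})

test_that("off-grid exposures fall back to the nearest time with a warning", {
  expect_warning(v <- interpolate_viability(tab, 0.1, 30), "nearest")
  expect_equal(v, 70) # 30 h snaps to 24 h
})

test_that("max safe concentration scans the tabulated row", {
  expect_equal(max_safe_concentration(tab, 90, 48), 0.1)
  expect_equal(max_safe_concentration(tab, 100, 24), 0) # only the control
  expect_equal(max_safe_concentration(tab, 30, 24), 1)  # all doses qualify
  expect_error(max_safe_concentration(tab, 0, 24), "floor")
  expect_error(max_safe_concentration(tab, 101, 24), "floor")
})

test_that("release profiles are classified against the ceiling", {
  flat <- classify_release_safety(rep(0.05, 5), threshold = 0.1,
                                  times = c(0, 1, 2, 4, 12))
  expect_true(flat$safe)
  expect_true(is.na(flat$first_exceedance_time))

  crossing <- classify_release_safety(
    c(0.01, 0.05, 0.12, 0.2), threshold = 0.1, times = c(0, 4, 12, 24)
  )
  expect_false(crossing$safe)
  expect_equal(crossing$first_exceedance_time, 12)
  expect_equal(crossing$max_observed_concentration, 0.2)

  expect_error(classify_release_safety(c(-0.1, 0.2), times = c(0, 1)),
               "negative")
  expect_error(classify_release_safety(numeric(0), times = numeric(0)),
               "matching|empty")
})

test_that("raising the ceiling never turns a safe profile unsafe", {
  set.seed(5)
  conc <- cumsum(runif(10, 0, 0.03))
  times <- 1:10
  thresholds <- seq(0.01, 0.4, by = 0.01)
  safe <- vapply(thresholds, function(th) {
    classify_release_safety(conc, threshold = th, times = times)$safe
  }, logical(1))
  expect_true(all(diff(safe) >= 0)) # FALSE -> TRUE only
})

test_that("anova from sums of squares matches stats::aov", {
  set.seed(21)
  g <- list(a = rnorm(5, 10), b = rnorm(6, 12), c = rnorm(4, 9))
  cg <- compare_groups(g)
  df <- data.frame(group = rep(names(g), lengths(g)), value = unlist(g))
  ref <- summary(stats::aov(value ~ group, df))[[1]]
  expect_equal(cg$f_statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(cg$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(cg$df, c(2, 12))
})

test_that("textbook hand-computed three-group anova is reproduced", {
  # small integer example where the sums of squares are exact by hand:
  # groups {1,2,3}, {2,3,4}, {4,5,6}; grand mean 10/3
  g <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(4, 5, 6))
  # SS_between = 3[(2-10/3)^2 + (3-10/3)^2 + (5-10/3)^2] = 14
  # SS_within = 2 + 2 + 2 = 6, df = (2, 6), F = (14/2)/(6/6) = 7
  cg <- compare_groups(g)
  expect_equal(cg$f_statistic, 7)
  expect_equal(cg$df, c(2, 6))
  expect_equal(cg$p_value, stats::pf(7, 2, 6, lower.tail = FALSE))
})

test_that("identical groups give F near zero and p near one", {
  g <- list(a = c(1, 2, 3, 2), b = c(1, 2, 3, 2))
  cg <- compare_groups(g)
  expect_lt(cg$f_statistic, 1e-12)
  expect_gt(cg$p_value, 0.999)
})

test_that("degenerate zero-variance data raise an error", {
  expect_error(compare_groups(list(a = c(1, 1), b = c(2, 2))), "variance")
  expect_error(compare_groups(list(a = 1:3)), "2 groups")
  expect_error(compare_groups(list(a = 1, b = 2)), "replicates")
})

test_that("anova p agrees with a permutation test within Monte-Carlo error", {
  set.seed(33)
  g <- list(a = rnorm(6, 0), b = rnorm(6, 1.2), c = rnorm(6, 0.5))
  cg <- compare_groups(g)
  pooled <- unlist(g)
  labels <- rep(names(g), lengths(g))
  n_perm <- 2000
  f_perm <- vapply(seq_len(n_perm), function(i) {
    compare_groups(split(pooled, sample(labels)))$f_statistic
  }, numeric(1))
  p_perm <- (sum(f_perm >= cg$f_statistic) + 1) / (n_perm + 1)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_perm - cg$p_value), 4 * mc_sd + 0.01)
})

test_that("lsd flags a large construct-vs-bolus effect at n = 6", {
  # effect sizes as declared by the viability generator: construct mean far
  # above bolus, moderate replicate noise
  set.seed(8)
  g <- list(bolus = rnorm(6, 40, 8), liposome = rnorm(6, 55, 8),
            construct = rnorm(6, 85, 8))
  cg <- compare_groups(g)
  row <- cg$lsd[cg$lsd$group1 == "bolus" & cg$lsd$group2 == "construct", ]
  expect_lte(row$p_value, 0.05)
  expect_true(row$significant)
})
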