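# ELISA calibration, cutoffs, positivity, correlations and the two-regime
# split.

test_that("OD-to-units conversion is linear, clamped at blank, and stable to collinear points", {
  cal <- elisa_calibration(c(0.05, 1.05), c(0, 100))
  expect_equal(od_to_units(0.55, cal), 50)
  expect_equal(od_to_units(0.05, cal), 0)
  expect_equal(od_to_units(0.01, cal), 0)  # below blank clamps to 0
  cal3 <- elisa_calibration(c(0.05, 0.55, 1.05), c(0, 50, 100))
  od <- c(0.2, 0.4, 0.9)
  expect_equal(od_to_units(od, cal3), od_to_units(od, cal))
  expect_error(elisa_calibration(0.5, 10), class = "pepzone_error_uncalibrated_assay")
  expect_error(elisa_calibration(c(1, 1), c(0, 10)),
               class = "pepzone_error_uncalibrated_assay")
  expect_error(od_to_units(0.5, list()), class = "pepzone_error_uncalibrated_assay")
})

test_that("percentile cutoff interpolates order statistics", {
  expect_equal(percentile_cutoff(1:100), 99.01)
  expect_equal(percentile_cutoff(rep(7, 30)), 7)
  v <- rlnorm(321, log(8), 0.5)
  cut <- percentile_cutoff(v)
  expect_lte(cut, max(v))
  expect_lte(percentile_cutoff(c(v, rep(0, 50))), cut)  # low values never raise it
  expect_error(percentile_cutoff(1:10), class = "pepzone_error_too_few_reference")
})

test_that("positivity is strictly greater-than the assay cutoff and monotone in it", {
  panel <- data.frame(id = c("a", "b", "c"),
                      anti_b2gp1_iga = c(20, 20.1, 0),
                      anti_d1_iga = c(23.9, 23.8, 0),
                      anti_d4_5_iga = c(30, 22, 0))
  flags <- classify_positivity(panel)
  expect_equal(flags$anti_b2gp1_iga, c(FALSE, TRUE, FALSE))  # 20 is not > 20
  expect_equal(flags$anti_d1_iga, c(TRUE, FALSE, FALSE))     # 23.9 > 23.8
  expect_equal(flags$anti_d4_5_iga, c(TRUE, FALSE, FALSE))
  # raising every cutoff never converts a negative into a positive
  raised <- classify_positivity(panel, cutoff_set(anti_b2gp1_iga = 25,
                                                  anti_d1_iga = 30,
                                                  anti_d4_5_iga = 35))
  for (a in c("anti_b2gp1_iga", "anti_d1_iga", "anti_d4_5_iga")) {
    expect_true(all(flags[[a]] | !raised[[a]]))
  }
  zero <- data.frame(id = "z", anti_b2gp1_iga = 0, anti_d1_iga = 0,
                     anti_d4_5_iga = 0)
  expect_false(any(unlist(classify_positivity(zero)[-1])))
  expect_error(classify_positivity(data.frame(id = 1, other = 2)),
               class = "pepzone_error_missing_assay")
})

test_that("pearson_ci reproduces the closed-form Fisher-z interval", {
  set.seed(10)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  res <- pearson_ci(x, y)
  z <- atanh(res$r)
  half <- qnorm(0.975) / sqrt(20 - 3)
  expect_equal(res$ci, tanh(c(z - half, z + half)), tolerance = 1e-12)
  expect_equal(res$n, 20L)

  # perfect linearity and independence limits
  expect_equal(pearson_ci(1:10, 2 * (1:10) + 1)$r, 1)
  set.seed(11)
  big <- pearson_ci(rnorm(2000), rnorm(2000))
  expect_lt(abs(big$r), 0.08)
  expect_error(pearson_ci(rep(1, 10), rnorm(10)),
               class = "pepzone_error_constant_input")

  # scale/shift invariance in each argument
  set.seed(12)
  a <- runif(30); b <- runif(30)
  r0 <- pearson_ci(a, b)$r
  expect_equal(pearson_ci(10 + 5 * a, b)$r, r0)
  expect_equal(pearson_ci(a, -2 * b + 3)$r, -r0)
})

test_that("Hinkle labels follow the rule-of-thumb bands", {
  expect_equal(pearson_ci(1:10, 2 * (1:10))$label, "very high")
  set.seed(13)
  x <- rnorm(500); y <- x + rnorm(500, 0, 1.05)
  res <- pearson_ci(x, y)
  expect_equal(res$label,
               c("negligible", "low", "moderate", "high", "very high")[
                 findInterval(abs(res$r), c(0, 0.3, 0.5, 0.7, 0.9))])
})

test_that("two-regime split recovers a planted mixture and flags homogeneous clouds", {
  # recovery of membership and of the correlated regime's r, averaged over a
  # fixed block of seeds (a single cohort draw leaves ~binomial wiggle on a
  # 93-serum split; the mean pins the property)
  fits <- lapply(1:15, function(s) {
    e <- gen_elisa(elisa_spec(seed = s))
    sp <- split_correlation(e$panel$anti_b2gp1_iga, e$panel$anti_d4_5_iga)
    truth_low <- e$truth$member == "uncorrelated"
    list(agree = mean((sp$group == "B") == truth_low), r_A = sp$r_A$r,
         informative = sp$informative)
  })
  expect_gte(mean(vapply(fits, `[[`, numeric(1), "agree")), 0.8)
  expect_lt(abs(mean(vapply(fits, `[[`, numeric(1), "r_A")) - 0.8), 0.1)
  expect_true(all(vapply(fits, `[[`, logical(1), "informative")))

  # homogeneous correlated cloud: split is non-informative
  set.seed(14)
  x <- rlnorm(93, log(60), 0.6)
  y <- 10 + 0.9 * x * exp(rnorm(93, 0, 0.2))
  hom <- split_correlation(x, y)
  expect_false(hom$informative)

  # infeasible minimum group size
  expect_error(split_correlation(x, y, min_frac = 0.6),
               class = "pepzone_error_no_feasible_split")
  expect_error(split_correlation(1:10, 1:10),
               class = "pepzone_error_no_feasible_split")
})

test_that("split correlation is deterministic and order-independent", {
  e <- gen_elisa(elisa_spec(seed = 2))
  x <- e$panel$anti_b2gp1_iga; y <- e$panel$anti_d4_5_iga
  sp1 <- split_correlation(x, y)
  perm <- sample(length(x))
  sp2 <- split_correlation(x[perm], y[perm])
  expect_equal(sp1$boundary, sp2$boundary)
  expect_equal(sp1$r_A$r, sp2$r_A$r)
  expect_equal(as.character(sp1$group)[perm], as.character(sp2$group))
})

test_that("group comparison picks chi-squared, Fisher, or Mann-Whitney appropriately", {
  # balanced null table -> Fisher (small expected counts), p = 1
  t_null <- matrix(c(3, 3, 3, 3), 2)
  res <- group_compare(t_null)
  expect_equal(res$method, "fisher")
  expect_equal(res$p, 1)

  # diagonal table vs exact hypergeometric enumeration
  t_diag <- matrix(c(10, 0, 0, 10), 2)
  res2 <- group_compare(t_diag)
  expect_equal(res2$method, "fisher")
  x_margin <- 0:10
  probs <- dhyper(x_margin, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(res2$p, p_exact)

  # large balanced counts -> Pearson chi-squared
  t_big <- matrix(c(30, 20, 22, 28), 2)
  expect_equal(group_compare(t_big)$method, "chisq")

  # identical numeric samples -> Mann-Whitney U at its null mean
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res3 <- group_compare(a, a)
  expect_equal(res3$method, "mann-whitney")
  expect_equal(res3$statistic, length(a)^2 / 2)
  expect_error(group_compare(matrix(0, 2, 2)),
               class = "pepzone_error_degenerate_table")
})

test_that("independent anti-D1 panels rarely show spurious moderate correlation", {
  # echoes the null anti-D1 finding as a property across seeds
  rs <- vapply(1:40, function(s) {
    e <- gen_elisa(elisa_spec(seed = s))
    pearson_ci(e$panel$anti_b2gp1_iga, e$panel$anti_d1_iga)$r
  }, numeric(1))
  expect_lt(mean(abs(rs) > 0.3), 0.05)
})
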