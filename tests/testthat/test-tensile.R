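test_that("true stress/strain transform matches hand arithmetic", {
  # gage 10 mm, diameter 2/sqrt(pi) um -> A0 = 1 um^2
  d <- 2 / sqrt(pi)
  tr <- tensile_trace(
    tibble::tibble(extension_mm = c(0, 5, 10), force_uN = c(2, 3, 4)),
    gage_length_mm = 10, diameter_um = d)
  cv <- true_curve(tr)
  expect_equal(cv$true_strain, c(0, log(1.5), log(2)))
  expect_equal(cv$true_stress_MPa, c(2, 3 * 1.5, 4 * 2))

  # true stress >= engineering stress; true strain <= engineering strain
  eng_stress <- tr$samples$force_uN / 1
  eng_strain <- tr$samples$extension_mm / 10
  expect_true(all(cv$true_stress_MPa >= eng_stress))
  expect_true(all(cv$true_strain <= eng_strain))

  expect_error(tensile_trace(tibble::tibble(extension_mm = c(0, -1),
                                            force_uN = c(0, 1)), 10, 1),
               "non-decreasing")
  expect_error(tensile_trace(tibble::tibble(extension_mm = c(0, 1),
                                            force_uN = c(0, 1)), 10, 0),
               "diameter")
})

test_that("linear and bilinear curves yield closed-form properties", {
  # sigma = E * eps to the break point: toughness = sigma_b * eps_b / 2
  e_mpa <- 5000
  eps <- seq(0, 0.4, length.out = 2001)
  curve <- tibble::tibble(true_strain = eps, true_stress_MPa = e_mpa * eps)
  props <- tensile_properties(curve)
  expect_equal(props$strength_MPa, e_mpa * 0.4)
  expect_equal(props$extensibility, 0.4)
  expect_equal(props$modulus_GPa, 5)
  expect_equal(props$toughness_MJ_m3, 0.5 * e_mpa * 0.4 * 0.4,
               tolerance = 1e-6)
  expect_lte(props$toughness_MJ_m3,
             props$strength_MPa * props$extensibility)

  # bilinear: stiff then soft
  tr <- simulate_tensile(modulus_GPa = 8, strength_MPa = 300,
                         extensibility = 0.3, yield_strain = 0.02)
  props2 <- tensile_properties(true_curve(tr))
  truth <- attr(tr, "truth")
  expect_equal(props2$modulus_GPa, truth$modulus_GPa)
  expect_equal(props2$strength_MPa, truth$strength_MPa)
  expect_equal(props2$extensibility, truth$extensibility)
  expect_equal(props2$toughness_MJ_m3, truth$toughness_MJ_m3)
})

test_that("toughness integration converges and resampling is stable", {
  e_mpa <- 2000; eps_b <- 0.5
  analytic <- 0.5 * e_mpa * eps_b^2
  for (n in c(100, 10000)) {
    eps <- seq(0, eps_b, length.out = n)
    t_n <- tensile_properties(
      tibble::tibble(true_strain = eps,
                     true_stress_MPa = e_mpa * eps))$toughness_MJ_m3
    if (n == 10000) expect_equal(t_n / analytic, 1, tolerance = 1e-3)
  }
  # uniform resampling of the loading portion leaves properties unchanged
  tr <- simulate_tensile(4, 250, 0.5, n_samples = 400)
  cv <- true_curve(tr)
  cv <- cv[seq_len(which.max(cv$true_stress_MPa)), ]
  dense <- tibble::tibble(
    true_strain = seq(0, max(cv$true_strain), length.out = 1500))
  dense$true_stress_MPa <- approx(cv$true_strain, cv$true_stress_MPa,
                                  dense$true_strain)$y
  p1 <- tensile_properties(cv)
  p2 <- tensile_properties(dense)
  expect_equal(p2$toughness_MJ_m3, p1$toughness_MJ_m3, tolerance = 1e-2)
  expect_equal(p2$strength_MPa, p1$strength_MPa, tolerance = 1e-2)
})

test_that("noisy simulated traces recover their parameters", {
  set.seed(73)
  res <- purrr::map_dfr(1:40, function(s) {
    tr <- simulate_tensile(3.9, 245, 0.57, noise_sd = 1.5,
                           n_samples = 400, seed = 100 + s)
    tensile_properties(true_curve(tr))
  })
  expect_lt(abs(mean(res$strength_MPa) - 245) / 245, 0.05)
  expect_lt(abs(mean(res$extensibility) - 0.57) / 0.57, 0.02)
  expect_lt(abs(mean(res$modulus_GPa) - 3.9) / 3.9, 0.25)
  truth_tough <- attr(simulate_tensile(3.9, 245, 0.57), "truth")$toughness_MJ_m3
  expect_lt(abs(mean(res$toughness_MJ_m3) - truth_tough) / truth_tough, 0.05)
})

test_that("trace files round-trip through the delimited format", {
  tr <- simulate_tensile(3, 200, 0.4, noise_sd = 0.5, seed = 5)
  path <- withr_local_file("trace.tsv")
  write_tensile_trace(tr, path)
  back <- read_tensile_trace(path)
  expect_equal(back$gage_length_mm, tr$gage_length_mm)
  expect_equal(back$diameter_um, tr$diameter_um)
  expect_equal(back$samples$force_uN, tr$samples$force_uN,
               tolerance = 1e-6)
  expect_s3_class(autoplot(back), "ggplot")
  broken <- withr_local_file("bad.tsv")
  writeLines(c("# gage_length_mm 10", "extension_mm\tforce_uN", "0\t1"),
             broken)
  expect_error(read_tensile_trace(broken), "diameter_um")
})

test_that("one-way ANOVA equals hand sums of squares with (2, 147) df", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                       y = c(1, 2, 3, 4, 6, 8))
  got <- anova_oneway(df, y, g)
  grand <- mean(df$y)
  ssb <- 3 * ((2 - grand)^2 + (6 - grand)^2)
  ssw <- sum((df$y[1:3] - 2)^2) + sum((df$y[4:6] - 6)^2)
  expect_equal(got$F, (ssb / 1) / (ssw / 4))
  expect_equal(c(got$df1, got$df2), c(1L, 4L))
  # cross-check against the stats machinery
  expect_equal(got$F, unname(summary(aov(y ~ g, df))[[1]]$`F value`[1]))
  expect_equal(got$p, unname(summary(aov(y ~ g, df))[[1]]$`Pr(>F)`[1]))

  set.seed(79)
  big <- tibble::tibble(g = rep(c("Lh", "Lg", "Sg"), each = 50),
                        y = rnorm(150))
  expect_equal(c(anova_oneway(big, y, g)$df1, anova_oneway(big, y, g)$df2),
               c(2L, 147L))
  ident <- tibble::tibble(g = rep(c("a", "b"), each = 4), y = rep(1:4, 2))
  expect_equal(anova_oneway(ident, y, g)$F, 0)
})

test_that("Tukey letters separate shifted groups and share otherwise", {
  expect_equal(misilk:::harmonic_mean(c(50, 50, 50)), 50)
  expect_equal(misilk:::harmonic_mean(c(40, 60)), 48)

  set.seed(83)
  same <- tibble::tibble(g = rep(c("a", "b", "c"), each = 30),
                         y = rnorm(90))
  letters_same <- tukey_hsd(same, y, g)
  expect_equal(length(unique(letters_same$letters)), 1L)

  shifted <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 30),
    y = c(rnorm(30), rnorm(30), rnorm(30) + 10))
  lt <- tukey_hsd(shifted, y, g)
  c_letter <- lt$letters[lt$group == "c"]
  others <- lt$letters[lt$group != "c"]
  expect_false(any(grepl(c_letter, others, fixed = TRUE)))
  # cross-check significance against stats::TukeyHSD on a balanced design
  hsd <- TukeyHSD(aov(y ~ g, shifted))$g
  sig <- rownames(hsd)[hsd[, "p adj"] < 0.05]
  expect_setequal(sig, c("c-a", "c-b"))
})
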