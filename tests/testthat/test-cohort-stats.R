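# The statistical layer: regressions, t-tests, slope Z-tests, correction,
# normative scores, distribution and trade-off checks.

fake_cohort <- function(n = 120, seed = 1, slope = 0, sex_shift = 0,
                        noise = 1) {
  set.seed(seed)
  age <- runif(n, 18, 93)
  sex <- rep(c("male", "female"), length.out = n)
  y <- 10 + slope * age + sex_shift * (sex == "male") + rnorm(n, 0, noise)
  data.frame(participant_id = sprintf("f%03d", 1:n), age = age, sex = sex,
             y = y, stringsAsFactors = FALSE)
}

test_that("age regression is exact on noiseless lines", {
  co <- fake_cohort(50, seed = 2)
  co$y <- 2 * co$age + 1
  r <- suppressWarnings(age_regression(co, "y"))   # exact fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-10)
  expect_equal(r$n, 50)
})

test_that("age regression equals the closed-form OLS oracle", {
  co <- fake_cohort(80, seed = 3, slope = -0.02)
  r <- age_regression(co, "y")
  expect_equal(r$slope, ols_slope_oracle(co$age, co$y), tolerance = 1e-10)
  # CI construction: point estimate inside, half-width = t quantile x SE
  expect_true(r$ci[1] <= r$slope && r$slope <= r$ci[2])
  expect_equal(r$ci[2] - r$slope, qt(0.975, r$n - 2) * r$se,
               tolerance = 1e-10)
})

test_that("an injected slope is recovered inside its own CI ~95% of the time", {
  hits <- 0L
  for (s in 1:100) {
    co <- fake_cohort(200, seed = s, slope = -0.01, noise = 0.2)
    r <- age_regression(co, "y")
    if (r$ci[1] <= -0.01 && -0.01 <= r$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 88)
})

test_that("degenerate regressions are refused informatively", {
  co <- fake_cohort(40)
  co$age <- 50
  expect_error(age_regression(co, "y"), "zero variance")
  expect_error(age_regression(fake_cohort(40), "nope"), "no column")
})

test_that("sex difference matches the pooled-t textbook oracle", {
  co <- fake_cohort(60, seed = 4, sex_shift = 0.8)
  got <- sex_difference(co, "y")
  want <- pooled_t_oracle(co$y[co$sex == "male"], co$y[co$sex == "female"])
  expect_equal(got$difference, want$difference, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$ci, want$ci, tolerance = 1e-10)
})

test_that("identical groups give zero difference, shifted groups cover delta", {
  set.seed(5)
  vals <- rnorm(20)
  co <- data.frame(age = runif(40, 18, 93),
                   sex = rep(c("male", "female"), each = 20),
                   y = c(vals, vals))   # same values in both groups
  got <- sex_difference(co, "y")
  expect_equal(got$difference, 0, tolerance = 1e-12)
  expect_equal(got$p, 1, tolerance = 1e-9)

  co2 <- fake_cohort(40, seed = 6, sex_shift = 2, noise = 1e-4)
  got2 <- sex_difference(co2, "y")
  expect_true(got2$ci[1] <= 2 && 2 <= got2$ci[2])
})

test_that("slope comparison Z-test: algebraic cases and antisymmetry", {
  a <- list(slope = -0.01, se = 0.002)
  b <- list(slope = -0.01, se = 0.003)
  eq <- compare_slopes(a, b)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  c1 <- list(slope = 0.002 * sqrt(2), se = 0.002)
  c2 <- list(slope = 0, se = 0.002)
  expect_equal(compare_slopes(c1, c2)$z, 1, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    r1 <- list(slope = rnorm(1), se = runif(1, 0.1, 1))
    r2 <- list(slope = rnorm(1), se = runif(1, 0.1, 1))
    expect_equal(compare_slopes(r1, r2)$z, -compare_slopes(r2, r1)$z)
  }
  expect_error(compare_slopes(list(slope = 1, se = 0),
                              list(slope = 1, se = 1)), "positive")
})

test_that("Bonferroni correction is plain division", {
  expect_equal(bonferroni(0.05, 68), 0.05 / 68)
  expect_equal(signif(bonferroni(0.05, 68), 2), 7.4e-4)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 10), 0.005)
  expect_error(bonferroni(0.05, 0), ">= 1")
})

test_that("effect projection is slope x years x scale", {
  expect_equal(project_effect(0.0005, 10), 0.005)
  expect_equal(project_effect(-0.1058 / 100, 10, 300), -3.174)
  expect_equal(project_effect(5, 0, 2), 0)
})

test_that("normative model: null slopes, in-sample standardisation, scores", {
  co <- fake_cohort(300, seed = 8, slope = 0, noise = 1)
  model <- fit_normative(co, "y")
  fit <- lm(y ~ age, data = co)
  ci <- confint(fit, "age")
  expect_true(ci[1] <= 0 && 0 <= ci[2])   # no age effect injected

  z <- vapply(seq_len(nrow(co)), function(i) {
    rapidmotor:::normative_z(model, co[i, , drop = FALSE])
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.05)
  expect_equal(sd(z), 1, tolerance = 0.05)

  # a participant exactly at the normative expectation scores 0
  f <- model$fits$y
  row <- data.frame(age = 50, sex = "female",
                    y = unname(f$coef[1] + f$coef[2] * 50))
  expect_equal(task_score(row, model), 0, tolerance = 1e-10)

  # orthogonal deviations add in quadrature: z = (3, 4) scores 5
  co2 <- co
  set.seed(9)
  co2$w <- rnorm(300)
  model2 <- fit_normative(co2, c("y", "w"))
  fy <- model2$fits$y; fw <- model2$fits$w
  row2 <- data.frame(age = 50, sex = "female",
                     y = unname(fy$coef[1] + fy$coef[2] * 50) + 3 * fy$sigma,
                     w = unname(fw$coef[1] + fw$coef[2] * 50) + 4 * fw$sigma)
  expect_equal(task_score(row2, model2), 5, tolerance = 1e-10)

  # missing parameters are excluded with a warning
  row3 <- row2; row3$w <- NA_real_
  expect_warning(s3 <- task_score(row3, model2), "missing")
  expect_equal(s3, 3, tolerance = 1e-10)
})

test_that("rank-based zeta standardisation is monotone and centred", {
  co <- fake_cohort(400, seed = 10)
  co$y <- exp(co$y / 3)    # skewed, one-sided
  model <- fit_normative(co, "y", types = c(y = "zeta"))
  zs <- vapply(seq_len(200), function(i) {
    rapidmotor:::normative_z(model, co[i, , drop = FALSE])
  }, numeric(1))
  expect_lt(abs(median(zs)), 0.2)
  expect_true(all(is.finite(zs)))
})

test_that("distribution check flags uniform but passes normal samples", {
  normal_pass <- 0L; uniform_reject <- 0L
  for (s in 1:20) {
    set.seed(s)
    if (distribution_check(rnorm(800))$p > 0.05) {
      normal_pass <- normal_pass + 1L
    }
    if (distribution_check(runif(800))$p < 0.05) {
      uniform_reject <- uniform_reject + 1L
    }
  }
  expect_gte(normal_pass, 18)
  expect_gte(uniform_reject, 18)

  set.seed(3)
  v <- rnorm(100)
  a <- distribution_check(v)
  b <- distribution_check(5 + 2 * v)      # affine invariance
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_error(distribution_check(rep(1, 50)), "constant")
})

test_that("trade-off regression: slopes for perfect, flat and skill cases", {
  perf <- data.frame(prop_targets_hit = seq(0.3, 0.9, 0.05))
  perf$prop_distractors_avoided <- perf$prop_targets_hit
  expect_equal(suppressWarnings(tradeoff_regression(perf))$slope, 1,
               tolerance = 1e-12)

  flat <- perf
  flat$prop_distractors_avoided <- 0.8
  expect_equal(suppressWarnings(tradeoff_regression(flat))$slope, 0,
               tolerance = 1e-12)

  # a shared skill factor lifts both proportions: positive slope
  set.seed(11)
  skill <- runif(200)
  sk <- data.frame(
    prop_targets_hit = pmin(1, 0.3 + 0.5 * skill + rnorm(200, 0, 0.05)),
    prop_distractors_avoided = pmin(1, 0.5 + 0.4 * skill +
                                      rnorm(200, 0, 0.05)))
  expect_gt(tradeoff_regression(sk)$slope, 0)
})

test_that("regression p-values agree with a permutation oracle", {
  co <- fake_cohort(30, seed = 12, slope = -0.015, noise = 0.6)
  r <- age_regression(co, "y")
  set.seed(13)
  n_perm <- 1000
  obs <- abs(ols_slope_oracle(co$age, co$y))
  perm <- vapply(seq_len(n_perm), function(i) {
    abs(ols_slope_oracle(co$age, sample(co$y)))
  }, numeric(1))
  p_perm <- (1 + sum(perm >= obs)) / (n_perm + 1)
  se_mc <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(r$p - p_perm), max(4 * se_mc, 0.02))
})

test_that("type-I error is calibrated with and without correction", {
  n_par <- 12
  uncorrected <- 0L; corrected <- 0L; total <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 150
    co <- data.frame(participant_id = sprintf("n%03d", 1:n),
                     age = runif(n, 18, 93),
                     sex = rep(c("male", "female"), length.out = n))
    for (j in seq_len(n_par)) co[[paste0("par", j)]] <- rnorm(n)
    res <- analyze_cohort(co, parameters = paste0("par", seq_len(n_par)),
                          n_comparisons = 68)
    uncorrected <- uncorrected + sum(res$age_effects$p < 0.05)
    corrected <- corrected + sum(res$age_effects$significant)
    total <- total + nrow(res$age_effects)
  }
  expect_lt(abs(uncorrected / total - 0.05), 0.04)
  expect_lte(corrected, 1)
})

test_that("identically generated sexes show no slope differences", {
  set.seed(21)
  n <- 400
  co <- data.frame(participant_id = sprintf("q%03d", 1:n),
                   age = runif(n, 18, 93),
                   sex = rep(c("male", "female"), length.out = n))
  co$steady_state_rate <- 2.5 - 0.01 * co$age + rnorm(n, 0, 0.3)
  res <- analyze_cohort(co, parameters = "steady_state_rate",
                        n_comparisons = 68)
  expect_true(all(res$slope_comparisons$p > res$corrected_alpha))
})
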