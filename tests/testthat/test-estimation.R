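test_that("the SSE objective matches hand-computed values", {
  imp <- lng_implant_150()
  # exact data from the model -> zero objective at the truth
  obs <- noise_free_obs("first_order", table2_first_order, with_rates = TRUE)
  expect_equal(
    objective_sse(obs, "first_order", table2_first_order, rate_weight = 3),
    0,
    tolerance = 1e-20
  )
  # single amount point: squared residual against the closed form
  one <- observation_set(
    data.frame(time_days = 365, type = "amount", value = 20), imp
  )
  q <- release_amount(365, "first_order", table2_first_order)
  expect_equal(
    objective_sse(one, "first_order", table2_first_order, rate_weight = 0),
    (20 - q)^2
  )
  expect_equal((20 - q)^2, 0.999, tolerance = 1e-2)
  # rate-only data with zero weight contributes nothing
  rate_only <- observation_set(
    data.frame(time_days = c(30, 365), type = "rate", value = c(0.1, 0.04)), imp
  )
  expect_equal(
    objective_sse(rate_only, "first_order", table2_first_order, rate_weight = 0),
    0
  )
  # the objective does not depend on row order
  shuffled <- observation_set(obs[sample(nrow(obs)), ], imp)
  expect_equal(
    objective_sse(shuffled, "first_order", table2_first_order, rate_weight = 3),
    objective_sse(obs, "first_order", table2_first_order, rate_weight = 3)
  )
})

test_that("noise-free data refits recover the generating parameters", {
  # amount-only, two-parameter exponential: 0.1% relative
  obs <- noise_free_obs("first_order", table2_first_order)
  fit <- fit_release_model(obs, "first_order")
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-6)
  expect_equal(fit$estimates$Qmax, 67.86, tolerance = 1e-3)
  expect_equal(fit$estimates$k1, 9e-4, tolerance = 1e-3)

  # joint amounts + label rates, three-parameter biexponential: 1%
  obs_b <- noise_free_obs("biexponential",
    list(Qb1 = 44.64, kb1 = 0.00127, kb2 = 8.985e-5),
    with_rates = TRUE
  )
  fit_b <- fit_release_model(obs_b, "biexponential")
  expect_true(fit_b$converged)
  expect_equal(fit_b$estimates$Dose, 150) # fixed, not fitted
  expect_equal(fit_b$estimates$Qb1, 44.64, tolerance = 1e-2)
  expect_equal(fit_b$estimates$kb1, 0.00127, tolerance = 1e-2)
  expect_equal(fit_b$estimates$kb2, 8.985e-5, tolerance = 1e-2)
})

test_that("every family refits its own noise-free data to near-zero SSE", {
  withr::local_seed(19)
  for (fam in release_families()$family_id) {
    p <- random_params(fam)
    obs <- suppressWarnings(noise_free_obs(fam, p))
    fit <- suppressWarnings(fit_release_model(obs, fam))
    expect_lt(fit$sse, 1e-6)
    tol <- if (length(fit$free) <= 1 ||
      fam %in% c("first_order", "zero_order", "higuchi")) 1e-3 else 1e-2
    for (nm in fit$free) {
      expect_equal(fit$estimates[[nm]], p[[nm]],
        tolerance = tol,
        label = paste(fam, nm)
      )
    }
  }
})

test_that("the zero-order fit reproduces analytic regression through the origin", {
  imp <- lng_implant_150()
  withr::local_seed(5)
  t <- c(100, 300, 700, 1200, 1825)
  y <- 0.03 * t + rnorm(5, 0, 1.5)
  obs <- observation_set(
    data.frame(time_days = t, type = "amount", value = y), imp
  )
  fit <- fit_release_model(obs, "zero_order")
  oracle <- ols_origin(t, y)
  expect_equal(fit$estimates$k, oracle$k, tolerance = 1e-8)
  expect_equal(as.numeric(fit$se), oracle$se, tolerance = 1e-6)
  cis <- parameter_cis(fit)
  expect_equal(cis$lower, oracle$lower, tolerance = 1e-6)
  expect_equal(cis$upper, oracle$upper, tolerance = 1e-6)
  expect_equal(fit$sse, oracle$rss, tolerance = 1e-10)
})

test_that("refitting from the optimum is idempotent and deterministic", {
  obs <- suppressWarnings(
    generate_ex_vivo(synthetic_config(noise = list(additive_sd = 2), seed = 21))
  )
  fit1 <- fit_release_model(obs, "first_order")
  fit2 <- fit_release_model(obs, "first_order",
    options = fit_options(starting_values = fit1$estimates[fit1$free])
  )
  expect_lt(abs(fit1$sse - fit2$sse), 1e-8)
  fit3 <- fit_release_model(obs, "first_order")
  expect_identical(unlist(fit1$estimates), unlist(fit3$estimates))
})

test_that("adjusted R-squared follows its definition", {
  expect_equal(adjusted_r_squared(0, 10, 13, 2), 1)
  # R2 = 0.9, n = 10, p = 2 -> 1 - 0.1 * 9 / 7
  expect_equal(adjusted_r_squared(1, 10, 10, 2), 1 - 0.1 * 9 / 7)
  # no free parameters: formula collapses to R2
  expect_equal(adjusted_r_squared(1, 10, 10, 0), 0.9)
  expect_error(adjusted_r_squared(1, 10, 3, 2), "Degenerate")
  expect_error(adjusted_r_squared(1, 0, 10, 2), "sst")
  # agreement with brute-force recomputation from raw residuals
  obs <- suppressWarnings(
    generate_ex_vivo(synthetic_config(noise = list(additive_sd = 2), seed = 33))
  )
  fit <- fit_release_model(obs, "first_order")
  res <- obs$value - release_amount(obs$time_days, "first_order", fit$estimates)
  sse <- sum(res^2)
  sst <- sum((obs$value - mean(obs$value))^2)
  r2 <- 1 - sse / sst
  expect_equal(fit$r2, r2, tolerance = 1e-12)
  expect_equal(
    fit$adjusted_r2,
    1 - (1 - r2) * (nrow(obs) - 1) / (nrow(obs) - 2 - 1),
    tolerance = 1e-12
  )
})

test_that("confidence intervals behave at the degenerate and ill-posed extremes", {
  # zero-residual fit: zero-width intervals
  obs <- noise_free_obs("first_order", table2_first_order)
  fit <- fit_release_model(obs, "first_order")
  cis <- parameter_cis(fit)
  expect_equal(cis$lower, cis$estimate, tolerance = 1e-6)
  expect_equal(cis$upper, cis$estimate, tolerance = 1e-6)
  # sparse noisy data for a 3-parameter biexponential: intervals may span
  # negative values and are flagged, not truncated
  withr::local_seed(9)
  imp <- lng_implant_150()
  t <- c(91, 365, 730, 1460, 1825)
  q <- release_amount(t, "biexponential", table2_biexponential)
  obs_sparse <- observation_set(
    data.frame(time_days = t, type = "amount", value = q + rnorm(5, 0, 2)),
    imp
  )
  fit_sparse <- fit_release_model(obs_sparse, "biexponential")
  cis_sparse <- parameter_cis(fit_sparse)
  expect_true(any(cis_sparse$spans_zero))
  expect_true(all(cis_sparse$lower <= cis_sparse$estimate))
  expect_true(all(cis_sparse$upper >= cis_sparse$estimate))
})

test_that("the prediction band brackets the fit and widens under extrapolation", {
  obs <- suppressWarnings(
    generate_ex_vivo(synthetic_config(noise = list(additive_sd = 2), seed = 2))
  )
  fit <- fit_release_model(obs, "first_order")
  band <- prediction_band(fit, c(100, 900, 3000))
  expect_true(all(band$lower <= band$fit & band$fit <= band$upper))
  half <- (band$upper - band$lower) / 2
  expect_gt(half[3], half[2]) # extrapolation beyond day 1825 widens the band
})

test_that("the 95% prediction band contains new noisy observations about 95% of the time", {
  # replicates of the study design; at each check time, a fresh observation
  # of the mean released amount (SE 2/sqrt(5) mg) should fall inside the
  # band at close to the nominal rate
  n_rep <- 300
  check_t <- c(365, 1095)
  hits <- matrix(NA, n_rep, length(check_t))
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(noise = list(additive_sd = 2), seed = 10000 + r)
    obs <- suppressWarnings(generate_ex_vivo(cfg))
    fit <- fit_release_model(obs, "first_order")
    band <- prediction_band(fit, check_t)
    q_true <- release_amount(check_t, "first_order", table2_first_order)
    new_obs <- q_true + rnorm(length(check_t), 0, 2 / sqrt(5))
    hits[r, ] <- new_obs >= band$lower & new_obs <= band$upper
  }
  cover <- colMeans(hits)
  expect_true(all(cover > 0.90 & cover < 0.99))
})

test_that("model ranking orders by adjusted R-squared with sane tie-breaks", {
  # ranking reproduced from reported goodness-of-fit values alone
  reported <- data.frame(
    family_id = c(
      "weibull", "biexponential", "first_order", "korsmeyer_peppas",
      "hixson_crowell"
    ),
    adjusted_r2 = c(0.9130, 0.9113, 0.9170, 0.9133, 0.9157)
  )
  ranking <- compare_models(reported)
  expect_equal(
    ranking$family_id,
    c(
      "first_order", "hixson_crowell", "korsmeyer_peppas", "weibull",
      "biexponential"
    )
  )
  # exact tie: fewer parameters first
  tie <- data.frame(
    family_id = c("weibull", "first_order"),
    adjusted_r2 = c(0.91, 0.91),
    n_params = c(3L, 2L)
  )
  expect_equal(compare_models(tie)$family_id[1], "first_order")
  # single fit ranks itself; non-converged fits go last
  one <- data.frame(family_id = "first_order", adjusted_r2 = 0.9)
  expect_equal(nrow(compare_models(one)), 1L)
  mixed <- data.frame(
    family_id = c("a", "b"),
    adjusted_r2 = c(0.99, 0.5),
    converged = c(FALSE, TRUE)
  )
  expect_equal(compare_models(mixed)$family_id, c("b", "a"))
})

test_that("ranking fit objects requires a common dataset", {
  obs1 <- noise_free_obs("first_order", table2_first_order)
  fit1 <- fit_release_model(obs1, "first_order")
  fit2 <- fit_release_model(obs1, "weibull")
  ranking <- compare_models(list(fit2, fit1))
  expect_equal(ranking$rank, 1:2)
  obs2 <- suppressWarnings(
    generate_ex_vivo(synthetic_config(noise = list(additive_sd = 2), seed = 4))
  )
  fit3 <- fit_release_model(obs2, "first_order")
  expect_error(compare_models(list(fit1, fit3)), "same observation set")
})

test_that("insufficient data is an explicit error, non-convergence a flag", {
  imp <- lng_implant_150()
  two <- observation_set(
    data.frame(time_days = c(100, 200), type = "amount", value = c(5, 9)), imp
  )
  expect_error(fit_release_model(two, "weibull"), "Insufficient data")
  # starved optimizer: one iteration on hard data must not throw
  obs <- noise_free_obs("biexponential", list(Qb1 = 44.64, kb1 = 0.00127, kb2 = 8.985e-5))
  fit <- fit_release_model(obs, "biexponential",
    options = fit_options(max_iterations = 1)
  )
  expect_false(fit$converged)
})

test_that("tidy, glance and augment expose the fit as tables", {
  obs <- noise_free_obs("biexponential", list(Qb1 = 44.64, kb1 = 0.00127, kb2 = 8.985e-5))
  fit <- fit_release_model(obs, "biexponential")
  td <- tidy(fit)
  expect_setequal(td$term, c("Qb1", "kb1", "kb2", "Dose"))
  expect_true(td$fixed[td$term == "Dose"])
  gl <- glance(fit)
  expect_equal(gl$family_id, "biexponential")
  expect_lte(gl$adj.r.squared, gl$r.squared)
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$value - aug$.fitted)
})
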