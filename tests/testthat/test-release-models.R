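families_all <- release_families()$family_id

test_that("cumulative release matches worked examples and quadrature of the rate", {
  p <- table2_first_order
  expect_equal(release_amount(0, "first_order", p), 0)
  # closed form vs numerically integrating the rate over [0, 365]
  q365 <- release_amount(365, "first_order", p)
  quad <- integrate(function(u) release_rate(u, "first_order", p), 0, 365,
    rel.tol = 1e-10
  )$value
  expect_equal(q365, quad, tolerance = 1e-8)
  expect_equal(q365, 19.0006, tolerance = 1e-4)
  # Weibull with l = 1 collapses to first-order
  wq <- release_amount(365, "weibull", list(Qmax = 67.86, kw = 9e-4, l = 1))
  expect_equal(wq, q365, tolerance = 1e-12)
})

test_that("release rates match worked examples and are flat for linear release", {
  expect_equal(
    release_rate(0, "first_order", table2_first_order),
    67.86 * 9e-4
  )
  expect_equal(
    release_rate(0, "biexponential", table2_biexponential),
    0.00127 * 44.64 + 8.985e-5 * (150 - 44.64)
  )
  # Korsmeyer-Peppas with n = 1 is zero-order: constant rate
  r <- release_rate(c(1, 100, 1000), "korsmeyer_peppas", list(kkp = 0.03, n = 1))
  expect_equal(r, rep(0.03, 3))
})

test_that("Q(0) = 0, monotone growth, and asymptote bounds hold for random parameters", {
  withr::local_seed(42)
  grid <- seq(0, 3650, length.out = 400)
  for (fam in families_all) {
    for (rep in 1:5) {
      p <- random_params(fam)
      q <- suppressWarnings(release_amount(grid, fam, p))
      expect_equal(q[1], 0, tolerance = 1e-12, label = paste(fam, "Q(0)"))
      expect_true(all(diff(q) >= -1e-9), label = paste(fam, "monotone"))
      if (fam %in% c("first_order", "weibull", "second_order")) {
        # strictly below the asymptote over the study window; at extreme
        # extrapolation the gap can underflow to 0 in double precision
        expect_true(all(q[grid <= 1825] < p$Qmax), label = paste(fam, "below Qmax"))
        expect_true(all(q <= p$Qmax), label = paste(fam, "at most Qmax"))
      }
      if (fam == "biexponential") {
        expect_true(all(q[grid <= 1825] < p$Dose), label = "biexponential below Dose")
        expect_true(all(q <= p$Dose), label = "biexponential at most Dose")
      }
    }
  }
})

test_that("the analytic rate equals the numerical derivative of the cumulative form", {
  withr::local_seed(7)
  t_int <- c(10, 50, 200, 700, 1500) # interior points, away from t = 0
  for (fam in families_all) {
    p <- random_params(fam)
    if (fam == "hixson_crowell") {
      td <- p$Qhc^(1 / 3) / p$khc
      t_use <- t_int[t_int < 0.9 * td]
    } else {
      t_use <- t_int
    }
    dq <- release_rate(t_use, fam, p)
    num <- vapply(
      t_use,
      function(tt) {
        num_deriv(function(u) suppressWarnings(release_amount(u, fam, p)), tt,
          h = 1e-3 * max(tt, 1)
        )
      },
      numeric(1)
    )
    expect_equal(dq, num, tolerance = 1e-6, label = paste(fam, "rate"))
  }
})

test_that("the second-order form solves dQ/dt = k2 (Qmax - Q)^2", {
  withr::local_seed(11)
  grid <- seq(0, 3650, length.out = 200)
  for (rep in 1:5) {
    p <- random_params("second_order")
    q <- release_amount(grid, "second_order", p)
    lhs <- release_rate(grid, "second_order", p)
    rhs <- p$k2 * (p$Qmax - q)^2
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("Hixson-Crowell clamps at depletion with a classed warning", {
  p <- list(Qhc = 64, khc = 0.004) # depletion at 4/0.004 = 1000 days
  expect_warning(
    q <- release_amount(c(500, 1000, 1500), "hixson_crowell", p),
    class = "larkin_depletion_clamp"
  )
  expect_equal(q[2], 64)
  expect_equal(q[3], 64)
  expect_equal(release_rate(1500, "hixson_crowell", p), 0)
})

test_that("negative times and unknown families are rejected", {
  expect_error(release_amount(-1, "first_order", table2_first_order), "Times")
  expect_error(release_amount(10, "gompertz", list(a = 1)), "Unknown model family")
  expect_error(
    release_amount(10, "first_order", list(Qmax = 67.86)),
    "needs parameter"
  )
})

test_that("special-case reductions preserve the curve exactly", {
  t <- c(0, 10, 100, 1000)
  red <- reduce_special_case("weibull", list(Qmax = 67.86, kw = 9e-4, l = 1))
  expect_equal(red$family, "first_order")
  expect_equal(red$params$k1, 9e-4)
  expect_equal(
    release_amount(t, red$family, red$params),
    release_amount(t, "weibull", list(Qmax = 67.86, kw = 9e-4, l = 1))
  )

  red <- reduce_special_case("korsmeyer_peppas", list(kkp = 0.03, n = 1))
  expect_equal(red$family, "zero_order")
  expect_equal(red$params$k, 0.03)

  red <- reduce_special_case("korsmeyer_peppas", list(kkp = 1.2, n = 0.5))
  expect_equal(red$family, "higuchi")
  expect_equal(
    release_amount(t, "higuchi", red$params),
    release_amount(t, "korsmeyer_peppas", list(kkp = 1.2, n = 0.5))
  )

  red <- reduce_special_case("peppas_sahlin", list(kps1 = 1, kps2 = 0.01, m = 0.5))
  expect_equal(red$family, "population_council")
  expect_equal(
    release_amount(t, "population_council", red$params),
    release_amount(t, "peppas_sahlin", list(kps1 = 1, kps2 = 0.01, m = 0.5))
  )

  # away from the special value the input comes back unchanged
  same <- reduce_special_case("weibull", list(Qmax = 67.86, kw = 9e-4, l = 0.8))
  expect_equal(same$family, "weibull")
  expect_equal(same$params$l, 0.8)
})

test_that("parameter JSON serialization round-trips deterministically", {
  j1 <- params_to_json("biexponential", table2_biexponential)
  j2 <- params_to_json(
    "biexponential",
    table2_biexponential[c("kb2", "Qb1", "Dose", "kb1")] # scrambled order
  )
  expect_identical(as.character(j1), as.character(j2))
  back <- params_from_json(j1)
  expect_equal(back$family, "biexponential")
  expect_equal(back$params, table2_biexponential[c("Dose", "Qb1", "kb1", "kb2")])
})

test_that("remaining releasable drug starts at (1 - f) * Dose and decays as printed", {
  imp <- lng_implant_150()
  expect_equal(remaining_releasable(0, imp, "first_order", list(k1 = 9e-4)), 75)
  expect_equal(
    remaining_releasable(0, imp, "biexponential", table2_biexponential),
    75
  )
  expect_equal(
    remaining_releasable(365, imp, "first_order", list(k1 = 9e-4)),
    75 * exp(-9e-4 * 365),
    tolerance = 1e-12
  )
  expect_equal(
    remaining_releasable(365, imp, "first_order", list(k1 = 9e-4)),
    54.00, # = 75 * exp(-0.3285)
    tolerance = 1e-4
  )
  t <- seq(0, 5000, by = 50)
  li <- remaining_releasable(t, imp, "biexponential", table2_biexponential)
  expect_true(all(diff(li) <= 0))
  expect_error(
    remaining_releasable(0, imp, "higuchi", list(kH = 1)),
    "first_order.*biexponential"
  )
})

test_that("the implant input rate integrates back to the released amount", {
  imp <- lng_implant_150()
  expect_equal(
    implant_input_rate(0, imp, "first_order", list(k1 = 9e-4)),
    0.5 * 150 * 9e-4 # = 0.0675 mg/day
  )
  expect_lt(implant_input_rate(1e7, imp, "first_order", list(k1 = 9e-4)), 1e-12)

  for (fam in c("first_order", "biexponential")) {
    p <- if (fam == "first_order") list(k1 = 9e-4) else table2_biexponential
    # rate matches the finite difference of the remaining amount
    for (tt in c(5, 100, 900, 1800)) {
      fd <- -num_deriv(
        function(u) remaining_releasable(u, imp, fam, p), tt,
        h = 1e-3 * tt
      )
      expect_equal(
        implant_input_rate(tt, imp, fam, p), fd,
        tolerance = 1e-6, label = paste(fam, "input rate FD")
      )
    }
    # conservation: Li(0) - Li(t) = integral of the input rate
    for (tt in c(365, 1825)) {
      quad <- integrate(function(u) implant_input_rate(u, imp, fam, p),
        0, tt,
        rel.tol = 1e-10
      )$value
      expect_equal(
        remaining_releasable(0, imp, fam, p) -
          remaining_releasable(tt, imp, fam, p),
        quad,
        tolerance = 1e-6
      )
    }
    # total input over [0, Inf) is the releasable amount
    total <- integrate(function(u) implant_input_rate(u, imp, fam, p),
      0, Inf,
      rel.tol = 1e-10
    )$value
    expect_equal(total, 75, tolerance = 1e-6)
  }
})

test_that("the two biexponential (1 - f) conventions scale the same curve", {
  imp <- lng_implant_150()
  t <- c(0, 100, 1000)
  as_printed <- remaining_releasable(t, imp, "biexponential", table2_biexponential)
  rescaled <- remaining_releasable(t, imp, "biexponential", table2_biexponential,
    rescale_qb1 = TRUE
  )
  expect_equal(as_printed, rescaled, tolerance = 1e-12)
})
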