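test_that("finite-sum scaled time matches closed forms for constant size", {
  m <- constant_size(1000)
  # one step's worth of slack: the grid 0..500 carries 501 unit masses
  expect_lt(abs(scale_time_numeric(m, 500) - 0.5), 0.0011)
  # the accumulator starts at step/N(0), so t = 0 carries one step's mass
  expect_equal(scale_time_numeric(m, 0), 1 / 1000)
  cfg <- finite_sum_config(step = 0.25)
  expect_equal(scale_time_numeric(m, 0, cfg), 0.25 / 1000)
})

test_that("finite-sum scaled time approximates the exponential integral", {
  m <- table2_exponential()
  v <- scale_time_numeric(m, 2097.8)
  expect_equal(v, 1.7983473, tolerance = 1e-6)   # frozen left-endpoint sum
  # deviation from the true integral is the half-step discretization mass
  expect_lt(abs(v - 1.8), 2.5e-3)
  # a finer step closes the gap
  expect_lt(abs(scale_time_numeric(m, 2097.8, finite_sum_config(step = 0.01)) - 1.8),
            3e-5)
})

test_that("analytic g matches its closed forms and a quadrature oracle", {
  expect_equal(scale_time_analytic(constant_size(1000), 1000), 1)
  m <- table2_exponential()
  expect_equal(scale_time_analytic(m, 2097.8),
               (exp(0.003 * 2097.8) - 1) / (1e5 * 0.003), tolerance = 1e-14)
  # re-derived logistic form against adaptive quadrature of 1/N
  for (gam in c(0.003, 0.015)) {
    lg <- logistic_growth(1e4, gam, 5000)
    tt <- c(1, 50, 1000, 2500, 4999)
    expect_equal(scale_time_analytic(lg, tt), quad_g(lg, tt),
                 tolerance = 1e-9)
  }
  # small-rate limit degenerates to the constant form
  tiny <- exponential_growth(1e5, 1e-12)
  expect_equal(scale_time_analytic(tiny, 1234), 1234 / 1e5, tolerance = 1e-6)
  expect_error(scale_time_analytic(table2_gompertz(), 10),
               class = "coalafs_unsupported_family_error")
  expect_error(scale_time_analytic(piecewise_history(0, 10), 10),
               class = "coalafs_unsupported_family_error")
})

test_that("finite-sum inversion hits closed-form targets within one step", {
  expect_equal(as.numeric(invert_scale_finite_sum(constant_size(1000), 1.0)),
               1000, tolerance = 1)
  m <- table2_exponential()
  mus <- sort(kingman_expected_scaled(10))
  out <- as.numeric(invert_scale_finite_sum(m, mus))
  expect_equal(out[length(out)], 2097.8, tolerance = 1.1)
  # single-pass scan: times strictly increase in consumption order here
  expect_true(all(diff(out) > 0))
})

test_that("finite-sum scan enforces sorted targets and flags non-coalescing histories", {
  m <- constant_size(1000)
  expect_error(invert_scale_finite_sum(m, c(1.0, 0.5)), "sorted",
               class = "coalafs_validation_error")
  expect_error(invert_scale_finite_sum(m, -1), class = "coalafs_validation_error")
  huge <- piecewise_history(0, 1e9)
  expect_error(invert_scale_finite_sum(huge, 1, finite_sum_config(max_time = 1e3)),
               class = "coalafs_non_coalescing_error")
})

test_that("overshoot rules differ exactly as specified at the boundary", {
  m <- constant_size(1000)
  # G after t=0 is 0.001, after t=1 it is 0.002; target 0.0012 overshoots
  # by 0.0008 < one-step mass, so the classic rule keeps t = 1 while the
  # nearest rule prefers the pre-overshoot grid point
  expect_equal(as.numeric(invert_scale_finite_sum(m, 0.0012)), 1)
  expect_equal(as.numeric(invert_scale_finite_sum(
    m, 0.0012, finite_sum_config(overshoot_rule = "nearest"))), 0)
})

test_that("a sub-generation step is recommended when sizes drop below 100", {
  m <- piecewise_history(c(0, 10), c(1000, 50))
  expect_warning(invert_scale_finite_sum(m, 0.3), "sub-generation")
  expect_silent(invert_scale_finite_sum(constant_size(1000), 0.5))
})

test_that("root inversion solves g(t) = mu to tolerance", {
  expect_equal(invert_scale_root(constant_size(1000), 1.0, tol = 1e-10), 1000,
               tolerance = 1e-8)
  expect_equal(invert_scale_root(table2_exponential(), 1.8), 2097.80,
               tolerance = 0.01)
  lg <- fig1_logistic()
  expect_equal(invert_scale_root(lg, 1.8), invert_scale_analytic(lg, 1.8),
               tolerance = 1e-6)
  # quadrature path for families without closed forms
  gp <- table2_gompertz()
  t1 <- invert_scale_root(gp, 1.8)
  expect_equal(quad_g(gp, t1), 1.8, tolerance = 1e-7)
  expect_error(invert_scale_root(constant_size(10), 1, tol = -1),
               class = "coalafs_validation_error")
  expect_error(invert_scale_root(piecewise_history(0, 1e9), 1, max_time = 1e3),
               class = "coalafs_non_coalescing_error")
})

test_that("closed-form inversion reproduces the exponential formula and its limit", {
  m <- table2_exponential()
  expect_equal(invert_scale_analytic(m, 1.8), log(541) / 0.003,
               tolerance = 1e-12)
  tiny <- exponential_growth(1e5, 1e-12)
  expect_equal(invert_scale_analytic(tiny, 0.7), 1e5 * 0.7, tolerance = 1e-6)
  expect_equal(invert_scale_analytic(constant_size(250), 0.4), 100)
  expect_error(invert_scale_analytic(table2_gompertz(), 1),
               class = "coalafs_unsupported_family_error")
})

test_that("Lambert-W logistic inversion agrees with root-finding over a grid", {
  for (Nk in c(1e3, 1e4)) for (gam in c(0.003, 0.015)) {
    lg <- logistic_growth(Nk, gam, 5000)
    for (mu in c(0.02, 0.5, 1.8)) {
      ta <- invert_scale_analytic(lg, mu)
      tr <- invert_scale_root(lg, mu, tol = 1e-12)
      expect_equal(ta, tr, tolerance = 1e-8)
    }
  }
})

test_that("log-scale Lambert W matches an independent implementation", {
  z <- c(-30, -2, 0, 1, 5, 50, 200)
  w <- coalafs:::lambert_w_exp(z)
  expect_equal(w[z <= 50], pracma::lambertWp(exp(z[z <= 50])),
               tolerance = 1e-12)
  # defining identity holds even where exp(z) overflows
  expect_equal(w + log(w), z, tolerance = 1e-12)
})

test_that("every inversion scheme round-trips through its own g", {
  lg <- fig1_logistic()
  mus <- c(0.01, 0.2, 1, 1.9)
  for (mu in mus) {
    expect_equal(scale_time_analytic(lg, invert_scale_analytic(lg, mu)), mu,
                 tolerance = 1e-10)
    expect_equal(scale_time_analytic(lg, invert_scale_root(lg, mu)), mu,
                 tolerance = 1e-9)
  }
  fs <- as.numeric(invert_scale_finite_sum(lg, mus))
  for (i in seq_along(mus)) {
    gap <- abs(scale_time_numeric(lg, fs[i]) - mus[i])
    expect_lt(gap, 1 / population_size(lg, fs[i]) + 1e-12)  # one step's mass
  }
})

test_that("the three schemes agree across an exponential/logistic grid", {
  grid <- expand.grid(i = 1:3, j = 1:3)
  mus <- sort(kingman_expected_scaled(10))
  for (r in seq_len(nrow(grid))) {
    for (fam in c("exponential", "logistic")) {
      m <- if (fam == "exponential")
        exponential_growth(c(1e4, 1e5, 1e6)[grid$i[r]],
                           c(0.001, 0.003, 0.01)[grid$j[r]])
      else
        logistic_growth(c(1e3, 1e4, 1e5)[grid$i[r]],
                        c(0.003, 0.006, 0.015)[grid$j[r]], 5000)
      an <- invert_scale_analytic(m, mus)
      rt <- invert_scale_root(m, mus)
      fs <- suppressWarnings(as.numeric(invert_scale_finite_sum(m, mus)))
      expect_equal(rt, an, tolerance = 1e-8)
      expect_true(all(abs(fs - an) <= 1 + 1e-9))   # within one generation step
    }
  }
})

test_that("g is non-decreasing in t for randomly drawn histories", {
  set.seed(42)
  for (rep in 1:10) {
    fam <- sample(c("constant", "exponential", "logistic", "gompertz",
                    "piecewise"), 1)
    m <- switch(fam,
      constant = constant_size(runif(1, 10, 1e5)),
      exponential = exponential_growth(runif(1, 1e3, 1e6), runif(1, 1e-4, 0.01)),
      logistic = logistic_growth(runif(1, 1e3, 1e5), runif(1, 1e-3, 0.01),
                                 runif(1, 1e3, 1e4)),
      gompertz = gompertz_growth(runif(1, 1, 10), runif(1, 5e-3, 0.05),
                                 runif(1, 5e-4, 5e-3), runif(1, 1e3, 5e3)),
      piecewise = piecewise_history(c(0, sort(runif(3, 1, 5e3))),
                                    runif(4, 10, 1e5)))
    # keep within the onset for gompertz: far beyond it the size underflows
    # to zero, which evaluation correctly rejects
    tmax <- if (fam == "gompertz") m$params$onset else 4e3
    tt <- sort(runif(8, 0, tmax))
    expect_true(all(diff(scale_time_numeric(m, tt)) >= 0))
  }
})

test_that("evaluation count is set by the largest target, not by how many", {
  m <- table2_exponential()
  one <- invert_scale_finite_sum(m, 1.8)
  many <- invert_scale_finite_sum(m, c(0.01, 0.2, 0.9, 1.3, 1.8))
  expect_identical(attr(one, "n_evaluations"), attr(many, "n_evaluations"))
})
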