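test_that("constructors enforce the positivity and finiteness contracts", {
  expect_s3_class(rnai_params(), "rnai_params")
  expect_equal(unlist(rnai_params()),
               c(n = 5, iota_a = 10, iota_b = 0.001, iota_c = 1,
                 iota_h = 1000, iota_g = 1, iota_m = 1, iota_r = 0.1))
  expect_error(rnai_params(iota_a = 0), class = "rnai_invalid_input")
  expect_error(rnai_params(n = -1), class = "rnai_invalid_input")
  expect_error(rnai_state(NaN, 0, 0, 1), class = "rnai_invalid_input")
  expect_error(rnai_state(Inf, 0, 0, 1), class = "rnai_invalid_input")
  expect_error(rnai_noise(sigma1 = -0.1), class = "rnai_invalid_input")
  expect_true(rnai_state_nonneg(rnai_state(0, 0, 0, 1000)))
  expect_false(rnai_state_nonneg(rnai_state(-1e-9, 0, 0, 1000)))
})

test_that("vector field matches hand-substituted values and rejects bad input", {
  p <- table_params()
  expect_equal(rnai_rhs(rnai_state(0, 0, 0, 1000), p),
               c(dS = 0, dR = 0, dC = 0, dM = 0))
  expect_equal(rnai_rhs(rnai_state(10, 0, 0, 1000), p),
               c(dS = -100, dR = 500, dC = 0, dM = 0))
  expect_error(rnai_rhs(c(1, 2, NA, 4), p), class = "rnai_invalid_input")
})

test_that("both steady states are recovered with near-zero residuals", {
  eq <- rnai_equilibria(table_params())
  expect_equal(eq$xi0, rnai_state(0, 0, 0, 1000))
  expect_identical(eq$residual_xi0, 0)
  expect_true(eq$feasible)
  expect_equal(unname(eq$xi_star), unname(table_xi_star()), tolerance = 1e-12)
  expect_lt(eq$residual_xi_star, 1e-9)
  expect_true(eq$printed_inequality_holds)
  expect_identical(nrow(tidy(eq)), 2L)
  # repeated calls are bytewise identical
  expect_identical(eq$xi_star, rnai_equilibria(table_params())$xi_star)
})

test_that("the interior steady state agrees with a root-finder oracle", {
  p <- table_params()
  f <- function(x) rnai_rhs(rnai_state(x[1], x[2], x[3], x[4]), p)
  root <- pracma::fsolve(f, c(40, 12000, 400, 70), tol = 1e-12)$x
  expect_equal(unname(rnai_equilibria(p)$xi_star), root, tolerance = 1e-6)
})

test_that("infeasible regimes drop the interior state without error", {
  eq1 <- rnai_equilibria(rnai_params(n = 1))  # branch denominator negative
  expect_null(eq1$xi_star)
  expect_false(eq1$feasible)
  expect_false(rnai_feasible(rnai_params(n = 1)))
  # tiny mRNA synthesis: C* < 0 even though the branch denominator is positive
  expect_false(rnai_feasible(rnai_params(iota_h = 1e-6)))
  expect_true(rnai_feasible(table_params()))
})

test_that("R0 closed form equals the spectral radius and the known values", {
  ngm <- rnai_r0(table_params())
  expect_equal(ngm$r0, 5 / 2.2, tolerance = 1e-12)
  expect_equal(ngm$r0_spectral, ngm$r0_closed_form, tolerance = 1e-10)
  expect_equal(rnai_r0(rnai_params(iota_h = 2000))$r0, 10 / 4.2,
               tolerance = 1e-12)
  # F has exactly one nonzero entry, at the (C, R) position
  nz <- which(ngm$F != 0, arr.ind = TRUE)
  expect_identical(nrow(nz), 1L)
  expect_identical(rownames(ngm$F)[nz[1, "row"]], "C")
  expect_identical(colnames(ngm$F)[nz[1, "col"]], "R")
  expect_equal(ngm$F["C", "R"], 1)
  # boundary limit iota_b = 0 permitted only via the explicit escape hatch
  p0 <- unclass(table_params()); p0$iota_b <- 0
  expect_equal(rnai_r0(p0, allow_boundary = TRUE)$r0, 0)
})

test_that("R0 agreement and the feasibility equivalence hold on a random sweep", {
  set.seed(401)
  n_feasible <- 0L
  for (i in 1:300) {
    p <- draw_params()
    ngm <- rnai_r0(p)
    expect_lt(abs(ngm$r0_spectral - ngm$r0_closed_form) /
                max(ngm$r0_closed_form, 1e-300), 1e-10)
    eq <- rnai_equilibria(p)
    expect_identical(eq$feasible, ngm$r0 > 1)
    if (eq$feasible) {
      n_feasible <- n_feasible + 1L
      expect_lt(eq$residual_xi_star, 1e-9)
      expect_true(all(eq$xi_star > 0))
    }
  }
  expect_gt(n_feasible, 25)  # the sweep exercises both regimes
})

test_that("RISC/complex mass flow cancels the binding term", {
  set.seed(402)
  p <- table_params()
  for (i in 1:50) {
    x <- draw_state()
    d <- rnai_rhs(x, p)
    expect_equal(unname(d[["dR"]] + d[["dC"]]),
                 p$n * p$iota_a * x[["S"]] - p$iota_r * x[["R"]] -
                   (p$iota_g + p$iota_c) * x[["C"]],
                 tolerance = 1e-12)
  }
})

test_that("growth and Lipschitz constants follow their defining formulas", {
  p <- table_params()
  b <- rnai_bound_constants(c(1, 1, 1, 1), p)
  expect_equal(b$N_SS, 11)
  expect_equal(b$kappa_C, 2)
  expect_equal(b$kappa_S, 10)
  expect_equal(b$kappa_R, 0.1 + 0.001)
  expect_equal(b$kappa_M, 1 + 0.001)
  expect_equal(b$N_RR, 50 + 0.1 + 0.001)
  expect_equal(b$N_CC, 0.001 + 2)
  expect_equal(b$N_MM, 1000 + 1 + 0.001)
  # homogeneity: scaling every rate by t scales every output linearly
  t <- 3.7
  pt <- rnai_params(5, 10 * t, 0.001 * t, 1 * t, 1000 * t, 1 * t, 1 * t,
                    0.1 * t)
  # n is a count, not a rate; scale the iota_a*n product via iota_a only
  bt <- rnai_bound_constants(c(1, 1, 1, 1), pt)
  for (col in c("N_SS", "N_RR", "N_CC", "N_MM",
                "kappa_S", "kappa_R", "kappa_C", "kappa_M")) {
    expect_equal(bt[[col]], t * b[[col]], tolerance = 1e-12)
  }
  expect_error(rnai_bound_constants(c(0, 1, 1, 1), p),
               class = "rnai_invalid_input")
})
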