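test_that("Euler step reproduces hand-substituted updates and fixed points", {
  p <- table_params()
  expect_equal(rnai_euler_step(rnai_state(10, 0, 0, 1000), p, 0.001),
               c(S = 9.9, R = 0.5, C = 0, M = 1000))
  xi0 <- rnai_state(0, 0, 0, 1000)
  expect_identical(rnai_euler_step(xi0, p, 0.5), xi0)
  xs <- rnai_equilibria(p)$xi_star
  expect_equal(rnai_euler_step(xs, p, 0.001), xs, tolerance = 1e-12)
  expect_error(rnai_euler_step(xi0, p, 0), class = "rnai_usage_error")
})

test_that("Milstein step matches hand substitution in paper-literal mode", {
  p <- table_params()
  ns <- rnai_noise(sigma1 = 0.2)
  x <- rnai_state(10, 0, 0, 1000)
  # all draws zero: only the (tau^2 - 1) = -1 correction acts
  s0 <- rnai_milstein_step(x, p, ns, 0.001, c(0, 0, 0, 0),
                           "milstein_paper_literal")
  expect_equal(s0, c(S = 9.9002, R = 0.495, C = 0, M = 1000),
               tolerance = 1e-12)
  # tau1 = 1: correction vanishes, diffusion term remains
  s1 <- rnai_milstein_step(x, p, ns, 0.001, c(1, 0, 0, 0),
                           "milstein_paper_literal")
  expect_equal(s1[["S"]], 9.9 - 0.2 * 10 * sqrt(0.001), tolerance = 1e-12)
  # Ito mode flips the S correction sign relative to the literal mode
  i0 <- rnai_milstein_step(x, p, ns, 0.001, c(0, 0, 0, 0), "milstein_ito")
  expect_equal(i0[["S"]], 9.9 - 0.0002, tolerance = 1e-12)
  expect_error(rnai_milstein_step(x, p, ns, 0.001, c(0, 0, 0, 0), "rk4"),
               class = "rnai_usage_error")
})

test_that("all schemes collapse to the Euler step when every intensity is zero", {
  set.seed(403)
  p <- table_params()
  z <- rnai_noise()
  for (i in 1:200) {
    x <- draw_state()
    dt <- stats::runif(1, 1e-4, 0.1)
    draws <- stats::rnorm(4)
    ref <- rnai_euler_step(x, p, dt)
    expect_identical(rnai_milstein_step(x, p, z, dt, draws,
                                        "milstein_paper_literal"), ref)
    expect_identical(rnai_milstein_step(x, p, z, dt, draws, "milstein_ito"),
                     ref)
    expect_identical(rnai_milstein_step(x, p, z, dt, draws, "euler"), ref)
  }
})

test_that("trajectories are seed-deterministic and carry the grid contract", {
  p <- table_params()
  ns <- rnai_noise(0.2, 0.2, 0.2, 0.2)
  x0 <- rnai_state(10, 0, 0, 1000)
  a <- rnai_simulate(x0, p, ns, dt = 0.01, t_end = 1, seed = 99)
  b <- rnai_simulate(x0, p, ns, dt = 0.01, t_end = 1, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(a$t[1], 0)
  expect_identical(unlist(a[1, c("S", "R", "C", "M")]), x0)
  expect_identical(nrow(a), 101L)
  # shortened final step: ceil(1/0.3) = 4 steps, last of length 0.1
  g <- rnai_simulate(x0, p, ns, dt = 0.3, t_end = 1, seed = 1)
  expect_equal(g$t, c(0, 0.3, 0.6, 0.9, 1))
  c2 <- rnai_simulate(x0, p, ns, dt = 0.01, t_end = 1, seed = 100)
  expect_false(identical(a$S, c2$S))
  expect_error(rnai_simulate(x0, p, ns, dt = 0.01, t_end = 0),
               class = "rnai_usage_error")
})

test_that("deterministic runs from low and high doses converge to the interior state", {
  p <- table_params()
  xs <- rnai_equilibria(p)$xi_star
  for (S0 in c(10, 1000)) {
    traj <- rnai_simulate(rnai_state(S0, 0, 0, 1000), p, rnai_noise(),
                          dt = 0.001, t_end = 80, scheme = "euler")
    fin <- final_state(traj)
    expect_lt(max(abs(fin - xs) / xs), 0.01)
    expect_identical(attr(traj, "positivity_violations"), 0L)
  }
})

test_that("ensembles derive distinct replicate seeds and reduce correctly", {
  p <- table_params()
  x0 <- rnai_state(10, 0, 0, 1000)
  ns <- rnai_noise(sigma1 = 0.2)
  ens <- rnai_ensemble(x0, p, ns, dt = 0.01, t_end = 0.5, n_reps = 3,
                       base_seed = 7)
  seeds <- attr(ens, "seeds")
  expect_identical(length(unique(seeds)), 3L)
  # replicate 1 equals a plain simulation with the derived seed
  r1 <- dplyr::filter(tibble::as_tibble(ens), replicate == 1)
  solo <- rnai_simulate(x0, p, ns, dt = 0.01, t_end = 0.5,
                        seed = rnai_replicate_seed(7, 1))
  expect_identical(r1$S, solo$S)
  expect_identical(r1$M, solo$M)
  # no noise: replicates coincide; nonzero noise: they differ
  ens0 <- rnai_ensemble(x0, p, rnai_noise(), dt = 0.01, t_end = 0.5,
                        n_reps = 3, base_seed = 7)
  w <- tidyr::pivot_wider(ens0[, c("replicate", "t", "S")],
                          names_from = "replicate", values_from = "S")
  expect_identical(w$`1`, w$`2`)
  expect_identical(w$`1`, w$`3`)
  w2 <- tidyr::pivot_wider(ens[, c("replicate", "t", "S")],
                           names_from = "replicate", values_from = "S")
  expect_false(identical(w2$`1`, w2$`2`))
})

test_that("ensemble moments are the trajectory itself for one replicate and zero-variance without noise", {
  p <- table_params()
  x0 <- rnai_state(10, 0, 0, 1000)
  ens1 <- rnai_ensemble(x0, p, rnai_noise(sigma1 = 0.2), dt = 0.01,
                        t_end = 0.2, n_reps = 1, base_seed = 3)
  mom1 <- ensemble_moments(ens1)
  expect_true(all(mom1$variance == 0))
  mS <- dplyr::filter(mom1, component == "S")
  expect_identical(mS$mean, dplyr::filter(tibble::as_tibble(ens1),
                                          replicate == 1)$S)
  ens0 <- rnai_ensemble(x0, p, rnai_noise(), dt = 0.01, t_end = 0.2,
                        n_reps = 4, base_seed = 3)
  expect_true(all(ensemble_moments(ens0)$variance == 0))
  bad <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(ens1), replicate = 1L),
    dplyr::mutate(tibble::as_tibble(ens1)[-2, ], replicate = 2L))
  expect_error(ensemble_moments(bad), class = "rnai_invalid_input")
})

test_that("discrete-time negative excursions are counted, and clipping is opt-in", {
  p <- table_params()
  x0 <- rnai_state(10, 0, 0, 1000)
  ns <- rnai_noise(0.2, 0.2, 0.2, 0.2)
  ens <- rnai_ensemble(x0, p, ns, dt = 0.001, t_end = 5, n_reps = 20,
                       base_seed = 17)
  viol <- attr(ens, "positivity_violations")
  expect_identical(length(viol), 20L)
  expect_true(all(is.finite(viol)) && all(viol >= 0))
  expect_true(all(viol <= 5000))
  clipped <- rnai_simulate(x0, p, ns, dt = 0.001, t_end = 5, seed = 17,
                           clip_at_zero = TRUE)
  expect_true(all(as.matrix(clipped[, c("S", "R", "C", "M")]) >= 0))
})

test_that("strong-order estimation recovers order one for single-channel Milstein", {
  p <- table_params()
  x0 <- rnai_state(10, 0, 0, 1000)
  ord <- rnai_strong_order(x0, p, rnai_noise(sigma1 = 0.2), "milstein_ito",
                           dt_list = 2^-(5:8), dt_ref = 2^-12, t_end = 1,
                           n_paths = 60, base_seed = 21)
  expect_gt(ord$slope, 0.75)
  expect_lt(ord$slope, 1.25)
  # zero noise: pure ODE discretization error, Euler order one
  ord0 <- rnai_strong_order(x0, p, rnai_noise(), "euler",
                            dt_list = 2^-(5:8), dt_ref = 2^-12, t_end = 1,
                            n_paths = 2, base_seed = 21)
  expect_gt(ord0$slope, 0.75)
  expect_lt(ord0$slope, 1.25)
  expect_error(
    rnai_strong_order(x0, p, rnai_noise(sigma1 = 0.2, sigma2 = 0.2),
                      "milstein_ito", dt_list = 2^-(5:6), dt_ref = 2^-12,
                      t_end = 1, n_paths = 2, base_seed = 1),
    class = "rnai_usage_error")
  expect_error(
    rnai_strong_order(x0, p, rnai_noise(sigma1 = 0.2), "milstein_ito",
                      dt_list = c(0.3), dt_ref = 2^-12, t_end = 1,
                      n_paths = 2, base_seed = 1),
    class = "rnai_usage_error")
})
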