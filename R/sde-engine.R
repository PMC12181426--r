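#' @importFrom rlang abort
NULL

# Preserve the caller's RNG state across seeded simulation calls.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Derive the seed of one ensemble replicate
#'
#' Fixed splitting rule: replicate `k` of an ensemble with base seed `b` uses
#' `((b mod m) * 48271 + k) mod m` with `m = 2^31 - 1`, guaranteeing pairwise
#' distinct seeds for distinct replicates of the same ensemble.
#'
#' @param base_seed Integer base seed of the ensemble.
#' @param k Replicate index (1-based).
#' @return An integer seed.
#' @export
rnai_replicate_seed <- function(base_seed, k) {
  m <- 2147483647
  as.integer((((as.numeric(base_seed) %% m) * 48271) %% m + k) %% m)
}

rnai_schemes <- c("milstein_ito", "milstein_paper_literal", "euler")

check_scheme <- function(scheme) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% rnai_schemes) {
    abort(paste0("`scheme` must be one of: ",
                 paste(rnai_schemes, collapse = ", ")),
          class = "rnai_usage_error")
  }
  scheme
}

# Uniform grid with a shortened final step when dt does not divide t_end.
# Number of steps is ceiling(t_end / dt).
rnai_grid_steps <- function(dt, t_end) {
  ratio <- t_end / dt
  n_near <- round(ratio)
  if (n_near >= 1 && abs(ratio - n_near) <= 1e-9 * n_near) {
    rep(dt, n_near)
  } else {
    n_full <- floor(ratio)
    c(rep(dt, n_full), t_end - n_full * dt)
  }
}

# One discretization step, vectorized over replicates. S,R,C,M and t1..t4 are
# equal-length numeric vectors; returns the updated components.
# "euler" is Euler-Maruyama (diffusion, no correction); the two Milstein modes
# differ only in the second-order correction terms.
rnai_step_core <- function(S, R, C, M, p, ns, dt, sqdt, t1, t2, t3, t4,
                           scheme) {
  a <- p$iota_a; b <- p$iota_b; cc <- p$iota_c; h <- p$iota_h
  g <- p$iota_g; mm <- p$iota_m; r <- p$iota_r; n <- p$n
  s1 <- ns$sigma1; s2 <- ns$sigma2; s3 <- ns$sigma3; s4 <- ns$sigma4
  bRM <- b * R * M
  dS <- -a * S + g * C
  dR <- n * a * S - r * R - bRM
  dC <- bRM - (g + cc) * C
  dM <- h - mm * M - bRM
  S1 <- S + dS * dt - s1 * S * sqdt * t1
  R1 <- R + dR * dt + s1 * n * S * sqdt * t1 - s2 * R * sqdt * t2
  C1 <- C + dC * dt - s3 * C * sqdt * t3
  M1 <- M + dM * dt - s4 * M * sqdt * t4
  if (scheme == "milstein_paper_literal") {
    # Literature-literal correction terms: printed signs and the n^2 factor
    # in the R equation are reproduced verbatim.
    S1 <- S1 - 0.5 * s1^2 * S * (t1^2 - 1) * dt
    R1 <- R1 + 0.5 * s1^2 * n^2 * S * (t1^2 - 1) * dt -
      0.5 * s2^2 * R * (t2^2 - 1) * dt
    C1 <- C1 - 0.5 * s3^2 * C * (t3^2 - 1) * dt
    M1 <- M1 - 0.5 * s4^2 * M * (t4^2 - 1) * dt
  } else if (scheme == "milstein_ito") {
    # Standard Ito-Milstein correction 0.5 * b * b' * (tau^2 - 1) * dt per
    # diffusion term; R's B1 diffusion sigma1*n*S corrects through the
    # S-channel chain rule (b_S = -sigma1*S), giving the negative sign.
    # Cross-channel Levy-area terms are omitted.
    S1 <- S1 + 0.5 * s1^2 * S * (t1^2 - 1) * dt
    R1 <- R1 - 0.5 * s1^2 * n * S * (t1^2 - 1) * dt +
      0.5 * s2^2 * R * (t2^2 - 1) * dt
    C1 <- C1 + 0.5 * s3^2 * C * (t3^2 - 1) * dt
    M1 <- M1 + 0.5 * s4^2 * M * (t4^2 - 1) * dt
  }
  list(S = S1, R = R1, C = C1, M = M1)
}

#' One deterministic Euler step
#'
#' Advances a state by `state + rhs(state) * dt`, the zero-noise limit of the
#' stochastic schemes.
#'
#' @inheritParams rnai_rhs
#' @param dt Time step (> 0).
#' @return The updated state vector.
#' @examples
#' rnai_euler_step(rnai_state(10, 0, 0, 1000), rnai_params(), 0.001)
#' @export
rnai_euler_step <- function(state, params, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number", class = "rnai_usage_error")
  }
  x <- as_rnai_state(state)
  p <- as_rnai_params(params)
  out <- rnai_step_core(x[["S"]], x[["R"]], x[["C"]], x[["M"]], p,
                        rnai_noise(), dt, sqrt(dt), 0, 0, 0, 0, "euler")
  res <- c(S = out$S, R = out$R, C = out$C, M = out$M)
  if (any(!is.finite(res))) {
    bad <- names(res)[!is.finite(res)][1]
    abort(paste0("overflow in component ", bad, " during Euler step"),
          class = "rnai_overflow_error")
  }
  res
}

#' One stochastic (Milstein or Euler-Maruyama) step
#'
#' Advances a state by one step of the discretized stochastic model. Each of
#' the four Brownian channels carries its own independent standard normal
#' draw for the step (`tau1..tau4`); a term inherits the draw of the channel
#' it discretizes (the R equation mixes channels 1 and 2).
#'
#' Two Milstein variants are provided: `"milstein_paper_literal"` reproduces
#' the published discretization term-for-term (its correction signs and the
#' n-squared factor in the R equation differ from the standard derivation),
#' while `"milstein_ito"` applies the conventional Ito-Milstein correction
#' `0.5 * b * b' * (tau^2 - 1) * dt` derived from the model's diffusion
#' coefficients and is the recommended default. `"euler"` is plain
#' Euler-Maruyama. With all intensities zero every mode reduces exactly to
#' [rnai_euler_step()].
#'
#' @inheritParams rnai_euler_step
#' @param noise Noise intensities (see [rnai_noise()]).
#' @param draws Numeric vector of 4 standard normal draws `(tau1..tau4)`.
#' @param scheme `"milstein_ito"`, `"milstein_paper_literal"` or `"euler"`.
#' @return The updated state vector.
#' @examples
#' rnai_milstein_step(rnai_state(10, 0, 0, 1000), rnai_params(),
#'                    rnai_noise(sigma1 = 0.2), 0.001, c(0, 0, 0, 0),
#'                    scheme = "milstein_paper_literal")
#' @export
rnai_milstein_step <- function(state, params, noise, dt, draws,
                               scheme = "milstein_ito") {
  check_scheme(scheme)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number", class = "rnai_usage_error")
  }
  if (!is.numeric(draws) || length(draws) != 4L || any(!is.finite(draws))) {
    abort("`draws` must be 4 finite numbers (tau1..tau4)",
          class = "rnai_usage_error")
  }
  x <- as_rnai_state(state)
  p <- as_rnai_params(params)
  ns <- as_rnai_noise(noise)
  out <- rnai_step_core(x[["S"]], x[["R"]], x[["C"]], x[["M"]], p, ns,
                        dt, sqrt(dt),
                        draws[[1]], draws[[2]], draws[[3]], draws[[4]],
                        scheme)
  res <- c(S = out$S, R = out$R, C = out$C, M = out$M)
  if (any(!is.finite(res))) {
    bad <- names(res)[!is.finite(res)][1]
    abort(paste0("overflow in component ", bad, " during stochastic step"),
          class = "rnai_overflow_error")
  }
  res
}

# Vectorized integration over replicates. tau is a list of four
# (n_steps x n_reps) matrices, or NULL for an all-zero driving path.
# Returns component arrays ((n_steps + 1) x n_reps) plus per-replicate
# positivity violation and clip counts; errors on overflow.
rnai_integrate <- function(initial, p, ns, steps, tau, scheme,
                           clip_at_zero = FALSE, store = TRUE) {
  n_steps <- length(steps)
  n_reps <- if (is.matrix(initial)) ncol(initial) else 1L
  if (!is.matrix(initial)) initial <- matrix(initial, nrow = 4)
  S <- initial[1, ]; R <- initial[2, ]; C <- initial[3, ]; M <- initial[4, ]
  if (store) {
    arrS <- matrix(NA_real_, n_steps + 1L, n_reps); arrS[1, ] <- S
    arrR <- arrS; arrR[1, ] <- R
    arrC <- arrS; arrC[1, ] <- C
    arrM <- arrS; arrM[1, ] <- M
  }
  zero <- numeric(n_reps)
  viol <- integer(n_reps)
  clips <- integer(n_reps)
  for (j in seq_len(n_steps)) {
    dtj <- steps[[j]]
    sq <- sqrt(dtj)
    if (is.null(tau)) {
      t1 <- zero; t2 <- zero; t3 <- zero; t4 <- zero
    } else {
      t1 <- tau[[1]][j, ]; t2 <- tau[[2]][j, ]
      t3 <- tau[[3]][j, ]; t4 <- tau[[4]][j, ]
    }
    st <- rnai_step_core(S, R, C, M, p, ns, dtj, sq, t1, t2, t3, t4, scheme)
    S <- st$S; R <- st$R; C <- st$C; M <- st$M
    bad <- !is.finite(S) | !is.finite(R) | !is.finite(C) | !is.finite(M)
    if (any(bad)) {
      k <- which(bad)[1]
      abort(sprintf("overflow at step %d (replicate %d)", j, k),
            class = "rnai_overflow_error", step = j, replicate = k)
    }
    neg <- S < 0 | R < 0 | C < 0 | M < 0
    viol <- viol + as.integer(neg)
    if (clip_at_zero && any(neg)) {
      clips <- clips + as.integer(neg)
      S[S < 0] <- 0; R[R < 0] <- 0; C[C < 0] <- 0; M[M < 0] <- 0
    }
    if (store) {
      arrS[j + 1L, ] <- S; arrR[j + 1L, ] <- R
      arrC[j + 1L, ] <- C; arrM[j + 1L, ] <- M
    }
  }
  out <- list(final = rbind(S = S, R = R, C = C, M = M),
              positivity_violations = viol, clips = clips)
  if (store) {
    out$S <- arrS; out$R <- arrR; out$C <- arrC; out$M <- arrM
  }
  out
}

# Draw the per-step noise matrix for one trajectory: row j holds the four
# i.i.d. N(0,1) draws of step j in channel order tau1..tau4. Exactly four
# draws are taken per step regardless of which intensities are zero, so the
# stream does not shift when a sigma changes.
rnai_draws <- function(seed, n_steps) {
  with_preserved_rng({
    set.seed(seed)
    matrix(stats::rnorm(4L * n_steps), nrow = n_steps, ncol = 4L, byrow = TRUE)
  })
}

validate_settings <- function(dt, t_end) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number", class = "rnai_usage_error")
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    abort("`t_end` must be a single positive number",
          class = "rnai_usage_error")
  }
  if (dt > t_end) {
    abort("`dt` must not exceed `t_end`", class = "rnai_usage_error")
  }
}

#' Simulate one seeded trajectory
#'
#' Integrates the stochastic (or, with zero noise, deterministic) RNA
#' silencing model on a uniform grid from `t = 0` to `t_end` with step `dt`
#' (the final step is shortened when `dt` does not divide `t_end`; diffusion
#' terms then use the square root of the actual step). One random generator
#' is initialized from `seed` per trajectory and exactly four standard normal
#' draws are taken per step, in channel order, regardless of which
#' intensities are zero. Identical settings and seed yield bitwise-identical
#' trajectories.
#'
#' Discrete-time excursions below zero are not clipped by default (the exact
#' solution is positive, the discretization need not be); each grid point
#' with any negative component is counted in the `positivity_violations`
#' attribute. With `clip_at_zero = TRUE` negative components are set to zero
#' after each step and clips are counted in the `clips` attribute.
#'
#' @param initial Initial state (see [rnai_state()]).
#' @inheritParams rnai_milstein_step
#' @param t_end Final time (> 0, >= `dt`).
#' @param seed Integer seed for the trajectory's noise stream.
#' @param clip_at_zero Clip negative components to zero after each step?
#' @return A tibble of class `rnai_trajectory` with columns `t, S, R, C, M`
#'   and attributes `params`, `noise`, `settings`, `positivity_violations`,
#'   `clips`.
#' @examples
#' traj <- rnai_simulate(rnai_state(10, 0, 0, 1000), rnai_params(),
#'                       dt = 0.01, t_end = 1)
#' tail(traj)
#' @export
rnai_simulate <- function(initial, params, noise = rnai_noise(),
                          dt = 0.001, t_end = 50,
                          scheme = "milstein_ito", seed = 1L,
                          clip_at_zero = FALSE) {
  check_scheme(scheme)
  validate_settings(dt, t_end)
  x0 <- as_rnai_state(initial)
  p <- as_rnai_params(params)
  ns <- as_rnai_noise(noise)
  steps <- rnai_grid_steps(dt, t_end)
  draws <- rnai_draws(seed, length(steps))
  tau <- list(matrix(draws[, 1], ncol = 1), matrix(draws[, 2], ncol = 1),
              matrix(draws[, 3], ncol = 1), matrix(draws[, 4], ncol = 1))
  res <- rnai_integrate(matrix(x0, nrow = 4), p, ns, steps, tau, scheme,
                        clip_at_zero = clip_at_zero, store = TRUE)
  out <- tibble::tibble(t = cumsum(c(0, steps)),
                        S = res$S[, 1], R = res$R[, 1],
                        C = res$C[, 1], M = res$M[, 1])
  structure(out,
            class = c("rnai_trajectory", class(out)),
            params = p, noise = ns,
            settings = list(dt = dt, t_end = t_end, scheme = scheme,
                            seed = seed, clip_at_zero = clip_at_zero),
            positivity_violations = res$positivity_violations[[1]],
            clips = res$clips[[1]])
}

#' Simulate an ensemble of independent replicates
#'
#' Runs `n_reps` trajectories sharing the grid, parameters and intensities;
#' replicate `k` uses the seed [rnai_replicate_seed]`(base_seed, k)`, so
#' replicates are independent and the whole ensemble is reproducible from
#' `base_seed`.
#'
#' @inheritParams rnai_simulate
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer seed from which replicate seeds are derived.
#' @return A tibble of class `rnai_ensemble` with columns
#'   `replicate, t, S, R, C, M` and attributes `params`, `noise`, `settings`,
#'   `seeds`, `positivity_violations` (per replicate), `clips`.
#' @examples
#' ens <- rnai_ensemble(rnai_state(10, 0, 0, 1000), rnai_params(),
#'                      rnai_noise(sigma1 = 0.2), dt = 0.01, t_end = 1,
#'                      n_reps = 3, base_seed = 42)
#' ensemble_moments(ens)
#' @export
rnai_ensemble <- function(initial, params, noise = rnai_noise(),
                          dt = 0.001, t_end = 50,
                          scheme = "milstein_ito", n_reps, base_seed,
                          clip_at_zero = FALSE) {
  check_scheme(scheme)
  validate_settings(dt, t_end)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    abort("`n_reps` must be >= 1", class = "rnai_usage_error")
  }
  n_reps <- as.integer(n_reps)
  x0 <- as_rnai_state(initial)
  p <- as_rnai_params(params)
  ns <- as_rnai_noise(noise)
  steps <- rnai_grid_steps(dt, t_end)
  n_steps <- length(steps)
  seeds <- vapply(seq_len(n_reps), function(k) rnai_replicate_seed(base_seed, k),
                  integer(1))
  tau <- list(matrix(NA_real_, n_steps, n_reps),
              matrix(NA_real_, n_steps, n_reps),
              matrix(NA_real_, n_steps, n_reps),
              matrix(NA_real_, n_steps, n_reps))
  for (k in seq_len(n_reps)) {
    d <- rnai_draws(seeds[[k]], n_steps)
    tau[[1]][, k] <- d[, 1]; tau[[2]][, k] <- d[, 2]
    tau[[3]][, k] <- d[, 3]; tau[[4]][, k] <- d[, 4]
  }
  init_mat <- matrix(x0, nrow = 4, ncol = n_reps)
  res <- tryCatch(
    rnai_integrate(init_mat, p, ns, steps, tau, scheme,
                   clip_at_zero = clip_at_zero, store = TRUE),
    rnai_overflow_error = function(e) {
      abort(paste0(conditionMessage(e), " in ensemble"),
            class = "rnai_overflow_error",
            replicate = e$replicate, step = e$step)
    })
  times <- cumsum(c(0, steps))
  out <- tibble::tibble(
    replicate = rep(seq_len(n_reps), each = n_steps + 1L),
    t = rep(times, times = n_reps),
    S = as.vector(res$S), R = as.vector(res$R),
    C = as.vector(res$C), M = as.vector(res$M)
  )
  structure(out,
            class = c("rnai_ensemble", class(out)),
            params = p, noise = ns,
            settings = list(dt = dt, t_end = t_end, scheme = scheme,
                            base_seed = base_seed,
                            clip_at_zero = clip_at_zero),
            seeds = seeds,
            positivity_violations = res$positivity_violations,
            clips = res$clips)
}

#' Pointwise ensemble moments
#'
#' Sample mean and unbiased sample variance of each component at each grid
#' point across replicates (variance is 0 for a single replicate). All
#' replicates must share the time grid.
#'
#' @param ens An `rnai_ensemble` tibble (or any tibble with columns
#'   `replicate, t, S, R, C, M`).
#' @return A tibble with columns `t, component, mean, variance`.
#' @export
ensemble_moments <- function(ens) {
  need <- c("replicate", "t", "S", "R", "C", "M")
  if (!all(need %in% names(ens))) {
    abort("ensemble must have columns replicate, t, S, R, C, M",
          class = "rnai_invalid_input")
  }
  grids <- ens |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(key = paste(format(.data$t, digits = 17),
                                 collapse = ","), .groups = "drop")
  if (dplyr::n_distinct(grids$key) != 1L) {
    abort("replicates do not share a common time grid",
          class = "rnai_invalid_input")
  }
  n_reps <- dplyr::n_distinct(ens$replicate)
  ens |>
    tidyr::pivot_longer(dplyr::all_of(c("S", "R", "C", "M")),
                        names_to = "component", values_to = "value") |>
    dplyr::group_by(.data$t, .data$component) |>
    dplyr::summarise(
      mean = mean(.data$value),
      variance = if (n_reps > 1L) stats::var(.data$value) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("S", "R", "C", "M"))) |>
    dplyr::arrange(.data$t, .data$component)
}

#' Empirical strong convergence order
#'
#' Estimates the strong order of a scheme by the standard nested-grid device:
#' for each sample path a single Brownian path is drawn on the reference grid
#' `dt_ref` and coarsened (block-summed increments) onto each test step in
#' `dt_list`; the strong error at a step size is the mean over paths of the
#' end-time max-norm gap to the `dt_ref` reference solution, and the returned
#' estimate is the least-squares slope of `log(error)` against `log(dt)`.
#'
#' Restricted to at most one active noise channel: with two state-dependent
#' channels an exact order-1 Milstein scheme would require Levy-area
#' simulation, which this package deliberately omits.
#'
#' @inheritParams rnai_simulate
#' @param dt_list Step sizes to test; each must be an integer multiple of
#'   `dt_ref` and divide `t_end`.
#' @param dt_ref Reference (fine) step size.
#' @param n_paths Number of sample paths.
#' @param base_seed Seed for the Brownian paths.
#' @return An object of class `rnai_order`: list with `slope`, `errors`
#'   (tibble of `dt, error`), `scheme`, `n_paths`.
#' @examples
#' \donttest{
#' ord <- rnai_strong_order(rnai_state(10, 0, 0, 1000), rnai_params(),
#'                          rnai_noise(sigma1 = 0.2), scheme = "milstein_ito",
#'                          dt_list = 2^-(6:8), dt_ref = 2^-12, t_end = 1,
#'                          n_paths = 50, base_seed = 7)
#' ord$slope
#' }
#' @export
rnai_strong_order <- function(initial, params, noise, scheme,
                              dt_list, dt_ref, t_end = 1,
                              n_paths, base_seed) {
  check_scheme(scheme)
  x0 <- as_rnai_state(initial)
  p <- as_rnai_params(params)
  ns <- as_rnai_noise(noise)
  sig <- unlist(ns)
  active <- which(sig > 0)
  if (length(active) > 1L) {
    abort("strong-order estimation requires at most one active noise channel",
          class = "rnai_usage_error")
  }
  ratios <- dt_list / dt_ref
  if (any(abs(ratios - round(ratios)) > 1e-9)) {
    abort("every dt in `dt_list` must be an integer multiple of `dt_ref`",
          class = "rnai_usage_error")
  }
  n_ref <- round(t_end / dt_ref)
  if (abs(n_ref * dt_ref - t_end) > 1e-9 * t_end) {
    abort("`dt_ref` must divide `t_end`", class = "rnai_usage_error")
  }
  ncoarse <- round(t_end / dt_list)
  if (any(abs(ncoarse * dt_list - t_end) > 1e-9 * t_end)) {
    abort("every dt in `dt_list` must divide `t_end`",
          class = "rnai_usage_error")
  }
  # Brownian increments of the active channel on the fine grid, one column
  # per path; inactive channels never influence the state so their draws are
  # not needed here.
  dW <- with_preserved_rng({
    set.seed(base_seed)
    if (length(active) == 1L) {
      matrix(stats::rnorm(n_ref * n_paths, sd = sqrt(dt_ref)), n_ref, n_paths)
    } else {
      NULL
    }
  })
  init_mat <- matrix(x0, nrow = 4, ncol = n_paths)
  zero_tau <- function(n) matrix(0, n, n_paths)
  make_tau <- function(incr, dt) {
    tau <- list(zero_tau(nrow(incr)), zero_tau(nrow(incr)),
                zero_tau(nrow(incr)), zero_tau(nrow(incr)))
    tau[[active]] <- incr / sqrt(dt)
    tau
  }
  run_final <- function(dt, incr) {
    steps <- rep(dt, round(t_end / dt))
    tau <- if (is.null(incr)) NULL else make_tau(incr, dt)
    rnai_integrate(init_mat, p, ns, steps, tau, scheme, store = FALSE)$final
  }
  ref_final <- run_final(dt_ref, dW)
  errs <- vapply(seq_along(dt_list), function(i) {
    dt <- dt_list[[i]]
    m <- round(dt / dt_ref)
    incr <- if (is.null(dW)) NULL else
      rowsum(dW, group = rep(seq_len(n_ref / m), each = m))
    fin <- run_final(dt, incr)
    mean(apply(abs(fin - ref_final), 2, max))
  }, numeric(1))
  fit <- stats::lm(log(errs) ~ log(dt_list))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 errors = tibble::tibble(dt = dt_list, error = errs),
                 scheme = scheme, n_paths = n_paths),
            class = "rnai_order")
}

#' @export
print.rnai_order <- function(x, ...) {
  cat("<rnai_order>  scheme:", x$scheme,
      " slope:", format(x$slope, digits = 4), "\n")
  invisible(x)
}

#' @describeIn rnai_strong_order Tidy the per-step-size errors.
#' @param x An `rnai_order` object.
#' @param ... Unused.
#' @method tidy rnai_order
#' @export
tidy.rnai_order <- function(x, ...) x$errors

#' @describeIn rnai_strong_order One-row summary with the fitted slope.
#' @method glance rnai_order
#' @export
glance.rnai_order <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, slope = x$slope, n_paths = x$n_paths,
                 n_dt = nrow(x$errors))
}
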