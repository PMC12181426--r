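#' Exponential p-stability thresholds for the noise intensities
#'
#' Sufficient conditions for exponential p-stability of the silencing-free
#' equilibrium of the stochastic model bound the scaled squared intensities
#' `sigma_i^2 * (p - 1) / 2` (i = 1, 2, 3) strictly below three thresholds
#' that depend only on the rate constants:
#' \deqn{\iota_a, \quad \iota_r + \iota_b \iota_h / \iota_m, \quad
#'       \iota_g + \iota_c.}
#' The fourth channel carries no condition. The thresholds are independent of
#' `p`; only the left-hand sides scale with `p - 1`.
#'
#' @inheritParams rnai_rhs
#' @param p Moment order (>= 2).
#' @return Named numeric triple `c(sigma1 = , sigma2 = , sigma3 = )` of
#'   thresholds.
#' @examples
#' rnai_stability_thresholds(rnai_params(), p = 2)  # 10, 1.1, 2
#' @export
rnai_stability_thresholds <- function(params, p = 2) {
  pm <- as_rnai_params(params)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 2) {
    rlang::abort("`p` must be a single number >= 2",
                 class = "rnai_usage_error")
  }
  c(sigma1 = pm$iota_a,
    sigma2 = pm$iota_r + pm$iota_b * pm$iota_h / pm$iota_m,
    sigma3 = pm$iota_g + pm$iota_c)
}

#' Check noise intensities against the p-stability conditions
#'
#' Evaluates, with strict inequalities and no tolerance (boundary equality
#' reports not-satisfied), whether `sigma_i^2 (p-1)/2 < threshold_i` for
#' i = 1, 2, 3. At `p = 2` the conditions imply the silencing-free
#' equilibrium of the stochastic system is globally asymptotically stable in
#' the second-moment sense.
#'
#' @inheritParams rnai_stability_thresholds
#' @param noise Noise intensities (see [rnai_noise()]).
#' @return An object of class `rnai_stability`: list with `p`, `lhs`,
#'   `thresholds`, `satisfied` (logical triple), `all_satisfied`, `margins`
#'   (`thresholds - lhs`).
#' @examples
#' rep <- rnai_check_noise(rnai_params(), rnai_noise(0.2, 0.2, 0.2, 0.2))
#' rep$all_satisfied
#' tidy(rep)
#' @export
rnai_check_noise <- function(params, noise, p = 2) {
  thr <- rnai_stability_thresholds(params, p)
  ns <- as_rnai_noise(noise)
  lhs <- c(sigma1 = ns$sigma1^2 * (p - 1) / 2,
           sigma2 = ns$sigma2^2 * (p - 1) / 2,
           sigma3 = ns$sigma3^2 * (p - 1) / 2)
  sat <- lhs < thr
  structure(list(p = p, lhs = lhs, thresholds = thr, satisfied = sat,
                 all_satisfied = all(sat), margins = thr - lhs),
            class = "rnai_stability")
}

#' @export
print.rnai_stability <- function(x, ...) {
  cat("<rnai_stability>  p =", x$p,
      " all_satisfied:", x$all_satisfied, "\n")
  print(tidy(x))
  invisible(x)
}

#' @describeIn rnai_check_noise One row per condition.
#' @param x An `rnai_stability` object.
#' @param ... Unused.
#' @method tidy rnai_stability
#' @export
tidy.rnai_stability <- function(x, ...) {
  tibble::tibble(condition = names(x$lhs),
                 lhs = unname(x$lhs),
                 threshold = unname(x$thresholds),
                 margin = unname(x$margins),
                 satisfied = unname(x$satisfied))
}

#' @describeIn rnai_check_noise One-row overall summary.
#' @method glance rnai_stability
#' @export
glance.rnai_stability <- function(x, ...) {
  tibble::tibble(p = x$p, all_satisfied = x$all_satisfied,
                 min_margin = min(x$margins))
}

#' Logarithmic Lyapunov function
#'
#' The positivity-proof Lyapunov function
#' `V(S,R,C,M) = sum over components of (x - 1 - log x)`, nonnegative on the
#' positive orthant with equality only at (1,1,1,1).
#'
#' @param state State with strictly positive components.
#' @return Nonnegative scalar.
#' @examples
#' rnai_lyapunov_v(rnai_state(1, 1, 1, 1))  # 0
#' @export
rnai_lyapunov_v <- function(state) {
  x <- as_rnai_state(state)
  if (any(x <= 0)) {
    rlang::abort("lyapunov V requires strictly positive components",
                 class = "rnai_domain_error")
  }
  sum(x - 1 - log(x))
}

#' Power-type Lyapunov function for moment stability
#'
#' `V_p = (S^p + R^p + C^p + (iota_h/iota_m - M)^p) / p`, defined on the
#' domain `S, R, C >= 0`, `M <= iota_h/iota_m` (the last term is a real power
#' of a nonnegative base only there). Vanishes exactly at the silencing-free
#' equilibrium.
#'
#' @inheritParams rnai_stability_thresholds
#' @param state State with `S, R, C >= 0` and `M <= iota_h/iota_m`.
#' @return Nonnegative scalar.
#' @examples
#' rnai_lyapunov_vp(rnai_state(0, 0, 0, 1000), rnai_params(), p = 2)  # 0
#' @export
rnai_lyapunov_vp <- function(state, params, p = 2) {
  x <- as_rnai_state(state)
  pm <- as_rnai_params(params)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 2) {
    rlang::abort("`p` must be a single number >= 2",
                 class = "rnai_usage_error")
  }
  gap <- pm$iota_h / pm$iota_m - x[["M"]]
  if (gap < 0) {
    rlang::abort("V_p is defined only for M <= iota_h/iota_m",
                 class = "rnai_domain_error")
  }
  if (any(x[c("S", "R", "C")] < 0)) {
    rlang::abort("V_p is defined only for S, R, C >= 0",
                 class = "rnai_domain_error")
  }
  (x[["S"]]^p + x[["R"]]^p + x[["C"]]^p + gap^p) / p
}

#' Drift bound of the positivity proof
#'
#' The state-dependent bound on the generator applied to the logarithmic
#' Lyapunov function:
#' \deqn{\tfrac12(\sigma_1^2+\sigma_2^2+\sigma_3^2+\sigma_4^2)
#'   + \sigma_1^2 n^2 S^2 / (2R^2) + \iota_a + \iota_a n S + \iota_r
#'   + \iota_b M + \iota_g + \iota_c + \iota_h + \iota_m + \iota_b R.}
#' Requires `R > 0` (the bound contains `S^2/R^2`).
#'
#' @inheritParams rnai_check_noise
#' @param state State with `R > 0`.
#' @return Scalar bound value; nondecreasing in each squared intensity.
#' @examples
#' rnai_drift_bound(rnai_state(1, 1, 1, 1), rnai_params(), rnai_noise())
#' @export
rnai_drift_bound <- function(state, params, noise) {
  x <- as_rnai_state(state)
  p <- as_rnai_params(params)
  ns <- as_rnai_noise(noise)
  if (x[["R"]] <= 0) {
    rlang::abort("drift bound requires R > 0", class = "rnai_domain_error")
  }
  0.5 * (ns$sigma1^2 + ns$sigma2^2 + ns$sigma3^2 + ns$sigma4^2) +
    ns$sigma1^2 * p$n^2 * x[["S"]]^2 / (2 * x[["R"]]^2) +
    p$iota_a + p$iota_a * p$n * x[["S"]] + p$iota_r +
    p$iota_b * x[["M"]] + p$iota_g + p$iota_c + p$iota_h + p$iota_m +
    p$iota_b * x[["R"]]
}

#' Empirical p-th moment decay toward the silencing-free equilibrium
#'
#' Simulates an ensemble, computes the p-th moment of the max-norm distance
#' to the silencing-free equilibrium at each grid point,
#' `m(t) = E max_i |X_i(t) - xi0_i|^p`, and fits the least-squares slope of
#' `log m(t)` against `t` over the second half of the time window. A negative
#' slope is the empirical signature of exponential p-stability. The
#' p-stability condition check for the supplied intensities is attached to
#' the result for comparison.
#'
#' @inheritParams rnai_ensemble
#' @param p Moment order (>= 2).
#' @return An object of class `rnai_decay`: list with `slope`, `p`,
#'   `moments` (tibble `t, moment`), `stability` (the [rnai_check_noise()]
#'   report), `n_reps`.
#' @examples
#' \donttest{
#' dec <- rnai_moment_decay(rnai_params(n = 1), rnai_noise(0.2, 0.2, 0.2, 0.2),
#'                          p = 2, initial = rnai_state(10, 1, 1, 990),
#'                          dt = 0.01, t_end = 5, n_reps = 20, base_seed = 1)
#' dec$slope
#' }
#' @export
rnai_moment_decay <- function(params, noise, p = 2, initial,
                              dt = 0.001, t_end = 10,
                              scheme = "milstein_ito",
                              n_reps = 200, base_seed = 1) {
  if (n_reps < 1) {
    rlang::abort("`n_reps` must be >= 1", class = "rnai_usage_error")
  }
  pm <- as_rnai_params(params)
  ns <- as_rnai_noise(noise)
  stab <- rnai_check_noise(pm, ns, p)
  ens <- rnai_ensemble(initial, pm, ns, dt = dt, t_end = t_end,
                       scheme = scheme, n_reps = n_reps,
                       base_seed = base_seed)
  xi0 <- rnai_equilibria(pm)$xi0
  dist_p <- pmax(abs(ens$S - xi0[["S"]]), abs(ens$R - xi0[["R"]]),
                 abs(ens$C - xi0[["C"]]), abs(ens$M - xi0[["M"]]))^p
  mom <- tibble::tibble(t = ens$t, d = dist_p) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(moment = mean(.data$d), .groups = "drop")
  half <- mom |> dplyr::filter(.data$t >= t_end / 2, .data$moment > 0)
  fit <- stats::lm(log(moment) ~ t, data = half)
  structure(list(slope = unname(stats::coef(fit)[2]), p = p,
                 moments = mom, stability = stab, n_reps = n_reps),
            class = "rnai_decay")
}

#' @export
print.rnai_decay <- function(x, ...) {
  cat("<rnai_decay>  p =", x$p, " slope:", format(x$slope, digits = 4),
      " conditions satisfied:", x$stability$all_satisfied, "\n")
  invisible(x)
}

#' @describeIn rnai_moment_decay The per-time moment series.
#' @param x An `rnai_decay` object.
#' @param ... Unused.
#' @method tidy rnai_decay
#' @export
tidy.rnai_decay <- function(x, ...) x$moments

#' @describeIn rnai_moment_decay One-row summary.
#' @method glance rnai_decay
#' @export
glance.rnai_decay <- function(x, ...) {
  tibble::tibble(p = x$p, slope = x$slope, n_reps = x$n_reps,
                 conditions_satisfied = x$stability$all_satisfied)
}
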