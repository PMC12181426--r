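#' Deterministic vector field of the RNA silencing model
#'
#' Evaluates the right-hand side of the kinetic system at a state:
#' `dS = -iota_a*S + iota_g*C`, `dR = n*iota_a*S - iota_r*R - iota_b*R*M`,
#' `dC = iota_b*R*M - (iota_g + iota_c)*C`, `dM = iota_h - iota_m*M -
#' iota_b*R*M`.
#'
#' @param state State vector (see [rnai_state()]).
#' @param params Rate constants (see [rnai_params()]).
#' @return Named numeric vector `c(dS, dR, dC, dM)` (molecules per time unit).
#' @examples
#' rnai_rhs(rnai_state(10, 0, 0, 1000), rnai_params())
#' @export
rnai_rhs <- function(state, params) {
  x <- as_rnai_state(state)
  p <- as_rnai_params(params)
  S <- x[["S"]]; R <- x[["R"]]; C <- x[["C"]]; M <- x[["M"]]
  c(dS = -p$iota_a * S + p$iota_g * C,
    dR = p$n * p$iota_a * S - p$iota_r * R - p$iota_b * R * M,
    dC = p$iota_b * R * M - (p$iota_g + p$iota_c) * C,
    dM = p$iota_h - p$iota_m * M - p$iota_b * R * M)
}

#' Steady states of the deterministic model
#'
#' The system always has the silencing-free steady state
#' `xi0 = (0, 0, 0, iota_h/iota_m)`, where no silencing occurs. A second,
#' interior (silencing) steady state `xi*` exists when all of its components
#' are strictly positive. Its closed form, derived directly from the
#' steady-state equations, is
#' \deqn{M^* = (\iota_g+\iota_c)\iota_r / (\iota_b D), \quad
#'       C^* = \iota_h/(\iota_g+\iota_c) - \iota_m \iota_r/(\iota_b D), \quad
#'       R^* = C^* D/\iota_r, \quad S^* = (\iota_g/\iota_a) C^*}
#' with \eqn{D = \iota_g(n-1) - \iota_c}. (A commonly printed variant of
#' \eqn{C^*} omits the factor \eqn{\iota_b} in the second term's denominator;
#' that variant does not annihilate the vector field, so the derived form is
#' used here, with residuals reported for verification. The companion literal
#' inequality \eqn{\iota_h(\iota_g(n-1)-\iota_c) > \iota_m\iota_c\iota_r} is
#' evaluated and returned as `printed_inequality_holds` for reference only.)
#'
#' @inheritParams rnai_rhs
#' @return An object of class `rnai_equilibria`: a list with elements
#'   `xi0`, `xi_star` (state vector or `NULL`), `feasible`,
#'   `residual_xi0`, `residual_xi_star` (max-norm of the vector field at each
#'   point; `NA` when `xi_star` is absent), `printed_inequality_holds`, and
#'   `params`.
#' @examples
#' eq <- rnai_equilibria(rnai_params())
#' eq$xi_star
#' tidy(eq)
#' @export
rnai_equilibria <- function(params) {
  p <- as_rnai_params(params)
  xi0 <- rnai_state(0, 0, 0, p$iota_h / p$iota_m)
  D <- p$iota_g * (p$n - 1) - p$iota_c
  xi_star <- NULL
  residual_star <- NA_real_
  feasible <- FALSE
  if (D > 0) {
    M_star <- (p$iota_g + p$iota_c) * p$iota_r / (p$iota_b * D)
    C_star <- p$iota_h / (p$iota_g + p$iota_c) -
      p$iota_m * p$iota_r / (p$iota_b * D)
    R_star <- C_star * D / p$iota_r
    S_star <- (p$iota_g / p$iota_a) * C_star
    cand <- c(S = S_star, R = R_star, C = C_star, M = M_star)
    if (all(cand > 0)) {
      feasible <- TRUE
      xi_star <- rnai_state(S_star, R_star, C_star, M_star)
      residual_star <- max(abs(rnai_rhs(xi_star, p)))
    }
  }
  structure(
    list(xi0 = xi0,
         xi_star = xi_star,
         feasible = feasible,
         residual_xi0 = max(abs(rnai_rhs(xi0, p))),
         residual_xi_star = residual_star,
         printed_inequality_holds =
           p$iota_h * D > p$iota_m * p$iota_c * p$iota_r,
         params = p),
    class = "rnai_equilibria"
  )
}

#' @export
print.rnai_equilibria <- function(x, ...) {
  cat("<rnai_equilibria>\n")
  cat("xi0      :", paste(format(x$xi0), collapse = " "), "\n")
  if (x$feasible) {
    cat("xi_star  :", paste(format(x$xi_star), collapse = " "), "\n")
  } else {
    cat("xi_star  : absent (infeasible)\n")
  }
  cat("feasible :", x$feasible, "\n")
  invisible(x)
}

#' @describeIn rnai_equilibria Tidy summary: one row per steady state with
#'   components and residual.
#' @param x An `rnai_equilibria` object.
#' @param ... Unused.
#' @method tidy rnai_equilibria
#' @export
tidy.rnai_equilibria <- function(x, ...) {
  rows <- list(
    tibble::tibble(equilibrium = "xi0",
                   S = x$xi0[["S"]], R = x$xi0[["R"]],
                   C = x$xi0[["C"]], M = x$xi0[["M"]],
                   residual = x$residual_xi0)
  )
  if (x$feasible) {
    rows <- c(rows, list(
      tibble::tibble(equilibrium = "xi_star",
                     S = x$xi_star[["S"]], R = x$xi_star[["R"]],
                     C = x$xi_star[["C"]], M = x$xi_star[["M"]],
                     residual = x$residual_xi_star)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Is the silencing steady state feasible?
#'
#' `TRUE` iff the interior steady state exists with all four components
#' strictly positive (the condition for the silencing reaction to be
#' self-sustaining). Algebraically this is equivalent to the basic
#' reproduction number exceeding one.
#'
#' @inheritParams rnai_rhs
#' @return Logical scalar.
#' @examples
#' rnai_feasible(rnai_params())        # TRUE
#' rnai_feasible(rnai_params(n = 1))   # FALSE
#' @export
rnai_feasible <- function(params) {
  rnai_equilibria(params)$feasible
}

#' Basic reproduction number via the next-generation matrix
#'
#' Builds the new-silencing matrix `F` and transition matrix `V` of the model
#' linearised at the silencing-free equilibrium, and computes
#' \eqn{R_0 = \rho(F V^{-1})} both by the closed form
#' \deqn{R_0 = n \iota_g \iota_b \iota_h /
#'   ((\iota_g+\iota_c)(\iota_b\iota_h + \iota_r\iota_m))}
#' and by the numeric spectral radius of \eqn{F V^{-1}}. The two routes must
#' agree to 1e-10 relative error; the closed-form value is reported as `r0`.
#'
#' `F` has a single nonzero entry, `iota_b*iota_h/iota_m`, in the complex row
#' / RISC column (new complexes are seeded by RISC meeting mRNA at its
#' silencing-free level).
#'
#' @inheritParams rnai_rhs
#' @param allow_boundary Permit `iota_b = 0` (a limit case with `r0 = 0`);
#'   for this call only, `params` may be an unclassed list with that boundary
#'   value.
#' @return An object of class `rnai_ngm`: list with 4x4 matrices `F` and `V`
#'   (rows/columns ordered S, R, C, M), `r0`, `r0_closed_form`,
#'   `r0_spectral`.
#' @examples
#' rnai_r0(rnai_params())$r0   # 5/2.2
#' @export
rnai_r0 <- function(params, allow_boundary = FALSE) {
  if (allow_boundary && is.list(params) && !inherits(params, "rnai_params")) {
    p <- params
    need <- c("n", "iota_a", "iota_b", "iota_c",
              "iota_h", "iota_g", "iota_m", "iota_r")
    if (!all(need %in% names(p)) ||
        any(vapply(p[need], function(v) !is.finite(v) || v < 0, logical(1)))) {
      rlang::abort("boundary parameter list must contain all eight rates, finite and >= 0",
                   class = "rnai_invalid_input")
    }
  } else {
    p <- as_rnai_params(params)
  }
  comp <- c("S", "R", "C", "M")
  M0 <- p$iota_h / p$iota_m
  Fm <- matrix(0, 4, 4, dimnames = list(comp, comp))
  Fm["C", "R"] <- p$iota_b * M0
  Vm <- matrix(0, 4, 4, dimnames = list(comp, comp))
  Vm["S", "S"] <- p$iota_a
  Vm["S", "C"] <- -p$iota_g
  Vm["R", "S"] <- -p$iota_a * p$n
  Vm["R", "R"] <- p$iota_r + p$iota_b * M0
  Vm["C", "C"] <- p$iota_g + p$iota_c
  Vm["M", "R"] <- p$iota_b * M0
  Vm["M", "M"] <- p$iota_m
  r0_cf <- p$n * p$iota_g * p$iota_b * p$iota_h /
    ((p$iota_g + p$iota_c) * (p$iota_b * p$iota_h + p$iota_r * p$iota_m))
  Vinv <- tryCatch(solve(Vm), error = function(e) {
    rlang::abort(paste0("transition matrix V is numerically singular: ",
                        conditionMessage(e)),
                 class = "rnai_numerical_error")
  })
  r0_sp <- max(Mod(eigen(Fm %*% Vinv, only.values = TRUE)$values))
  rel <- if (r0_cf == 0) abs(r0_sp) else abs(r0_sp - r0_cf) / abs(r0_cf)
  if (rel > 1e-10) {
    rlang::abort(
      sprintf("closed-form R0 (%.12g) and spectral radius (%.12g) disagree (rel %.3g)",
              r0_cf, r0_sp, rel),
      class = "rnai_numerical_error"
    )
  }
  structure(list(F = Fm, V = Vm, r0 = r0_cf,
                 r0_closed_form = r0_cf, r0_spectral = r0_sp),
            class = "rnai_ngm")
}

#' @export
print.rnai_ngm <- function(x, ...) {
  cat("<rnai_ngm>  R0 =", format(x$r0, digits = 10), "\n")
  invisible(x)
}

#' @describeIn rnai_r0 One-row summary with both computation routes.
#' @param x An `rnai_ngm` object.
#' @param ... Unused.
#' @method glance rnai_ngm
#' @export
glance.rnai_ngm <- function(x, ...) {
  tibble::tibble(r0 = x$r0,
                 r0_closed_form = x$r0_closed_form,
                 r0_spectral = x$r0_spectral,
                 rel_gap = abs(x$r0_spectral - x$r0_closed_form) /
                   max(abs(x$r0_closed_form), .Machine$double.eps))
}

#' Linear-growth and Lipschitz diagnostic constants
#'
#' Given assumed sup-norm bounds `N_S, N_R, N_C, N_M` on the four components,
#' computes the linear-growth bounds on the vector field and the Lipschitz
#' constants that certify existence and uniqueness of solutions:
#' `N_SS = iota_a*N_S + iota_g*N_C`,
#' `N_RR = iota_a*n*N_S + iota_r*N_R + iota_b*N_R*N_M`,
#' `N_CC = iota_b*N_R*N_M + (iota_g+iota_c)*N_C`,
#' `N_MM = iota_h + iota_m*N_M + iota_b*N_R*N_M`,
#' `kappa_S = iota_a`, `kappa_R = iota_r + iota_b*N_M`,
#' `kappa_C = iota_g + iota_c`, `kappa_M = iota_m + iota_b*N_R`.
#'
#' The mRNA Lipschitz constant uses `N_R`: the factor multiplying `iota_b` in
#' the mRNA difference bound is the RISC amount, so its sup bound is the one
#' that applies.
#'
#' @param sup_bounds Numeric vector of 4 strictly positive sup-norm bounds
#'   `(N_S, N_R, N_C, N_M)`.
#' @inheritParams rnai_rhs
#' @return A one-row tibble with columns `N_S..N_M`, `N_SS..N_MM`,
#'   `kappa_S, kappa_R, kappa_C, kappa_M`.
#' @examples
#' rnai_bound_constants(c(1, 1, 1, 1), rnai_params())
#' @export
rnai_bound_constants <- function(sup_bounds, params) {
  p <- as_rnai_params(params)
  if (!is.numeric(sup_bounds) || length(sup_bounds) != 4L ||
      any(!is.finite(sup_bounds)) || any(sup_bounds <= 0)) {
    rlang::abort("`sup_bounds` must be 4 strictly positive finite numbers",
                 class = "rnai_invalid_input")
  }
  N_S <- sup_bounds[[1]]; N_R <- sup_bounds[[2]]
  N_C <- sup_bounds[[3]]; N_M <- sup_bounds[[4]]
  tibble::tibble(
    N_S = N_S, N_R = N_R, N_C = N_C, N_M = N_M,
    N_SS = p$iota_a * N_S + p$iota_g * N_C,
    N_RR = p$iota_a * p$n * N_S + p$iota_r * N_R + p$iota_b * N_R * N_M,
    N_CC = p$iota_b * N_R * N_M + (p$iota_g + p$iota_c) * N_C,
    N_MM = p$iota_h + p$iota_m * N_M + p$iota_b * N_R * N_M,
    kappa_S = p$iota_a,
    kappa_R = p$iota_r + p$iota_b * N_M,
    kappa_C = p$iota_g + p$iota_c,
    kappa_M = p$iota_m + p$iota_b * N_R
  )
}
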