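#' Rate constants of the RNA silencing model
#'
#' Constructs the full set of kinetic rate constants for the four-compartment
#' RNA interference model. The state variables are S (dsRNA), R (RISC),
#' C (RISC--mRNA complex) and M (mRNA); the vector field is
#' \deqn{dS/dt = -\iota_a S + \iota_g C}
#' \deqn{dR/dt = n \iota_a S - \iota_r R - \iota_b R M}
#' \deqn{dC/dt = \iota_b R M - (\iota_g + \iota_c) C}
#' \deqn{dM/dt = \iota_h - \iota_m M - \iota_b R M}
#' Defaults are the reference parameterisation of the model
#' (n = 5, iota_a = 10, iota_b = 0.001, iota_c = 1, iota_h = 1000,
#' iota_g = 1, iota_m = 1, iota_r = 0.1).
#'
#' All parameters must be strictly positive; `n` is treated as a positive real
#' (it enters every formula as a rate multiplier, so integrality is not
#' required).
#'
#' @param n siRNAs generated per secondary dsRNA molecule (dimensionless).
#' @param iota_a Dicer-mediated dsRNA degradation rate (per molecule per time).
#' @param iota_b Mass-action rate of RISC--mRNA complex formation
#'   (per molecule^2 per time).
#' @param iota_c Complex collapse rate (per complex per time).
#' @param iota_h mRNA synthesis rate (per cell per time).
#' @param iota_g dsRNA synthesis rate by the complex (per complex per time).
#' @param iota_m Nonspecific mRNA degradation rate (per molecule per time).
#' @param iota_r RISC degradation rate (per RISC per time).
#' @return An object of class `rnai_params`: a named list of the eight rates.
#' @examples
#' p <- rnai_params()
#' rnai_rhs(rnai_state(10, 0, 0, 1000), p)
#' @export
rnai_params <- function(n = 5, iota_a = 10, iota_b = 0.001, iota_c = 1,
                        iota_h = 1000, iota_g = 1, iota_m = 1, iota_r = 0.1) {
  p <- list(n = n, iota_a = iota_a, iota_b = iota_b, iota_c = iota_c,
            iota_h = iota_h, iota_g = iota_g, iota_m = iota_m, iota_r = iota_r)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      rlang::abort(
        paste0("parameter `", nm, "` must be a single strictly positive ",
               "finite number (got ", format(v), ")"),
        class = "rnai_invalid_input"
      )
    }
    p[[nm]] <- as.numeric(v)
  }
  structure(p, class = "rnai_params")
}

#' @export
print.rnai_params <- function(x, ...) {
  cat("<rnai_params>\n")
  print(unlist(x))
  invisible(x)
}

#' White-noise intensities of the stochastic model
#'
#' Intensities of the four independent Brownian channels perturbing the rates
#' iota_a, iota_r, iota_c and iota_m respectively (units: per sqrt(time)).
#' Setting all four to zero recovers the deterministic model exactly.
#'
#' @param sigma1 Intensity on the dsRNA degradation rate iota_a.
#' @param sigma2 Intensity on the RISC degradation rate iota_r.
#' @param sigma3 Intensity on the complex collapse rate iota_c.
#' @param sigma4 Intensity on the mRNA degradation rate iota_m.
#' @return An object of class `rnai_noise`.
#' @examples
#' rnai_noise(0.2, 0.2, 0.2, 0.2)
#' @export
rnai_noise <- function(sigma1 = 0, sigma2 = 0, sigma3 = 0, sigma4 = 0) {
  s <- list(sigma1 = sigma1, sigma2 = sigma2,
            sigma3 = sigma3, sigma4 = sigma4)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      rlang::abort(
        paste0("noise intensity `", nm, "` must be a single finite ",
               "nonnegative number (got ", format(v), ")"),
        class = "rnai_invalid_input"
      )
    }
    s[[nm]] <- as.numeric(v)
  }
  structure(s, class = "rnai_noise")
}

#' @export
print.rnai_noise <- function(x, ...) {
  cat("<rnai_noise>\n")
  print(unlist(x))
  invisible(x)
}

#' Model state (S, R, C, M)
#'
#' A point in state space: amounts of dsRNA (S), RISC (R), RISC--mRNA complex
#' (C) and mRNA (M), in molecules. Components must be finite; negativity is
#' permitted at construction (numerical schemes can produce small negative
#' excursions) and checked separately with [rnai_state_nonneg()].
#'
#' @param S,R,C,M Component amounts (molecules); finite reals.
#' @return A named numeric vector `c(S =, R =, C =, M =)`.
#' @examples
#' rnai_state(10, 0, 0, 1000)
#' @export
rnai_state <- function(S, R, C, M) {
  x <- c(S = S, R = R, C = C, M = M)
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x))) {
    rlang::abort("state components must be finite numbers",
                 class = "rnai_invalid_input")
  }
  as.numeric(x) |> stats::setNames(c("S", "R", "C", "M"))
}

#' Is a state biologically valid (componentwise nonnegative)?
#'
#' @param state State vector as returned by [rnai_state()].
#' @return `TRUE` iff every component is >= 0.
#' @export
rnai_state_nonneg <- function(state) {
  state <- as_rnai_state(state)
  all(state >= 0)
}

# Coerce a length-4 numeric (named or not) to the canonical state layout.
as_rnai_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 4L) {
    rlang::abort("a state must be 4 numbers (S, R, C, M)",
                 class = "rnai_invalid_input")
  }
  if (!is.null(names(state)) && all(c("S", "R", "C", "M") %in% names(state))) {
    state <- state[c("S", "R", "C", "M")]
  }
  if (any(!is.finite(state))) {
    rlang::abort("state components must be finite",
                 class = "rnai_invalid_input")
  }
  stats::setNames(as.numeric(state), c("S", "R", "C", "M"))
}

as_rnai_params <- function(params) {
  if (inherits(params, "rnai_params")) return(params)
  rlang::abort("`params` must be created with rnai_params()",
               class = "rnai_invalid_input")
}

as_rnai_noise <- function(noise) {
  if (is.null(noise)) return(rnai_noise())
  if (inherits(noise, "rnai_noise")) return(noise)
  rlang::abort("`noise` must be created with rnai_noise()",
               class = "rnai_invalid_input")
}
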