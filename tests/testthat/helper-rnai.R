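# Reference parameterisation used throughout the tests.
table_params <- function() rnai_params()

table_xi_star <- function() {
  # closed form at the reference rates: D = 3
  c(S = 140 / 3, R = 14000, C = 1400 / 3, M = 200 / 3)
}

# Random rate draws at the magnitudes of the reference parameterisation:
# each rate scaled log-uniformly in [0.5x, 2x] of its default.
draw_params <- function() {
  base <- unlist(table_params())
  fac <- exp(stats::runif(8, log(0.5), log(2)))
  v <- base * fac
  rnai_params(v[["n"]], v[["iota_a"]], v[["iota_b"]], v[["iota_c"]],
              v[["iota_h"]], v[["iota_g"]], v[["iota_m"]], v[["iota_r"]])
}

draw_state <- function(scale = c(50, 15000, 500, 1000)) {
  rnai_state(stats::runif(1, 0, scale[1]), stats::runif(1, 0, scale[2]),
             stats::runif(1, 0, scale[3]), stats::runif(1, 0, scale[4]))
}

final_state <- function(traj) {
  unlist(traj[nrow(traj), c("S", "R", "C", "M")])
}
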