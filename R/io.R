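#' Scenario presets for the published simulation regimes
#'
#' Twelve presets mirror the simulation regimes of the study figures:
#' `fig1a`/`fig1b` are the deterministic runs (all intensities zero) from a
#' low (`S(0) = 10`) and high (`S(0) = 1000`) initial dsRNA dose; `fig2a`/
#' `fig2b` set all four intensities to 0.2 for the same two doses; `fig3`--
#' `fig6` vary one channel's intensity between 0.02 (a) and 1.2 (b), channels
#' 1--4 respectively, keeping the other three at 0.2, with `S(0) = 10`.
#' All presets use the reference rate constants and the initial condition
#' `R(0) = C(0) = 0`, `M(0) = 1000`.
#'
#' @param scenario Scenario name, e.g. `"fig3b"`; `NULL` lists all names.
#' @return For a name: a list with elements `noise` ([rnai_noise()]),
#'   `initial` (state vector) and `pins` (the flat config keys the scenario
#'   fixes). For `NULL`: the character vector of the 12 names.
#' @examples
#' rnai_scenario("fig2b")$noise
#' rnai_scenario()
#' @export
rnai_scenario <- function(scenario = NULL) {
  base_sigma <- function(s, varied = NULL, value = NULL) {
    v <- rep(s, 4)
    if (!is.null(varied)) v[varied] <- value
    v
  }
  tab <- list(
    fig1a = list(sigma = rep(0, 4), S0 = 10),
    fig1b = list(sigma = rep(0, 4), S0 = 1000),
    fig2a = list(sigma = rep(0.2, 4), S0 = 10),
    fig2b = list(sigma = rep(0.2, 4), S0 = 1000),
    fig3a = list(sigma = base_sigma(0.2, 1, 0.02), S0 = 10),
    fig3b = list(sigma = base_sigma(0.2, 1, 1.2), S0 = 10),
    fig4a = list(sigma = base_sigma(0.2, 2, 0.02), S0 = 10),
    fig4b = list(sigma = base_sigma(0.2, 2, 1.2), S0 = 10),
    fig5a = list(sigma = base_sigma(0.2, 3, 0.02), S0 = 10),
    fig5b = list(sigma = base_sigma(0.2, 3, 1.2), S0 = 10),
    fig6a = list(sigma = base_sigma(0.2, 4, 0.02), S0 = 10),
    fig6b = list(sigma = base_sigma(0.2, 4, 1.2), S0 = 10)
  )
  if (is.null(scenario)) return(names(tab))
  if (!scenario %in% names(tab)) {
    rlang::abort(paste0("unknown scenario `", scenario, "`; valid: ",
                        paste(names(tab), collapse = ", ")),
                 class = "rnai_usage_error")
  }
  sc <- tab[[scenario]]
  list(noise = rnai_noise(sc$sigma[1], sc$sigma[2], sc$sigma[3], sc$sigma[4]),
       initial = rnai_state(sc$S0, 0, 0, 1000),
       pins = c("sigma1", "sigma2", "sigma3", "sigma4",
                "S0", "R0", "C0", "M0"))
}

rnai_config_keys <- c(
  "n", "iota_a", "iota_b", "iota_c", "iota_h", "iota_g", "iota_m", "iota_r",
  "sigma1", "sigma2", "sigma3", "sigma4",
  "S0", "R0", "C0", "M0",
  "dt", "t_end", "scheme", "seed", "clip_at_zero", "scenario"
)

#' Load a run configuration
#'
#' Reads a flat JSON configuration file (documented key set below), fills
#' missing keys with the reference defaults (Table-of-rates values, zero
#' noise, initial state `(10, 0, 0, 1000)`, `dt = 0.001`, `t_end = 50`,
#' scheme `milstein_ito`, `seed = 1`) and validates every field. The default
#' configuration therefore reproduces the deterministic low-dose regime.
#' Unknown keys are an error. A `scenario` key applies a preset
#' ([rnai_scenario()]); explicitly setting a field that the scenario pins to
#' a different value is an error, not a silent override.
#'
#' Keys: `n, iota_a, iota_b, iota_c, iota_h, iota_g, iota_m, iota_r`
#' (rates), `sigma1..sigma4` (intensities), `S0, R0, C0, M0` (initial
#' state), `dt, t_end, scheme, seed, clip_at_zero, scenario`.
#'
#' @param path Path to a JSON file containing one flat object (an empty
#'   object or empty file yields the full default configuration).
#' @return An object of class `rnai_config`: list with `params`, `noise`,
#'   `initial`, `settings` (list `dt, t_end, scheme, seed, clip_at_zero`)
#'   and `scenario` (name or `NULL`).
#' @examples
#' cfg_file <- tempfile(fileext = ".json")
#' writeLines('{"scenario": "fig2b"}', cfg_file)
#' rnai_load_config(cfg_file)$noise
#' @export
rnai_load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "rnai_io_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (!nzchar(trimws(txt))) list() else
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) {
               rlang::abort(paste0("config parse error in ", path, ": ",
                                   conditionMessage(e)),
                            class = "rnai_io_error")
             })
  if (!is.list(raw)) {
    rlang::abort("config must be a flat JSON object",
                 class = "rnai_io_error")
  }
  unknown <- setdiff(names(raw), rnai_config_keys)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "rnai_validation_error")
  }
  rnai_build_config(raw)
}

# Assemble and validate a config from a named list of overrides.
rnai_build_config <- function(raw) {
  defaults <- list(
    n = 5, iota_a = 10, iota_b = 0.001, iota_c = 1, iota_h = 1000,
    iota_g = 1, iota_m = 1, iota_r = 0.1,
    sigma1 = 0, sigma2 = 0, sigma3 = 0, sigma4 = 0,
    S0 = 10, R0 = 0, C0 = 0, M0 = 1000,
    dt = 0.001, t_end = 50, scheme = "milstein_ito", seed = 1,
    clip_at_zero = FALSE, scenario = NULL
  )
  cfg <- defaults
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  scenario <- cfg$scenario
  if (!is.null(scenario)) {
    sc <- rnai_scenario(scenario)
    pinned <- list(sigma1 = sc$noise$sigma1, sigma2 = sc$noise$sigma2,
                   sigma3 = sc$noise$sigma3, sigma4 = sc$noise$sigma4,
                   S0 = sc$initial[["S"]], R0 = sc$initial[["R"]],
                   C0 = sc$initial[["C"]], M0 = sc$initial[["M"]])
    for (nm in names(pinned)) {
      if (nm %in% names(raw) && !isTRUE(all.equal(raw[[nm]], pinned[[nm]]))) {
        rlang::abort(
          paste0("config key `", nm, "` conflicts with scenario `",
                 scenario, "` (scenario pins ", format(pinned[[nm]]), ")"),
          class = "rnai_validation_error")
      }
      cfg[[nm]] <- pinned[[nm]]
    }
  }
  check_num <- function(nm, lower, strict = TRUE) {
    v <- cfg[[nm]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (strict) v > lower else v >= lower)
    if (!ok) {
      rlang::abort(paste0("invalid config value for `", nm, "`: ",
                          format(v)),
                   class = "rnai_validation_error")
    }
  }
  for (nm in c("n", "iota_a", "iota_b", "iota_c", "iota_h", "iota_g",
               "iota_m", "iota_r", "dt", "t_end")) check_num(nm, 0)
  for (nm in c("sigma1", "sigma2", "sigma3", "sigma4")) {
    check_num(nm, 0, strict = FALSE)
  }
  for (nm in c("S0", "R0", "C0", "M0")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(paste0("invalid config value for `", nm, "`"),
                   class = "rnai_validation_error")
    }
  }
  check_scheme(cfg$scheme)
  if (!is.logical(cfg$clip_at_zero) || length(cfg$clip_at_zero) != 1L) {
    rlang::abort("`clip_at_zero` must be true or false",
                 class = "rnai_validation_error")
  }
  if (cfg$dt > cfg$t_end) {
    rlang::abort("`dt` must not exceed `t_end`",
                 class = "rnai_validation_error")
  }
  structure(
    list(params = rnai_params(cfg$n, cfg$iota_a, cfg$iota_b, cfg$iota_c,
                              cfg$iota_h, cfg$iota_g, cfg$iota_m, cfg$iota_r),
         noise = rnai_noise(cfg$sigma1, cfg$sigma2, cfg$sigma3, cfg$sigma4),
         initial = rnai_state(cfg$S0, cfg$R0, cfg$C0, cfg$M0),
         settings = list(dt = cfg$dt, t_end = cfg$t_end, scheme = cfg$scheme,
                         seed = as.integer(cfg$seed),
                         clip_at_zero = cfg$clip_at_zero),
         scenario = scenario),
    class = "rnai_config")
}

#' Run a configuration
#'
#' Convenience wrapper: simulate the trajectory a config describes.
#'
#' @param config An `rnai_config` from [rnai_load_config()].
#' @return An `rnai_trajectory` tibble.
#' @export
rnai_run_config <- function(config) {
  if (!inherits(config, "rnai_config")) {
    rlang::abort("`config` must come from rnai_load_config()",
                 class = "rnai_invalid_input")
  }
  s <- config$settings
  rnai_simulate(config$initial, config$params, config$noise,
                dt = s$dt, t_end = s$t_end, scheme = s$scheme,
                seed = s$seed, clip_at_zero = s$clip_at_zero)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has header `t,S,R,C,M`, one row per grid point, UTF-8, LF line
#' endings, no index column, and numbers rendered with 17 significant digits
#' so that reading the file back reproduces every double bit-exactly. A
#' sidecar file `<path>.meta.json` records the parameters, intensities,
#' initial state, integration settings, seed, scheme, positivity-violation
#' count and package version. `read_trajectory(write_trajectory(x))` is the
#' identity on the numeric content.
#'
#' @param traj An `rnai_trajectory` (or any tibble with columns `t,S,R,C,M`).
#' @param path Output CSV path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns an `rnai_trajectory` tibble (with attributes restored from the
#'   sidecar when present).
#' @export
write_trajectory <- function(traj, path) {
  need <- c("t", "S", "R", "C", "M")
  if (!all(need %in% names(traj))) {
    rlang::abort("trajectory must have columns t, S, R, C, M",
                 class = "rnai_invalid_input")
  }
  lines <- c("t,S,R,C,M",
             paste(fmt17(traj$t), fmt17(traj$S), fmt17(traj$R),
                   fmt17(traj$C), fmt17(traj$M), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  st <- attr(traj, "settings")
  meta <- list(
    params = unclass(attr(traj, "params")),
    noise = unclass(attr(traj, "noise")),
    initial = as.list(traj[1, c("S", "R", "C", "M")]),
    dt = st$dt, t_end = st$t_end, scheme = st$scheme, seed = st$seed,
    positivity_violations = attr(traj, "positivity_violations"),
    package_version = as.character(utils::packageVersion("rnaisim"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such trajectory file: ", path),
                 class = "rnai_io_error")
  }
  header <- readLines(path, n = 1L)
  if (!identical(header, "t,S,R,C,M")) {
    rlang::abort(paste0("bad trajectory header (row 1): got `", header,
                        "`, expected `t,S,R,C,M`"),
                 class = "rnai_format_error")
  }
  # base R read.csv parses doubles via strtod (correctly rounded), which the
  # bit-exact round-trip contract requires
  df <- tryCatch(
    utils::read.csv(path, colClasses = rep("numeric", 5)),
    error = function(e) {
      rlang::abort(paste0("malformed trajectory file: ",
                          conditionMessage(e)),
                   class = "rnai_format_error")
    })
  if (any(!vapply(df, is.numeric, logical(1))) || anyNA(df)) {
    bad <- which(apply(is.na(df), 1, any))[1]
    rlang::abort(paste0("malformed trajectory data at row ", bad),
                 class = "rnai_format_error")
  }
  out <- tibble::as_tibble(df)
  meta_path <- paste0(path, ".meta.json")
  attrs <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
    attrs <- list(
      params = do.call(rnai_params, as.list(meta$params)),
      noise = do.call(rnai_noise, as.list(meta$noise)),
      settings = list(dt = meta$dt, t_end = meta$t_end,
                      scheme = meta$scheme, seed = meta$seed),
      positivity_violations = meta$positivity_violations
    )
  }
  structure(out, class = c("rnai_trajectory", class(out)),
            params = attrs$params, noise = attrs$noise,
            settings = attrs$settings,
            positivity_violations = attrs$positivity_violations)
}

#' Generate seeded reference fixtures
#'
#' Writes small reference trajectories for regression testing: the two
#' deterministic regimes (low and high initial dose, `dt = 0.01` to
#' `t = 5`) and one seeded stochastic run per scenario preset (`dt = 0.01`
#' to `t = 2`), plus a JSON manifest of MD5 checksums. Repeated invocations
#' produce identical files and checksums.
#'
#' @param out_dir Output directory (created if missing).
#' @return A tibble manifest with columns `file, scenario, kind, md5`,
#'   invisibly; also written to `manifest.json` in `out_dir`.
#' @export
rnai_generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- rnai_params()
  rows <- list()
  emit <- function(traj, file, scenario, kind) {
    path <- file.path(out_dir, file)
    write_trajectory(traj, path)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      file = file, scenario = scenario, kind = kind,
      md5 = unname(tools::md5sum(path)))
  }
  for (det in c("fig1a", "fig1b")) {
    sc <- rnai_scenario(det)
    emit(rnai_simulate(sc$initial, p, sc$noise, dt = 0.01, t_end = 5,
                       scheme = "milstein_ito", seed = 1L),
         paste0("deterministic_", det, ".csv"), det, "deterministic")
  }
  scns <- rnai_scenario()
  for (i in seq_along(scns)) {
    sc <- rnai_scenario(scns[[i]])
    emit(rnai_simulate(sc$initial, p, sc$noise, dt = 0.01, t_end = 2,
                       scheme = "milstein_ito", seed = 1000L + i),
         paste0("stochastic_", scns[[i]], ".csv"), scns[[i]], "stochastic")
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
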