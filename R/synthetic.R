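# Synthetic-data generator: constant-force traces with the two-step kinetic
# structure (mean-field ODE or stochastic per-site Gillespie backend),
# saturated force-extension point sets, and full simulated experiments. The
# generator's defaults mirror the study conditions of the constant-force
# protocol: forces 20/30/50 pN, ligand 1-7 nM, 600 s traces sampled at 1 Hz,
# Gaussian measurement noise of 0.002 nm/bp.

#' Configuration for a simulated constant-force trace
#'
#' Validates and assembles everything [simulate_trace()] needs: the
#' zero-force Bell laws of the four elementary rates (the "truth"), the
#' condition (force, concentration), the recording (duration, sample rate,
#' noise, drift), the polymer parameters that set the saturated excess
#' extension at the working force, and the backend.
#'
#' @param bells named list of four [bell_params()] (`k1`, `k_m1`, `k2`,
#'   `k_m2`) describing the zero-force rates and transition distances;
#'   defaults to the packaged flex-Ru2 kinetic set.
#' @param force applied force, pN.
#' @param concentration ligand concentration, nM (held constant; excess
#'   ligand, no depletion).
#' @param duration trace length, s.
#' @param sample_rate sampling rate, Hz.
#' @param noise_sd i.i.d. Gaussian measurement noise, nm/bp.
#' @param drift_rate slow linear instrument drift, nm/bp per s.
#' @param n_sites number of independent binding sites (stochastic backend).
#' @param seed integer seed; every simulated trace is reproducible.
#' @param backend `"meanfield"` (deterministic mean path + noise) or
#'   `"gillespie"` (per-site stochastic kinetics + noise).
#' @param polymer_sat,polymer_ds [polymer_params()] of the saturated complex
#'   and bare DNA, used to compute the saturated excess extension at
#'   `force`; default to the packaged flex-Ru2 and dsDNA rows.
#' @param kBT thermal energy, pN nm.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(bells = NULL, force = 20, concentration = 5,
                              duration = 600, sample_rate = 1,
                              noise_sd = 0.002, drift_rate = 0,
                              n_sites = 1000, seed = 1,
                              backend = c("meanfield", "gillespie"),
                              polymer_sat = NULL, polymer_ds = NULL,
                              kBT = 4.05) {
  backend <- match.arg(backend)
  if (is.null(bells) || is.null(polymer_sat) || is.null(polymer_ds)) {
    fx <- flex_ru2_parameters()
    if (is.null(bells)) bells <- fx$bells
    if (is.null(polymer_sat)) polymer_sat <- fx$flexRu2_sat
    if (is.null(polymer_ds)) polymer_ds <- fx$dsDNA
  }
  .check_number(force, "force", positive = TRUE)
  .check_number(concentration, "concentration")
  if (concentration < 0) stop("'concentration' must be >= 0", call. = FALSE)
  .check_number(duration, "duration", positive = TRUE)
  .check_number(sample_rate, "sample_rate", positive = TRUE)
  .check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  .check_number(drift_rate, "drift_rate")
  if (backend == "gillespie" && (n_sites < 1 || n_sites != round(n_sites)))
    stop("'n_sites' must be a positive integer for the gillespie backend",
         call. = FALSE)
  .check_number(seed, "seed")
  structure(list(bells = bells, force = force, concentration = concentration,
                 duration = duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 n_sites = as.integer(n_sites), seed = as.integer(seed),
                 backend = backend, polymer_sat = polymer_sat,
                 polymer_ds = polymer_ds, kBT = kBT),
            class = "simulation_config")
}

#' Saturated excess extension at a force
#'
#' Difference between the saturated-complex and bare-DNA WLC extensions at
#' the same force: the extension scale `dx_sat(F)` that converts site
#' occupancy into excess extension per base pair.
#'
#' @param polymer_sat,polymer_ds [polymer_params()] of the saturated complex
#'   and of bare DNA.
#' @param force force, pN (vectorised).
#' @param kBT thermal energy, pN nm.
#' @return saturated excess extension, nm/bp.
#' @export
dx_sat_at_force <- function(polymer_sat, polymer_ds, force, kBT = 4.05) {
  wlc_extension(polymer_sat, force, kBT) - wlc_extension(polymer_ds, force, kBT)
}

# Mean-field site fractions (P1, P2) on a time grid, by numerical
# integration of the linear ODE (deSolve); start from ligand-free DNA.
.meanfield_fractions <- function(rates, C, times, atol = 1e-12, rtol = 1e-10) {
  kon <- rates$k1 * C
  deriv <- function(t, y, parms) {
    dP1 <- kon * (1 - y[1] - y[2]) - (rates$k_m1 + rates$k2) * y[1] +
      rates$k_m2 * y[2]
    dP2 <- rates$k2 * y[1] - rates$k_m2 * y[2]
    list(c(dP1, dP2))
  }
  need0 <- times[1] > 0
  tt <- if (need0) c(0, times) else times
  sol <- deSolve::ode(y = c(P1 = 0, P2 = 0), times = tt, func = deriv,
                      parms = NULL, atol = atol, rtol = rtol)
  if (need0) sol <- sol[-1, , drop = FALSE]
  list(P1 = sol[, "P1"], P2 = sol[, "P2"])
}

#' Simulate a constant-force extension trace
#'
#' Generates one excess-extension trace `dx(t)` under the two-step
#' intercalation scheme at the configured force and ligand concentration.
#' The four elementary rates are obtained from the zero-force Bell laws
#' scaled to the working force. With the `meanfield` backend the mean path
#' is the numerical solution of the linear mean-field ODE for the site
#' fractions (P0, P1, P2) starting from bare DNA, with extension readout
#' `dx_sat(F) * (P1/2 + P2)` (a mono-intercalated site contributes half the
#' saturated per-site elongation). The `gillespie` backend simulates
#' `n_sites` independent sites with exponential waiting times and reads out
#' the site average. Gaussian noise and optional linear drift are added to
#' either backend. Identical configuration and seed give a bit-identical
#' trace.
#'
#' @param cfg a [simulation_config()].
#' @return a [threading_trace()].
#' @examples
#' cfg <- simulation_config(force = 20, concentration = 5, duration = 60,
#'                          noise_sd = 0, seed = 42)
#' tr <- simulate_trace(cfg)
#' head(tr)
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  rates <- rates_at_force(cfg$bells, cfg$force, cfg$kBT)
  dxs <- dx_sat_at_force(cfg$polymer_sat, cfg$polymer_ds, cfg$force, cfg$kBT)
  times <- seq(1 / cfg$sample_rate, cfg$duration, by = 1 / cfg$sample_rate)
  set.seed(cfg$seed)
  if (cfg$backend == "meanfield") {
    fr <- .meanfield_fractions(rates, cfg$concentration, times)
    mean_dx <- dxs * (.mono_extension_share * fr$P1 + fr$P2)
  } else {
    counts <- gillespie_counts(cfg$n_sites, rates$k1 * cfg$concentration,
                               rates$k_m1, rates$k2, rates$k_m2, times)
    mean_dx <- dxs * (.mono_extension_share * counts[, 2] + counts[, 3]) /
      cfg$n_sites
  }
  dx <- mean_dx + cfg$drift_rate * times
  if (cfg$noise_sd > 0) dx <- dx + rnorm(length(times), sd = cfg$noise_sd)
  threading_trace(times, dx, cfg$force, cfg$concentration,
                  meta = list(seed = cfg$seed, backend = cfg$backend,
                              noise_sd = cfg$noise_sd,
                              drift_rate = cfg$drift_rate))
}

#' Simulate a saturated force-extension point set
#'
#' WLC extensions of a saturated complex evaluated on a force grid, with
#' optional Gaussian noise: the input for [fit_wlc()] round-trip studies.
#' The default five-force grid spans the entropic and enthalpic regimes of
#' the constant-force protocol.
#'
#' @param params [polymer_params()] of the (saturated) polymer.
#' @param forces force grid, pN (all > 0).
#' @param noise_sd Gaussian noise on extensions, nm/bp (absolute).
#' @param seed integer seed used when `noise_sd > 0`.
#' @param kBT thermal energy, pN nm.
#' @return data frame with columns `force` (pN) and `extension` (nm/bp).
#' @export
simulate_saturated_curve <- function(params, forces = c(5, 10, 20, 35, 50),
                                     noise_sd = 0, seed = 1, kBT = 4.05) {
  if (any(forces <= 0))
    stop("'forces' must be strictly positive", call. = FALSE)
  x <- wlc_extension(params, forces, kBT)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(x), sd = noise_sd)
  }
  data.frame(force = forces, extension = x)
}

#' Simulate a full constant-force experiment grid
#'
#' Generates one trace per (force, concentration) condition, mirroring the
#' constant-force protocol: three forces and four ligand concentrations by
#' default. Per-trace seeds are derived deterministically from `seed` so the
#' whole experiment is reproducible. If `dir` is given, traces and a JSON
#' manifest (conditions, seeds, file checksums) are written there.
#'
#' @param forces forces, pN.
#' @param concentrations ligand concentrations, nM.
#' @param seed master integer seed.
#' @param dir optional output directory (created if missing).
#' @param ... further arguments passed to [simulation_config()]
#'   (`duration`, `noise_sd`, `bells`, `backend`, ...).
#' @return invisibly, a list with `traces` (list of [threading_trace()])
#'   and `manifest` (condition table; includes file names and checksums when
#'   written to disk).
#' @export
simulate_experiment <- function(forces = c(20, 30, 50),
                                concentrations = c(1, 3, 5, 7),
                                seed = 1, dir = NULL, ...) {
  grid <- expand.grid(concentration = concentrations, force = forces)
  traces <- vector("list", nrow(grid))
  # per-trace seeds derived from the master seed; folded to stay well inside
  # the 32-bit integer range
  seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- simulation_config(force = grid$force[i],
                             concentration = grid$concentration[i],
                             seed = seeds[i], ...)
    traces[[i]] <- simulate_trace(cfg)
  }
  manifest <- data.frame(force = grid$force,
                         concentration = grid$concentration, seed = seeds)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- sprintf("trace_F%g_C%g.tsv", grid$force, grid$concentration)
    for (i in seq_len(nrow(grid)))
      write_trace(traces[[i]], file.path(dir, files[i]))
    manifest$file <- files
    manifest$md5 <- unname(tools::md5sum(file.path(dir, files)))
    jsonlite::write_json(
      list(master_seed = seed, conditions = manifest),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(traces = traces, manifest = manifest))
}
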