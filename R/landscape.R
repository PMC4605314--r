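# Zero-force free-energy profile of the two-step intercalation versus
# complex elongation: three minima (non-, mono-, bis-intercalated) and two
# transition states, from zero-force rates, equilibrium constants, and
# transition distances. Energies are in units of kBT; barrier heights depend
# on the attempt-rate convention k0 through dG = kBT ln(k0 / k).

#' Build the zero-force free-energy landscape
#'
#' Places the five states of the two-step intercalation on the elongation
#' axis (zero at the non-intercalated complex) and assigns free energies in
#' kBT units with the bis-intercalated state as reference:
#' \itemize{
#'   \item non-intercalated: elongation 0, `G = ln(C/Kd)` (concentration
#'     dependent; level with the bis state at `C = Kd`);
#'   \item first transition state: elongation `x_dagger(k1)`,
#'     `G = G_non + ln(k0_attempt / (k1 C))`;
#'   \item mono-intercalated: elongation `x1 = x_dagger(k1) - x_dagger(k_m1)`,
#'     `G = ln(Kd1/Kd)` (or `ln(K2)` under the `"K2"` convention);
#'   \item second transition state: elongation `x1 + x_dagger(k2)`,
#'     `G = G_mono + ln(k0_attempt / k2)`;
#'   \item bis-intercalated: elongation `x1 + x2`, `G = 0`.
#' }
#' The two mono-state conventions exist because the zero-force `Kd`, `Kd1`
#' and `K2` are each fitted independently, so `Kd1/Kd` and `K2` need not
#' agree exactly; both are exposed and neither is silently preferred.
#'
#' @param rates0 zero-force [elementary_rates()].
#' @param distances named vector of signed transition distances
#'   (`k1`, `k_m1`, `k2`, `k_m2`), nm.
#' @param Kd,Kd1 zero-force dissociation constants, nM.
#' @param concentration ligand concentration, nM (only the non-intercalated
#'   minimum depends on it).
#' @param attempt_rate attempt rate `k0`, s^-1: the prefactor convention
#'   converting rates to barriers. Reported with the landscape since barrier
#'   absolute values depend on it.
#' @param mono_convention `"Kd_ratio"` puts the mono state at
#'   `ln(Kd1/Kd)`; `"K2"` puts it at `ln(K2)` with `K2` from the rate
#'   ratio `k2/k_m2`.
#' @param K2 optional explicit `K2` for the `"K2"` convention (defaults to
#'   `k2/k_m2` from `rates0`).
#' @return an object of class `"energy_landscape"`: a data frame with
#'   columns `label`, `elongation` (nm), `energy` (kBT), with attributes
#'   `concentration`, `attempt_rate`, `mono_convention`.
#' @examples
#' fx <- flex_ru2_parameters()
#' build_landscape(fx$rates0, fx$distances, Kd = 15, Kd1 = 35,
#'                 concentration = 15)
#' @export
build_landscape <- function(rates0, distances, Kd, Kd1, concentration,
                            attempt_rate = 1,
                            mono_convention = c("Kd_ratio", "K2"),
                            K2 = NULL) {
  stopifnot(inherits(rates0, "elementary_rates"))
  mono_convention <- match.arg(mono_convention)
  need <- c("k1", "k_m1", "k2", "k_m2")
  if (!all(need %in% names(distances)))
    stop("'distances' must be named k1, k_m1, k2, k_m2", call. = FALSE)
  .check_number(Kd, "Kd", positive = TRUE)
  .check_number(Kd1, "Kd1", positive = TRUE)
  .check_number(concentration, "concentration", positive = TRUE)
  .check_number(attempt_rate, "attempt_rate", positive = TRUE)
  if (rates0$k1 <= 0 || rates0$k2 <= 0)
    stop("forward rates must be positive to place transition states",
         call. = FALSE)

  x1 <- step_elongation(distances[["k1"]], distances[["k_m1"]])
  x2 <- step_elongation(distances[["k2"]], distances[["k_m2"]])
  elong <- c(0, distances[["k1"]], x1, x1 + distances[["k2"]], x1 + x2)
  if (any(diff(elong) <= 0))
    stop("transition distances give non-increasing elongations: ",
         paste(signif(elong, 3), collapse = ", "), call. = FALSE)

  G_non <- log(concentration / Kd)
  G_mono <- if (mono_convention == "Kd_ratio") log(Kd1 / Kd) else {
    if (is.null(K2)) K2 <- rates0$k2 / rates0$k_m2
    log(K2)
  }
  G_ts1 <- G_non + log(attempt_rate / (rates0$k1 * concentration))
  G_ts2 <- G_mono + log(attempt_rate / rates0$k2)
  out <- data.frame(
    label = c("non", "TS1", "mono", "TS2", "bis"),
    elongation = elong,
    energy = c(G_non, G_ts1, G_mono, G_ts2, 0),
    stringsAsFactors = FALSE)
  if (G_ts1 <= max(G_non, G_mono) || G_ts2 <= max(G_mono, 0))
    warning("a barrier does not exceed its adjacent minima at this ",
            "concentration / attempt rate", call. = FALSE)
  structure(out, concentration = concentration, attempt_rate = attempt_rate,
            mono_convention = mono_convention, rates0 = rates0,
            class = c("energy_landscape", "data.frame"))
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(
    "Zero-force free-energy landscape (C = %g nM, attempt rate %g s^-1, mono convention: %s)\n",
    attr(x, "concentration"), attr(x, "attempt_rate"),
    attr(x, "mono_convention")))
  print.data.frame(cbind(x[1:2], energy_kBT = round(x$energy, 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Barrier height from a landscape
#'
#' Free-energy difference between a minimum and its adjacent transition
#' state, `dG = G_TS - G_from`, in kBT. Valid transitions are
#' non <-> mono (via TS1) and mono <-> bis (via TS2).
#'
#' @param landscape an [build_landscape()] result.
#' @param from label of the departing minimum (`"non"`, `"mono"`, `"bis"`).
#' @param direction `"forward"` (towards bis) or `"reverse"`.
#' @return barrier height, kBT.
#' @examples
#' fx <- flex_ru2_parameters()
#' l <- build_landscape(fx$rates0, fx$distances, 15, 35, concentration = 15)
#' barrier_heights(l, "mono", "forward")  # ~5.1 kBT
#' @export
barrier_heights <- function(landscape, from = c("non", "mono", "bis"),
                            direction = c("forward", "reverse")) {
  stopifnot(inherits(landscape, "energy_landscape"))
  from <- match.arg(from)
  direction <- match.arg(direction)
  ts <- switch(from,
               non = if (direction == "forward") "TS1" else
                 stop("no reverse transition from the non-intercalated state",
                      call. = FALSE),
               mono = if (direction == "forward") "TS2" else "TS1",
               bis = if (direction == "reverse") "TS2" else
                 stop("no forward transition from the bis-intercalated state",
                      call. = FALSE))
  g <- function(lab) landscape$energy[landscape$label == lab]
  g(ts) - g(from)
}

#' Barrier height from a rate under an attempt-rate convention
#'
#' `dG = kBT ln(k0_attempt / k)`, in kBT units. The inverse of
#' `k = k0_attempt * exp(-dG)`.
#'
#' @param rate rate, s^-1 (a pseudo-first-order `k1*C` for the bimolecular
#'   step).
#' @param attempt_rate attempt rate, s^-1.
#' @return barrier, kBT.
#' @examples
#' barrier_from_rate(5.8e-3)  # ~5.1 kBT
#' @export
barrier_from_rate <- function(rate, attempt_rate = 1) {
  if (any(rate <= 0)) stop("'rate' must be positive", call. = FALSE)
  .check_number(attempt_rate, "attempt_rate", positive = TRUE)
  log(attempt_rate / rate)
}

#' Plot a free-energy landscape
#'
#' Piecewise spline interpolation through the five states, for visual
#' inspection only; the quantitative content is the five (elongation,
#' energy) points themselves.
#'
#' @param x an `"energy_landscape"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.energy_landscape <- function(x, ...) {
  sp <- stats::spline(x$elongation, x$energy, n = 200, method = "natural")
  plot(sp, type = "l", xlab = "elongation (nm)",
       ylab = expression(G ~ (k[B] * T)), ...)
  points(x$elongation, x$energy, pch = 19)
  text(x$elongation, x$energy, labels = x$label, pos = 3, cex = 0.8)
  invisible(x)
}
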