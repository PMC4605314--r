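# Observable layer: bi-exponential extension relaxation and the equilibrium
# amplitude model linking extensions to binding constants. Traces store the
# excess extension dx(t) above the bare-DNA extension at the same force.

# Fraction of the per-site saturated elongation contributed by a
# mono-intercalated ligand (the bis state contributes 1). The analysis
# assumes the complex lengthens by the same amount in each of the two
# intercalation events; kept as a module constant so sensitivity studies can
# vary it.
.mono_extension_share <- 0.5

#' Bi-exponential relaxation parameters
#'
#' Parameters of the two-mode extension relaxation
#' \deqn{dx(t) = dx_{eq} - dx_f e^{-k_f t} - dx_s e^{-k_s t}}
#' for a trace that starts at `dx(0) = dx_eq - dx_f - dx_s >= 0` and relaxes
#' towards `dx_eq`.
#'
#' @param dx_eq equilibrium excess extension, nm/bp.
#' @param dx_f amplitude of the fast mode, nm/bp.
#' @param dx_s amplitude of the slow mode, nm/bp.
#' @param k_f fast rate, s^-1 (must be >= `k_s`).
#' @param k_s slow rate, s^-1 (> 0).
#' @param tol tolerance on the start-of-trace constraint
#'   `dx_f + dx_s <= dx_eq + tol`; fits of noisy traces pass their residual
#'   scale here, since measurement noise lets the fitted start dip slightly
#'   below zero excess extension.
#' @return an object of class `"relaxation_params"`.
#' @export
relaxation_params <- function(dx_eq, dx_f, dx_s, k_f, k_s, tol = 0) {
  for (nm in c("dx_eq", "dx_f", "dx_s"))
    if (get(nm) < -1e-12)
      stop(sprintf("'%s' must be non-negative", nm), call. = FALSE)
  .check_number(k_s, "k_s", positive = TRUE)
  .check_number(k_f, "k_f", positive = TRUE)
  if (k_f < k_s)
    stop("'k_f' must be the faster rate (k_f >= k_s)", call. = FALSE)
  if (dx_f + dx_s > dx_eq + tol + 1e-9 + 1e-6 * dx_eq)
    stop("dx_f + dx_s exceeds dx_eq: trace would start below zero excess extension",
         call. = FALSE)
  structure(list(dx_eq = dx_eq, dx_f = dx_f, dx_s = dx_s,
                 k_f = k_f, k_s = k_s),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat("Bi-exponential relaxation parameters\n")
  cat(sprintf("  dx_eq = %.4g nm/bp  dx_f = %.4g  dx_s = %.4g\n",
              x$dx_eq, x$dx_f, x$dx_s))
  cat(sprintf("  k_f = %.4g s^-1  k_s = %.4g s^-1  (ratio %.3g)\n",
              x$k_f, x$k_s, x$k_f / x$k_s))
  invisible(x)
}

#' Evaluate the bi-exponential relaxation
#'
#' @param p a [relaxation_params()] object.
#' @param t times, s (>= 0, vectorised).
#' @return excess extension dx(t), nm/bp.
#' @examples
#' p <- relaxation_params(0.1, 0.04, 0.06, 0.1, 0.01)
#' biexp_extension(p, c(0, 10, Inf))
#' @export
biexp_extension <- function(p, t) {
  stopifnot(inherits(p, "relaxation_params"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  p$dx_eq - p$dx_f * exp(-p$k_f * t) - p$dx_s * exp(-p$k_s * t)
}

#' Equilibrium excess extension from the simple binding isotherm
#'
#' \deqn{dx_{eq}(C) = dx_{sat} \frac{C/K_d}{C/K_d + 1}}
#'
#' @param C ligand concentration, nM (vectorised, >= 0).
#' @param Kd overall dissociation constant, nM.
#' @param dx_sat saturated excess extension at the same force, nm/bp.
#' @return equilibrium excess extension, nm/bp.
#' @export
equilibrium_extension <- function(C, Kd, dx_sat) {
  .check_number(Kd, "Kd", positive = TRUE)
  if (any(C < 0)) stop("'C' must be non-negative", call. = FALSE)
  r <- C / Kd
  dx_sat * r / (r + 1)
}

#' Equilibrium probability of the mono-intercalated state
#'
#' `f = (C/Kd1) / (C/Kd1 + 1)`: the occupancy of the first binding step
#' alone, which controls how the relaxation amplitude splits between the
#' fast and slow modes.
#'
#' @param C ligand concentration, nM (vectorised).
#' @param Kd1 first-step dissociation constant, nM.
#' @return fraction in \[0, 1).
#' @export
mono_state_probability <- function(C, Kd1) {
  .check_number(Kd1, "Kd1", positive = TRUE)
  if (any(C < 0)) stop("'C' must be non-negative", call. = FALSE)
  r <- C / Kd1
  r / (r + 1)
}

#' Partition the equilibrium amplitude into fast and slow modes
#'
#' Under the equal-step-elongation assumption the fast mode carries a share
#' `f/2` of the total equilibrium amplitude and the slow mode the rest:
#' `dx_f = dx_eq * f/2`, `dx_s = dx_eq * (1 - f/2)`, where `f` is the
#' mono-state probability and `dx_eq` follows the simple isotherm. The two
#' amplitudes sum to `dx_eq` exactly.
#'
#' @param C ligand concentration, nM (vectorised).
#' @param Kd overall dissociation constant, nM.
#' @param Kd1 first-step dissociation constant, nM.
#' @param dx_sat saturated excess extension, nm/bp.
#' @return list with components `dx_f` and `dx_s`, nm/bp.
#' @export
amplitude_partition <- function(C, Kd, Kd1, dx_sat) {
  dx_eq <- equilibrium_extension(C, Kd, dx_sat)
  half_f <- .mono_extension_share * mono_state_probability(C, Kd1)
  list(dx_f = dx_eq * half_f, dx_s = dx_eq * (1 - half_f))
}

#' Fast-to-slow amplitude ratio
#'
#' \deqn{dx_f/dx_s = \frac{C/K_{d1}}{C/K_{d1} + 2}}
#' Depends only on the first-step constant `Kd1`, which is what makes the
#' amplitude ratio a clean probe of the mono-intercalation equilibrium. The
#' ratio is strictly increasing in `C` and bounded above by 1.
#'
#' @param C ligand concentration, nM (vectorised).
#' @param Kd1 first-step dissociation constant, nM.
#' @return dimensionless ratio in \[0, 1).
#' @export
amplitude_ratio <- function(C, Kd1) {
  .check_number(Kd1, "Kd1", positive = TRUE)
  if (any(C < 0)) stop("'C' must be non-negative", call. = FALSE)
  r <- C / Kd1
  r / (r + 2)
}

#' Exact bi-exponential solution of the mean-field two-step scheme
#'
#' Solves the linear mean-field kinetics of the two-step scheme analytically
#' for a trace starting from ligand-free DNA: site fractions (P0, P1, P2)
#' start at (1, 0, 0), the extension readout is
#' `dx = dx_sat * (share * P1 + P2)` with `share = 0.5` (equal step
#' elongations), and the result is returned as the exact
#' [relaxation_params()] whose rates are the scheme's eigenrates and whose
#' amplitudes follow from the eigenvectors. This is the closed form a
#' noiseless mean-field trace follows exactly.
#'
#' @param rates an [elementary_rates()] object (at the force of interest).
#' @param C ligand concentration, nM.
#' @param dx_sat saturated excess extension at the same force, nm/bp.
#' @return a [relaxation_params()] object.
#' @export
relaxation_from_scheme <- function(rates, C, dx_sat) {
  stopifnot(inherits(rates, "elementary_rates"))
  .check_number(C, "C")
  if (C < 0) stop("'C' must be non-negative", call. = FALSE)
  .check_number(dx_sat, "dx_sat", positive = TRUE)
  kon <- rates$k1 * C
  # d(P1,P2)/dt = J %*% (P1,P2) + (kon, 0), with P0 eliminated
  J <- matrix(c(-(kon + rates$k_m1 + rates$k2), rates$k_m2 - kon,
                rates$k2, -rates$k_m2),
              nrow = 2, byrow = TRUE)
  Peq <- solve(J, -c(kon, 0))
  ev <- eigen(J)
  lam <- -Re(ev$values)            # relaxation rates, both >= 0
  V <- Re(ev$vectors)
  cc <- solve(V, -Peq)             # P(t) = Peq + V %*% (cc * exp(-lam t))
  w <- c(.mono_extension_share, 1)
  amp <- -dx_sat * as.numeric(w %*% (V * rep(cc, each = 2)))
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; amp <- amp[ord]
  relaxation_params(dx_eq = dx_sat * sum(w * Peq),
                    dx_f = max(amp[1], 0), dx_s = max(amp[2], 0),
                    k_f = lam[1], k_s = lam[2])
}

#' Constant-force extension trace
#'
#' A trace records the excess extension per base pair, `dx(t)`, of a
#' DNA-ligand complex held at constant force, together with the condition it
#' was recorded (or simulated) under.
#'
#' @param time times, s, strictly increasing.
#' @param dx excess extensions, nm/bp (same length as `time`).
#' @param force applied force, pN.
#' @param concentration ligand concentration, nM.
#' @param meta named list of metadata (seed, molecule id, backend, ...).
#' @return a data frame of class `"threading_trace"` with columns `time` and
#'   `dx` and attributes `force`, `concentration`, `meta`.
#' @export
threading_trace <- function(time, dx, force, concentration, meta = list()) {
  if (length(time) != length(dx))
    stop("'time' and 'dx' must have the same length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  .check_number(force, "force", positive = TRUE)
  .check_number(concentration, "concentration")
  structure(data.frame(time = time, dx = dx),
            force = force, concentration = concentration, meta = meta,
            class = c("threading_trace", "data.frame"))
}

#' @export
print.threading_trace <- function(x, ...) {
  cat(sprintf(
    "Constant-force trace: %d samples over %.4g s at %g pN, C = %g nM\n",
    nrow(x), max(x$time) - min(x$time),
    attr(x, "force"), attr(x, "concentration")))
  m <- attr(x, "meta")
  if (length(m))
    cat("  meta: ", paste(names(m), unlist(m), sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
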