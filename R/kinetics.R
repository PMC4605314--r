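# Two-step sequential intercalation scheme:
#   L + DNA  <=>[k1*C / k_m1]  mono  <=>[k2 / k_m2]  bis
# Observed relaxation rates (exact eigenrates and the pre-equilibrium
# approximation), Bell-type force dependence, equilibrium constants and step
# elongations. Concentrations are in nM throughout (k1 in nM^-1 s^-1).

#' Elementary rates of the two-step intercalation scheme
#'
#' @param k1 bimolecular on-rate of the first (mono) intercalation step,
#'   nM^-1 s^-1.
#' @param k_m1 off-rate of the mono-intercalated state, s^-1.
#' @param k2 forward rate of the mono-to-bis conversion, s^-1.
#' @param k_m2 reverse rate of the bis-to-mono conversion, s^-1.
#' @param force force at which the rates apply, pN (`NA` for zero-force /
#'   unspecified).
#' @param se optional named numeric vector of standard errors.
#' @return an object of class `"elementary_rates"`.
#' @examples
#' elementary_rates(1.8e-3, 68e-3, 5.8e-3, 3.6e-3)
#' @export
elementary_rates <- function(k1, k_m1, k2, k_m2, force = NA_real_, se = NULL) {
  for (nm in c("k1", "k_m1", "k2", "k_m2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm), call. = FALSE)
  }
  if (k1 == 0 && k_m1 == 0)
    stop("at least one of 'k1', 'k_m1' must be positive", call. = FALSE)
  structure(list(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2,
                 force = force, se = se),
            class = "elementary_rates")
}

#' @export
print.elementary_rates <- function(x, ...) {
  cat("Elementary two-step intercalation rates",
      if (is.finite(x$force)) sprintf(" at %g pN", x$force), "\n", sep = "")
  fmt <- function(nm, v, unit) {
    s <- if (!is.null(x$se) && nm %in% names(x$se))
      sprintf(" +/- %.2g", x$se[[nm]]) else ""
    cat(sprintf("  %-5s %.4g%s %s\n", nm, v, s, unit))
  }
  fmt("k1", x$k1, "nM^-1 s^-1")
  fmt("k_m1", x$k_m1, "s^-1")
  fmt("k2", x$k2, "s^-1")
  fmt("k_m2", x$k_m2, "s^-1")
  invisible(x)
}

#' Observed fast and slow rates under the pre-equilibrium approximation
#'
#' When the first binding step is much faster than the second
#' (`k1*C + k_m1 >> k2 + k_m2`), the bi-exponential relaxation rates are
#' \deqn{k_f = k_1 C + k_{-1}}
#' \deqn{k_s = k_2 \frac{k_1 C}{k_1 C + k_{-1}} + k_{-2}}
#'
#' @param rates an [elementary_rates()] object.
#' @param C ligand concentration, nM (vectorised, >= 0).
#' @return list with components `k_f` and `k_s`, s^-1.
#' @seealso [observed_rates_exact()] for the exact eigenrates,
#'   [preequilibrium_ratio()] for the validity diagnostic.
#' @examples
#' r <- elementary_rates(1.8e-3, 68e-3, 5.8e-3, 3.6e-3)
#' observed_rates_preequilibrium(r, C = 3)
#' @export
observed_rates_preequilibrium <- function(rates, C) {
  stopifnot(inherits(rates, "elementary_rates"))
  if (any(C < 0)) stop("'C' must be non-negative", call. = FALSE)
  a <- rates$k1 * C + rates$k_m1
  if (any(a == 0))
    stop("k1*C + k_m1 = 0: slow rate undefined", call. = FALSE)
  list(k_f = a, k_s = rates$k2 * (rates$k1 * C) / a + rates$k_m2)
}

#' Exact relaxation eigenrates of the two-step scheme
#'
#' The linear two-step scheme relaxes with the two eigenvalues of its 2x2
#' rate matrix. With `a = k1*C + k_m1`, `S = a + k2 + k_m2` and
#' `P = k1*C*(k2 + k_m2) + k_m1*k_m2`, the eigenrates are
#' `(S +/- sqrt(S^2 - 4P)) / 2`; both are real and non-negative. These are
#' the rates a bi-exponential fit of a mean-field trace actually measures;
#' the pre-equilibrium formulas approximate them.
#'
#' @inheritParams observed_rates_preequilibrium
#' @return list with components `lambda_fast` and `lambda_slow`, s^-1.
#' @examples
#' r <- elementary_rates(1.8e-3, 68e-3, 5.8e-3, 3.6e-3)
#' observed_rates_exact(r, C = 3)
#' @export
observed_rates_exact <- function(rates, C) {
  stopifnot(inherits(rates, "elementary_rates"))
  if (any(C < 0)) stop("'C' must be non-negative", call. = FALSE)
  a <- rates$k1 * C + rates$k_m1
  S <- a + rates$k2 + rates$k_m2
  P <- rates$k1 * C * (rates$k2 + rates$k_m2) + rates$k_m1 * rates$k_m2
  disc <- pmax(S^2 - 4 * P, 0)  # non-negative analytically; guard rounding
  root <- sqrt(disc)
  list(lambda_fast = (S + root) / 2, lambda_slow = (S - root) / 2)
}

#' Pre-equilibrium validity ratio
#'
#' Ratio `(k1*C + k_m1) / (k2 + k_m2)` of first-step to second-step
#' relaxation scales. The pre-equilibrium formulas are accurate when this
#' ratio is large; the pipeline warns when it drops below `warn_below`.
#'
#' @inheritParams observed_rates_preequilibrium
#' @param warn_below threshold below which a warning is emitted (default 10).
#' @param quiet suppress the warning.
#' @return the ratio (possibly `Inf` when `k2 + k_m2 = 0`).
#' @examples
#' r <- elementary_rates(1.8e-3, 68e-3, 5.8e-3, 3.6e-3)
#' preequilibrium_ratio(r, C = 0, quiet = TRUE)  # 68/9.4
#' @export
preequilibrium_ratio <- function(rates, C, warn_below = 10, quiet = FALSE) {
  stopifnot(inherits(rates, "elementary_rates"))
  slow <- rates$k2 + rates$k_m2
  ratio <- if (slow == 0) rep(Inf, length(C)) else
    (rates$k1 * C + rates$k_m1) / slow
  if (!quiet && any(ratio < warn_below))
    warning(sprintf(
      "pre-equilibrium ratio %.2g < %g: fast/slow separation is marginal",
      min(ratio), warn_below), call. = FALSE)
  ratio
}

#' Bell-model parameters of a force-dependent rate
#'
#' @param k0 zero-force rate (units of the underlying rate).
#' @param x_dagger signed distance to the transition state, nm. Positive
#'   means the complex is longer at the transition state than in the
#'   departing state, so force accelerates the step.
#' @param se optional named standard errors (`k0`, `x_dagger`).
#' @return an object of class `"bell_params"`.
#' @export
bell_params <- function(k0, x_dagger, se = NULL) {
  .check_number(k0, "k0", positive = TRUE)
  .check_number(x_dagger, "x_dagger")
  structure(list(k0 = k0, x_dagger = x_dagger, se = se),
            class = "bell_params")
}

#' @export
print.bell_params <- function(x, ...) {
  cat(sprintf("Bell rate law: k0 = %.4g, x_dagger = %+.3g nm\n",
              x$k0, x$x_dagger))
  invisible(x)
}

#' Evaluate a Bell-model rate at force
#'
#' \deqn{k(F) = k^0 e^{F x^\dagger / k_B T}}
#'
#' @param bp a [bell_params()] object.
#' @param force force, pN (vectorised).
#' @param kBT thermal energy, pN nm.
#' @return rate at each force.
#' @examples
#' bell_rate(bell_params(68e-3, -0.06), force = 20)  # ~0.0506 s^-1
#' @export
bell_rate <- function(bp, force, kBT = 4.05) {
  stopifnot(inherits(bp, "bell_params"))
  .check_number(kBT, "kBT", positive = TRUE)
  bp$k0 * exp(force * bp$x_dagger / kBT)
}

#' Force-scaled elementary rates from four Bell laws
#'
#' Evaluates four [bell_params()] laws (for k1, k_m1, k2, k_m2) at a common
#' force, returning the [elementary_rates()] at that force.
#'
#' @param bells named list with components `k1`, `k_m1`, `k2`, `k_m2`, each a
#'   [bell_params()].
#' @param force force, pN.
#' @param kBT thermal energy, pN nm.
#' @return an [elementary_rates()] object at `force`.
#' @export
rates_at_force <- function(bells, force, kBT = 4.05) {
  need <- c("k1", "k_m1", "k2", "k_m2")
  if (!all(need %in% names(bells)))
    stop("'bells' must contain k1, k_m1, k2, k_m2", call. = FALSE)
  elementary_rates(
    k1   = bell_rate(bells$k1, force, kBT),
    k_m1 = bell_rate(bells$k_m1, force, kBT),
    k2   = bell_rate(bells$k2, force, kBT),
    k_m2 = bell_rate(bells$k_m2, force, kBT),
    force = force)
}

#' Equilibrium constants from elementary rates
#'
#' \deqn{K_{d1} = k_{-1}/k_1, \quad K_2 = k_2/k_{-2}, \quad K_d = K_{d1}/K_2}
#' `Kd1` and `Kd` are dissociation constants in nM; `K2` is the
#' dimensionless equilibrium constant of the second (unimolecular) step.
#'
#' @param rates an [elementary_rates()] object with `k1 > 0` and `k2 > 0`.
#' @return object of class `"equilibrium_constants"` with fields `Kd1`,
#'   `K2`, `Kd` and `force`.
#' @examples
#' equilibrium_from_rates(elementary_rates(1.8e-3, 68e-3, 5.8e-3, 3.6e-3))
#' @export
equilibrium_from_rates <- function(rates) {
  stopifnot(inherits(rates, "elementary_rates"))
  if (rates$k1 <= 0 || rates$k2 <= 0)
    stop("forward rates k1 and k2 must be positive to form equilibrium constants",
         call. = FALSE)
  if (rates$k_m2 <= 0)
    stop("k_m2 must be positive: K2 undefined otherwise", call. = FALSE)
  Kd1 <- rates$k_m1 / rates$k1
  K2 <- rates$k2 / rates$k_m2
  structure(list(Kd1 = Kd1, K2 = K2, Kd = Kd1 / K2, force = rates$force),
            class = "equilibrium_constants")
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat("Equilibrium constants",
      if (is.finite(x$force)) sprintf(" at %g pN", x$force), "\n", sep = "")
  cat(sprintf("  Kd1 = %.4g nM   K2 = %.4g   Kd = %.4g nM\n",
              x$Kd1, x$K2, x$Kd))
  invisible(x)
}

#' Force law of an equilibrium constant
#'
#' \deqn{K(F) = K^0 e^{-F x^0 / k_B T}}
#' with `x0` the equilibrium elongation of the step; positive `x0` means
#' force strengthens binding (lowers a dissociation constant).
#'
#' @param K0 zero-force constant (nM for dissociation constants,
#'   dimensionless for `K2`).
#' @param x0 equilibrium elongation, nm.
#' @param se optional named standard errors.
#' @return an object of class `"force_law"`.
#' @export
force_law <- function(K0, x0, se = NULL) {
  .check_number(K0, "K0", positive = TRUE)
  .check_number(x0, "x0")
  structure(list(K0 = K0, x0 = x0, se = se), class = "force_law")
}

#' @export
print.force_law <- function(x, ...) {
  cat(sprintf("Equilibrium force law: K0 = %.4g, x0 = %+.3g nm\n", x$K0, x$x0))
  invisible(x)
}

#' Evaluate an equilibrium force law
#'
#' @param law a [force_law()] object.
#' @param force force, pN (vectorised).
#' @param kBT thermal energy, pN nm.
#' @return the constant at each force.
#' @examples
#' equilibrium_force_law_eval(force_law(15, 0.44), force = 20)
#' @export
equilibrium_force_law_eval <- function(law, force, kBT = 4.05) {
  stopifnot(inherits(law, "force_law"))
  .check_number(kBT, "kBT", positive = TRUE)
  law$K0 * exp(-force * law$x0 / kBT)
}

#' Equilibrium step elongation from transition distances
#'
#' The equilibrium elongation of one binding step is the difference between
#' the forward and reverse transition distances, `x_i = x_{+i} - x_{-i}`.
#'
#' @param x_plus forward transition distance, nm.
#' @param x_minus reverse transition distance, nm (typically negative for
#'   intercalation, where force slows the reverse step).
#' @return elongation, nm.
#' @examples
#' step_elongation(0.19, -0.06)  # 0.25 nm
#' step_elongation(0.08, -0.15)  # 0.23 nm
#' @export
step_elongation <- function(x_plus, x_minus) {
  x_plus - x_minus
}
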