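# Extensible worm-like-chain elasticity of bare and ligand-saturated DNA, and
# conversion of complex extension to fractional ligand occupancy.

#' Worm-like-chain polymer parameters
#'
#' Container for the three parameters of the extensible worm-like chain
#' (WLC): contour length per base pair, persistence length and stretch
#' (elastic) modulus. Extensions are stored per base pair throughout the
#' package; per-molecule lengths require an explicit base-pair count.
#'
#' @param contour_per_bp contour length per base pair, nm/bp. Must lie in
#'   (0.1, 1) nm/bp, the physically sensible range for single- and
#'   double-stranded nucleic acids with or without intercalated ligand.
#' @param persistence persistence length, nm.
#' @param stretch_modulus elastic (stretch) modulus, pN.
#' @param label optional name for printing.
#' @return an object of class `"polymer_params"`.
#' @seealso [wlc_extension()], [fit_wlc()]
#' @examples
#' polymer_params(0.34, 47, 1270, label = "dsDNA")
#' @export
polymer_params <- function(contour_per_bp, persistence, stretch_modulus,
                           label = NULL) {
  .check_number(contour_per_bp, "contour_per_bp", positive = TRUE)
  .check_number(persistence, "persistence", positive = TRUE)
  .check_number(stretch_modulus, "stretch_modulus", positive = TRUE)
  if (contour_per_bp <= 0.1 || contour_per_bp >= 1.0)
    stop("'contour_per_bp' must lie in (0.1, 1) nm/bp", call. = FALSE)
  structure(
    list(contour_per_bp = contour_per_bp, persistence = persistence,
         stretch_modulus = stretch_modulus, label = label),
    class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat("Extensible WLC parameters",
      if (!is.null(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat(sprintf("  contour length : %.4g nm/bp\n", x$contour_per_bp))
  cat(sprintf("  persistence    : %.4g nm\n", x$persistence))
  cat(sprintf("  stretch modulus: %.4g pN\n", x$stretch_modulus))
  invisible(x)
}

#' Extensible worm-like-chain extension at a given force
#'
#' High-force interpolation formula for the extension per base pair of an
#' extensible WLC:
#' \deqn{x(F) = x_{max} (1 - \frac{1}{2\sqrt{F A / k_B T}} + F/S)}
#' The entropic term diverges at zero force, so `force` must be strictly
#' positive; the enthalpic term `F/S` lets the extension exceed the contour
#' length at high force.
#'
#' @param params a [polymer_params()] object.
#' @param force applied force, pN (vectorised, all > 0).
#' @param kBT thermal energy, pN nm.
#' @return extension per base pair, nm/bp.
#' @examples
#' dsdna <- polymer_params(0.34, 47, 1270)
#' wlc_extension(dsdna, force = c(5, 20, 50))
#' @export
wlc_extension <- function(params, force, kBT = 4.05) {
  stopifnot(inherits(params, "polymer_params"))
  .check_number(kBT, "kBT", positive = TRUE)
  if (!is.numeric(force) || length(force) < 1L || anyNA(force))
    stop("'force' must be numeric and non-missing", call. = FALSE)
  if (any(force <= 0))
    stop("'force' must be strictly positive: the entropic WLC term diverges at F = 0",
         call. = FALSE)
  params$contour_per_bp *
    (1 - 1 / (2 * sqrt(force * params$persistence / kBT)) +
       force / params$stretch_modulus)
}

#' Fit the extensible worm-like chain to force-extension data
#'
#' Least-squares fit of the three WLC parameters (contour length per bp,
#' persistence length, stretch modulus) to force-extension points, by
#' Levenberg-Marquardt minimisation. Unweighted by default; supply per-point
#' standard deviations through `sigma` for inverse-variance weighting.
#'
#' @param force forces, pN (>= 4 points spanning at least a two-fold range).
#' @param extension extensions per base pair, nm/bp.
#' @param kBT thermal energy, pN nm.
#' @param sigma optional per-point standard deviations of `extension`.
#' @param start optional named list with starting values `contour_per_bp`,
#'   `persistence`, `stretch_modulus`.
#' @param label optional label stored with the result.
#' @return an object of class `"wlc_fit"`: a list with elements `params`
#'   (a [polymer_params()]), `se` (standard errors from the fit covariance),
#'   `cov`, `residual_rms`, `n`, `converged`, and the underlying `nls` fit.
#' @seealso [wlc_extension()], [predict.wlc_fit()]
#' @examples
#' truth <- polymer_params(0.49, 2.9, 800)
#' f <- c(5, 10, 20, 35, 50)
#' fit <- fit_wlc(f, wlc_extension(truth, f))
#' coef(fit)
#' @export
fit_wlc <- function(force, extension, kBT = 4.05, sigma = NULL, start = NULL,
                    label = NULL) {
  if (length(force) != length(extension))
    stop("'force' and 'extension' must have the same length", call. = FALSE)
  keep <- is.finite(force) & is.finite(extension)
  force <- force[keep]; extension <- extension[keep]
  if (length(force) < 4L)
    stop("at least 4 force-extension points are required to fit 3 WLC parameters",
         call. = FALSE)
  if (max(force) < 2 * min(force))
    stop("force-extension points must span at least a two-fold force range",
         call. = FALSE)
  if (any(force <= 0)) stop("all forces must be positive", call. = FALSE)
  weights <- if (is.null(sigma)) rep(1, length(force)) else {
    if (length(sigma) != length(extension) || any(sigma <= 0))
      stop("'sigma' must be positive and match 'extension' in length", call. = FALSE)
    1 / sigma[keep]^2
  }
  if (is.null(start))
    start <- list(contour_per_bp = max(extension), persistence = 10,
                  stretch_modulus = 1000)
  dat <- data.frame(F = force, x = extension, w = weights)
  fit <- try(minpack.lm::nlsLM(
    x ~ cmax * (1 - 1 / (2 * sqrt(F * A / kBT)) + F / S),
    data = dat,
    start = list(cmax = start$contour_per_bp, A = start$persistence,
                 S = start$stretch_modulus),
    weights = dat$w,
    lower = c(1e-4, 1e-4, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("WLC fit failed: ", attr(fit, "condition")$message, call. = FALSE)
  converged <- fit$convInfo$isConv
  if (!converged)
    warning("WLC fit did not converge; result flagged", call. = FALSE)
  est <- coef(fit)
  cv <- try(vcov(fit), silent = TRUE)
  if (inherits(cv, "try-error")) cv <- matrix(NA_real_, 3, 3)
  se <- sqrt(pmax(diag(cv), 0))
  names(se) <- c("contour_per_bp", "persistence", "stretch_modulus")
  res <- structure(
    list(params = polymer_params(est[["cmax"]], est[["A"]], est[["S"]],
                                 label = label),
         se = se, cov = cv,
         residual_rms = sqrt(mean(residuals(fit)^2)),
         n = length(force), kBT = kBT, converged = converged, fit = fit),
    class = "wlc_fit")
  res
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat("Extensible WLC fit (", x$n, " points",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  est <- coef(x)
  lab <- c("contour length (nm/bp)", "persistence (nm)", "stretch modulus (pN)")
  for (i in seq_along(est))
    cat(sprintf("  %-22s %.4g +/- %.2g\n", lab[i], est[i], x$se[i]))
  cat(sprintf("  residual rms: %.3g nm/bp\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.wlc_fit <- function(object, ...) {
  p <- object$params
  c(contour_per_bp = p$contour_per_bp, persistence = p$persistence,
    stretch_modulus = p$stretch_modulus)
}

#' Predict WLC extension from a fitted model
#'
#' @param object a `"wlc_fit"`.
#' @param force forces (pN) at which to evaluate; defaults to the fitted data.
#' @param ... unused.
#' @return extension per base pair, nm/bp.
#' @export
predict.wlc_fit <- function(object, force = NULL, ...) {
  if (is.null(force)) force <- object$fit$m$getEnv()$F
  wlc_extension(object$params, force, kBT = object$kBT)
}

#' @export
summary.wlc_fit <- function(object, ...) {
  est <- coef(object)
  data.frame(parameter = names(est), estimate = unname(est),
             se = unname(object$se), row.names = NULL)
}

#' Fractional ligand occupancy from complex extension
#'
#' Linear interpolation between the bare-DNA and ligand-saturated extensions
#' at the same force:
#' \deqn{\Theta = (x - x_{ds}) / (x_{sat} - x_{ds})}
#' Values are returned raw so that fitting stages see unbiased data; a value
#' outside \[-0.05, 1.05\] triggers a warning, and `clip = TRUE` clamps the
#' result to \[0, 1\] on explicit request only.
#'
#' @param x measured extension per base pair, nm/bp (vectorised).
#' @param x_ds bare-DNA extension at the same force, nm/bp.
#' @param x_sat saturated-complex extension at the same force, nm/bp
#'   (must exceed `x_ds`).
#' @param clip clamp to \[0, 1\]?
#' @return fractional occupancy.
#' @examples
#' occupancy_from_extension(0.385, x_ds = 0.34, x_sat = 0.43)
#' @export
occupancy_from_extension <- function(x, x_ds, x_sat, clip = FALSE) {
  .check_number(x_ds, "x_ds")
  .check_number(x_sat, "x_sat")
  if (x_sat <= x_ds)
    stop("'x_sat' must exceed 'x_ds': saturated complex is longer than bare DNA",
         call. = FALSE)
  theta <- (x - x_ds) / (x_sat - x_ds)
  if (clip) return(pmin(pmax(theta, 0), 1))
  if (any(theta < -0.05 | theta > 1.05, na.rm = TRUE))
    warning("occupancy outside [-0.05, 1.05]: check extension baselines",
            call. = FALSE)
  theta
}

#' Per-moiety elongation from saturated contour lengths
#'
#' Converts the zero-force contour-length difference between the saturated
#' complex and bare DNA into the elongation contributed by each intercalating
#' moiety, given the binding-site size and the number of intercalating
#' moieties per ligand:
#' `(x_sat_max - x_ds_max) * site_size_bp / moieties_per_ligand`.
#'
#' @param x_sat_max saturated-complex contour length, nm/bp.
#' @param x_ds_max bare-DNA contour length, nm/bp.
#' @param site_size_bp binding-site size, base pairs per ligand.
#' @param moieties_per_ligand intercalating moieties per ligand (1 gives the
#'   elongation per whole ligand).
#' @return elongation, nm.
#' @examples
#' saturation_geometry(0.49, 0.34, 4, 2)  # per dppz moiety
#' saturation_geometry(0.49, 0.34, 4, 1)  # per ligand
#' @export
saturation_geometry <- function(x_sat_max, x_ds_max, site_size_bp,
                                moieties_per_ligand) {
  .check_number(x_sat_max, "x_sat_max", positive = TRUE)
  .check_number(x_ds_max, "x_ds_max", positive = TRUE)
  .check_number(site_size_bp, "site_size_bp", positive = TRUE)
  .check_number(moieties_per_ligand, "moieties_per_ligand", positive = TRUE)
  (x_sat_max - x_ds_max) * site_size_bp / moieties_per_ligand
}
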