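# Packaged reference parameter sets for the flex-Ru2 / DNA system: WLC
# polymer rows and the zero-force two-step binding parameters from the
# kinetic and equilibrium analysis routes, shipped as plain CSV under
# inst/extdata and exposed as typed records.

#' Reference parameter sets for flex-Ru2 bis-intercalation of dsDNA
#'
#' Loads the packaged parameter tables for the flexibly linked ruthenium
#' dimer (flex-Ru2) threading into double-stranded DNA: extensible-WLC
#' polymer parameters for bare dsDNA, ssDNA, and DNA saturated with the
#' mono-intercalator Ru1 or with flex-Ru2, and the zero-force kinetic and
#' equilibrium binding parameters of the two-step intercalation scheme with
#' their uncertainties and associated elongations / transition distances.
#'
#' @return a list with elements:
#' \describe{
#'   \item{polymer}{data frame of WLC rows (value and standard error).}
#'   \item{binding}{data frame of zero-force binding parameters, kinetic and
#'     equilibrium columns.}
#'   \item{rates0}{[elementary_rates()] at zero force (kinetic column).}
#'   \item{bells}{named list of four [bell_params()] (k1, k_m1, k2, k_m2)
#'     combining the zero-force rates with their transition distances.}
#'   \item{distances}{named vector of the four signed transition distances,
#'     nm.}
#'   \item{kinetic, equilibrium}{named lists with `Kd`, `Kd1`, `K2` and the
#'     corresponding elongations `x0` from each analysis route.}
#'   \item{dsDNA, flexRu2_sat}{[polymer_params()] for bare DNA and the
#'     flex-Ru2-saturated complex.}
#' }
#' @examples
#' fx <- flex_ru2_parameters()
#' fx$rates0
#' fx$kinetic$Kd
#' @export
flex_ru2_parameters <- function() {
  poly <- utils::read.csv(
    system.file("extdata", "flex_ru2_polymer.csv", package = "threadkin",
                mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE)
  bind <- utils::read.csv(
    system.file("extdata", "flex_ru2_binding.csv", package = "threadkin",
                mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE)
  row <- function(p) bind[bind$parameter == p, , drop = FALSE]
  kin <- function(p) row(p)$kinetic_value
  kx <- function(p) row(p)$kinetic_x0
  eq <- function(p) row(p)$equilibrium_value
  ex <- function(p) row(p)$equilibrium_x0
  prow <- function(nm) {
    r <- poly[poly$polymer == nm, , drop = FALSE]
    polymer_params(r$contour_per_bp, r$persistence, r$stretch_modulus,
                   label = nm)
  }
  rates0 <- elementary_rates(kin("k1"), kin("k_m1"), kin("k2"), kin("k_m2"),
                             force = 0)
  dist <- c(k1 = kx("k1"), k_m1 = kx("k_m1"), k2 = kx("k2"), k_m2 = kx("k_m2"))
  bells <- list(k1 = bell_params(kin("k1"), dist[["k1"]]),
                k_m1 = bell_params(kin("k_m1"), dist[["k_m1"]]),
                k2 = bell_params(kin("k2"), dist[["k2"]]),
                k_m2 = bell_params(kin("k_m2"), dist[["k_m2"]]))
  list(
    polymer = poly,
    binding = bind,
    rates0 = rates0,
    bells = bells,
    distances = dist,
    kinetic = list(Kd = kin("Kd"), Kd1 = kin("Kd1"), K2 = kin("K2"),
                   x0 = c(Kd = kx("Kd"), Kd1 = kx("Kd1"), K2 = kx("K2"))),
    equilibrium = list(Kd = eq("Kd"), Kd1 = eq("Kd1"), K2 = eq("K2"),
                       x0 = c(Kd = ex("Kd"), Kd1 = ex("Kd1"), K2 = ex("K2"))),
    dsDNA = prow("dsDNA"),
    flexRu2_sat = prow("dsDNA_flexRu2"),
    Ru1_sat = prow("dsDNA_Ru1"),
    ssDNA = prow("ssDNA"))
}
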