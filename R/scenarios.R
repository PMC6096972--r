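# Multi-sorbent equilibrium scenarios: dissolved fraction of a compound in
# a water body containing organic carbon and microplastic particles.

#' Scenario specification for a two-sorbent water body
#'
#' Describes a water body with two competing sorbent pools: natural organic
#' carbon at concentration \code{oc_conc} (kg/L) and plastic particles at a
#' liquid-to-solid ratio \code{lsr_plastic} (L water per kg plastic). Two
#' presets bracket the interesting range: \code{scenario_preset("I")}
#' matches batch-experiment plastic loadings (LSR \eqn{10^3} L/kg) and
#' \code{scenario_preset("II")} environmental loadings (LSR \eqn{10^{10}}
#' L/kg, wastewater-effluent particle counts), both with
#' \eqn{10^{-5}} kg/L organic carbon.
#'
#' @param lsr_plastic Liquid-to-solid ratio of the plastic pool, L/kg (> 0).
#' @param oc_conc Organic-carbon concentration, kg/L (>= 0).
#' @param c0 Total (initial) compound concentration, µg/L (> 0); default 5.
#' @return An object of class \code{"scenario_spec"}.
#' @examples
#' scenario_spec(1e3, 1e-5)
#' scenario_preset("II")
#' @export
scenario_spec <- function(lsr_plastic, oc_conc = 1e-5, c0 = 5) {
  if (!is.finite(lsr_plastic) || lsr_plastic <= 0)
    stop("lsr_plastic must be positive", call. = FALSE)
  if (!is.finite(oc_conc) || oc_conc < 0)
    stop("oc_conc must be non-negative", call. = FALSE)
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be positive", call. = FALSE)
  structure(list(lsr_plastic = lsr_plastic, oc_conc = oc_conc, c0 = c0),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param which \code{"I"} (experimental plastic loading, LSR 1e3 L/kg) or
#'   \code{"II"} (environmental loading, LSR 1e10 L/kg).
#' @export
scenario_preset <- function(which = c("I", "II"), c0 = 5) {
  which <- match.arg(which)
  scenario_spec(lsr_plastic = if (which == "I") 1e3 else 1e10,
                oc_conc = 1e-5, c0 = c0)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> plastic LSR %.3g L/kg, OC %.3g kg/L, c0 %.3g ug/L\n",
    x$lsr_plastic, x$oc_conc, x$c0))
  invisible(x)
}

#' Dissolved fraction in a two-sorbent water body
#'
#' Equilibrium fraction of the compound remaining freely dissolved when it
#' partitions to organic carbon (coefficient \eqn{K_{OC}}) and plastic
#' (coefficient \eqn{K_P}):
#' \deqn{f_{diss} = \frac{1}{1 + K_{OC}\, m_{OC}/V_W + K_P\, m_P/V_W},}
#' with \eqn{m_{OC}/V_W} the organic-carbon concentration and
#' \eqn{m_P/V_W = 1/LSR} the plastic loading. Equals 1 when both sorbent
#' terms vanish.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param koc Organic-carbon partition coefficient(s), L/kg (>= 0).
#' @param kp Plastic partition coefficient(s), L/kg (>= 0).
#' @return Dissolved fraction(s) in (0, 1].
#' @examples
#' sc1 <- scenario_preset("I")
#' dissolved_fraction(sc1, koc = 0, kp = 9.9e3)  # ~0.092: mostly sorbed
#' sc2 <- scenario_preset("II")
#' dissolved_fraction(sc2, koc = 0, kp = 9.9e3)  # ~1: plastics negligible
#' @export
dissolved_fraction <- function(spec, koc, kp) {
  stopifnot(inherits(spec, "scenario_spec"))
  koc <- as.numeric(koc); kp <- as.numeric(kp)
  if (any(!is.finite(koc)) || any(koc < 0) ||
      any(!is.finite(kp)) || any(kp < 0))
    stop("koc and kp must be non-negative", call. = FALSE)
  1 / (1 + koc * spec$oc_conc + kp / spec$lsr_plastic)
}

#' Equilibrium distribution map over sorption-coefficient grids
#'
#' Full outer grid of \code{\link{dissolved_fraction}} and the equilibrium
#' aqueous concentration \eqn{c_W = c_0 f_{diss}} over \eqn{K_{OC}} and
#' \eqn{K_P}. Individual compounds can be overlaid by passing their
#' \code{(koc, kp)} pairs in \code{overlay} (organic-carbon coefficients
#' are not derivable from batch data and must be supplied, e.g. from an
#' estimation suite).
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param koc_grid,kp_grid Ascending positive grids, L/kg; defaults span
#'   \eqn{10^0}--\eqn{10^7} with 71 log-spaced points.
#' @param overlay Optional data frame with columns \code{name}, \code{koc},
#'   \code{kp} (and any others, carried through).
#' @return A list of class \code{"scenario_result"}: \code{grid} (data frame
#'   \code{koc}, \code{kp}, \code{f_diss}, \code{cw_eq}), \code{overlay}
#'   (same columns plus the input's, or \code{NULL}), \code{spec}.
#' @examples
#' m <- scenario_map(scenario_preset("I"), koc_grid = 10^(0:3),
#'                   kp_grid = 10^(0:3))
#' head(m$grid)
#' @export
scenario_map <- function(spec, koc_grid = 10^seq(0, 7, length.out = 71),
                         kp_grid = 10^seq(0, 7, length.out = 71),
                         overlay = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(koc_grid) == 0L || length(kp_grid) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  if (is.unsorted(koc_grid, strictly = TRUE) ||
      is.unsorted(kp_grid, strictly = TRUE))
    stop("grids must be strictly ascending", call. = FALSE)
  grid <- expand.grid(koc = koc_grid, kp = kp_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$f_diss <- dissolved_fraction(spec, grid$koc, grid$kp)
  grid$cw_eq <- spec$c0 * grid$f_diss
  if (!is.null(overlay)) {
    stopifnot(all(c("name", "koc", "kp") %in% names(overlay)))
    overlay$f_diss <- dissolved_fraction(spec, overlay$koc, overlay$kp)
    overlay$cw_eq <- spec$c0 * overlay$f_diss
  }
  structure(list(grid = grid, overlay = overlay, spec = spec),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> %d grid points (plastic LSR %.3g L/kg, OC %.3g kg/L)\n",
    nrow(x$grid), x$spec$lsr_plastic, x$spec$oc_conc))
  cat(sprintf("  f_diss range: %.3g - %.3g\n",
              min(x$grid$f_diss), max(x$grid$f_diss)))
  if (!is.null(x$overlay))
    cat(sprintf("  %d overlay compounds\n", nrow(x$overlay)))
  invisible(x)
}

#' Orders of magnitude between two liquid-to-solid ratios
#'
#' \eqn{\log_{10}(LSR_{env}/LSR_{exp})}: how far an environmental plastic
#' loading is from an experimental batch loading. Environmental LSRs
#' (typically \eqn{> 10^9} L/kg) sit 6--7 orders of magnitude above the
#' \eqn{10^3} L/kg of a batch experiment, which is why batch-scale sorption
#' does not translate into relevant mass sequestration in the field.
#'
#' @param lsr_env Environmental liquid-to-solid ratio, L/kg (> 0).
#' @param lsr_exp Experimental liquid-to-solid ratio, L/kg (> 0).
#' @return Orders of magnitude (log10 units).
#' @examples
#' lsr_gap(1e10, 1e3)  # 7
#' @export
lsr_gap <- function(lsr_env, lsr_exp) {
  if (any(!is.finite(c(lsr_env, lsr_exp))) || lsr_env <= 0 || lsr_exp <= 0)
    stop("liquid-to-solid ratios must be positive", call. = FALSE)
  log10(lsr_env / lsr_exp)
}
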