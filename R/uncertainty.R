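# Analytical-uncertainty error model: how measurement error and the
# liquid-to-solid ratio bound the partition coefficients a batch design can
# resolve.

#' Analytical error model for a batch design
#'
#' Couples the relative analytical uncertainty of the concentration
#' measurement, \eqn{\varepsilon}, with the batch geometry (water volume
#' \eqn{V_W}, sorbent mass \eqn{m_P}). The relative deviation between the
#' true ("calculated") and the measured partition coefficient is
#' \deqn{\frac{K_{P,c} - K_{P,m}}{K_{P,c}} =
#'   \frac{\varepsilon}{1+\varepsilon}
#'   \left(1 + \frac{V_W}{m_P K_{P,c}}\right),}
#' so weakly sorbing compounds (small \eqn{K_{P,c}} relative to the
#' liquid-to-solid ratio) are measured with escalating error.
#'
#' @param epsilon Relative analytical uncertainty, dimensionless in (0, 1)
#'   (e.g. 0.05 for 5%).
#' @param vw Water volume, L (> 0).
#' @param mp Sorbent mass, kg (> 0).
#' @return An object of class \code{"error_model"} with fields
#'   \code{epsilon}, \code{vw}, \code{mp}, \code{lsr}.
#' @examples
#' error_model(0.05, vw = 0.1, mp = 1e-4)  # the study design, LSR 1000
#' @export
error_model <- function(epsilon, vw = 0.1, mp = 1e-4) {
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  if (!is.finite(vw) || vw <= 0) stop("vw must be positive", call. = FALSE)
  if (!is.finite(mp) || mp <= 0) stop("mp must be positive", call. = FALSE)
  structure(list(epsilon = epsilon, vw = vw, mp = mp, lsr = vw / mp),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model> epsilon %.3g, LSR %.3g L/kg (error floor %.3g)\n",
    x$epsilon, x$lsr, x$epsilon / (1 + x$epsilon)))
  invisible(x)
}

#' Relative error of a measured partition coefficient
#'
#' Evaluates the error model at a true partition coefficient:
#' \eqn{\varepsilon/(1+\varepsilon) \cdot (1 + LSR/K_{P,c})}. As
#' \eqn{K_{P,c} \to \infty} the error approaches the floor
#' \eqn{\varepsilon/(1+\varepsilon)} set by the analytical uncertainty
#' alone; as \eqn{K_{P,c}} falls below the liquid-to-solid ratio the error
#' grows without bound.
#'
#' @param model An \code{\link{error_model}}.
#' @param kp_c True partition coefficient(s), L/kg (> 0; vectorized).
#' @return Relative error(s), dimensionless (1 = 100%).
#' @examples
#' m <- error_model(0.05, 0.1, 1e-4)
#' relative_error(m, 50)    # 1.0: a 100% error at the reliability limit
#' relative_error(m, 1e6)   # ~ the 0.0476 floor
#' @export
relative_error <- function(model, kp_c) {
  stopifnot(inherits(model, "error_model"))
  kp_c <- as.numeric(kp_c)
  if (any(!is.finite(kp_c)) || any(kp_c <= 0))
    stop("kp_c must be positive", call. = FALSE)
  (model$epsilon / (1 + model$epsilon)) * (1 + model$lsr / kp_c)
}

#' Smallest reliably determinable partition coefficient
#'
#' Inverts the error model: the partition coefficient at which the relative
#' error equals \code{max_error},
#' \deqn{K_P^{min} = \frac{LSR}{max\_error (1+\varepsilon)/\varepsilon - 1}.}
#' With a 5% analytical error and a 100% error bound at a liquid-to-solid
#' ratio of 1000 L/kg this gives 50 L/kg — coefficients below that cannot be
#' distinguished from zero sorption and are censored in reporting.
#'
#' @param model An \code{\link{error_model}}.
#' @param max_error Acceptable relative error (> error floor
#'   \eqn{\varepsilon/(1+\varepsilon)}); default 1 (100%).
#' @return The minimum reliable partition coefficient, L/kg.
#' @examples
#' min_reliable_kp(error_model(0.05, 0.1, 1e-4))        # 50 L/kg
#' min_reliable_kp(error_model(0.10, 0.1, 1e-4))        # 100 L/kg
#' @export
min_reliable_kp <- function(model, max_error = 1) {
  stopifnot(inherits(model, "error_model"))
  floor_err <- model$epsilon / (1 + model$epsilon)
  if (!is.finite(max_error) || max_error <= floor_err)
    stop(sprintf(
      "max_error (%.4g) must exceed the analytical error floor eps/(1+eps) = %.4g; no partition coefficient attains it",
      max_error, floor_err), call. = FALSE)
  model$lsr / (max_error * (1 + model$epsilon) / model$epsilon - 1)
}

#' Relative-error map over partition coefficients and analytical errors
#'
#' Tabulates \code{\link{relative_error}} over a grid of true partition
#' coefficients (rows) and analytical uncertainties (columns) at the batch
#' geometry of \code{model} — the numbers behind the classic
#' uncertainty-vs-\eqn{K_P} curves used to justify batch designs.
#'
#' @param model An \code{\link{error_model}} (supplies \code{vw}, \code{mp};
#'   its own epsilon is not used).
#' @param kp_grid Positive partition coefficients, L/kg.
#' @param epsilons Positive analytical uncertainties in (0, 1); default
#'   \code{c(0.05, 0.10)}.
#' @return A data frame: column \code{kp} then one column
#'   \code{eps_<value>} of relative errors per epsilon.
#' @examples
#' error_map(error_model(0.05, 0.1, 1e-4), kp_grid = 10^(1:4))
#' @export
error_map <- function(model, kp_grid, epsilons = c(0.05, 0.10)) {
  stopifnot(inherits(model, "error_model"))
  if (length(kp_grid) == 0L || length(epsilons) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  out <- data.frame(kp = as.numeric(kp_grid))
  for (eps in epsilons) {
    m <- error_model(eps, model$vw, model$mp)
    out[[sprintf("eps_%.3g", eps)]] <- relative_error(m, kp_grid)
  }
  out
}
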