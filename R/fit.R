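# Species-specific partition coefficients by non-negative linear least
# squares, plus the censoring/QC reporting rules.

# Exact 2-parameter NNLS via candidate enumeration. The two-species model
# D_P = kp_n * f_n + kp_i * f_i is linear in (kp_n, kp_i), so the
# non-negative optimum is either the interior normal-equation solution or
# lies on one of the three boundary faces {kp_i = 0}, {kp_n = 0},
# {kp_n = kp_i = 0}; all four candidates are evaluated and the feasible one
# with smallest RSS returned. Exact up to floating arithmetic — no
# iteration, no starting values.
nnls2 <- function(f_n, f_i, y) {
  rss_of <- function(b) sum((y - b[1] * f_n - b[2] * f_i)^2)
  cand <- list()

  a11 <- sum(f_n * f_n); a12 <- sum(f_n * f_i); a22 <- sum(f_i * f_i)
  b1 <- sum(f_n * y); b2 <- sum(f_i * y)
  det <- a11 * a22 - a12 * a12
  # interior (unconstrained) solution, when the design is identifiable
  if (det > 1e-12 * a11 * max(a22, .Machine$double.eps)) {
    sol <- c((a22 * b1 - a12 * b2) / det, (a11 * b2 - a12 * b1) / det)
    if (all(sol >= 0)) cand <- c(cand, list(sol))
  }
  if (a11 > 0) cand <- c(cand, list(c(max(0, b1 / a11), 0)))
  if (a22 > 0) cand <- c(cand, list(c(0, max(0, b2 / a22))))
  cand <- c(cand, list(c(0, 0)))

  rss <- vapply(cand, rss_of, numeric(1))
  best <- cand[[which.min(rss)]]
  list(coef = best, rss = min(rss))
}

#' Fit species-specific partition coefficients across pH
#'
#' Estimates the neutral- and ionized-species partition coefficients
#' \eqn{K_{P,n}} and \eqn{K_{P,i}} by least squares of the two-species model
#' \eqn{D_P = K_{P,n} f_n + K_{P,i} f_i} against measured distribution
#' coefficients, under the physical constraint that both coefficients are
#' non-negative. Because the model is linear in the coefficients, the
#' non-negative optimum is computed exactly (closed-form active set), with
#' no initialization or iteration.
#'
#' All individual per-measurement \eqn{D_P} values are used unweighted
#' (pooled across replicates and sampling times); pass per-pH means instead
#' if a mean-based fit is wanted.
#'
#' When the ionized species is essentially absent over the whole design
#' (max \eqn{f_i} < \code{indeterminate_tol}), \eqn{K_{P,i}} is not
#' identifiable from the data and the fit is flagged
#' \code{kp_i_indeterminate} (reported as "n.a." downstream).
#'
#' @param ph Numeric vector of pH values, one per observation.
#' @param dp Numeric vector of measured distribution coefficients (L/kg);
#'   negative values (noise on weak sorbers) are legal and retained.
#' @param pka Acid dissociation constant of the compound.
#' @param ion_class \code{"acid"} or \code{"base"} (a neutral compound has
#'   constant \eqn{f_n = 1}, leaving the two coefficients unidentifiable —
#'   use the mean \eqn{D_P} instead, as \code{\link{run_pipeline}} does).
#' @param censor_threshold Coefficients strictly below this value (L/kg)
#'   are flagged censored (default 50, the reliability limit at a
#'   liquid-to-solid ratio of 1000 L/kg; see \code{\link{min_reliable_kp}}).
#' @param indeterminate_tol Maximum-\eqn{f_i} threshold below which
#'   \eqn{K_{P,i}} is flagged indeterminate (default 0.01).
#'
#' @return An object of class \code{"species_fit"}: a list with
#'   \code{kp_n}, \code{kp_i} (L/kg), \code{rss}, \code{n_points},
#'   \code{kp_n_censored}, \code{kp_i_censored}, \code{kp_i_indeterminate},
#'   plus the inputs' \code{pka} and \code{ion_class}.
#' @examples
#' sp <- neutral_fraction(c(4, 7, 10), pka = 5, ion_class = "acid")
#' dp <- model_dp(1000, 100, sp)
#' fit_species_k(c(4, 7, 10), dp, pka = 5, ion_class = "acid")
#' @export
fit_species_k <- function(ph, dp, pka, ion_class = c("acid", "base"),
                          censor_threshold = 50, indeterminate_tol = 0.01) {
  ion_class <- match.arg(ion_class)
  ph <- as.numeric(ph); dp <- as.numeric(dp)
  if (length(ph) != length(dp))
    stop("ph and dp must have equal length", call. = FALSE)
  if (length(ph) < 2L || length(unique(ph)) < 2L)
    stop("invalid design: need observations at >= 2 distinct pH values",
         call. = FALSE)
  spec <- neutral_fraction(ph, pka = pka, ion_class = ion_class)
  if (diff(range(spec$f_n)) < 1e-12)
    stop("unidentifiable design: neutral fraction identical at all pH ",
         "(only the mixture kp_n*f_n + kp_i*f_i is resolvable)",
         call. = FALSE)
  sol <- nnls2(spec$f_n, spec$f_i, dp)
  kp_n <- sol$coef[1]; kp_i <- sol$coef[2]
  structure(
    list(
      kp_n = kp_n, kp_i = kp_i, rss = sol$rss, n_points = length(dp),
      kp_n_censored = kp_n < censor_threshold,
      kp_i_censored = kp_i < censor_threshold,
      kp_i_indeterminate = max(spec$f_i) < indeterminate_tol,
      pka = pka, ion_class = ion_class,
      censor_threshold = censor_threshold
    ),
    class = "species_fit"
  )
}

#' @export
print.species_fit <- function(x, ...) {
  cat(sprintf("<species_fit> %s, pKa %.3g (n = %d, RSS = %.4g)\n",
              x$ion_class, x$pka, x$n_points, x$rss))
  cat(sprintf("  K_P,n = %s\n", format_kp(x$kp_n, x$kp_n_censored, FALSE,
                                          x$censor_threshold)))
  cat(sprintf("  K_P,i = %s\n", format_kp(x$kp_i, x$kp_i_censored,
                                          x$kp_i_indeterminate,
                                          x$censor_threshold)))
  invisible(x)
}

# Render a fitted coefficient as the report token: numeric (6 significant
# digits, scientific), the censored token "<5e+01", or "n.a." when the
# ionized species never occurs in the design.
format_kp <- function(value, censored, indeterminate, threshold = 50) {
  if (indeterminate) return("n.a.")
  if (censored) return(sprintf("<%.0e", threshold))
  sprintf("%.5e", value)
}

#' Censored report row for a fitted compound
#'
#' Applies the two reporting rules to a \code{\link{fit_species_k}} result:
#' fitted coefficients strictly below the censoring threshold (default
#' 50 L/kg) are rendered as the token \code{"<5e+01"} — at the study's
#' liquid-to-solid ratio smaller coefficients cannot be reliably determined
#' — and any per-pH coefficient of variation above the CV threshold
#' (default 100%) raises a warning flag on that pH. The numeric coefficient
#' values are retained in shadow columns for diagnostics; censoring only
#' affects the rendered token.
#'
#' @param fit A \code{species_fit}.
#' @param dp_estimates List of \code{\link{aggregate_dp}} results, one per
#'   pH level of the design.
#' @param cv_threshold CV warning threshold in percent (default 100).
#' @return A one-row data frame: \code{kp_n_label}, \code{kp_i_label}
#'   (report tokens), \code{kp_n}, \code{kp_i} (numeric shadows),
#'   censoring/indeterminacy flags, \code{n_points}, \code{rss}, and per-pH
#'   columns \code{cv_ph<ph>} / \code{cv_flag_ph<ph>}.
#' @examples
#' sp <- neutral_fraction(c(4, 7, 10), pka = 5, ion_class = "acid")
#' fit <- fit_species_k(c(4, 7, 10), model_dp(1000, 12, sp), 5, "acid")
#' ests <- list(aggregate_dp(c(900, 1000, 1100), 4),
#'              aggregate_dp(c(80, 100, 120), 7),
#'              aggregate_dp(c(8, 10, 12), 10))
#' censor_fit(fit, ests)
#' @export
censor_fit <- function(fit, dp_estimates, cv_threshold = 100) {
  stopifnot(inherits(fit, "species_fit"))
  if (inherits(dp_estimates, "dp_estimate")) dp_estimates <- list(dp_estimates)
  stopifnot(all(vapply(dp_estimates, inherits, TRUE, "dp_estimate")))
  row <- data.frame(
    kp_n_label = format_kp(fit$kp_n, fit$kp_n_censored, FALSE,
                           fit$censor_threshold),
    kp_i_label = format_kp(fit$kp_i, fit$kp_i_censored,
                           fit$kp_i_indeterminate, fit$censor_threshold),
    kp_n = fit$kp_n, kp_i = fit$kp_i,
    kp_n_censored = fit$kp_n_censored,
    kp_i_censored = fit$kp_i_censored,
    kp_i_indeterminate = fit$kp_i_indeterminate,
    n_points = fit$n_points, rss = fit$rss,
    stringsAsFactors = FALSE
  )
  for (est in dp_estimates) {
    tag <- gsub("[^0-9a-zA-Z]+", "_", format(est$ph))
    row[[paste0("cv_ph", tag)]] <- est$cv_percent
    row[[paste0("cv_flag_ph", tag)]] <-
      !is.na(est$cv_percent) && est$cv_percent > cv_threshold
  }
  row
}
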