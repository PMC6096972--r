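# Batch mass balance: per-measurement distribution coefficients, replicate
# aggregation, the two-species mixing model, and sorbed-fraction reporting.

#' Batch experimental condition
#'
#' Water volume, plastic mass, initial aqueous concentration and pH of one
#' equilibrium batch. The liquid-to-solid ratio \code{lsr = vw/mp} (L/kg) is
#' derived and carried along; sampling-induced volume changes are neglected
#' (they stay below the analytical error for the designs considered here).
#'
#' @param vw Water volume in L (> 0).
#' @param mp Plastic mass in kg (> 0).
#' @param c0 Initial aqueous concentration in µg/L (> 0).
#' @param ph Batch pH.
#' @return An object of class \code{"batch_condition"}.
#' @examples
#' batch_condition(vw = 0.1, mp = 1e-4, c0 = 5, ph = 7)  # LSR 1000 L/kg
#' @export
batch_condition <- function(vw, mp, c0, ph) {
  if (!is.finite(vw) || vw <= 0) stop("vw must be positive", call. = FALSE)
  if (!is.finite(mp) || mp <= 0) stop("mp must be positive", call. = FALSE)
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be positive", call. = FALSE)
  structure(
    list(vw = vw, mp = mp, c0 = c0, ph = ph, lsr = vw / mp),
    class = "batch_condition"
  )
}

#' @export
print.batch_condition <- function(x, ...) {
  cat(sprintf(
    "<batch_condition> pH %.4g | %.3g L water, %.3g kg plastic (LSR %.3g L/kg), c0 %.3g ug/L\n",
    x$ph, x$vw, x$mp, x$lsr, x$c0))
  invisible(x)
}

#' Distribution coefficient from one aqueous measurement
#'
#' Mass balance of a closed batch: the sorbed concentration is
#' \eqn{c_P = (c_0 - c_W) V_W / m_P} and the overall distribution
#' coefficient \eqn{D_P = c_P / c_W}, i.e.
#' \eqn{D_P = (c_0 - c_W)/c_W \cdot V_W/m_P} in L/kg. Measurement noise can
#' push \eqn{c_W} above \eqn{c_0}; the resulting negative \eqn{D_P} is
#' returned unclamped so that aggregation and fitting remain unbiased
#' (only \code{\link{sorbed_fraction}} clamps for reporting).
#'
#' @param cond A \code{\link{batch_condition}}.
#' @param cw Measured aqueous concentration(s) in µg/L (> 0; vectorized).
#' @return Distribution coefficient(s) in L/kg.
#' @examples
#' cond <- batch_condition(0.1, 1e-4, c0 = 5, ph = 7)
#' dp_from_measurement(cond, cw = 2.5)  # 1000 L/kg
#' dp_from_measurement(cond, cw = 4)    # 250 L/kg
#' @export
dp_from_measurement <- function(cond, cw) {
  stopifnot(inherits(cond, "batch_condition"))
  cw <- as.numeric(cw)
  if (any(!is.finite(cw)) || any(cw < 0))
    stop("cw must be non-negative", call. = FALSE)
  if (any(cw == 0))
    stop("cw = 0: aqueous concentration below the model's domain ",
         "(division by zero in the mass balance)", call. = FALSE)
  ((cond$c0 - cw) / cw) * (cond$vw / cond$mp)
}

#' Aggregate replicate distribution coefficients at one pH
#'
#' Arithmetic mean of per-measurement \eqn{D_P} values together with their
#' coefficient of variation, CV = 100 * sample standard deviation / |mean|
#' (in percent). The CV is undefined — reported \code{NA} — for fewer than
#' two values or a zero mean. CVs above 100% conventionally mark the
#' estimate as unreliable (see \code{\link{censor_fit}}).
#'
#' @param values Numeric vector of per-measurement \eqn{D_P} values (L/kg);
#'   negative values are legal and retained.
#' @param ph The pH the values were measured at.
#' @return An object of class \code{"dp_estimate"}: a list with
#'   \code{ph}, \code{dp_mean}, \code{cv_percent}, \code{n_obs}.
#' @examples
#' aggregate_dp(c(1, 2, 3), ph = 7)  # mean 2, CV 50%
#' @export
aggregate_dp <- function(values, ph) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("values must be a non-empty numeric vector", call. = FALSE)
  m <- mean(values)
  cv <- if (length(values) < 2L || m == 0) NA_real_
        else 100 * stats::sd(values) / abs(m)
  structure(
    list(ph = ph, dp_mean = m, cv_percent = cv, n_obs = length(values)),
    class = "dp_estimate"
  )
}

#' @export
print.dp_estimate <- function(x, ...) {
  cv <- if (is.na(x$cv_percent)) "CV n/a" else sprintf("CV %.1f%%", x$cv_percent)
  cat(sprintf("<dp_estimate> pH %.4g: D_P = %.4g L/kg (%s, n = %d)\n",
              x$ph, x$dp_mean, cv, x$n_obs))
  invisible(x)
}

#' Two-species distribution coefficient model
#'
#' Speciation-weighted mixture of the species-specific partition
#' coefficients: \eqn{D_P = K_{P,n} f_n + K_{P,i} f_i}. This is the sorption
#' analogue of a pharmaceutical logD curve. For a neutral compound
#' (\eqn{f_n = 1}) it reduces to \eqn{K_{P,n}} at every pH.
#'
#' @param kp_n Partition coefficient of the neutral species, L/kg (>= 0).
#' @param kp_i Partition coefficient of the ionized species, L/kg (>= 0).
#' @param spec A \code{speciation} data frame from
#'   \code{\link{neutral_fraction}} (or anything with \code{f_n}, \code{f_i}).
#' @return \eqn{D_P} in L/kg, one value per row of \code{spec}.
#' @examples
#' sp <- neutral_fraction(10, pka = 10.7, ion_class = "acid")
#' model_dp(6.0e3, 7.2e2, sp)  # ~5.1e3 L/kg
#' @export
model_dp <- function(kp_n, kp_i, spec) {
  if (!is.finite(kp_n) || kp_n < 0 || !is.finite(kp_i) || kp_i < 0)
    stop("partition coefficients must be non-negative", call. = FALSE)
  stopifnot(all(c("f_n", "f_i") %in% names(spec)))
  kp_n * spec$f_n + kp_i * spec$f_i
}

#' Sorbed fraction at a given liquid-to-solid ratio
#'
#' Fraction of total compound mass on the sorbent at equilibrium,
#' \eqn{D_P / (D_P + LSR)}. Negative \eqn{D_P} values (noise artefacts of
#' weak sorbers) are clamped to a sorbed fraction of zero for reporting.
#'
#' @param dp Distribution coefficient(s), L/kg; may be negative.
#' @param lsr Liquid-to-solid ratio, L/kg (> 0).
#' @return Sorbed fraction(s) in \[0, 1\].
#' @examples
#' sorbed_fraction(1000, 1000)  # 0.5
#' sorbed_fraction(-50, 1000)   # 0
#' @export
sorbed_fraction <- function(dp, lsr) {
  if (!is.finite(lsr) || lsr <= 0) stop("lsr must be positive", call. = FALSE)
  pmax(0, dp / (dp + lsr))
}

#' Read a batch measurement table
#'
#' CSV dialect \code{compound,polymer,ph,replicate,time_days,c0_ug_per_L,}
#' \code{cw_ug_per_L}: one row per measurement, free-text polymer labels
#' (e.g. PE, PS). Day-0 rows record the actual initial concentration and are
#' excluded from distribution-coefficient estimation by the pipeline.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the columns above, types coerced and validated.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  wanted <- c("compound", "polymer", "ph", "replicate", "time_days",
              "c0_ug_per_L", "cw_ug_per_L")
  d <- utils::read.csv(path, strip.white = TRUE, check.names = FALSE)
  if (!identical(names(d), wanted))
    stop("malformed measurement header; expected: ",
         paste(wanted, collapse = ","), call. = FALSE)
  num_cols <- c("ph", "time_days", "c0_ug_per_L", "cw_ug_per_L")
  for (col in num_cols)
    if (!is.numeric(d[[col]]))
      stop("non-numeric values in column '", col, "'", call. = FALSE)
  if (any(d$cw_ug_per_L < 0)) stop("negative cw in measurements", call. = FALSE)
  if (any(d$time_days < 0)) stop("negative time_days", call. = FALSE)
  d
}

#' Write a batch measurement table
#'
#' @param measurements Data frame in the \code{\link{read_measurements}}
#'   dialect.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
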