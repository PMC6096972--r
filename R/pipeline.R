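# End-to-end analysis pipeline: measurements -> per-pH distribution
# coefficients -> species fits -> censored report -> scenario maps.

#' Build a validated pipeline configuration
#'
#' @param compounds Path to the compound property CSV
#'   (\code{\link{read_compound_table}} dialect).
#' @param measurements Path to the measurement CSV
#'   (\code{\link{read_measurements}} dialect).
#' @param out_dir Output directory (created if missing).
#' @param vw,mp Batch geometry in L and kg (defaults 0.1, 1e-4: the
#'   1000 L/kg design).
#' @param epsilon Analytical relative uncertainty used for the reliability
#'   threshold (default 0.05).
#' @param error_bound Relative-error bound defining "reliably determinable"
#'   (default 1, i.e. 100%).
#' @param censor_threshold Censoring threshold in L/kg; by default derived
#'   from \code{epsilon}, \code{error_bound} and the batch geometry via
#'   \code{\link{min_reliable_kp}} (50 L/kg for the defaults).
#' @param cv_threshold Per-pH CV warning threshold in percent (default 100).
#' @param scenarios Character vector of scenario presets to map
#'   (subset of \code{c("I", "II")}).
#' @param overlay Optional data frame \code{name}, \code{koc}, \code{kp}
#'   overlaid on the scenario maps (organic-carbon coefficients must be
#'   user-supplied).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(compounds, measurements, out_dir,
                       vw = 0.1, mp = 1e-4,
                       epsilon = 0.05, error_bound = 1,
                       censor_threshold = NULL, cv_threshold = 100,
                       scenarios = c("I", "II"), overlay = NULL) {
  if (!file.exists(compounds))
    stop("compound table not found: ", compounds, call. = FALSE)
  if (!file.exists(measurements))
    stop("measurement table not found: ", measurements, call. = FALSE)
  if (is.null(censor_threshold))
    censor_threshold <- min_reliable_kp(error_model(epsilon, vw, mp),
                                        max_error = error_bound)
  if (censor_threshold <= 0 || cv_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  scenarios <- match.arg(scenarios, c("I", "II"), several.ok = TRUE)
  structure(
    list(compounds = compounds, measurements = measurements,
         out_dir = out_dir, vw = vw, mp = mp, epsilon = epsilon,
         error_bound = error_bound, censor_threshold = censor_threshold,
         cv_threshold = cv_threshold, scenarios = scenarios,
         overlay = overlay),
    class = "run_config"
  )
}

#' Read a pipeline configuration file
#'
#' JSON (always available) or YAML (if the \pkg{yaml} package is installed)
#' with fields matching the arguments of \code{\link{run_config}}.
#'
#' @param path Path to a \code{.json}, \code{.yml} or \code{.yaml} file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(fields$overlay)) fields$overlay <- as.data.frame(fields$overlay)
  do.call(run_config, fields)
}

# Per-measurement D_P values for post-day-0 rows of one compound x polymer
# x pH cell; c0 is taken from the measurement rows themselves.
cell_dp_values <- function(rows, vw, mp) {
  post <- rows[rows$time_days > 0, ]
  vapply(seq_len(nrow(post)), function(i) {
    cond <- batch_condition(vw, mp, c0 = post$c0_ug_per_L[i],
                            ph = post$ph[i])
    dp_from_measurement(cond, post$cw_ug_per_L[i])
  }, numeric(1))
}

# Least-squares "fit" for a neutral compound: D_P is pH-independent, so
# K_P,n is the (non-negative) mean of the pooled values and the ionic
# coefficient is structurally absent.
fit_neutral_k <- function(dp, censor_threshold = 50) {
  kp_n <- max(0, mean(dp))
  structure(
    list(kp_n = kp_n, kp_i = NA_real_, rss = sum((dp - kp_n)^2),
         n_points = length(dp), kp_n_censored = kp_n < censor_threshold,
         kp_i_censored = FALSE, kp_i_indeterminate = TRUE,
         pka = NA_real_, ion_class = "neutral",
         censor_threshold = censor_threshold),
    class = "species_fit"
  )
}

#' Run the full analysis pipeline
#'
#' Sequences the complete analysis from CSV inputs to report files:
#' \enumerate{
#'   \item read and validate the compound and measurement tables (a
#'     measurement of a compound absent from the property table is an
#'     error naming the compound);
#'   \item compute per-measurement distribution coefficients from the
#'     batch mass balance (post-day-0 samples only) and aggregate them per
#'     compound x polymer x pH with replicate CVs;
#'   \item fit species-specific partition coefficients per compound x
#'     polymer (non-negative least squares; neutral compounds use the
#'     pooled mean);
#'   \item apply the censoring and CV-warning rules and write the fit
#'     report;
#'   \item map the equilibrium dissolved fraction for the requested
#'     scenario presets.
#' }
#'
#' Outputs written to \code{config$out_dir}: \code{dp_table.csv},
#' \code{fit_report.csv}, \code{fit_report.json},
#' \code{scenario_I.csv} / \code{scenario_II.csv} (grids), plus
#' \code{scenario_*_overlay.csv} when an overlay is configured. The run is
#' deterministic: identical inputs give byte-identical reports. Progress is
#' logged via \code{message()} (standard error), results go to files only.
#'
#' @param config A \code{\link{run_config}} (or a path to a config file,
#'   which is passed through \code{\link{read_run_config}}).
#' @return Invisibly, a list with \code{dp_table}, \code{fit_report}
#'   (data frames) and \code{files} (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  compounds <- read_compound_table(config$compounds)
  meas <- read_measurements(config$measurements)
  message(sprintf("read %d compounds, %d measurement rows",
                  length(compounds), nrow(meas)))

  unknown <- setdiff(unique(meas$compound), names(compounds))
  if (length(unknown) > 0L)
    stop("measurements reference compounds missing from the compound ",
         "table: ", paste(unknown, collapse = ", "), call. = FALSE)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: per-pH distribution coefficients
  cells <- unique(meas[, c("compound", "polymer", "ph")])
  cells <- cells[order(cells$compound, cells$polymer, cells$ph), ]
  dp_rows <- vector("list", nrow(cells))
  dp_values <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- meas$compound == cells$compound[i] &
      meas$polymer == cells$polymer[i] & meas$ph == cells$ph[i]
    vals <- cell_dp_values(meas[sel, ], config$vw, config$mp)
    est <- aggregate_dp(vals, ph = cells$ph[i])
    dp_values[[i]] <- vals
    dp_rows[[i]] <- data.frame(
      compound = cells$compound[i], polymer = cells$polymer[i],
      ph = cells$ph[i], dp_mean = est$dp_mean,
      cv_percent = est$cv_percent, n_obs = est$n_obs,
      stringsAsFactors = FALSE
    )
  }
  dp_table <- do.call(rbind, dp_rows)
  message(sprintf("aggregated D_P for %d compound x polymer x pH cells",
                  nrow(dp_table)))

  # stage 2: species fits + censored report
  groups <- unique(cells[, c("compound", "polymer")])
  report_rows <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    idx <- which(cells$compound == groups$compound[g] &
                   cells$polymer == groups$polymer[g])
    ph_all <- rep(cells$ph[idx], lengths(dp_values[idx]))
    dp_all <- unlist(dp_values[idx], use.names = FALSE)
    cmp <- compounds[[groups$compound[g]]]
    fit <- if (cmp$ion_class == "neutral")
      fit_neutral_k(dp_all, config$censor_threshold)
    else
      fit_species_k(ph_all, dp_all, pka = cmp$pka,
                    ion_class = cmp$ion_class,
                    censor_threshold = config$censor_threshold)
    ests <- lapply(idx, function(i)
      aggregate_dp(dp_values[[i]], ph = cells$ph[i]))
    row <- censor_fit(fit, ests, cv_threshold = config$cv_threshold)
    report_rows[[g]] <- cbind(
      data.frame(compound = groups$compound[g],
                 polymer = groups$polymer[g],
                 log_kow = cmp$log_kow, stringsAsFactors = FALSE),
      row)
  }
  fit_report <- do.call(rbind, report_rows)
  n_cens <- sum(fit_report$kp_n_censored | fit_report$kp_i_censored)
  message(sprintf("fitted %d compound x polymer groups (%d with censored coefficients; censor threshold %.4g L/kg)",
                  nrow(fit_report), n_cens, config$censor_threshold))

  files <- character(0)
  f <- file.path(config$out_dir, "dp_table.csv")
  utils::write.csv(dp_table, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(config$out_dir, "fit_report.csv")
  utils::write.csv(fit_report, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(config$out_dir, "fit_report.json")
  jsonlite::write_json(fit_report, f, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  files <- c(files, f)

  # stage 3: scenario maps
  for (which in config$scenarios) {
    sc <- scenario_preset(which)
    m <- scenario_map(sc, overlay = config$overlay)
    f <- file.path(config$out_dir, sprintf("scenario_%s.csv", which))
    utils::write.csv(m$grid, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    if (!is.null(m$overlay)) {
      f <- file.path(config$out_dir,
                     sprintf("scenario_%s_overlay.csv", which))
      utils::write.csv(m$overlay, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    message(sprintf("scenario %s mapped (%d grid points)", which,
                    nrow(m$grid)))
  }

  invisible(list(dp_table = dp_table, fit_report = fit_report,
                 files = files))
}
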