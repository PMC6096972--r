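# Seeded synthetic batch experiments: noise-free equilibrium concentrations
# from the two-species model, multiplicative analytical noise, and a full
# study-design fixture generator.

#' Ground truth for a synthetic compound
#'
#' The quantities the generator treats as known: species-specific partition
#' coefficients, speciation parameters, the relative analytical noise on
#' concentration measurements, and the seed of the random stream. Identical
#' truth + design gives bit-identical simulated data.
#'
#' @param kp_n,kp_i Species-specific partition coefficients, L/kg (>= 0).
#' @param pka Acid dissociation constant, or \code{NA} for neutral.
#' @param ion_class \code{"acid"}, \code{"base"} or \code{"neutral"}.
#' @param epsilon Relative noise standard deviation on measured
#'   concentrations (>= 0, < 1; the multiplicative noise model breaks down
#'   at epsilon >= 1).
#' @param seed Integer seed of the generator's random stream.
#' @return An object of class \code{"synthetic_truth"}.
#' @examples
#' synthetic_truth(1000, 100, pka = 5, ion_class = "acid",
#'                 epsilon = 0.05, seed = 1)
#' @export
synthetic_truth <- function(kp_n, kp_i, pka = NA_real_,
                            ion_class = c("acid", "base", "neutral"),
                            epsilon = 0.05, seed = 1L) {
  ion_class <- match.arg(ion_class)
  if (!is.finite(kp_n) || kp_n < 0 || !is.finite(kp_i) || kp_i < 0)
    stop("kp_n and kp_i must be non-negative", call. = FALSE)
  if (!is.finite(epsilon) || epsilon < 0)
    stop("epsilon must be non-negative", call. = FALSE)
  if (epsilon >= 1)
    stop("epsilon >= 1: multiplicative noise model breaks down",
         call. = FALSE)
  if (ion_class != "neutral" && is.na(pka))
    stop("pKa required for ion_class '", ion_class, "'", call. = FALSE)
  structure(
    list(kp_n = kp_n, kp_i = kp_i, pka = as.numeric(pka),
         ion_class = ion_class, epsilon = epsilon,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

# Deterministic 31-bit hash of a key string, folded with the global seed.
# Each (compound, polymer, pH, replicate) batch draws from its own
# substream, so adding a compound to a fixture never perturbs the draws of
# any other compound.
substream_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Noise-free equilibrium aqueous concentration
#'
#' Combines the batch mass balance with the two-species model: at
#' equilibrium \eqn{c_W = c_0 / (1 + D_P(pH)\, m_P/V_W)}, where
#' \eqn{D_P(pH)} is the truth's \code{\link{model_dp}} value at the batch
#' pH. Mass is conserved exactly: \eqn{c_W V_W + (D_P c_W) m_P = c_0 V_W}.
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @param cond A \code{\link{batch_condition}}.
#' @return The equilibrium aqueous concentration, µg/L.
#' @examples
#' tr <- synthetic_truth(1000, 100, 5, "acid", epsilon = 0)
#' equilibrium_cw(tr, batch_condition(0.1, 1e-4, 5, ph = 4))
#' @export
equilibrium_cw <- function(truth, cond) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(cond, "batch_condition"))
  spec <- neutral_fraction(cond$ph, pka = truth$pka,
                           ion_class = truth$ion_class)
  dp <- model_dp(truth$kp_n, truth$kp_i, spec)
  cond$c0 / (1 + dp * cond$mp / cond$vw)
}

#' Simulate one batch experiment
#'
#' Draws replicate aqueous-concentration measurements around the noise-free
#' equilibrium value with multiplicative Gaussian noise,
#' \eqn{c_{W,obs} = c_W (1 + \varepsilon z)}, truncated below at
#' \eqn{10^{-6} c_0} to keep concentrations positive. Day-0 samples (one
#' per replicate) are drawn around \eqn{c_0} with the same noise. Each
#' replicate has its own seeded substream keyed by
#' (compound, polymer, pH, replicate), so datasets are reproducible and
#' composable.
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @param cond A \code{\link{batch_condition}}.
#' @param n_replicates Number of independent batches (default 3,
#'   triplicate design).
#' @param sample_times Post-spike sampling times in days (default
#'   \code{c(2, 4, 7)}, the polyethylene design; use
#'   \code{c(2, 4, 7, 11)} for the polystyrene design).
#' @param compound,polymer Labels written into the output (also key the
#'   noise substreams).
#' @return A data frame in the measurement-CSV dialect
#'   (\code{\link{read_measurements}}), including the day-0 rows.
#' @examples
#' tr <- synthetic_truth(1000, 100, 5, "acid", epsilon = 0.05, seed = 1)
#' simulate_batch(tr, batch_condition(0.1, 1e-4, 5, ph = 7))
#' @export
simulate_batch <- function(truth, cond, n_replicates = 3L,
                           sample_times = c(2, 4, 7),
                           compound = "compound", polymer = "PE") {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(cond, "batch_condition"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(sample_times) == 0L || any(sample_times <= 0))
    stop("sample_times must be positive (day 0 is added automatically)",
         call. = FALSE)
  cw_eq <- equilibrium_cw(truth, cond)
  times <- c(0, sort(sample_times))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    key <- paste(compound, polymer, format(cond$ph), r, sep = "|")
    rng <- substream_seed(truth$seed, key)
    z <- withr_seed_rnorm(rng, length(times))
    target <- ifelse(times == 0, cond$c0, cw_eq)
    cw_obs <- pmax(target * (1 + truth$epsilon * z), 1e-6 * cond$c0)
    rows[[r]] <- data.frame(
      compound = compound, polymer = polymer, ph = cond$ph,
      replicate = r, time_days = times,
      c0_ug_per_L = cond$c0, cw_ug_per_L = cw_obs,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Draw n standard normals from a private, seeded stream without disturbing
# the caller's RNG state.
withr_seed_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Parse a censored species-coefficient table
#'
#' Reads the report CSV dialect used for fitted-coefficient tables:
#' columns \code{compound,log_kow,kp_n,kp_i,cv_ph4,cv_ph7,cv_ph10}, where
#' the coefficient cells hold either a number, the censored token
#' \code{"<5e+01"}, or \code{"n.a."} (no ionic species). Tokens are parsed
#' into numeric columns (\code{NA} where censored/absent) plus flag columns.
#' The two bundled study tables are
#' \code{mpsorb_example("fits_table2_pe.csv")} (polyethylene) and
#' \code{mpsorb_example("fits_table3_ps.csv")} (polystyrene).
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns \code{compound}, \code{log_kow},
#'   \code{kp_n}, \code{kp_i}, \code{kp_n_censored}, \code{kp_i_censored},
#'   \code{kp_i_na}, \code{cv_ph4}, \code{cv_ph7}, \code{cv_ph10}.
#' @export
read_fits_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  parse_tok <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    list(value = v, censored = grepl("^<", x), na = x == "n.a.")
  }
  kn <- parse_tok(d$kp_n); ki <- parse_tok(d$kp_i)
  data.frame(
    compound = d$compound, log_kow = as.numeric(d$log_kow),
    kp_n = kn$value, kp_i = ki$value,
    kp_n_censored = kn$censored, kp_i_censored = ki$censored,
    kp_i_na = ki$na,
    cv_ph4 = as.numeric(d$cv_ph4), cv_ph7 = as.numeric(d$cv_ph7),
    cv_ph10 = as.numeric(d$cv_ph10),
    stringsAsFactors = FALSE
  )
}

#' Synthetic ground-truth table for the bundled study design
#'
#' Builds a per-compound truth table for \code{\link{generate_study_fixture}}
#' from the bundled fitted-coefficient tables. Raw concentrations were never
#' published for the study the fixtures mirror, so this table is synthetic
#' by construction: censored coefficients (reported only as below the
#' 50 L/kg reliability limit) are assigned a nominal true value of
#' \code{censored_value} (default 10 L/kg, comfortably below the limit),
#' and "n.a." ionic coefficients become 0.
#'
#' @param polymer \code{"PE"} or \code{"PS"}.
#' @param censored_value Stand-in true value for censored coefficients,
#'   L/kg.
#' @return A data frame: \code{compound}, \code{polymer}, \code{kp_n},
#'   \code{kp_i}.
#' @examples
#' head(study_truths("PE"))
#' @export
study_truths <- function(polymer = c("PE", "PS"), censored_value = 10) {
  polymer <- match.arg(polymer)
  file <- if (polymer == "PE") "fits_table2_pe.csv" else "fits_table3_ps.csv"
  tab <- read_fits_table(mpsorb_example(file))
  kp_n <- ifelse(tab$kp_n_censored, censored_value, tab$kp_n)
  kp_i <- ifelse(tab$kp_i_na, 0,
                 ifelse(tab$kp_i_censored, censored_value, tab$kp_i))
  data.frame(compound = tab$compound, polymer = polymer,
             kp_n = kp_n, kp_i = kp_i, stringsAsFactors = FALSE)
}

# Study-design initial concentrations: 5 ug/L, except the two strong
# sorbers spiked higher to keep equilibrium concentrations measurable.
study_c0 <- function(compound) {
  ifelse(compound == "Phenanthrene", 50,
         ifelse(compound == "4-Nonylphenol", 30, 5))
}

#' Generate a complete synthetic study dataset
#'
#' Simulates the full batch study design for a set of compounds: triplicate
#' batches at pH 4, 7 and 10, liquid-to-solid ratio 1000 L/kg (0.1 L water,
#' 1e-4 kg plastic), sampling times 2/4/7 days for PE-style designs and
#' 2/4/7/11 days for PS-style designs, initial concentrations 5 µg/L
#' (50 for phenanthrene, 30 for 4-nonylphenol). Truths default to
#' \code{\link{study_truths}}. The result is a measurement table the rest
#' of the pipeline (\code{\link{run_pipeline}}) consumes directly.
#'
#' @param compound_table List of \code{\link{compound_record}}s (provides
#'   pKa and ion class per compound).
#' @param truth_table Data frame with columns \code{compound},
#'   \code{polymer}, \code{kp_n}, \code{kp_i}; every compound must exist in
#'   \code{compound_table}.
#' @param seed Global integer seed; fans out to per-batch substreams.
#' @param epsilon Relative analytical noise (default 0.05).
#' @param vw,mp Batch geometry (defaults 0.1 L, 1e-4 kg: LSR 1000 L/kg).
#' @param ph_levels Batch pH levels (default \code{c(4, 7, 10)}).
#' @return A measurement data frame (see \code{\link{read_measurements}}).
#' @examples
#' compounds <- read_compound_table(mpsorb_example("compounds_table1.csv"))
#' meas <- generate_study_fixture(compounds, study_truths("PE"), seed = 42)
#' nrow(meas)  # 19 compounds x 3 pH x 3 replicates x 4 times (incl. day 0)
#' @export
generate_study_fixture <- function(compound_table,
                                   truth_table = study_truths("PE"),
                                   seed = 1L, epsilon = 0.05,
                                   vw = 0.1, mp = 1e-4,
                                   ph_levels = c(4, 7, 10)) {
  empty <- data.frame(
    compound = character(), polymer = character(), ph = numeric(),
    replicate = integer(), time_days = numeric(),
    c0_ug_per_L = numeric(), cw_ug_per_L = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(truth_table) == 0L) return(empty)
  missing <- setdiff(truth_table$compound, names(compound_table))
  if (length(missing) > 0L)
    stop("compounds in truth table but not in compound table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- vector("list", nrow(truth_table) * length(ph_levels))
  k <- 0L
  for (i in seq_len(nrow(truth_table))) {
    tr_row <- truth_table[i, ]
    cmp <- compound_table[[tr_row$compound]]
    truth <- synthetic_truth(tr_row$kp_n, tr_row$kp_i, pka = cmp$pka,
                             ion_class = cmp$ion_class, epsilon = epsilon,
                             seed = seed)
    times <- if (tr_row$polymer == "PS") c(2, 4, 7, 11) else c(2, 4, 7)
    for (ph in ph_levels) {
      cond <- batch_condition(vw, mp, c0 = study_c0(tr_row$compound),
                              ph = ph)
      k <- k + 1L
      out[[k]] <- simulate_batch(truth, cond, n_replicates = 3L,
                                 sample_times = times,
                                 compound = tr_row$compound,
                                 polymer = tr_row$polymer)
    }
  }
  do.call(rbind, out)
}
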