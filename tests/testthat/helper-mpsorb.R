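# Shared helpers: an exhaustive grid-search minimizer used as the
# independent oracle for the non-negative least-squares fit, and small
# design constructors.

# Brute-force minimizer of sum((y - kn*f_n - ki*f_i)^2) over an integer
# grid [0, kmax]^2 with the given step. Direct enumeration of the
# objective; shares no code with the package solver.
grid_nnls <- function(f_n, f_i, y, kmax, step = 1) {
  ks <- seq(0, kmax, by = step)
  best <- list(kn = NA, ki = NA, rss = Inf)
  for (kn in ks) {
    resid <- y - kn * f_n
    # inner loop vectorized over ki for speed; objective still evaluated
    # point by point as sum of squares
    rss_ki <- vapply(ks, function(ki) sum((resid - ki * f_i)^2), numeric(1))
    j <- which.min(rss_ki)
    if (rss_ki[j] < best$rss)
      best <- list(kn = kn, ki = ks[j], rss = rss_ki[j])
  }
  best
}

# The study's batch geometry: 0.1 L water, 1e-4 kg plastic (LSR 1000 L/kg).
study_condition <- function(c0 = 5, ph = 7)
  batch_condition(vw = 0.1, mp = 1e-4, c0 = c0, ph = ph)

# Simulated observations for one compound across the pH design, returning
# pooled (ph, dp) pairs ready for fit_species_k. Uses the package's own
# generator; day-0 rows are dropped as in the pipeline.
simulate_design_dp <- function(truth, ph_levels = c(4, 7, 10), c0 = 5,
                               times = c(2, 4, 7)) {
  out <- lapply(ph_levels, function(ph) {
    cond <- study_condition(c0 = c0, ph = ph)
    d <- simulate_batch(truth, cond, n_replicates = 3L,
                        sample_times = times)
    d <- d[d$time_days > 0, ]
    data.frame(ph = ph, dp = dp_from_measurement(cond, d$cw_ug_per_L))
  })
  do.call(rbind, out)
}
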