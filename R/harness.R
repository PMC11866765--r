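#' Accuracy scan: MAHI versus reference lambda forces
#'
#' Reproduces the relative-deviation benchmark: for each seed a random
#' benchmark system is generated, MAHI lambda forces and end-state-combined
#' reference forces are computed at identical multipole order p and depth d,
#' and the per-lambda relative deviation `(F - F_ref) / F_ref` is recorded.
#' The reference is always evaluated in double precision; `precision` applies
#' to the MAHI pipeline. Reference forces below `1e-12` in magnitude are
#' flagged and excluded from relative statistics.
#'
#' @param p_list multipole orders
#' @param d_list octree depths
#' @param precisions character vector, subset of `c("double", "single")`
#' @param seeds seeds of the replicate systems
#' @param placement `"typical"` or `"worst_case"`
#' @param n_env environment size
#' @param site `c(n_particles, n_forms)` of the single site
#' @param neutralize passed to [generator_spec()]
#' @param op optional prebuilt lattice operator (built at `max(p_list)`)
#' @return data frame of class `deviation_curve` with one row per
#'   (seed, p, d, precision, lambda variable)
#' @export
run_accuracy_scan <- function(p_list = c(2, 8, 16), d_list = 0,
                              precisions = "double", seeds = 1:5,
                              placement = "typical", n_env = 1000,
                              site = c(10, 2), neutralize = FALSE,
                              op = NULL) {
  if (is.null(op)) op <- lattice_operator(max(p_list))
  rows <- list()
  for (seed in seeds) {
    gen <- generate_random_system(generator_spec(
      n_env = n_env, sites = list(site), placement = placement,
      seed = seed, neutralize = neutralize))
    for (d in d_list) for (p in p_list) {
      ref <- reference_forces(gen$system, gen$topology, gen$lambda,
                              backend = "fmm", p = p, d = d, op = op)
      fr <- unlist(ref$F_lambda)
      for (prec in precisions) {
        mah <- mahi_lambda_forces(gen$system, gen$topology, gen$lambda,
                                  p = p, d = d, precision = prec, op = op)
        fm <- unlist(mah$F_lambda)
        small <- abs(fr) < 1e-12
        dev <- ifelse(small, NA_real_, (fm - fr) / fr)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, p = p, d = d, precision = prec,
          lambda_index = seq_along(fr), F_mahi = fm, F_ref = fr,
          deviation = dev, ref_too_small = small)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("deviation_curve", "data.frame")
  out
}

#' Summarize a deviation curve
#' @param object a `deviation_curve`
#' @param ... unused
#' @return data frame with max and median absolute deviation per
#'   (p, d, precision)
#' @export
summary.deviation_curve <- function(object, ...) {
  key <- interaction(object$p, object$d, object$precision, drop = TRUE)
  do.call(rbind, lapply(split(object, key), function(g) data.frame(
    p = g$p[1], d = g$d[1], precision = g$precision[1],
    max_abs_dev = max(abs(g$deviation), na.rm = TRUE),
    median_abs_dev = median(abs(g$deviation), na.rm = TRUE),
    n = sum(!is.na(g$deviation)))))
}

#' Head-to-head HI versus QI sampling comparison
#'
#' Runs paired-seed lambda-dynamics replicas of a two-form fixture in HI and
#' QI mode, counts protonation-state transitions with hysteresis thresholds,
#' and translates the mean rate ratio into a TST barrier difference.
#' Replicas with zero transitions are excluded from the rate log-ratio with
#' a warning.
#'
#' @param fixture fixture list (default [make_fixture()]`("symmetric_site")`)
#' @param n_replicas number of replicas per mode
#' @param n_steps integration steps per replica
#' @param config base [dynamics_config()] (mode is overridden per run)
#' @param sample_every sampling stride
#' @param thresholds hysteresis thresholds `c(lo, hi)`
#' @param seeds optional replica seeds (defaults to `1:n_replicas`)
#' @return list with per-replica `table`, mean `rates`, mean lambda per mode,
#'   and the TST `barrier` (k_B T)
#' @export
run_hi_qi_comparison <- function(fixture = make_fixture("symmetric_site"),
                                 n_replicas = 10, n_steps = 1e6,
                                 config = dynamics_config(),
                                 sample_every = 10,
                                 thresholds = c(0.2, 0.8), seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_replicas)
  op <- lattice_operator(24)
  rows <- list()
  for (mode in c("hi", "qi")) {
    cfg <- config
    cfg$mode <- mode
    for (i in seq_len(n_replicas)) {
      cfg$seed <- seeds[i]
      traj <- propagate(fixture$system, fixture$topology, fixture$lambda,
                        cfg, n_steps, sample_every = sample_every, op = op)
      tr <- count_transitions(traj, thresholds[1], thresholds[2])
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, replica = i, seed = seeds[i],
        mean_lambda = mean(traj$lambda[, 1]),
        transitions = tr$count, rate_per_ns = tr$rate_per_ns)
    }
  }
  tab <- do.call(rbind, rows)
  rates <- tapply(tab$rate_per_ns, tab$mode, function(r) {
    if (any(r == 0)) warning("replica with zero transitions excluded from rate mean")
    mean(r[r > 0])
  })
  mean_lambda <- tapply(tab$mean_lambda, tab$mode, mean)
  barrier <- if (all(is.finite(rates)) && all(rates > 0))
    tst_barrier_from_rates(rates[["hi"]], rates[["qi"]],
                           config$temperature) else NA_real_
  list(table = tab, rates = rates, mean_lambda = mean_lambda,
       barrier = barrier)
}
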