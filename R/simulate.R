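#' Scenario configuration for the community-collapse simulator
#'
#' Collects every knob of [simulate_community()]. The generator realizes the
#' qualitative event taxonomy of collapse records: one-sample *pulse*
#' perturbations (dominant crashes by a factor `1 - pulse_dom_drop`, an
#' indicator taxon blooms by `pulse_ind_gain`, total counts dip), persistent
#' *step* shifts of a latent environmental driver (the successor taxon is
#' boosted, assemblage growth flattens), a dominance-turnover *collapse* at
#' `collapse_time`, optionally a second turnover (*recovery*), an
#' opportunistic delayed dominant decline, and a critical-slowing-down ramp
#' of the dominant's latent AR(1) coefficient.
#'
#' @param n_samples series length (default 30).
#' @param n_taxa number of taxa, at least 5 (default 20).
#' @param dominant,successor,indicator,recovery_taxon taxon indices of the
#'   pre-collapse dominant, its successor, the pulse-indicator taxon, and
#'   (optional) the recovery dominant.
#' @param pulse_times integer sample indices of one-sample pulses (may be
#'   empty); must precede `collapse_time`.
#' @param pulse_dom_drop fractional crash of the dominant at a pulse,
#'   in (0, 1) (default 0.6: the dominant keeps 40% of its latent abundance).
#' @param pulse_ind_gain multiplicative bloom of the indicator taxon at a
#'   pulse, > 1 (default 4).
#' @param pulse_driver one-sample spike added to the environmental driver at
#'   each pulse (default 1).
#' @param pulse_abund_drop fractional dip of total counted individuals at a
#'   pulse (default 0.5).
#' @param step_time sample index of the persistent driver shift, or `NULL`.
#' @param step_mag permanent driver shift from `step_time` on (default 1;
#'   negative for cooling-type scenarios).
#' @param succ_step_boost immediate latent log-boost of the successor at the
#'   step (default 0.8), the mechanism that drives the monitored ratio over
#'   its critical threshold at the step itself.
#' @param collapse_time sample index of the dominance turnover, or `NULL`
#'   for a collapse-free series. The old dominant and its successor cross
#'   half a sample earlier, so the successor strictly leads from
#'   `collapse_time` onward.
#' @param recovery_time optional sample index at which `recovery_taxon`
#'   overtakes the successor.
#' @param opportunist when `TRUE` and a step exists, the dominant is boosted
#'   for `opp_lag` samples after the step before declining (the
#'   "opportunistic dominant" pattern).
#' @param opp_lag,opp_boost lag (samples) and latent log-boost of the
#'   opportunist response (defaults 3 and 1).
#' @param csd when `TRUE` the dominant's latent deviations follow an AR(1)
#'   whose coefficient ramps linearly from `phi0` to `phi1` over the
#'   pre-collapse window — the critical-slowing-down signature.
#' @param phi0,phi1 AR(1) ramp endpoints, `0 < phi0 <= phi1 < 1`.
#' @param csd_sd innovation standard deviation of the dominant's AR(1)
#'   deviations when `csd` is on (default 0.25, larger than the background
#'   observation noise: fluctuations near a tipping point both slow down and
#'   grow — the flickering signature).
#' @param noise_sd standard deviation of the latent log-abundance
#'   observation noise (default 0.1).
#' @param total_count nominal number of individuals counted per sample
#'   (default 300, the conventional micropaleontological count size).
#' @param abund_growth,abund_growth_post linear growth of the counting
#'   activity factor per sample before and after the step (defaults 0.06
#'   and 0.012: the post-step slope is five times gentler).
#' @param succ_rise successor latent log-rise per sample after the first
#'   event (default 0.12).
#' @param close_rate log-units per sample at which the dominant closes on
#'   the successor near the turnover (default 0.8).
#' @param seed integer seed consumed by [simulate_community()].
#' @return A `scenario_config` list.
#' @seealso [simulate_community()], [preset_scenarios()]
#' @export
scenario_config <- function(n_samples = 30, n_taxa = 20, dominant = 1,
                            successor = 2, indicator = 3,
                            recovery_taxon = NULL,
                            pulse_times = integer(0), pulse_dom_drop = 0.6,
                            pulse_ind_gain = 4, pulse_driver = 1,
                            pulse_abund_drop = 0.5,
                            step_time = NULL, step_mag = 1,
                            succ_step_boost = 0.8,
                            collapse_time = NULL, recovery_time = NULL,
                            opportunist = FALSE, opp_lag = 3, opp_boost = 1,
                            csd = FALSE, phi0 = 0.2, phi1 = 0.9, csd_sd = 0.25,
                            noise_sd = 0.1, total_count = 300,
                            abund_growth = 0.06, abund_growth_post = 0.012,
                            succ_rise = 0.12, close_rate = 0.8, seed = 1) {
  cfg <- as.list(environment())
  cfg$pulse_times <- as.integer(pulse_times)
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario <- function(cfg) {
  with(cfg, {
    if (n_samples < 5) abort("n_samples must be at least 5")
    if (n_taxa < 5) abort("n_taxa must be at least 5")
    foci <- c(dominant, successor, indicator, recovery_taxon)
    if (anyDuplicated(foci) || any(foci > n_taxa)) {
      abort("dominant/successor/indicator/recovery_taxon must be distinct taxon indices")
    }
    if (!is.null(collapse_time)) {
      if (length(pulse_times) && any(pulse_times >= collapse_time)) {
        abort("pulse_times must precede collapse_time")
      }
      if (!is.null(step_time) && step_time >= collapse_time) {
        abort("step_time must precede collapse_time")
      }
      if (!is.null(recovery_time) && recovery_time <= collapse_time) {
        abort("recovery_time must follow collapse_time")
      }
    }
    if (length(pulse_times) && any(pulse_times < 1 | pulse_times > n_samples)) {
      abort("pulse_times out of range")
    }
    if (!(pulse_dom_drop > 0 && pulse_dom_drop < 1)) {
      abort("pulse_dom_drop must be in (0, 1)")
    }
    if (pulse_ind_gain <= 1) abort("pulse_ind_gain must exceed 1")
    if (!(phi0 > 0 && phi0 <= phi1 && phi1 < 1)) {
      abort("need 0 < phi0 <= phi1 < 1")
    }
  })
  invisible(cfg)
}

#' Preset collapse scenarios
#'
#' Four ready-made [scenario_config()]s mirroring the structure of classic
#' collapse records: `kpg_like` — a single large pulse before the turnover,
#' 26 samples; `pe_like` — a small pulse followed by a step with an
#' opportunistic dominant and a recovery phase, 31 samples; `modern_like` —
#' a step only, with the rising-taxon/dominant ratio monitored, 18 samples;
#' `em_like` — a pulse plus a cooling-signed step, 33 samples.
#'
#' @param name one of `"kpg_like"`, `"pe_like"`, `"modern_like"`, `"em_like"`.
#' @param seed seed stored in the config.
#' @return A `scenario_config`.
#' @export
preset_scenarios <- function(name, seed = 1) {
  presets <- list(
    kpg_like = function() scenario_config(
      n_samples = 26, pulse_times = 10L, collapse_time = 16, seed = seed),
    pe_like = function() scenario_config(
      n_samples = 31, pulse_times = 8L, pulse_dom_drop = 0.5,
      pulse_ind_gain = 3, step_time = 12, collapse_time = 18,
      opportunist = TRUE, recovery_taxon = 4, recovery_time = 26, seed = seed),
    modern_like = function() scenario_config(
      n_samples = 18, step_time = 7, collapse_time = 12, seed = seed),
    em_like = function() scenario_config(
      n_samples = 33, pulse_times = 10L, pulse_driver = -1, step_time = 14,
      step_mag = -1, collapse_time = 20, seed = seed)
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  presets[[name]]()
}

#' Simulate a labelled community-collapse series
#'
#' Generates a counts-and-percent community series whose latent structure
#' realizes the configured events, together with the ground truth needed to
#' score a detection pipeline.
#'
#' Per taxon, latent log-abundance is a baseline plus a Gaussian-niche
#' response to a latent environmental driver `E_t` (constant, permanently
#' shifted at the step, spiked for one sample at each pulse). The dominant
#' sits on a high baseline and, after the first event, declines linearly in
#' log-abundance so that its successor overtakes it half a sample before
#' `collapse_time`; pulses multiply the dominant down and the indicator
#' taxon up for one sample. Observation: counts are drawn from a multinomial
#' of size `total_count` times a deterministic activity factor (growing,
#' flattening after the step, dipping at pulses) over the softmax of the
#' noisy latents, then closed to percent. In `mode = "expected"` the noise
#' is switched off and expected counts are returned, which makes the
#' constructed shapes exact.
#'
#' @param config a [scenario_config()].
#' @param mode `"sample"` (multinomial draws, default) or `"expected"`
#'   (deterministic expected counts).
#' @return A list with `series` (a [community_ts()] carrying counts and
#'   percentages) and `truth` (a `ground_truth` list: `events` tibble,
#'   `collapse_sample`, `recovery_sample`, `dominants` schedule, `driver`
#'   path, and the config).
#' @export
simulate_community <- function(config, mode = c("sample", "expected")) {
  stopifnot(inherits(config, "scenario_config"))
  mode <- match.arg(mode)
  cfg <- config
  n <- cfg$n_samples
  m <- cfg$n_taxa
  set.seed(cfg$seed)

  d <- cfg$dominant; su <- cfg$successor; ind <- cfg$indicator
  rec <- cfg$recovery_taxon
  foci <- c(d, su, ind, rec)
  others <- setdiff(seq_len(m), foci)

  # environmental driver
  E <- rep(0, n)
  if (!is.null(cfg$step_time)) {
    E[cfg$step_time:n] <- E[cfg$step_time:n] + cfg$step_mag
  }
  E[cfg$pulse_times] <- E[cfg$pulse_times] + cfg$pulse_driver

  first_event <- suppressWarnings(min(c(cfg$pulse_times, cfg$step_time, Inf)))

  b_dom <- 3; b_suc <- 1.6; b_ind <- 0.5; b_rec_floor <- 0.2
  lat <- matrix(0, n, m)

  # background taxa: fixed baselines + Gaussian-niche response to E
  if (length(others)) {
    base_oth <- seq(0.8, -0.8, length.out = length(others))
    mu_oth <- seq(-1, 1, length.out = length(others))
    for (k in seq_along(others)) {
      lat[, others[k]] <- base_oth[k] - (E - mu_oth[k])^2 / (2 * 1.5^2)
    }
  }
  lat[, ind] <- b_ind - (E - 0.5)^2 / (2 * 1.5^2)

  t_seq <- seq_len(n)
  succ <- rep(b_suc, n)
  if (is.finite(first_event)) {
    succ <- succ + cfg$succ_rise * pmax(0, t_seq - first_event)
  }
  if (!is.null(cfg$step_time)) {
    succ[t_seq >= cfg$step_time] <- succ[t_seq >= cfg$step_time] +
      cfg$succ_step_boost
  }
  # the successor stays strictly below the dominant's baseline until the
  # turnover (competitive suppression), and saturates one log-unit above it
  # afterwards so late samples keep a realistic mixed assemblage
  succ <- pmin(succ, b_dom + 1)
  if (!is.null(cfg$collapse_time)) {
    pre <- t_seq < cfg$collapse_time
    succ[pre] <- pmin(succ[pre], b_dom - 0.25)
  }
  lat[, su] <- succ

  dom <- rep(b_dom, n)
  if (!is.null(cfg$collapse_time)) {
    t_cross <- cfg$collapse_time - 0.5
    target <- succ + cfg$close_rate * (t_cross - t_seq)
    declining <- t_seq >= max(1, min(first_event, n))
    if (!is.finite(first_event)) declining <- rep(TRUE, n)
    dom[declining] <- pmin(b_dom, target[declining])
  }
  if (cfg$opportunist && !is.null(cfg$step_time)) {
    win <- cfg$step_time:min(n, cfg$step_time + cfg$opp_lag - 1)
    dom[win] <- dom[win] + cfg$opp_boost
  }
  dom[cfg$pulse_times] <- dom[cfg$pulse_times] + log(1 - cfg$pulse_dom_drop)
  lat[, d] <- dom
  lat[cfg$pulse_times, ind] <- lat[cfg$pulse_times, ind] +
    log(cfg$pulse_ind_gain)

  if (!is.null(rec)) {
    stopifnot(!is.null(cfg$recovery_time))
    r_cross <- cfg$recovery_time - 0.5
    lat[, rec] <- pmax(b_rec_floor,
                       pmin(succ + cfg$close_rate * (t_seq - r_cross),
                            b_dom + 2))
  }

  # noise: iid latent log-noise; the dominant's deviations optionally AR(1)
  # with a coefficient ramping over the pre-collapse window (CSD)
  if (mode == "sample" && cfg$noise_sd > 0) {
    eps <- matrix(rnorm(n * m, 0, cfg$noise_sd), n, m)
    if (cfg$csd) {
      T_pre <- cfg$collapse_time %||% n
      phi <- cfg$phi0 + (cfg$phi1 - cfg$phi0) *
        pmin(1, (t_seq - 1) / max(1, T_pre - 1))
      innov <- rnorm(n, 0, cfg$csd_sd)
      z <- numeric(n)
      z[1] <- innov[1]
      for (t in 2:n) z[t] <- phi[t] * z[t - 1] + innov[t]
      eps[, d] <- z
    }
    lat <- lat + eps
  }

  # activity factor: growth flattens after the step, dips at pulses
  act <- rep(1, n)
  if (!is.null(cfg$step_time)) {
    st <- cfg$step_time
    act <- 1 + cfg$abund_growth * (pmin(t_seq, st) - 1) +
      cfg$abund_growth_post * pmax(0, t_seq - st)
  }
  act[cfg$pulse_times] <- act[cfg$pulse_times] * (1 - cfg$pulse_abund_drop)
  N <- round(cfg$total_count * act)

  P <- exp(lat)
  P <- P / rowSums(P)
  counts <- matrix(0, n, m)
  if (mode == "sample") {
    for (t in seq_len(n)) counts[t, ] <- rmultinom(1, N[t], P[t, ])
  } else {
    counts <- P * N
  }
  colnames(counts) <- sprintf("sp%02d", seq_len(m))
  series <- community_ts(axis = as.numeric(t_seq), counts = counts,
                         axis_direction = "time")
  series <- to_relative(series)

  events <- dplyr::bind_rows(
    if (length(cfg$pulse_times)) tibble(sample = cfg$pulse_times, kind = "pulse"),
    if (!is.null(cfg$step_time)) tibble(sample = as.integer(cfg$step_time),
                                        kind = "step")
  )
  if (is.null(events)) events <- tibble(sample = integer(), kind = character())
  dominants <- dplyr::bind_rows(
    tibble(role = "pre_collapse", taxon = colnames(counts)[d]),
    if (!is.null(cfg$collapse_time))
      tibble(role = "collapse", taxon = colnames(counts)[su]),
    if (!is.null(rec)) tibble(role = "recovery", taxon = colnames(counts)[rec])
  )
  truth <- structure(
    list(events = events,
         collapse_sample = if (is.null(cfg$collapse_time)) NA_integer_ else
           as.integer(cfg$collapse_time),
         recovery_sample = if (is.null(cfg$recovery_time)) NA_integer_ else
           as.integer(cfg$recovery_time),
         dominants = dominants, driver = E, config = cfg),
    class = "ground_truth")
  list(series = series, truth = truth)
}

#' Write simulator ground truth as a JSON side-car
#'
#' @param truth a `ground_truth` object.
#' @param path output file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  x <- list(events = truth$events, collapse_sample = truth$collapse_sample,
            recovery_sample = truth$recovery_sample,
            dominants = truth$dominants, driver = truth$driver,
            config = unclass(truth$config))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
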