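#' Pipeline configuration
#'
#' Every tunable of the analysis pipeline in one flat list, so that a config
#' plus an input fully determine a run.
#'
#' @param k zone count for the community cut; `NULL` = automatic
#'   ([choose_zone_count()]).
#' @param ar1_window rolling AR(1) window (default 20 samples).
#' @param ar1_target series fed to AR(1): `"dominant"` (default) or
#'   `"total_abundance"`.
#' @param span,degree loess band parameters (defaults 1 and 2).
#' @param quantile_prob Student-t probability of the band (default 0.95,
#'   the one-sided quantile; see [confidence_band()]).
#' @param presence_threshold richness presence cutoff (default 0).
#' @param outlier_factor dendrogram outlier multiplier (default 2).
#' @param min_run,slope_factor large-scale signal parameters (3 and 2).
#' @param ratio_threshold,persist ratio-crossing parameters (0.5 and 2).
#' @param subcluster_k fine cut for step evidence; `NULL` = the scale-free
#'   merge-height rule (see [detect_step_events()]).
#' @param subcluster_factor median-height multiplier of that rule (1.5).
#' @param quorum evidence flags required per event call (default 2).
#' @param peak_alpha familywise level of the pulse peak-significance gate
#'   (default 0.05; see [detect_pulse_events()]).
#' @param pulse_sigma robust-sigma fallback gate for percent-only inputs
#'   (default 3; see [detect_pulse_events()]).
#' @param ratio_pair optional `c(numerator, denominator)` taxa for the
#'   monitored ratio; `NULL` picks the collapse dominant (or the
#'   second-ranked taxon) over the pre-collapse dominant.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = NULL, ar1_window = 20,
                            ar1_target = c("dominant", "total_abundance"),
                            span = 1, degree = 2, quantile_prob = 0.95,
                            presence_threshold = 0, outlier_factor = 2,
                            min_run = 3, slope_factor = 2,
                            ratio_threshold = 0.5, persist = 2,
                            subcluster_k = NULL, subcluster_factor = 1.5,
                            quorum = 2, peak_alpha = 0.05, pulse_sigma = 3,
                            ratio_pair = NULL) {
  ar1_target <- match.arg(ar1_target)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full collapse-detection pipeline
#'
#' Read (or simulate) - interpolate - cluster - zone/boundary - indicators -
#' loess bands - signals - events, with stage-tagged logging and a
#' machine-readable report. Inputs may be a file path (see
#' [read_community_table()]), a [community_ts()], a preset name
#' ([preset_scenarios()]), or a [scenario_config()].
#'
#' @param input file path, `community_ts`, preset name, or `scenario_config`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the report JSON and the
#'   zones/indicators/signals/events TSVs are written there.
#' @param seed seed for simulated inputs (overrides the config's seed).
#' @param quiet suppress stage logging (default `FALSE`; messages go to
#'   stderr).
#' @param ... passed to [read_community_table()] for file inputs.
#' @return A `pipeline_report` list: `input_summary`, `zones`, `boundary`,
#'   `indicators` (named list of tibbles), `signals`, `events`, `truth`
#'   (simulated inputs only), `params`, `version`, `seed`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         seed = NULL, quiet = FALSE, ...) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(stage, msg) {
    if (!quiet) message("[", stage, "] ", msg)
  }
  truth <- NULL
  used_seed <- seed
  if (is.character(input) && length(input) == 1 && !file.exists(input)) {
    cfg <- preset_scenarios(input, seed = seed %||% 1)
    used_seed <- cfg$seed
    log_stage("simulate", paste0("preset '", input, "', seed ", cfg$seed))
    sim <- simulate_community(cfg)
    x <- sim$series; truth <- sim$truth
  } else if (inherits(input, "scenario_config")) {
    if (!is.null(seed)) input$seed <- seed
    used_seed <- input$seed
    log_stage("simulate", paste0("scenario config, seed ", input$seed))
    sim <- simulate_community(input)
    x <- sim$series; truth <- sim$truth
  } else if (inherits(input, "community_ts")) {
    x <- input
  } else {
    log_stage("read", input)
    x <- read_community_table(input, ...)
  }
  if (is.null(x$rel_abund)) x <- to_relative(x)
  n_missing <- sum(x$missing)
  if (n_missing > 0) {
    log_stage("interpolate", paste0(n_missing, " missing cell(s) filled"))
    x <- interpolate_missing(x)
  }

  log_stage("cluster", "constrained UPGMA, Euclidean distance on percent")
  tree <- constrained_upgma(x)

  zl <- collapse_boundary(x, tree, k = config$k)
  log_stage("zones", paste0(nrow(zl), " zone(s); collapse ",
    if (attr(zl, "collapse_detected"))
      paste0("boundary at sample ", attr(zl, "boundary_sample"))
    else "not detected"))
  pre_dom <- zl$dominant[1]
  col_dom <- if (attr(zl, "collapse_detected"))
    zl$dominant[zl$role == "collapse"][1] else NA_character_

  log_stage("indicators", "computing the indicator suite")
  ind <- list()
  ind$dominant <- dominant_rel_abund(x, pre_dom)
  ind$cross_sd <- cross_sd(x)
  ind$species_richness <- species_richness(x, config$presence_threshold)
  if (!is.null(x$counts)) ind$total_abundance <- total_abundance(x)
  ar1_base <- if (config$ar1_target == "total_abundance" &&
                  !is.null(ind$total_abundance)) {
    ind$total_abundance
  } else ind$dominant
  ind$ar1 <- rolling_ar1(ar1_base, window = min(config$ar1_window,
                                                n_samples(x)))
  ratio_pair <- config$ratio_pair
  if (is.null(ratio_pair)) {
    num <- if (!is.na(col_dom) && col_dom != pre_dom) col_dom else {
      mu <- colMeans(abundance_matrix(x, "rel_abund"))
      x$taxa[order(mu, decreasing = TRUE)][2]
    }
    ratio_pair <- c(num, pre_dom)
  }
  ind$ratio <- species_ratio(x, ratio_pair[1], ratio_pair[2])

  log_stage("signals", "loess bands and signal extraction per indicator")
  sigs <- purrr::map(ind, function(s) {
    if (sum(s$valid) < config$degree + 2) return(NULL)
    extract_signals(s, span = config$span, degree = config$degree,
                    quantile_prob = config$quantile_prob,
                    min_run = config$min_run,
                    slope_factor = config$slope_factor)
  })
  sigs <- purrr::compact(sigs)

  log_stage("events", "pulse/step classification on the pre-collapse window")
  boundary <- attr(zl, "boundary_sample")
  pulses <- detect_pulse_events(x, tree, dominant = pre_dom,
                                outlier_factor = config$outlier_factor,
                                span = config$span, degree = config$degree,
                                quantile_prob = config$quantile_prob,
                                quorum = config$quorum,
                                peak_alpha = config$peak_alpha,
                                pulse_sigma = config$pulse_sigma,
                                before = boundary)
  steps <- detect_step_events(x, tree, ratio = ind$ratio,
                              threshold = config$ratio_threshold,
                              persist = config$persist,
                              subcluster_k = config$subcluster_k,
                              subcluster_factor = config$subcluster_factor,
                              span = config$span, degree = config$degree,
                              min_run = config$min_run,
                              slope_factor = config$slope_factor,
                              quorum = config$quorum, before = boundary)
  events <- reconcile_events(new_event_calls(dplyr::bind_rows(
    as_tibble(pulses), as_tibble(steps))))

  report <- structure(list(
    input_summary = list(n_samples = n_samples(x), n_taxa = length(x$taxa),
                         axis_direction = x$axis_direction,
                         axis_range = range(x$axis),
                         interpolated_cells = n_missing),
    zones = zl,
    boundary = list(collapse_detected = attr(zl, "collapse_detected"),
                    boundary_sample = attr(zl, "boundary_sample"),
                    boundary_axis = if (attr(zl, "collapse_detected"))
                      x$axis[attr(zl, "boundary_sample")] else NA_real_,
                    pre_collapse_dominant = pre_dom,
                    collapse_dominant = col_dom),
    indicators = purrr::map(ind, as_tibble),
    signals = sigs, events = events, truth = truth,
    params = unclass(config), ratio_pair = ratio_pair,
    version = as.character(utils::packageVersion("collapsescope")),
    seed = used_seed
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    log_stage("write", out_dir)
    write_report(report, out_dir, series = x)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$input_summary$n_samples, " samples x ",
      x$input_summary$n_taxa, " taxa\n", sep = "")
  cat("  collapse: ",
      if (x$boundary$collapse_detected)
        paste0("sample ", x$boundary$boundary_sample, " (axis ",
               format(x$boundary$boundary_axis), "); ",
               x$boundary$pre_collapse_dominant, " -> ",
               x$boundary$collapse_dominant)
      else "not detected", "\n", sep = "")
  cat("  events: ", nrow(x$events), "; indicators: ",
      paste(names(x$indicators), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (the full machine-readable report, no timestamps, so
#' identical runs produce byte-identical files) plus `zones.tsv`,
#' `indicators.tsv`, `signals.tsv`, `events.tsv`.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory, created if needed.
#' @param series optionally the analysed [community_ts()], written as
#'   `series.tsv`.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, series = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    input_summary = report$input_summary,
    zones = as.data.frame(report$zones),
    boundary = report$boundary,
    signals = purrr::map(report$signals,
                         function(s) list(small = as.data.frame(s$small),
                                          large = as.data.frame(s$large))),
    events = as.data.frame(report$events),
    params = report$params, ratio_pair = report$ratio_pair,
    version = report$version, seed = report$seed
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_zones_tsv(report$zones, file.path(out_dir, "zones.tsv"))
  write_indicator_tsv(report$indicators, file.path(out_dir, "indicators.tsv"))
  write_signals_tsv(report$signals, file.path(out_dir, "signals.tsv"))
  write_events_tsv(report$events, file.path(out_dir, "events.tsv"))
  if (!is.null(series)) {
    write_community_table(series, file.path(out_dir, "series.tsv"))
  }
  invisible(out_dir)
}
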