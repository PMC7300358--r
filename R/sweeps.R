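#' Equilibrium-snapshot phase diagram over supplementation doses
#'
#' For each combination of adenine dose (x axis) and lysine-to-adenine
#' ratio (y axis), runs the given supplementation regime from a fixed
#' initial ADE-up fraction and records the ADE-up fraction at the snapshot
#' time. The snapshot convention (state at a fixed time, default 300,
#' identical across cells and regimes) is used instead of equilibrium
#' detection because intermittent and continuous disturbances keep the
#' system permanently out of equilibrium; comparing at the same time point
#' is the only fair comparison across regimes.
#'
#' @param params A [cf_params()].
#' @param regime_template A [cf_regime()] whose doses are overwritten per
#'   cell (`doseA = x`, `doseL = x * y`); its mode, timing and
#'   `include_initial_dose` are kept.
#' @param doses_A Adenine dose values (> 0 unless 0 means "unsupplemented").
#'   Default: logarithmic grid 1e-2 to 1e1.
#' @param ratios_L Lysine-to-adenine ratio values. Default: logarithmic
#'   grid 1e-1 to 1e1.
#' @param init_fraction Initial ADE-up fraction (default 0.5).
#' @param init_total Initial total strain density (default 0.2).
#' @param snapshot_time Reporting time of evaluation (default 300).
#' @param ... Passed to [cf_simulate()] (e.g. `continuous_as`).
#' @return A `cf_phase_diagram`: list with `grid` (long-format data.frame
#'   with columns `doseA`, `ratioL`, `doseL`, `frac_ADE`), the axes, the
#'   regime template and `snapshot_time`.
#' @export
phase_diagram <- function(params, regime_template,
                          doses_A = 10^seq(-2, 1, length.out = 7),
                          ratios_L = 10^seq(-1, 1, length.out = 7),
                          init_fraction = 0.5, init_total = 0.2,
                          snapshot_time = 300, ...) {
  stopifnot(inherits(regime_template, "cf_regime"),
            all(doses_A >= 0), all(ratios_L > 0),
            init_fraction > 0, init_fraction < 1)
  cells <- expand.grid(doseA = doses_A, ratioL = ratios_L,
                       KEEP.OUT.ATTRS = FALSE)
  cells$doseL <- cells$doseA * cells$ratioL
  init <- cf_init(init_fraction, total = init_total)
  cells$frac_ADE <- vapply(seq_len(nrow(cells)), function(i) {
    reg <- regime_template
    reg$doseA <- cells$doseA[i]
    reg$doseL <- cells$doseL[i]
    tr <- tryCatch(
      cf_simulate(params, init, reg, t_end = snapshot_time, ...),
      error = function(e)
        stop(sprintf("phase_diagram cell (doseA = %g, ratioL = %g): %s",
                     cells$doseA[i], cells$ratioL[i], conditionMessage(e)),
             call. = FALSE))
    final_ade_fraction(tr, at = snapshot_time)
  }, numeric(1))
  structure(list(grid = cells, doses_A = doses_A, ratios_L = ratios_L,
                 regime = regime_template, snapshot_time = snapshot_time,
                 init_fraction = init_fraction),
            class = "cf_phase_diagram")
}

#' @export
print.cf_phase_diagram <- function(x, ...) {
  cat(sprintf(
    "<cf_phase_diagram> %s regime, %d x %d grid, snapshot at t = %g\n",
    x$regime$mode, length(x$doses_A), length(x$ratios_L), x$snapshot_time))
  cat(sprintf("  ADE-up fraction range: [%.3f, %.3f]; coexistence zone: %.3f\n",
              min(x$grid$frac_ADE), max(x$grid$frac_ADE),
              coexistence_zone(x)))
  invisible(x)
}

#' Coexistence-zone fraction of a phase diagram
#'
#' Fraction of grid cells whose snapshot ADE-up fraction lies in
#' `[lo, hi]` -- the zone where both mutualists are present at appreciable
#' frequency. The default band \[0.2, 0.8\] is symmetric around the
#' near-equal unsupplemented equilibrium; its size measures the resilience
#' of the mutualism under the regime.
#'
#' @param diagram A `cf_phase_diagram` (or bare numeric vector of cell
#'   values).
#' @param lo,hi Band limits, `0 < lo < hi < 1`.
#' @return Fraction in \[0, 1\].
#' @export
coexistence_zone <- function(diagram, lo = 0.2, hi = 0.8) {
  stopifnot(lo < hi, lo > 0, hi < 1)
  vals <- if (inherits(diagram, "cf_phase_diagram")) diagram$grid$frac_ADE
          else as.numeric(diagram)
  if (!length(vals)) stop("empty phase diagram", call. = FALSE)
  mean(vals >= lo & vals <= hi)
}

#' Intermittent-supplementation timing sweep
#'
#' Snapshot ADE-up fractions over combinations of dosing period, per-event
#' dose, initial ADE-up fraction, and start time of the schedule. All runs
#' are evaluated at the same snapshot time (default 300) so that cycle
#' length times number of cycles is constant across periods.
#'
#' Two conventions from the sweep figures are supported: period sweeps
#' (supplement every 10/30/60 steps from `start = period`, with the dose
#' also applied at `t = 0` for comparability -- the default when
#' `start_times` is `NULL`) and delayed-start sweeps (first dose at
#' `start`, nothing at `t = 0`; set `include_initial_dose = FALSE`).
#'
#' @param params A [cf_params()].
#' @param periods Dosing periods (> 0).
#' @param doses Per-event doses; applied to the metabolite(s) selected by
#'   `dose_which`.
#' @param init_fractions Initial ADE-up fractions (default 0.5).
#' @param start_times First dose times, recycled against periods; `NULL`
#'   (default) uses `start = period`.
#' @param snapshot_time Common evaluation time (default 300).
#' @param dose_which `"adenine"`, `"lysine"` or `"both"` (default
#'   `"adenine"`, the experimentally supplemented metabolite).
#' @param include_initial_dose Whether the dose is also applied at
#'   `t = 0` (default `TRUE`).
#' @param init_total Initial total strain density (default 0.2).
#' @param ... Passed to [cf_simulate()].
#' @return Data.frame with one row per combination: `period`, `start`,
#'   `dose`, `init_fraction`, `frac_ADE`.
#' @export
timing_sweep <- function(params, periods, doses, init_fractions = 0.5,
                         start_times = NULL, snapshot_time = 300,
                         dose_which = c("adenine", "lysine", "both"),
                         include_initial_dose = TRUE, init_total = 0.2,
                         ...) {
  dose_which <- match.arg(dose_which)
  stopifnot(all(periods > 0), all(doses >= 0))
  combos <- expand.grid(period = periods, dose = doses,
                        init_fraction = init_fractions,
                        KEEP.OUT.ATTRS = FALSE)
  if (is.null(start_times)) combos$start <- combos$period
  else combos <- merge(combos, data.frame(start = start_times))
  combos$frac_ADE <- vapply(seq_len(nrow(combos)), function(i) {
    dA <- if (dose_which %in% c("adenine", "both")) combos$dose[i] else 0
    dL <- if (dose_which %in% c("lysine", "both")) combos$dose[i] else 0
    reg <- cf_regime("intermittent", doseA = dA, doseL = dL,
                     period = combos$period[i], start = combos$start[i],
                     include_initial_dose = include_initial_dose)
    tr <- cf_simulate(params, cf_init(combos$init_fraction[i],
                                      total = init_total),
                      reg, t_end = snapshot_time, ...)
    final_ade_fraction(tr, at = snapshot_time)
  }, numeric(1))
  combos[, c("period", "start", "dose", "init_fraction", "frac_ADE")]
}

#' Dominance grid for the ultimate-overproducer system
#'
#' For each overproducer growth rate `ro`, intervention time `tau` and
#' per-event lysine dose, runs the three-strain system with lysine
#' supplementation starting at `tau` and repeating every `tau` time steps
#' (the intervention schedule), then labels the dominant strain at the
#' snapshot time. `dose = 0` rows are the no-supplementation baseline.
#'
#' @param params A [cf_params()]; its `ro` field is overwritten per grid.
#' @param ro_values Overproducer growth rates. Default: the illustrative
#'   set `c(0.1, 0.14, 0.16, 0.17, 0.20, 0.4, 0.5, 0.7)`.
#' @param intervention_times First-dose times `tau` (also the periods).
#' @param lysine_doses Per-event lysine doses (0 allowed: baseline).
#' @param snapshot_time Common evaluation time (default 300).
#' @param init Initial [cf_state()]; default: total density 0.2 split
#'   equally among the three strains, no free metabolites.
#' @param ... Passed to [cf_simulate()].
#' @return A `cf_dominance_grid`: data.frame with columns `ro`, `tau`,
#'   `dose`, `dominant` plus attributes.
#' @export
overproducer_grid <- function(params,
                              ro_values = c(0.1, 0.14, 0.16, 0.17, 0.20,
                                            0.4, 0.5, 0.7),
                              intervention_times = c(1, 2, 5, 10, 25),
                              lysine_doses = c(0, 0.1, 1, 10),
                              snapshot_time = 300, init = NULL, ...) {
  stopifnot(all(ro_values > 0), all(intervention_times > 0),
            all(lysine_doses >= 0))
  if (is.null(init))
    init <- cf_state(xL = 0.2 / 3, xA = 0.2 / 3, xO = 0.2 / 3)
  combos <- expand.grid(ro = ro_values, tau = intervention_times,
                        dose = lysine_doses, KEEP.OUT.ATTRS = FALSE)
  combos$dominant <- vapply(seq_len(nrow(combos)), function(i) {
    p <- params
    p$ro <- combos$ro[i]
    reg <- if (combos$dose[i] > 0)
      cf_regime("intermittent", doseA = 0, doseL = combos$dose[i],
                period = combos$tau[i], start = combos$tau[i],
                include_initial_dose = FALSE)
    else cf_regime("none")
    tr <- cf_simulate(p, init, reg, t_end = snapshot_time, ...)
    dominant_strain(tr)
  }, character(1))
  structure(combos, class = c("cf_dominance_grid", "data.frame"),
            snapshot_time = snapshot_time)
}

#' Write a sweep grid as long-format CSV plus a JSON metadata record
#'
#' @param x A `cf_phase_diagram`, `cf_dominance_grid` or plain data.frame.
#' @param csv_path Output CSV path.
#' @param meta_path Optional JSON metadata path; records the regime,
#'   snapshot time and package version.
#' @return `csv_path`, invisibly.
#' @export
write_grid <- function(x, csv_path, meta_path = NULL) {
  df <- if (inherits(x, "cf_phase_diagram")) x$grid else as.data.frame(x)
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(package = "crossfeedr",
                 version = as.character(packageVersion("crossfeedr")),
                 class = class(x)[1])
    if (inherits(x, "cf_phase_diagram")) {
      meta$regime <- unclass(x$regime)
      meta$snapshot_time <- x$snapshot_time
      meta$init_fraction <- x$init_fraction
    }
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, null = "null")
  }
  invisible(csv_path)
}
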