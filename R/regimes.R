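#' Supplementation regime
#'
#' Describes how adenine and lysine are added to the culture from outside:
#'
#' * `"none"` — no supplementation.
#' * `"initial"` — a single dose folded into the initial condition at
#'   `t = 0` (the batch-culture scenario).
#' * `"intermittent"` — impulsive doses at `start, start + period, ...`,
#'   turning the smooth flow into a hybrid dynamical system.
#' * `"continuous"` — a dose at every unit reporting step (the discrete
#'   reading of a constant nutrient feed); see [cf_simulate()] for the
#'   alternative constant-influx formulation.
#'
#' For comparability with the initial regime, intermittent runs can also
#' apply the dose at `t = 0` (`include_initial_dose`, default `TRUE`);
#' sweeps that study delayed intervention set it to `FALSE`.
#'
#' @param mode One of `"none"`, `"initial"`, `"intermittent"`,
#'   `"continuous"`.
#' @param doseA,doseL Amounts of adenine and lysine added per event
#'   (concentration units); must be non-negative.
#' @param period Time between intermittent doses (model time units).
#' @param start Time of the first scheduled dose (intermittent only).
#' @param include_initial_dose Whether the dose is also applied at `t = 0`
#'   (intermittent and continuous modes; `"initial"` is by definition a
#'   `t = 0` dose and `"none"` has no doses).
#' @return An object of class `cf_regime`.
#' @export
#' @examples
#' cf_regime("intermittent", doseA = 1, doseL = 1, period = 25, start = 25)
cf_regime <- function(mode = c("none", "initial", "intermittent",
                               "continuous"),
                      doseA = 0, doseL = 0, period = NULL, start = NULL,
                      include_initial_dose = TRUE) {
  mode <- match.arg(mode)
  if (doseA < 0 || doseL < 0)
    stop("doses must be non-negative", call. = FALSE)
  if (mode == "intermittent") {
    if (is.null(period)) stop("intermittent regime needs a period",
                              call. = FALSE)
    if (period <= 0) stop("period must be > 0", call. = FALSE)
    if (is.null(start)) start <- period
    if (start < 0) stop("start must be >= 0", call. = FALSE)
  }
  structure(list(mode = mode, doseA = doseA, doseL = doseL,
                 period = period, start = start,
                 include_initial_dose = isTRUE(include_initial_dose)),
            class = "cf_regime")
}

#' @export
print.cf_regime <- function(x, ...) {
  cat(sprintf("<cf_regime %s> doseA = %g, doseL = %g", x$mode, x$doseA,
              x$doseL))
  if (x$mode == "intermittent")
    cat(sprintf(", start = %g, period = %g", x$start, x$period))
  if (x$mode %in% c("intermittent", "continuous"))
    cat(sprintf(", initial dose: %s",
                if (x$include_initial_dose) "yes" else "no"))
  cat("\n")
  invisible(x)
}

#' Apply one supplementation dose to a state
#'
#' An impulse: metabolite concentrations jump by the regime's doses;
#' strain densities and time are untouched.
#'
#' @param state A [cf_state()].
#' @param regime A [cf_regime()] (only its doses are used).
#' @return The supplemented `cf_state`.
#' @export
apply_dose <- function(state, regime) {
  stopifnot(inherits(state, "cf_state"), inherits(regime, "cf_regime"))
  if (regime$doseA < 0 || regime$doseL < 0)
    stop("doses must be non-negative", call. = FALSE)
  state$cA <- state$cA + regime$doseA
  state$cL <- state$cL + regime$doseL
  state
}

#' Scheduled dose times of a regime
#'
#' Times strictly after 0 at which doses are applied, up to and including
#' `t_end`. The optional `t = 0` dose (`include_initial_dose`, or mode
#' `"initial"`) is reported separately by [cf_simulate()]'s bookkeeping
#' and is not part of this schedule for intermittent regimes; for
#' `"initial"` the schedule is `0`; for `"continuous"` it is every unit
#' reporting step in `[0, t_end]` (starting at 0 only when
#' `include_initial_dose`).
#'
#' @param regime A [cf_regime()].
#' @param t_end End of the simulation window (> 0).
#' @return Numeric vector of event times (possibly empty).
#' @export
#' @examples
#' event_times(cf_regime("intermittent", period = 25, start = 25), 300)
event_times <- function(regime, t_end) {
  stopifnot(inherits(regime, "cf_regime"), t_end > 0)
  switch(regime$mode,
    none = numeric(0),
    initial = 0,
    continuous = {
      from <- if (regime$include_initial_dose) 0 else 1
      if (from > t_end) numeric(0) else seq(from, t_end, by = 1)
    },
    intermittent = {
      if (regime$start > t_end) numeric(0)
      else seq(regime$start, t_end, by = regime$period)
    })
}
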