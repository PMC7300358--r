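#' Integrate the cross-feeding system under a supplementation regime
#'
#' Produces a trajectory on the unit reporting grid `0, 1, ..., t_end`.
#' Between scheduled doses the smooth system is integrated with an
#' adaptive Dormand-Prince 5(4) method (compiled; `method = "r"` selects
#' the pure-R reference path, identical algorithm). Doses are applied as
#' exact impulsive jumps between integration segments -- the literal
#' hybrid-system reading of intermittent supplementation -- so no stiff
#' source terms are involved. The reporting grid, with step 1 model time
#' unit, is the grid on which equilibration is judged and on which
#' "every time step" regimes are defined; it is independent of the
#' integrator's internal adaptive steps.
#'
#' Continuous supplementation is by default the discrete reading (one dose
#' per unit reporting step); `continuous_as = "influx"` instead adds a
#' constant term `doseA` (resp. `doseL`) per unit time to the metabolite
#' derivatives, for sensitivity checks.
#'
#' @param params A [cf_params()].
#' @param init A [cf_state()] (see [cf_init()]). Doses due at `t = 0`
#'   (mode `"initial"`, or `include_initial_dose` regimes) are applied to
#'   `init` before the first reported state, so the reported `t = 0` state
#'   includes them.
#' @param regime A [cf_regime()]; default no supplementation.
#' @param t_end End time, a positive integer multiple of the unit
#'   reporting step (default 300, the snapshot convention used by all
#'   sweeps).
#' @param method `"cpp"` (compiled, default) or `"r"` (reference).
#' @param continuous_as `"impulse"` (default) or `"influx"`, see above.
#' @param rtol,atol Integrator tolerances (defaults 1e-9).
#' @return A `cf_trajectory`: list with `times`, `states` (matrix with
#'   columns `xL, xA, xO, cA, cL`), `params`, `regime`, `events`.
#' @export
#' @examples
#' tr <- cf_simulate(cf_preset("informed"), cf_init(0.2), t_end = 100)
#' tail(fractions(tr)$frac_ADE, 1) # close to 0.6
cf_simulate <- function(params, init, regime = cf_regime("none"),
                        t_end = 300, method = c("cpp", "r"),
                        continuous_as = c("impulse", "influx"),
                        rtol = 1e-9, atol = 1e-9) {
  stopifnot(inherits(params, "cf_params"), inherits(init, "cf_state"),
            inherits(regime, "cf_regime"))
  method <- match.arg(method)
  continuous_as <- match.arg(continuous_as)
  if (t_end <= 0 || abs(t_end - round(t_end)) > 1e-9)
    stop("t_end must be a positive multiple of the unit reporting step",
         call. = FALSE)
  t_end <- round(t_end)
  check_state(init)

  use_influx <- regime$mode == "continuous" && continuous_as == "influx"
  influxA <- if (use_influx) regime$doseA else 0
  influxL <- if (use_influx) regime$doseL else 0
  pv <- params_vec(params, influxA, influxL)

  ev <- if (use_influx) numeric(0) else event_times(regime, t_end)
  # the t = 0 dose of an intermittent comparability run is extra bookkeeping
  if (regime$mode == "intermittent" && regime$include_initial_dose &&
      !(0 %in% ev))
    ev <- c(0, ev)

  y <- state_vec(init)
  if (0 %in% ev) {
    y["cA"] <- y["cA"] + regime$doseA
    y["cL"] <- y["cL"] + regime$doseL
  }

  report <- 0:t_end
  states <- matrix(NA_real_, length(report), 5,
                   dimnames = list(NULL, c("xL", "xA", "xO", "cA", "cL")))
  states[1, ] <- y

  breaks <- sort(unique(c(ev[ev > 0 & ev <= t_end], t_end)))
  seg_start <- 0
  clip_tol <- 100 * atol

  for (b in breaks) {
    inner <- report[report > seg_start & report <= b]
    outs <- sort(unique(c(inner, b)))
    seg <- tryCatch(
      integrate_segment(y, c(seg_start, outs), pv, rtol, atol, method),
      error = function(e)
        stop(sprintf("integration failed in [%g, %g] (last good t = %g): %s",
                     seg_start, b, seg_start, conditionMessage(e)),
             call. = FALSE))
    rownames(seg) <- NULL
    seg <- clip_negatives(seg, clip_tol)
    if (length(inner))
      states[match(inner, report), ] <- seg[match(inner, outs) + 1L, ]
    y <- seg[nrow(seg), ]
    if (b %in% ev && b > 0) {
      y[4] <- y[4] + regime$doseA
      y[5] <- y[5] + regime$doseL
      if (b %in% report) states[match(b, report), ] <- y
    }
    seg_start <- b
  }

  structure(list(times = report, states = states, params = params,
                 regime = regime, events = ev, t_end = t_end,
                 method = method, continuous_as = continuous_as),
            class = "cf_trajectory")
}

integrate_segment <- function(y, times, pv, rtol, atol, method) {
  if (length(times) < 2) return(matrix(y, 1, 5))
  if (method == "cpp")
    .cf_integrate_cpp(unname(y), times, pv, rtol, atol, 1.0)
  else
    rk45(cf_rhs_vec, unname(y), times, pv = pv, rtol = rtol, atol = atol,
         hmax = 1.0)
}

clip_negatives <- function(m, tol) {
  neg <- m < 0
  if (any(neg)) {
    if (any(m[neg] < -tol))
      stop("integrator produced a negative component beyond tolerance (",
           format(min(m[neg])), "); likely an integration bug",
           call. = FALSE)
    m[neg] <- 0
  }
  m
}

#' @export
print.cf_trajectory <- function(x, ...) {
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("<cf_trajectory> t in [0, %d], regime %s, %d dose events\n",
              x$t_end, x$regime$mode, length(x$events)))
  cat(sprintf("  final: xL = %.4g, xA = %.4g, xO = %.4g, cA = %.4g, cL = %.4g\n",
              fin[1], fin[2], fin[3], fin[4], fin[5]))
  invisible(x)
}

#' Relative strain and metabolite fractions along a trajectory
#'
#' Normalized fractions `xi / (xL + xA + xO)` for the strains and
#' `cA / (cA + cL)`, `cL / (cA + cL)` for the metabolites; `NA` where the
#' corresponding total is 0.
#'
#' @param traj A `cf_trajectory`.
#' @return A data.frame with columns `t`, `frac_LYS`, `frac_ADE`,
#'   `frac_O`, `frac_cA`, `frac_cL`.
#' @export
fractions <- function(traj) {
  stopifnot(inherits(traj, "cf_trajectory"))
  s <- traj$states
  totx <- rowSums(s[, 1:3, drop = FALSE])
  totc <- rowSums(s[, 4:5, drop = FALSE])
  totx[totx == 0] <- NA_real_
  totc[totc == 0] <- NA_real_
  data.frame(t = traj$times,
             frac_LYS = s[, "xL"] / totx,
             frac_ADE = s[, "xA"] / totx,
             frac_O = s[, "xO"] / totx,
             frac_cA = s[, "cA"] / totc,
             frac_cL = s[, "cL"] / totc)
}

#' Final ADE-up fraction of a trajectory
#'
#' @param traj A `cf_trajectory`.
#' @param at Reporting time at which to evaluate (default: last).
#' @return Scalar fraction in \[0, 1\].
#' @export
final_ade_fraction <- function(traj, at = NULL) {
  fr <- fractions(traj)
  if (is.null(at)) return(fr$frac_ADE[nrow(fr)])
  i <- match(at, fr$t)
  if (is.na(i)) stop("time ", at, " is not on the reporting grid",
                     call. = FALSE)
  fr$frac_ADE[i]
}

#' Detect equilibration of a trajectory
#'
#' The culture is considered equilibrated when the strain densities change
#' by no more than `tol` between two consecutive reporting steps (the
#' criterion is judged on strain densities only; metabolites are excluded
#' unless `all_components = TRUE`). The default threshold is 1e-4 per unit
#' reporting step.
#'
#' @param traj A `cf_trajectory` with at least 2 reporting points.
#' @param tol Threshold on the per-step change (default `1e-4`).
#' @param all_components If `TRUE`, metabolite concentrations must also
#'   satisfy the criterion (a stricter variant).
#' @return List of class `cf_equilibration` with fields `equilibrated`
#'   (criterion holds at the final step), `first_time` (earliest reporting
#'   time from which the criterion holds at every later step; `NA` if
#'   never), `max_step_change` (at the final step) and `tol`.
#' @export
detect_equilibration <- function(traj, tol = 1e-4, all_components = FALSE) {
  stopifnot(inherits(traj, "cf_trajectory"))
  if (length(traj$times) < 2)
    stop("trajectory needs at least 2 reporting points", call. = FALSE)
  cols <- if (all_components) 1:5 else 1:3
  d <- abs(diff(traj$states[, cols, drop = FALSE]))
  step_change <- apply(d, 1, max)
  ok <- step_change <= tol
  n <- length(ok)
  first <- NA_real_
  if (any(ok)) {
    # earliest step index from which every later step also satisfies tol
    run <- rev(cumprod(rev(ok)))
    if (run[n] == 1 || any(run == 1))
      first <- traj$times[which(run == 1)[1] + 1L]
  }
  structure(list(equilibrated = unname(ok[n]), first_time = first,
                 max_step_change = unname(step_change[n]), tol = tol),
            class = "cf_equilibration")
}

#' @export
print.cf_equilibration <- function(x, ...) {
  cat(sprintf(
    "<cf_equilibration> equilibrated: %s (max step change %.3g vs tol %g)",
    x$equilibrated, x$max_step_change, x$tol))
  if (!is.na(x$first_time)) cat(sprintf(", since t = %g", x$first_time))
  cat("\n")
  invisible(x)
}

#' Dominant strain of a culture state
#'
#' The strain with the strictly highest relative fraction; fractions equal
#' within `1e-12` give `"tie"`.
#'
#' @param state A [cf_state()] or a `cf_trajectory` (in which case the
#'   final reported state is used).
#' @return One of `"LYS"`, `"ADE"`, `"overproducer"`, `"tie"`.
#' @export
dominant_strain <- function(state) {
  if (inherits(state, "cf_trajectory")) {
    v <- state$states[nrow(state$states), ]
    state <- vec_state(v, t = state$t_end)
  }
  stopifnot(inherits(state, "cf_state"))
  x <- c(LYS = state$xL, ADE = state$xA, overproducer = state$xO)
  tot <- sum(x)
  if (tot <= 0) stop("extinct culture: total strain density is 0",
                     call. = FALSE)
  f <- x / tot
  top <- max(f)
  cand <- names(f)[f >= top - 1e-12]
  if (length(cand) > 1) "tie" else cand
}

#' Write / read a trajectory as CSV
#'
#' Columns `t, xL, xA, xO, cA, cL, frac_LYS, frac_ADE, frac_O`; values are
#' written with full precision so the state columns round-trip losslessly.
#'
#' @param traj A `cf_trajectory`.
#' @param path Output CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a data.frame.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path)
}

#' @export
as.data.frame.cf_trajectory <- function(x, ...) {
  fr <- fractions(x)
  data.frame(t = x$times, as.data.frame(x$states),
             frac_LYS = fr$frac_LYS, frac_ADE = fr$frac_ADE,
             frac_O = fr$frac_O)
}
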