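#' Monod (Michaelis-Menten) saturation fraction
#'
#' `c / (c + k)`, with the convention that the fraction is 0 at `c = 0`
#' (an auxotroph cannot grow without its required metabolite). `k` must be
#' strictly positive so the expression is never 0/0.
#'
#' @param c Concentration(s), non-negative.
#' @param k Half-saturation constant, strictly positive.
#' @return Numeric in \[0, 1).
#' @export
monod <- function(c, k) {
  if (any(k <= 0)) stop("half-saturation constant must be > 0", call. = FALSE)
  ifelse(c <= 0, 0, c / (c + k))
}

check_state <- function(state) {
  v <- state_vec(state)
  if (any(!is.finite(v)) || any(v < 0))
    stop("invalid state: components must be finite and non-negative",
         call. = FALSE)
  invisible(v)
}

#' Growth terms of the two mutualist strains
#'
#' Time derivatives of the strain densities: each strain grows at its
#' maximum rate scaled by Monod saturation in the partner-supplied
#' metabolite and by the shared logistic crowding factor
#' `1 - (xL + xA + xO) / K`.
#'
#' @param state A [cf_state()].
#' @param params A [cf_params()].
#' @return Named list with components `dxL`, `dxA`.
#' @export
#' @examples
#' p <- cf_preset("informed")
#' strain_rhs(cf_state(0.2, 0.2, cA = 0.1, cL = 0.1), p)
strain_rhs <- function(state, params) {
  check_state(state)
  validate_params(params)
  crowd <- 1 - (state$xL + state$xA + state$xO) / params$K
  list(dxL = state$xL * params$r1 * monod(state$cA, params$kcA) * crowd,
       dxA = state$xA * params$r2 * monod(state$cL, params$kcL) * crowd)
}

#' Production/uptake terms of the free metabolite pools
#'
#' Adenine is secreted constitutively by the ADE-up strain (and the
#' ultimate overproducer, when present) at rate `beta1` and consumed by the
#' LYS-up strain with Monod-saturated uptake at maximum rate `gamma1`;
#' symmetrically for lysine.
#'
#' @inheritParams strain_rhs
#' @return Named list with components `dcA`, `dcL`.
#' @export
metabolite_rhs <- function(state, params) {
  check_state(state)
  validate_params(params)
  list(dcA = params$beta1 * (state$xA + state$xO) -
         params$gamma1 * monod(state$cA, params$kcA) * state$xL,
       dcL = params$beta2 * (state$xL + state$xO) -
         params$gamma2 * monod(state$cL, params$kcL) * state$xA)
}

#' Growth term of the ultimate overproducer
#'
#' The hypothetical strain that overproduces both metabolites grows at a
#' flat rate `ro` independent of metabolite concentrations, limited only by
#' the shared crowding factor.
#'
#' @inheritParams strain_rhs
#' @return Named list with component `dxO`.
#' @export
overproducer_rhs <- function(state, params) {
  check_state(state)
  validate_params(params)
  crowd <- 1 - (state$xL + state$xA + state$xO) / params$K
  list(dxO = state$xO * params$ro * crowd)
}

#' Assembled right-hand side of the full system
#'
#' Concatenates [strain_rhs()], [overproducer_rhs()] and
#' [metabolite_rhs()] into the single derivative vector integrators see,
#' in the canonical order `(xL, xA, xO, cA, cL)`. Optional constant influx
#' terms implement the flux formulation of continuous supplementation.
#'
#' @inheritParams strain_rhs
#' @param influxA,influxL Constant metabolite influx rates (concentration
#'   per time), default 0.
#' @return Named numeric vector of the five derivatives.
#' @export
cf_rhs <- function(state, params, influxA = 0, influxL = 0) {
  s <- strain_rhs(state, params)
  o <- overproducer_rhs(state, params)
  m <- metabolite_rhs(state, params)
  c(dxL = s$dxL, dxA = s$dxA, dxO = o$dxO,
    dcA = m$dcA + influxA, dcL = m$dcL + influxL)
}

# RHS on bare vectors, used by the pure-R reference integrator; no
# validation so it can be called hundreds of thousands of times.
cf_rhs_vec <- function(t, y, pv) {
  crowd <- 1 - (y[1] + y[2] + y[3]) / pv[3]
  mA <- if (y[4] <= 0) 0 else y[4] / (y[4] + pv[8])
  mL <- if (y[5] <= 0) 0 else y[5] / (y[5] + pv[9])
  c(y[1] * pv[1] * mA * crowd,
    y[2] * pv[2] * mL * crowd,
    y[3] * pv[10] * crowd,
    pv[4] * (y[2] + y[3]) - pv[6] * mA * y[1] + pv[11],
    pv[5] * (y[1] + y[3]) - pv[7] * mL * y[2] + pv[12])
}
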