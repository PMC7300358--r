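#' Model parameters for the cross-feeding system
#'
#' Bundle of all rate constants of the two-strain cross-feeding model and
#' its three-strain extension with an "ultimate overproducer". All
#' quantities are in normalized, dimensionless model units (carrying
#' capacity `K = 1` in the shipped presets); conversion to experimental
#' units (cells/ml, ug/ml) is the concern of the synthetic-data generators,
#' never of the dynamical core.
#'
#' @param r1 Maximum growth rate of the lysine overproducer (LYS-up), which
#'   is limited by adenine.
#' @param r2 Maximum growth rate of the adenine overproducer (ADE-up),
#'   which is limited by lysine.
#' @param K Carrying capacity of the culture vessel (total density units).
#' @param beta1,beta2 Constitutive production rates of adenine (by ADE-up)
#'   and lysine (by LYS-up), concentration per density per time.
#' @param gamma1,gamma2 Maximum uptake rates of adenine (by LYS-up) and
#'   lysine (by ADE-up).
#' @param kcA,kcL Normalized half-saturation constants for adenine and
#'   lysine. Must be strictly positive.
#' @param ro Flat, metabolite-independent growth rate of the ultimate
#'   overproducer; 0 disables the third strain.
#' @return An object of class `cf_params` (a named list).
#' @seealso [cf_preset()] for the shipped "informed" and "neutral" sets,
#'   [read_params()] to load a set from a YAML config file.
#' @export
#' @examples
#' cf_params(r1 = 1, r2 = 2, kcA = 2, kcL = 1)
cf_params <- function(r1 = 1, r2 = 1, K = 1, beta1 = 0.1, beta2 = 0.1,
                      gamma1 = 1, gamma2 = 1, kcA = 1, kcL = 1, ro = 0) {
  p <- list(r1 = r1, r2 = r2, K = K, beta1 = beta1, beta2 = beta2,
            gamma1 = gamma1, gamma2 = gamma2, kcA = kcA, kcL = kcL, ro = ro)
  validate_params(p)
  structure(p, class = "cf_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar",
                             call. = FALSE)
  }
  pos <- c("r1", "r2", "K", "beta1", "beta2", "gamma1", "gamma2")
  for (nm in pos) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative",
                          call. = FALSE)
  }
  if (p$K <= 0) stop("carrying capacity K must be strictly positive",
                     call. = FALSE)
  # k = 0 would make the Monod fraction 0/0 at c = 0
  if (p$kcA <= 0 || p$kcL <= 0)
    stop("half-saturation constants kcA, kcL must be strictly positive",
         call. = FALSE)
  if (p$ro < 0) stop("overproducer growth rate ro must be >= 0",
                     call. = FALSE)
  invisible(p)
}

#' Named parameter presets
#'
#' Two presets ship with the package: `"informed"`, the experimentally
#' informed set in which the ADE-up strain grows twice as fast and
#' half-saturates at twice the concentration of the LYS-up strain
#' (r1 = 1, r2 = 2, kcA = 2, kcL = 1); and `"neutral"`, the fully
#' symmetric set (r1 = r2 = 1, kcA = kcL = 1). Both use
#' beta = 0.1, gamma = 1, K = 1.
#'
#' @param name Preset name, `"informed"` or `"neutral"`.
#' @param ... Overrides passed on to [cf_params()] fields.
#' @return A `cf_params` object.
#' @export
#' @examples
#' cf_preset("informed")
#' cf_preset("neutral", ro = 0.5)
cf_preset <- function(name = c("informed", "neutral"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    informed = list(r1 = 1, r2 = 2, K = 1, beta1 = 0.1, beta2 = 0.1,
                    gamma1 = 1, gamma2 = 1, kcA = 2, kcL = 1, ro = 0),
    neutral  = list(r1 = 1, r2 = 1, K = 1, beta1 = 0.1, beta2 = 0.1,
                    gamma1 = 1, gamma2 = 1, kcA = 1, kcL = 1, ro = 0))
  do.call(cf_params, modifyList(base, list(...)))
}

#' @export
print.cf_params <- function(x, ...) {
  cat("<cf_params>\n")
  cat(sprintf("  growth:  r1 = %g, r2 = %g, ro = %g, K = %g\n",
              x$r1, x$r2, x$ro, x$K))
  cat(sprintf("  exchange: beta = (%g, %g), gamma = (%g, %g)\n",
              x$beta1, x$beta2, x$gamma1, x$gamma2))
  cat(sprintf("  half-saturation: kcA = %g, kcL = %g\n", x$kcA, x$kcL))
  invisible(x)
}

#' Read or write model parameters as a YAML config
#'
#' The file holds a flat mapping whose keys are the [cf_params()] field
#' names; missing keys take the defaults of [cf_params()], or of a named
#' preset given under a `preset` key.
#'
#' @param path Path of the YAML file.
#' @param params A `cf_params` object (for writing).
#' @return `read_params()` returns a `cf_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset
  cfg$preset <- NULL
  unknown <- setdiff(names(cfg), names(formals(cf_params)))
  if (length(unknown))
    stop("unknown parameter key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(preset)) do.call(cf_preset, c(list(name = preset), cfg))
  else do.call(cf_params, cfg)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cf_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' System state of the cross-feeding culture
#'
#' One snapshot of the culture: densities of the two mutualists and the
#' optional ultimate overproducer, plus free metabolite concentrations.
#' The canonical component order, used for every state vector in the
#' package, is `(xL, xA, xO, cA, cL)`.
#'
#' @param xL Density of the LYS-up strain.
#' @param xA Density of the ADE-up strain.
#' @param xO Density of the ultimate overproducer (0 when absent).
#' @param cA,cL Free adenine and lysine concentrations.
#' @param t Time, in model time units.
#' @return An object of class `cf_state`.
#' @export
#' @examples
#' cf_state(xL = 0.16, xA = 0.04)
cf_state <- function(xL, xA, xO = 0, cA = 0, cL = 0, t = 0) {
  s <- c(xL = xL, xA = xA, xO = xO, cA = cA, cL = cL)
  if (any(!is.finite(s))) stop("state components must be finite",
                               call. = FALSE)
  if (any(s < 0)) stop("state components must be non-negative",
                       call. = FALSE)
  structure(list(xL = xL, xA = xA, xO = xO, cA = cA, cL = cL, t = t),
            class = "cf_state")
}

#' Initial state from an ADE-up fraction and total density
#'
#' Convenience constructor mirroring the experimental design: cultures are
#' inoculated at a fraction of carrying capacity (1/20 in the lab protocol;
#' the modelling convention here is total density 0.2) and mixed at a given
#' ADE-up : LYS-up ratio, with no free metabolites.
#'
#' @param frac_ade Initial relative fraction of the ADE-up strain among the
#'   mutualists, in (0, 1).
#' @param total Initial total strain density.
#' @param frac_o Fraction of the total density given to the ultimate
#'   overproducer (default 0).
#' @param cA,cL Initial free metabolite concentrations.
#' @return A `cf_state`.
#' @export
cf_init <- function(frac_ade, total = 0.2, frac_o = 0, cA = 0, cL = 0) {
  stopifnot(frac_ade >= 0, frac_ade <= 1, frac_o >= 0, frac_o < 1,
            total > 0)
  mut <- total * (1 - frac_o)
  cf_state(xL = mut * (1 - frac_ade), xA = mut * frac_ade,
           xO = total * frac_o, cA = cA, cL = cL)
}

#' @export
print.cf_state <- function(x, ...) {
  cat(sprintf(
    "<cf_state t = %g>  xL = %.6g  xA = %.6g  xO = %.6g  cA = %.6g  cL = %.6g\n",
    x$t, x$xL, x$xA, x$xO, x$cA, x$cL))
  invisible(x)
}

state_vec <- function(state) {
  c(xL = state$xL, xA = state$xA, xO = state$xO, cA = state$cA, cL = state$cL)
}

vec_state <- function(v, t = 0) {
  cf_state(xL = v[[1]], xA = v[[2]], xO = v[[3]], cA = v[[4]], cL = v[[5]],
           t = t)
}

params_vec <- function(params, influxA = 0, influxL = 0) {
  c(params$r1, params$r2, params$K, params$beta1, params$beta2,
    params$gamma1, params$gamma2, params$kcA, params$kcL, params$ro,
    influxA, influxL)
}
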