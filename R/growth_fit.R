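#' Single-strain growth-rate dataset
#'
#' Growth rates of one auxotrophic strain measured at a series of
#' supplement concentrations (the metabolite the strain cannot make:
#' lysine for ADE-up, adenine for LYS-up), with replicate structure
#' preserved. This is the input to Monod fitting.
#'
#' @param strain Strain label, `"ADE"` or `"LYS"`.
#' @param concentration Supplement concentrations, ug/ml, `>= 0`.
#' @param growth_rate Measured growth rates (same length).
#' @param replicate Replicate identifiers (same length).
#' @param metabolite Which supplement was varied; defaults to the
#'   metabolite the strain is auxotrophic for.
#' @return A `cf_growth_dataset` (data.frame with attributes).
#' @export
growth_dataset <- function(strain = c("ADE", "LYS"), concentration,
                           growth_rate, replicate = 1L,
                           metabolite = NULL) {
  strain <- match.arg(strain)
  if (is.null(metabolite))
    metabolite <- if (strain == "ADE") "lysine" else "adenine"
  n <- length(concentration)
  stopifnot(length(growth_rate) == n)
  replicate <- rep_len(replicate, n)
  if (any(concentration < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(data.frame(strain = strain, concentration = concentration,
                       growth_rate = growth_rate, replicate = replicate),
            class = c("cf_growth_dataset", "data.frame"),
            metabolite = metabolite)
}

#' Read growth-rate data from delimited text
#'
#' Expects columns `strain`, `concentration_ug_ml`, `growth_rate`,
#' `replicate` (comma- or tab-separated, inferred from the filename or
#' `sep`).
#'
#' @param path File path.
#' @param strain Optional filter: keep only this strain's records.
#' @param sep Field separator; default inferred (`"\t"` for `.tsv`).
#' @return A `cf_growth_dataset`.
#' @export
read_growth_csv <- function(path, strain = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("strain", "concentration_ug_ml", "growth_rate", "replicate")
  if (!all(need %in% names(df)))
    stop("growth table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(strain)) df <- df[df$strain == strain, ]
  if (!nrow(df)) stop("no records", call. = FALSE)
  growth_dataset(strain = unique(df$strain)[1],
                 concentration = df$concentration_ug_ml,
                 growth_rate = df$growth_rate,
                 replicate = df$replicate)
}

#' Fit a Monod (Michaelis-Menten) curve to growth-rate data
#'
#' Least-squares fit of `rate(s) = vmax * s / (s + k_half)` to the
#' replicate-level records (all points jointly, so the residual spread
#' reflects biological replication; set `use_means = TRUE` to fit
#' per-concentration means instead). The curve passes through the origin
#' by construction -- auxotrophs cannot grow unsupplemented -- so `s = 0`
#' points are retained with model value 0 and no basal-offset parameter is
#' fitted. Unweighted least squares is used; the choice of loss is a
#' package convention, not an estimate from data.
#'
#' Initialization: `vmax0` is the largest observed rate and `k0` the
#' concentration whose mean rate is nearest `vmax0 / 2`; the problem is
#' well-conditioned, and the fit is invariant to record order.
#'
#' @param data A [growth_dataset()] with at least 3 distinct
#'   concentrations.
#' @param use_means Fit per-concentration means instead of all replicate
#'   points.
#' @return A `cf_monod_fit`: list with `vmax`, `k_half`, standard errors
#'   `vmax_se`, `k_half_se`, `sigma` (residual SD), `n`, `k_boundary`
#'   (flag: `k_half` collapsed to the 0 boundary, i.e. the data are
#'   saturated at every measured concentration), and the underlying `nls`
#'   fit.
#' @export
#' @examples
#' s <- c(0, 0.1, 1, 10, 25, 50, 100, 200)
#' d <- growth_dataset("ADE", s, 25.4 * s / (s + 32.9))
#' fit_monod(d)
fit_monod <- function(data, use_means = FALSE) {
  stopifnot(inherits(data, "cf_growth_dataset"))
  if (length(unique(data$concentration)) < 3)
    stop("need at least 3 distinct concentrations to fit a Monod curve",
         call. = FALSE)
  df <- data.frame(s = data$concentration, rate = data$growth_rate)
  if (use_means) {
    agg <- aggregate(rate ~ s, df, mean)
    df <- agg
  }
  vmax0 <- max(df$rate)
  if (vmax0 <= 0) stop("all growth rates are <= 0; cannot fit",
                       call. = FALSE)
  means <- aggregate(rate ~ s, df, mean)
  pos <- means[means$s > 0, ]
  k0 <- pos$s[which.min(abs(pos$rate - vmax0 / 2))]
  if (!length(k0) || k0 <= 0) k0 <- max(df$s) / 10

  fit <- tryCatch(
    nls(rate ~ vmax * s / (s + k_half), data = df,
        start = list(vmax = vmax0, k_half = k0),
        algorithm = "port", lower = c(vmax = 1e-12, k_half = 1e-12),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e)
      stop("Monod fit failed to converge: ", conditionMessage(e),
           "\n  starts were vmax0 = ", signif(vmax0, 4), ", k0 = ",
           signif(k0, 4), call. = FALSE))
  co <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(vmax = NA_real_, k_half = NA_real_))
  sigma <- tryCatch(summary(fit)$sigma, error = function(e) {
    sqrt(sum(residuals(fit)^2) / max(1, nrow(df) - 2))
  })
  k_boundary <- co[["k_half"]] < 1e-6 * max(df$s)
  if (k_boundary)
    warning("fitted k_half is at the 0 boundary: growth is saturated at ",
            "every measured concentration", call. = FALSE)
  structure(list(vmax = co[["vmax"]], k_half = co[["k_half"]],
                 vmax_se = se[["vmax"]], k_half_se = se[["k_half"]],
                 sigma = sigma, n = nrow(df),
                 k_boundary = k_boundary, strain = data$strain[1],
                 metabolite = attr(data, "metabolite"), fit = fit),
            class = "cf_monod_fit")
}

#' @export
print.cf_monod_fit <- function(x, ...) {
  cat(sprintf(
    "<cf_monod_fit %s (%s)> vmax = %.4g (se %.3g), k_half = %.4g (se %.3g), n = %d\n",
    x$strain, x$metabolite, x$vmax, x$vmax_se, x$k_half, x$k_half_se, x$n))
  if (x$k_boundary) cat("  [k_half at 0 boundary: saturated data]\n")
  invisible(x)
}

#' Predicted Monod curve of a fit
#'
#' @param object A `cf_monod_fit`.
#' @param s Concentrations at which to evaluate.
#' @param ... Unused.
#' @return Predicted growth rates.
#' @export
predict.cf_monod_fit <- function(object, s, ...) {
  object$vmax * s / (s + object$k_half)
}

#' Normalize two strain fits to model parameters
#'
#' Converts the per-strain Monod fits into the dimensionless growth and
#' half-saturation parameters of the dynamical model, everything relative
#' to the LYS-up strain's fit: `r1 = 1`, `r2 = vmax_ADE / vmax_LYS`,
#' `kcL = 1`, `kcA = k_ADE / k_LYS`. With `round_to_preset = TRUE` the
#' ratios are rounded to the nearest integer-valued preset (the convention
#' behind the "informed" parameter set, where both ratios are ~2).
#'
#' @param fit_ADE,fit_LYS `cf_monod_fit` objects for the two strains.
#' @param round_to_preset Round the normalized ratios (default `FALSE`:
#'   exact ratios are propagated).
#' @return Named list with `r1`, `r2`, `kcA`, `kcL` (a `cf_params`
#'   fragment, e.g. for `do.call(cf_preset, c(list("informed"), frag))`).
#' @export
#' @examples
#' # Table-style values: vmax 25.4 vs 13, k 32.9 vs 15.3 -> ratios ~ 2
#' a <- list(vmax = 25.4, k_half = 32.9)
#' l <- list(vmax = 13, k_half = 15.3)
#' class(a) <- class(l) <- "cf_monod_fit"
#' normalize_params(a, l)
normalize_params <- function(fit_ADE, fit_LYS, round_to_preset = FALSE) {
  stopifnot(inherits(fit_ADE, "cf_monod_fit"),
            inherits(fit_LYS, "cf_monod_fit"))
  out <- list(r1 = 1,
              r2 = fit_ADE$vmax / fit_LYS$vmax,
              kcA = fit_ADE$k_half / fit_LYS$k_half,
              kcL = 1)
  if (round_to_preset) {
    out$r2 <- round(out$r2)
    out$kcA <- round(out$kcA)
  }
  out
}

#' Write a fit report as JSON
#'
#' @param fit A `cf_monod_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cf_monod_fit"))
  rec <- fit[c("strain", "metabolite", "vmax", "k_half", "vmax_se",
               "k_half_se", "sigma", "n", "k_boundary")]
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
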