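#' Minimal eco-evolutionary reduction of the mutualism
#'
#' A two-dimensional reduction of the cross-feeding system in terms of
#' total population density `z = xL + xA` (ecology) and ADE-up fraction
#' `f = xA / z` (evolution), with metabolites eliminated: each strain's
#' growth is proportional to its partner's density (the cross-feeding
#' benefit scales with partner abundance), crowding is logistic, and an
#' explicit uniform death rate `d` is included:
#'
#' \deqn{\dot z = (r_1 + r_2)\, f (1-f)\, z^2 (1-z) - d z}
#' \deqn{\dot f = z (1-z)\, f (1-f)\, (r_2 - f (r_1 + r_2))}
#'
#' The fraction dynamics are independent of `d`; the interior fraction
#' equilibrium is `f* = r2 / (r1 + r2)`. At `f*`, nontrivial density
#' equilibria solve a quadratic whose two roots (stable upper, unstable
#' lower branch) collide in a saddle-node bifurcation at density 1/2 --
#' structurally, independent of the growth rates -- beyond which the only
#' stable state is extinction.
#'
#' @param r1,r2 Growth rates of the LYS-up and ADE-up strains.
#' @param d Death rate, `>= 0`.
#' @return `minimal_params()` returns a `cf_minimal_params` object.
#' @name minimal_model
NULL

#' @rdname minimal_model
#' @export
minimal_params <- function(r1 = 1, r2 = 2, d = 0) {
  stopifnot(is.numeric(r1), is.numeric(r2), is.numeric(d),
            length(r1) == 1, length(r2) == 1, length(d) == 1)
  if (r1 <= 0 || r2 <= 0) stop("growth rates must be > 0", call. = FALSE)
  if (d < 0) stop("death rate must be >= 0", call. = FALSE)
  structure(list(r1 = r1, r2 = r2, d = d), class = "cf_minimal_params")
}

#' Right-hand side of the minimal model
#'
#' @param z Total population density, in \[0, 1\].
#' @param f ADE-up fraction, in \[0, 1\].
#' @param p A [minimal_params()].
#' @return Named numeric vector `c(dz, df)`.
#' @export
#' @examples
#' minimal_rhs(0.5, 2 / 3, minimal_params(1, 2, 0.1))
minimal_rhs <- function(z, f, p) {
  stopifnot(inherits(p, "cf_minimal_params"))
  if (!is.finite(z) || z < 0 || z > 1)
    stop("density z must lie in [0, 1]", call. = FALSE)
  if (!is.finite(f) || f < 0 || f > 1)
    stop("fraction f must lie in [0, 1]", call. = FALSE)
  g <- (p$r1 + p$r2) * f * (1 - f)
  c(dz = g * z^2 * (1 - z) - p$d * z,
    df = z * (1 - z) * f * (1 - f) * (p$r2 - f * (p$r1 + p$r2)))
}

# interior fraction equilibrium and the effective growth factor there
minimal_fstar <- function(p) p$r2 / (p$r1 + p$r2)
minimal_gstar <- function(p) p$r1 * p$r2 / (p$r1 + p$r2)

#' Equilibrium density branches of the minimal model over death rates
#'
#' At the interior fraction equilibrium `f*`, nontrivial equilibria of the
#' density satisfy `g* z (1 - z) = d` with `g* = r1 r2 / (r1 + r2)`, a
#' quadratic in `z`. For `d < d* = g*/4` there are two roots: the stable
#' upper branch (attracting) and the unstable lower branch (the Allee
#' threshold below which the population collapses). The branches coalesce
#' at `z = 1/2` and annihilate in a saddle-node bifurcation at `d = d*`;
#' past it, extinction is the only stable state.
#'
#' @param d_values Death-rate values; should include 0 and extend past the
#'   bifurcation.
#' @param r1,r2 Growth rates.
#' @return A `cf_branch_diagram`: data.frame with columns `d`, `stable_z`,
#'   `unstable_z` (`NA` past the bifurcation), with the saddle-node
#'   location in attributes `d_star`, `z_star`.
#' @export
#' @examples
#' equilibrium_branches(seq(0, 0.25, by = 0.05), r1 = 1, r2 = 2)
equilibrium_branches <- function(d_values, r1 = 1, r2 = 2) {
  p <- minimal_params(r1, r2, 0)
  gs <- minimal_gstar(p)
  if (!is.finite(minimal_fstar(p)))
    stop("no interior fraction equilibrium", call. = FALSE)
  disc <- 1 - 4 * d_values / gs
  sq <- ifelse(disc >= 0, sqrt(pmax(disc, 0)), NA_real_)
  bif <- find_bifurcation(r1, r2)
  structure(data.frame(d = d_values,
                       stable_z = (1 + sq) / 2,
                       unstable_z = (1 - sq) / 2),
            class = c("cf_branch_diagram", "data.frame"),
            d_star = bif$d_star, z_star = bif$z_star, r1 = r1, r2 = r2)
}

#' Saddle-node bifurcation of the minimal model
#'
#' Location `(d_star, z_star)` where the stable and unstable density
#' branches meet. The analytic form follows from the vanishing
#' discriminant of the equilibrium quadratic: `d_star = r1 r2 / (4 (r1 +
#' r2))` and `z_star = 1/2` (independent of the growth rates). The
#' `"continuation"` method instead locates the largest death rate for
#' which an equilibrium exists by bisection on the maximized density
#' nullcline -- an independent numeric route, used to cross-check the
#' closed form.
#'
#' @param r1,r2 Growth rates.
#' @param method `"analytic"` (default) or `"continuation"`.
#' @param tol Bisection tolerance for the continuation method.
#' @return List with `d_star` and `z_star`.
#' @export
#' @examples
#' find_bifurcation(1, 2) # d_star = 1/6, z_star = 0.5
find_bifurcation <- function(r1, r2, method = c("analytic", "continuation"),
                             tol = 1e-10) {
  method <- match.arg(method)
  p <- minimal_params(r1, r2, 0)
  gs <- minimal_gstar(p)
  if (method == "analytic")
    return(list(d_star = gs / 4, z_star = 0.5))
  # continuation: d_star is the largest d with a root of g* z (1 - z) = d,
  # i.e. the maximum over z of the nullcline; locate it by golden-section
  # search without using the closed form.
  opt <- optimize(function(z) gs * z * (1 - z), c(0, 1), maximum = TRUE,
                  tol = tol)
  list(d_star = opt$objective, z_star = opt$maximum)
}

#' Integrate the minimal model
#'
#' Pure-R adaptive integration of the `(z, f)` system, mainly for
#' stability checks of the equilibrium branches.
#'
#' @param p A [minimal_params()].
#' @param z0,f0 Initial density and fraction.
#' @param t_end End time.
#' @param by Reporting step.
#' @return Data.frame with columns `t`, `z`, `f`.
#' @export
minimal_simulate <- function(p, z0, f0, t_end = 100, by = 1) {
  stopifnot(inherits(p, "cf_minimal_params"))
  times <- seq(0, t_end, by = by)
  rhs <- function(t, y, p) {
    y <- pmin(pmax(y, 0), 1) # guard tiny overshoots at the boundary
    g <- (p$r1 + p$r2) * y[2] * (1 - y[2])
    c(g * y[1]^2 * (1 - y[1]) - p$d * y[1],
      y[1] * (1 - y[1]) * y[2] * (1 - y[2]) * (p$r2 - y[2] * (p$r1 + p$r2)))
  }
  m <- rk45(rhs, c(z0, f0), times, p = p, rtol = 1e-9, atol = 1e-12)
  data.frame(t = times, z = m[, 1], f = m[, 2])
}

#' Write a branch diagram as CSV (+ optional JSON bifurcation record)
#'
#' @param bd A `cf_branch_diagram`.
#' @param csv_path Output CSV path (`d, stable_z, unstable_z`).
#' @param json_path Optional path for a JSON record of
#'   `(d_star, z_star)`.
#' @return `csv_path`, invisibly.
#' @export
write_branches <- function(bd, csv_path, json_path = NULL) {
  stopifnot(inherits(bd, "cf_branch_diagram"))
  write.csv(as.data.frame(bd), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(d_star = attr(bd, "d_star"),
                              z_star = attr(bd, "z_star"),
                              r1 = attr(bd, "r1"), r2 = attr(bd, "r2")),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
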