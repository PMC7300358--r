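#' Experimental design for synthetic data generation
#'
#' Captures the batch-culture design emulated by the synthetic-data
#' generators: cultures grown to a carrying capacity of about 5e7 cells,
#' inoculated at a 1-in-20 dilution, sampled every 24 h over 120-144 h in
#' biological triplicate, with strain ratios estimated by replica-plating
#' a fixed number of colonies. The plate-count depth (colonies typed per
#' sample) is a design parameter; 100 is a realistic plate count.
#'
#' @param carrying_capacity_cells Culture capacity in cells (default 5e7).
#' @param dilution Initial density as a fraction of capacity (default
#'   1/20).
#' @param sample_interval_h Sampling interval, hours (default 24).
#' @param duration_h Experiment duration, hours (default 144).
#' @param replicates Biological replicates (default 3).
#' @param plate_count_depth Colonies replica-plated per sample (default
#'   100).
#' @param hours_per_time_unit Mapping from model time to hours, used only
#'   by the generators (default 1).
#' @param seed Integer random seed; identical seeds give identical
#'   datasets.
#' @return An `cf_design` list.
#' @export
experiment_design <- function(carrying_capacity_cells = 5e7,
                              dilution = 1 / 20, sample_interval_h = 24,
                              duration_h = 144, replicates = 3,
                              plate_count_depth = 100,
                              hours_per_time_unit = 1, seed = 1L) {
  stopifnot(carrying_capacity_cells > 0, dilution > 0, dilution < 1,
            sample_interval_h > 0, duration_h > 0, replicates >= 1,
            hours_per_time_unit > 0)
  if (plate_count_depth <= 0)
    stop("plate_count_depth must be positive", call. = FALSE)
  structure(list(carrying_capacity_cells = carrying_capacity_cells,
                 dilution = dilution, sample_interval_h = sample_interval_h,
                 duration_h = duration_h, replicates = replicates,
                 plate_count_depth = plate_count_depth,
                 hours_per_time_unit = hours_per_time_unit,
                 seed = as.integer(seed)),
            class = "cf_design")
}

# run code under a private RNG stream so generators are pure in (input, seed)
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic single-strain growth-rate dataset
#'
#' Draws replicate growth-rate measurements on a Monod curve with known
#' truth: `rate = vmax * s / (s + k_half)` plus Gaussian noise with
#' standard deviation `noise_sd_fraction * vmax`, truncated at 0 (a plate
#' cannot yield a negative rate). The default concentration series is the
#' experimental one: 0, 0.1, 1, 10, 25, 50, 100, 200 ug/ml.
#'
#' @param vmax,k_half Generating Monod truth (e.g. the fitted
#'   experimental values 25.4 and 32.9 for the ADE-up strain, 13 and 15.3
#'   for LYS-up).
#' @param design An [experiment_design()] (supplies replicates and seed).
#' @param noise_sd_fraction Noise SD as a fraction of `vmax` (default
#'   0.05; 0 gives exact curve values).
#' @param concentrations Supplement concentrations, ug/ml.
#' @param strain Strain label for the dataset.
#' @return A [growth_dataset()].
#' @export
#' @examples
#' d <- generate_growth_dataset(25.4, 32.9, experiment_design(seed = 7))
#' fit_monod(d)
generate_growth_dataset <- function(vmax, k_half,
                                    design = experiment_design(),
                                    noise_sd_fraction = 0.05,
                                    concentrations = c(0, 0.1, 1, 10, 25,
                                                       50, 100, 200),
                                    strain = "ADE") {
  stopifnot(inherits(design, "cf_design"), vmax > 0, k_half > 0)
  if (noise_sd_fraction < 0)
    stop("noise_sd_fraction must be non-negative", call. = FALSE)
  s <- rep(concentrations, times = design$replicates)
  rep_id <- rep(seq_len(design$replicates), each = length(concentrations))
  truth <- vmax * s / (s + k_half)
  rates <- if (noise_sd_fraction == 0) truth else
    with_seed(design$seed,
              pmax(0, truth + rnorm(length(s), 0,
                                    noise_sd_fraction * vmax)))
  growth_dataset(strain = strain, concentration = s, growth_rate = rates,
                 replicate = rep_id)
}

#' Sample plate-count coculture data from a model trajectory
#'
#' Emulates the CFU / replica-plating measurement: at each sampling time
#' (every `sample_interval_h` hours, mapped onto model time), the total
#' CFU density is a Poisson draw around `density x carrying capacity`
#' (thinned through a counting dilution so expected colony numbers are
#' realistic, then scaled back to CFU/ml-equivalent units), and strain
#' identities of `plate_count_depth` colonies are drawn multinomially from
#' the trajectory's relative fractions. Counting noise is multinomial on
#' colonies -- not Gaussian -- which gives the correct small-count
#' behaviour at extreme fractions.
#'
#' @param traj A `cf_trajectory` (from [cf_simulate()]).
#' @param design An [experiment_design()].
#' @return Data.frame with one row per (time, replicate): `time_h`,
#'   `replicate`, `total_cfu` (estimated), `n_LYS`, `n_ADE`, `n_O` (colony
#'   counts), and `est_frac_LYS`, `est_frac_ADE`, `est_frac_O`.
#' @export
generate_coculture_counts <- function(traj, design = experiment_design()) {
  stopifnot(inherits(traj, "cf_trajectory"), inherits(design, "cf_design"))
  if (design$plate_count_depth <= 0)
    stop("plate_count_depth must be positive", call. = FALSE)
  t_h <- seq(0, design$duration_h, by = design$sample_interval_h)
  t_model <- t_h / design$hours_per_time_unit
  t_model <- t_model[t_model <= traj$t_end]
  t_h <- t_h[seq_along(t_model)]
  idx <- match(round(t_model), traj$times)
  if (anyNA(idx))
    stop("sampling times fall off the trajectory reporting grid",
         call. = FALSE)
  fr <- fractions(traj)
  dens <- rowSums(traj$states[, 1:3, drop = FALSE])
  # thin to countable colony numbers, then scale the estimate back up
  count_dilution <- design$carrying_capacity_cells / 500

  R <- design$replicates
  with_seed(design$seed + 1L, {
    rows <- lapply(seq_along(idx), function(j) {
      i <- idx[j]
      p <- c(fr$frac_LYS[i], fr$frac_ADE[i], fr$frac_O[i])
      lambda <- dens[i] * design$carrying_capacity_cells / count_dilution
      tot <- rpois(R, lambda) * count_dilution
      counts <- if (anyNA(p)) matrix(0L, 3, R)
                else rmultinom(R, design$plate_count_depth, p)
      depth <- colSums(counts)
      est <- sweep(counts, 2, ifelse(depth > 0, depth, NA_real_), "/")
      data.frame(time_h = t_h[j], replicate = seq_len(R), total_cfu = tot,
                 n_LYS = counts[1, ], n_ADE = counts[2, ],
                 n_O = counts[3, ], est_frac_LYS = est[1, ],
                 est_frac_ADE = est[2, ], est_frac_O = est[3, ])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a growth dataset in the CSV dialect consumed by the fitter
#'
#' @param data A [growth_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(data, path) {
  stopifnot(inherits(data, "cf_growth_dataset"))
  out <- data.frame(strain = data$strain,
                    concentration_ug_ml = data$concentration,
                    growth_rate = data$growth_rate,
                    replicate = data$replicate)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
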