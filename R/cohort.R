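#' Configuration for a synthetic paddle-IRE cohort
#'
#' Describes the generative model for a study-like cohort: each animal
#' contributes three application sites (one per treatment group), with
#' per-group peak-current distributions and thickness ranges taken from
#' the study's ablative characteristics, and a per-animal true necrosis
#' threshold shared across its three sites (which is what makes the
#' within-subject analysis meaningful).
#'
#' The per-animal, per-group true threshold is
#' \eqn{\theta_{ig} = \mu_g + b_i}, with \eqn{b_i \sim N(0,
#' \sigma_b)} the animal effect, truncated to stay positive.  The serial
#' group's mean defaults to the pooled single-application mean divided by
#' `serial_reduction`, modelling the serial effect at the threshold level
#' (not as pulse-accumulation physics).
#'
#' @param n_pigs Number of animals (default 12).
#' @param paddle_radius Paddle radius, mm (default 12.5).
#' @param thickness_range Integer mm range for the per-site tissue
#'   thickness, drawn discrete-uniform per site (default 4--12).
#' @param group_current_mean,group_current_sd Named per-group mean/SD of
#'   the site-level peak current in A (defaults 25.3/3.1, 32.4/5.4,
#'   22.4/2.9 for 50J, 100J, 4x50J).
#' @param true_threshold_mean Optional named vector of per-group true
#'   threshold means (A/cm\eqn{^2}).  Default: 4.3 and 5.1 for the single
#'   groups and their pooled mean / `serial_reduction` for the serial
#'   group.
#' @param serial_reduction Factor by which serial application lowers the
#'   effective threshold (default 1.4).
#' @param threshold_sd_between_pigs SD of the shared animal effect,
#'   A/cm\eqn{^2} (default 0.25).
#' @param histology_noise_sd Measurement noise on section half-widths, mm
#'   (default 0.5).
#' @param pulse_jitter_sd Within-site SD of per-pulse peak currents in the
#'   serial group, A (default 0.3).
#' @param arcing_prob Named per-group probability of an arcing artefact
#'   flag (default 0, 2/12, 0).
#' @param transition_fraction Delivered-dose fraction of the necrosis
#'   threshold down to which tissue shows transition change (default
#'   0.75).
#' @param vital_island_prob Named per-group probability that a section
#'   shows vital islands amid necrosis (default 1, 0.5, 0).
#' @param n_sections_range Integer range of histology sections per site
#'   (default 2--4).
#' @param resistance_mean,resistance_sd Site-level peak resistance
#'   distribution in ohm used to synthesise plausible voltages (defaults
#'   30, 6).
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return A validated list of class `cohort_config`.
#' @examples
#' cohort_config(n_pigs = 6, seed = 42)
#' @export
cohort_config <- function(n_pigs = 12,
                          paddle_radius = 12.5,
                          thickness_range = c(4L, 12L),
                          group_current_mean = c("50J" = 25.3, "100J" = 32.4, "4x50J" = 22.4),
                          group_current_sd = c("50J" = 3.1, "100J" = 5.4, "4x50J" = 2.9),
                          true_threshold_mean = NULL,
                          serial_reduction = 1.4,
                          threshold_sd_between_pigs = 0.25,
                          histology_noise_sd = 0.5,
                          pulse_jitter_sd = 0.3,
                          arcing_prob = c("50J" = 0, "100J" = 2 / 12, "4x50J" = 0),
                          transition_fraction = 0.75,
                          vital_island_prob = c("50J" = 1, "100J" = 0.5, "4x50J" = 0),
                          n_sections_range = c(2L, 4L),
                          resistance_mean = 30,
                          resistance_sd = 6,
                          seed = 1L) {
  if (is.null(true_threshold_mean)) {
    single <- c("50J" = 4.3, "100J" = 5.1)
    true_threshold_mean <- c(single, "4x50J" = unname(mean(single)) / serial_reduction)
  }
  cfg <- list(
    n_pigs = as.integer(n_pigs), paddle_radius = paddle_radius,
    thickness_range = as.integer(thickness_range),
    group_current_mean = group_current_mean[ire_groups()],
    group_current_sd = group_current_sd[ire_groups()],
    true_threshold_mean = true_threshold_mean[ire_groups()],
    serial_reduction = serial_reduction,
    threshold_sd_between_pigs = threshold_sd_between_pigs,
    histology_noise_sd = histology_noise_sd,
    pulse_jitter_sd = pulse_jitter_sd,
    arcing_prob = arcing_prob[ire_groups()],
    transition_fraction = transition_fraction,
    vital_island_prob = vital_island_prob[ire_groups()],
    n_sections_range = as.integer(n_sections_range),
    resistance_mean = resistance_mean, resistance_sd = resistance_sd,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  if (cfg$n_pigs < 1) stop_validation("`n_pigs` must be at least 1.")
  if (cfg$paddle_radius <= 0) stop_validation("`paddle_radius` must be positive.")
  tr <- cfg$thickness_range
  if (length(tr) != 2 || tr[1] > tr[2] || tr[1] <= 1 || tr[2] >= 30) {
    stop_validation("`thickness_range` must be an increasing integer pair inside (1, 30) mm.")
  }
  for (nm in c("group_current_mean", "group_current_sd", "true_threshold_mean",
               "arcing_prob", "vital_island_prob")) {
    v <- cfg[[nm]]
    if (length(v) != 3 || any(is.na(v))) {
      stop_validation(sprintf("`%s` must supply one finite value per group (%s).",
                              nm, paste(ire_groups(), collapse = ", ")))
    }
  }
  sds <- c(cfg$group_current_sd, cfg$threshold_sd_between_pigs,
           cfg$histology_noise_sd, cfg$pulse_jitter_sd, cfg$resistance_sd)
  if (any(sds < 0)) stop_validation("All standard deviations must be >= 0.")
  if (any(cfg$group_current_mean <= 0) || any(cfg$true_threshold_mean <= 0)) {
    stop_validation("Current and threshold means must be positive.")
  }
  if (any(cfg$arcing_prob < 0 | cfg$arcing_prob > 1) ||
      any(cfg$vital_island_prob < 0 | cfg$vital_island_prob > 1)) {
    stop_validation("Probabilities must lie in [0, 1].")
  }
  if (cfg$transition_fraction <= 0 || cfg$transition_fraction >= 1) {
    stop_validation("`transition_fraction` must lie in (0, 1).")
  }
  ns <- cfg$n_sections_range
  if (length(ns) != 2 || ns[1] > ns[2] || ns[1] < 1) {
    stop_validation("`n_sections_range` must be an increasing integer pair >= 1.")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d pigs x 3 sites; paddle radius %.3g mm; thickness %d-%d mm\n",
              x$n_pigs, x$paddle_radius, x$thickness_range[1], x$thickness_range[2]))
  cat(sprintf("  peak current (A): %s\n",
              paste(sprintf("%s %.1f (%.1f)", ire_groups(), x$group_current_mean,
                            x$group_current_sd), collapse = ", ")))
  cat(sprintf("  true thresholds (A/cm^2): %s; between-pig SD %.2f\n",
              paste(sprintf("%s %.2f", ire_groups(), x$true_threshold_mean),
                    collapse = ", "), x$threshold_sd_between_pigs))
  cat(sprintf("  histology noise %.2f mm; seed %d\n", x$histology_noise_sd, x$seed))
  invisible(x)
}

# sample() treats a length-1 vector as 1:n; this doesn't.
draw_one <- function(x) x[sample.int(length(x), 1L)]

# Positive-truncated normal draws by inverse-CDF so no rejection loop is
# needed and draws stay reproducible count-for-count.
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, .Machine$double.eps), n))
  lo <- stats::pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a complete study-like cohort from a [cohort_config()]: per
#' animal, three application sites (one per group) with thickness and
#' peak currents from the configured distributions and a shared
#' animal-level threshold effect.  Histology is generated by inverting
#' the same nominal density model used for estimation: a site succeeds
#' iff its delivered centre density reaches the site's true threshold,
#' the necrotic half-width is the largest radial offset where delivered
#' density still reaches the threshold (0 if none), and the transition
#' half-width extends to where the dose falls to `transition_fraction`
#' of the threshold.  Per-section half-widths are perturbed with the
#' configured histology noise and clipped at zero.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#'
#' @return A list with elements `sites` (an `ablation_sites` tibble with
#'   nested `sections`) and `truth` (per pig x group: `true_threshold_a_cm2`,
#'   the animal effect, and the delivered centre density).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pigs = 3, seed = 11))
#' cohort$truth
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config")) {
    stop_input("`config` must be created with cohort_config().")
  }
  validate_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  groups <- ire_groups()
  pigs <- sprintf("pig%02d", seq_len(cfg$n_pigs))
  pig_effect <- rnorm(cfg$n_pigs, 0, cfg$threshold_sd_between_pigs)

  rows <- vector("list", cfg$n_pigs * 3L)
  truth <- vector("list", cfg$n_pigs * 3L)
  r <- 0L
  for (i in seq_len(cfg$n_pigs)) {
    for (g in groups) {
      r <- r + 1L
      theta <- max(cfg$true_threshold_mean[[g]] + pig_effect[i], 1e-6)
      thickness <- draw_one(seq(cfg$thickness_range[1], cfg$thickness_range[2]))
      n_pulses <- pulses_per_group()[[g]]
      i_site <- rnorm_pos(1, cfg$group_current_mean[[g]], cfg$group_current_sd[[g]])
      i_pulses <- if (n_pulses == 1) i_site else
        rnorm_pos(n_pulses, i_site, cfg$pulse_jitter_sd)
      resistance <- rnorm_pos(1, cfg$resistance_mean, cfg$resistance_sd)
      v_pulses <- i_pulses * resistance
      arcing <- runif(1) < cfg$arcing_prob[[g]]

      prof <- cached_profile(cfg$paddle_radius, thickness)
      i_summary <- mean(i_pulses)
      delivered0 <- prof$j_a_per_cm2[1] * i_summary
      success <- delivered0 >= theta
      # a dose so far above threshold that the lesion outruns the table is
      # clipped at the grid end (only reachable in stress regimes)
      grid_end <- max(prof$x_mm)
      xb <- if (success) {
        min(profile_invert(prof, theta / i_summary), grid_end, na.rm = TRUE)
      } else 0
      xt <- if (delivered0 >= cfg$transition_fraction * theta) {
        min(profile_invert(prof, cfg$transition_fraction * theta / i_summary),
            grid_end, na.rm = TRUE)
      } else 0

      n_sec <- draw_one(seq(cfg$n_sections_range[1], cfg$n_sections_range[2]))
      nec <- pmax(0, xb + rnorm(n_sec, 0, cfg$histology_noise_sd) * (xb > 0))
      tra <- pmax(nec, xt + rnorm(n_sec, 0, cfg$histology_noise_sd) * (xt > 0))
      sections <- tibble(
        section = seq_len(n_sec),
        necrotic_halfwidth_mm = nec,
        transition_halfwidth_mm = tra,
        contains_vital_inside = runif(n_sec) < cfg$vital_island_prob[[g]],
        spans_between_paddles = rep(success, n_sec)
      )

      rows[[r]] <- tibble(
        pig_id = pigs[i], group = g, thickness_mm = as.numeric(thickness),
        peak_voltages_v = list(v_pulses), peak_currents_a = list(i_pulses),
        arcing = arcing, sections = list(sections)
      )
      truth[[r]] <- tibble(
        pig_id = pigs[i], group = g, true_threshold_a_cm2 = theta,
        pig_effect = pig_effect[i], delivered_center_a_cm2 = delivered0,
        success = success
      )
    }
  }
  sites <- dplyr::bind_rows(rows)
  sites$group <- group_factor(sites$group)
  class(sites) <- c("ablation_sites", class(sites))
  truth <- dplyr::bind_rows(truth)
  truth$group <- group_factor(truth$group)
  list(sites = sites, truth = truth)
}

#' End-to-end parameter recovery over repeated synthetic cohorts
#'
#' Runs generate -> estimate -> aggregate `n_cohorts` times (cohort c
#' uses seed `seed + c`) and summarises, per group, how well the group
#' threshold estimates recover the configured true means.
#'
#' @param config A [cohort_config()].
#' @param n_cohorts Number of cohorts to simulate.
#' @param estimator Passed to [group_thresholds()].
#' @param success_filter Passed to [group_thresholds()]; the default
#'   `"success_only"` drops failed sites, whose thresholds are only
#'   bounded below by the delivered dose.
#' @param seed Base seed (default `config$seed`).
#'
#' @return A tibble per group: `true_mean`, `mean_estimate` (Monte-Carlo
#'   average of cohort group means), `bias`, `rmse`, `mc_se`, `n_cohorts`.
#' @examples
#' rec <- end_to_end_recovery(cohort_config(n_pigs = 6, seed = 3), n_cohorts = 5)
#' rec
#' @export
end_to_end_recovery <- function(config, n_cohorts,
                                estimator = c("boundary", "center"),
                                success_filter = c("success_only", "all"),
                                seed = NULL) {
  if (!inherits(config, "cohort_config")) stop_input("`config` must be a cohort_config().")
  if (n_cohorts < 1) stop_input("`n_cohorts` must be >= 1.")
  estimator <- match.arg(estimator)
  success_filter <- match.arg(success_filter)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)

  per_cohort <- purrr::map(seq_len(n_cohorts), function(cix) {
    cohort <- generate_cohort(config, seed = seed + cix)
    group_thresholds(cohort$sites, estimator = estimator,
                     success_filter = success_filter,
                     paddle_radius = config$paddle_radius) |>
      dplyr::mutate(cohort = cix)
  }) |>
    dplyr::bind_rows()

  truth <- tibble(group = group_factor(ire_groups()),
                  true_mean = unname(config$true_threshold_mean))
  per_cohort |>
    dplyr::left_join(truth, by = "group") |>
    dplyr::summarise(
      true_mean = .data$true_mean[1],
      mean_estimate = mean(.data$mean_a_cm2),
      bias = mean(.data$mean_a_cm2 - .data$true_mean),
      rmse = sqrt(mean((.data$mean_a_cm2 - .data$true_mean)^2)),
      mc_se = sd(.data$mean_a_cm2) / sqrt(dplyr::n()),
      n_cohorts = dplyr::n(),
      .by = "group"
    ) |>
    dplyr::arrange(.data$group) |>
    dplyr::mutate(estimator = estimator, filter = success_filter)
}
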