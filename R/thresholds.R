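#' Classify ablation success from histology sections
#'
#' A successful ablation is a region of non-viable parenchyma spanning the
#' tissue between the two paddles; a site is successful if any of its
#' sections shows such a bridge.
#'
#' @param sections A tibble of sections for one site (with a
#'   `spans_between_paddles` column), or a logical vector of per-section
#'   bridge flags.
#' @return `TRUE` or `FALSE`.
#' @examples
#' classify_success(c(FALSE, TRUE, FALSE))
#' @export
classify_success <- function(sections) {
  spans <- if (is.data.frame(sections)) sections$spans_between_paddles else sections
  if (is.null(spans) || length(spans) == 0) {
    stop_input("At least one histology section is required to classify success.")
  }
  if (any(is.na(spans))) stop_input("`spans_between_paddles` contains missing values.")
  any(spans)
}

#' Per-site success indicators
#'
#' @param sites An `ablation_sites` tibble with nested `sections`.
#' @return `sites` with an added logical `success` column.
#' @export
success_by_site <- function(sites) {
  if (!"sections" %in% names(sites)) {
    stop_input("`sites` must carry a nested `sections` column (read with sections_path=).")
  }
  dplyr::mutate(sites, success = purrr::map_lgl(.data$sections, classify_success))
}

#' Success-rate table by treatment group
#'
#' @param sites An `ablation_sites` tibble with nested `sections`.
#' @return A tibble with one row per group: `group`, `n`, `n_success`,
#'   `success_rate`.
#' @export
success_table <- function(sites) {
  success_by_site(sites) |>
    as_tibble() |>
    dplyr::summarise(
      n = dplyr::n(),
      n_success = sum(.data$success),
      success_rate = mean(.data$success),
      .by = "group"
    ) |>
    dplyr::arrange(.data$group)
}

#' Per-site current-density threshold estimates
#'
#' Two estimators of the necrosis threshold at each application site, both
#' built on the nominal per-ampere mid-plane profile for the site's tissue
#' thickness scaled by the recorded peak current:
#'
#' * `"center"`: the delivered density at the lesion centre (x = 0),
#'   `J_nominal(0; h) * I_peak`.  This reads off the dose actually
#'   delivered at the mid-plane centre, the convention used to report
#'   group thresholds from recorded currents.
#' * `"boundary"`: the delivered density evaluated at the radial edge of
#'   complete necrosis, `J_nominal(x_b; h) * I_peak`, with `x_b` the
#'   median necrotic half-width across the site's histology sections.
#'   At the necrosis/transition boundary the delivered dose equals the
#'   tissue threshold, so for a measurable lesion this is a direct,
#'   minimal-dose estimate.  A site with `x_b = 0` (no measurable
#'   necrotic extent) falls back to the centre density, which is then
#'   only a lower bound for that site.
#'
#' Profiles are tabulated per whole-millimetre thickness (lookup mode) and
#' cached, mirroring tabulation of nominal curves in 1 mm steps;
#' `thickness_mode = "continuous"` evaluates at the exact thickness.
#'
#' @param sites An `ablation_sites` tibble (with nested `sections` when the
#'   boundary estimator is requested).
#' @param estimator `"center"` (default) or `"boundary"`.
#' @param paddle_radius Paddle radius in mm (default 12.5).
#' @param current_summary How serial per-pulse peaks collapse to one
#'   current; see [summary_current()].
#' @param thickness_mode `"lookup"` (default) or `"continuous"`.
#' @param grid_max,grid_step Radial extent and spacing (mm) of the cached
#'   profile used by the boundary estimator.
#'
#' @return `sites` with added columns `peak_current_a`, `threshold_a_cm2`
#'   and (when sections are present) `success`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pigs = 4, seed = 1))
#' site_thresholds(cohort$sites)
#' @export
site_thresholds <- function(sites,
                            estimator = c("center", "boundary"),
                            paddle_radius = 12.5,
                            current_summary = c("mean", "max", "last"),
                            thickness_mode = c("lookup", "continuous"),
                            grid_max = 40, grid_step = 0.25) {
  estimator <- match.arg(estimator)
  current_summary <- match.arg(current_summary)
  thickness_mode <- match.arg(thickness_mode)
  sites <- summary_current(sites, current_summary)

  center_density <- function(h) {
    if (thickness_mode == "lookup") {
      cached_profile(paddle_radius, h, xmax = grid_max, step = grid_step)$j_a_per_cm2[1]
    } else {
      nominal_midplane_density(paddle_geometry(paddle_radius, h), 0)
    }
  }

  if (estimator == "center") {
    sites <- dplyr::mutate(
      sites,
      threshold_a_cm2 = purrr::map_dbl(.data$thickness_mm, center_density) *
        .data$peak_current_a
    )
  } else {
    if (!"sections" %in% names(sites)) {
      stop_input("The boundary estimator needs the nested `sections` column.")
    }
    sites <- dplyr::mutate(
      sites,
      threshold_a_cm2 = purrr::pmap_dbl(
        list(.data$thickness_mm, .data$peak_current_a, .data$sections),
        function(h, ipk, sec) {
          if (is.null(sec) || nrow(sec) == 0) {
            stop_estimation("Boundary estimator: a site has no histology sections.")
          }
          xb <- median(sec$necrotic_halfwidth_mm)
          if (xb <= 0) return(center_density(h) * ipk)
          prof <- cached_profile(paddle_radius, if (thickness_mode == "lookup") h else h,
                                 xmax = grid_max, step = grid_step)
          if (thickness_mode == "continuous") {
            return(nominal_midplane_density(paddle_geometry(paddle_radius, h), xb) * ipk)
          }
          if (xb > max(prof$x_mm)) {
            stop_estimation(sprintf(
              "Boundary estimator: necrotic half-width %.1f mm exceeds the profile grid (%.1f mm).",
              xb, max(prof$x_mm)))
          }
          profile_density_at(prof, xb) * ipk
        })
    )
  }
  if ("sections" %in% names(sites)) sites <- success_by_site(sites)
  attr(sites, "estimator") <- estimator
  sites
}

#' Group-level threshold estimates
#'
#' Mean and standard deviation (n - 1 denominator) of per-site threshold
#' estimates within each treatment group.  Because a failed ablation
#' leaves no measurable lesion, its per-site value is only a lower bound;
#' `success_filter = "success_only"` restricts the aggregation to
#' successful sites, `"all"` (default) keeps every site.  The estimator
#' and filter used are recorded in the output.
#'
#' @inheritParams site_thresholds
#' @param success_filter `"all"` (default) or `"success_only"`.
#' @param ... Passed on to [site_thresholds()].
#'
#' @return A tibble with one row per group: `group`, `n`, `mean_a_cm2`,
#'   `sd_a_cm2`, `estimator`, `filter`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pigs = 6, seed = 7))
#' group_thresholds(cohort$sites, estimator = "boundary",
#'                  success_filter = "success_only")
#' @export
group_thresholds <- function(sites,
                             estimator = c("center", "boundary"),
                             success_filter = c("all", "success_only"),
                             ...) {
  estimator <- match.arg(estimator)
  success_filter <- match.arg(success_filter)
  per_site <- site_thresholds(sites, estimator = estimator, ...)
  if (success_filter == "success_only") {
    if (!"success" %in% names(per_site)) {
      stop_input("success_only filtering needs nested `sections` to classify success.")
    }
    per_site <- dplyr::filter(per_site, .data$success)
  }
  if (nrow(per_site) == 0) stop_estimation("No sites left to aggregate.")
  empty <- setdiff(ire_groups(), as.character(unique(per_site$group)))
  if (length(empty) > 0 && length(empty) < 3) {
    warn(sprintf("No sites in group(s): %s", paste(empty, collapse = ", ")))
  }
  per_site |>
    as_tibble() |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_a_cm2 = mean(.data$threshold_a_cm2),
      sd_a_cm2 = sd(.data$threshold_a_cm2),
      .by = "group"
    ) |>
    dplyr::arrange(.data$group) |>
    dplyr::mutate(estimator = estimator, filter = success_filter)
}
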