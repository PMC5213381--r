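test_that("success classification requires a spanning necrotic bridge", {
  expect_true(classify_success(c(TRUE, TRUE, TRUE)))
  expect_true(classify_success(c(FALSE, TRUE)))
  expect_false(classify_success(c(FALSE, FALSE)))
  expect_error(classify_success(logical(0)), class = "paddleire_input_error")
  expect_error(classify_success(make_sections(numeric(0))),
               class = "paddleire_input_error")
})

test_that("a cohort built to the published histology yields 5/12, 11/12, 12/12", {
  cohort <- make_study_success_cohort()
  tab <- success_table(cohort)
  expect_equal(tab$n_success, c(5L, 11L, 12L))
  expect_equal(tab$n, rep(12L, 3))
  expect_equal(tab$success_rate, c(5, 11, 12) / 12)
})

test_that("centre estimator is the delivered density at x = 0", {
  geo <- paddle_geometry(separation = 7)
  j0 <- nominal_midplane_density(geo, 0)

  zero <- make_site(currents = 1e-12)  # vanishing current, vanishing dose
  expect_equal(site_thresholds(zero)$threshold_a_cm2, 1e-12 * j0, tolerance = 1e-6)

  site <- make_site(thickness = 7, currents = 25.3)
  est <- site_thresholds(site)$threshold_a_cm2
  expect_equal(est, 25.3 * j0, tolerance = 1e-12)

  # doubling the recorded current doubles every estimate exactly
  cohort <- generate_cohort(cohort_config(n_pigs = 3, seed = 5))$sites
  t1 <- site_thresholds(cohort)$threshold_a_cm2
  doubled <- dplyr::mutate(cohort,
    peak_currents_a = purrr::map(peak_currents_a, ~ .x * 2))
  t2 <- site_thresholds(doubled)$threshold_a_cm2
  expect_identical(t2, 2 * t1)
})

test_that("centre estimator agrees with the finite-difference oracle", {
  geo <- paddle_geometry(separation = 7)
  fd <- fd_reference_solver(geo, spacing = 0.5)
  site <- make_site(thickness = 7, currents = 25.3)
  est <- site_thresholds(site)$threshold_a_cm2
  expect_equal(est, 25.3 * attr(fd, "center_density"), tolerance = 0.01)
})

test_that("boundary estimator reads the dose at the lesion edge", {
  # a site with no measurable necrotic extent falls back to the centre dose
  site0 <- make_site(sections = make_sections(c(0, 0), spans = FALSE))
  expect_equal(site_thresholds(site0, estimator = "boundary")$threshold_a_cm2,
               site_thresholds(site0, estimator = "center")$threshold_a_cm2)

  # noiseless synthetic lesions invert back to the per-site truth
  cfg <- cohort_config(n_pigs = 6, seed = 21, histology_noise_sd = 0,
                       true_threshold_mean = c("50J" = 1.5, "100J" = 1.5, "4x50J" = 1.2),
                       threshold_sd_between_pigs = 0.1)
  cohort <- generate_cohort(cfg)
  est <- site_thresholds(cohort$sites, estimator = "boundary")
  expect_true(all(est$success))
  joined <- dplyr::left_join(as.data.frame(est)[c("pig_id", "group", "threshold_a_cm2")],
                             as.data.frame(cohort$truth),
                             by = c("pig_id", "group"))
  expect_lt(max(abs(joined$threshold_a_cm2 - joined$true_threshold_a_cm2) /
                  joined$true_threshold_a_cm2), 0.01)

  # for a decaying profile the lesion-edge dose cannot exceed the centre dose
  cfg2 <- cohort_config(n_pigs = 6, seed = 22)
  sites2 <- generate_cohort(cfg2)$sites
  b <- site_thresholds(sites2, estimator = "boundary")$threshold_a_cm2
  ctr <- site_thresholds(sites2, estimator = "center")$threshold_a_cm2
  expect_true(all(b <= ctr + 1e-9))

  expect_error(site_thresholds(make_site(), estimator = "boundary"),
               class = "paddleire_input_error")  # no sections attached
})

test_that("group aggregation reports mean and n-1 standard deviation", {
  geo <- paddle_geometry(separation = 7)
  j0 <- nominal_midplane_density(paddle_geometry(separation = 7), 0)
  # currents chosen so centre estimates are exactly {4, 5} and {3, 4}
  cohort <- dplyr::bind_rows(
    make_site("p1", "50J", 7, currents = 4 / j0),
    make_site("p2", "50J", 7, currents = 5 / j0),
    make_site("p1", "100J", 7, currents = 3 / j0),
    make_site("p2", "100J", 7, currents = 4 / j0)
  )
  g <- suppressWarnings(group_thresholds(cohort))
  expect_equal(g$mean_a_cm2, c(4.5, 3.5), tolerance = 1e-12)
  expect_equal(g$sd_a_cm2, rep(sqrt(0.5), 2), tolerance = 1e-12)

  # identical sites: zero dispersion
  same <- dplyr::bind_rows(make_site("p1", currents = 25),
                           make_site("p2", currents = 25))
  expect_equal(suppressWarnings(group_thresholds(same))$sd_a_cm2, 0)

  # the success filter is recorded and an empty aggregate errors
  none <- make_site(sections = make_sections(c(0, 0), spans = FALSE))
  expect_error(
    group_thresholds(none, success_filter = "success_only"),
    class = "paddleire_estimation_error")
})
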