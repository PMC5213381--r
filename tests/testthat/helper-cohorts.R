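# Programmatic fixtures: small cohorts built in code, no files needed.

# One application site as a one-row ablation_sites tibble.
make_site <- function(pig_id = "pig01", group = "50J", thickness = 7,
                      voltages = 750, currents = 25, arcing = FALSE,
                      sections = NULL) {
  out <- tibble::tibble(
    pig_id = pig_id, group = factor(group, levels = c("50J", "100J", "4x50J")),
    thickness_mm = thickness,
    peak_voltages_v = list(voltages), peak_currents_a = list(currents),
    arcing = arcing
  )
  if (!is.null(sections)) out$sections <- list(sections)
  out
}

make_sections <- function(necrotic, transition = necrotic + 1,
                          spans = necrotic > 0, vital = FALSE) {
  tibble::tibble(
    section = seq_along(necrotic),
    necrotic_halfwidth_mm = necrotic,
    transition_halfwidth_mm = transition,
    contains_vital_inside = rep_len(vital, length(necrotic)),
    spans_between_paddles = rep_len(spans, length(necrotic))
  )
}

# A 12-animal cohort whose histology reproduces the published success
# pattern exactly: 5/12 at 50J, 11/12 at 100J, 12/12 serial, nested
# (nobody succeeds at a weaker setting while failing at a stronger one).
make_study_success_cohort <- function() {
  succ <- list("50J" = 1:5, "100J" = 1:11, "4x50J" = 1:12)
  rows <- list()
  for (i in 1:12) {
    for (g in names(succ)) {
      ok <- i %in% succ[[g]]
      n_pulses <- if (g == "4x50J") 4 else 1
      rows[[length(rows) + 1]] <- make_site(
        pig_id = sprintf("pig%02d", i), group = g, thickness = 7,
        voltages = rep(750, n_pulses), currents = rep(25, n_pulses),
        sections = make_sections(necrotic = if (ok) c(5, 6) else c(0, 0),
                                 spans = ok)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ablation_sites", class(out))
  out
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "paddleire", mustWork = TRUE)
}
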