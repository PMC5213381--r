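#' Read ablation-site records
#'
#' Reads a cohort of paddle-IRE application sites from `sites.csv`, and
#' optionally the per-site histology sections from a sibling
#' `sections.csv`, validating both against the schema below.  One row of
#' `sites.csv` is one application site; the per-pulse peak lists are
#' semicolon-joined inside a single cell so that a cohort stays a single
#' human-editable file.
#'
#' `sites.csv` columns:
#' \describe{
#'   \item{pig_id}{animal identifier (character)}
#'   \item{group}{one of `50J`, `100J`, `4x50J`}
#'   \item{thickness_mm}{tissue thickness between the paddles, mm}
#'   \item{peak_voltages_v}{semicolon-joined per-pulse peak voltages, V}
#'   \item{peak_currents_a}{semicolon-joined per-pulse peak currents, A}
#'   \item{arcing}{TRUE if sparking distorted the waveform}
#' }
#' `sections.csv` columns: `pig_id`, `group`, `section`,
#' `necrotic_halfwidth_mm`, `transition_halfwidth_mm`,
#' `contains_vital_inside`, `spans_between_paddles`.
#'
#' Validation is total: every malformed row raises a classed error
#' (`paddleire_parse_error` or `paddleire_validation_error`) naming the
#' offending row; nothing is silently dropped.  Enforced invariants:
#' single-energy groups carry exactly 1 pulse and the serial group 4;
#' thickness lies in (1, 30) mm; currents and voltages are positive;
#' section half-widths satisfy 0 <= necrotic <= transition.
#'
#' @param path Path to `sites.csv`.
#' @param sections_path Optional path to `sections.csv`; if supplied the
#'   sections are nested into a `sections` list-column.
#'
#' @return A tibble of class `ablation_sites`, one row per site, with
#'   list-columns `peak_voltages_v` and `peak_currents_a` (and `sections`
#'   when available).
#' @examples
#' cohort <- read_sites(
#'   system.file("extdata", "synthetic_sites.csv", package = "paddleire"),
#'   system.file("extdata", "synthetic_sections.csv", package = "paddleire")
#' )
#' cohort
#' @export
read_sites <- function(path, sections_path = NULL) {
  if (!file.exists(path)) stop_input(sprintf("No such file: %s", path))
  raw <- tryCatch(
    # suppressWarnings: a missing column triggers a readr name-mismatch
    # warning; the explicit schema check below turns it into a parse error
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      pig_id = readr::col_character(),
      group = readr::col_character(),
      thickness_mm = readr::col_double(),
      peak_voltages_v = readr::col_character(),
      peak_currents_a = readr::col_character(),
      arcing = readr::col_logical()
    ), progress = FALSE)),
    error = function(e) stop_parse(sprintf("Failed to read %s: %s", path, conditionMessage(e)))
  )
  required <- c("pig_id", "group", "thickness_mm", "peak_voltages_v",
                "peak_currents_a", "arcing")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_parse(sprintf("sites file is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop_parse(sprintf("sites file row %d, column '%s': expected %s, got '%s'",
                       prob$row[1], names(raw)[prob$col[1]], prob$expected[1],
                       prob$actual[1]))
  }
  sites <- raw |>
    dplyr::mutate(
      group = as.character(.data$group),
      peak_voltages_v = parse_pulse_list(.data$peak_voltages_v, "peak_voltages_v"),
      peak_currents_a = parse_pulse_list(.data$peak_currents_a, "peak_currents_a")
    )
  sites <- validate_sites(sites)
  if (!is.null(sections_path)) {
    sections <- read_sections(sections_path)
    sites <- attach_sections(sites, sections)
  }
  class(sites) <- c("ablation_sites", class(sites))
  sites
}

parse_pulse_list <- function(x, col) {
  purrr::imap(x, function(cell, row) {
    vals <- suppressWarnings(as.numeric(strsplit(cell, ";", fixed = TRUE)[[1]]))
    if (length(vals) == 0 || any(is.na(vals))) {
      stop_parse(sprintf("Row %d, column '%s': cannot parse '%s' as a semicolon-joined numeric list.",
                         row, col, cell))
    }
    vals
  })
}

validate_sites <- function(sites) {
  need <- pulses_per_group()
  for (row in seq_len(nrow(sites))) {
    g <- sites$group[row]
    if (!g %in% ire_groups()) {
      stop_validation(sprintf("Row %d: unknown group '%s' (expected %s).",
                              row, g, paste(ire_groups(), collapse = ", ")))
    }
    nv <- length(sites$peak_voltages_v[[row]])
    ni <- length(sites$peak_currents_a[[row]])
    if (nv != need[[g]] || ni != need[[g]]) {
      stop_validation(sprintf(
        "Row %d: group %s requires %d pulse(s) but found %d voltage / %d current value(s).",
        row, g, need[[g]], nv, ni))
    }
    th <- sites$thickness_mm[row]
    if (!is.finite(th) || th <= 1 || th >= 30) {
      stop_validation(sprintf("Row %d: thickness %.3g mm outside the sanity window (1, 30).", row, th))
    }
    if (any(sites$peak_currents_a[[row]] <= 0) || any(sites$peak_voltages_v[[row]] <= 0)) {
      stop_validation(sprintf("Row %d: peak currents and voltages must be positive.", row))
    }
    if (is.na(sites$arcing[row])) {
      stop_validation(sprintf("Row %d: arcing flag must be TRUE or FALSE.", row))
    }
  }
  dup <- duplicated(sites[, c("pig_id", "group")])
  if (any(dup)) {
    stop_validation(sprintf("Row %d: duplicate (pig_id, group) pair; one site per animal per group.",
                            which(dup)[1]))
  }
  sites$group <- group_factor(sites$group)
  sites
}

read_sections <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("No such file: %s", path))
  sec <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      pig_id = readr::col_character(),
      group = readr::col_character(),
      section = readr::col_integer(),
      necrotic_halfwidth_mm = readr::col_double(),
      transition_halfwidth_mm = readr::col_double(),
      contains_vital_inside = readr::col_logical(),
      spans_between_paddles = readr::col_logical()
    ), progress = FALSE),
    error = function(e) stop_parse(sprintf("Failed to read %s: %s", path, conditionMessage(e)))
  )
  prob <- readr::problems(sec)
  if (nrow(prob) > 0) {
    stop_parse(sprintf("sections file row %d, column %d: expected %s, got '%s'",
                       prob$row[1], prob$col[1], prob$expected[1], prob$actual[1]))
  }
  bad <- which(!(sec$necrotic_halfwidth_mm >= 0 &
                 sec$necrotic_halfwidth_mm <= sec$transition_halfwidth_mm))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "sections file row %d: requires 0 <= necrotic_halfwidth_mm <= transition_halfwidth_mm.",
      bad[1]))
  }
  sec$group <- group_factor(sec$group)
  if (any(is.na(sec$group))) stop_validation("sections file: unknown group label.")
  sec
}

attach_sections <- function(sites, sections) {
  nested <- sections |>
    tidyr::nest(sections = !dplyr::all_of(c("pig_id", "group")))
  out <- dplyr::left_join(sites, nested, by = c("pig_id", "group"))
  missing <- purrr::map_lgl(out$sections, is.null)
  out$sections[missing] <- list(sections[0, setdiff(names(sections), c("pig_id", "group"))])
  out
}

#' Write ablation-site records in canonical form
#'
#' Inverse of [read_sites()].  Numbers are written with up to 10
#' significant digits and pulse lists re-joined with semicolons, so that
#' `write_sites(read_sites(f))` reproduces a canonically formatted file
#' byte for byte.
#'
#' @param sites An `ablation_sites` tibble.
#' @param path Output path for `sites.csv`.
#' @param sections_path Optional output path for `sections.csv` (requires
#'   a `sections` list-column).
#' @return `sites`, invisibly.
#' @export
write_sites <- function(sites, path, sections_path = NULL) {
  if (!inherits(sites, "data.frame")) stop_input("`sites` must be a data frame.")
  fmt <- function(x) vapply(x, function(v) format(v, digits = 10, scientific = FALSE),
                            character(1))
  flat <- tibble(
    pig_id = as.character(sites$pig_id),
    group = as.character(sites$group),
    thickness_mm = fmt(sites$thickness_mm),
    peak_voltages_v = purrr::map_chr(sites$peak_voltages_v, ~ paste(fmt(.x), collapse = ";")),
    peak_currents_a = purrr::map_chr(sites$peak_currents_a, ~ paste(fmt(.x), collapse = ";")),
    arcing = sites$arcing
  )
  readr::write_csv(flat, path, progress = FALSE)
  if (!is.null(sections_path)) {
    if (!"sections" %in% names(sites)) {
      stop_input("`sites` has no nested `sections` column to write.")
    }
    sec <- sites |>
      dplyr::select(dplyr::all_of(c("pig_id", "group", "sections"))) |>
      tidyr::unnest("sections") |>
      dplyr::mutate(group = as.character(.data$group))
    num_cols <- c("necrotic_halfwidth_mm", "transition_halfwidth_mm")
    sec[num_cols] <- lapply(sec[num_cols], fmt)
    readr::write_csv(sec, sections_path, progress = FALSE)
  }
  invisible(sites)
}

#' Descriptive electric field at each site
#'
#' Applied peak voltage divided by paddle separation, in V/cm.  This is a
#' descriptive quantity only: electrode--tissue interface polarisation
#' means the in-tissue voltage gradient is smaller than applied voltage,
#' so current-density dosimetry should be preferred.
#'
#' @param sites An `ablation_sites` tibble.
#' @return `sites` with an added `electric_field_v_cm` column
#'   (`max(peak voltages) / thickness`, converted to V/cm).
#' @examples
#' # 700 V across 7 mm is 1000 V/cm
#' @export
electric_field <- function(sites) {
  if (any(sites$thickness_mm <= 0)) stop_domain("Thickness must be positive.")
  sites |>
    dplyr::mutate(
      electric_field_v_cm =
        10 * purrr::map_dbl(.data$peak_voltages_v, max) / .data$thickness_mm
    )
}

#' Per-pulse resistance at each site
#'
#' Peak voltage over peak current for every recorded pulse (descriptive).
#'
#' @param sites An `ablation_sites` tibble.
#' @return A tibble with one row per pulse: `pig_id`, `group`, `pulse`,
#'   `resistance_ohm`.
#' @export
site_resistance <- function(sites) {
  if (any(purrr::map_lgl(sites$peak_currents_a, ~ any(.x <= 0)))) {
    stop_domain("Peak currents must be positive to form resistances.")
  }
  sites |>
    as_tibble() |>
    dplyr::select(dplyr::all_of(c("pig_id", "group", "peak_voltages_v", "peak_currents_a"))) |>
    dplyr::mutate(pulse = purrr::map(.data$peak_currents_a, seq_along)) |>
    tidyr::unnest(dplyr::all_of(c("pulse", "peak_voltages_v", "peak_currents_a"))) |>
    dplyr::mutate(resistance_ohm = .data$peak_voltages_v / .data$peak_currents_a) |>
    dplyr::select(dplyr::all_of(c("pig_id", "group", "pulse", "resistance_ohm")))
}

#' Summary peak current per site
#'
#' Collapses the per-pulse peak currents of a site into one value.  The
#' study scales the nominal density curve by "the" peak current without
#' stating how four serial pulses combine; the default is their mean
#' (consistent with one reported mean per group), with `max` and `last`
#' available.
#'
#' @param sites An `ablation_sites` tibble.
#' @param method `"mean"` (default), `"max"` or `"last"`.
#' @return `sites` with an added `peak_current_a` column.
#' @export
summary_current <- function(sites, method = c("mean", "max", "last")) {
  method <- match.arg(method)
  f <- switch(method, mean = mean, max = max, last = function(x) x[length(x)])
  dplyr::mutate(sites, peak_current_a = purrr::map_dbl(.data$peak_currents_a, f))
}
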