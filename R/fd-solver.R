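#' Finite-volume reference solution for the mid-plane density
#'
#' Independent numerical oracle for [nominal_midplane_density()].  Solves
#' the steady conduction problem in axisymmetric cylindrical coordinates
#' (r, z) with the mid-plane as a zero-potential symmetry plane (the
#' source/sink pair is antisymmetric in z, so only the upper half-space is
#' discretised).  Two electrode idealisations are available:
#'
#' * `"uniform_source"`: the paddle injects a uniform current per unit
#'   area over its face (total 1 A).  This matches the semi-analytical
#'   elliptic-integral model exactly in the continuum limit and is the
#'   mode used for oracle-equivalence checks.
#' * `"equipotential"`: the paddle face is held at a fixed potential (an
#'   ideal conductor); the solution is post-scaled so that exactly 1 A
#'   crosses the mid-plane.  Edge current crowding makes this profile
#'   differ from the uniform-source one; the discrepancy quantifies the
#'   uniform-source approximation and is reported, not hidden.
#'
#' The discretisation is a symmetric finite-volume 5-point stencil with
#' conductances \eqn{2\pi r_{face}} (the cell size cancels); the sparse
#' symmetric positive-definite system is solved exactly with a Cholesky
#' factorisation, so there is no iteration to converge.  The outer
#' cylindrical wall is insulating and pushed far away (defaults: radial
#' extent 12 paddle radii, axial half-extent 6), far enough that the
#' truncation error stays below the discretisation error for x <= 2a.
#'
#' @param geometry A [paddle_geometry()].
#' @param spacing Grid spacing in mm.  Default `radius / 50`.
#' @param radial_extent Domain radius in mm.  Default `12 * radius`; must
#'   be at least `4 * radius`.
#' @param axial_extent Axial half-extent (mid-plane to top wall) in mm.
#'   Default `6 * radius`; must exceed `separation / 2`.
#' @param electrode_condition `"uniform_source"` (default) or
#'   `"equipotential"`.
#'
#' @return A tibble of class `nominal_profile` (method `"fd_oracle"`)
#'   giving the mid-plane density at the radial cell centres, per 1 A
#'   delivered.  The extrapolated on-axis density is attached as attribute
#'   `center_density` and the (pre-normalisation) mid-plane current as
#'   `total_current_a`.
#' @examples
#' \donttest{
#' geo <- paddle_geometry(separation = 7)
#' fd <- fd_reference_solver(geo, spacing = 0.5)
#' attr(fd, "center_density")
#' }
#' @export
fd_reference_solver <- function(geometry,
                                spacing = geometry$radius / 50,
                                radial_extent = 12 * geometry$radius,
                                axial_extent = 6 * geometry$radius,
                                electrode_condition = c("uniform_source", "equipotential")) {
  check_geometry(geometry)
  electrode_condition <- match.arg(electrode_condition)
  a <- geometry$radius
  h <- geometry$separation
  if (spacing <= 0 || radial_extent <= 0 || axial_extent <= 0) {
    stop_input("`spacing`, `radial_extent` and `axial_extent` must be positive.")
  }
  if (radial_extent < 4 * a) {
    stop_input("`radial_extent` must be at least 4 paddle radii for a usable far boundary.")
  }
  if (axial_extent <= h / 2 + 2 * spacing) {
    stop_input("`axial_extent` must exceed separation/2 (the electrode must fit in the domain).")
  }

  nr <- as.integer(round(radial_extent / spacing))
  nz <- as.integer(round(axial_extent / spacing))
  n <- nr * nz
  idx <- function(i, j) i + (j - 1L) * nr
  r_center <- (seq_len(nr) - 0.5) * spacing

  # Face conductances (sigma = 1; spacing cancels for a square stencil).
  ir <- rep(seq_len(nr - 1L), nz)
  jr <- rep(seq_len(nz), each = nr - 1L)
  g_rad <- 2 * pi * (ir * spacing)
  iz <- rep(seq_len(nr), nz - 1L)
  jz <- rep(seq_len(nz - 1L), each = nr)
  g_ax <- 2 * pi * ((iz - 0.5) * spacing)
  ti <- c(idx(ir, jr), idx(iz, jz + 1L))
  tj <- c(idx(ir + 1L, jr), idx(iz, jz))
  gg <- c(g_rad, g_ax)
  A <- Matrix::sparseMatrix(i = c(ti, tj), j = c(tj, ti), x = -c(gg, gg),
                            dims = c(n, n))
  diag_lap <- -Matrix::rowSums(A)
  # Mid-plane (z = 0) is a Dirichlet phi = 0 plane a half-cell below row 1.
  diag_bc <- numeric(n)
  diag_bc[idx(seq_len(nr), 1L)] <- 4 * pi * r_center
  A <- A + Matrix::Diagonal(n, x = diag_lap + diag_bc)

  # Fraction of each annular cell covered by the disc face.
  r_in <- (seq_len(nr) - 1L) * spacing
  r_out <- seq_len(nr) * spacing
  cover <- pmax(0, pmin(r_out, a)^2 - pmin(r_in, a)^2) / a^2

  # The electrode plane z = h/2 in cell-layer coordinates; the unit source
  # is shared between the two straddling layers by linear weights so that
  # a face-aligned electrode is represented symmetrically.
  zf <- (h / 2) / spacing
  j_lo <- max(1L, min(nz - 1L, as.integer(floor(zf + 0.5))))
  w_hi <- min(1, max(0, zf - (j_lo - 0.5)))

  if (electrode_condition == "uniform_source") {
    b <- numeric(n)
    b[idx(seq_len(nr), j_lo)] <- (1 - w_hi) * cover
    b[idx(seq_len(nr), j_lo + 1L)] <- w_hi * cover
    phi <- solve_spd(A, b)
  } else {
    # Ideal-conductor paddle: a zero-thickness disc held at unit potential
    # on the grid face nearest z = h/2.  Both adjacent cell layers couple
    # to the fixed-potential face through half-cell conductances, which
    # keeps the system symmetric positive definite and the electrode
    # plane exactly on the face.  The profile is normalised to 1 A below.
    j_face <- max(1L, min(nz - 1L, as.integer(round(zf))))
    ri <- which(r_center <= a)
    g_half <- 4 * pi * r_center[ri]  # conductance cell centre -> face
    add <- numeric(n)
    add[idx(ri, j_face)] <- g_half
    add[idx(ri, j_face + 1L)] <- g_half
    A <- A + Matrix::Diagonal(n, x = add)
    b <- numeric(n)
    b[idx(ri, j_face)] <- g_half
    b[idx(ri, j_face + 1L)] <- g_half
    phi <- solve_spd(A, b)
  }

  phi1 <- phi[idx(seq_len(nr), 1L)]
  phi2 <- phi[idx(seq_len(nr), 2L)]
  # Second-order one-sided gradient at the phi = 0 plane, A/mm^2 -> A/cm^2.
  j_mid <- (9 * phi1 - phi2) / (3 * spacing) * 100
  total <- sum(j_mid / 100 * 2 * pi * r_center * spacing)
  if (electrode_condition == "equipotential") {
    j_mid <- j_mid / total
  }
  center <- (9 * j_mid[1] - j_mid[2]) / 8  # even quadratic extrapolation to x = 0

  out <- new_profile(r_center, j_mid, paddle_geometry(a, h),
                     method = "fd_oracle", peak_current = 1)
  attr(out, "center_density") <- center
  attr(out, "total_current_a") <- total
  attr(out, "electrode_condition") <- electrode_condition
  out
}

solve_spd <- function(A, b) {
  phi <- tryCatch(
    as.numeric(Matrix::solve(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"), b)),
    error = function(e) stop_numerical(
      sprintf("Sparse solve of the conduction system failed: %s", conditionMessage(e)))
  )
  if (any(!is.finite(phi))) {
    stop_numerical("Sparse solve of the conduction system returned non-finite potentials.")
  }
  phi
}
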