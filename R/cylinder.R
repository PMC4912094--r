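#' Cylinder fit quality for a given axis
#'
#' The fit quality is the root-mean-square deviation of the atom-to-axis
#' distances from their mean: `r = sqrt(mean((d_i - dbar)^2))` over the `m`
#' backbone atoms of the segment (m = 24 for a six-residue segment). The
#' mean radius `dbar` is re-estimated for whatever axis is supplied, so this
#' also scores non-optimal (e.g. perturbed) axes.
#'
#' @param xyz Numeric matrix (m x 3) of atom coordinates, Angstrom.
#' @param axis_point Length-3 point on the axis.
#' @param axis_direction Length-3 direction (normalised internally).
#' @return List with `r` (A), `mean_radius` (A) and `distances`.
#' @export
cylinder_residual <- function(xyz, axis_point, axis_direction) {
  u <- axis_direction / sqrt(sum(axis_direction^2))
  v <- sweep(xyz, 2, axis_point)
  proj <- as.vector(v %*% u)
  perp <- v - outer(proj, u)
  d <- sqrt(rowSums(perp^2))
  dbar <- mean(d)
  list(r = sqrt(mean((d - dbar)^2)), mean_radius = dbar, distances = d)
}

# objective in a local frame where the initial axis guess is +z;
# params = (p, q, a, b): direction ~ (p, q, 1), axis point = centroid + (a, b, 0)
.cyl_obj <- function(par, yloc) {
  u <- c(par[1], par[2], 1)
  u <- u / sqrt(sum(u^2))
  v <- sweep(yloc, 2, c(par[3], par[4], 0))
  proj <- as.vector(v %*% u)
  perp <- v - outer(proj, u)
  d <- sqrt(rowSums(perp^2))
  sqrt(mean((d - mean(d))^2))
}

#' Fit a cylinder to a six-residue helix segment
#'
#' Finds the axis (point + direction) minimising the fit quality `r`
#' (see [cylinder_residual()]) over both axis position and direction, for
#' the 24 backbone atoms of six consecutive residues. The axis is
#' initialised at the principal axis of the atoms through their centroid and
#' refined by local minimisation (Nelder-Mead then BFGS polish, tolerance
#' 1e-8 on `r`). The returned direction is oriented N- to C-terminal: its
#' dot product with the displacement from the first to the last residue's
#' centroid is positive.
#'
#' @param xyz Numeric 24 x 3 matrix, atoms ordered residue-major (N, CA, C,
#'   O within each residue) from the N-terminal residue onward; or a
#'   [helix_backbone()] together with `start`.
#' @param start When `xyz` is a `helix_backbone`: 0-based index of the
#'   segment's first residue.
#' @param segment_start_index Stored in the result for bookkeeping.
#' @return An object of class `cylinder_fit`: list with `axis_point`,
#'   `axis_direction` (unit, N->C), `mean_radius` (A), `r` (A) and
#'   `segment_start_index`.
#' @export
#' @examples
#' h <- generate_ideal_helix(12)
#' fit_cylinder(h, start = 0)$r
fit_cylinder <- function(xyz, start = NULL, segment_start_index = start) {
  if (inherits(xyz, "helix_backbone")) {
    if (is.null(start)) stop("supply `start` with a helix_backbone", call. = FALSE)
    xyz <- segment_xyz(xyz, start)
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != 24L || ncol(xyz) != 3L) {
    stop("a six-residue segment must supply exactly 24 backbone atoms (24 x 3)",
         call. = FALSE)
  }
  ctr <- colMeans(xyz)
  centred <- sweep(xyz, 2, ctr)
  sv <- svd(centred, nu = 0)
  if (sv$d[1] < 1e-8 || sv$d[2] < 1e-8) {
    stop("degenerate geometry: atoms are collinear or coincident", call. = FALSE)
  }
  u0 <- sv$v[, 1]
  # canonical local frame: +z along the principal axis oriented N->C, +x
  # towards the first atom. Because the frame is derived from the points
  # themselves, any rigid motion of the input yields (numerically) the same
  # local coordinates, making the optimisation reproducible under rigid
  # motions.
  nc0 <- colMeans(xyz[21:24, , drop = FALSE]) - colMeans(xyz[1:4, , drop = FALSE])
  if (sum(u0 * nc0) < 0) u0 <- -u0
  e1 <- centred[1, ] - sum(centred[1, ] * u0) * u0
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- sv$v[, 2] - sum(sv$v[, 2] * u0) * u0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u0[2] * e1[3] - u0[3] * e1[2],
          u0[3] * e1[1] - u0[1] * e1[3],
          u0[1] * e1[2] - u0[2] * e1[1])
  Q <- cbind(e1, e2, u0)
  yloc <- centred %*% Q
  opt <- stats::optim(c(0, 0, 0, 0), .cyl_obj, yloc = yloc,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, .cyl_obj, yloc = yloc, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14,
                                      abstol = 1e-14,
                                      ndeps = rep(1e-6, 4)))
  par <- if (opt2$value <= opt$value) opt2$par else opt$par
  uloc <- c(par[1], par[2], 1)
  uloc <- uloc / sqrt(sum(uloc^2))
  u <- as.vector(Q %*% uloc)
  p0 <- ctr + as.vector(Q %*% c(par[3], par[4], 0))
  # orient N -> C using the first and last residue centroids
  nc <- colMeans(xyz[21:24, , drop = FALSE]) - colMeans(xyz[1:4, , drop = FALSE])
  if (sum(u * nc) < 0) u <- -u
  res <- cylinder_residual(xyz, p0, u)
  structure(
    list(axis_point = p0, axis_direction = u, mean_radius = res$mean_radius,
         r = res$r, segment_start_index = segment_start_index),
    class = "cylinder_fit"
  )
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat("<cylinder_fit> r =", format(x$r, digits = 4), "A, mean radius =",
      format(x$mean_radius, digits = 4), "A\n")
  invisible(x)
}

#' Unsigned angle between two axis directions
#'
#' @param u1,u2 Length-3 direction vectors (need not be unit).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_between <- function(u1, u2) {
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- u2 / sqrt(sum(u2^2))
  acos(min(1, max(-1, sum(u1 * u2)))) * 180 / pi
}

#' Measure the per-site kink-angle profile of a helix
#'
#' Fits a cylinder to every six-residue segment and, at each interior site
#' `s`, measures the angle between the axes of the two disjoint flanking
#' segments (residues `s-5 ... s` and `s+1 ... s+6`, both oriented N->C).
#' The angle is assigned to the final residue of the first segment, so a
#' helix of length `L` has sites at 0-based indices `5 ... L-7` and only
#' helices of 12 residues or more can be analysed. The fit qualities of the
#' two segments (`r_n`, `r_c`) are recorded and the error model supplies the
#' 95% confidence half-width `epsilon` for each angle.
#'
#' @param helix A [helix_backbone()] of length >= 12.
#' @param model A [kink_error_model()] used to fill `epsilon_deg`; `NULL`
#'   leaves the column `NA`.
#' @return A tibble of class `angle_profile` with columns `helix_id`,
#'   `site_index`, `auth_res`, `theta_deg`, `r_n`, `r_c`, `epsilon_deg`.
#' @export
#' @examples
#' measure_angles(generate_kinked_helix(20, 30, 10))
measure_angles <- function(helix, model = kink_error_model()) {
  L <- helix_length(helix)
  if (L < 12L) {
    stop("only helices 12 residues or longer can be analysed (got ", L,
         ")", call. = FALSE)
  }
  idx <- sort(unique(helix$res_index))
  starts <- 0:(L - 6L)
  fits <- lapply(starts, function(s) fit_cylinder(helix, start = idx[s + 1L],
                                                  segment_start_index = s))
  sites <- 5:(L - 7L)
  auth <- vapply(sites, function(s) {
    helix$auth_res[helix$res_index == idx[s + 1L]][1]
  }, character(1))
  theta <- vapply(sites, function(s) {
    angle_between(fits[[s - 4L]]$axis_direction, fits[[s + 2L]]$axis_direction)
  }, numeric(1))
  r_n <- vapply(sites, function(s) fits[[s - 4L]]$r, numeric(1))
  r_c <- vapply(sites, function(s) fits[[s + 2L]]$r, numeric(1))
  out <- tibble::tibble(
    helix_id = helix$helix_id[1],
    site_index = as.integer(sites),
    auth_res = auth,
    theta_deg = theta,
    r_n = r_n,
    r_c = r_c,
    epsilon_deg = if (is.null(model)) NA_real_ else estimate_error(r_n, r_c, model)
  )
  attr(out, "fits") <- fits
  class(out) <- c("angle_profile", class(tibble::tibble()))
  out
}

#' Extract a kink site (two flanking segments and their fits) from a helix
#'
#' Bundles everything the perturbation simulation needs about one site: the
#' coordinates of the N- and C-terminal six-residue segments, their optimal
#' cylinder fits, and the angle between the fitted axes, which plays the
#' role of the "true" angle in the error calibration.
#'
#' @param helix A [helix_backbone()].
#' @param site 0-based site index (`5 <= site <= L - 7`).
#' @return Object of class `kink_site`: list with `xyz_n`, `xyz_c`, `fit_n`,
#'   `fit_c`, `true_angle` (degrees), `sum_r` (A).
#' @export
kink_site <- function(helix, site) {
  L <- helix_length(helix)
  if (site < 5 || site > L - 7) {
    stop("site must lie in 5 ... L-7", call. = FALSE)
  }
  idx <- sort(unique(helix$res_index))
  xyz_n <- segment_xyz(helix, idx[site - 4L])
  xyz_c <- segment_xyz(helix, idx[site + 2L])
  fit_n <- fit_cylinder(xyz_n, segment_start_index = site - 5L)
  fit_c <- fit_cylinder(xyz_c, segment_start_index = site + 1L)
  structure(
    list(xyz_n = xyz_n, xyz_c = xyz_c, fit_n = fit_n, fit_c = fit_c,
         true_angle = angle_between(fit_n$axis_direction, fit_c$axis_direction),
         sum_r = fit_n$r + fit_c$r),
    class = "kink_site"
  )
}
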