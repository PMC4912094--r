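# Independent brute-force oracle for the cylinder fit: grid search over axis
# directions (2 degree spacing, spherical cap around the principal axis) with
# per-direction optimisation of the axis position in the normal plane.
brute_force_cylinder_r <- function(xyz, cap_deg = 30, step_deg = 2) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  centred <- sweep(xyz, 2, ctr)
  u0 <- svd(centred, nu = 0)$v[, 1]
  r_for_direction <- function(u) {
    f1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p1 <- f1 - sum(f1 * u) * u; p1 <- p1 / sqrt(sum(p1^2))
    p2 <- c(u[2] * p1[3] - u[3] * p1[2],
            u[3] * p1[1] - u[1] * p1[3],
            u[1] * p1[2] - u[2] * p1[1])
    obj <- function(ab) {
      p <- ctr + ab[1] * p1 + ab[2] * p2
      v <- sweep(xyz, 2, p)
      proj <- as.vector(v %*% u)
      d <- sqrt(rowSums((v - outer(proj, u))^2))
      sqrt(mean((d - mean(d))^2))
    }
    stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-12))$value
  }
  scan_cap <- function(centre, cap, step) {
    # orthonormal frame around the scan centre
    f <- if (abs(centre[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    g1 <- f - sum(f * centre) * centre; g1 <- g1 / sqrt(sum(g1^2))
    g2 <- c(centre[2] * g1[3] - centre[3] * g1[2],
            centre[3] * g1[1] - centre[1] * g1[3],
            centre[1] * g1[2] - centre[2] * g1[1])
    best_r <- r_for_direction(centre)
    best_u <- centre
    for (polar in seq(step, cap, by = step)) {
      sp <- sin(polar * pi / 180)
      n_az <- max(8L, ceiling(360 * sp / step))
      for (az in seq(0, 360 - 360 / n_az, by = 360 / n_az)) {
        u <- cos(polar * pi / 180) * centre +
          sp * (cos(az * pi / 180) * g1 + sin(az * pi / 180) * g2)
        r <- r_for_direction(u)
        if (r < best_r) { best_r <- r; best_u <- u }
      }
    }
    list(r = best_r, u = best_u)
  }
  coarse <- scan_cap(u0, cap_deg, step_deg)
  # refine on a 0.2 degree grid around the best coarse direction, so the
  # enumeration resolves r to well below 1e-3 A
  fine <- scan_cap(coarse$u, 2 * step_deg, 0.2)
  fine$r
}

# random rotation matrix from a seeded axis-angle draw
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

residue_centroid_for_test <- function(helix, res_index) {
  colMeans(as.matrix(helix[helix$res_index == res_index, c("x", "y", "z")]))
}

# two-structure fixture for the neighbouring-sequence-identity test: a
# 12-residue ideal helix plus 6 single-atom residues in contact (within 3 A
# of a helix atom) and 3 placed far away, all on the same chain.
make_contact_fixture <- function() {
  h <- generate_ideal_helix(12)
  base <- tibble::tibble(
    chain = "A", resno = h$res_index + 1L, insert = "",
    auth_res = as.character(h$res_index + 1L), resid = "ALA",
    atom = h$atom, x = h$x, y = h$y, z = h$z, occupancy = 1
  )
  anchor <- as.matrix(h[h$atom == "CA" & h$res_index %in% c(2L, 4L, 6L),
                        c("x", "y", "z")])
  near <- do.call(rbind, lapply(1:6, function(i) {
    p <- anchor[((i - 1) %% 3) + 1, ] + c(3, 0, 0) * (1 - 0.05 * i)
    tibble::tibble(chain = "A", resno = 12L + i, insert = "",
                   auth_res = as.character(12L + i), resid = "GLY",
                   atom = "CA", x = p[1], y = p[2], z = p[3], occupancy = 1)
  }))
  far <- do.call(rbind, lapply(1:3, function(i) {
    tibble::tibble(chain = "A", resno = 18L + i, insert = "",
                   auth_res = as.character(18L + i), resid = "GLY",
                   atom = "CA", x = 50 + i, y = 50, z = 50, occupancy = 1)
  }))
  model <- dplyr::bind_rows(base, near, far)
  class(model) <- c("structure_model", class(tibble::tibble()))
  model
}
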