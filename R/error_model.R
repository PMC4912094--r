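#' Heuristic confidence-interval model for kink angles
#'
#' The half-width of the 95% confidence interval on a measured kink angle
#' is predicted from the summed fit quality of the two flanking cylinder
#' fits: `epsilon = a * ln(r_n + r_c - c) + b` (degrees). The default
#' coefficients are the published calibration `a = 6.349`, `b = 13.15`,
#' `c = 0.2937`; [calibrate_error_model()] re-derives coefficients from a
#' perturbation simulation.
#'
#' The raw curve diverges to minus infinity as `r_n + r_c` approaches `c`
#' from above, and physically the sum can fall below `c` (an ideal straight
#' helix reaches about 0.27 A). The model is therefore made total by two
#' clamps: `r_n + r_c` is floored at `floor_sum_r` and the resulting epsilon
#' is floored at 0, keeping the map non-negative and monotone
#' non-decreasing.
#'
#' @param a Log slope, degrees.
#' @param b Offset, degrees.
#' @param c Horizontal shift, Angstrom.
#' @param floor_sum_r Clamp threshold on `r_n + r_c`, Angstrom.
#' @param provenance `"default"` for the shipped coefficients,
#'   `"recalibrated"` for coefficients from [calibrate_error_model()].
#' @return Object of class `kink_error_model`.
#' @export
#' @examples
#' m <- kink_error_model()
#' estimate_error(0.6, 0.6937, m)  # ln term vanishes at sum 1.2937 -> 13.15
kink_error_model <- function(a = 6.349, b = 13.15, c = 0.2937,
                             floor_sum_r = c + 0.01,
                             provenance = "default") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), floor_sum_r > c)
  structure(
    list(a = a, b = b, c = c, floor_sum_r = floor_sum_r,
         provenance = provenance),
    class = "kink_error_model"
  )
}

#' @export
print.kink_error_model <- function(x, ...) {
  cat(sprintf(
    "<kink_error_model> epsilon = %.4g * ln(sum_r - %.4g) + %.4g deg  [%s]\n",
    x$a, x$c, x$b, x$provenance))
  invisible(x)
}

#' Predict the confidence half-width for a measured angle
#'
#' @param r_n,r_c Fit quality (A) of the N- and C-terminal cylinder fits;
#'   vectorised.
#' @param model A [kink_error_model()].
#' @return `epsilon` in degrees (non-negative), the half-width of the 95%
#'   interval `theta +/- epsilon`.
#' @export
estimate_error <- function(r_n, r_c, model = kink_error_model()) {
  sum_r <- pmax(r_n + r_c, model$floor_sum_r)
  pmax(0, model$a * log(sum_r - model$c) + model$b)
}

#' Are two measured angles significantly different?
#'
#' Two angles differ when their 95% confidence intervals do not overlap:
#' `|theta1 - theta2| > epsilon1 + epsilon2`.
#'
#' @param theta1,theta2 Measured angles, degrees.
#' @param eps1,eps2 Their confidence half-widths, degrees (>= 0).
#' @return Logical (vectorised).
#' @export
angles_differ <- function(theta1, eps1, theta2, eps2) {
  abs(theta1 - theta2) > (eps1 + eps2)
}

# uniformly random unit vector(s): n x 3 matrix
.runif_sphere <- function(n) {
  z <- 2 * stats::runif(n) - 1
  phi <- 2 * pi * stats::runif(n)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Rodrigues rotation matrix for axis k (unit) and angle ang (radians)
.rotation_matrix <- function(k, ang) {
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# midpoint of a fitted cylinder: centroid of the segment projected onto the axis
.axis_midpoint <- function(xyz, fit) {
  ctr <- colMeans(xyz)
  p <- fit$axis_point
  u <- fit$axis_direction
  p + sum((ctr - p) * u) * u
}

#' Simulate measurement error by randomly rotating both fitted cylinders
#'
#' Starting from the optimal cylinder fits of a kink site (whose axes define
#' the "true" angle), each cylinder is independently rotated about its own
#' midpoint by a random rotation: rotation axis uniform on the sphere, tilt
#' angle uniform in `(0, max_tilt]`. The angle is re-measured from the
#' rotated (non-optimal) axes, and the fit quality of each segment's atoms
#' against its rotated axis is recomputed with a re-estimated mean radius,
#' giving the perturbed `r_n + r_c`. The deviation `alpha = theta -
#' true_angle` and `sum_r` of every sample feed the calibration in
#' [calibrate_error_model()].
#'
#' @param kink A [kink_site()].
#' @param n Number of perturbation samples.
#' @param max_tilt Maximum tilt angle in degrees (> 0).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `true_angle`, `theta`, `alpha` (degrees) and
#'   `sum_r` (A), one row per sample.
#' @export
perturb_measurement <- function(kink, n = 1000L, max_tilt = 15, seed = 1L) {
  if (max_tilt <= 0) stop("max_tilt must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  axes <- list(.runif_sphere(n), .runif_sphere(n))
  tilts <- list(stats::runif(n, 0, max_tilt), stats::runif(n, 0, max_tilt))
  segs <- list(list(xyz = kink$xyz_n, fit = kink$fit_n),
               list(xyz = kink$xyz_c, fit = kink$fit_c))
  dirs <- vector("list", 2)
  rs <- vector("list", 2)
  for (j in 1:2) {
    xyz <- segs[[j]]$xyz
    fit <- segs[[j]]$fit
    mid <- .axis_midpoint(xyz, fit)
    dmat <- matrix(NA_real_, n, 3)
    rvec <- numeric(n)
    for (i in seq_len(n)) {
      R <- .rotation_matrix(axes[[j]][i, ], tilts[[j]][i] * pi / 180)
      u <- as.vector(R %*% fit$axis_direction)
      p <- mid + as.vector(R %*% (fit$axis_point - mid))
      dmat[i, ] <- u
      rvec[i] <- cylinder_residual(xyz, p, u)$r
    }
    dirs[[j]] <- dmat
    rs[[j]] <- rvec
  }
  dot <- rowSums(dirs[[1]] * dirs[[2]])
  theta <- acos(pmin(1, pmax(-1, dot))) * 180 / pi
  tibble::tibble(
    true_angle = kink$true_angle,
    theta = theta,
    alpha = theta - kink$true_angle,
    sum_r = rs[[1]] + rs[[2]]
  )
}

# bin samples by sum_r into fixed-width bins, then merge bins holding fewer
# than min_bin samples into their smaller neighbour until all are full
.bin_samples <- function(sum_r, bin_width, min_bin) {
  lo <- floor(min(sum_r) / bin_width) * bin_width
  hi <- ceiling(max(sum_r) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width)
  bin <- findInterval(sum_r, breaks, rightmost.closed = TRUE)
  edges <- lapply(seq_len(length(breaks) - 1L),
                  function(k) c(breaks[k], breaks[k + 1L]))
  counts <- tabulate(bin, nbins = length(edges))
  keep <- counts > 0
  edges <- edges[keep]
  groups <- split(seq_along(sum_r), bin)[as.character(which(keep))]
  counts <- counts[keep]
  while (length(counts) > 1 && any(counts < min_bin)) {
    k <- which.min(counts)
    nb <- if (k == 1) 2L else if (k == length(counts)) k - 1L else {
      if (counts[k - 1] <= counts[k + 1]) k - 1L else k + 1L
    }
    a <- min(k, nb); b <- max(k, nb)
    groups[[a]] <- c(groups[[a]], groups[[b]])
    edges[[a]] <- c(edges[[a]][1], edges[[b]][2])
    counts[a] <- counts[a] + counts[b]
    groups[[b]] <- NULL; edges[[b]] <- NULL; counts <- counts[-b]
  }
  list(groups = groups, edges = edges)
}

#' Calibrate the error model from perturbation samples
#'
#' Bins samples by `r_n + r_c`, takes the 95th percentile of `|alpha|` in
#' each bin (linear interpolation between order statistics) as the bin's
#' epsilon, and least-squares fits `epsilon = a * ln(x - c) + b` over the
#' bin midpoints. Samples must come from kinks with true angle above 10
#' degrees — below that the error ceases to depend only on `r_n + r_c` and
#' such kinks are excluded from calibration.
#'
#' @param samples Tibble as returned by [perturb_measurement()] (columns
#'   `alpha`, `sum_r`, and `true_angle` used for the >10 degree check).
#' @param bin_width Bin width on `r_n + r_c`, Angstrom. Default 0.05.
#' @param min_bin Minimum samples per bin; sparser bins are merged with a
#'   neighbour. Default 100.
#' @param percentile Percentile of `|alpha|` per bin. Default 0.95.
#' @return A [kink_error_model()] with `provenance = "recalibrated"` and an
#'   attribute `bins`: tibble of `x_mid`, `epsilon`, `n` per bin.
#' @export
calibrate_error_model <- function(samples, bin_width = 0.05, min_bin = 100L,
                                  percentile = 0.95) {
  if ("true_angle" %in% names(samples)) {
    drop <- samples$true_angle <= 10
    if (any(drop)) samples <- samples[!drop, ]
  }
  if (nrow(samples) == 0) stop("no samples from kinks above 10 degrees", call. = FALSE)
  binned <- .bin_samples(samples$sum_r, bin_width, min_bin)
  if (length(binned$groups) < 5) {
    stop("calibration needs at least 5 populated bins (got ",
         length(binned$groups), ")", call. = FALSE)
  }
  x_mid <- unname(vapply(binned$edges, mean, numeric(1)))
  eps <- unname(vapply(binned$groups, function(i) {
    unname(stats::quantile(abs(samples$alpha[i]), percentile, type = 7))
  }, numeric(1)))
  n_bin <- unname(lengths(binned$groups))
  start_c <- min(x_mid) - 0.05
  fit <- minpack.lm::nlsLM(
    eps ~ a * log(x_mid - c) + b,
    data = data.frame(x_mid = x_mid, eps = eps),
    start = list(a = 6, b = 13, c = start_c),
    upper = c(a = Inf, b = Inf, c = min(x_mid) - 1e-4),
    lower = c(a = 1e-6, b = -Inf, c = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  model <- kink_error_model(a = unname(cf["a"]), b = unname(cf["b"]),
                            c = unname(cf["c"]),
                            floor_sum_r = unname(cf["c"]) + 0.01,
                            provenance = "recalibrated")
  attr(model, "bins") <- tibble::tibble(x_mid = x_mid, epsilon = eps, n = n_bin)
  attr(model, "bin_edges") <- binned$edges
  model
}

#' Empirical coverage of the binned confidence intervals
#'
#' Assigns fresh perturbation samples to the calibration bins of a
#' recalibrated model and reports, per bin, the fraction of samples with
#' `|alpha|` at or below the bin's epsilon. Coverage near the calibration
#' percentile (95%) on samples not used in calibration is the check that
#' the interval means what it claims.
#'
#' @param model A recalibrated [kink_error_model()] carrying a `bins`
#'   attribute.
#' @param samples Fresh samples from [perturb_measurement()].
#' @return Tibble with `x_mid`, `epsilon`, `n` and `coverage` per bin
#'   (bins receiving no fresh samples are dropped).
#' @export
coverage_by_bin <- function(model, samples) {
  edges <- attr(model, "bin_edges")
  bins <- attr(model, "bins")
  if (is.null(edges) || is.null(bins)) {
    stop("model carries no calibration bins; use calibrate_error_model()",
         call. = FALSE)
  }
  if ("true_angle" %in% names(samples)) {
    samples <- samples[samples$true_angle > 10, ]
  }
  out <- vector("list", length(edges))
  for (k in seq_along(edges)) {
    lo <- edges[[k]][1]; hi <- edges[[k]][2]
    inb <- if (k == length(edges)) {
      samples$sum_r >= lo & samples$sum_r <= hi
    } else {
      samples$sum_r >= lo & samples$sum_r < hi
    }
    if (!any(inb)) next
    out[[k]] <- tibble::tibble(
      x_mid = bins$x_mid[k], epsilon = bins$epsilon[k], n = sum(inb),
      coverage = mean(abs(samples$alpha[inb]) <= bins$epsilon[k])
    )
  }
  dplyr::bind_rows(out)
}
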