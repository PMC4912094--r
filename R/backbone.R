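#' Construct a helix backbone table
#'
#' A helix backbone is a tibble with one row per backbone atom (N, CA, C, O)
#' of each residue of a single helix, ordered N-terminal to C-terminal.
#' It is the unit of input for [fit_cylinder()] and [measure_angles()].
#'
#' @param x A data frame with columns `helix_id`, `chain_id`, `res_index`
#'   (0-based, contiguous within the helix), `auth_res` (author residue
#'   identifier, kept verbatim), `resid` (3-letter residue name), `atom`
#'   (one of `"N"`, `"CA"`, `"C"`, `"O"`) and coordinates `x`, `y`, `z`
#'   in Angstroms.
#'
#' @details Construction enforces that residues are strictly ordered with no
#'   duplicates and that every residue carries all four backbone atoms;
#'   residues missing any backbone atom are rejected here, not silently
#'   dropped. Helices of any length can be constructed — the 12-residue
#'   minimum applies to angle measurement, not to the container
#'   (see [is_measurable()]).
#'
#' @return A tibble of class `helix_backbone`.
#' @export
#' @examples
#' h <- generate_ideal_helix(14)
#' helix_length(h)
helix_backbone <- function(x) {
  needed <- c("helix_id", "chain_id", "res_index", "auth_res", "resid",
              "atom", "x", "y", "z")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("helix_backbone is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[needed]
  x$res_index <- as.integer(x$res_index)
  ridx <- unique(x$res_index)
  if (any(diff(ridx) <= 0)) {
    stop("residues must be strictly ordered N- to C-terminal with no duplicates",
         call. = FALSE)
  }
  per_res <- split(x$atom, x$res_index)
  ok <- vapply(per_res, function(a) setequal(a, c("N", "CA", "C", "O")) &&
                 length(a) == 4L, logical(1))
  if (!all(ok)) {
    bad <- names(per_res)[!ok]
    stop("residue(s) ", paste(bad, collapse = ", "),
         " lack a complete N/CA/C/O backbone", call. = FALSE)
  }
  # canonical atom order within each residue
  x$atom <- factor(x$atom, levels = c("N", "CA", "C", "O"))
  x <- dplyr::arrange(x, .data$res_index, .data$atom)
  x$atom <- as.character(x$atom)
  class(x) <- c("helix_backbone", class(tibble::tibble()))
  x
}

#' Number of residues in a helix backbone
#' @param helix A `helix_backbone`.
#' @return Integer residue count.
#' @export
helix_length <- function(helix) {
  length(unique(helix$res_index))
}

#' Can a helix be analysed for kink angles?
#'
#' Angle measurement needs two disjoint six-residue segments, so only
#' helices of 12 residues or more can be analysed.
#'
#' @param helix A `helix_backbone`.
#' @return Logical.
#' @export
is_measurable <- function(helix) {
  helix_length(helix) >= 12L
}

#' Coordinates of a six-residue segment
#'
#' Returns the 24 x 3 coordinate matrix of the six-residue segment starting
#' at 0-based residue index `start` (atoms ordered residue-major, N/CA/C/O
#' within each residue) — the input unit of [fit_cylinder()].
#'
#' @param helix A `helix_backbone`.
#' @param start 0-based index of the segment's first residue.
#' @return A 24 x 3 numeric matrix, Angstrom.
#' @export
segment_xyz <- function(helix, start) {
  idx <- sort(unique(helix$res_index))
  want <- idx[(match(start, idx)):(match(start, idx) + 5L)]
  seg <- helix[helix$res_index %in% want, ]
  if (nrow(seg) != 24L) {
    stop("segment starting at residue index ", start,
         " does not span six complete residues", call. = FALSE)
  }
  as.matrix(seg[, c("x", "y", "z")])
}

# centroid of a residue's four backbone atoms
residue_centroid <- function(helix, res_index) {
  r <- helix[helix$res_index == res_index, c("x", "y", "z")]
  colMeans(as.matrix(r))
}

#' Apply a rigid motion (and optionally a reflection) to a helix backbone
#'
#' Utility for invariance checks: kink angles must be unchanged under any
#' rotation, translation or reflection of the coordinates.
#'
#' @param helix A `helix_backbone`.
#' @param rotation 3x3 orthogonal matrix (determinant +1 or -1).
#' @param translation Length-3 numeric vector, Angstroms.
#' @return The transformed `helix_backbone`.
#' @export
transform_helix <- function(helix, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(helix[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  helix$x <- xyz[, 1]
  helix$y <- xyz[, 2]
  helix$z <- xyz[, 3]
  helix
}

#' Reverse the residue order of a helix backbone
#'
#' Relabels residues so the C-terminus becomes residue 0. Used for the
#' angle-symmetry property: the multiset of kink angles is direction-blind.
#'
#' @param helix A `helix_backbone`.
#' @return A `helix_backbone` with reversed residue order.
#' @export
reverse_helix <- function(helix) {
  n <- helix_length(helix)
  old <- sort(unique(helix$res_index))
  helix$res_index <- (n - 1L) - as.integer(helix$res_index)
  helix <- helix[order(helix$res_index, match(helix$atom, c("N", "CA", "C", "O"))), ]
  helix_backbone(helix)
}
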