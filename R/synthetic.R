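# Cylindrical placement of backbone atoms for the canonical straight helix.
# Radii and the phase / rise offsets of N, C, O relative to CA were computed
# once from a backbone built by internal coordinates at phi = -57, psi = -47,
# omega = 180 (Engh-Huber bond lengths and angles); the helix pitch is then
# idealised to a rise of 1.5 A and a twist of 100 deg per residue. This is
# the fixture's definition of "ideal": a geometrically regular alpha-helix,
# not any particular crystal structure.
.ideal_geom <- list(
  rise = 1.5,                         # A per residue
  twist = 100,                        # degrees per residue
  atoms = data.frame(
    atom   = c("N", "CA", "C", "O"),
    radius = c(1.5514, 2.2759, 1.6661, 1.9208),   # A
    dphase = c(-26.771, 0, 26.743, 20.338),       # deg, relative to CA
    dz     = c(-0.9187, 0, 1.0689, 2.2566)        # A, relative to CA
  )
)

#' Generate a geometrically ideal straight alpha-helix backbone
#'
#' Places N, CA, C and O atoms on coaxial cylinders with a rise of
#' 1.5 Angstrom and a twist of 100 degrees per residue, using fixed
#' per-atom-type radii and phase offsets taken from standard alpha-helical
#' internal coordinates (phi = -57, psi = -47). The helix axis is the
#' z-axis. Deterministic: the same `n` always yields identical coordinates.
#'
#' @param n Number of residues (>= 1).
#' @param helix_id,chain_id Identifiers stored in the output table.
#' @param start_resno First author residue number.
#' @return A [helix_backbone()] tibble of `n` residues.
#' @export
#' @examples
#' h <- generate_ideal_helix(20)
#' range(measure_angles(h)$theta_deg)  # essentially straight
generate_ideal_helix <- function(n, helix_id = "ideal", chain_id = "A",
                                 start_resno = 1L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  g <- .ideal_geom
  res <- rep(seq_len(n) - 1L, each = 4L)
  at <- g$atoms[rep(seq_len(4L), n), ]
  phase <- (res * g$twist + at$dphase) * pi / 180
  helix_backbone(tibble::tibble(
    helix_id = helix_id,
    chain_id = chain_id,
    res_index = res,
    auth_res = as.character(res + as.integer(start_resno)),
    resid = "ALA",
    atom = at$atom,
    x = at$radius * cos(phase),
    y = at$radius * sin(phase),
    z = res * g$rise + at$dz
  ))
}

#' Generate a synthetic kinked helix with known kink angle
#'
#' Builds an ideal straight helix and rotates the C-terminal arm (residues
#' after `kink_position`) by `kink_angle` about an axis through the junction
#' point perpendicular to the N-arm axis. The final residue of the N-arm is
#' shared; no residues are removed, so the measured kink site falls at
#' `kink_position`. Optional isotropic Gaussian coordinate noise emulates
#' imperfect real geometry; with a fixed seed the output is bit-identical
#' across calls.
#'
#' @param n Number of residues.
#' @param kink_angle Kink angle in degrees, `0 <= kink_angle < 180`
#'   (0 reproduces [generate_ideal_helix()] exactly when `noise_sd = 0`).
#' @param kink_position 0-based residue index of the kink site; must satisfy
#'   `5 <= kink_position <= n - 7` so both flanking six-residue segments
#'   exist.
#' @param noise_sd Standard deviation (Angstrom) of iid Gaussian noise added
#'   to every coordinate. Default 0.
#' @param seed Integer RNG seed used when `noise_sd > 0`.
#' @param helix_id,chain_id,start_resno Passed to the underlying generator.
#' @return A [helix_backbone()] tibble.
#' @export
#' @examples
#' k <- generate_kinked_helix(20, kink_angle = 30, kink_position = 10)
#' prof <- measure_angles(k)
#' prof$site_index[which.max(prof$theta_deg)]  # 10
generate_kinked_helix <- function(n, kink_angle, kink_position,
                                  noise_sd = 0, seed = 1L,
                                  helix_id = "kinked", chain_id = "A",
                                  start_resno = 1L) {
  if (kink_angle < 0 || kink_angle >= 180) {
    stop("kink_angle must be in [0, 180)", call. = FALSE)
  }
  if (kink_angle > 0 && (kink_position < 5 || kink_position > n - 7)) {
    stop("kink_position must be between 5 and n - 7 for a measurable kink",
         call. = FALSE)
  }
  h <- generate_ideal_helix(n, helix_id = helix_id, chain_id = chain_id,
                            start_resno = start_resno)
  if (kink_angle > 0) {
    g <- .ideal_geom
    junction <- c(0, 0, (kink_position + 0.5) * g$rise)
    ang <- kink_angle * pi / 180
    # rotation about the x-axis (perpendicular to the N-arm axis, z)
    rot <- matrix(c(1, 0, 0,
                    0, cos(ang), -sin(ang),
                    0, sin(ang),  cos(ang)), 3, 3, byrow = TRUE)
    move <- h$res_index > kink_position
    xyz <- as.matrix(h[move, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, junction)
    xyz <- xyz %*% t(rot)
    xyz <- sweep(xyz, 2, junction, "+")
    h[move, c("x", "y", "z")] <- as.data.frame(xyz)
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    m <- nrow(h)
    h$x <- h$x + stats::rnorm(m, 0, noise_sd)
    h$y <- h$y + stats::rnorm(m, 0, noise_sd)
    h$z <- h$z + stats::rnorm(m, 0, noise_sd)
  }
  h
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate an aligned helix-family fixture on disk
#'
#' Writes one PDB file per member (a synthetic kinked or straight helix), a
#' helix-annotation TSV covering all members, and an aligned FASTA whose
#' sequences are consistent with the generated helices. The spectrum of
#' per-member kink angles controls the family class the downstream
#' classification should produce, which makes this the end-to-end fixture
#' for family tests.
#'
#' @param kink_angles Numeric vector of per-member kink angles in degrees
#'   (0 = straight member); one member per element.
#' @param dir Output directory (created if needed).
#' @param n Residues per member helix.
#' @param kink_position 0-based kink site shared by all kinked members.
#' @param noise_sd Coordinate noise per member, Angstrom.
#' @param seed Integer seed; member i uses `seed + i`.
#' @param gap_columns Optional named list: for a member id, integer vector of
#'   0-based alignment columns at which that member carries a gap. Gapped
#'   members are generated with correspondingly fewer residues so sequences
#'   and structures stay consistent.
#' @return A tibble with one row per member: `member`, `pdb`, `helix_id`,
#'   `kink_angle`, plus attributes `annotations` (path to the TSV) and
#'   `alignment` (path to the FASTA).
#' @export
generate_family_fixture <- function(kink_angles, dir,
                                    n = 20L, kink_position = 10L,
                                    noise_sd = 0, seed = 1L,
                                    gap_columns = NULL) {
  n_members <- length(kink_angles)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  members <- sprintf("mem%02d", seq_len(n_members))
  ncol_aln <- n
  rows <- vector("list", n_members)
  seqs <- character(n_members)
  annot <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    gaps <- integer(0)
    if (!is.null(gap_columns) && members[i] %in% names(gap_columns)) {
      gaps <- as.integer(gap_columns[[members[i]]])
    }
    n_i <- n - length(gaps)
    kp_i <- kink_position - sum(gaps <= kink_position)
    h <- generate_kinked_helix(n_i, kink_angles[i], kp_i,
                               noise_sd = noise_sd, seed = seed + i,
                               helix_id = members[i], chain_id = "A")
    pdb <- file.path(dir, paste0(members[i], ".pdb"))
    write_helix_pdb(h, pdb)
    rows[[i]] <- tibble::tibble(member = members[i], pdb = pdb,
                                helix_id = members[i],
                                kink_angle = kink_angles[i])
    chars <- rep("A", ncol_aln)
    if (length(gaps)) chars[gaps + 1L] <- "-"
    seqs[i] <- paste(chars, collapse = "")
    annot[[i]] <- tibble::tibble(helix_id = members[i], chain = "A",
                                 start_res = 1L, end_res = n_i)
  }
  annot_path <- file.path(dir, "helices.tsv")
  utils::write.table(dplyr::bind_rows(annot), annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  aln_path <- file.path(dir, "family.fasta")
  writeLines(as.vector(rbind(paste0(">", members), seqs)), aln_path)
  out <- dplyr::bind_rows(rows)
  attr(out, "annotations") <- annot_path
  attr(out, "alignment") <- aln_path
  out
}
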