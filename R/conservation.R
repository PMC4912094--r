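#' Read a gapped (aligned) FASTA file
#'
#' @param path Path to an aligned FASTA.
#' @return Named character vector of upper-case gapped sequences.
#' @export
read_alignment <- function(path) {
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          forceDNAtolower = FALSE)
  out <- toupper(vapply(s, function(x) as.character(x)[1], character(1)))
  names(out) <- names(s)
  out
}

# 0-based alignment column of each residue ordinal (1..n non-gap chars)
.residue_columns <- function(gapped) {
  chars <- strsplit(gapped, "")[[1]]
  which(chars != "-") - 1L
}

#' Map an angle profile onto alignment columns
#'
#' Residue `i` of the helix (0-based) corresponds to the `i+1`-th non-gap
#' character of its gapped alignment row. Errors if the alignment row does
#' not carry enough residues for the profile's sites.
#'
#' @param profile An `angle_profile` from [measure_angles()].
#' @param gapped The helix's gapped sequence from the alignment.
#' @return The profile with an added 0-based `column` and the aligned
#'   residue letter `aa`.
#' @export
aligned_profile <- function(profile, gapped) {
  cols <- .residue_columns(gapped)
  need <- max(profile$site_index) + 7L   # helix length implied by the profile
  if (length(cols) < need) {
    stop("alignment row has ", length(cols), " residues but the profile's ",
         "helix has ", need, call. = FALSE)
  }
  chars <- strsplit(gapped, "")[[1]]
  profile$column <- cols[profile$site_index + 1L]
  profile$aa <- chars[profile$column + 1L]
  profile
}

#' Homology filter for candidate helix pairs
#'
#' A candidate pair of helices from two structurally aligned chains passes
#' when (i) the longer chain is no more than 50% longer than the shorter,
#' (ii) the structural alignment's TM-score exceeds 0.5 (same fold),
#' (iii) alignment sequence identity (ignoring gaps) is at least 10%, and
#' (iv) both helix ends are offset by no more than four residues in the
#' alignment. All arguments vectorise.
#'
#' @param len_a,len_b Chain lengths, residues.
#' @param tm_score TM-score of the chain alignment, in `[0, 1]`.
#' @param seq_identity Alignment sequence identity ignoring gaps, `[0, 1]`.
#' @param offset_n,offset_c Absolute offsets (residues) of the helices'
#'   N- and C-terminal ends in the alignment.
#' @return Logical: is the pair considered homologous?
#' @export
#' @examples
#' filter_homologous_pair(100, 160, 0.8, 0.5, 0, 0)  # FALSE: 160 > 150
filter_homologous_pair <- function(len_a, len_b, tm_score, seq_identity,
                                   offset_n, offset_c) {
  longer <- pmax(len_a, len_b)
  shorter <- pmin(len_a, len_b)
  longer <= 1.5 * shorter &
    tm_score > 0.5 &
    seq_identity >= 0.10 &
    abs(offset_n) <= 4 &
    abs(offset_c) <= 4
}

#' Locate the most disrupted site of a homologous helix pair
#'
#' The site of the greatest angle in either helix is the pair's most
#' disrupted site (`theta_max`). The other helix contributes its largest
#' angle within a window of +/-4 alignment columns of that site
#' (`theta_min`). If gaps leave no angle in that window, the pair is
#' removed from analysis (flagged, not an error).
#'
#' @param profile_a,profile_b Aligned profiles (see [aligned_profile()]),
#'   i.e. carrying a `column`.
#' @param window Window half-width in alignment columns. Default 4.
#' @return One-row tibble: `removed`, `max_helix` ("a"/"b"), `col_max`,
#'   `col_min`, `theta_max`, `theta_min`, `eps1`, `eps2` (epsilon of the
#'   max- and min-angle measurements).
#' @export
pair_most_disrupted <- function(profile_a, profile_b, window = 4L) {
  stopifnot("column" %in% names(profile_a), "column" %in% names(profile_b))
  if (nrow(profile_a) == 0 || nrow(profile_b) == 0) {
    stop("both profiles must be non-empty", call. = FALSE)
  }
  both <- dplyr::bind_rows(
    dplyr::mutate(profile_a, .helix = "a"),
    dplyr::mutate(profile_b, .helix = "b")
  )
  imax <- which.max(both$theta_deg)
  max_helix <- both$.helix[imax]
  col_max <- both$column[imax]
  other <- if (max_helix == "a") profile_b else profile_a
  inwin <- other[abs(other$column - col_max) <= window, ]
  if (nrow(inwin) == 0) {
    return(tibble::tibble(removed = TRUE, max_helix = max_helix,
                          col_max = col_max, col_min = NA_integer_,
                          theta_max = both$theta_deg[imax],
                          theta_min = NA_real_,
                          eps1 = both$epsilon_deg[imax], eps2 = NA_real_))
  }
  jmin <- which.max(inwin$theta_deg)
  tibble::tibble(
    removed = FALSE, max_helix = max_helix,
    col_max = col_max, col_min = inwin$column[jmin],
    theta_max = both$theta_deg[imax], theta_min = inwin$theta_deg[jmin],
    eps1 = both$epsilon_deg[imax], eps2 = inwin$epsilon_deg[jmin]
  )
}

#' Classify a homologous helix pair
#'
#' Four classes partition all pairs (threshold default 20 degrees):
#' Conserved Straight (`theta_max < 20`), Conserved Kinked
#' (`theta_min > 20` and `theta_max - theta_min < eps1 + eps2`),
#' Not Conserved (`theta_max > 20` and `theta_max - theta_min >
#' eps1 + eps2`), and Other (everything else). The result is invariant
#' under swapping the two helices because it depends only on the ordered
#' pair (`theta_max >= theta_min`) and the summed errors.
#'
#' @param theta_max,theta_min Larger and smaller angle at the most
#'   disrupted site, degrees.
#' @param eps1,eps2 Confidence half-widths of the two angles, degrees.
#' @param kink_threshold Kink threshold, degrees. Default 20.
#' @return Character vector: `"ConservedStraight"`, `"ConservedKinked"`,
#'   `"NotConserved"` or `"Other"` (vectorised).
#' @export
#' @examples
#' classify_pair(15, 3, 5, 5)    # ConservedStraight
#' classify_pair(30, 25, 4, 5)   # ConservedKinked
classify_pair <- function(theta_max, theta_min, eps1, eps2,
                          kink_threshold = 20) {
  stopifnot(all(theta_max >= theta_min, na.rm = TRUE))
  dtheta <- theta_max - theta_min
  sig <- dtheta > (eps1 + eps2)
  dplyr::case_when(
    theta_max < kink_threshold ~ "ConservedStraight",
    theta_min > kink_threshold & !sig ~ "ConservedKinked",
    theta_max > kink_threshold & sig ~ "NotConserved",
    TRUE ~ "Other"
  )
}

# does helix carry proline at residue ordinal `site` (0-based) or the four
# following residues? `gapped` is its alignment row.
.proline_flag <- function(gapped, site) {
  chars <- strsplit(gapped, "")[[1]]
  res <- chars[chars != "-"]
  idx <- site + 1L + 0:4
  idx <- idx[idx <= length(res)]
  any(res[idx] == "P")
}

#' Classify a homologous helix pair end to end
#'
#' Convenience pipeline: map both profiles onto the alignment, find the
#' most disrupted site, classify, and flag proline at the kink (present at
#' the position of the largest angle or in the four following residues of
#' each helix).
#'
#' @param profile_a,profile_b Angle profiles from [measure_angles()].
#' @param gapped_a,gapped_b Gapped alignment rows for the two helices.
#' @param window Alignment-column window half-width. Default 4.
#' @param kink_threshold Degrees. Default 20.
#' @return One-row tibble with the [pair_most_disrupted()] fields plus
#'   `delta_theta`, `class`, `proline_max`, `proline_min` (proline flag of
#'   the larger- and smaller-angle helix).
#' @export
classify_helix_pair <- function(profile_a, profile_b, gapped_a, gapped_b,
                                window = 4L, kink_threshold = 20) {
  pa <- aligned_profile(profile_a, gapped_a)
  pb <- aligned_profile(profile_b, gapped_b)
  md <- pair_most_disrupted(pa, pb, window = window)
  if (md$removed) {
    md$delta_theta <- NA_real_
    md$class <- "Removed"
    md$proline_max <- NA
    md$proline_min <- NA
    return(md)
  }
  md$delta_theta <- md$theta_max - md$theta_min
  md$class <- classify_pair(md$theta_max, md$theta_min, md$eps1, md$eps2,
                            kink_threshold = kink_threshold)
  pmax_prof <- if (md$max_helix == "a") pa else pb
  pmin_prof <- if (md$max_helix == "a") pb else pa
  gmax <- if (md$max_helix == "a") gapped_a else gapped_b
  gmin <- if (md$max_helix == "a") gapped_b else gapped_a
  site_max <- pmax_prof$site_index[pmax_prof$column == md$col_max][1]
  site_min <- pmin_prof$site_index[pmin_prof$column == md$col_min][1]
  md$proline_max <- .proline_flag(gmax, site_max)
  md$proline_min <- .proline_flag(gmin, site_min)
  md
}

#' Smooth aligned angles with a three-column maximum window
#'
#' For one helix's angles mapped to alignment columns, the smoothed angle
#' at column `c` is the maximum of the available angles at columns
#' `c-1, c, c+1`; it is defined wherever at least one angle exists in the
#' window (so smoothing absorbs one-column alignment inaccuracies). The
#' epsilon carried forward is that of the winning (maximum) angle.
#'
#' @param aligned Tibble with columns `column`, `theta_deg` and optionally
#'   `epsilon_deg` (one helix).
#' @return Tibble `column`, `theta_smoothed`, `epsilon_deg`, `n_window`.
#' @export
#' @examples
#' x <- tibble::tibble(column = 0:3, theta_deg = c(10, 30, 12, 5),
#'                     epsilon_deg = 5)
#' smooth_profile(x)$theta_smoothed  # 30 30 30 12
smooth_profile <- function(aligned) {
  stopifnot(all(c("column", "theta_deg") %in% names(aligned)))
  if (nrow(aligned) == 0) {
    return(tibble::tibble(column = integer(0), theta_smoothed = numeric(0),
                          epsilon_deg = numeric(0), n_window = integer(0)))
  }
  eps <- if ("epsilon_deg" %in% names(aligned)) aligned$epsilon_deg else
    rep(NA_real_, nrow(aligned))
  cols <- seq(min(aligned$column) - 1L, max(aligned$column) + 1L)
  out <- lapply(cols, function(cc) {
    inwin <- which(abs(aligned$column - cc) <= 1L)
    if (length(inwin) == 0) return(NULL)
    k <- inwin[which.max(aligned$theta_deg[inwin])]
    tibble::tibble(column = cc, theta_smoothed = aligned$theta_deg[k],
                   epsilon_deg = eps[k], n_window = length(inwin))
  })
  dplyr::bind_rows(out)
}

#' Smooth every member of an aligned family
#'
#' @param family Long tibble with columns `member`, `column`, `theta_deg`,
#'   `epsilon_deg`.
#' @return Long tibble `member`, `column`, `theta_smoothed`, `epsilon_deg`.
#' @export
smooth_family <- function(family) {
  out <- lapply(split(family, family$member), function(m) {
    s <- smooth_profile(m)
    s$member <- m$member[1]
    s
  })
  x <- dplyr::bind_rows(out)
  x[order(x$member, x$column), c("member", "column", "theta_smoothed",
                                 "epsilon_deg", "n_window")]
}

#' Most disrupted site of an aligned helix family
#'
#' Among alignment columns with at least `min_angles` smoothed angles, the
#' column with the highest mean smoothed angle; ties resolve to the
#' smallest column index.
#'
#' @param smoothed Output of [smooth_family()].
#' @param min_angles Minimum recorded smoothed angles per eligible column.
#'   Default 5.
#' @return Integer column index.
#' @export
family_most_disrupted <- function(smoothed, min_angles = 5L) {
  per_col <- dplyr::summarise(
    dplyr::group_by(smoothed, .data$column),
    n = dplyr::n(), mean_theta = mean(.data$theta_smoothed), .groups = "drop"
  )
  per_col <- per_col[per_col$n >= min_angles, ]
  if (nrow(per_col) == 0) {
    stop("no alignment column has at least ", min_angles,
         " smoothed angles", call. = FALSE)
  }
  per_col <- per_col[order(-per_col$mean_theta, per_col$column), ]
  as.integer(per_col$column[1])
}

#' Classify an aligned helix family
#'
#' At the most disrupted site, the spread of angles across members
#' (standard deviation, n-1 denominator) is compared to the mean error:
#' Conserved Straight when `theta_median < 20` and `sigma <= mu_eps`;
#' Conserved Kinked when `theta_median >= 20` and `sigma <= mu_eps`;
#' Not Conserved when `sigma > mu_eps` and the maximum angle exceeds 20;
#' Other otherwise. Ties (`sigma == mu_eps`) fall on the conserved side.
#'
#' @param smoothed Output of [smooth_family()] (>= 5 members).
#' @param column Most disrupted column; `NULL` computes it via
#'   [family_most_disrupted()].
#' @param kink_threshold Degrees. Default 20.
#' @param min_angles Minimum angles at the site. Default 5.
#' @return One-row tibble: `column`, `n`, `theta_median`, `sigma_theta`,
#'   `mu_eps`, `theta_max`, `class`.
#' @export
classify_family <- function(smoothed, column = NULL, kink_threshold = 20,
                            min_angles = 5L) {
  if (is.null(column)) {
    column <- family_most_disrupted(smoothed, min_angles = min_angles)
  }
  at <- smoothed[smoothed$column == column, ]
  if (nrow(at) < min_angles) {
    stop("most disrupted site has fewer than ", min_angles, " angles",
         call. = FALSE)
  }
  theta <- at$theta_smoothed
  sigma <- stats::sd(theta)
  mu_eps <- mean(at$epsilon_deg)
  med <- stats::median(theta)
  cls <- if (sigma <= mu_eps && med < kink_threshold) "ConservedStraight"
  else if (sigma <= mu_eps) "ConservedKinked"
  else if (max(theta) > kink_threshold) "NotConserved"
  else "Other"
  tibble::tibble(column = as.integer(column), n = nrow(at),
                 theta_median = med, sigma_theta = sigma, mu_eps = mu_eps,
                 theta_max = max(theta), class = cls)
}

#' Prune a candidate helix family by connectivity
#'
#' Every member of a family must be connected (share a homologous-pair
#' edge) with more than 90% of the other members. While any member fails,
#' the member with the lowest connectivity is removed (ties remove the
#' lexicographically smallest id, making the loop deterministic) and
#' connectivities are recomputed. Families reduced below `min_size`
#' members are discarded.
#'
#' @param members Character vector of member ids.
#' @param edges Two-column data frame / tibble of undirected edges between
#'   member ids.
#' @param min_connectivity Required fraction of other members. Default 0.9.
#' @param min_size Minimum family size to keep. Default 5.
#' @return Character vector of retained members (sorted), or `character(0)`
#'   if the family is discarded.
#' @export
prune_family <- function(members, edges, min_connectivity = 0.9,
                         min_size = 5L) {
  members <- sort(unique(as.character(members)))
  e1 <- as.character(edges[[1]]); e2 <- as.character(edges[[2]])
  repeat {
    if (length(members) < 2) break
    deg <- vapply(members, function(m) {
      nb <- unique(c(e2[e1 == m], e1[e2 == m]))
      sum(nb %in% setdiff(members, m))
    }, numeric(1))
    conn <- deg / (length(members) - 1)
    if (all(conn > min_connectivity)) break
    worst <- members[conn == min(conn)]
    members <- setdiff(members, sort(worst)[1])
  }
  if (length(members) < min_size) character(0) else sort(members)
}

#' Sequence identity between two aligned (gapped) sequences
#'
#' Identity is matches divided by the number of compared columns; columns
#' where either sequence has a gap are ignored. An optional 0-based column
#' subset restricts the comparison (e.g. to neighbouring residues).
#'
#' @param gapped_a,gapped_b Gapped sequences of equal length.
#' @param columns Optional integer vector of 0-based alignment columns.
#' @return Identity in `[0, 1]`, or `NA` if no column is comparable.
#' @export
#' @examples
#' sequence_identity("ACDEF", "ACD-F")  # 1: the gap column is ignored
sequence_identity <- function(gapped_a, gapped_b, columns = NULL) {
  a <- strsplit(gapped_a, "")[[1]]
  b <- strsplit(gapped_b, "")[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  use <- seq_along(a)
  if (!is.null(columns)) use <- intersect(use, columns + 1L)
  use <- use[a[use] != "-" & b[use] != "-"]
  if (length(use) == 0) return(NA_real_)
  mean(a[use] == b[use])
}

#' Mean pairwise sequence identity of a family alignment
#'
#' @param gapped Character vector (>= 2) of gapped sequences.
#' @param columns Optional 0-based column subset.
#' @return Mean of [sequence_identity()] over all member pairs.
#' @export
family_sequence_identity <- function(gapped, columns = NULL) {
  n <- length(gapped)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  pairs <- utils::combn(n, 2)
  vals <- apply(pairs, 2, function(ij) {
    sequence_identity(gapped[ij[1]], gapped[ij[2]], columns = columns)
  })
  mean(vals, na.rm = TRUE)
}

#' Neighbouring sequence identity of a homologous helix pair
#'
#' For each structure, the neighbour set is the residues of the helix's own
#' chain outside the helix with at least one atom within `cutoff` (4 A) of
#' any helix atom. Identity is computed over the union of the two neighbour
#' sets' alignment columns, ignoring gap columns. An empty union yields
#' `NA` (missing), never 0.
#'
#' @param model_a,model_b `structure_model` tables.
#' @param chain_a,chain_b Chain ids carrying the helices.
#' @param range_a,range_b Length-2 integer vectors `(start_res, end_res)`
#'   of the helices, author numbering.
#' @param gapped_a,gapped_b Gapped chain sequences from the chain
#'   alignment (residue ordinals follow the order of residues in the
#'   model's chain).
#' @param cutoff Contact distance, Angstrom. Default 4.
#' @return List: `identity` (fraction or `NA`), `columns` (0-based union
#'   columns used), `n_neighbours_a`, `n_neighbours_b`.
#' @export
neighbouring_sequence_identity <- function(model_a, model_b,
                                           chain_a, range_a, gapped_a,
                                           chain_b, range_b, gapped_b,
                                           cutoff = 4) {
  nb_cols <- function(model, chain, range, gapped) {
    m <- model[model$chain == chain, ]
    res_keys <- unique(paste(m$resno, m$insert, sep = "\r"))
    in_helix <- function(key) {
      resno <- as.integer(sub("\r.*", "", key))
      resno >= range[1] & resno <= range[2]
    }
    helix_atoms <- as.matrix(m[in_helix(paste(m$resno, m$insert, sep = "\r")),
                               c("x", "y", "z")])
    if (nrow(helix_atoms) == 0) {
      stop("helix range not found in chain ", chain, call. = FALSE)
    }
    nb <- vapply(res_keys, function(key) {
      if (in_helix(key)) return(FALSE)
      a <- as.matrix(m[paste(m$resno, m$insert, sep = "\r") == key,
                       c("x", "y", "z")])
      d2 <- outer(rowSums(a^2), rowSums(helix_atoms^2), "+") -
        2 * a %*% t(helix_atoms)
      any(d2 <= cutoff^2)
    }, logical(1))
    cols <- .residue_columns(gapped)
    ord <- which(nb)   # residue ordinals (1-based) of neighbours
    ord <- ord[ord <= length(cols)]
    list(cols = cols[ord], n = sum(nb))
  }
  a <- nb_cols(model_a, chain_a, range_a, gapped_a)
  b <- nb_cols(model_b, chain_b, range_b, gapped_b)
  union_cols <- sort(union(a$cols, b$cols))
  ident <- if (length(union_cols) == 0) NA_real_ else
    sequence_identity(gapped_a, gapped_b, columns = union_cols)
  list(identity = ident, columns = union_cols,
       n_neighbours_a = a$n, n_neighbours_b = b$n)
}

#' Spearman correlation between the angles at two family sites
#'
#' Over the members having an angle at both alignment columns, computes
#' Spearman's rank correlation (average ranks for ties). Requires at least
#' `min_members` paired observations.
#'
#' @param smoothed Long tibble (`member`, `column`, `theta_smoothed`),
#'   e.g. from [smooth_family()].
#' @param col_i,col_j Alignment columns to correlate.
#' @param min_members Minimum paired members. Default 5.
#' @return Spearman's rho.
#' @export
correlate_sites <- function(smoothed, col_i, col_j, min_members = 5L) {
  xi <- smoothed[smoothed$column == col_i, c("member", "theta_smoothed")]
  xj <- smoothed[smoothed$column == col_j, c("member", "theta_smoothed")]
  m <- merge(xi, xj, by = "member")
  if (nrow(m) < min_members) {
    stop("fewer than ", min_members, " members have angles at both sites",
         call. = FALSE)
  }
  stats::cor(m$theta_smoothed.x, m$theta_smoothed.y, method = "spearman")
}
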