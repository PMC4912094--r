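#' Per-site summary table for an aligned helix family
#'
#' One row per alignment column: number of smoothed angles, five-number
#' summary (min, lower quartile, median, upper quartile, max), mean
#' epsilon, and a flag on the most disrupted site. The family-level
#' classification statistics are attached as attributes (`class`,
#' `sigma_theta`, `mu_eps`) so report writers can reproduce the usual
#' per-helix annotation.
#'
#' @param smoothed Output of [smooth_family()].
#' @param classification Optional one-row tibble from [classify_family()];
#'   computed when `NULL`.
#' @param min_angles Eligibility threshold for the most disrupted site.
#' @return Tibble: `column`, `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `mean_eps`, `most_disrupted`.
#' @export
family_profile_report <- function(smoothed, classification = NULL,
                                  min_angles = 5L) {
  if (is.null(classification)) {
    classification <- classify_family(smoothed, min_angles = min_angles)
  }
  per_col <- dplyr::summarise(
    dplyr::group_by(smoothed, .data$column),
    n = dplyr::n(),
    min = min(.data$theta_smoothed),
    q1 = unname(stats::quantile(.data$theta_smoothed, 0.25)),
    median = stats::median(.data$theta_smoothed),
    q3 = unname(stats::quantile(.data$theta_smoothed, 0.75)),
    max = max(.data$theta_smoothed),
    mean_eps = mean(.data$epsilon_deg),
    .groups = "drop"
  )
  per_col$most_disrupted <- per_col$column == classification$column
  attr(per_col, "class_label") <- classification$class
  attr(per_col, "sigma_theta") <- classification$sigma_theta
  attr(per_col, "mu_eps") <- classification$mu_eps
  per_col
}

#' Split a family site's angles by subgroup labels
#'
#' Emits, for one alignment column, the angles of each labelled subgroup
#' (e.g. receptor subfamily, agonist vs antagonist bound) and the
#' per-label medians, for external plotting or testing of bimodal
#' distributions.
#'
#' @param smoothed Output of [smooth_family()].
#' @param labels Named character vector mapping member id to label; every
#'   member at the column must be labelled.
#' @param column Alignment column of interest.
#' @return List with `angles` (tibble `member`, `label`, `theta_smoothed`)
#'   and `medians` (tibble `label`, `n`, `median`).
#' @export
subgroup_split_report <- function(smoothed, labels, column) {
  at <- smoothed[smoothed$column == column, ]
  unknown <- setdiff(at$member, names(labels))
  if (length(unknown) > 0) {
    stop("unlabelled member(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  at$label <- unname(labels[at$member])
  medians <- dplyr::summarise(
    dplyr::group_by(at, .data$label),
    n = dplyr::n(), median = stats::median(.data$theta_smoothed),
    .groups = "drop"
  )
  list(angles = tibble::as_tibble(at[, c("member", "label", "theta_smoothed")]),
       medians = medians)
}

#' Build a long family angle table from profiles and an alignment
#'
#' @param profiles Named list of `angle_profile` tibbles (names = member
#'   ids matching the alignment).
#' @param alignment Named character vector of gapped sequences (see
#'   [read_alignment()]).
#' @return Long tibble `member`, `column`, `theta_deg`, `epsilon_deg`.
#' @export
family_angles <- function(profiles, alignment) {
  missing_aln <- setdiff(names(profiles), names(alignment))
  if (length(missing_aln) > 0) {
    stop("no alignment row for member(s): ",
         paste(missing_aln, collapse = ", "), call. = FALSE)
  }
  out <- lapply(names(profiles), function(m) {
    ap <- aligned_profile(profiles[[m]], alignment[[m]])
    tibble::tibble(member = m, column = ap$column,
                   theta_deg = ap$theta_deg, epsilon_deg = ap$epsilon_deg)
  })
  dplyr::bind_rows(out)
}
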