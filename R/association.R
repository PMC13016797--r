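# Pairwise association detection from calibrated trajectories: frame-wise
# Euclidean distance matrices thresholded at a body-length-based radius, and
# dyadic aggregation with relatedness / sex / mating-status labels.

#' Derive the association distance threshold
#'
#' The association radius is a multiple of mean body length: with fish
#' averaging 1.76 cm, two body lengths give the default 3.52 cm radius.
#'
#' @param mean_body_length cm.
#' @param multiplier body-length multiple (2 = default close-range criterion;
#'   up to 4 is used for looser shoal-membership definitions).
#' @return an object of class `association_threshold` with fields `radius`
#'   (cm), `basis`, `multiplier`, `mean_body_length`.
#' @export
derive_threshold <- function(mean_body_length = 1.76, multiplier = 2) {
  check_number(mean_body_length, "mean_body_length", lower = 1e-9)
  check_number(multiplier, "multiplier", lower = 1e-9)
  structure(list(radius = multiplier * mean_body_length,
                 basis = "body-length-multiple", multiplier = multiplier,
                 mean_body_length = mean_body_length),
            class = "association_threshold")
}

#' Fixed association threshold
#'
#' @param radius cm.
#' @return an `association_threshold` with `basis = "fixed"`.
#' @export
fixed_threshold <- function(radius) {
  check_number(radius, "radius", lower = 1e-9)
  structure(list(radius = radius, basis = "fixed", multiplier = NA_real_,
                 mean_body_length = NA_real_),
            class = "association_threshold")
}

#' Euclidean distance matrix at one frame
#'
#' @param traj a [trajectory_set()].
#' @param frame 0-based frame index (matching the on-disk dialect).
#' @return symmetric `n x n` matrix of centroid distances in cm; rows/columns
#'   of missing individuals are `NA`, the diagonal is 0 where the individual
#'   is present.
#' @export
frame_distance_matrix <- function(traj, frame) {
  nf <- n_frames(traj)
  if (length(frame) != 1L || !is.finite(frame) || frame < 0 || frame >= nf)
    stop_kinpref("frame %s out of range [0, %d]", format(frame), nf - 1L)
  xy <- traj$positions[frame + 1L, , , drop = TRUE]
  xy <- matrix(xy, ncol = 2)
  d <- as.matrix(stats::dist(xy))
  miss <- is.na(xy[, 1]) | is.na(xy[, 2])
  d[miss, ] <- NA_real_
  d[, miss] <- NA_real_
  diag(d)[!miss] <- 0
  dimnames(d) <- list(traj$individual_ids, traj$individual_ids)
  d
}

#' Detect pairwise associations across a trial
#'
#' Two individuals are associated at a frame iff both centroids are valid and
#' their Euclidean distance is at most the threshold radius (inclusive
#' boundary). Frames where either centroid is missing are excluded from both
#' the numerator and the denominator of that dyad.
#'
#' @param traj a calibrated [trajectory_set()].
#' @param thr an [derive_threshold()] / [fixed_threshold()] object, or a
#'   radius in cm.
#' @param design a [trial_design()] covering all tracked individuals.
#' @return tibble with one row per unordered dyad: `arena_id`, `id_a`,
#'   `id_b`, `associated_frames`, `valid_frames`, `association_duration_s`,
#'   `relatedness` (related/unrelated), `sex_class`, `status_class`.
#' @export
detect_associations <- function(traj, thr, design) {
  if (is.numeric(thr)) thr <- fixed_threshold(thr)
  if (!inherits(thr, "association_threshold"))
    stop_kinpref("`thr` must be an association_threshold or a radius in cm")
  ids <- traj$individual_ids
  if (!setequal(ids, design$individuals$id))
    stop_kinpref("trajectory individuals do not match the trial design: %s",
                 paste(symdiff_chr(ids, design$individuals$id), collapse = ", "))
  n <- length(ids)
  pairs <- utils::combn(n, 2)
  X <- traj$positions[, , 1]
  Y <- traj$positions[, , 2]
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    dx <- X[, i] - X[, j]
    dy <- Y[, i] - Y[, j]
    d2 <- dx * dx + dy * dy
    valid <- !is.na(d2)
    assoc <- valid & d2 <= thr$radius^2
    a <- ids[i]
    b <- ids[j]
    sexes <- sort(c(design_field(design, a, "sex"),
                    design_field(design, b, "sex")))
    stats_ <- sort(c(design_field(design, a, "mating_status"),
                     design_field(design, b, "mating_status")))
    tibble::tibble(
      arena_id = design$arena_id %||% NA_character_,
      id_a = a, id_b = b,
      associated_frames = sum(assoc),
      valid_frames = sum(valid),
      association_duration_s = sum(assoc) / traj$frame_rate,
      relatedness = if (is_related(design, a, b)) "related" else "unrelated",
      sex_class = paste(sexes, collapse = "-"),
      status_class = paste(stats_, collapse = "-")
    )
  })
  dplyr::bind_rows(rows)
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Extract association bouts for one dyad
#'
#' Optional bout view of the frame-wise association indicator: maximal runs
#' of associated frames, after merging gaps shorter than `merge_gap_s` and
#' dropping bouts shorter than `min_bout_s`. Total association time is
#' aggregated frame-wise by [detect_associations()]; bouts are descriptive
#' only and both filters default to off.
#'
#' @param traj a [trajectory_set()].
#' @param thr threshold object or radius in cm.
#' @param id_a,id_b the dyad.
#' @param min_bout_s drop bouts shorter than this, seconds.
#' @param merge_gap_s merge gaps shorter than this, seconds.
#' @return tibble with `start_frame`, `end_frame` (0-based, inclusive) and
#'   `duration_s`.
#' @export
association_bouts <- function(traj, thr, id_a, id_b, min_bout_s = 0,
                              merge_gap_s = 0) {
  if (is.numeric(thr)) thr <- fixed_threshold(thr)
  i <- match(id_a, traj$individual_ids)
  j <- match(id_b, traj$individual_ids)
  if (is.na(i) || is.na(j))
    stop_kinpref("unknown individual(s): %s",
                 paste(c(id_a, id_b)[is.na(c(i, j))], collapse = ", "))
  dx <- traj$positions[, i, 1] - traj$positions[, j, 1]
  dy <- traj$positions[, i, 2] - traj$positions[, j, 2]
  assoc <- !is.na(dx) & !is.na(dy) & (dx^2 + dy^2) <= thr$radius^2
  fr <- traj$frame_rate
  if (merge_gap_s > 0) {
    r <- rle(assoc)
    gap <- !r$values & r$lengths < merge_gap_s * fr
    gap[c(1L, length(gap))] <- FALSE  # only interior gaps can be merged
    r$values[gap] <- TRUE
    assoc <- inverse.rle(r)
  }
  r <- rle(assoc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout_s * fr
  tibble::tibble(start_frame = starts[keep] - 1L, end_frame = ends[keep] - 1L,
                 duration_s = r$lengths[keep] / fr)
}

#' Count unordered dyads across arenas
#'
#' @param designs a [trial_design()] or list of them (one per arena).
#' @param subset `"all"`, `"opposite-sex"` or `"same-sex"`.
#' @return total dyad count over arenas (e.g. 12 arenas of 8 give
#'   `12 * choose(8, 2) = 336` all pairs and, in the mixed-sex design with 4
#'   females and 4 males per arena, `12 * 16 = 192` female-male pairs).
#' @export
dyad_census <- function(designs, subset = c("all", "opposite-sex", "same-sex")) {
  subset <- match.arg(subset)
  if (inherits(designs, "trial_design")) designs <- list(designs)
  sum(vapply(designs, function(d) {
    sex <- d$individuals$sex
    n <- length(sex)
    nf <- sum(sex == "female")
    nm <- n - nf
    switch(subset,
           "all" = choose(n, 2),
           "opposite-sex" = nf * nm,
           "same-sex" = choose(nf, 2) + choose(nm, 2))
  }, numeric(1)))
}
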