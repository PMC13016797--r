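# Trajectory and trial-metadata ingestion: calibrated multi-animal centroid
# tracks, gap repair, and per-trial stimulus trait differences.

## ---- arena / tank geometry -------------------------------------------------

#' Circular arena geometry
#'
#' @param radius arena radius in cm (default 18 cm, a 36 cm diameter cylinder).
#' @param center arena center, cm.
#' @return an object of class `kinpref_geometry`.
#' @export
arena_circle <- function(radius = 18, center = c(0, 0)) {
  check_number(radius, "radius", lower = 1e-9)
  structure(list(type = "circle", radius = radius, center = center),
            class = "kinpref_geometry")
}

#' Dichotomous choice-tank geometry (main compartment)
#'
#' The main compartment of the three-compartment choice tank, with the origin
#' at its lower-left corner. `width` runs between the two stimulus
#' compartments; the association zones sit at the low-x and high-x ends.
#'
#' @param width main-compartment length along the choice axis, cm.
#' @param depth tank depth (the other horizontal axis), cm.
#' @return an object of class `kinpref_geometry`.
#' @export
choice_tank <- function(width = 27, depth = 24) {
  check_number(width, "width", lower = 1e-9)
  check_number(depth, "depth", lower = 1e-9)
  structure(list(type = "rect", width = width, depth = depth),
            class = "kinpref_geometry")
}

# TRUE/FALSE/NA per row of xy (n x 2, cm); NA input -> NA.
# tol: relative tolerance on the containment test (tracking jitter).
geometry_contains <- function(geom, xy, tol = 0.02) {
  xy <- matrix(xy, ncol = 2)
  if (geom$type == "circle") {
    r <- sqrt((xy[, 1] - geom$center[1])^2 + (xy[, 2] - geom$center[2])^2)
    r <= geom$radius * (1 + tol)
  } else {
    sx <- geom$width * tol
    sy <- geom$depth * tol
    xy[, 1] >= -sx & xy[, 1] <= geom$width + sx &
      xy[, 2] >= -sy & xy[, 2] <= geom$depth + sy
  }
}

## ---- TrajectorySet ---------------------------------------------------------

#' Construct a trajectory set
#'
#' Container for per-frame centroid positions of all individuals in one trial,
#' in calibrated cm. Frames are stored 0-based in the on-disk dialect; the
#' positions array row `t` holds frame `t - 1`, so that
#' `time(frame) = frame / frame_rate` seconds.
#'
#' @param positions numeric array, `n_frames x n_individuals x 2`, cm.
#'   Missing positions are `NA`.
#' @param frame_rate frames per second.
#' @param individual_ids character vector of stable labels.
#' @param geometry a [arena_circle()] or [choice_tank()] object.
#' @param calibration pixels per cm used at ingestion (kept for round-trips).
#' @return an object of class `trajectory_set`.
#' @export
trajectory_set <- function(positions, frame_rate, individual_ids, geometry,
                           calibration = 1) {
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[3] != 2L)
    stop_kinpref("`positions` must be an n_frames x n_individuals x 2 array")
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(calibration, "calibration", lower = 1e-12)
  if (!inherits(geometry, "kinpref_geometry"))
    stop_kinpref("`geometry` must be created by arena_circle() or choice_tank()")
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != dim(positions)[2])
    stop_kinpref("length(individual_ids) must equal dim(positions)[2]")
  if (anyDuplicated(individual_ids))
    stop_kinpref("individual_ids must be unique")
  xy <- cbind(as.vector(positions[, , 1]), as.vector(positions[, , 2]))
  ok <- geometry_contains(geometry, xy)
  if (any(!ok, na.rm = TRUE))
    stop_kinpref("%d positions lie outside the stated geometry (beyond 2%% tolerance)",
                 sum(!ok, na.rm = TRUE))
  dimnames(positions) <- list(NULL, individual_ids, c("x", "y"))
  structure(list(positions = positions, frame_rate = frame_rate,
                 individual_ids = individual_ids, geometry = geometry,
                 calibration = calibration),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory_set> %d frames x %d individuals @ %g fps (%s)\n",
              d[1], d[2], x$frame_rate,
              if (x$geometry$type == "circle")
                sprintf("circular arena r=%g cm", x$geometry$radius)
              else sprintf("choice tank %g x %g cm", x$geometry$width,
                           x$geometry$depth)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1]

#' Read multi-animal centroid trajectories
#'
#' Ingests the long-form tracker dialect: one record per frame per individual
#' with columns `frame` (0-based, complete and identical for every
#' individual), `individual_id`, `x_px`, `y_px` (`NA` = lost centroid).
#' Pixel coordinates are divided by `calibration` to give cm.
#'
#' @param source a data frame in the long dialect, or a path to a CSV file.
#' @param calibration pixels per cm, > 0.
#' @param frame_rate frames per second.
#' @param geometry tank or arena geometry, in cm.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(source, calibration, frame_rate, geometry) {
  check_number(calibration, "calibration", lower = 1e-12)
  df <- if (is.character(source)) {
    readr::read_csv(source, show_col_types = FALSE, comment = "#")
  } else as.data.frame(source)
  need <- c("frame", "individual_id", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop_kinpref("trajectory table must have columns: %s",
                 paste(need, collapse = ", "))
  dup <- duplicated(df[c("frame", "individual_id")])
  if (any(dup)) {
    d1 <- df[dup, ][1L, ]
    stop_kinpref("duplicate record for frame %s, individual %s",
                 format(d1$frame), d1$individual_id)
  }
  ids <- unique(as.character(df$individual_id))
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  if (!identical(as.numeric(frames), as.numeric(seq_len(nf) - 1)))
    stop_kinpref("frame index must be 0-based and gap-free; first offending frame: %s",
                 format(frames[which(frames != seq_len(nf) - 1)[1]]))
  if (nrow(df) != nf * length(ids)) {
    tab <- table(df$individual_id)
    bad <- names(tab)[tab != nf]
    stop_kinpref("ragged frames: individual(s) %s missing records (use NA positions for lost frames)",
                 paste(bad, collapse = ", "))
  }
  pos <- array(NA_real_, dim = c(nf, length(ids), 2))
  i_f <- match(df$frame, frames)
  i_i <- match(as.character(df$individual_id), ids)
  pos[cbind(i_f, i_i, 1L)] <- df$x_px / calibration
  pos[cbind(i_f, i_i, 2L)] <- df$y_px / calibration
  trajectory_set(pos, frame_rate, ids, geometry, calibration)
}

#' Write a trajectory set in the long on-disk dialect
#'
#' Inverse of [read_trajectories()]: positions are converted back to pixels
#' with the stored calibration, frames are written 0-based.
#'
#' @param traj a [trajectory_set()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  nf <- n_frames(traj)
  ni <- length(traj$individual_ids)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = ni),
    individual_id = rep(traj$individual_ids, each = nf),
    x_px = as.vector(traj$positions[, , 1]) * traj$calibration,
    y_px = as.vector(traj$positions[, , 2]) * traj$calibration
  )
  readr::write_csv(df, path)
  invisible(path)
}

## ---- gap repair ------------------------------------------------------------

#' Gap-repair policy for tracking dropouts
#'
#' @param max_interp_frames longest run of missing frames filled by linear
#'   interpolation; longer runs are left missing and flagged.
#' @param action_beyond what downstream computations do with frames that stay
#'   missing: drop the frame for the affected individual only (default) or
#'   for every dyad touching it.
#' @return an object of class `gap_policy`.
#' @export
gap_policy <- function(max_interp_frames = 5,
                       action_beyond = c("drop-frame-for-individual",
                                         "drop-frame-for-dyad")) {
  check_number(max_interp_frames, "max_interp_frames", lower = 0)
  structure(list(max_interp_frames = as.integer(max_interp_frames),
                 action_beyond = match.arg(action_beyond)),
            class = "gap_policy")
}

#' Repair short tracking gaps by linear interpolation
#'
#' Interior runs of missing positions no longer than
#' `policy$max_interp_frames` are filled by per-coordinate linear
#' interpolation; longer runs (and leading/trailing gaps, which cannot be
#' interpolated) are left missing. Idempotent.
#'
#' @param traj a [trajectory_set()].
#' @param policy a [gap_policy()].
#' @return list with elements `traj` (repaired set) and `report` (tibble with
#'   per-individual counts of interpolated and still-missing frames).
#' @export
repair_gaps <- function(traj, policy = gap_policy()) {
  pos <- traj$positions
  ni <- dim(pos)[2]
  filled <- integer(ni)
  left <- integer(ni)
  if (policy$max_interp_frames > 0) {
    for (i in seq_len(ni)) {
      miss_before <- is.na(pos[, i, 1]) | is.na(pos[, i, 2])
      for (k in 1:2) {
        pos[, i, k] <- zoo::na.approx(pos[, i, k], na.rm = FALSE,
                                      maxgap = policy$max_interp_frames)
      }
      miss_after <- is.na(pos[, i, 1]) | is.na(pos[, i, 2])
      filled[i] <- sum(miss_before & !miss_after)
      left[i] <- sum(miss_after)
    }
  } else {
    for (i in seq_len(ni))
      left[i] <- sum(is.na(pos[, i, 1]) | is.na(pos[, i, 2]))
  }
  out <- traj
  out$positions <- pos
  report <- tibble::tibble(individual_id = traj$individual_ids,
                           frames_interpolated = filled,
                           frames_missing = left)
  list(traj = out, report = report[report$frames_interpolated > 0 |
                                     report$frames_missing > 0, ])
}

## ---- trial metadata --------------------------------------------------------

#' Construct a trial design
#'
#' Metadata for one trial: the individuals present, their family of origin,
#' sex, mating status and body measurements, plus (for dichotomous-choice
#' trials) which side holds the related and the unrelated stimulus. The
#' pairwise relatedness matrix defaults to full-sibling structure: r = 0.5
#' within a family, 0 between families, 1 on the diagonal.
#'
#' @param individuals data frame with columns `id`, `family`, `sex`
#'   (`"female"`/`"male"`), `mating_status` (`"virgin"`/`"experienced"`) and
#'   optionally `role` (`"focal"`/`"stimulus"`), `side` (`"left"`/`"right"`),
#'   `body_length_mm`, `body_area_mm2`, `orange_area_mm2`.
#' @param stimulus_side named character vector mapping sides to relatedness
#'   classes, e.g. `c(left = "related", right = "unrelated")`; choice trials
#'   only.
#' @param relatedness optional pairwise relatedness matrix overriding the
#'   family-derived default.
#' @param arena_id optional arena/trial label.
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(individuals, stimulus_side = NULL, relatedness = NULL,
                         arena_id = NULL) {
  individuals <- tibble::as_tibble(individuals)
  need <- c("id", "family", "sex", "mating_status")
  if (!all(need %in% names(individuals)))
    stop_kinpref("`individuals` must have columns: %s",
                 paste(need, collapse = ", "))
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id))
    stop_kinpref("individual ids must be unique within a trial")
  if (!all(individuals$sex %in% c("female", "male")))
    stop_kinpref("sex must be 'female' or 'male'")
  if (!all(individuals$mating_status %in% c("virgin", "experienced")))
    stop_kinpref("mating_status must be 'virgin' or 'experienced'")
  n <- nrow(individuals)
  if (is.null(relatedness)) {
    relatedness <- outer(individuals$family, individuals$family,
                         function(a, b) ifelse(a == b, 0.5, 0))
    diag(relatedness) <- 1
  } else {
    relatedness <- as.matrix(relatedness)
    if (!isTRUE(all.equal(relatedness, t(relatedness))) ||
        any(abs(diag(relatedness) - 1) > 1e-8))
      stop_kinpref("relatedness matrix must be symmetric with unit diagonal")
  }
  dimnames(relatedness) <- list(individuals$id, individuals$id)
  if (!is.null(stimulus_side)) {
    if (!setequal(names(stimulus_side), c("left", "right")) ||
        !setequal(unname(stimulus_side), c("related", "unrelated")))
      stop_kinpref("stimulus_side must be a bijection from {left, right} to {related, unrelated}")
  }
  structure(list(individuals = individuals, relatedness = relatedness,
                 stimulus_side = stimulus_side, arena_id = arena_id),
            class = "trial_design")
}

# Are two individuals related (same family, r ~ 0.5)?
is_related <- function(design, id_a, id_b) {
  design$relatedness[id_a, id_b] >= 0.25
}

design_field <- function(design, id, field) {
  ind <- design$individuals
  ind[[field]][match(id, ind$id)]
}

#' Stimulus trait differences (related minus unrelated)
#'
#' For each choice trial, the difference in each measured trait between the
#' two stimulus individuals, computed as related-stimulus value minus
#' unrelated-stimulus value so that positive differences mean the related
#' stimulus is larger. Missing traits propagate as `NA`, never as zero.
#'
#' @param designs a single [trial_design()] or a list of them; each must have
#'   stimulus individuals with `role == "stimulus"` and a `side`, plus a
#'   `stimulus_side` mapping.
#' @return tibble with one row per trial: `arena_id`, and
#'   `diff_body_length_mm`, `diff_body_area_mm2`, `diff_orange_area_mm2`.
#' @export
trait_differences <- function(designs) {
  if (inherits(designs, "trial_design")) designs <- list(designs)
  rows <- lapply(designs, function(d) {
    if (is.null(d$stimulus_side))
      stop_kinpref("trait_differences needs choice-trial designs with a stimulus_side mapping")
    ind <- d$individuals
    stim <- ind[(ind$role %||% "stimulus") == "stimulus" & !is.na(ind$side), ]
    if (nrow(stim) != 2)
      stop_kinpref("choice trial must have exactly 2 stimulus individuals")
    cls <- unname(d$stimulus_side[stim$side])
    rel <- stim[cls == "related", ]
    unrel <- stim[cls == "unrelated", ]
    grab <- function(df, col) if (col %in% names(df)) df[[col]] else NA_real_
    tibble::tibble(
      arena_id = d$arena_id %||% NA_character_,
      diff_body_length_mm = grab(rel, "body_length_mm") - grab(unrel, "body_length_mm"),
      diff_body_area_mm2 = grab(rel, "body_area_mm2") - grab(unrel, "body_area_mm2"),
      diff_orange_area_mm2 = grab(rel, "orange_area_mm2") - grab(unrel, "orange_area_mm2")
    )
  })
  dplyr::bind_rows(rows)
}
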