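# Strength-of-preference (SOP) scoring. SOP = (T_R - T_UR) / (T_R + T_UR),
# where T_R and T_UR are times spent associated with the related and the
# unrelated option: +1 = exclusive kin preference, -1 = exclusive avoidance
# of kin (inbreeding avoidance), 0 = no bias; undefined when the focal never
# associates with either option.

## ---- zone geometry and occupancy ------------------------------------------

#' Association-zone geometry of the choice tank
#'
#' The two association zones are slabs of the main compartment abutting the
#' stimulus compartments: each `depth x zone_width` cm (default 5 x 24 cm).
#' Zone membership is boundary-inclusive on the outer (tank-wall) edge and
#' half-open against the neutral region.
#'
#' @param tank a [choice_tank()] geometry.
#' @param zone_width zone extent along the choice axis, cm.
#' @return an object of class `zone_geometry`.
#' @export
zone_geometry <- function(tank = choice_tank(), zone_width = 5) {
  check_number(zone_width, "zone_width", lower = 1e-9)
  if (2 * zone_width > tank$width)
    stop_kinpref("zones overlap: 2 x %g cm exceeds the %g cm compartment",
                 zone_width, tank$width)
  structure(list(tank = tank, zone_width = zone_width),
            class = "zone_geometry")
}

new_zone_occupancy <- function(T_R, T_UR, T_neutral, first_entry_related,
                               first_entry_unrelated, trial_duration,
                               valid_frames, frame_rate, states = NULL) {
  structure(list(T_R = T_R, T_UR = T_UR, T_neutral = T_neutral,
                 first_entry_related = first_entry_related,
                 first_entry_unrelated = first_entry_unrelated,
                 trial_duration = trial_duration, valid_frames = valid_frames,
                 frame_rate = frame_rate, states = states),
            class = "zone_occupancy")
}

# Build a zone_occupancy from a per-frame state factor
# (related/unrelated/neutral, NA = invalid frame).
occupancy_from_states <- function(states, frame_rate, trial_duration) {
  valid <- !is.na(states)
  fe <- function(lev) {
    w <- which(states == lev)
    if (length(w)) w[1] - 1L else NA_integer_   # 0-based
  }
  new_zone_occupancy(
    T_R = sum(states == "related", na.rm = TRUE) / frame_rate,
    T_UR = sum(states == "unrelated", na.rm = TRUE) / frame_rate,
    T_neutral = sum(states == "neutral", na.rm = TRUE) / frame_rate,
    first_entry_related = fe("related"),
    first_entry_unrelated = fe("unrelated"),
    trial_duration = trial_duration, valid_frames = sum(valid),
    frame_rate = frame_rate, states = states
  )
}

#' @export
print.zone_occupancy <- function(x, ...) {
  cat(sprintf(
    "<zone_occupancy> T_R = %.1f s, T_UR = %.1f s, neutral = %.1f s (%d valid frames)\n",
    x$T_R, x$T_UR, x$T_neutral, x$valid_frames))
  invisible(x)
}

#' Zone occupancy of a focal individual in a choice trial
#'
#' Classifies every frame of the focal trajectory by centroid-in-rectangle
#' membership in the left/right association zones, maps sides to
#' related/unrelated via the design's `stimulus_side` assignment, and
#' accumulates occupancy times and first-entry frames. Frames with a missing
#' centroid or a centroid outside the tank beyond tolerance are invalid.
#'
#' @param traj single-individual [trajectory_set()] in choice-tank
#'   coordinates (or a multi-individual set plus `focal`).
#' @param zones a [zone_geometry()].
#' @param design a [trial_design()] with a `stimulus_side` mapping.
#' @param focal id of the focal individual (defaults to the design's
#'   `role == "focal"` individual, or the only tracked one).
#' @return a `zone_occupancy` object (occupancy totals, first entries, and
#'   the per-frame state timeline).
#' @export
zone_occupancy <- function(traj, zones = zone_geometry(), design,
                           focal = NULL) {
  if (is.null(design$stimulus_side))
    stop_kinpref("`design` must carry a stimulus_side mapping for choice trials")
  if (is.null(focal)) {
    ind <- design$individuals
    focal <- if ("role" %in% names(ind) && any(ind$role == "focal", na.rm = TRUE))
      ind$id[which(ind$role == "focal")[1]] else traj$individual_ids[1]
  }
  i <- match(focal, traj$individual_ids)
  if (is.na(i)) stop_kinpref("focal '%s' not in trajectory set", focal)
  x <- traj$positions[, i, 1]
  y <- traj$positions[, i, 2]
  tank <- zones$tank
  inside <- geometry_contains(tank, cbind(x, y))
  valid <- !is.na(inside) & inside
  side <- rep(NA_character_, length(x))
  side[valid & x < zones$zone_width] <- "left"
  side[valid & x > tank$width - zones$zone_width] <- "right"
  states <- rep(NA_character_, length(x))
  states[valid] <- "neutral"
  for (s in c("left", "right"))
    states[!is.na(side) & side == s] <- design$stimulus_side[[s]]
  states <- factor(states, levels = c("related", "unrelated", "neutral"))
  occupancy_from_states(states, traj$frame_rate,
                        length(x) / traj$frame_rate)
}

## ---- SOP scores ------------------------------------------------------------

new_sop_score <- function(value, defined, window, basis) {
  structure(list(value = value, defined = defined, window = window,
                 basis = basis), class = "sop_score")
}

#' @export
print.sop_score <- function(x, ...) {
  cat(sprintf("<sop_score> %s (%s, %s)\n",
              if (x$defined) sprintf("%.3f", x$value) else "undefined",
              x$window, x$basis))
  invisible(x)
}

#' Strength of preference from zone occupancy
#'
#' `SOP = (T_R - T_UR) / (T_R + T_UR)`, in `[-1, 1]`. When the focal spends
#' no time in either zone the score is undefined and flagged (it is excluded
#' from downstream fits, never coerced to 0).
#'
#' @param occ a `zone_occupancy` object (or any list with `T_R`, `T_UR`).
#' @param window label recorded on the score.
#' @return a `sop_score` object with fields `value`, `defined`, `window`,
#'   `basis`.
#' @export
compute_sop <- function(occ, window = "total-trial") {
  if (!is.finite(occ$T_R) || !is.finite(occ$T_UR) ||
      occ$T_R < 0 || occ$T_UR < 0)
    stop_kinpref("occupancy times must be finite and non-negative")
  tot <- occ$T_R + occ$T_UR
  if (tot == 0) return(new_sop_score(NA_real_, FALSE, window,
                                     "dichotomous-zones"))
  new_sop_score((occ$T_R - occ$T_UR) / tot, TRUE, window, "dichotomous-zones")
}

#' Restrict occupancy to the informed-choice window
#'
#' Informed choice considers association time only after the focal has
#' visited both association zones at least once: occupancy is recomputed
#' from the later of the two first-entry frames to the end of the trial.
#' Trials where a zone is never visited, or where the second zone is visited
#' too late to leave a usable window, are flagged for exclusion.
#'
#' @param occ a `zone_occupancy` with a state timeline.
#' @param min_window_s shortest usable window, seconds (default 60).
#' @return list with `occupancy` (recomputed, or `NULL` if excluded),
#'   `excluded` flag, `reason`, and `window_start_frame` (0-based).
#' @export
informed_choice_window <- function(occ, min_window_s = 60) {
  if (is.null(occ$states))
    stop_kinpref("informed_choice_window needs the per-frame state timeline")
  fr <- occ$frame_rate
  fe_r <- occ$first_entry_related
  fe_u <- occ$first_entry_unrelated
  if (is.na(fe_r) || is.na(fe_u)) {
    return(list(occupancy = NULL, excluded = TRUE,
                reason = "zone never visited",
                window_start_frame = NA_integer_))
  }
  start <- max(fe_r, fe_u)
  nf <- length(occ$states)
  window_s <- (nf - start) / fr
  if (window_s < min_window_s) {
    return(list(occupancy = NULL, excluded = TRUE,
                reason = "both zones visited too late for a usable window",
                window_start_frame = start))
  }
  st <- occ$states[(start + 1L):nf]
  list(occupancy = occupancy_from_states(st, fr, window_s),
       excluded = FALSE, reason = NA_character_, window_start_frame = start)
}

#' SOP across choice intervals
#'
#' Applies the SOP definition to occupancy accumulated within each interval
#' of the trial (default: successive thirds), to examine consistency of the
#' preference over time.
#'
#' @param occ a `zone_occupancy` with a state timeline.
#' @param edges_s interval edges in seconds, strictly increasing, within the
#'   trial; default `seq(0, trial_duration, length.out = 4)`.
#' @return tibble with one row per interval: `interval`, `start_s`, `end_s`,
#'   `T_R`, `T_UR`, `sop`, `defined`.
#' @export
interval_sop <- function(occ, edges_s = NULL) {
  if (is.null(occ$states))
    stop_kinpref("interval_sop needs the per-frame state timeline")
  fr <- occ$frame_rate
  nf <- length(occ$states)
  dur <- nf / fr
  edges_s <- edges_s %||% seq(0, dur, length.out = 4)
  if (length(edges_s) < 2 || is.unsorted(edges_s, strictly = TRUE) ||
      edges_s[1] < 0 || edges_s[length(edges_s)] > dur + 1e-9)
    stop_kinpref("interval edges must be strictly increasing within [0, %g]", dur)
  times <- (seq_len(nf) - 1L) / fr   # frame start times, half-open intervals
  out <- lapply(seq_len(length(edges_s) - 1L), function(k) {
    lo <- edges_s[k]
    hi <- edges_s[k + 1]
    sel <- times >= lo & (if (k == length(edges_s) - 1L) times <= hi
                          else times < hi)
    st <- occ$states[sel]
    o <- occupancy_from_states(st, fr, sum(sel) / fr)
    s <- compute_sop(o, window = "interval")
    tibble::tibble(interval = k, start_s = lo, end_s = hi,
                   T_R = o$T_R, T_UR = o$T_UR,
                   sop = s$value, defined = s$defined)
  })
  dplyr::bind_rows(out)
}

#' Arena-based SOP from dyadic association durations
#'
#' SOP applied to summed association durations in free-swimming arenas. In
#' the mixed-sex design the focal's related set is its 2 related opposite-sex
#' partners and the unrelated set its 2 unrelated opposite-sex partners; in
#' the same-sex design the related set is the single sibling and the
#' unrelated set the 6 unrelated individuals. Raw summed durations are used
#' by default (so the 1-vs-6 same-sex comparison keeps its group-size
#' asymmetry); `per_capita = TRUE` divides each sum by its set size.
#'
#' @param assoc association table from [detect_associations()].
#' @param focal focal individual id.
#' @param design the arena's [trial_design()].
#' @param experiment `"mixed-sex"` (opposite-sex partners) or `"same-sex"`.
#' @param per_capita normalise sums by partner-set size.
#' @return a `sop_score` with `basis = "arena-association"`.
#' @export
arena_sop <- function(assoc, focal, design,
                      experiment = c("mixed-sex", "same-sex"),
                      per_capita = FALSE) {
  experiment <- match.arg(experiment)
  ind <- design$individuals
  if (!focal %in% ind$id) stop_kinpref("focal '%s' not in design", focal)
  f_sex <- design_field(design, focal, "sex")
  partner_sex <- if (experiment == "mixed-sex")
    setdiff(c("female", "male"), f_sex) else f_sex
  partners <- ind$id[ind$sex == partner_sex & ind$id != focal]
  rel <- partners[vapply(partners, function(p) is_related(design, focal, p),
                         logical(1))]
  unrel <- setdiff(partners, rel)
  if (length(rel) == 0 || length(unrel) == 0)
    stop_kinpref("focal '%s' has an empty related or unrelated partner set", focal)
  dur_with <- function(set) {
    sel <- (assoc$id_a == focal & assoc$id_b %in% set) |
      (assoc$id_b == focal & assoc$id_a %in% set)
    sum(assoc$association_duration_s[sel])
  }
  t_r <- dur_with(rel)
  t_ur <- dur_with(unrel)
  if (per_capita) {
    t_r <- t_r / length(rel)
    t_ur <- t_ur / length(unrel)
  }
  if (t_r + t_ur == 0)
    return(new_sop_score(NA_real_, FALSE, "total-trial", "arena-association"))
  new_sop_score((t_r - t_ur) / (t_r + t_ur), TRUE, "total-trial",
                "arena-association")
}
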