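# Synthetic-data generators emulating the three study designs: zone-occupancy
# time series in a dichotomous choice tank, free-swimming group trajectories
# in a circular arena, and overdispersed behaviour counts. These stand in for
# the original recordings so the whole pipeline is testable end-to-end.

## ---- zone-occupancy trials -------------------------------------------------

#' Parameters for a synthetic dichotomous-choice zone trial
#'
#' The focal's zone occupancy is modelled as a stationary three-state process
#' (related zone / unrelated zone / neutral) sampled at frame resolution. At
#' stationarity a fraction `p_zone` of time is spent in the two association
#' zones combined, split `bias_b : (1 - bias_b)` between the related and the
#' unrelated zone, so the expected strength of preference of a trial is
#' `2 * bias_b - 1` by construction.
#'
#' @param trial_duration trial length, seconds.
#' @param frame_rate frames per second.
#' @param p_zone stationary probability of being in either association zone.
#' @param bias_b related-zone share of zone time; 0.5 = no preference.
#' @param switch_rate expected state switches per minute.
#' @param delay_s initial span during which the focal stays in the neutral
#'   region before zone use begins (a slow explorer); default 0.
#' @param seed integer seed.
#' @return an object of class `zone_sim_params`.
#' @export
zone_sim_params <- function(trial_duration = 1800, frame_rate = 10,
                            p_zone = 0.68, bias_b = 0.5, switch_rate = 4,
                            delay_s = 0, seed = 1L) {
  check_number(trial_duration, "trial_duration", lower = 1e-9)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(p_zone, "p_zone", lower = 0, upper = 1)
  check_number(bias_b, "bias_b", lower = 0, upper = 1)
  check_number(switch_rate, "switch_rate", lower = 0)
  check_number(delay_s, "delay_s", lower = 0, upper = trial_duration)
  check_number(seed, "seed")
  structure(list(trial_duration = trial_duration, frame_rate = frame_rate,
                 p_zone = p_zone, bias_b = bias_b, switch_rate = switch_rate,
                 delay_s = delay_s, seed = as.integer(seed)),
            class = "zone_sim_params")
}

#' Simulate one dichotomous-choice zone trial
#'
#' Samples the three-state occupancy chain of [zone_sim_params()]: at each
#' frame the state is redrawn from the stationary distribution with a
#' probability calibrated to the requested switch rate, otherwise kept. The
#' chain starts in its stationary distribution, so occupancy shares are
#' unbiased at any trial length.
#'
#' @param params a [zone_sim_params()].
#' @return list with `occupancy` (a zone-occupancy object, see
#'   [zone_occupancy()]) and `states` (per-frame factor:
#'   related/unrelated/neutral).
#' @export
simulate_zone_trial <- function(params) {
  if (!inherits(params, "zone_sim_params"))
    stop_kinpref("`params` must be a zone_sim_params object")
  p <- params
  nf <- round(p$trial_duration * p$frame_rate)
  n_delay <- min(nf, round(p$delay_s * p$frame_rate))
  pi_ <- c(p$p_zone * p$bias_b, p$p_zone * (1 - p$bias_b), 1 - p$p_zone)
  # Redraw probability q such that the per-frame probability of an actual
  # state change, q * (1 - sum(pi^2)), matches the requested switch rate.
  divisor <- 1 - sum(pi_^2)
  target <- p$switch_rate / (60 * p$frame_rate)
  q <- if (divisor <= 1e-12) 0 else min(1, target / divisor)
  set.seed(p$seed)
  n_act <- nf - n_delay
  states <- integer(nf)
  if (n_delay > 0) states[seq_len(n_delay)] <- 3L
  if (n_act > 0) {
    vals <- sample.int(3L, n_act, replace = TRUE, prob = pi_)
    redraw <- stats::runif(n_act) < q
    redraw[1] <- TRUE
    idx <- cummax(ifelse(redraw, seq_len(n_act), 0L))
    states[n_delay + seq_len(n_act)] <- vals[idx]
  }
  st <- factor(c("related", "unrelated", "neutral")[states],
               levels = c("related", "unrelated", "neutral"))
  list(occupancy = occupancy_from_states(st, p$frame_rate, p$trial_duration),
       states = st)
}

## ---- free-swimming arenas --------------------------------------------------

#' Parameters for a synthetic free-swimming arena
#'
#' Each individual follows a biased correlated random walk: its heading is a
#' persistence-weighted carry-over of the previous heading plus a social pull
#' toward the other individuals (weighted by the signed pairwise `attraction`
#' matrix, direction-normalised with saturating magnitude, scaled by
#' `attraction_gain`) plus wrapped-Gaussian angular noise whose spread is set
#' so the heading autocorrelation matches `heading_persistence` in the
#' asocial case. The arena boundary reflects specularly.
#'
#' @param n_individuals number of fish (>= 2).
#' @param arena_radius cm.
#' @param speed_mean,speed_sd per-frame speed draw, cm/s (truncated at 0).
#' @param heading_persistence correlated-random-walk autocorrelation in (0, 1).
#' @param attraction square matrix of signed social-attraction weights, zero
#'   diagonal; entry (i, j) pulls i toward j.
#' @param attraction_gain global gain applied to the social pull.
#' @param frame_rate frames per second.
#' @param duration seconds.
#' @param seed integer seed.
#' @return an object of class `arena_sim_params`.
#' @export
arena_sim_params <- function(n_individuals = 8, arena_radius = 18,
                             speed_mean = 5, speed_sd = 2,
                             heading_persistence = 0.85,
                             attraction = NULL, attraction_gain = 1,
                             frame_rate = 10, duration = 1800, seed = 1L) {
  check_number(n_individuals, "n_individuals", lower = 2)
  check_number(arena_radius, "arena_radius", lower = 1e-9)
  check_number(speed_mean, "speed_mean", lower = 0)
  check_number(speed_sd, "speed_sd", lower = 0)
  check_number(heading_persistence, "heading_persistence", lower = 0.01,
               upper = 0.999)
  check_number(attraction_gain, "attraction_gain")
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(duration, "duration", lower = 1e-9)
  check_number(seed, "seed")
  n <- as.integer(n_individuals)
  if (is.null(attraction)) attraction <- matrix(0, n, n)
  attraction <- as.matrix(attraction)
  if (!is.numeric(attraction) || any(!is.finite(attraction)) ||
      nrow(attraction) != n || ncol(attraction) != n)
    stop_kinpref("`attraction` must be a finite %d x %d matrix", n, n)
  if (any(diag(attraction) != 0))
    stop_kinpref("`attraction` must have a zero diagonal")
  structure(list(n_individuals = n, arena_radius = arena_radius,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 heading_persistence = heading_persistence,
                 attraction = attraction, attraction_gain = attraction_gain,
                 frame_rate = frame_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "arena_sim_params")
}

#' Simulate free-swimming arena trajectories
#'
#' @param params an [arena_sim_params()].
#' @param individual_ids optional labels (default `ind1 ... indN`).
#' @return a complete [trajectory_set()] (no missing frames), positions in cm
#'   with the arena centered at the origin.
#' @export
simulate_arena <- function(params, individual_ids = NULL) {
  if (!inherits(params, "arena_sim_params"))
    stop_kinpref("`params` must be an arena_sim_params object")
  p <- params
  n <- p$n_individuals
  nf <- round(p$duration * p$frame_rate)
  R <- p$arena_radius
  ids <- individual_ids %||% paste0("ind", seq_len(n))
  set.seed(p$seed)
  sigma <- sqrt(-2 * log(p$heading_persistence))
  pos <- array(NA_real_, dim = c(nf, n, 2))
  r0 <- R * sqrt(stats::runif(n)) * 0.95
  th0 <- stats::runif(n, 0, 2 * pi)
  P <- cbind(r0 * cos(th0), r0 * sin(th0))
  ang <- stats::runif(n, 0, 2 * pi)
  U <- cbind(cos(ang), sin(ang))
  pos[1, , ] <- P
  social_on <- any(p$attraction != 0)
  for (t in 2:nf) {
    if (social_on) {
      mx <- outer(rep(1, n), P[, 1]) - P[, 1]   # (i,j): x_j - x_i
      my <- outer(rep(1, n), P[, 2]) - P[, 2]
      d <- sqrt(mx^2 + my^2)
      d[d < 1e-9] <- Inf
      wx <- rowSums(p$attraction * mx / d)
      wy <- rowSums(p$attraction * my / d)
      wn <- sqrt(wx^2 + wy^2)
      scl <- ifelse(wn > 1e-12, p$attraction_gain * tanh(wn) / wn, 0)
      sx <- wx * scl
      sy <- wy * scl
    } else {
      sx <- sy <- 0
    }
    vx <- p$heading_persistence * U[, 1] + sx
    vy <- p$heading_persistence * U[, 2] + sy
    still <- (vx^2 + vy^2) < 1e-18
    base <- ifelse(still, atan2(U[, 2], U[, 1]), atan2(vy, vx))
    a <- base + stats::rnorm(n, 0, sigma)
    speed <- pmax(stats::rnorm(n, p$speed_mean, p$speed_sd), 0)
    step <- speed / p$frame_rate
    ux <- cos(a)
    uy <- sin(a)
    Pn <- P + step * cbind(ux, uy)
    rr <- sqrt(rowSums(Pn^2))
    out <- rr > R
    if (any(out)) {
      nx <- Pn[out, 1] / rr[out]
      ny <- Pn[out, 2] / rr[out]
      Pn[out, 1] <- nx * (2 * R - rr[out])
      Pn[out, 2] <- ny * (2 * R - rr[out])
      dot <- ux[out] * nx + uy[out] * ny
      ux[out] <- ux[out] - 2 * dot * nx
      uy[out] <- uy[out] - 2 * dot * ny
    }
    P <- Pn
    U <- cbind(ux, uy)
    pos[t, , ] <- P
  }
  trajectory_set(pos, p$frame_rate, ids, arena_circle(radius = R))
}

## ---- behaviour counts ------------------------------------------------------

#' Parameters for synthetic behaviour-count cells
#'
#' Counts per aggregation cell (arena x mating status x relatedness) follow a
#' negative-binomial log-linear model with an arena-level random intercept:
#' `log mu = log(base_rate) + effect_relatedness * [unrelated] +
#' effect_status * [virgin] + arena effect`.
#'
#' @param base_rate expected events per cell for the reference cell
#'   (related, experienced) at zero arena effect.
#' @param effect_relatedness log rate ratio, unrelated vs related.
#' @param effect_status log rate ratio, virgin vs experienced.
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson.
#' @param arena_sd SD of the arena-level random intercept (log scale).
#' @param n_arenas number of arenas in the default design.
#' @param seed integer seed.
#' @return an object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(base_rate = 10, effect_relatedness = 0,
                                effect_status = 0, dispersion = 2,
                                arena_sd = 0.3, n_arenas = 12, seed = 1L) {
  check_number(base_rate, "base_rate", lower = 1e-12)
  check_number(effect_relatedness, "effect_relatedness")
  check_number(effect_status, "effect_status")
  if (!(length(dispersion) == 1L && is.numeric(dispersion) && dispersion > 0))
    stop_kinpref("`dispersion` must be a single positive number (Inf = Poisson)")
  check_number(arena_sd, "arena_sd", lower = 0)
  check_number(n_arenas, "n_arenas", lower = 1)
  check_number(seed, "seed")
  structure(list(base_rate = base_rate,
                 effect_relatedness = effect_relatedness,
                 effect_status = effect_status, dispersion = dispersion,
                 arena_sd = arena_sd, n_arenas = as.integer(n_arenas),
                 seed = as.integer(seed)),
            class = "behavior_sim_params")
}

#' Aggregation-cell scaffold for the study design
#'
#' The fully crossed cell structure of the group-level count analysis:
#' arenas x mating status (virgin/experienced) x relatedness
#' (related/unrelated), 4 cells per arena.
#'
#' @param n_arenas number of arenas.
#' @return tibble with columns `arena_id`, `mating_status`, `relatedness`.
#' @export
behavior_design <- function(n_arenas = 12) {
  tidyr::expand_grid(
    arena_id = sprintf("arena%02d", seq_len(n_arenas)),
    mating_status = c("experienced", "virgin"),
    relatedness = c("related", "unrelated")
  )
}

#' Simulate behaviour counts per aggregation cell
#'
#' @param params a [behavior_sim_params()].
#' @param design cell table with columns `arena_id`, `mating_status`,
#'   `relatedness` (see [behavior_design()]); extra columns pass through.
#' @return the design tibble with a `count` column appended.
#' @export
simulate_behavior_counts <- function(params, design = behavior_design(params$n_arenas)) {
  if (!inherits(params, "behavior_sim_params"))
    stop_kinpref("`params` must be a behavior_sim_params object")
  design <- tibble::as_tibble(design)
  if (nrow(design) == 0)
    stop_kinpref("`design` is empty: no aggregation cells to simulate")
  need <- c("arena_id", "mating_status", "relatedness")
  if (!all(need %in% names(design)))
    stop_kinpref("`design` must have columns: %s", paste(need, collapse = ", "))
  set.seed(params$seed)
  arenas <- unique(design$arena_id)
  re <- stats::rnorm(length(arenas), 0, params$arena_sd)
  names(re) <- arenas
  eta <- log(params$base_rate) +
    params$effect_relatedness * (design$relatedness == "unrelated") +
    params$effect_status * (design$mating_status == "virgin") +
    re[design$arena_id]
  mu <- exp(eta)
  design$count <- if (is.infinite(params$dispersion)) {
    stats::rpois(nrow(design), mu)
  } else {
    stats::rnbinom(nrow(design), mu = mu, size = params$dispersion)
  }
  design
}
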