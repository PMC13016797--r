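# Shared fixtures and independent oracles.

# A mixed-sex arena design: two families of four (both sexes and statuses).
make_mixed_design <- function(ids = paste0("i", 1:8), arena_id = "a1") {
  trial_design(tibble::tibble(
    id = ids,
    family = rep(c("A", "B"), each = 4),
    sex = rep(c("female", "female", "male", "male"), 2),
    mating_status = rep(c("virgin", "experienced"), 4)
  ), arena_id = arena_id)
}

# A minimal two-individual design (different families, opposite sexes).
make_pair_design <- function(ids = c("i1", "i2"), arena_id = "a1") {
  trial_design(tibble::tibble(
    id = ids, family = c("A", "B"), sex = c("female", "male"),
    mating_status = c("virgin", "experienced")
  ), arena_id = arena_id)
}

# A same-sex arena design: one pair of siblings from each of four families.
make_samesex_design <- function(sex = "female", arena_id = "a1") {
  trial_design(tibble::tibble(
    id = paste0("s", 1:8),
    family = rep(c("A", "B", "C", "D"), each = 2),
    sex = sex,
    mating_status = rep(c("virgin", "experienced"), 4)
  ), arena_id = arena_id)
}

# A choice-trial design: focal plus related/unrelated stimulus pair.
make_choice_design <- function(related_side = "left",
                               bl = c(related = 20, unrelated = 18),
                               orange = c(related = 11, unrelated = 10)) {
  other <- setdiff(c("left", "right"), related_side)
  trial_design(tibble::tibble(
    id = c("focal", "stimR", "stimU"),
    family = c("A", "A", "B"),
    sex = c("female", "male", "male"),
    mating_status = "virgin",
    role = c("focal", "stimulus", "stimulus"),
    side = c(NA, related_side, other),
    body_length_mm = c(NA, bl[["related"]], bl[["unrelated"]]),
    body_area_mm2 = c(NA, 105, 100),
    orange_area_mm2 = c(NA, orange[["related"]], orange[["unrelated"]])
  ), stimulus_side = stats::setNames(c("related", "unrelated"),
                                     c(related_side, other)),
  arena_id = "trial1")
}

# Trajectory set built from an explicit positions array.
make_traj <- function(pos, frame_rate = 10, geometry = arena_circle(18),
                      ids = NULL) {
  ids <- ids %||% paste0("i", seq_len(dim(pos)[2]))
  trajectory_set(pos, frame_rate, ids, geometry)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random in-arena trajectory array (uniform positions, optional NAs).
random_positions <- function(n_frames, n_ind, radius = 18, na_frac = 0) {
  r <- radius * sqrt(stats::runif(n_frames * n_ind))
  th <- stats::runif(n_frames * n_ind, 0, 2 * pi)
  pos <- array(c(r * cos(th), r * sin(th)), dim = c(n_frames, n_ind, 2))
  if (na_frac > 0) {
    drop <- which(stats::runif(n_frames * n_ind) < na_frac)
    for (k in drop) {
      f <- ((k - 1) %% n_frames) + 1
      i <- ((k - 1) %/% n_frames) + 1
      pos[f, i, ] <- NA
    }
  }
  pos
}

# Scaled-down study configuration for pipeline tests: 8 families (32 choice
# trials), 4 mixed-sex arenas, 4 same-sex arenas, shorter recordings.
small_cfg <- function(seed = 1, scenario_tweaks = list()) {
  sc <- default_scenario()
  sc$n_families <- 8
  sc$exp1$trial_duration <- 240
  sc$exp1$late_delay_s <- 200
  sc$exp2$n_arenas <- 4
  sc$exp2$duration <- 120
  sc$exp3$duration <- 120
  sc <- utils::modifyList(sc, scenario_tweaks)
  run_config(scenario = sc, seed = seed)
}

# Brute-force association oracle: frame-by-frame, pair-by-pair double loop.
oracle_associations <- function(pos, radius, frame_rate) {
  nf <- dim(pos)[1]
  ni <- dim(pos)[2]
  out <- list()
  k <- 0
  for (i in seq_len(ni - 1)) {
    for (j in (i + 1):ni) {
      n_assoc <- 0L
      n_valid <- 0L
      for (f in seq_len(nf)) {
        a <- pos[f, i, ]
        b <- pos[f, j, ]
        if (any(is.na(a)) || any(is.na(b))) next
        n_valid <- n_valid + 1L
        if (sqrt(sum((a - b)^2)) <= radius) n_assoc <- n_assoc + 1L
      }
      k <- k + 1
      out[[k]] <- data.frame(i = i, j = j, associated = n_assoc,
                             valid = n_valid,
                             duration = n_assoc / frame_rate)
    }
  }
  do.call(rbind, out)
}

# Brute-force BH oracle: for each p, the smallest q at which the step-up
# rule run at level q would reject it.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    qs <- sort(unique(pmin(1, p * m / rank(p, ties.method = "max"))))
    for (q in qs) {
      ok <- which(sort(p) <= seq_len(m) * q / m)
      if (length(ok) && pi <= sort(p)[max(ok)]) return(q)
    }
    1
  }, numeric(1))
}
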