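test_that("the threshold is a body-length multiple", {
  thr <- derive_threshold(1.76, 2)
  expect_equal(thr$radius, 3.52)
  expect_equal(derive_threshold(1.0, 1)$radius, 1.0)
  expect_equal(derive_threshold(1.76, 4)$radius, 7.04)
  expect_error(derive_threshold(-1, 2), "outside")
  expect_error(derive_threshold(1.76, 0), "outside")
})

test_that("frame distance matrices are Euclidean with missing propagation", {
  pos <- array(NA_real_, dim = c(2, 3, 2))
  pos[1, 1, ] <- c(0, 0)
  pos[1, 2, ] <- c(3, 4)
  pos[1, 3, ] <- c(0, 1)
  pos[2, 1, ] <- c(0, 0)
  pos[2, 3, ] <- c(1, 0)          # individual 2 missing at frame 1
  ts <- make_traj(pos, geometry = arena_circle(18))
  d0 <- frame_distance_matrix(ts, 0)
  expect_equal(unname(d0["i1", "i2"]), 5)  # 3-4-5 triangle
  expect_equal(unname(diag(d0)), c(0, 0, 0))
  expect_equal(d0, t(d0))

  d1 <- frame_distance_matrix(ts, 1)
  expect_true(all(is.na(d1["i2", ])))
  expect_true(all(is.na(d1[, "i2"])))
  expect_equal(unname(d1["i1", "i3"]), 1)

  expect_error(frame_distance_matrix(ts, 2), "out of range")
  expect_error(frame_distance_matrix(ts, -1), "out of range")
})

test_that("random frames match the brute-force double loop", {
  set.seed(10)
  pos <- random_positions(5, 8, radius = 17)
  ts <- make_traj(pos)
  for (f in 0:4) {
    d <- frame_distance_matrix(ts, f)
    for (i in 1:8) for (j in 1:8) {
      expect_equal(unname(d[i, j]),
                   sqrt(sum((pos[f + 1, i, ] - pos[f + 1, j, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("stationary dyads accumulate the expected association time", {
  pos <- array(0, dim = c(600, 2, 2))
  pos[, 2, 1] <- 3.0                       # 3 cm apart, under the threshold
  ts <- make_traj(pos, frame_rate = 10)
  d <- make_pair_design()
  at <- detect_associations(ts, derive_threshold(), d)
  expect_equal(at$associated_frames, 600)
  expect_equal(at$association_duration_s, 60)
})

test_that("the threshold boundary is inclusive", {
  pos <- array(0, dim = c(10, 2, 2))
  pos[, 2, 1] <- 3.52
  ts <- make_traj(pos, frame_rate = 10)
  d <- make_pair_design()
  at <- detect_associations(ts, derive_threshold(), d)
  expect_equal(at$associated_frames, 10)
  # just beyond: not associated
  pos[, 2, 1] <- 3.5201
  at2 <- detect_associations(make_traj(pos, frame_rate = 10),
                             derive_threshold(), d)
  expect_equal(at2$associated_frames, 0)
})

test_that("association tables equal the brute-force oracle with gaps", {
  set.seed(11)
  for (rep in 1:5) {
    pos <- random_positions(200, 8, radius = 17, na_frac = 0.05)
    ts <- make_traj(pos)
    d <- make_mixed_design()
    at <- detect_associations(ts, derive_threshold(), d)
    orc <- oracle_associations(pos, 3.52, frame_rate = 10)
    expect_equal(at$associated_frames, orc$associated)
    expect_equal(at$valid_frames, orc$valid)
    expect_equal(at$association_duration_s, orc$duration)
  }
})

test_that("association counts are conserved and monotone in the radius", {
  set.seed(12)
  pos <- random_positions(300, 6, radius = 17, na_frac = 0.08)
  ts <- make_traj(pos, ids = paste0("i", 1:6))
  d <- trial_design(tibble::tibble(
    id = paste0("i", 1:6), family = rep(c("A", "B", "C"), 2),
    sex = rep(c("female", "male"), 3),
    mating_status = rep(c("virgin", "experienced"), 3)))
  radii <- c(1, 2, 3.52, 7.04, 15)
  prev <- rep(0L, 15)
  for (r in radii) {
    at <- detect_associations(ts, fixed_threshold(r), d)
    # conservation: associated + non-associated valid + invalid = total
    invalid <- 300L - at$valid_frames
    expect_equal(at$associated_frames +
                   (at$valid_frames - at$associated_frames) + invalid,
                 rep(300L, nrow(at)))
    expect_true(all(at$associated_frames >= prev))
    prev <- at$associated_frames
  }
})

test_that("association analysis is invariant to individual relabeling", {
  set.seed(13)
  pos <- random_positions(150, 8, radius = 17)
  perm <- sample(8)
  d <- make_mixed_design()
  ts <- make_traj(pos)
  at <- detect_associations(ts, derive_threshold(), d)
  # permute columns of the positions and the design rows identically
  ts_p <- make_traj(pos[, perm, , drop = FALSE],
                    ids = paste0("i", 1:8)[perm])
  at_p <- detect_associations(ts_p, derive_threshold(), d)
  key <- function(tb) {
    tb$dyad <- paste(pmin(tb$id_a, tb$id_b), pmax(tb$id_a, tb$id_b))
    tb[order(tb$dyad), c("dyad", "associated_frames", "relatedness",
                         "sex_class", "status_class")]
  }
  expect_equal(key(at), key(at_p), ignore_attr = TRUE)
})

test_that("design/trajectory mismatches are rejected", {
  ts <- make_traj(random_positions(10, 3, radius = 15))
  expect_error(detect_associations(ts, derive_threshold(),
                                   make_mixed_design()), "match")
})

test_that("dyad censuses reproduce the study counts", {
  designs <- lapply(1:12, function(a)
    make_mixed_design(arena_id = sprintf("arena%02d", a)))
  expect_equal(dyad_census(designs, "all"), 336)
  expect_equal(dyad_census(designs, "opposite-sex"), 192)
  expect_equal(dyad_census(designs, "same-sex"), 144)
  expect_equal(dyad_census(make_pair_design(), "all"), 1)
})

test_that("association durations increase with the dyad's attraction weight", {
  d <- make_mixed_design()
  weights <- c(0, 0.1, 0.3, 0.6)
  durs <- vapply(weights, function(w) {
    mean(vapply(1:6, function(s) {
      A <- matrix(0, 8, 8)
      A[1, 2] <- A[2, 1] <- w
      ts <- simulate_arena(arena_sim_params(attraction = A, duration = 120,
                                            seed = s), paste0("i", 1:8))
      at <- detect_associations(ts, derive_threshold(), d)
      at$association_duration_s[at$id_a == "i1" & at$id_b == "i2"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(durs) > 0))
})

test_that("bout extraction respects minimum duration and gap merging", {
  pos <- array(0, dim = c(30, 2, 2))
  pos[, 2, 1] <- 10          # apart
  pos[5:10, 2, 1] <- 2       # bout 1: 6 frames
  pos[13:14, 2, 1] <- 2      # bout 2: 2 frames (gap of 2 before it)
  ts <- make_traj(pos, frame_rate = 10)
  b0 <- association_bouts(ts, derive_threshold(), "i1", "i2")
  expect_equal(nrow(b0), 2)
  expect_equal(b0$start_frame, c(4L, 12L))
  b_min <- association_bouts(ts, derive_threshold(), "i1", "i2",
                             min_bout_s = 0.5)
  expect_equal(nrow(b_min), 1)
  b_merge <- association_bouts(ts, derive_threshold(), "i1", "i2",
                               merge_gap_s = 0.3)
  expect_equal(nrow(b_merge), 1)
  expect_equal(b_merge$duration_s, 1.0)
})
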