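# Single-focal choice-tank trajectory: x positions along the choice axis
# (left zone x < 5, right zone x > 22 in the 27 cm compartment).
make_zone_traj <- function(x, y = 12, frame_rate = 10) {
  pos <- array(c(x, rep(y, length(x))), dim = c(length(x), 1, 2))
  trajectory_set(pos, frame_rate, "focal", choice_tank())
}

test_that("a focal parked in the related zone scores SOP = +1", {
  d <- make_choice_design(related_side = "left")
  traj <- make_zone_traj(rep(2, 18000))   # 30 min at 10 fps
  occ <- zone_occupancy(traj, zone_geometry(), d)
  expect_equal(occ$T_R, 1800)
  expect_equal(occ$T_UR, 0)
  expect_equal(compute_sop(occ)$value, 1)
})

test_that("zone occupancy is invariant under mirrored side assignment", {
  set.seed(20)
  x <- runif(500, 0, 27)
  d_left <- make_choice_design(related_side = "left")
  d_right <- make_choice_design(related_side = "right")
  occ1 <- zone_occupancy(make_zone_traj(x), zone_geometry(), d_left)
  occ2 <- zone_occupancy(make_zone_traj(27 - x), zone_geometry(), d_right)
  expect_equal(occ1$T_R, occ2$T_R)
  expect_equal(occ1$T_UR, occ2$T_UR)
  expect_equal(occ1$T_neutral, occ2$T_neutral)
})

test_that("synthetic zone trials reproduce the stationary zone share", {
  shares <- vapply(1:100, function(s) {
    tr <- simulate_zone_trial(zone_sim_params(trial_duration = 300,
                                              p_zone = 0.68, seed = s))
    occ <- tr$occupancy
    (occ$T_R + occ$T_UR) / occ$trial_duration
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.68), 3 * sd(shares) / sqrt(length(shares)))
})

test_that("SOP arithmetic follows its definition", {
  occ <- list(T_R = 600, T_UR = 600)
  expect_equal(compute_sop(occ)$value, 0)
  expect_equal(compute_sop(list(T_R = 15 * 60, T_UR = 5 * 60))$value, 0.5)
  undef <- compute_sop(list(T_R = 0, T_UR = 0))
  expect_false(undef$defined)
  expect_true(is.na(undef$value))
  expect_error(compute_sop(list(T_R = -1, T_UR = 5)), "non-negative")
})

test_that("SOP is antisymmetric under label swapping", {
  set.seed(21)
  for (i in 1:20) {
    tr <- runif(1, 0, 900)
    tur <- runif(1, 0, 900)
    s1 <- compute_sop(list(T_R = tr, T_UR = tur))$value
    s2 <- compute_sop(list(T_R = tur, T_UR = tr))$value
    expect_equal(s1, -s2)
  }
})

test_that("the informed-choice window starts at the later first entry", {
  # left zone (related) entered at frame 100, right at frame 500
  x <- rep(13, 1000)
  x[101:110] <- 2
  x[501:510] <- 25
  x[601:1000] <- rep(c(2, 25), 200)
  d <- make_choice_design(related_side = "left")
  occ <- zone_occupancy(make_zone_traj(x), zone_geometry(), d)
  expect_equal(occ$first_entry_related, 100L)
  expect_equal(occ$first_entry_unrelated, 500L)
  ic <- informed_choice_window(occ, min_window_s = 10)
  expect_false(ic$excluded)
  expect_equal(ic$window_start_frame, 500L)
  # occupancy before frame 500 is excluded from the IC totals
  expect_equal(ic$occupancy$T_R, sum(x[501:1000] < 5) / 10)
})

test_that("trials that never inform are flagged, not scored", {
  x <- rep(13, 1000)
  x[101:200] <- 2   # only the related zone is ever visited
  d <- make_choice_design(related_side = "left")
  occ <- zone_occupancy(make_zone_traj(x), zone_geometry(), d)
  ic <- informed_choice_window(occ)
  expect_true(ic$excluded)
  expect_match(ic$reason, "never visited")

  # both visited, but too late for a usable window
  x2 <- rep(13, 1000)
  x2[981:985] <- 2
  x2[991:995] <- 25
  occ2 <- zone_occupancy(make_zone_traj(x2), zone_geometry(), d)
  ic2 <- informed_choice_window(occ2, min_window_s = 60)
  expect_true(ic2$excluded)
})

test_that("IC SOP ignores everything before the window", {
  set.seed(22)
  # related zone first entered at frame 2, unrelated at frame 50; frames
  # 3..49 wander between the related zone and the neutral region
  pre <- sample(c(2, 13), 47, replace = TRUE)
  tail_x <- runif(500, 0, 27)
  x <- c(13, 13, 2, pre, 25, tail_x)
  d <- make_choice_design(related_side = "left")
  occ <- zone_occupancy(make_zone_traj(x), zone_geometry(), d)
  expect_equal(occ$first_entry_related, 2L)
  expect_equal(occ$first_entry_unrelated, 50L)
  ic1 <- informed_choice_window(occ, min_window_s = 1)
  expect_equal(ic1$window_start_frame, 50L)
  # reshuffle the pre-window wander: first entries and window unchanged
  x_perm <- c(13, 13, 2, sample(pre), 25, tail_x)
  occ2 <- zone_occupancy(make_zone_traj(x_perm), zone_geometry(), d)
  ic2 <- informed_choice_window(occ2, min_window_s = 1)
  expect_equal(ic2$window_start_frame, 50L)
  expect_equal(compute_sop(ic1$occupancy)$value,
               compute_sop(ic2$occupancy)$value)
})

test_that("interval SOP is consistent with the whole-trial score", {
  set.seed(23)
  x <- runif(900, 0, 27)
  d <- make_choice_design(related_side = "left")
  occ <- zone_occupancy(make_zone_traj(x), zone_geometry(), d)
  one <- interval_sop(occ, edges_s = c(0, 90))
  expect_equal(one$sop, compute_sop(occ)$value)

  # two intervals: related first half, unrelated second half
  x2 <- c(rep(2, 100), rep(25, 100))
  occ2 <- zone_occupancy(make_zone_traj(x2), zone_geometry(), d)
  two <- interval_sop(occ2, edges_s = c(0, 10, 20))
  expect_equal(two$sop, c(1, -1))

  # conservation: occupancy summed over intervals equals the total
  thirds <- interval_sop(occ)
  expect_equal(sum(thirds$T_R), occ$T_R)
  expect_equal(sum(thirds$T_UR), occ$T_UR)
})

test_that("arena SOP handles both experiment structures", {
  d <- make_mixed_design()      # focal i1 female, fam A; males i3,i4 (A), i7,i8 (B)
  at <- tibble::tibble(
    id_a = "i1", id_b = c("i3", "i4", "i7", "i8"),
    association_duration_s = 120)
  expect_equal(arena_sop(at, "i1", d, "mixed-sex")$value, 0)

  # same-sex arena: focal associates only with its sibling
  ds <- make_samesex_design()
  at2 <- tibble::tibble(id_a = "s1", id_b = paste0("s", 2:8),
                        association_duration_s = c(300, rep(0, 6)))
  expect_equal(arena_sop(at2, "s1", ds, "same-sex")$value, 1)

  # uniform association time exposes the 1-vs-6 raw-sum asymmetry
  at3 <- tibble::tibble(id_a = "s1", id_b = paste0("s", 2:8),
                        association_duration_s = 60)
  expect_equal(arena_sop(at3, "s1", ds, "same-sex")$value, -5 / 7)
  expect_equal(arena_sop(at3, "s1", ds, "same-sex", per_capita = TRUE)$value,
               0)
})

test_that("arena SOP flags degenerate cases", {
  ds <- make_samesex_design()
  at <- tibble::tibble(id_a = "s1", id_b = paste0("s", 2:8),
                       association_duration_s = 0)
  s <- arena_sop(at, "s1", ds, "same-sex")
  expect_false(s$defined)
  d_onefam <- trial_design(tibble::tibble(
    id = paste0("x", 1:4), family = "A", sex = "female",
    mating_status = "virgin"))
  expect_error(arena_sop(at, "x1", d_onefam, "same-sex"), "empty")
})

test_that("estimated SOP converges to 2 * bias - 1 on synthetic trials", {
  for (bias in c(0.4, 0.65)) {
    sops <- vapply(1:300, function(s) {
      tr <- simulate_zone_trial(zone_sim_params(
        trial_duration = 300, bias_b = bias, seed = s * 7 + 1))
      compute_sop(tr$occupancy)$value
    }, numeric(1))
    expect_lt(abs(mean(sops) - (2 * bias - 1)),
              3 * sd(sops) / sqrt(length(sops)))
  }
})
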