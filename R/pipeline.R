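# End-to-end orchestration of the three experiments over synthetic (or
# supplied) data: scenario configuration, deterministic seeding, filter
# ledgers, model fitting and cross-experiment consistency.

## ---- scenario & config -----------------------------------------------------

#' Default study scenario
#'
#' The synthetic-study conditions mirroring the original design: 24 families
#' of 4 fish (a virgin and an experienced individual of each sex, 96 in
#' total); 96 dichotomous-choice trials with 7 acclimation-breach exclusions
#' (3 virgin males, 2 experienced males, 2 experienced females) and one slow
#' explorer whose informed-choice window is unusably short; 12 mixed-sex
#' arenas of 8 (two families each); 12 same-sex arenas of 8 (four families
#' each, 6 female and 6 male arenas). Zone occupancy is 68% (females) and
#' 58% (males); relatedness bias, trait effects and kin attraction default
#' to null; stimulus trait differences are drawn so their mean absolute
#' values match the study cohort (e.g. 1.96 mm body length in females).
#'
#' @return nested scenario list; override fields via [read_scenario()] or
#'   [utils::modifyList()].
#' @export
default_scenario <- function() {
  list(
    n_families = 24,
    exp1 = list(
      trial_duration = 1800, frame_rate = 10,
      p_zone = c(female = 0.68, male = 0.58),
      bias_b = 0.5, switch_rate = 4,
      n_breach = c(virgin_male = 3, experienced_male = 2,
                   experienced_female = 2),
      n_late_explorers = 1, late_delay_s = 1750, min_ic_window_s = 60,
      # SD of the related-minus-unrelated trait difference, set so E|diff|
      # = sd * sqrt(2/pi) reproduces the cohort means (1.96 / 1.06 mm body
      # length, 15.1 / 6.2 mm^2 body area, 1.25 mm^2 orange area)
      trait_sd = list(
        body_length_mm = c(female = 2.456, male = 1.329),
        body_area_mm2 = c(female = 18.93, male = 7.77),
        orange_area_mm2 = c(male = 1.566)),
      trait_effect = 0     # logit-scale slope of zone bias per mm difference
    ),
    exp2 = list(
      duration = 1800, frame_rate = 10, n_arenas = 12, arena_radius = 18,
      speed_mean = 5, speed_sd = 2, heading_persistence = 0.85,
      base_attraction = 0.02, kin_attraction = 0, attraction_gain = 1,
      behavior_base_rate = list(
        female = c(orienting = 20, approaching = 12, gliding = 3),
        male = c(pursuing = 30, sigmoid = 10, mating = 3)),
      behavior_dispersion = 2, behavior_arena_sd = 0.3,
      effect_relatedness = 0, effect_status = 0
    ),
    exp3 = list(
      duration = 1800, frame_rate = 10, n_arenas = 12, arena_radius = 18,
      speed_mean = 5, speed_sd = 2, heading_persistence = 0.85,
      # females shoal, males rove: sex-specific baseline social attraction
      sex_attraction = c(female = 0.03, male = 0.005),
      kin_attraction = 0, attraction_gain = 1
    ),
    latent = list(pref_sd = 0, share = 1, gain = 0.5)
  )
}

#' Read a scenario file
#'
#' Declarative YAML scenario; fields present in the file override the
#' defaults of [default_scenario()], absent fields keep their defaults.
#'
#' @param path YAML file path.
#' @return scenario list.
#' @export
read_scenario <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_scenario(), user)
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    } else {
      v <- user[[nm]]
      if (is.list(v) && all(vapply(v, is.numeric, logical(1))) &&
          !is.null(names(v)))
        v <- unlist(v)
      base[[nm]] <- v
    }
  }
  base
}

#' Run configuration
#'
#' @param scenario scenario list (see [default_scenario()]).
#' @param seed master seed; all per-trial streams derive from it.
#' @param threshold association threshold (default 2 body lengths of
#'   1.76 cm = 3.52 cm).
#' @param gap gap-repair policy.
#' @param per_capita_sop use per-capita arena SOP sums.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = default_scenario(), seed = 1,
                       threshold = derive_threshold(), gap = gap_policy(),
                       per_capita_sop = FALSE) {
  check_number(seed, "seed")
  structure(list(scenario = scenario, seed = as.integer(seed),
                 threshold = threshold, gap = gap,
                 per_capita_sop = per_capita_sop,
                 hash = config_hash(list(scenario, threshold, gap,
                                         per_capita_sop))),
            class = "run_config")
}

# Deterministic per-stage master seeds.
stage_seeds <- function(cfg) {
  s <- spawn_seeds(cfg$seed, 6)
  list(roster = s[1], exp1 = s[2], exp2 = s[3], exp3 = s[4],
       latent = s[5], misc = s[6])
}

## ---- roster ----------------------------------------------------------------

# The 96 focal fish: per family a virgin and an experienced individual of
# each sex. Latent kin-preference draws (usually zero-variance) attach here.
make_roster <- function(cfg) {
  sc <- cfg$scenario
  ss <- stage_seeds(cfg)
  nfam <- sc$n_families
  roster <- tidyr::expand_grid(
    family = sprintf("fam%02d", seq_len(nfam)),
    sex = c("female", "male"),
    mating_status = c("virgin", "experienced"))
  roster$id <- sprintf("%s_%s%s", roster$family,
                       ifelse(roster$mating_status == "virgin", "V", "E"),
                       ifelse(roster$sex == "female", "F", "M"))
  lat <- sc$latent
  set.seed(ss$latent)
  z_shared <- stats::rnorm(nrow(roster))
  z_exp <- matrix(stats::rnorm(nrow(roster) * 3), ncol = 3)
  lam <- min(max(lat$share, 0), 1)
  roster$latent_exp1 <- lat$pref_sd *
    (sqrt(lam) * z_shared + sqrt(1 - lam) * z_exp[, 1])
  roster$latent_exp2 <- lat$pref_sd *
    (sqrt(lam) * z_shared + sqrt(1 - lam) * z_exp[, 2])
  roster$latent_exp3 <- lat$pref_sd *
    (sqrt(lam) * z_shared + sqrt(1 - lam) * z_exp[, 3])
  roster
}

## ---- experiment 1 ----------------------------------------------------------

#' Run Experiment 1: dichotomous mate choice
#'
#' Generates (or would ingest) one choice trial per roster fish, applies the
#' acclimation-breach exclusion, computes total-trial, informed-choice and
#' interval SOP scores, and fits the preference models: a one-sample t-test
#' of mean SOP against 0, an overall LMM (body-length difference + sex +
#' mating status, family random intercept) and per-sex LMMs with trait
#' differences.
#'
#' @param cfg a [run_config()].
#' @return list with `sop_table` (per-trial scores, flags and trait
#'   differences), `ledger` (trial counts through each filter), `t_test`,
#'   `models` (overall / female / male [fit_mixed_model()] results).
#' @export
run_experiment1 <- function(cfg) {
  sc <- cfg$scenario$exp1
  roster <- make_roster(cfg)
  ss <- stage_seeds(cfg)
  n <- nrow(roster)
  seeds <- spawn_seeds(ss$exp1, n + 2)

  # designed exclusions: breaches by status cell, one late explorer
  set.seed(seeds[n + 1])
  breach <- rep(FALSE, n)
  for (cell in names(sc$n_breach)) {
    parts <- strsplit(cell, "_")[[1]]
    pool <- which(roster$mating_status == parts[1] & roster$sex == parts[2] &
                    !breach)
    breach[sample(pool, sc$n_breach[[cell]])] <- TRUE
  }
  late <- rep(FALSE, n)
  if (sc$n_late_explorers > 0)
    late[sample(which(!breach), sc$n_late_explorers)] <- TRUE

  set.seed(seeds[n + 2])
  sides <- sample(c("left", "right"), n, replace = TRUE)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- roster[i, ]
    set.seed(seeds[i])
    # stimulus pair of the opposite sex with trait differences drawn at the
    # cohort scale
    sd_of <- function(trait) {
      v <- sc$trait_sd[[trait]]
      if (r$sex %in% names(v)) v[[r$sex]] else NA_real_
    }
    d_bl <- stats::rnorm(1, 0, sd_of("body_length_mm"))
    d_ba <- stats::rnorm(1, 0, sd_of("body_area_mm2"))
    d_or <- if (r$sex == "female")
      stats::rnorm(1, 0, sc$trait_sd$orange_area_mm2[["male"]]) else NA_real_
    stim_sex <- setdiff(c("female", "male"), r$sex)
    base_bl <- stats::rnorm(1, 18, 1.5)
    related_side <- sides[i]
    other_side <- setdiff(c("left", "right"), related_side)
    ind <- tibble::tibble(
      id = c(r$id, paste0(r$id, "_Rstim"), paste0(r$id, "_Ustim")),
      family = c(r$family, r$family, "stimfam"),
      sex = c(r$sex, stim_sex, stim_sex),
      mating_status = c(r$mating_status, "virgin", "virgin"),
      role = c("focal", "stimulus", "stimulus"),
      side = c(NA, related_side, other_side),
      body_length_mm = c(NA, base_bl + d_bl, base_bl),
      body_area_mm2 = c(NA, 100 + d_ba, 100),
      orange_area_mm2 = if (r$sex == "female") c(NA, 10 + d_or, 10)
                        else c(NA, NA, NA))
    design <- trial_design(
      ind,
      stimulus_side = stats::setNames(c("related", "unrelated"),
                                      c(related_side, other_side)),
      arena_id = sprintf("trial%02d", i))
    bias <- stats::plogis(stats::qlogis(sc$bias_b) +
                            sc$trait_effect * d_bl + r$latent_exp1)
    zp <- zone_sim_params(
      trial_duration = sc$trial_duration, frame_rate = sc$frame_rate,
      p_zone = sc$p_zone[[r$sex]], bias_b = bias,
      switch_rate = sc$switch_rate,
      delay_s = if (late[i]) sc$late_delay_s else 0,
      seed = seeds[i])
    trial <- simulate_zone_trial(zp)
    occ <- trial$occupancy
    sop_sc <- compute_sop(occ)
    ic <- informed_choice_window(occ, min_window_s = sc$min_ic_window_s)
    ic_sop <- if (ic$excluded) NA_real_ else compute_sop(ic$occupancy,
                                                         "informed-choice")$value
    td <- trait_differences(design)
    iv <- interval_sop(occ)
    rows[[i]] <- tibble::tibble(
      trial = design$arena_id, focal = r$id, family = r$family, sex = r$sex,
      mating_status = r$mating_status, breach = breach[i],
      sop = sop_sc$value, sop_defined = sop_sc$defined,
      ic_sop = ic_sop, ic_excluded = ic$excluded,
      sop_interval1 = iv$sop[1], sop_interval2 = iv$sop[2],
      sop_interval3 = iv$sop[3],
      zone_time_s = occ$T_R + occ$T_UR,
      diff_body_length_mm = td$diff_body_length_mm,
      diff_body_area_mm2 = td$diff_body_area_mm2,
      diff_orange_area_mm2 = td$diff_orange_area_mm2)
  }
  sop_table <- dplyr::bind_rows(rows)

  analyzed <- dplyr::filter(sop_table, !.data$breach)
  ic_kept <- dplyr::filter(analyzed, !.data$ic_excluded)
  if (nrow(analyzed) == 0) stop_kinpref("no usable trials after exclusions")
  ledger <- tibble::tibble(
    stage = c("performed", "after breach exclusion",
              "informed-choice usable"),
    n_trials = c(nrow(sop_table), nrow(analyzed), nrow(ic_kept)))

  fitdat <- dplyr::filter(analyzed, .data$sop_defined)
  models <- list(
    overall = fit_mixed_model(model_spec(
      "sop", "gaussian", c("diff_body_length_mm", "sex", "mating_status"),
      random = "family"), fitdat),
    female = fit_mixed_model(model_spec(
      "sop", "gaussian",
      c("diff_body_length_mm", "diff_orange_area_mm2", "mating_status"),
      random = "family"), dplyr::filter(fitdat, .data$sex == "female")),
    male = fit_mixed_model(model_spec(
      "sop", "gaussian", c("diff_body_length_mm", "mating_status"),
      random = "family"), dplyr::filter(fitdat, .data$sex == "male")))

  list(sop_table = sop_table, ledger = ledger,
       t_test = one_sample_t(fitdat$sop), models = models,
       config_hash = cfg$hash, seed = cfg$seed)
}

## ---- shared arena machinery ------------------------------------------------

arena_design <- function(roster_part, arena_id) {
  trial_design(roster_part[c("id", "family", "sex", "mating_status")],
               arena_id = arena_id)
}

# attraction matrix from a base level plus kin bonus plus per-individual
# latent kin preference
build_attraction <- function(design, base, kin, latent = NULL) {
  ids <- design$individuals$id
  n <- length(ids)
  A <- matrix(base, n, n)
  rel <- design$relatedness >= 0.25
  diag(rel) <- FALSE
  bonus <- matrix(kin, n, n)
  if (!is.null(latent)) bonus <- bonus + matrix(latent, n, n)
  A[rel] <- A[rel] + bonus[rel]
  diag(A) <- 0
  A
}

simulate_arena_trial <- function(design, walk, base, kin, latent, seed,
                                 gain = 1) {
  A <- build_attraction(design, base, kin, latent)
  params <- arena_sim_params(
    n_individuals = nrow(design$individuals),
    arena_radius = walk$arena_radius, speed_mean = walk$speed_mean,
    speed_sd = walk$speed_sd, heading_persistence = walk$heading_persistence,
    attraction = A, attraction_gain = gain, frame_rate = walk$frame_rate,
    duration = walk$duration, seed = seed)
  simulate_arena(params, individual_ids = design$individuals$id)
}

## ---- experiment 2 ----------------------------------------------------------

#' Run Experiment 2: free-swimming mate choice arenas
#'
#' Pairs families into mixed-sex arenas of 8, simulates trajectories and
#' behavioural events, aggregates events into group-level cells, and fits
#' the count layer: one NB GLMM per behaviour and sex (relatedness + mating
#' status, arena random intercept), a pooled all-behaviour GLMM per sex with
#' a behaviour-type random effect, and NB GLMMs on dyadic association frame
#' counts for female-male pairs and all pairs (with likelihood-ratio tests
#' and Tukey contrasts for multi-level predictors). BH-FDR is applied per
#' predictor across the models of each section.
#'
#' @param cfg a [run_config()].
#' @return list with `designs`, `assoc` (dyadic association table),
#'   `counts`, `behavior_table` (tidy per-term results with adjusted p),
#'   `models`, `assoc_models`, `assoc_anova`, `tukey`, `arena_sops`,
#'   `census`.
#' @export
run_experiment2 <- function(cfg) {
  sc <- cfg$scenario$exp2
  roster <- make_roster(cfg)
  ss <- stage_seeds(cfg)
  n_arenas <- sc$n_arenas
  fams <- unique(roster$family)
  if (length(fams) < 2 * n_arenas)
    stop_kinpref("scenario needs %d families for %d mixed-sex arenas",
                 2 * n_arenas, n_arenas)
  seeds <- spawn_seeds(ss$exp2, n_arenas + 10)

  designs <- list()
  assoc <- list()
  sop_rows <- list()
  for (a in seq_len(n_arenas)) {
    part <- roster[roster$family %in% fams[c(2 * a - 1, 2 * a)], ]
    d <- arena_design(part, sprintf("arena%02d", a))
    traj <- simulate_arena_trial(
      d, walk = sc, base = sc$base_attraction, kin = sc$kin_attraction,
      latent = cfg$scenario$latent$gain * part$latent_exp2,
      seed = seeds[a], gain = sc$attraction_gain)
    traj <- repair_gaps(traj, cfg$gap)$traj
    at <- detect_associations(traj, cfg$threshold, d)
    designs[[a]] <- d
    assoc[[a]] <- at
    sop_rows[[a]] <- tibble::tibble(
      focal = part$id, sex = part$sex, mating_status = part$mating_status,
      sop_exp2 = vapply(part$id, function(f)
        arena_sop(at, f, d, "mixed-sex",
                  per_capita = cfg$per_capita_sop)$value, numeric(1)))
  }
  assoc <- dplyr::bind_rows(assoc)
  arena_sops <- dplyr::bind_rows(sop_rows)

  # behavioural events: NB cell counts expanded into actor/recipient events,
  # then re-aggregated through the event pathway
  cell_design <- behavior_design(n_arenas)
  counts_true <- list()
  k <- 0
  for (s in c("female", "male")) {
    for (b in names(sc$behavior_base_rate[[s]])) {
      k <- k + 1
      bp <- behavior_sim_params(
        base_rate = sc$behavior_base_rate[[s]][[b]],
        effect_relatedness = sc$effect_relatedness,
        effect_status = sc$effect_status,
        dispersion = sc$behavior_dispersion,
        arena_sd = sc$behavior_arena_sd, n_arenas = n_arenas,
        seed = seeds[n_arenas + k])
      cc <- simulate_behavior_counts(bp, cell_design)
      cc$sex <- s
      cc$behavior <- b
      counts_true[[k]] <- cc
    }
  }
  counts_true <- dplyr::bind_rows(counts_true)
  events <- events_from_counts(counts_true, designs,
                               seed = seeds[n_arenas + 9])
  counts <- aggregate_counts(events, designs)

  fit_beh <- function(dat) fit_mixed_model(model_spec(
    "count", "negative-binomial", c("relatedness", "mating_status"),
    random = "arena_id"), dat)
  models <- list()
  for (s in c("female", "male")) {
    for (b in behavior_vocab(s)) {
      models[[paste(s, b, sep = ".")]] <- fit_beh(
        dplyr::filter(counts, .data$sex == s, .data$behavior == b))
    }
    pooled <- pool_behaviors(dplyr::filter(counts, .data$sex == s))
    models[[paste(s, "all", sep = ".")]] <- fit_mixed_model(model_spec(
      "count", "negative-binomial", c("relatedness", "mating_status"),
      random = c("arena_id", "behavior")), pooled)
  }

  behavior_table <- dplyr::bind_rows(lapply(names(models), function(nm) {
    res <- models[[nm]]$result
    res <- res[grepl("relatedness|mating_status", res$term), ]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    res$sex <- parts[1]
    res$model <- parts[2]
    res$predictor <- ifelse(grepl("relatedness", res$term),
                            "relatedness", "mating_status")
    res
  }))
  behavior_table <- dplyr::group_by(behavior_table, .data$sex,
                                    .data$predictor)
  behavior_table <- dplyr::ungroup(
    dplyr::mutate(behavior_table, p_adj = bh_fdr(.data$p_value)))

  # dyadic association models
  assoc$relatedness <- factor(assoc$relatedness)
  assoc$status_class <- factor(assoc$status_class)
  assoc$sex_class <- factor(assoc$sex_class)
  fm <- dplyr::filter(assoc, .data$sex_class == "female-male")
  # interactions limited to 2-way: in this dyad design the 3-way cells are
  # structurally empty (e.g. related female-female pairs are always one
  # virgin and one experienced sibling), so higher orders are inestimable
  assoc_models <- list(
    female_male = fit_mixed_model(model_spec(
      "associated_frames", "negative-binomial",
      c("relatedness", "status_class"), random = "arena_id",
      max_interaction_order = 2), fm),
    all_pairs = fit_mixed_model(model_spec(
      "associated_frames", "negative-binomial",
      c("relatedness", "status_class", "sex_class"),
      random = "arena_id", max_interaction_order = 2), assoc))
  assoc_anova <- lapply(assoc_models, likelihood_ratio_anova)
  assoc_anova <- lapply(assoc_anova, function(tb) {
    tb$p_adj <- NA_real_
    tb
  })
  for (p in c("relatedness", "status_class", "sex_class")) {
    fam_p <- unlist(lapply(assoc_anova, function(tb)
      tb$p_value[tb$term == p]))
    if (length(fam_p) && all(is.finite(fam_p))) {
      adj <- bh_fdr(fam_p)
      i <- 1
      for (nm in names(assoc_anova)) {
        sel <- assoc_anova[[nm]]$term == p
        if (any(sel)) {
          assoc_anova[[nm]]$p_adj[sel] <- adj[i]
          i <- i + 1
        }
      }
    }
  }
  tukey <- list()
  for (nm in names(assoc_models)) {
    tb <- assoc_anova[[nm]]
    for (p in tb$term[!is.na(tb$p_value) & tb$p_value < 0.05]) {
      if (length(levels(assoc[[p]])) >= 3)
        tukey[[paste(nm, p, sep = ".")]] <-
          tukey_pairwise(assoc_models[[nm]], p)
    }
  }

  census <- tibble::tibble(
    quantity = c("all_pairs", "female_male_pairs", "cells_per_behavior"),
    n = c(dyad_census(designs, "all"), dyad_census(designs, "opposite-sex"),
          nrow(dplyr::filter(counts, .data$sex == "female",
                             .data$behavior == "orienting"))))

  list(designs = designs, assoc = assoc, counts = counts, events = events,
       behavior_table = behavior_table, models = models,
       assoc_models = assoc_models, assoc_anova = assoc_anova,
       tukey = tukey, arena_sops = arena_sops, census = census,
       config_hash = cfg$hash, seed = cfg$seed)
}

# Expand simulated cell counts into scored events through the actor/recipient
# structure of each arena, so aggregation is exercised end-to-end.
events_from_counts <- function(counts, designs, seed) {
  set.seed(seed)
  names(designs) <- vapply(designs, function(d) d$arena_id, character(1))
  rows <- list()
  k <- 0
  for (r in seq_len(nrow(counts))) {
    cc <- counts[r, ]
    if (cc$count == 0) next
    d <- designs[[cc$arena_id]]
    ind <- d$individuals
    actors <- ind$id[ind$sex == cc$sex & ind$mating_status == cc$mating_status]
    for (e in seq_len(cc$count)) {
      actor <- if (length(actors) > 1) sample(actors, 1) else actors
      partners <- ind$id[ind$sex != cc$sex]
      rel_ok <- vapply(partners, function(p)
        (is_related(d, actor, p) && cc$relatedness == "related") ||
          (!is_related(d, actor, p) && cc$relatedness == "unrelated"),
        logical(1))
      recipient <- sample(partners[rel_ok], 1)
      # raw male mating events are split between successful matings and
      # forced attempts; they are merged back at aggregation
      beh <- if (cc$behavior == "mating" && stats::runif(1) < 0.5)
        "forced-mating" else cc$behavior
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        arena_id = cc$arena_id, actor = actor, recipient = recipient,
        behavior = beh, onset_s = stats::runif(1, 0, 1800), duration_s = 0)
    }
  }
  if (k == 0) return(tibble::tibble(arena_id = character(0),
                                    actor = character(0),
                                    recipient = character(0),
                                    behavior = character(0),
                                    onset_s = numeric(0),
                                    duration_s = numeric(0)))
  dplyr::bind_rows(rows)
}

## ---- experiment 3 ----------------------------------------------------------

#' Run Experiment 3: same-sex social arenas
#'
#' Groups families four at a time into same-sex arenas of 8 (6 female and 6
#' male arenas), simulates trajectories, and fits an NB GLMM of dyadic
#' association frame counts on relatedness and sex with an arena random
#' intercept; also returns the same-sex arena SOP (1 related sibling vs 6
#' unrelated) per individual for the cross-experiment stage.
#'
#' @param cfg a [run_config()].
#' @return list with `assoc`, `model`, `model_table` (per-term results with
#'   adjusted p), `arena_sops`, `census`.
#' @export
run_experiment3 <- function(cfg) {
  sc <- cfg$scenario$exp3
  roster <- make_roster(cfg)
  ss <- stage_seeds(cfg)
  fams <- unique(roster$family)
  n_groups <- length(fams) %/% 4
  seeds <- spawn_seeds(ss$exp3, 2 * n_groups + 1)
  designs <- list()
  assoc <- list()
  sop_rows <- list()
  a <- 0
  for (s in c("female", "male")) {
    for (g in seq_len(n_groups)) {
      a <- a + 1
      part <- roster[roster$family %in% fams[(4 * g - 3):(4 * g)] &
                       roster$sex == s, ]
      d <- arena_design(part, sprintf("ss_arena%02d", a))
      traj <- simulate_arena_trial(
        d, walk = sc, base = sc$sex_attraction[[s]],
        kin = sc$kin_attraction,
        latent = cfg$scenario$latent$gain * part$latent_exp3,
        seed = seeds[a], gain = sc$attraction_gain)
      traj <- repair_gaps(traj, cfg$gap)$traj
      at <- detect_associations(traj, cfg$threshold, d)
      at$arena_sex <- s
      designs[[a]] <- d
      assoc[[a]] <- at
      sop_rows[[a]] <- tibble::tibble(
        focal = part$id, sex = s,
        sop_exp3 = vapply(part$id, function(f)
          arena_sop(at, f, d, "same-sex",
                    per_capita = cfg$per_capita_sop)$value, numeric(1)))
    }
  }
  assoc <- dplyr::bind_rows(assoc)
  assoc$relatedness <- factor(assoc$relatedness)
  assoc$arena_sex <- factor(assoc$arena_sex)
  model <- fit_mixed_model(model_spec(
    "associated_frames", "negative-binomial",
    c("relatedness", "arena_sex"), random = "arena_id",
    max_interaction_order = 2), assoc)
  model_table <- model$result
  model_table$p_adj <- model_table$p_value   # single-model family
  list(designs = designs, assoc = assoc, model = model,
       model_table = model_table,
       arena_sops = dplyr::bind_rows(sop_rows),
       census = tibble::tibble(quantity = "same_sex_dyads",
                               n = dyad_census(designs, "all")),
       config_hash = cfg$hash, seed = cfg$seed)
}

## ---- cross-experiment consistency -------------------------------------------

#' Cross-experiment consistency of kin preference
#'
#' Spearman rank correlations, per sex, between the per-individual SOP for
#' relatives measured in the three designs: Experiment 2 vs 1, 3 vs 1 and
#' 2 vs 3. Undefined or excluded SOPs drop pairwise.
#'
#' @param exp1,exp2,exp3 results of the three `run_experiment*()` calls.
#' @return tibble with `sex`, `comparison`, `rho`, `n`, `p_value`.
#' @export
run_cross_experiment <- function(exp1, exp2, exp3) {
  s1 <- dplyr::filter(exp1$sop_table, !.data$breach)
  s1 <- s1[c("focal", "sex", "sop")]
  names(s1)[3] <- "sop_exp1"
  merged <- dplyr::left_join(s1, exp2$arena_sops[c("focal", "sop_exp2")],
                             by = "focal")
  merged <- dplyr::left_join(merged, exp3$arena_sops[c("focal", "sop_exp3")],
                             by = "focal")
  unmatched <- merged$focal[is.na(merged$sop_exp2) & is.na(merged$sop_exp3)]
  comparisons <- list(
    c("exp2_vs_exp1", "sop_exp2", "sop_exp1"),
    c("exp3_vs_exp1", "sop_exp3", "sop_exp1"),
    c("exp2_vs_exp3", "sop_exp2", "sop_exp3"))
  rows <- list()
  for (s in c("female", "male")) {
    sub <- merged[merged$sex == s, ]
    for (cmp in comparisons) {
      sc <- spearman_consistency(sub[[cmp[2]]], sub[[cmp[3]]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        sex = s, comparison = cmp[1], rho = sc$rho, n = sc$n,
        p_value = sc$p_value)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full study pipeline
#'
#' All three experiments plus the cross-experiment consistency stage. The
#' adjusted p-values of the association-duration models are recomputed per
#' predictor across Experiments 2 and 3 jointly (the association models form
#' one declared FDR family).
#'
#' @param cfg a [run_config()].
#' @return list with `exp1`, `exp2`, `exp3`, `cross`, and
#'   `assoc_family_adj` (cross-table adjusted association p-values).
#' @export
run_all <- function(cfg) {
  e1 <- run_experiment1(cfg)
  e2 <- run_experiment2(cfg)
  e3 <- run_experiment3(cfg)
  cross <- run_cross_experiment(e1, e2, e3)

  # association-duration FDR family across experiments 2 and 3
  rel_p <- c(vapply(e2$assoc_anova, function(tb)
    tb$p_value[tb$term == "relatedness"], numeric(1)),
    exp3 = e3$model$result$p_value[grepl("relatedness",
                                         e3$model$result$term)][1])
  assoc_family_adj <- tibble::tibble(
    model = names(rel_p), predictor = "relatedness", p_value = unname(rel_p),
    p_adj = bh_fdr(unname(rel_p)))

  list(exp1 = e1, exp2 = e2, exp3 = e3, cross = cross,
       assoc_family_adj = assoc_family_adj,
       config_hash = cfg$hash, seed = cfg$seed)
}

#' Write the pipeline's tables to a directory
#'
#' Each CSV carries a provenance comment line with the configuration hash
#' and master seed; identical configurations and seeds produce byte-identical
#' files.
#'
#' @param results output of [run_experiment1()], [run_experiment2()],
#'   [run_experiment3()] or [run_all()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_run_outputs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- results$config_hash
  s <- results$seed
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    write_stamped_csv(df, p, hash = h, seed = s)
    paths <<- c(paths, p)
  }
  if (!is.null(results$sop_table)) {
    emit(results$sop_table, "exp1_sop")
    emit(results$ledger, "exp1_ledger")
    emit(results$t_test, "exp1_t_test")
    for (nm in names(results$models))
      emit(results$models[[nm]]$result, paste0("exp1_model_", nm))
  }
  if (!is.null(results$behavior_table)) {
    emit(results$behavior_table, "exp2_behavior_models")
    emit(results$counts, "exp2_counts")
    emit(results$assoc, "exp2_associations")
    for (nm in names(results$assoc_anova))
      emit(results$assoc_anova[[nm]], paste0("exp2_assoc_anova_", nm))
    emit(results$arena_sops, "exp2_arena_sops")
  }
  if (!is.null(results$model_table)) {
    emit(results$model_table, "exp3_model")
    emit(results$assoc, "exp3_associations")
    emit(results$arena_sops, "exp3_arena_sops")
  }
  if (!is.null(results$exp1)) {
    for (nm in c("exp1", "exp2", "exp3")) {
      sub <- results[[nm]]
      sub$config_hash <- h
      sub$seed <- s
      paths <- c(paths, write_run_outputs(sub, dir))
    }
    emit(results$cross, "cross_consistency")
    emit(results$assoc_family_adj, "assoc_family_fdr")
  }
  invisible(unique(paths))
}
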