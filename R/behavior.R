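# Observer-scored behavioural events and their aggregation into the
# group-level cells used by the count models (arena x focal mating status x
# relatedness of the actor-recipient pair).

#' Behaviour vocabulary by sex
#'
#' Female sexual behaviours: orienting, approaching, gliding. Male sexual
#' behaviours: pursuing, sigmoid (displays), mating and forced-mating; the
#' last two are merged into a single "mating" response at aggregation, so
#' the modelled male behaviours are pursuing, sigmoid and mating.
#'
#' @param sex `"female"` or `"male"`.
#' @param modelled if `TRUE` (default) return the aggregation-level
#'   vocabulary (mating behaviours merged); otherwise the raw event
#'   vocabulary.
#' @return character vector of behaviour names.
#' @export
behavior_vocab <- function(sex = c("female", "male"), modelled = TRUE) {
  sex <- match.arg(sex)
  if (sex == "female") return(c("orienting", "approaching", "gliding"))
  if (modelled) c("pursuing", "sigmoid", "mating")
  else c("pursuing", "sigmoid", "mating", "forced-mating")
}

#' Aggregate behavioural events into analysis cells
#'
#' Counts events per (arena x actor mating status x actor-recipient
#' relatedness) cell for each behaviour, separately by actor sex. Successful
#' matings and forced mating attempts are merged into one "mating" response.
#' Every cell of the fully crossed design is emitted, with zero counts where
#' no events occurred.
#'
#' @param events tibble of scored events with columns `arena_id`, `actor`,
#'   `recipient`, `behavior` and optionally `onset_s`, `duration_s`.
#' @param designs a [trial_design()] or list of them (one per arena, with
#'   `arena_id` set when a list).
#' @param duration_behaviors behaviours aggregated as total duration in
#'   seconds (rounded to integer) instead of event counts; off by default
#'   (state events such as pursuing are modelled as counts).
#' @return tibble with columns `sex`, `behavior`, `arena_id`,
#'   `mating_status`, `relatedness`, `count`.
#' @export
aggregate_counts <- function(events, designs, duration_behaviors = character(0)) {
  if (inherits(designs, "trial_design")) designs <- list(designs)
  names(designs) <- vapply(designs, function(d) d$arena_id %||% "arena01",
                           character(1))
  events <- tibble::as_tibble(events)
  need <- c("arena_id", "actor", "recipient", "behavior")
  if (nrow(events) > 0 && !all(need %in% names(events)))
    stop_kinpref("`events` must have columns: %s", paste(need, collapse = ", "))

  # full cell scaffold, per sex and behaviour
  scaffold <- dplyr::bind_rows(lapply(designs, function(d) {
    tidyr::expand_grid(
      sex = c("female", "male"),
      arena_id = d$arena_id %||% "arena01",
      mating_status = c("experienced", "virgin"),
      relatedness = c("related", "unrelated")
    )
  }))
  scaffold <- dplyr::bind_rows(lapply(c("female", "male"), function(s) {
    tidyr::expand_grid(
      behavior = behavior_vocab(s),
      dplyr::filter(scaffold, .data$sex == s)
    )
  }))

  if (nrow(events) > 0) {
    ev <- events
    bad_arena <- !ev$arena_id %in% names(designs)
    if (any(bad_arena))
      stop_kinpref("event(s) reference unknown arena(s): %s",
                   paste(unique(ev$arena_id[bad_arena]), collapse = ", "))
    per <- lapply(seq_len(nrow(ev)), function(r) {
      e <- ev[r, ]
      d <- designs[[e$arena_id]]
      ids <- d$individuals$id
      if (!e$actor %in% ids || !e$recipient %in% ids)
        stop_kinpref("event %d references unknown individual '%s' in %s",
                     r, setdiff(c(e$actor, e$recipient), ids)[1], e$arena_id)
      if (e$actor == e$recipient)
        stop_kinpref("event %d has actor == recipient ('%s')", r, e$actor)
      s <- design_field(d, e$actor, "sex")
      beh <- if (e$behavior == "forced-mating") "mating" else e$behavior
      if (!beh %in% behavior_vocab(s))
        stop_kinpref("event %d: behavior '%s' is not a %s behaviour",
                     r, e$behavior, s)
      w <- if (beh %in% duration_behaviors) {
        if (is.null(e$duration_s) || is.na(e$duration_s))
          stop_kinpref("event %d needs duration_s for duration aggregation", r)
        e$duration_s
      } else 1
      tibble::tibble(
        sex = s, behavior = beh, arena_id = e$arena_id,
        mating_status = design_field(d, e$actor, "mating_status"),
        relatedness = if (is_related(d, e$actor, e$recipient))
          "related" else "unrelated",
        w = w
      )
    })
    tallies <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(per), .data$sex, .data$behavior,
                      .data$arena_id, .data$mating_status, .data$relatedness),
      count = round(sum(.data$w)), .groups = "drop")
  } else {
    tallies <- scaffold[0, ]
    tallies$count <- integer(0)
  }

  out <- dplyr::left_join(scaffold, tallies,
                          by = c("sex", "behavior", "arena_id",
                                 "mating_status", "relatedness"))
  out$count[is.na(out$count)] <- 0L
  out$count <- as.integer(out$count)
  dplyr::arrange(out, .data$sex, .data$behavior, .data$arena_id,
                 .data$mating_status, .data$relatedness)
}

#' Stack per-behaviour count tables for a pooled fit
#'
#' Verifies that every behaviour shares the same cell structure and returns
#' one long table with `behavior` as a grouping label, ready for a pooled
#' model with a behaviour-type random effect.
#'
#' @param counts either the output of [aggregate_counts()] (already long) or
#'   a named list of per-behaviour cell tables with identical keys.
#' @return long tibble with columns `behavior`, `arena_id`, `mating_status`,
#'   `relatedness`, `count` (plus `sex` if present).
#' @export
pool_behaviors <- function(counts) {
  if (is.data.frame(counts)) {
    stacked <- tibble::as_tibble(counts)
  } else {
    counts <- lapply(names(counts), function(b) {
      df <- tibble::as_tibble(counts[[b]])
      df$behavior <- b
      df
    })
    stacked <- dplyr::bind_rows(counts)
  }
  keys <- c("arena_id", "mating_status", "relatedness")
  if (!all(c(keys, "behavior", "count") %in% names(stacked)))
    stop_kinpref("pooled table needs columns behavior, count and keys: %s",
                 paste(keys, collapse = ", "))
  cells <- split(stacked[keys], stacked$behavior)
  key_str <- lapply(cells, function(df)
    sort(do.call(paste, c(df, sep = "\r"))))
  if (length(unique(key_str)) != 1L)
    stop_kinpref("behaviours have mismatched cell keys; pooled fit undefined")
  stacked
}
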