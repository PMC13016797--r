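# Statistical layer: SOP t-tests, Gaussian and negative-binomial mixed models
# with stepwise interaction pruning, likelihood-ratio analysis of deviance,
# Tukey post-hoc contrasts, Benjamini-Hochberg FDR, rank-sum tests and
# cross-experiment Spearman consistency.

#' One-sample t-test against a null preference
#'
#' @param x numeric SOP values (NAs dropped).
#' @param null null mean (0 = no preference).
#' @return tibble with `mean`, `t`, `df`, `p_value`, `n`.
#' @export
one_sample_t <- function(x, null = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2)
    stop_kinpref("one_sample_t needs at least 2 non-missing values")
  if (stats::sd(x) == 0) {
    # degenerate: all values identical; t is 0 when equal to the null
    tstat <- if (x[1] == null) 0 else Inf * sign(x[1] - null)
    return(tibble::tibble(mean = x[1], t = tstat, df = length(x) - 1,
                          p_value = if (x[1] == null) 1 else 0,
                          n = length(x)))
  }
  tt <- stats::t.test(x, mu = null)
  tibble::tibble(mean = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 n = length(x))
}

## ---- mixed models ----------------------------------------------------------

#' Specify a mixed model
#'
#' @param response response column name.
#' @param family `"gaussian"` (LMM) or `"negative-binomial"` (log-link NB
#'   GLMM parameterised by mean and dispersion).
#' @param fixed character vector of fixed-effect column names.
#' @param random character vector of random-intercept grouping columns.
#' @param max_interaction_order interactions among fixed effects included at
#'   the start of the stepwise pruning (default all 2- and 3-way; 1 = main
#'   effects only).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, family = c("gaussian", "negative-binomial"),
                       fixed, random = character(0),
                       max_interaction_order = 3) {
  family <- match.arg(family)
  check_number(max_interaction_order, "max_interaction_order", lower = 1)
  if (length(fixed) == 0) stop_kinpref("at least one fixed effect required")
  structure(list(response = response, family = family, fixed = fixed,
                 random = random,
                 max_interaction_order = as.integer(max_interaction_order)),
            class = "model_spec")
}

spec_formula <- function(spec, fixed_terms = NULL) {
  if (is.null(fixed_terms)) {
    ord <- min(spec$max_interaction_order, length(spec$fixed))
    fx <- if (ord > 1)
      sprintf("(%s)^%d", paste(spec$fixed, collapse = " + "), ord)
    else paste(spec$fixed, collapse = " + ")
  } else {
    fx <- paste(fixed_terms, collapse = " + ")
  }
  re <- if (length(spec$random))
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ") else NULL
  stats::as.formula(paste(spec$response, "~",
                          paste(c(fx, re), collapse = " + ")))
}

tmb_family <- function(spec) {
  if (spec$family == "gaussian") stats::gaussian() else glmmTMB::nbinom2()
}

fit_converged <- function(fit) {
  isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
}

# Wald per-term p-values used only to steer the pruning loop.
term_p_values <- function(fit) {
  a <- try(car::Anova(fit, type = "II"), silent = TRUE)
  if (inherits(a, "try-error")) return(NULL)
  stats::setNames(a[["Pr(>Chisq)"]], rownames(a))
}

#' Fit a mixed model with stepwise interaction pruning
#'
#' Builds the design from a [model_spec()], starts from all interactions up
#' to the requested order, and repeatedly drops the least significant
#' currently-droppable interaction (largest per-term Wald p at or above
#' `alpha`, highest order first, respecting marginality) until only
#' significant interactions or main effects remain. Main effects are never
#' dropped. Fitting is delegated to \pkg{glmmTMB}; convergence problems are
#' flagged on the result, never silently ignored.
#'
#' @param spec a [model_spec()].
#' @param data data frame holding response, predictors and grouping columns.
#' @param alpha significance threshold for retaining interactions.
#' @return an object of class `kinpref_model`: list with `result` (tidy
#'   per-coefficient table: `term`, `estimate`, `conf_low`, `conf_high`,
#'   `se`, `statistic`, `p_value`), `fit` (the glmmTMB fit), `spec`,
#'   `formula`, `dropped` (pruned interaction terms), `converged`,
#'   `dispersion`.
#' @export
fit_mixed_model <- function(spec, data, alpha = 0.05) {
  if (!inherits(spec, "model_spec"))
    stop_kinpref("`spec` must be a model_spec")
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(spec$response, spec$fixed, spec$random),
                          names(data))
  if (length(missing_cols))
    stop_kinpref("data lacks columns: %s", paste(missing_cols, collapse = ", "))
  for (r in spec$random)
    if (length(unique(data[[r]])) < 2)
      stop_kinpref("random effect '%s' needs >= 2 levels", r)

  # rank check on the fixed-effect design
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(spec$fixed, collapse = " + "))), data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop_kinpref("rank-deficient design; collinear terms: %s",
                 paste(bad, collapse = ", "))
  }

  form <- spec_formula(spec)
  terms_now <- attr(stats::terms(form), "term.labels")
  terms_now <- terms_now[!grepl("\\|", terms_now)]
  dropped <- character(0)
  fit <- NULL
  repeat {
    form <- spec_formula(spec, fixed_terms = terms_now)
    fit <- suppressWarnings(
      glmmTMB::glmmTMB(form, data = data, family = tmb_family(spec)))
    inter <- terms_now[grepl(":", terms_now)]
    if (length(inter) == 0) break
    # droppable: interactions not marginal to a retained higher-order term
    droppable <- inter[vapply(inter, function(tm) {
      parts <- strsplit(tm, ":")[[1]]
      !any(vapply(setdiff(inter, tm), function(other) {
        all(parts %in% strsplit(other, ":")[[1]])
      }, logical(1)))
    }, logical(1))]
    pv <- term_p_values(fit)
    if (is.null(pv)) break
    pv <- pv[droppable]
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0 || max(pv) < alpha) break
    worst <- names(pv)[which.max(pv)]
    terms_now <- setdiff(terms_now, worst)
    dropped <- c(dropped, worst)
  }

  converged <- fit_converged(fit)
  if (!converged)
    warning("mixed model did not converge cleanly; result flagged",
            call. = FALSE)
  co <- summary(fit)$coefficients$cond
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  result <- tibble::tibble(
    term = rownames(co), estimate = unname(est),
    conf_low = unname(est - stats::qnorm(0.975) * se),
    conf_high = unname(est + stats::qnorm(0.975) * se),
    se = unname(se), statistic = unname(co[, "z value"]),
    p_value = unname(co[, "Pr(>|z|)"])
  )
  structure(list(result = result, fit = fit, spec = spec,
                 formula = form, dropped = dropped, converged = converged,
                 dispersion = tryCatch(glmmTMB::sigma(fit),
                                       error = function(e) NA_real_)),
            class = "kinpref_model")
}

#' @export
print.kinpref_model <- function(x, ...) {
  cat(sprintf("<kinpref_model> %s [%s]%s\n", deparse(x$formula),
              x$spec$family,
              if (!x$converged) " (NOT CONVERGED)" else ""))
  print(as.data.frame(x$result), digits = 3)
  invisible(x)
}

#' Likelihood-ratio analysis of deviance (type II)
#'
#' Per-predictor chi-square tests by nested-model comparison, following the
#' marginality principle: each main effect is tested by comparing a model
#' holding all terms that do not involve the predictor plus its main effect
#' against the same model without it (interactions involving the predictor
#' are excluded from both sides). Used where predictors have more than two
#' levels, feeding the post-hoc stage; also the calibrated marginal test of
#' a main effect when an interaction survived pruning.
#'
#' @param model a [fit_mixed_model()] result.
#' @param predictors predictors to test (default: all fixed effects).
#' @return tibble with `term`, `chisq`, `df`, `p_value`.
#' @export
likelihood_ratio_anova <- function(model, predictors = NULL) {
  spec <- model$spec
  predictors <- predictors %||% spec$fixed
  final_terms <- attr(stats::terms(model$formula), "term.labels")
  final_terms <- final_terms[!grepl("\\|", final_terms)]
  data <- model$fit$frame
  refit <- function(terms_) {
    if (length(terms_) == 0) terms_ <- "1"
    f <- spec_formula(spec, fixed_terms = terms_)
    fit <- try(suppressWarnings(
      glmmTMB::glmmTMB(f, data = data, family = tmb_family(spec))),
      silent = TRUE)
    if (inherits(fit, "try-error") || !fit_converged(fit)) NULL else fit
  }
  rows <- lapply(predictors, function(tm) {
    others <- final_terms[!vapply(final_terms, function(t2)
      tm %in% strsplit(t2, ":")[[1]], logical(1))]
    full <- refit(c(others, tm))
    red <- refit(others)
    if (is.null(full) || is.null(red)) {
      warning(sprintf("nested fits for '%s' failed; flagged", tm),
              call. = FALSE)
      return(tibble::tibble(term = tm, chisq = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    }
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
    chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                           as.numeric(stats::logLik(red))))
    tibble::tibble(term = tm, chisq = chisq, df = df,
                   p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Tukey pairwise post-hoc contrasts
#'
#' All pairwise contrasts between the levels of a factor in a fitted mixed
#' model, with familywise (Tukey) adjustment, on the link scale. Requires at
#' least 3 levels (with 2 the main-effect test already answers the question).
#'
#' @param model a [fit_mixed_model()] result.
#' @param factor name of a categorical fixed effect.
#' @return tibble with `contrast`, `estimate`, `se`, `z`, `p_adj`.
#' @export
tukey_pairwise <- function(model, factor) {
  data <- model$fit$frame
  if (!factor %in% names(data))
    stop_kinpref("'%s' is not a model predictor", factor)
  nlev <- length(unique(data[[factor]]))
  if (nlev < 3)
    stop_kinpref("'%s' has %d levels; Tukey contrasts need >= 3", factor, nlev)
  em <- emmeans::emmeans(model$fit, specs = factor)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  tibble::tibble(contrast = as.character(ct$contrast),
                 estimate = ct$estimate, se = ct$SE,
                 z = ct$estimate / ct$SE, p_adj = ct$p.value)
}

## ---- classical tests -------------------------------------------------------

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values implemented from the definition: sort the m raw
#' p-values ascending, set `adj_(i) = min_{j >= i} (m * p_(j) / j)` capped at
#' 1, and restore the original order. Applied within an explicitly declared
#' family of tests (e.g. one predictor across the models of a results table).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_kinpref("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison with mid-rank ties: exact for small,
#' tie-free samples, otherwise the normal approximation with continuity
#' correction.
#'
#' @param x,y the two samples.
#' @return tibble with `W`, `p_value`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop_kinpref("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  tibble::tibble(W = unname(wt$statistic), p_value = wt$p.value,
                 n_x = length(x), n_y = length(y))
}

#' Spearman consistency of preference across experiments
#'
#' Rank correlation (mid-rank ties) between two per-individual SOP vectors;
#' pairs with an undefined score on either side are dropped listwise.
#'
#' @param sop_a,sop_b numeric vectors aligned by individual.
#' @return tibble with `rho`, `n`, `p_value`.
#' @export
spearman_consistency <- function(sop_a, sop_b) {
  if (length(sop_a) != length(sop_b))
    stop_kinpref("SOP vectors must be aligned by individual (equal length)")
  keep <- !is.na(sop_a) & !is.na(sop_b)
  if (sum(keep) < 3)
    stop_kinpref("need >= 3 complete pairs; got %d", sum(keep))
  ct <- suppressWarnings(stats::cor.test(sop_a[keep], sop_b[keep],
                                         method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), n = sum(keep),
                 p_value = ct$p.value)
}
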