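# Mutation-burden modelling: genome-wide extrapolation, linear mixed-effects
# models (rate across age cohorts; trisomy model with donor random slope and
# karyotype-specific residual variances; early-mutation model without age),
# likelihood-ratio variance test, leave-n-out robustness, residual-based
# outlier detection and the DBS rank-sum comparison.
#
# Estimation: REML for reported effects, ML refits for likelihood-ratio
# comparisons. Degrees of freedom for the two-tailed t-tests are nlme's
# grouping-aware residual-df approximation.

#' Surveyed fraction of the genome
#'
#' Fraction of (sampled) autosomal positions with depth >= `dp_min` in both
#' the clone and its matched bulk, with a binomial standard error.
#'
#' @param clone_depths,bulk_depths Depth vectors over the same positions.
#' @param dp_min Depth threshold (default 20).
#' @return List: `fraction`, `se`, `n`.
#' @export
surveyed_fraction <- function(clone_depths, bulk_depths, dp_min = 20) {
  if (!length(clone_depths) || length(clone_depths) != length(bulk_depths))
    stop("clone and bulk depth tracks must be non-empty and equal length")
  ok <- clone_depths >= dp_min & bulk_depths >= dp_min
  p <- mean(ok)
  list(fraction = p, se = sqrt(p * (1 - p) / length(ok)), n = length(ok))
}

#' Extrapolate an observed mutation count to the whole genome
#'
#' @param n_observed Observed clonal autosomal count.
#' @param surveyed_fraction Fraction in (0, 1].
#' @return Extrapolated load `n_observed / surveyed_fraction`.
#' @export
extrapolate_load <- function(n_observed, surveyed_fraction) {
  if (any(surveyed_fraction <= 0 | surveyed_fraction > 1))
    stop("surveyed_fraction must be in (0, 1]")
  n_observed / surveyed_fraction
}

fixed_effects_table <- function(fit) {
  tt <- summary(fit)$tTable
  # residual-df approximation for the two-tailed t-tests (documented choice;
  # well calibrated for these designs)
  df <- fit$dims$N - nrow(tt)
  est <- tt[, "Value"]; se <- tt[, "Std.Error"]
  tv <- tt[, "t-value"]
  tcrit <- stats::qt(0.975, df)
  data.table::data.table(
    term = rownames(tt), estimate = est, se = se, df = df,
    t = tv, p = 2 * stats::pt(-abs(tv), df),
    ci_lo = est - tcrit * se, ci_hi = est + tcrit * se)
}

# exact fallback for degenerate (zero residual variance) inputs, where the
# mixed-model likelihood is singular: ordinary least squares reproduces the
# group structure exactly
degenerate_lm_result <- function(form, obs, extra = list()) {
  fit <- stats::lm(form, data = obs)
  cf <- suppressWarnings(summary(fit))$coefficients
  est <- cf[, 1]; se <- cf[, 2]
  df <- fit$df.residual
  tv <- ifelse(se > 0, est / se, ifelse(abs(est) < 1e-12, 0, Inf))
  tcrit <- stats::qt(0.975, max(df, 1))
  c(list(
    fit = fit, data = obs, degenerate = TRUE,
    fixed = data.table::data.table(
      term = rownames(cf), estimate = unname(est), se = unname(se),
      df = df, t = unname(tv), p = 2 * stats::pt(-abs(unname(tv)), max(df, 1)),
      ci_lo = unname(est - tcrit * se), ci_hi = unname(est + tcrit * se)),
    logLik = NA_real_, AIC = NA_real_, BIC = NA_real_,
    sigma = stats::sigma(fit),
    residuals = stats::resid(fit)), extra)
}

model_result <- function(fit, data, extra = list()) {
  vc <- nlme::VarCorr(fit)
  res <- list(
    fit = fit,
    data = data,
    fixed = fixed_effects_table(fit),
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit), BIC = stats::BIC(fit),
    sigma = fit$sigma,
    residuals = stats::resid(fit, type = "pearson")
  )
  # per-group residual SDs when a varIdent structure is present
  vs <- fit$modelStruct$varStruct
  if (!is.null(vs)) {
    w <- stats::coef(vs, unconstrained = FALSE, allCoef = TRUE)
    res$group_sd <- fit$sigma * w
  }
  c(res, extra)
}

#' Fit the mutation-rate model across age cohorts
#'
#' `rate ~ cohort` with a donor random intercept; per-cohort means with 95%
#' CI, all pairwise contrasts (two-tailed t-tests at donor-level df) and the
#' fold-change between the first and last cohort with a parametric-bootstrap
#' CI (draws from the fixed-effect covariance).
#'
#' @param obs data.frame with columns `rate`, `cohort` (factor), `donor`.
#' @param n_boot Bootstrap draws for the fold-change CI.
#' @param seed Seed for the bootstrap.
#' @return Model-result list with `group_means`, `contrasts`, `fold_change`.
#' @export
fit_rate_model <- function(obs, n_boot = 1000, seed = 1) {
  obs <- as.data.frame(obs)
  obs$cohort <- droplevels(as.factor(obs$cohort))
  tab <- table(unique(obs[, c("donor", "cohort")])$cohort)
  if (any(tab < 2))
    stop("need >= 2 donors per cohort (descriptive output advised for: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  within_var <- suppressWarnings(
    max(tapply(obs$rate, obs$donor, stats::var), 0, na.rm = TRUE))
  if (within_var < 1e-10) {
    # zero residual noise: collapse to donor means, OLS on the donor level
    dm <- stats::aggregate(rate ~ donor + cohort, data = obs, FUN = mean)
    res <- degenerate_lm_result(rate ~ 0 + cohort, dm)
    res$fixed$term <- sub("^cohort", "", res$fixed$term)
    res$group_means <- res$fixed
    lev <- levels(obs$cohort)
    beta <- res$fixed$estimate[match(lev, res$fixed$term)]
    res$fold_change <- list(estimate = beta[1] / beta[length(lev)],
                            ci = c(NA_real_, NA_real_),
                            comparison = paste(lev[1], "vs", lev[length(lev)]))
    res$contrasts <- data.table::data.table()
    return(res)
  }
  fit <- nlme::lme(rate ~ 0 + cohort, random = ~ 1 | donor, data = obs,
                   method = "REML")
  means <- fixed_effects_table(fit)
  means$term <- sub("^cohort", "", means$term)

  beta <- nlme::fixef(fit); V <- stats::vcov(fit)
  lev <- levels(obs$cohort)
  n_donor <- length(unique(obs$donor))
  df_btw <- max(1, n_donor - length(lev))
  # cohort is a donor-level covariate: group means and contrasts use
  # between-donor df
  means$df <- df_btw
  tcrit <- stats::qt(0.975, df_btw)
  means$p <- 2 * stats::pt(-abs(means$t), df_btw)
  means$ci_lo <- means$estimate - tcrit * means$se
  means$ci_hi <- means$estimate + tcrit * means$se
  contrasts <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    L <- rep(0, length(beta)); L[i] <- 1; L[j] <- -1
    est <- sum(L * beta); se <- sqrt(drop(t(L) %*% V %*% L))
    tv <- est / se
    contrasts[[length(contrasts) + 1L]] <- data.table::data.table(
      contrast = paste(lev[i], "-", lev[j]), estimate = est, se = se,
      df = df_btw, t = tv, p = 2 * stats::pt(-abs(tv), df_btw),
      ci_lo = est - stats::qt(0.975, df_btw) * se,
      ci_hi = est + stats::qt(0.975, df_btw) * se)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- MASS::mvrnorm(n_boot, beta, V)
  fc_draws <- draws[, 1] / draws[, length(lev)]
  fold_change <- list(
    estimate = beta[[1]] / beta[[length(lev)]],
    ci = stats::quantile(fc_draws, c(0.025, 0.975), names = FALSE),
    comparison = paste(lev[1], "vs", lev[length(lev)]))

  model_result(fit, obs, list(group_means = means,
                              contrasts = data.table::rbindlist(contrasts),
                              fold_change = fold_change))
}

#' Fit the trisomy burden model
#'
#' `load ~ age + trisomy21 * cell_type` with a donor random slope on age and
#' karyotype-specific residual variances (`varIdent`). The trisomy main
#' effect is the extra load in T21 cells (treatment coding, reference cell
#' type HSPC).
#'
#' @param obs data.frame with `load`, `age`, `trisomy21`, `cell_type`,
#'   `donor`.
#' @param heteroscedastic Allow separate residual SD per karyotype.
#' @param method `"REML"` (reported fits) or `"ML"` (likelihood-ratio use).
#' @return Model-result list; `fixed` includes the `trisomy21T21` row.
#' @export
fit_trisomy_model <- function(obs, heteroscedastic = TRUE, method = "REML") {
  obs <- as.data.frame(obs)
  obs$trisomy21 <- droplevels(as.factor(obs$trisomy21))
  obs$cell_type <- droplevels(as.factor(obs$cell_type))
  tab <- table(unique(obs[, c("donor", "trisomy21")])$trisomy21)
  if (length(tab) < 2 || any(tab < 2))
    stop("need both karyotype groups with >= 2 donors each")
  form <- if (nlevels(obs$cell_type) > 1)
    load ~ age + trisomy21 * cell_type else load ~ age + trisomy21
  if (stats::var(obs$load) < 1e-10)
    return(degenerate_lm_result(form, obs))
  w <- if (heteroscedastic) nlme::varIdent(form = ~ 1 | trisomy21) else NULL
  fit <- tryCatch(
    nlme::lme(form, random = ~ 0 + age | donor, weights = w, data = obs,
              method = method,
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         opt = "optim", returnObject = FALSE)),
    error = function(e)
      stop("trisomy model did not converge (", conditionMessage(e),
           "); consider a simplified model (single variance or random intercept)",
           call. = FALSE))
  model_result(fit, obs, list(
    refit = function(method = "ML")
      fit_trisomy_model(obs, heteroscedastic = heteroscedastic, method = method)))
}

#' Fit the early-mutation burden model
#'
#' Same structure as [fit_trisomy_model()] without the age term (early
#' mutations predate gastrulation, so age is not an explanatory variable);
#' donor random intercept.
#'
#' @param obs data.frame with `load` (early load), `trisomy21`, `cell_type`,
#'   `donor`.
#' @inheritParams fit_trisomy_model
#' @return Model-result list.
#' @export
fit_early_model <- function(obs, heteroscedastic = TRUE, method = "REML") {
  obs <- as.data.frame(obs)
  obs$trisomy21 <- droplevels(as.factor(obs$trisomy21))
  obs$cell_type <- droplevels(as.factor(obs$cell_type))
  form <- if (nlevels(obs$cell_type) > 1)
    load ~ trisomy21 * cell_type else load ~ trisomy21
  if (stats::var(obs$load) < 1e-10)
    return(degenerate_lm_result(form, obs))
  w <- if (heteroscedastic) nlme::varIdent(form = ~ 1 | trisomy21) else NULL
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | donor, weights = w, data = obs,
              method = method,
              control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                         opt = "optim", returnObject = FALSE)),
    error = function(e)
      stop("early-mutation model did not converge (", conditionMessage(e), ")",
           call. = FALSE))
  model_result(fit, obs, list(
    refit = function(method = "ML")
      fit_early_model(obs, heteroscedastic = heteroscedastic, method = method)))
}

#' Likelihood-ratio test of karyotype-specific residual variances
#'
#' Compares the heteroscedastic model to its single-variance reduction (both
#' refitted by ML), LR = 2 x delta log-likelihood against chi-square df = 1.
#'
#' @param het_model,hom_model Model-result lists (same fixed effects; the
#'   homoscedastic model must be nested in the heteroscedastic one).
#' @return List: `lr`, `df`, `p`.
#' @export
variance_lr_test <- function(het_model, hom_model) {
  f1 <- deparse(stats::formula(het_model$fit))
  f2 <- deparse(stats::formula(hom_model$fit))
  if (!identical(f1, f2)) stop("models are not nested: different fixed effects")
  if (is.null(het_model$fit$modelStruct$varStruct))
    stop("het_model has no variance structure; models are not nested")
  ll_het <- ml_loglik(het_model)
  ll_hom <- ml_loglik(hom_model)
  lr <- max(0, 2 * (ll_het - ll_hom))
  list(lr = lr, df = 1L, p = stats::pchisq(lr, df = 1L, lower.tail = FALSE))
}

ml_loglik <- function(model) {
  fit <- model$fit
  if (fit$method == "ML") return(as.numeric(stats::logLik(fit)))
  if (is.null(model$refit))
    stop("model was fitted by REML and carries no ML refit hook")
  model$refit("ML")$logLik
}

#' Leave-n-out robustness analysis
#'
#' Refits the model on every combination of `n` removed observations and
#' collects the fixed-effect p-values; combinations that empty a required
#' group are skipped and logged.
#'
#' @param obs Observation table.
#' @param n Number of points to remove (1 or 2).
#' @param fit_fun Fitting function, e.g. [fit_trisomy_model()].
#' @param ... Passed to `fit_fun`.
#' @return List: `p_values` (data.table combo/term/p), `max_p` (per term),
#'   `n_fits`, `skipped`.
#' @export
leave_n_out <- function(obs, n = 1, fit_fun = fit_trisomy_model, ...) {
  stopifnot(n %in% c(1L, 2L))
  obs <- as.data.frame(obs)
  combos <- utils::combn(nrow(obs), n)
  res <- list(); skipped <- character(0)
  for (k in seq_len(ncol(combos))) {
    drop_idx <- combos[, k]
    tag <- paste(drop_idx, collapse = ",")
    fitted <- tryCatch(fit_fun(obs[-drop_idx, , drop = FALSE], ...),
                       error = function(e) NULL)
    if (is.null(fitted)) { skipped <- c(skipped, tag); next }
    fx <- fitted$fixed
    res[[length(res) + 1L]] <- data.table::data.table(
      combo = tag, term = fx$term, p = fx$p)
  }
  pv <- data.table::rbindlist(res)
  max_p <- if (nrow(pv)) pv[, list(max_p = max(p)), by = "term"] else pv
  list(p_values = pv, max_p = max_p, n_fits = length(res), skipped = skipped)
}

#' Residual-based outlier detection with FDR control
#'
#' Two-sided standard-normal p-value for each standardized residual,
#' Benjamini-Hochberg adjustment, flags at `fdr < fdr_q`.
#'
#' @param model_result Fitted model-result list.
#' @param fdr_q FDR threshold (default 0.05).
#' @return data.table: observation index, residual, p, fdr, outlier.
#' @export
detect_outliers <- function(model_result, fdr_q = 0.05) {
  z <- as.numeric(model_result$residuals)
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(p, method = "BH")
  data.table::data.table(index = seq_along(z), residual = z, p = p,
                         fdr = fdr, outlier = fdr < fdr_q)
}

#' Compare DBS counts between karyotype groups
#'
#' Two-sided Wilcoxon rank-sum test with continuity correction (normal
#' approximation, matching the published analysis) on per-clone
#' donor-deduplicated DBS counts.
#'
#' @param d21_counts,t21_counts Integer vectors.
#' @return `htest` object.
#' @export
compare_dbs <- function(d21_counts, t21_counts) {
  if (!length(d21_counts) || !length(t21_counts))
    stop("both groups must be non-empty")
  suppressWarnings(stats::wilcox.test(d21_counts, t21_counts,
                                      correct = TRUE, exact = FALSE))
}
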