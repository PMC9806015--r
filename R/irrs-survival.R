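#' Stratified train/test split
#'
#' Splits a cohort into training and testing subsets with stratified
#' sampling (by event status by default), so each stratum's training
#' proportion is within one patient of `train_fraction` and the total
#' training size is exactly `round(train_fraction * n)`.
#'
#' @param strata Vector of stratum labels, one per patient (e.g. the event
#'   indicator).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @examples
#' sp <- stratified_split(rep(0:1, c(313, 240)), seed = 1)
#' length(sp$train)  # 387 of 553
#' @export
stratified_split <- function(strata, train_fraction = 0.7, seed) {
  strata <- as.factor(strata)
  tab <- table(strata)
  if (any(tab < 2L)) stop("every stratum needs at least 2 patients")
  n <- length(strata)
  target_total <- round(train_fraction * n)
  base <- floor(train_fraction * tab)
  rem <- train_fraction * tab - base
  short <- target_total - sum(base)
  take <- as.numeric(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    take[add] <- take[add] + 1
  }
  set.seed(seed)
  train <- unlist(lapply(seq_along(levels(strata)), function(k) {
    idx <- which(strata == levels(strata)[k])
    sample(idx, take[k])
  }))
  train <- sort(as.integer(train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Univariate Cox regression for one candidate variable
#'
#' A proportional-hazards fit with Efron tie handling. Degenerate inputs
#' (constant variable, non-convergence, monotone likelihood / infinite
#' coefficient) are flagged so the variable can be excluded from the
#' candidate pool rather than silently carried forward.
#'
#' @param x Numeric covariate vector.
#' @param time,event Follow-up times and event indicators (1 = event).
#' @return A list with `hr`, `log_hr`, `ci_lower`, `ci_upper`, `p`, `n`,
#'   `n_events` and `ok` (FALSE when the fit is unusable).
#' @export
univariate_cox <- function(x, time, event) {
  bad <- function(msg) list(hr = NA_real_, log_hr = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            p = NA_real_, n = length(time),
                            n_events = sum(event), ok = FALSE, reason = msg)
  if (length(unique(x[!is.na(x)])) < 2L) return(bad("constant variable"))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(fit)) {
    # refit capturing the estimate but flagging the warning
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[1L]) ||
        abs(coef(fit)[1L]) > 15) {
      return(bad("non-convergence or monotone likelihood"))
    }
  }
  b <- unname(coef(fit)[1L])
  se <- sqrt(diag(fit$var))[1L]
  if (!is.finite(b) || !is.finite(se)) return(bad("unstable fit"))
  z <- b / se
  list(hr = exp(b), log_hr = b,
       ci_lower = exp(b - qnorm(0.975) * se),
       ci_upper = exp(b + qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(z)),
       n = fit$n, n_events = fit$nevent, ok = TRUE, reason = NULL)
}

#' Screen candidate variables by univariate Cox significance
#'
#' @param features Data.frame of candidate variables.
#' @param time,event Survival outcome.
#' @param alpha Two-sided significance gate (default 0.05).
#' @return A data.frame (one row per variable) of univariate results with a
#'   `selected` column; failed fits are retained with `ok = FALSE`.
#' @export
screen_candidates <- function(features, time, event, alpha = 0.05) {
  rows <- lapply(names(features), function(v) {
    res <- univariate_cox(features[[v]], time, event)
    data.frame(variable = v, hr = res$hr, log_hr = res$log_hr,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper,
               p = res$p, ok = res$ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$ok & !is.na(out$p) & out$p < alpha
  out
}

#' LASSO-Cox variable selection with cross-validation
#'
#' Fits an L1-penalised Cox model over a log-spaced lambda path (100 values
#' spanning four decades below the full-shrinkage lambda) and selects the
#' lambda minimising the mean 10-fold cross-validated partial-likelihood
#' deviance. The selected variables are those with non-zero coefficients at
#' that lambda. When fewer events than folds are available the fold count is
#' reduced with a warning.
#'
#' @param x Numeric matrix or data.frame of pre-screened candidates.
#' @param time,event Survival outcome.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @return A list with `selected` (variable names), `lambda_min`, `lambda`
#'   (path), `cvm` (mean CV deviance per lambda), `coefs` (coefficients at
#'   `lambda_min`) and the `cv_fit`.
#' @export
lasso_cox_select <- function(x, time, event, nfolds = 10, seed = 1) {
  x <- as.matrix(x)
  if (sum(event) < nfolds) {
    nfolds <- max(3L, sum(event))
    warning(sprintf("fewer events than folds; reduced to %d folds", nfolds))
  }
  set.seed(seed)
  y <- survival::Surv(time, event)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = nfolds,
                          nlambda = 100, lambda.min.ratio = 1e-4)
  co <- as.matrix(coef(cv, s = "lambda.min"))
  sel <- rownames(co)[co[, 1L] != 0]
  list(selected = sel, lambda_min = cv$lambda.min, lambda = cv$lambda,
       cvm = cv$cvm, coefs = setNames(co[, 1L], rownames(co)), cv_fit = cv)
}

#' Compute the immune-related risk score
#'
#' `IRRS = sum_z ln(HR_z) * proportion_z` over the model's selected
#' variables, where `ln(HR_z)` is the variable's univariate Cox log hazard
#' ratio estimated on the training cohort and `proportion_z` is the
#' patient's value of the variable on its proportion scale. Patients missing
#' any model variable receive `NA`.
#'
#' @param features Data.frame (patients x variables) containing all model
#'   variables.
#' @param model An `irrs_model` (see [build_irrs_model()]) or a named weight
#'   vector of log hazard ratios.
#' @return Numeric score per patient.
#' @examples
#' compute_irrs(data.frame(a = 0.5), c(a = log(2)))  # 0.3466
#' @export
compute_irrs <- function(features, model) {
  weights <- if (inherits(model, "irrs_model")) model$weights else model
  miss <- setdiff(names(weights), names(features))
  if (length(miss) > 0) {
    stop("missing model variables: ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(features[, names(weights), drop = FALSE])
  as.numeric(m %*% weights)
}

#' Optimal survival cutpoint by log-rank scanning
#'
#' Emulates X-tile cutpoint selection: candidate cutoffs are the distinct
#' score values between the 10th and 90th percentiles; the cutoff maximising
#' the two-group log-rank chi-square is returned, subject to both groups
#' holding at least `min_group_fraction` of the cohort. The selected
#' chi-square's nominal p-value is reported without correction for the scan,
#' a known source of optimism; the cutoff learned here is meant to be applied
#' unchanged to validation cohorts.
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival outcome.
#' @param min_group_fraction Minimum group size as a fraction (default 0.1).
#' @param max_candidates Thin the candidate set to at most this many
#'   quantile-spaced values (default 100).
#' @return List with `cutoff`, `chisq`, `p` and `n_candidates`.
#' @export
optimal_cutoff <- function(scores, time, event, min_group_fraction = 0.1,
                           max_candidates = 100) {
  if (length(scores) < 20L) stop("at least 20 patients required")
  qs <- quantile(scores, c(0.1, 0.9), names = FALSE, type = 7)
  cand <- sort(unique(scores[scores >= qs[1L] & scores <= qs[2L]]))
  # a cutoff at the largest value would leave the high group empty
  cand <- cand[cand < max(scores)]
  if (length(cand) == 0L) stop("no valid cutoff: scores do not vary")
  if (length(cand) > max_candidates) {
    cand <- unique(quantile(cand, seq(0, 1, length.out = max_candidates),
                            names = FALSE, type = 1))
  }
  n <- length(scores)
  best <- NULL
  for (cut in cand) {
    grp <- scores > cut
    if (min(sum(grp), sum(!grp)) < min_group_fraction * n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    if (is.null(best) || sd$chisq > best$chisq) {
      best <- list(cutoff = cut, chisq = sd$chisq,
                   p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
    }
  }
  if (is.null(best)) stop("no cutoff satisfies the minimum group size")
  best$n_candidates <- length(cand)
  best
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' @param time,event Survival outcome.
#' @param groups Group labels.
#' @return List with `fit` (a [survival::survfit] object), `logrank_chisq`
#'   and `logrank_p` (`NA` with a single group).
#' @export
km_logrank <- function(time, event, groups) {
  groups <- as.factor(groups)
  df <- data.frame(time = time, event = event, groups = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups, data = df)
  if (nlevels(droplevels(groups)) < 2L) {
    return(list(fit = fit, logrank_chisq = NA_real_, logrank_p = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups, data = df)
  list(fit = fit, logrank_chisq = sd$chisq,
       logrank_p = pchisq(sd$chisq, df = length(sd$n) - 1,
                          lower.tail = FALSE))
}

#' Multivariable Cox model with clinical adjustment
#'
#' Fits `Surv(time, event) ~ .` on the supplied terms (typically the
#' high/low risk-group indicator plus sex, age, T stage, N stage, vascular
#' cancer embolus and dissected lymph-node count). Exactly collinear
#' covariates are refused rather than silently dropped, and a warning is
#' raised when events fall below ten per model term (the 10-EPV rule of
#' thumb).
#'
#' @param terms Data.frame of model terms.
#' @param time,event Survival outcome.
#' @return A data.frame with one row per coefficient: `term`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`; the `coxph` fit is attached as attribute
#'   `"fit"`.
#' @export
multivariate_cox <- function(terms, time, event) {
  mm <- stats::model.matrix(~ ., data = terms)[, -1L, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) {
    stop("collinear covariates; refusing to drop terms silently")
  }
  if (sum(event) < 10 * ncol(mm)) {
    warning("fewer than 10 events per variable; estimates may be unstable")
  }
  df <- data.frame(time = time, event = event, mm, check.names = FALSE)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ .,
    data = df[, c("time", "event", colnames(mm))], ties = "efron")
  s <- summary(fit)
  out <- data.frame(
    term = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative-case / dynamic-control AUC at each horizon t: cases are
#' patients with an observed event by t, controls are patients still at risk
#' beyond t. Cases are weighted by `1 / G(T_i-)` and controls by `1 / G(t)`,
#' where G is the Kaplan-Meier estimate of the censoring distribution, which
#' corrects for censoring before the horizon.
#'
#' @param scores Risk scores (higher = riskier).
#' @param time,event Survival outcome.
#' @param horizons Evaluation times in days (default 365, 1095, 1825 for
#'   1/3/5 years).
#' @return A data.frame `horizon`, `auc`, `n_cases`, `n_controls`; horizons
#'   without cases or beyond follow-up yield `NA`.
#' @export
time_dependent_auc <- function(scores, time, event,
                               horizons = c(365, 1095, 1825)) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  # G(t-): left limit of the censoring survival at t
  G_minus <- function(t) vapply(t, function(ti) {
    keep <- cens_fit$time < ti
    if (!any(keep)) 1 else cens_fit$surv[max(which(keep))]
  }, numeric(1))
  out <- lapply(horizons, function(h) {
    case <- which(time <= h & event == 1)
    ctrl <- which(time > h)
    if (length(case) == 0L || length(ctrl) == 0L) {
      return(data.frame(horizon = h, auc = NA_real_,
                        n_cases = length(case), n_controls = length(ctrl)))
    }
    w_case <- 1 / G_minus(time[case])
    gh <- G(h)
    if (gh <= 0) {
      return(data.frame(horizon = h, auc = NA_real_,
                        n_cases = length(case), n_controls = length(ctrl)))
    }
    w_ctrl <- rep(1 / gh, length(ctrl))
    sc <- scores[case]; st <- scores[ctrl]
    num <- 0
    for (i in seq_along(case)) {
      num <- num + w_case[i] * sum(w_ctrl * ((sc[i] > st) + 0.5 * (sc[i] == st)))
    }
    auc <- num / (sum(w_case) * sum(w_ctrl))
    data.frame(horizon = h, auc = auc,
               n_cases = length(case), n_controls = length(ctrl))
  })
  do.call(rbind, out)
}

#' ROC coordinates at a fixed horizon
#'
#' Sensitivity/specificity pairs over all score thresholds for the
#' IPCW-weighted case/control sets at `horizon` (same definitions as
#' [time_dependent_auc()]).
#'
#' @inheritParams time_dependent_auc
#' @param horizon Single evaluation time.
#' @return A data.frame `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(scores, time, event, horizon) {
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  thr <- sort(unique(scores))
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[case] >= t), 1),
    specificity = vapply(thr, function(t) mean(scores[ctrl] < t), 1)
  )
}

#' Compare two scores' AUCs by DeLong's test
#'
#' A thin contract over [pROC::roc.test] for comparing the discrimination of
#' two risk scores against the same binary outcome (e.g. recurrence by a
#' horizon).
#'
#' @param scores1,scores2 Two score vectors.
#' @param outcome Binary outcome (1 = event).
#' @return List with `auc1`, `auc2`, `p`.
#' @export
delong_test <- function(scores1, scores2, outcome) {
  if (!requireNamespace("pROC", quietly = TRUE)) {
    stop("delong_test requires the pROC package")
  }
  r1 <- pROC::roc(outcome, scores1, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(outcome, scores2, quiet = TRUE, direction = "<")
  tst <- pROC::roc.test(r1, r2, method = "delong")
  list(auc1 = as.numeric(pROC::auc(r1)), auc2 = as.numeric(pROC::auc(r2)),
       p = tst$p.value)
}

#' Cohort-level survival summary
#'
#' Event percentage, Kaplan-Meier median disease-free survival, and 1/3/5
#' year recurrence rates (one minus the KM survival at 365/1095/1825 days).
#'
#' @param time,event Survival outcome.
#' @param horizons Recurrence-rate horizons in days.
#' @return List with `n`, `n_events`, `event_pct`, `median_dfs` and
#'   `recurrence_rates` (percent, named by horizon).
#' @export
cohort_summary <- function(time, event, horizons = c(365, 1095, 1825)) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  sv <- summary(fit, times = horizons, extend = TRUE)$surv
  list(n = length(time), n_events = sum(event),
       event_pct = 100 * sum(event) / length(time),
       median_dfs = med,
       recurrence_rates = setNames(100 * (1 - sv), horizons))
}

#' Build the IRRS model on a training cohort
#'
#' The full construction: (1) univariate Cox screening of all candidates at
#' `alpha`; (2) 10-fold cross-validated LASSO-Cox on the significant
#' candidates, keeping the variables with non-zero coefficients at the
#' deviance-minimising lambda; (3) weights set to the selected variables'
#' univariate log hazard ratios on the training cohort; (4) scores computed
#' and the optimal log-rank cutoff learned on the training cohort. The
#' returned model carries everything needed to score and dichotomise new
#' patients with the identical formula and cutoff.
#'
#' @param features Training-feature data.frame (proportion-scale values).
#' @param time,event Training outcome.
#' @param alpha Univariate screening gate (default 0.05).
#' @param nfolds LASSO cross-validation folds (default 10).
#' @param seed Integer seed (fold assignment and cutoff scan are the only
#'   stochastic steps).
#' @param min_group_fraction Minimum cutpoint group size (default 0.1).
#' @return An object of class `irrs_model`: list with `weights` (named
#'   ln(HR)), `cutoff`, `screen` (screening table), `lasso` (selection
#'   detail), `train_scores` and `provenance = "training"`.
#' @export
build_irrs_model <- function(features, time, event, alpha = 0.05,
                             nfolds = 10, seed = 1,
                             min_group_fraction = 0.1) {
  screen <- screen_candidates(features, time, event, alpha = alpha)
  cand <- screen$variable[screen$selected]
  if (length(cand) < 2L) {
    stop("fewer than 2 candidates pass univariate screening")
  }
  lasso <- lasso_cox_select(features[, cand, drop = FALSE], time, event,
                            nfolds = nfolds, seed = seed)
  sel <- lasso$selected
  if (length(sel) == 0L) stop("LASSO selected no variables")
  weights <- setNames(
    screen$log_hr[match(sel, screen$variable)], sel)
  scores <- compute_irrs(features, weights)
  cut <- optimal_cutoff(scores, time, event,
                        min_group_fraction = min_group_fraction)
  structure(
    list(weights = weights, cutoff = cut$cutoff,
         cutoff_chisq = cut$chisq, screen = screen, lasso = lasso,
         train_scores = scores, provenance = "training"),
    class = "irrs_model"
  )
}

#' Score and dichotomise patients with a fitted IRRS model
#'
#' Applies the identical score formula and training-derived cutoff to any
#' cohort (no re-optimisation).
#'
#' @param model An `irrs_model`.
#' @param features Feature data.frame.
#' @return A data.frame with `score` and `group` (`"high"` / `"low"`).
#' @export
apply_irrs <- function(model, features) {
  stopifnot(inherits(model, "irrs_model"))
  score <- compute_irrs(features, model)
  data.frame(score = score,
             group = ifelse(score > model$cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' @export
print.irrs_model <- function(x, ...) {
  cat("IRRS model (", length(x$weights), " variables, fit on ",
      x$provenance, " cohort)\n", sep = "")
  cat("  cutoff:", format(x$cutoff, digits = 4), "\n")
  w <- sort(x$weights, decreasing = TRUE)
  for (v in names(w)) {
    cat(sprintf("  %-24s ln(HR) = %+.3f\n", v, w[[v]]))
  }
  invisible(x)
}

#' Run the full IRRS construction and validation pipeline
#'
#' Stratified 70/30 split by event status, model construction on the
#' training cohort ([build_irrs_model()]), then validation of the frozen
#' score formula and cutoff on the training, testing and entire cohorts:
#' Kaplan-Meier/log-rank separation, covariate-adjusted Cox hazard ratio of
#' the high-IRRS group, and time-dependent AUC at 1/3/5 years.
#'
#' @param patients Data.frame with `time_days`, `event`, the candidate
#'   feature columns and optionally clinical covariates.
#' @param feature_cols Names of candidate feature columns.
#' @param covariate_cols Names of adjustment covariates (may be empty).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @param alpha,nfolds,min_group_fraction Passed to [build_irrs_model()].
#' @return List with `model`, `split`, and per-cohort `evaluation` (each:
#'   `logrank_p`, `hr_adjusted` table, `auc` table, group sizes).
#' @export
fit_irrs_pipeline <- function(patients, feature_cols, covariate_cols =
                                character(0), train_fraction = 0.7,
                              seed = 1, alpha = 0.05, nfolds = 10,
                              min_group_fraction = 0.1) {
  stopifnot(all(c("time_days", "event") %in% names(patients)))
  sp <- stratified_split(patients$event, train_fraction, seed = seed)
  train <- patients[sp$train, , drop = FALSE]
  model <- build_irrs_model(train[, feature_cols, drop = FALSE],
                            train$time_days, train$event,
                            alpha = alpha, nfolds = nfolds, seed = seed,
                            min_group_fraction = min_group_fraction)
  evaluate <- function(dat) {
    sc <- apply_irrs(model, dat[, feature_cols, drop = FALSE])
    grp <- factor(sc$group, levels = c("low", "high"))
    km <- km_logrank(dat$time_days, dat$event, grp)
    terms <- data.frame(irrs_group = grp)
    if (length(covariate_cols) > 0) {
      terms <- cbind(terms, dat[, covariate_cols, drop = FALSE])
    }
    hr <- tryCatch(multivariate_cox(terms, dat$time_days, dat$event),
                   error = function(e) NULL)
    auc <- time_dependent_auc(sc$score, dat$time_days, dat$event)
    list(scores = sc$score, group = grp, logrank_p = km$logrank_p,
         km = km$fit, hr_adjusted = hr, auc = auc,
         n = nrow(dat), n_high = sum(grp == "high"))
  }
  list(model = model, split = sp,
       evaluation = list(
         train = evaluate(train),
         test = evaluate(patients[sp$test, , drop = FALSE]),
         entire = evaluate(patients)
       ))
}
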