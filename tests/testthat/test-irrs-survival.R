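test_that("stratified splits hit the exact sizes and preserve event rates", {
  strata <- rep(0:1, c(313, 240))
  sp <- stratified_split(strata, seed = 1)
  expect_equal(length(sp$train), 387)
  expect_equal(length(sp$test), 166)
  expect_equal(sort(c(sp$train, sp$test)), 1:553)

  sp10 <- stratified_split(rep(1, 10), train_fraction = 0.7, seed = 2)
  expect_equal(length(sp10$train), 7)
  expect_equal(length(sp10$test), 3)

  # determinism and seed sensitivity
  expect_identical(stratified_split(strata, seed = 5),
                   stratified_split(strata, seed = 5))
  expect_false(identical(stratified_split(strata, seed = 5)$train,
                         stratified_split(strata, seed = 6)$train))

  # stratification: training event share close to the cohort share
  set.seed(30)
  ev <- rbinom(400, 1, 0.4)
  for (s in 1:25) {
    sp <- stratified_split(ev, seed = s)
    expect_lt(abs(mean(ev[sp$train]) - mean(ev)), 0.02)
  }
  expect_error(stratified_split(c(0, 1, 1, 1), seed = 1), "stratum")
})

test_that("univariate Cox recovers known effects and flags degenerate input", {
  gen <- function(n) data.frame(V1 = rbinom(n, 1, 0.5))
  co <- simulate_cohort(cohort_spec(n_patients = 2000,
                                    true_log_hr = c(V1 = log(2)),
                                    censoring_rate = 0.3, seed = 41), gen)
  fit <- univariate_cox(co$V1, co$time_days, co$event)
  expect_true(fit$ok)
  expect_lt(abs(fit$log_hr - log(2)), 0.15)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)

  const <- univariate_cox(rep(2, 100), co$time_days[1:100], co$event[1:100])
  expect_false(const$ok)

  # null-covariate CI coverage across seeded simulations
  hits <- 0
  for (s in 1:60) {
    con <- simulate_cohort(cohort_spec(n_patients = 300,
                                       censoring_rate = 0.3, seed = 100 + s))
    f <- univariate_cox(con$V1, con$time_days, con$event)
    if (f$ci_lower <= 1 && 1 <= f$ci_upper) hits <- hits + 1
  }
  expect_gte(hits, 53)  # ~95% coverage, allowing binomial noise
})

test_that("screening gates candidates at the univariate significance level", {
  beta <- c(V1 = 0.8, V2 = -0.8)
  co <- simulate_cohort(cohort_spec(n_patients = 600, true_log_hr = beta,
                                    censoring_rate = 0.3, seed = 51),
                        gaussian_feature_generator(6))
  sc <- screen_candidates(co[paste0("V", 1:6)], co$time_days, co$event)
  expect_true(all(c("V1", "V2") %in% sc$variable[sc$selected]))
  expect_true(all(sc$p[sc$selected] < 0.05))
})

test_that("lasso-cox selects true prognosticators and matches the
           unpenalised limit", {
  # the lambda = 0 limit equals unpenalised multivariable Cox coefficients
  beta <- c(V1 = 0.7, V2 = -0.5, V3 = 0.3)
  co <- simulate_cohort(cohort_spec(n_patients = 500, true_log_hr = beta,
                                    censoring_rate = 0.2, seed = 61),
                        gaussian_feature_generator(3))
  x <- as.matrix(co[paste0("V", 1:3)])
  y <- survival::Surv(co$time_days, co$event)
  gfit <- glmnet::glmnet(x, y, family = "cox", lambda = c(0.05, 0),
                         thresh = 1e-14)
  cox <- survival::coxph(y ~ x, ties = "breslow")
  expect_equal(as.numeric(coef(gfit, s = 0)), unname(coef(cox)),
               tolerance = 1e-3)

  # full-shrinkage limit selects nothing
  sel0 <- lasso_cox_select(x, co$time_days, co$event, seed = 1)
  path_top <- glmnet::glmnet(x, y, family = "cox",
                             lambda = max(sel0$lambda))
  expect_equal(sum(abs(coef(path_top))), 0)
})

test_that("IRRS scoring is the weighted proportion sum and is monotone", {
  expect_equal(compute_irrs(data.frame(a = 0.3), c(a = 0)), 0)
  expect_equal(compute_irrs(data.frame(a = 0.5), c(a = log(2))),
               0.5 * log(2))
  # linear in the feature vector
  w <- c(a = log(2), b = log(0.5))
  f <- data.frame(a = 0.4, b = 0.7)
  expect_equal(compute_irrs(2 * f, w), 2 * compute_irrs(f, w))
  # strictly increasing in a variable with HR > 1
  f2 <- f; f2$a <- f$a + 0.1
  expect_gt(compute_irrs(f2, w), compute_irrs(f, w))
  expect_error(compute_irrs(data.frame(a = 1), c(zz = 1)), "missing")
})

test_that("optimal cutoff recovers a true bimodal separation and transfers",
{
  set.seed(71)
  n <- 300
  grp <- rbinom(n, 1, 0.5)
  scores <- rnorm(n, mean = ifelse(grp == 1, 3, 0), sd = 0.5)
  time <- rexp(n, rate = ifelse(grp == 1, 3, 1) / 1000)
  event <- rep(1L, n)
  cut <- optimal_cutoff(scores, time, event)
  # the cutoff falls in the gap between the modes at 0 and 3: thresholding
  # at it recovers the true risk groups almost perfectly
  expect_gt(mean((scores > cut$cutoff) == (grp == 1)), 0.95)
  expect_lt(cut$p, 0.001)

  # two distinct score values: the unique valid cutoff sits between them
  s2 <- rep(c(1, 2), each = 150)
  cut2 <- optimal_cutoff(s2, time, event)
  expect_equal(cut2$cutoff, 1)

  # null scores: scan maximum stays modest (no spurious huge chi-square)
  null_scores <- rnorm(n)
  cutn <- optimal_cutoff(null_scores, time, event)
  expect_lt(cutn$chisq, 25)

  expect_error(optimal_cutoff(rep(1, 100), time[1:100], event[1:100]),
               "vary")
  expect_error(optimal_cutoff(scores[1:10], time[1:10], event[1:10]),
               "20 patients")
})

test_that("KM estimates and multivariable Cox behave as their closed forms",
{
  # no censoring: KM median equals the sample median
  set.seed(81)
  t0 <- rexp(201, 1 / 500)
  cs <- cohort_summary(t0, rep(1, 201))
  expect_equal(cs$median_dfs, median(t0))
  expect_equal(cs$event_pct, 100)

  # exponential closed form for the 1-year recurrence rate
  lam <- 1 / 1200
  tt <- rexp(5000, lam)
  cs2 <- cohort_summary(tt, rep(1, 5000))
  p1 <- 1 - exp(-365 * lam)
  expect_lt(abs(cs2$recurrence_rates[["365"]] / 100 - p1),
            3 * sqrt(p1 * (1 - p1) / 5000))

  # group hazard ratio recovery through km_logrank + coxph
  gen <- function(n) data.frame(V1 = rbinom(n, 1, 0.5))
  co <- simulate_cohort(cohort_spec(n_patients = 550,
                                    true_log_hr = c(V1 = log(2.7)),
                                    censoring_rate = 0.3, seed = 82), gen)
  km <- km_logrank(co$time_days, co$event, co$V1)
  expect_lt(km$logrank_p, 1e-6)
  mv <- multivariate_cox(data.frame(V1 = co$V1), co$time_days, co$event)
  expect_lt(abs(mv$hr[1] - 2.7) / 2.7, 0.25)

  # adjusted score-HR is close to unadjusted when covariates are independent
  co2 <- cbind(co, noise1 = rnorm(550), noise2 = rnorm(550))
  mv2 <- multivariate_cox(co2[, c("V1", "noise1", "noise2")],
                          co2$time_days, co2$event)
  expect_lt(abs(log(mv2$hr[mv2$term == "V1"]) - log(mv$hr[1])), 0.1)

  # exact collinearity is refused
  expect_error(
    multivariate_cox(data.frame(a = co$V1, b = co$V1 * 2),
                     co$time_days, co$event),
    "collinear")

  # single group: curves only
  one <- km_logrank(co$time_days, co$event, rep("all", 550))
  expect_true(is.na(one$logrank_p))
})

test_that("time-dependent AUC hits its forced limits and anti-symmetry", {
  set.seed(91)
  n <- 400
  time <- rexp(n, 1 / 800)
  event <- rbinom(n, 1, 0.8)
  # a score equal to the event-by-horizon indicator is a perfect marker
  h <- 365
  perfect <- as.numeric(time <= h & event == 1)
  auc <- time_dependent_auc(perfect, time, event, horizons = h)
  expect_equal(auc$auc, 1)

  # anti-symmetry under score negation
  sc <- rnorm(n)
  a1 <- time_dependent_auc(sc, time, event, horizons = c(180, 365))
  a2 <- time_dependent_auc(-sc, time, event, horizons = c(180, 365))
  expect_equal(a2$auc, 1 - a1$auc, tolerance = 1e-12)

  # horizon beyond follow-up flagged missing
  far <- time_dependent_auc(sc, time, event, horizons = max(time) + 1)
  expect_true(is.na(far$auc))
})

test_that("the assembled pipeline transfers one frozen cutoff to validation",
{
  set.seed(101)
  p <- 12
  beta <- setNames(c(0.7, -0.7, 0.8, rep(0, p - 3)), paste0("V", 1:p))
  co <- simulate_cohort(cohort_spec(n_patients = 300,
                                    true_log_hr = beta[beta != 0],
                                    censoring_rate = 0.4, seed = 102),
                        gaussian_feature_generator(p))
  pipe <- fit_irrs_pipeline(co, paste0("V", 1:p), seed = 5, nfolds = 5)
  model <- pipe$model
  # cutoff transfer: test groups are derived from the training cutoff
  test_rows <- co[pipe$split$test, ]
  reapplied <- apply_irrs(model, test_rows[paste0("V", 1:p)])
  expect_identical(as.character(pipe$evaluation$test$group),
                   reapplied$group)
  expect_true(model$cutoff >= min(model$train_scores) &&
                model$cutoff <= max(model$train_scores))
  # weights are the training univariate log-HRs of the selected variables
  sc <- model$screen
  expect_equal(unname(model$weights),
               sc$log_hr[match(names(model$weights), sc$variable)])
  expect_lt(pipe$evaluation$train$logrank_p, 0.01)
})
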