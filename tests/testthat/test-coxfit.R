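test_that("full-cohort fit matches survival::coxph coefficients and SEs", {
  library(survival)
  set.seed(101)
  for (ties in c("breslow", "efron")) {
    d <- random_survival_data(80, 3)
    f1 <- fit_cox(d, c("x1", "x2", "x3"), risk_rule = "full_cohort",
                  ties = ties)
    f2 <- coxph(Surv(time, event) ~ x1 + x2 + x3, data = d, ties = ties,
                robust = TRUE)
    expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-8)
    expect_equal(unname(f1$se_robust), unname(sqrt(diag(vcov(f2)))),
                 tolerance = 1e-7)
    expect_equal(unname(f1$se_naive),
                 unname(sqrt(diag(f2$naive.var))), tolerance = 1e-7)
    expect_equal(f1$loglik, unname(f2$loglik[2]), tolerance = 1e-8)
  }
})

test_that("delayed entry matches coxph counting-process form", {
  library(survival)
  set.seed(102)
  d <- random_survival_data(70, 2)
  d$entry <- runif(70, 0, d$time * 0.8)
  f1 <- fit_cox(d, c("x1", "x2"), risk_rule = "full_cohort")
  f2 <- coxph(Surv(entry, time, event) ~ x1 + x2, data = d,
              ties = "breslow")
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-8)
})

test_that("Prentice rule uses only subcohort risk sets plus the case", {
  set.seed(103)
  d <- random_survival_data(60, 1)
  d$in_subcohort <- c(rep(TRUE, 40), rep(FALSE, 20))
  d <- d[d$in_subcohort | d$event == 1, ]
  fit <- fit_cox(d, "x1", risk_rule = "prentice")
  # manual pseudo-partial likelihood at the fitted beta
  b <- unname(coef(fit))
  eta <- d$x1 * b
  ll <- 0
  for (i in which(d$event == 1)) {
    rs <- (d$in_subcohort & d$time >= d$time[i]) | seq_len(nrow(d)) == i
    ll <- ll + eta[i] - log(sum(exp(eta[rs])))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
  # and its score is zero at the maximum
  num <- sapply(which(d$event == 1), function(i) {
    rs <- (d$in_subcohort & d$time >= d$time[i]) | seq_len(nrow(d)) == i
    d$x1[i] - sum(d$x1[rs] * exp(eta[rs])) / sum(exp(eta[rs]))
  })
  expect_lt(abs(sum(num)), 1e-7)
})

test_that("factors, missing data and constant columns are handled", {
  set.seed(104)
  d <- random_survival_data(90, 1)
  d$grp <- factor(sample(c("a", "b", "c"), 90, replace = TRUE))
  d$x1[1:5] <- NA
  fit <- fit_cox(d, c("x1", "grp"), risk_rule = "full_cohort")
  expect_equal(fit$n_dropped_incomplete, 5L)
  expect_equal(fit$n, 85L)
  expect_equal(fit$term_names, c("x1", "grpb", "grpc"))
  d$flat <- 1
  expect_error(fit_cox(d, "flat", risk_rule = "full_cohort"),
               "constant covariate")
  expect_error(fit_cox(d, "nope", risk_rule = "full_cohort"), "not found")
})

test_that("separation is reported instead of silently diverging", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 1, 0, 0, 0),
                  x = c(1, 1, 1, 0, 0, 0))
  # the likelihood is monotone in beta; with the convergence criteria
  # disabled the optimizer must hit the divergence guard, not loop forever
  fit <- fit_cox(d, "x", risk_rule = "full_cohort",
                 control = cox_control(eps_score = 0, eps_loglik = 0))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|diverging|iterations")
})

test_that("linear predictor reproduces the design times coefficients", {
  set.seed(105)
  d <- random_survival_data(50, 2)
  d$grp <- factor(sample(c("a", "b"), 50, replace = TRUE))
  fit <- fit_cox(d, c("x1", "grp"), risk_rule = "full_cohort")
  lp <- linear_predictor(fit, d)
  manual <- d$x1 * fit$beta[["x1"]] +
    (d$grp == "b") * fit$beta[["grpb"]]
  expect_equal(lp, unname(manual), tolerance = 1e-12)
  expect_error(linear_predictor(fit, d[, "time", drop = FALSE]),
               "lacks term")
})

test_that("proportional-hazards test agrees with survival::cox.zph", {
  library(survival)
  set.seed(106)
  d <- random_survival_data(150, 2)
  f1 <- fit_cox(d, c("x1", "x2"), risk_rule = "full_cohort")
  f2 <- coxph(Surv(time, event) ~ x1 + x2, data = d, ties = "breslow")
  z1 <- schoenfeld_ph_test(f1, transform = "identity")
  # exact check of the documented pooled-variance statistic, recomputed
  # here from first principles
  r <- f1$schoenfeld
  g <- f1$schoenfeld_time - mean(f1$schoenfeld_time)
  u <- colSums(g * r)
  nev <- nrow(r)
  manual_global <- nev / sum(g^2) * drop(t(u) %*% solve(f1$info) %*% u)
  expect_equal(z1$chisq[3], manual_global, tolerance = 1e-10)
  expect_equal(z1$chisq[1], nev * u[[1]]^2 / (sum(g^2) * f1$info[1, 1]),
               tolerance = 1e-10)
  # survival >= 3 computes the exact per-event variance instead of the
  # classic pooled approximation; agreement is approximate by construction
  z2 <- cox.zph(f2, transform = "identity", global = TRUE)
  expect_equal(z1$chisq, unname(z2$table[, "chisq"]), tolerance = 0.15)
  expect_equal(z1$p, unname(z2$table[, "p"]), tolerance = 0.35)
  z1r <- schoenfeld_ph_test(f1, transform = "rank")
  z2r <- cox.zph(f2, transform = "rank", global = TRUE)
  expect_equal(z1r$chisq, unname(z2r$table[, "chisq"]), tolerance = 0.2)
})

test_that("fit serializes to JSON", {
  set.seed(107)
  d <- random_survival_data(40, 1)
  fit <- fit_cox(d, "x1", risk_rule = "full_cohort")
  f <- tempfile(fileext = ".json")
  write_fit_json(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$beta, unname(coef(fit)), tolerance = 1e-12)
  expect_true(back$converged)
  unlink(f)
})
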