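test_that("Kaplan-Meier estimate reduces to known closed forms", {
  # one event at t=1 (n=3 at risk), censor at 2, event at 3 (n=1 at risk)
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3, 1))

  # no censoring: S equals the empirical survivor function
  times <- c(5, 1, 3, 2, 4)
  km2 <- km_estimate(times, rep(1, 5))
  expect_equal(km2$surv, 1 - rank(sort(times)) / 5, ignore_attr = TRUE)

  # all censored: no event times, S stays at 1
  km3 <- km_estimate(1:4, rep(0, 4))
  expect_length(km3$time, 0)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("median split uses the >= median rule", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(attr(s, "cutoff"), 2.5)
  expect_identical(as.character(s), c("low", "low", "high", "high"))
  s3 <- median_split(c(1, 2, 3))
  expect_identical(as.character(s3), c("low", "high", "high"))
  expect_warning(flat <- median_split(c(2, 2)), "identical")
  expect_identical(as.character(flat), c("high", "high"))
})

test_that("log-rank test matches a hand-built risk table and survdiff", {
  # 6 subjects, two groups; hand-computed O-E/V table:
  # events at t=1 (A), t=2 (B), t=4 (A); censor at t=3 (B), t=5 (both)
  times <- c(1, 4, 5, 2, 3, 5)
  events <- c(1, 1, 0, 1, 0, 0)
  groups <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(times, events, groups)
  # t=1: n=6, nA=3, d=1, dA=1 -> E += 1/2,  V += (1/2)(1/2)(5/5)
  # t=2: n=5, nA=2, d=1, dA=0 -> E += 2/5,  V += (2/5)(3/5)(4/4)
  # t=4: n=3, nA=2, d=1, dA=1 -> E += 2/3,  V += (2/3)(1/3)(2/2)
  O <- 2; E <- 1 / 2 + 2 / 5 + 2 / 3
  V <- 1 / 4 + 6 / 25 + 2 / 9
  expect_equal(lr$observed, O)
  expect_equal(lr$expected, E)
  expect_equal(lr$chi_square, (O - E)^2 / V)
  ref <- survival::survdiff(survival::Surv(times, events) ~ groups)
  expect_equal(lr$chi_square, ref$chisq, tolerance = 1e-12)

  same <- logrank_test(rep(times[1:3], 2), rep(events[1:3], 2),
                       rep(c("A", "B"), each = 3))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p, 1)
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("A", 3)), "2")
})

test_that("cox_fit reports coherent coefficients, HRs, CIs and Wald p", {
  x <- withr::with_seed(81, cbind(biomarker = rnorm(300),
                                  male = rbinom(300, 1, 0.5)))
  surv <- simulate_survival(300, covariates = x, coefs = c(0.8, -0.3),
                            seed = 81)
  fit <- cox_fit(x, surv$time, surv$event)
  expect_identical(fit$term, c("biomarker", "male"))
  expect_equal(fit$hazard_ratio, exp(fit$coefficient))
  expect_equal(fit$ci_low, exp(fit$coefficient - 1.96 * fit$se))
  expect_equal(fit$ci_high, exp(fit$coefficient + 1.96 * fit$se))
  expect_true(all(fit$ci_low < fit$hazard_ratio &
                    fit$hazard_ratio < fit$ci_high))
  ref <- survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                         ties = "breslow")
  expect_equal(fit$coefficient, unname(coef(ref)), tolerance = 1e-8)

  expect_error(cox_fit(cbind(k = rep(1, 10)), 1:10, rep(1, 10)),
               "constant")
  expect_error(cox_fit(cbind(a = rnorm(10), b = rnorm(10)), 1:10,
                       c(1, rep(0, 9))), "events")
})

test_that("cox score test at beta = 0 equals the log-rank statistic", {
  for (s in 1:4) {
    surv <- simulate_survival(40, seed = 90 + s, censor_rate = 0.02)
    grp <- withr::with_seed(90 + s, rbinom(40, 1, 0.5))
    if (length(unique(grp)) < 2) next
    fit <- cox_fit(cbind(g = grp), surv$time, surv$event)
    lr <- logrank_test(surv$time, surv$event, grp)
    expect_equal(attr(fit, "score"), lr$chi_square, tolerance = 1e-8)
  }
})

test_that("risk model stratifies samples at the median linear predictor", {
  sim <- simulate_expression(n_genes = 20, n_case = 15, n_control = 15,
                             n_up = 0, n_down = 0, seed = 87)
  coefs <- c(g01 = 1)
  rm1 <- risk_model(coefs, sim$matrix)
  expect_equal(unname(rm1$score), unname(sim$matrix$values["g01", ]))
  expect_equal(rm1$cutoff, median(rm1$score))
  expect_identical(as.character(rm1$group),
                   unname(ifelse(rm1$score >= rm1$cutoff, "high", "low")))
  expect_lte(abs(sum(rm1$group == "high") - sum(rm1$group == "low")), 1)
  expect_error(risk_model(c(nope = 1), sim$matrix), "nope")
  expect_warning(risk_model(c(g01 = 0), sim$matrix), "degenerate")

  # planted hazard: high-risk group has worse survival
  expr <- withr::with_seed(88, matrix(rnorm(2 * 500), 2, 500,
                                      dimnames = list(c("gA", "gB"),
                                                      paste0("s", 1:500))))
  surv <- simulate_survival(500, covariates = t(expr), coefs = c(1, -0.5),
                            censor_rate = 0.02, seed = 88)
  rm2 <- risk_model(c(gA = 1, gB = -0.5), expr, surv$time, surv$event)
  expect_lt(rm2$logrank$p, 0.05)
  km_high <- km_estimate(surv$time[rm2$group == "high"],
                         surv$event[rm2$group == "high"])
  km_low <- km_estimate(surv$time[rm2$group == "low"],
                        surv$event[rm2$group == "low"])
  median_surv <- function(km) km$time[which(km$surv <= 0.5)[1]]
  expect_lt(median_surv(km_high), median_surv(km_low))
})

test_that("univariate screen flags planted prognostic genes", {
  hits <- vapply(1:100, function(i) {
    expr <- withr::with_seed(200 + i,
                             matrix(rnorm(200), 1, 200,
                                    dimnames = list("gene1",
                                                    paste0("s", 1:200))))
    surv <- simulate_survival(200, covariates = t(expr), coefs = 1,
                              censor_rate = 0.02, seed = 200 + i)
    x <- expression_matrix(rbind(expr),
                           rep(c("case", "control"), each = 100))
    screen <- prognostic_screen(x, surv$time, surv$event)
    screen$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
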