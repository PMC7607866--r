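test_that("percent_reduction is exact, scale-invariant, and guarded", {
  expect_equal(percent_reduction(c(5, 5), c(5, 5)), 0)
  expect_equal(percent_reduction(c(10, 10), c(3, 3)), 70)
  expect_equal(percent_reduction(c(4, 6), c(0, 0)), 100)
  # the planted ISS stage pattern at zero noise
  expect_equal(percent_reduction(100, 75), 25)
  expect_equal(percent_reduction(100, 69), 31)
  set.seed(60)
  x <- rgamma(10, 5); y <- rgamma(8, 3)
  expect_equal(percent_reduction(x, y), percent_reduction(7 * x, 7 * y),
               tolerance = 1e-12)
  expect_error(percent_reduction(c(0, 0), c(1, 2)), "reference mean")
})

test_that("condition comparison matches exact Mann-Whitney enumeration", {
  # identical distributions: reduction 0 and p near 1
  st <- data.frame(condition = rep(c("NPC", "NDMM"), each = 4),
                   hmc_percent = rep(c(1, 2, 3, 4), 2),
                   mc_percent = rep(c(1, 2, 3, 4), 2))
  r <- suppressWarnings(compare_conditions(st, "hmc"))
  expect_equal(r$reduction, 0)
  expect_gt(r$p, 0.8)

  # toy 2 vs 2 with known ranks: exact enumeration oracle
  set.seed(61)
  for (i in 1:20) {
    x <- round(runif(4), 6); y <- round(runif(4) + runif(1), 6)
    st2 <- data.frame(condition = rep(c("NPC", "NDMM"), each = 4),
                      hmc_percent = c(x, y), mc_percent = 1)
    r2 <- compare_conditions(st2, "hmc")
    expect_equal(r2$p, oracle_mw_p(x, y), tolerance = 1e-9)
  }

  # missing values dropped with a notice
  st$hmc_percent[1] <- NA
  expect_message(suppressWarnings(compare_conditions(st, "hmc")), "missing")
})

test_that("the planted cohort reductions are recovered", {
  # across clinical-only simulations: planted 69% (5hmC) / 34% (5mC)
  red <- vapply(1:20, function(s) {
    st <- simulate_sample_table(cohort_config(seed = s))
    suppressMessages(c(compare_conditions(st, "hmc")$reduction,
                       compare_conditions(st, "mc")$reduction))
  }, c(0, 0))
  expect_lt(abs(mean(red[1, ]) - 69), 8)
  expect_lt(abs(mean(red[2, ]) - 34), 8)
})

test_that("ISS trend recovers the planted stage gradient", {
  st <- simulate_sample_table(cohort_config(seed = 2, noise_cv = 1e-6))
  tr <- iss_trend(st, "hmc")
  # at (near) zero noise the planted 25% / 31% pattern is exact
  expect_equal(tr$reduction_I_vs_II, 25, tolerance = 0.1)
  expect_equal(tr$reduction_I_vs_III, 31, tolerance = 0.1)
  expect_lt(tr$p_I_vs_II, 0.05)
  # 5mC has no stage effect
  tm <- iss_trend(st, "mc")
  expect_lt(abs(tm$reduction_I_vs_III), 2)
  st2 <- st[!(st$iss %in% "II"), ]
  expect_error(iss_trend(st2, "hmc"), "stage")
})

test_that("covariate associations behave as designed", {
  st <- simulate_sample_table(cohort_config(seed = 3))
  a <- covariate_association(st, "hmc", "age")
  expect_true(abs(a$statistic) <= 1)
  # a perfectly age-correlated analyte gives r = 1
  st3 <- st
  st3$hmc_percent <- st3$age * 0.001
  expect_equal(covariate_association(st3, "hmc", "age")$statistic, 1,
               tolerance = 1e-12)
  s <- covariate_association(st, "hmc", "sex")
  expect_true(s$p >= 0 && s$p <= 1)
  st4 <- st; st4$sex <- "F"
  expect_error(covariate_association(st4, "hmc", "sex"), "constant")
})

test_that("median split gives 20/19 and sane Cox output on the cohort", {
  st <- simulate_sample_table(cohort_config(seed = 4))
  r <- dichotomized_survival(st, "hmc")
  expect_equal(r$n_low, 20)
  expect_equal(r$n_high, 19)
  expect_true(r$ci_low <= r$hr && r$hr <= r$ci_high)
  expect_equal(r$n_low + r$n_high, 39)
})

test_that("KM with no censoring equals the empirical survival exactly", {
  t_ev <- c(3, 7, 1, 12, 9, 5, 20, 15)
  st <- data.frame(condition = "NDMM",
                   hmc_percent = c(1, 2, 3, 4, 11, 12, 13, 14),
                   os_months = t_ev, os_event = 1)
  r <- dichotomized_survival(st, "hmc")
  km_low <- r$km[r$km$group == "low", ]
  emp <- vapply(km_low$time, function(tt) mean(t_ev[1:4] > tt), 0)
  expect_equal(km_low$survival, emp)
})

test_that("Cox HR for swapped groups is the reciprocal, and toy HR is exact", {
  set.seed(62)
  n <- 30    # even n: a value flip swaps the two groups exactly
  st <- data.frame(condition = "NDMM", hmc_percent = runif(n),
                   os_months = rexp(n, 0.05), os_event = rbinom(n, 1, 0.7))
  r <- dichotomized_survival(st, "hmc")
  st_sw <- st
  st_sw$hmc_percent <- 2 - st$hmc_percent   # reverses low/high membership
  r_sw <- dichotomized_survival(st_sw, "hmc")
  expect_equal(r_sw$hr, 1 / r$hr, tolerance = 1e-6)

  # 4 subjects, one event: closed-form two-group partial likelihood
  # event in group low at t = 1 with risk set {low, low, high, high}:
  # L(b) = e^b / (2 e^b + 2), maximized at b -> boundary unless another event
  st4 <- data.frame(condition = "NDMM", hmc_percent = c(1, 2, 10, 11),
                    os_months = c(1, 8, 5, 9), os_event = c(1, 0, 1, 0))
  r4 <- dichotomized_survival(st4, "hmc")
  # two events: low at t=1 (risk set 2 low + 2 high), high at t=5
  # (risk set 1 low + 2 high); score equation solved by hand:
  # L(b)= [e^b/(2e^b+2)] * [1/(e^b+2)]; dl/db = 0 -> 1 - 2e^b/(2e^b+2)
  #   - e^b/(e^b+2) = 0 -> e^{2b} + ... solved numerically here as oracle
  f <- function(b) 1 - 2 * exp(b) / (2 * exp(b) + 2) -
    exp(b) / (exp(b) + 2)
  b_hat <- uniroot(f, c(-5, 5))$root
  expect_equal(log(r4$hr), b_hat, tolerance = 1e-4)
})

test_that("a zero-event group is flagged unstable", {
  st <- data.frame(condition = "NDMM", hmc_percent = c(1, 2, 3, 10, 11, 12),
                   os_months = c(1, 2, 3, 50, 50, 50),
                   os_event = c(1, 1, 1, 0, 0, 0))
  r <- dichotomized_survival(st, "hmc")
  expect_true(r$unstable)
})
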