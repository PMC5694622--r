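test_that("VUS anchors: perfect separation gives 1, total ties give 1/6", {
  x <- full_data(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
  expect_identical(vus_point(x$dmat, x$test), 1)
  x_tied <- full_data(rep(2.5, 12), rep(1:3, 4))
  expect_equal(vus_point(x_tied$dmat, x_tied$test), 1 / 6,
               tolerance = 1e-15)
})

test_that("the fast kernel equals the brute-force triple sum", {
  set.seed(2024)
  for (trial in 1:60) {
    n <- sample(10:60, 1)
    t <- if (trial %% 2 == 0) {
      sample(1:8, n, replace = TRUE)        # heavy ties
    } else {
      rnorm(n)                               # continuous
    }
    d <- matrix(rexp(3 * n), n, 3)           # arbitrary nonneg weights
    if (trial %% 3 == 0) d[sample(n, 2), ] <- 0
    expect_equal(vus_point(d, t), brute_vus(t, d), tolerance = 1e-12)
  }
})

test_that("VUS equals the concordant-triple fraction on distinct data", {
  set.seed(7)
  t <- sample(seq(0, 1, length.out = 60))
  cls <- rep(1:3, each = 20)
  x <- full_data(t, cls)
  conc <- 0
  for (i in which(cls == 1)) for (j in which(cls == 2))
    for (l in which(cls == 3))
      conc <- conc + (t[i] < t[j] && t[j] < t[l])
  expect_equal(vus_point(x$dmat, x$test), conc / (20^3))
})

test_that("VUS is invariant to monotone transforms and permutations", {
  set.seed(5)
  t <- sample(1:10, 40, replace = TRUE)
  d <- matrix(runif(120), 40, 3)
  v0 <- vus_point(d, t)
  expect_identical(vus_point(d, exp(t)), v0)
  expect_identical(vus_point(d, qlogis(t / 11)), v0)
  p <- sample(40)
  expect_equal(vus_point(d[p, ], t[p]), v0, tolerance = 1e-14)
})

test_that("a useless test yields VUS near 1/6 on average", {
  set.seed(31)
  vals <- replicate(300, {
    cls <- sample(1:3, 30, replace = TRUE, prob = c(0.4, 0.35, 0.25))
    if (any(tabulate(cls, 3) == 0)) return(NA_real_)
    vus_point(diag(3)[cls, ], rnorm(30))  # test independent of class
  })
  vals <- vals[!is.na(vals)]
  expect_lt(abs(mean(vals) - 1 / 6), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("zero estimated class mass is an error", {
  d <- matrix(1, 5, 3)
  d[, 2] <- 0
  expect_error(vus_point(d, 1:5), "class 2")
})

test_that("confidence intervals reproduce the published FI row", {
  ci_l <- vus_ci(0.5150, 0.0404, 0.95, "logit")
  expect_equal(unname(ci_l), c(0.4360, 0.5932), tolerance = 2e-4)
  ci_n <- vus_ci(0.5150, 0.0404, 0.95, "normal")
  expect_equal(unname(ci_n), c(0.4358, 0.5942), tolerance = 2e-4)
  # zero-width interval collapses to the estimate on both scales
  expect_equal(unname(vus_ci(0.3, 0, 0.9, "normal")), c(0.3, 0.3))
  expect_equal(unname(vus_ci(0.3, 0, 0.9, "logit")), c(0.3, 0.3))
  expect_error(vus_ci(1.2, 0.1, 0.95, "logit"), "inside")
  # logit bounds always stay inside (0, 1)
  ci_big <- vus_ci(0.9, 0.5, 0.99, "logit")
  expect_true(all(ci_big > 0 & ci_big < 1))
})

test_that("the useless-test statistic matches its definition and Table row", {
  null_case <- vus_test(1 / 6, 0.01)
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p.value, 0.5)
  fi <- vus_test(0.5150, 0.0404^2)
  expect_equal(fi$statistic, 8.6168, tolerance = 1e-3)
  expect_lt(fi$p.value, 1e-4)
  spe <- vus_test(0.5581, 0.0443^2)
  expect_equal(spe$statistic, 8.8270, tolerance = 1e-2)
  expect_error(vus_test(0.5, 0), "positive")
})

test_that("jackknife variance matches the sampling variance on full data", {
  cfg <- sim_config(verif_coef = c(100, 0, 0))  # everyone verified
  ests <- ses <- numeric(60)
  for (r in 1:60) {
    x <- sim_prepared(300, cfg, seed = 52000 + r)
    dh <- disease_hat(x, "full")
    ests[r] <- vus_point(dh, x$test)
    ses[r] <- sqrt(vus_variance_jackknife(dh, x$test))
  }
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.25)
  x <- sim_prepared(5, cfg, seed = 1)
  expect_error(vus_variance_jackknife(x$dmat, x$test), "at least 10")
})

test_that("jackknife and bootstrap agree for the full-data estimator", {
  cfg <- sim_config(verif_coef = c(100, 0, 0))
  x <- sim_prepared(300, cfg, seed = 99)
  dh <- disease_hat(x, "full")
  jse <- sqrt(vus_variance_jackknife(dh, x$test))
  bse <- sqrt(vus_variance_bootstrap(x, "full", B = 200, seed = 4))
  expect_lt(abs(jse - bse) / bse, 0.25)
})

test_that("bootstrap is seed-reproducible and worker-invariant", {
  x <- sim_prepared(150, seed = 61)
  v1 <- vus_variance_bootstrap(x, "fi", B = 20, seed = 5, workers = 1)
  v2 <- vus_variance_bootstrap(x, "fi", B = 20, seed = 5, workers = 2)
  expect_equal(as.numeric(v1), as.numeric(v2))
  expect_identical(attr(v1, "replicates"), attr(v2, "replicates"))
  v3 <- vus_variance_bootstrap(x, "fi", B = 20, seed = 6)
  expect_false(identical(as.numeric(v1), as.numeric(v3)))
  expect_error(vus_variance_bootstrap(x, "fi", B = 1, seed = 1),
               "at least 2")
})

test_that("vus() composes the pieces and is deterministic", {
  cfg <- sim_config(verif_coef = c(100, 0, 0))
  x <- sim_prepared(120, cfg, seed = 71)
  r <- vus(x, "full")
  expect_equal(r$estimate, vus_point(x$dmat, x$test))
  expect_equal(r$variance, vus_variance_jackknife(x$dmat, x$test))
  expect_equal(r$t_stat, (r$estimate - 1 / 6) / r$se)
  expect_equal(r$p_value, pnorm(r$t_stat, lower.tail = FALSE))
  expect_true(r$ci_logit[1] > 0 && r$ci_logit[2] < 1)

  x2 <- sim_prepared(200, seed = 81)
  a <- vus(x2, "spe", variance = "bootstrap", B = 25, seed = 3)
  b <- vus(x2, "spe", variance = "bootstrap", B = 25, seed = 3)
  expect_identical(a, b)
})

test_that("all corrected estimators recover the truth at moderate n", {
  tv <- true_vus(m = 2e5, seed = 12345)$value
  x <- sim_prepared(1000, seed = 314)
  # tolerance = 3 x the Monte-Carlo sd of each estimator at n = 1000
  # (fi/msi ~ 0.026; ipw/spe are weight-inflated, ~ 0.075)
  tol <- c(fi = 0.08, msi = 0.08, ipw = 0.22, spe = 0.22)
  for (m in names(tol)) {
    est <- vus(x, m)$estimate
    expect_lt(abs(est - tv), tol[[m]])
  }
})
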