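test_that("intercept-only verification model recovers the sample rate", {
  set.seed(2)
  d <- data.frame(T = rnorm(100), V = rep(c(1L, 0L), c(60, 40)))
  d$D <- ifelse(d$V == 1, rep(1:3, length.out = 100), NA)
  x <- prepare_roc3(d, "T", "D", "V")
  pf <- fit_verification(x, predictors = character(0))
  expect_equal(pf$pi, rep(0.6, 100), tolerance = 1e-8)
})

test_that("verification model recovers the generating coefficients", {
  x <- sim_prepared(20000, seed = 42)
  pf <- fit_verification(x)
  est <- unname(coef(pf$fit))
  se <- unname(sqrt(diag(vcov(pf$fit))))
  expect_true(all(abs(est - c(1, -2.2, 4)) < 3 * se))
  expect_true(all(pf$pi > 0 & pf$pi <= 1))
})

test_that("probit and threshold links give close but distinct fits", {
  x <- sim_prepared(2000, seed = 8)
  p_logit <- fit_verification(x, link = "logit")$pi
  p_probit <- fit_verification(x, link = "probit")$pi
  p_thresh <- fit_verification(x, link = "threshold")$pi
  expect_gt(cor(p_logit, p_probit), 0.99)
  expect_false(identical(p_logit, p_probit))
  expect_false(identical(p_logit, p_thresh))
  expect_error(fit_verification(x, link = "cauchit"))
})

test_that("perfect separation is reported with the offending predictor", {
  d <- data.frame(T = c(rnorm(50, 0), rnorm(50, 30)),
                  V = rep(c(0L, 1L), each = 50))
  d$D <- ifelse(d$V == 1, rep(1:3, length.out = 100), NA)
  x <- prepare_roc3(d, "T", "D", "V")
  expect_error(fit_verification(x, predictors = "T"), "separation.*T")
})

test_that("intercept-only multinomial fit gives class proportions", {
  set.seed(3)
  d <- data.frame(T = rnorm(100),
                  D = rep(1:3, c(40, 35, 25))[sample(100)], V = 1L)
  x <- prepare_roc3(d, "T", "D", "V", class_order = 1:3)
  rho <- fit_rho_mlogit(x, predictors = character(0))
  expect_equal(rho$rho,
               matrix(rep(c(0.40, 0.35, 0.25), each = 100), 100, 3,
                      dimnames = list(NULL, paste0("rho", 1:3))),
               tolerance = 1e-4)
})

test_that("multinomial rho rows sum to one and track the Bayes posterior", {
  x <- sim_prepared(20000, seed = 13)
  rho <- fit_rho_mlogit(x)
  expect_equal(rowSums(rho$rho), rep(1, x$n), tolerance = 1e-8)
  truth <- bayes_rho(x$frame$T, x$frame$A)
  expect_lt(mean(abs(rho$rho - truth)), 0.05)
})

test_that("multinomial fit requires every class among verified subjects", {
  d <- simulate_roc3(200, seed = 3)
  d$V[d$D_true == 3] <- 0L
  d$D[d$V == 0] <- NA
  expect_error(prepare_roc3(d, "T", "D", "V", "A"), "three distinct")
})

test_that("pi and rho are invariant to affine predictor rescaling", {
  x <- sim_prepared(800, seed = 21)
  x_scaled <- x
  x_scaled$frame$A <- 100 * x$frame$A - 7
  expect_equal(fit_verification(x)$pi, fit_verification(x_scaled)$pi,
               tolerance = 1e-6)
  expect_equal(fit_rho_mlogit(x)$rho, fit_rho_mlogit(x_scaled)$rho,
               tolerance = 1e-5)
  expect_equal(fit_rho_knn(x, k = 7)$rho, fit_rho_knn(x_scaled, k = 7)$rho)
})

test_that("KNN disease probabilities match an exhaustive-search oracle", {
  x <- sim_prepared(30, seed = 6)
  k <- 3
  rho <- fit_rho_knn(x, k = k)$rho
  ver <- which(x$verified == 1L)
  X <- as.matrix(x$frame)
  ctr <- colMeans(X[ver, , drop = FALSE])
  scl <- apply(X[ver, , drop = FALSE], 2, sd)
  Xs <- scale(X, ctr, scl)
  for (i in seq_len(x$n)) {
    d2 <- rowSums((Xs[ver, , drop = FALSE] -
                     matrix(Xs[i, ], length(ver), 2, byrow = TRUE))^2)
    nb <- ver[order(d2, ver)][1:k]
    expect_equal(unname(rho[i, ]), unname(colMeans(x$dmat[nb, ])))
  }
})

test_that("KNN limiting cases: all neighbors, and a subject's own row", {
  x <- sim_prepared(120, seed = 17)
  nv <- sum(x$verified)
  props <- as.vector(table(factor(x$disease[x$verified == 1], 1:3))) / nv
  rho_all <- fit_rho_knn(x, k = nv)$rho
  for (i in seq_len(x$n))
    expect_equal(unname(rho_all[i, ]), props)
  # K = 1 at a verified subject returns its own indicator row
  rho1 <- fit_rho_knn(x, k = 1)$rho
  ver <- which(x$verified == 1L)
  expect_equal(unname(rho1[ver, ]), unname(x$dmat[ver, ]))
  # larger K shrinks rho toward the global proportions
  dev <- function(r) mean(abs(sweep(r, 2, props)))
  expect_lt(dev(fit_rho_knn(x, k = nv - 5)$rho),
            dev(fit_rho_knn(x, k = 3)$rho))
  expect_error(fit_rho_knn(x, k = nv + 1), "exceeds")
  expect_error(fit_rho_knn(x, k = 0), "at least 1")
})

test_that("choose_k is seeded, honors a singleton grid, and is stable", {
  x <- sim_prepared(400, seed = 23)
  expect_equal(choose_k(x, k_grid = 5, seed = 1)$k, 5)
  s1 <- choose_k(x, seed = 99)
  s2 <- choose_k(x, seed = 99)
  expect_identical(s1, s2)
  expect_error(choose_k(x, folds = 1), "at least 2")
  expect_error(choose_k(x, folds = 1e6), "exceeds")

  ks <- vapply(1:20, function(s) {
    choose_k(sim_prepared(500, seed = 600 + s), seed = s)$k
  }, numeric(1))
  # selection concentrates on a narrow upper band of the default grid
  expect_gte(mean(ks %in% c(13, 15, 17)), 0.7)
})
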