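test_that("the per-method corrections reproduce hand-computed rows", {
  # one verified subject with D = (0,1,0), pi = 0.5, rho = (.2,.5,.3),
  # plus an unverified companion
  d <- data.frame(T = c(1, 2, 3, 4), D = c(2, 1, 2, 3), V = 1L)
  x <- prepare_roc3(d, "T", "D", "V", class_order = 1:3)
  x$verified <- c(1L, 1L, 1L, 0L)
  x$disease[4] <- NA
  x$dmat[4, ] <- NA
  rho <- fake_rho(matrix(c(0.2, 0.5, 0.3), 4, 3, byrow = TRUE))
  pi_fit <- fake_verif(rep(0.5, 4))

  ipw <- disease_hat(x, "ipw", verif = pi_fit)
  expect_equal(unname(ipw[1, ]), c(0, 2, 0))
  expect_equal(unname(ipw[4, ]), c(0, 0, 0))  # unverified rows are zero

  spe <- disease_hat(x, "spe", rho = rho, verif = pi_fit)
  expect_equal(unname(spe[1, ]), c(-0.2, 1.5, -0.3))
  expect_equal(unname(spe[4, ]), c(0.2, 0.5, 0.3))  # V = 0: rho row

  fi <- disease_hat(x, "fi", rho = rho)
  expect_equal(unname(fi[, ]), unname(rho$rho))

  msi <- disease_hat(x, "msi", rho = rho)
  expect_equal(unname(msi[1, ]), c(0, 1, 0))      # verified: indicator
  expect_equal(unname(msi[4, ]), c(0.2, 0.5, 0.3))  # unverified: rho
})

test_that("with full verification msi, ipw and spe return the indicators", {
  x <- full_data(c(1, 5, 2, 8, 3, 9), c(1, 2, 1, 3, 2, 3))
  set.seed(1)
  r <- matrix(runif(18), 6, 3)
  rho <- fake_rho(r / rowSums(r))
  pi_one <- fake_verif(rep(1, 6))
  D <- unname(unclass(x$dmat))
  for (m in c("msi", "ipw", "spe")) {
    dh <- disease_hat(x, m, rho = rho, verif = pi_one)
    expect_equal(unname(dh[, ]), D)  # subsetting drops the fit metadata
  }
})

test_that("method preconditions are enforced", {
  x <- sim_prepared(100, seed = 1)
  expect_error(disease_hat(x, "full"), "V = 0")
  expect_error(disease_hat(x, "fi"), "disease model")
  expect_error(disease_hat(x, "ipw"), "verification model")
  expect_error(disease_hat(x, "spe", rho = fake_rho(matrix(1 / 3, 100, 3))),
               "verification model")
  expect_error(disease_hat(x, "knn",
                           rho = fake_rho(matrix(1 / 3, 100, 3), "mlogit")),
               "fit_rho_knn")
})

test_that("column means of corrected matrices estimate the prevalences", {
  # fi/msi: across-replicate check (coefficient noise is shared across
  # rows, so the iid within-sample SE would understate the variance)
  R <- 40
  cm <- array(NA_real_, c(R, 3, 2))
  for (r in 1:R) {
    x <- sim_prepared(2000, seed = 4000 + r)
    rho <- fit_rho_mlogit(x)
    cm[r, , 1] <- colMeans(disease_hat(x, "fi", rho = rho))
    cm[r, , 2] <- colMeans(disease_hat(x, "msi", rho = rho))
  }
  theta <- c(0.40, 0.35, 0.25)
  for (j in 1:2) {
    dev <- abs(colMeans(cm[, , j]) - theta)
    mcse <- apply(cm[, , j], 2, sd) / sqrt(R)
    expect_true(all(dev < 3 * mcse))
  }
  # spe: self-consistent within-sample SE (inflated by inverse weights)
  x <- sim_prepared(5000, seed = 31)
  dh <- disease_hat(x, "spe", rho = fit_rho_mlogit(x),
                    verif = fit_verification(x))
  expect_true(all(abs(colMeans(dh) - theta) <
                    3 * apply(dh, 2, sd) / sqrt(x$n)))
})

test_that("ipw column means are consistent under a bounded-weight design", {
  # under the default sharp verification model the Horvitz-Thompson
  # column means are too heavy-tailed for a 3-SE check at any feasible
  # Monte-Carlo size; the consistency property is asserted where the
  # weights are bounded
  cfg <- sim_config(verif_coef = c(0.3, -0.4, 0.8))
  R <- 30
  cm <- matrix(NA_real_, R, 3)
  for (r in 1:R) {
    x <- sim_prepared(2000, cfg, seed = 8800 + r)
    cm[r, ] <- colMeans(disease_hat(x, "ipw", verif = fit_verification(x)))
  }
  dev <- abs(colMeans(cm) - c(0.40, 0.35, 0.25))
  expect_true(all(dev < 3 * apply(cm, 2, sd) / sqrt(R)))
})

test_that("spe is doubly robust: one wrong nuisance model is tolerated", {
  cfg <- sim_config(verif_coef = c(0.3, -0.4, 0.8))
  x <- sim_prepared(5000, cfg, seed = 77)
  rho_ok <- fit_rho_mlogit(x)
  rho_bad <- fit_rho_mlogit(x, predictors = "A")   # drops the test
  pi_ok <- fit_verification(x)
  pi_bad <- fit_verification(x, predictors = "T")  # drops the covariate
  theta <- c(0.40, 0.35, 0.25)
  dev <- function(rho, verif)
    max(abs(colMeans(disease_hat(x, "spe", rho = rho, verif = verif)) -
              theta))
  expect_lt(dev(rho_ok, pi_ok), 0.02)
  expect_lt(dev(rho_bad, pi_ok), 0.02)   # wrong disease model
  expect_lt(dev(rho_ok, pi_bad), 0.02)   # wrong verification model
  expect_gt(dev(rho_bad, pi_bad), 0.03)  # both wrong: bias shows
})

test_that("msi equals fi on unverified rows and full on verified rows", {
  x <- sim_prepared(400, seed = 55)
  rho <- fit_rho_mlogit(x)
  msi <- disease_hat(x, "msi", rho = rho)
  fi <- disease_hat(x, "fi", rho = rho)
  unv <- x$verified == 0L
  expect_equal(unclass(msi)[unv, ], unclass(fi)[unv, ])
  expect_equal(unname(unclass(msi)[!unv, ]),
               unname(unclass(x$dmat)[!unv, ]))
})
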