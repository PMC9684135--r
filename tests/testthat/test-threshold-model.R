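# The binomial-logit threshold model: fitting, the 50% threshold and its
# delta-method uncertainty, ROC diagnostics, and per-stratum batching.

test_that("threshold algebra: -beta0/beta1 and the definitional round-trip", {
  expect_equal(vpd_p50(-5, 2), 2.5)
  expect_equal(vpd_p50(0, 3), 0)
  v <- vpd_p50(-3.7, 1.4)
  expect_equal(plogis(-3.7 + 1.4 * v), 0.5)
  expect_error(vpd_p50(-5, -1), "non-increasing")
  expect_error(vpd_p50(-5, 0), "non-increasing")
})

test_that("planted parameters are recovered within 3 SE at n = 10,000", {
  d <- planted_sample(10000L, -5, 2, seed = 101L)
  fit <- fire_threshold(burned ~ vpd, d)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(coef(fit)[1L] - (-5)), 3 * se[1L])
  expect_lt(abs(coef(fit)[2L] - 2), 3 * se[2L])
  expect_true(fit$converged)
  expect_false(fit$separated)
  # fitted probability at the reported threshold is exactly one half
  expect_equal(predict(fit, newdata = fit$vpd_p50), 0.5)

  # the MLE beats truth-perturbed parameters on the fitted deviance
  loglik <- function(b0, b1)
    sum(dbinom(d$burned, 1L, plogis(b0 + b1 * d$vpd), log = TRUE))
  at_fit <- loglik(coef(fit)[1L], coef(fit)[2L])
  for (db in list(c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1)))
    expect_gte(at_fit, loglik(coef(fit)[1L] + db[1L], coef(fit)[2L] + db[2L]))
})

test_that("symmetric two-point data puts the 50% crossing midway (separated)", {
  d <- data.frame(vpd = rep(c(1, 3), each = 50L),
                  burned = rep(c(0L, 1L), each = 50L))
  fit <- fire_threshold(burned ~ vpd, d)
  expect_true(fit$separated)
  expect_equal(fit$vpd_p50, 2)
  expect_equal(fit$auc, 1)
  expect_equal(fit$tpr, 1)
  expect_equal(predict(fit, newdata = c(1.9, 2, 2.1)), c(0, 0.5, 1))
})

test_that("degenerate inputs are rejected with explicit diagnostics", {
  expect_error(fire_threshold(burned ~ vpd,
                              data.frame(vpd = 1:10, burned = 1L)),
               "unfittable")
  expect_error(fire_threshold(burned ~ vpd,
                              data.frame(vpd = c(1, 2, 3, 4),
                                         burned = c(1L, 1L, 0L, 0L))),
               "non-increasing")
  expect_error(fire_threshold(burned ~ vpd + year,
                              planted_sample(100L, -5, 2, 1L)),
               "one predictor")
})

test_that("delta-method SE: zero covariance degenerates, bootstrap agrees within 10%", {
  unc0 <- threshold_uncertainty(-5, 2, matrix(0, 2, 2))
  expect_equal(unc0$se, 0)
  expect_equal(unc0$ci, c(2.5, 2.5))
  expect_true(all(is.na(threshold_uncertainty(-5, 2,
    matrix(c(Inf, 0, 0, 1), 2))$ci)))

  d <- planted_sample(1500L, -5, 2, seed = 55L)
  fit <- fire_threshold(burned ~ vpd, d)
  boot <- withr::with_seed(56L, vapply(1:500, function(b) {
    idx <- sample.int(nrow(d), replace = TRUE)
    f <- suppressWarnings(glm(burned ~ vpd, binomial(), d[idx, ]))
    -coef(f)[1L] / coef(f)[2L]
  }, numeric(1L)))
  expect_lt(abs(fit$se_p50 - sd(boot)) / sd(boot), 0.10)
  # the reported interval is point +/- 2 SE and spans the point
  expect_equal(fit$ci_p50, fit$vpd_p50 + c(-2, 2) * fit$se_p50)
})

test_that("at n = 1e6 the +/- 2 SE interval is narrower than +/- 0.01 kPa", {
  # the large-sample regime in which threshold intervals become too
  # narrow to be worth reporting
  d <- planted_sample(1e6L, -5, 2, seed = 88L)
  fit <- fire_threshold(burned ~ vpd, d)
  expect_lt(2 * fit$se_p50, 0.01)
  expect_lt(abs(fit$vpd_p50 - 2.5), 0.01)
})

test_that("trapezoidal AUC equals the brute-force pair fraction and Mann-Whitney", {
  d <- planted_sample(200L, -4, 1.8, seed = 77L)
  s <- plogis(-4 + 1.8 * d$vpd)
  expect_equal(auc_roc(s, d$burned), auc_brute(s, d$burned), tolerance = 1e-13)

  # with heavy ties (rounded scores) the half-credit convention must agree
  sr <- round(s, 1)
  expect_equal(auc_roc(sr, d$burned), auc_brute(sr, d$burned),
               tolerance = 1e-13)

  # invariant to monotone transforms of the score
  expect_equal(auc_roc(qlogis(s), d$burned), auc_roc(s, d$burned))
  expect_equal(auc_roc(rank(s), d$burned), auc_roc(s, d$burned))

  # independent reference implementation
  skip_if_not_installed("pROC")
  expect_equal(auc_roc(s, d$burned),
               as.numeric(pROC::auc(pROC::roc(d$burned, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC edge cases: separation, label noise, single class", {
  expect_equal(auc_roc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  big <- withr::with_seed(5L, data.frame(s = runif(4000),
                                         y = rbinom(4000, 1, 0.5)))
  expect_lt(abs(auc_roc(big$s, big$y) - 0.5), 0.03)
  expect_warning(out <- auc_roc(1:5, rep(1L, 5L)), "one class")
  expect_true(is.na(out))
})

test_that("skill diagnostics match their definitions on held data", {
  d <- planted_sample(3000L, -5, 2, seed = 31L)
  fit <- fire_threshold(burned ~ vpd, d)
  sk <- model_skill(fit)
  expect_equal(sk$auc, fit$auc)
  expect_equal(sk$tpr, fit$tpr)
  expect_equal(sk$deviance_explained, fit$deviance_explained,
               tolerance = 1e-6)
  # TPR is the burned-row fraction with predicted probability >= 0.5,
  # i.e. (for an increasing fit) VPD at or above the fitted threshold
  p <- predict(fit, type = "response")
  expect_equal(fit$tpr, mean(p[d$burned == 1] >= 0.5))
  expect_equal(fit$tpr, mean(d$vpd[d$burned == 1] >= fit$vpd_p50))
  # deviance explained uses the intercept-only null
  expect_true(sk$deviance_explained > 0 && sk$deviance_explained < 100)
})

test_that("model methods: print, summary, residuals, simulate, plot", {
  d <- planted_sample(800L, -5, 2, seed = 61L)
  fit <- fire_threshold(burned ~ vpd, d)
  expect_output(print(fit), "VPD_P=50")
  expect_output(print(summary(fit)), "Coefficients")
  r <- residuals(fit)
  expect_equal(length(r), 800L)
  expect_equal(sign(r), sign(d$burned - predict(fit)))
  sims <- simulate(fit, nsim = 3, seed = 9L)
  expect_equal(dim(sims), c(800L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  sims2 <- simulate(fit, nsim = 3, seed = 9L)
  expect_identical(sims, sims2)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("per-stratum fitting recovers three planted thresholds and flags unfittable strata", {
  planted <- c(A = 1.3, B = 2.3, C = 2.7)
  d <- do.call(rbind, lapply(names(planted), function(st)
    planted_sample(4000L, -2 * planted[[st]], 2, seed = 300L + match(st, names(planted)),
                   stratum = st)))
  bad <- data.frame(vpd = c(1, 2), burned = 1L, year = 2003L, stratum = "D")
  fits <- fit_strata(rbind(d, bad))
  expect_named(fits$fits, c("A", "B", "C"))
  expect_equal(names(fits$unfittable), "D")
  tab <- as.data.frame(fits)
  for (st in names(planted)) {
    row <- tab[tab$stratum == st, ]
    expect_lt(abs(row$vpd_p50 - planted[[st]]), 3 * row$se)
  }
  # identical data in every stratum -> identical models
  same <- do.call(rbind, lapply(c("X", "Y"), function(st) {
    s <- planted_sample(1000L, -5, 2, seed = 9L, stratum = st)
    s
  }))
  fs <- fit_strata(same)
  expect_equal(fs$fits$X$coefficients, fs$fits$Y$coefficients)

  # summary medians per group
  grp <- c(A = "low", B = "high", C = "high")
  sm <- summary(fit_strata(d, groups = grp))
  expect_equal(sort(sm$by_group$group), c("high", "low"))
  expect_lt(sm$by_group$median_vpd_p50[sm$by_group$group == "low"],
            sm$by_group$median_vpd_p50[sm$by_group$group == "high"])
})
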