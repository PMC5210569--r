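test_that("q-values reproduce the worked target-decoy example", {
  p <- data.frame(score = c(10, 9, 8, 7, 9.5, 6),
                  is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  q <- computeQvalues(p)$q_value
  expect_equal(q[1:4], c(0, 0.25, 0.25, 0.25))
  # no decoys: all q are zero, with a warning
  expect_warning(q0 <- computeQvalues(data.frame(score = 1:3,
                                                 is_decoy = FALSE)),
                 "no decoy")
  expect_identical(q0$q_value, c(0, 0, 0))
  # no targets is an error
  expect_error(computeQvalues(data.frame(score = 1, is_decoy = TRUE)),
               "no target")
})

test_that("q-values agree exactly with the brute-force oracle", {
  for (s in 1:200) {
    p <- random_psms(n = sample(5:120, 1), seed = 1000 + s)
    p$is_decoy[1] <- FALSE
    if (!any(p$is_decoy)) p$is_decoy[2] <- TRUE
    got <- computeQvalues(p)$q_value
    expect_equal(got, oracle_qvalues(p$score, p$is_decoy))
  }
})

test_that("q-values are monotone non-increasing in score and in [0,1]", {
  p <- random_psms(500, seed = 77)
  p$is_decoy[1] <- FALSE
  q <- computeQvalues(p)$q_value
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p$score, decreasing = TRUE)
  expect_true(all(diff(q[o]) >= 0))
})

test_that("global FDR counts identifications beyond the threshold", {
  p <- data.frame(score = c(rep(5, 8), rep(4, 2)),
                  is_decoy = c(rep(FALSE, 8), rep(TRUE, 2)))
  expect_equal(globalFdrAt(3, p), 2 / 8)
  expect_warning(out <- globalFdrAt(10, p), "no target")
  expect_equal(out, 0)
  # inclusive counting picks up PSMs at the threshold itself
  expect_equal(globalFdrAt(4, p, inclusive = TRUE), 2 / 8)
  expect_equal(globalFdrAt(4, p, inclusive = FALSE), 0)
})

test_that("gamma fit recovers a constant mutation fraction", {
  set.seed(3)
  n <- 4000
  p <- data.frame(score = rnorm(n), is_decoy = TRUE,
                  is_mutation = runif(n) < 0.07)
  p$is_decoy[1] <- FALSE   # fit uses decoys only
  fit <- fitGamma(p)
  expect_false(fit@fallback)
  expect_lt(abs(fit@a), 0.02)
  expect_lt(abs(fit@b - 0.07), 0.02)
  expect_equal(predictGamma(fit, 0), fit@b, tolerance = 1e-12)
})

test_that("gamma fit recovers a known score-dependent tilt", {
  set.seed(4)
  n <- 20000
  score <- rnorm(n, 0, 2)
  p <- data.frame(score = score, is_decoy = TRUE,
                  is_mutation = runif(n) < pmin(1, pmax(0, 0.05 + 0.01 * score)))
  p$is_decoy[1] <- FALSE
  fit <- fitGamma(p)
  expect_lt(abs(fit@a - 0.01), 0.003)
  expect_lt(abs(fit@b - 0.05), 0.01)
  # prediction clamps to [0, 1]
  expect_identical(predictGamma(fit, -1e6), 0)
  expect_identical(predictGamma(fit, 1e6), 1)
})

test_that("sparse decoy data fall back to a constant fit", {
  p <- data.frame(score = c(1, 2, 3), is_decoy = c(FALSE, TRUE, TRUE),
                  is_mutation = c(FALSE, TRUE, FALSE))
  expect_warning(fit <- fitGamma(p), "falling back")
  expect_true(fit@fallback)
  expect_identical(fit@a, 0)
  expect_equal(fit@b, 0.5)
})

test_that("transferred FDR evaluates the published formula", {
  fit <- methods::new("GammaFit", a = 0, b = 0.04, scoreGrid = c(0, 1),
                      cellScore = numeric(0), gammaObserved = numeric(0),
                      cellCounts = integer(0), fallback = TRUE,
                      mode = "binned")
  # N/N_k * gamma * FDR = (100/5) * 0.04 * 0.01
  expect_equal(transferredFdr(5, n = 100, nk = 5, fit = fit,
                              fdrGlobal = 0.01), 0.008)
  # N_k = 0 is undefined, reported as missing
  expect_true(is.na(transferredFdr(5, n = 100, nk = 0, fit = fit,
                                   fdrGlobal = 0.01)))
  # clamped to [0, 1]
  big <- methods::new("GammaFit", a = 0, b = 1, scoreGrid = c(0, 1),
                      cellScore = numeric(0), gammaObserved = numeric(0),
                      cellCounts = integer(0), fallback = TRUE,
                      mode = "binned")
  expect_identical(transferredFdr(5, n = 1000, nk = 1, fit = big,
                                  fdrGlobal = 0.9), 1)
})

test_that("transferred FDR collapses to global FDR when gamma = N_k/N", {
  # if the mutation fraction among false hits equals the mutation share
  # of all target hits, the subgroup estimate cancels to the global one
  n <- 200; nk <- 30; fdr <- 0.02
  fit <- methods::new("GammaFit", a = 0, b = nk / n, scoreGrid = c(0, 1),
                      cellScore = numeric(0), gammaObserved = numeric(0),
                      cellCounts = integer(0), fallback = TRUE,
                      mode = "binned")
  expect_equal(transferredFdr(2, n = n, nk = nk, fit = fit,
                              fdrGlobal = fdr), fdr)
})

test_that("group q-values are monotone and land on mutation PSMs only", {
  sim <- shared_sim_db()
  cfg <- simConfig(nSpectra = 8000L, seed = 31L)
  p <- simulatePsms(sim$db, cfg, pools = sim$pools)
  p <- computeQvalues(p)
  p <- groupQvalues(p, fitGamma(p))
  mut <- !p$is_decoy & p$is_mutation
  expect_true(all(is.na(p$group_q_value[!mut])))
  expect_true(all(!is.na(p$group_q_value[mut])))
  gq <- p$group_q_value[mut]
  expect_true(all(gq >= 0 & gq <= 1))
  o <- order(p$score[mut], decreasing = TRUE)
  expect_true(all(diff(gq[o]) >= 0))
  # a lone top-scoring mutation PSM above every decoy has group q 0
  expect_equal(min(gq[o][1]), gq[o][1])
  top <- data.frame(score = c(10, 5, 4, 1, 0.5),
                    is_decoy = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                    is_mutation = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  top <- computeQvalues(top)
  expect_warning(fit <- fitGamma(top))
  top <- groupQvalues(top, fit)
  expect_identical(top$group_q_value[1], 0)
})

test_that("group q-values have no mutation PSMs to act on: warn, no-op", {
  p <- data.frame(score = c(3, 2, 1), is_decoy = c(FALSE, FALSE, TRUE),
                  is_mutation = FALSE)
  p <- computeQvalues(p)
  fit <- methods::new("GammaFit", a = 0, b = 0.1, scoreGrid = c(0, 1),
                      cellScore = numeric(0), gammaObserved = numeric(0),
                      cellCounts = integer(0), fallback = TRUE,
                      mode = "binned")
  expect_warning(out <- groupQvalues(p, fit), "no mutation")
  expect_true(all(is.na(out$group_q_value)))
})

test_that("the FDR curve tabulates consistent counts", {
  sim <- shared_sim_db()
  cfg <- simConfig(nSpectra = 4000L, seed = 53L)
  p <- simulatePsms(sim$db, cfg, pools = sim$pools)
  p <- computeQvalues(p)
  fit <- fitGamma(p)
  curve <- fdrCurve(p, fit)
  expect_true(all(curve$N >= curve$N_k))
  expect_true(all(diff(curve$N) >= 0))   # descending thresholds
  expect_true(all(curve$FDR >= 0))
  expect_true(all(curve$gamma_hat >= 0 & curve$gamma_hat <= 1))
})
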