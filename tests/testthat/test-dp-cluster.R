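# Dirichlet-process CCF clustering: planted recovery, invariances,
# likelihood bookkeeping.

test_that("a single planted cluster is recovered at its location", {
  pl <- make_planted_counts(matrix(c(1, 1), 1), 300, c(1, 1), depth = 100,
                            seed = 1)
  fit <- dp_cluster(pl$alt, pl$depth, pl$purity,
                    control = dp_control(seed = 2))
  expect_equal(nrow(fit$cluster_ccf), 1)
  expect_true(all(abs(fit$cluster_ccf - 1) <= 0.03))
})

test_that("two planted clusters are recovered within 0.05", {
  cc <- rbind(c(1, 1), c(0.4, 0.05))
  pl <- make_planted_counts(cc, c(300, 300), c(1, 1), depth = 100, seed = 3)
  fit <- dp_cluster(pl$alt, pl$depth, pl$purity,
                    control = dp_control(seed = 4))
  expect_equal(nrow(fit$cluster_ccf), 2)
  err <- max(abs(fit$cluster_ccf - cc))
  expect_lte(err, 0.05)
  # posterior locations never leave [0, 1.25]
  expect_true(all(fit$cluster_ccf >= 0 & fit$cluster_ccf <= 1.25))
  expect_true(all(fit$ccf_lo >= 0 & fit$ccf_hi <= 1.25))
  # sizes account for every mutation
  expect_equal(sum(fit$cluster_size), 600)
})

test_that("degenerate inputs error or fall back as documented", {
  expect_error(dp_cluster(matrix(numeric(0), 0, 2),
                          matrix(numeric(0), 0, 2), c(1, 1)),
               "no mutations")
  pl <- make_planted_counts(matrix(c(0.8, 0.8), 1), 20, c(1, 1), seed = 5)
  expect_warning(fit <- dp_cluster(pl$alt, pl$depth, pl$purity),
                 "single-cluster")
  expect_equal(nrow(fit$cluster_ccf), 1)
  expect_true(all(abs(fit$cluster_ccf - 0.8) < 0.1))
})

test_that("clustering is invariant to input row order (same seed)", {
  cc <- rbind(c(1, 1), c(0.5, 0.2))
  pl <- make_planted_counts(cc, c(150, 150), c(0.9, 0.8), depth = 90,
                            seed = 6)
  rownames(pl$alt) <- rownames(pl$depth) <- paste0("m", seq_len(300))
  fit1 <- dp_cluster(pl$alt, pl$depth, pl$purity,
                     control = dp_control(seed = 7))
  perm <- sample(300)
  fit2 <- dp_cluster(pl$alt[perm, ], pl$depth[perm, ], pl$purity,
                     control = dp_control(seed = 7))
  expect_equal(fit1$cluster_ccf, fit2$cluster_ccf)
  expect_equal(fit1$assignment[rownames(pl$alt)],
               fit2$assignment[rownames(pl$alt)])
})

test_that("solution log-likelihood matches a first-principles computation", {
  # perfect-fit noiseless toy: y = N * f exactly, 3 mutations
  cc <- matrix(c(0.8, 0.4), 1)
  N <- matrix(c(100, 50, 200, 100, 50, 200), 3, 2)
  f <- rbind(cc, cc, cc) * 0.5
  y <- round(N * f)
  sol <- list(assignment = rep(1L, 3),
              cluster_ccf = cc,
              data = list(alt = y, depth = N,
                          cmat = matrix(0.5, 3, 2)))
  expect_equal(solution_loglik(sol),
               bf_binom_loglik(y, N, f))
  # permuting mutation order leaves the value unchanged
  sol2 <- sol
  sol2$data$alt <- y[c(3, 1, 2), ]
  sol2$data$depth <- N[c(3, 1, 2), ]
  expect_equal(solution_loglik(sol2), solution_loglik(sol))
  # moving the cluster CCF off the MLE decreases the likelihood
  worse <- sol
  worse$cluster_ccf <- cc + 0.1
  expect_lt(solution_loglik(worse), solution_loglik(sol))
})

test_that("ten-fold depth tightens the credible intervals", {
  cc <- matrix(c(0.6, 0.3), 1)
  lo_w <- sapply(c(40, 400), function(dp) {
    pl <- make_planted_counts(cc, 200, c(1, 1), depth = dp, seed = 8)
    fit <- dp_cluster(pl$alt, pl$depth, pl$purity,
                      control = dp_control(seed = 9))
    mean(fit$ccf_hi[1, ] - fit$ccf_lo[1, ])
  })
  expect_lt(lo_w[2], lo_w[1])
})

test_that("methods print, summarize and report coefficients", {
  pl <- make_planted_counts(matrix(c(1, 1), 1), 100, c(1, 1), seed = 10)
  fit <- dp_cluster(pl$alt, pl$depth, pl$purity,
                    control = dp_control(seed = 11))
  expect_output(print(fit), "Dirichlet-process")
  expect_output(print(summary(fit)), "Cluster CCFs")
  expect_equal(coef(fit), fit$cluster_ccf)
  expect_s3_class(logLik(fit), "logLik")
  expect_lt(as.numeric(logLik(fit)), 0)
})

test_that("missing regions (depth 0) contribute no likelihood", {
  pl <- make_planted_counts(matrix(c(0.8, 0.8), 1), 100, c(1, 1), seed = 12)
  pl$alt[, 2] <- 0L
  pl$depth[, 2] <- 0L
  fit <- dp_cluster(pl$alt, pl$depth, pl$purity,
                    control = dp_control(seed = 13))
  expect_equal(nrow(fit$cluster_ccf), 1)
  expect_lt(abs(fit$cluster_ccf[1, 1] - 0.8), 0.05)
})
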