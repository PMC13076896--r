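# Expression scoring, deconvolution and clustering.

make_expr <- function(n_genes = 60, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, 3, 1), n_genes, n_samples,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

test_that("gene_set_score is a mean z-score with the documented edge cases", {
  expr <- make_expr()
  set <- rownames(expr)[1:10]
  sc <- gene_set_score(expr, set)
  # constant set genes across samples -> score 0
  expr2 <- expr
  expr2[1:10, ] <- 5
  expect_equal(unname(gene_set_score(expr2, set)), rep(0, ncol(expr)))
  # sample shifted +2 SD on every set gene scores ~ 2
  lx <- log2(expr + 1)
  expr3 <- expr
  expr3[1:10, 1] <- 2^(lx[1:10, 1] + 2 * apply(lx[1:10, ], 1, sd)) - 1
  expect_gt(gene_set_score(expr3, set)[1], 1)  # shift inflates the gene SDs
  # permuting samples permutes scores identically
  perm <- sample(ncol(expr))
  expect_equal(gene_set_score(expr[, perm], set), sc[perm])
  expect_error(gene_set_score(expr, c("NOPE1", "NOPE2")), "NOPE1")
})

test_that("gradient score is exactly antisymmetric and separates subtypes", {
  expr <- make_expr()
  sq <- rownames(expr)[1:8]; cl <- rownames(expr)[9:16]
  g1 <- gradient_score(expr, sq, cl)
  g2 <- gradient_score(expr, cl, sq)
  expect_equal(g1, -g2)
  # all-equal expression -> 0
  expr0 <- matrix(7, 10, 4, dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
  expect_equal(unname(gradient_score(expr0, "G1", "G2")), rep(0, 4))
  # construction: squamous-shifted samples rank above classical-shifted
  gs <- default_gene_sets()
  sim <- simulate_expression(
    matrix(0.05, 1, 6, dimnames = list("CAF", NULL)),
    subtype = rep(c("squamous", "classical"), each = 3), noise_sd = 0,
    seed = 3)
  g <- gradient_score(sim$expr, gs$squamous, gs$classical)
  expect_true(min(g[1:3]) > max(g[4:6]))  # AUC 1 separation
})

test_that("ssgsea scores behave as rank statistics", {
  expr <- make_expr(40, 5, seed = 2)
  # hand-computed 3-gene example: set = top-ranked gene
  e3 <- matrix(c(30, 20, 10), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s"))
  # ranked list g1,g2,g3; Pin = (1,1,1); Pout = (0,.5,1); dev = (1,.5,0)
  expect_equal(unname(ssgsea_score(e3, "g1", statistic = "max")), 1)
  expect_equal(unname(ssgsea_score(e3, "g1", statistic = "sum")), 1.5)
  # top-k set scores strictly above bottom-k set
  ord <- order(-expr[, 1])
  top <- rownames(expr)[ord[1:5]]; bot <- rownames(expr)[ord[36:40]]
  expect_gt(ssgsea_score(expr, top)[1], ssgsea_score(expr, bot)[1])
  # monotone-transformation invariance within samples (rank-based)
  expect_equal(ssgsea_score(expr, top), ssgsea_score(expr^2, top))
  # random set vs complement anti-correlated across samples
  set.seed(4)
  s <- sample(rownames(expr), 15)
  a <- ssgsea_score(expr, s)
  b <- ssgsea_score(expr, setdiff(rownames(expr), s))
  expect_lt(cor(a, b), 0)
})

test_that("estimate-like scores sum stromal and immune enrichment", {
  expr <- make_expr(50, 4, seed = 5)
  st <- rownames(expr)[1:10]; im <- rownames(expr)[11:20]
  es <- estimate_scores(expr, st, im)
  expect_equal(es$estimate, es$stromal + es$immune)
})

test_that("deconvolution recovers noiseless and noisy mixtures", {
  R <- synthetic_reference_profiles()
  w <- c(CAF = 0.2, CD8_T = 0.3, macrophage = 0.1)
  g <- R[, names(w), drop = FALSE] %*% w
  est <- deconvolve_fractions(g, R)
  expect_equal(unname(unlist(est[1, names(w)])), unname(w), tolerance = 1e-6)
  expect_equal(est$uncharacterized[1], 1 - sum(w) +
                 est$epithelial[1] + est$endothelial[1] + est$CD4_T[1] +
                 est$B_cell[1], tolerance = 1e-6)
  # a pure reference column returns weight 1 on that type
  est2 <- deconvolve_fractions(R[, "CAF", drop = FALSE], R)
  expect_equal(est2$CAF[1], 1, tolerance = 1e-6)
  # lognormal noise sd 0.2: recovery within 0.05 per type on average
  set.seed(6)
  errs <- replicate(30, {
    wr <- c(CAF = runif(1, 0, 0.3), CD8_T = runif(1, 0, 0.2))
    gg <- (R[, names(wr)] %*% wr + R[, "epithelial"] * (1 - sum(wr))) *
      exp(rnorm(nrow(R), 0, 0.2))
    ee <- deconvolve_fractions(gg, R)
    max(abs(unlist(ee[1, names(wr)]) - wr))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("fraction rows sum to one and respect the simplex", {
  R <- synthetic_reference_profiles()
  set.seed(7)
  g <- R %*% runif(ncol(R), 0, 0.4) * exp(rnorm(nrow(R), 0, 0.3))
  est <- deconvolve_fractions(g, R)
  vals <- unlist(est[1, -1])
  expect_true(all(vals >= -1e-9))
  expect_equal(sum(vals), 1, tolerance = 1e-6)
})

test_that("pca clustering separates planted groups and is stable", {
  skip_if_no_mclust()
  gs <- default_gene_sets()
  sim <- simulate_expression(
    matrix(0.05, 1, 10, dimnames = list("CAF", NULL)),
    subtype = rep(c("squamous", "classical"), each = 5), noise_sd = 0.05,
    seed = 8)
  lab <- pca_cluster(sim$expr, 2, n_pcs = 5, seed = 1,
                     squamous_set = gs$squamous, classical_set = gs$classical)
  truth <- rep(1:2, each = 5)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  # squamous-like group gets label 1 by the gradient ordering
  expect_true(all(lab[1:5] == 1))
  # duplicated samples cluster together
  dup <- sim$expr[, c(1, 1, 2, 6, 7, 6)]
  colnames(dup) <- paste0("X", 1:6)
  lab2 <- pca_cluster(dup, 2, n_pcs = 3, seed = 1)
  expect_equal(lab2[["X1"]], lab2[["X2"]])
  expect_equal(lab2[["X4"]], lab2[["X6"]])
  # permutation of samples leaves labels invariant
  perm <- c(3, 9, 1, 5, 2, 10, 4, 8, 6, 7)
  lab3 <- pca_cluster(sim$expr[, perm], 2, n_pcs = 5, seed = 1,
                      squamous_set = gs$squamous,
                      classical_set = gs$classical)
  expect_equal(lab3[names(lab)], lab)
  expect_warning(pca_cluster(sim$expr[1:20, 1:4], 2, n_pcs = 15, seed = 1),
                 "rank")
})
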