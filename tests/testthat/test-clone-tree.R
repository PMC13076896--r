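# Tree reconstruction: nesting/crossing/sum rules, trajectory calls,
# subclone fractions, SV-burden comparison.

sol_of <- function(ccf, sizes = NULL) {
  if (is.null(sizes)) sizes <- setNames(rep(10L, nrow(ccf)), rownames(ccf))
  list(cluster_ccf = ccf, cluster_size = sizes)
}

test_that("clonal cluster identification respects the tolerance", {
  ccf <- matrix(c(1, 1, 0.5, 0.2), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("R1", "R2")))
  cl <- identify_clonal_clusters(sol_of(ccf))
  expect_equal(cl$cluster, c("A", "A"))
  expect_false(any(cl$pseudo_clonal))
  ccf2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("R1", "R2")))
  cl2 <- identify_clonal_clusters(sol_of(ccf2))
  expect_equal(cl2$cluster, c("A", "B"))
  ccf3 <- matrix(c(0.6, 0.5, 0.3, 0.2), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("R1", "R2")))
  expect_true(all(identify_clonal_clusters(sol_of(ccf3))$pseudo_clonal))
})

test_that("crossing forces siblings; nesting forces a chain", {
  ccf <- matrix(c(1, 1, 0.6, 0, 0, 0.5), 3, 2, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("R1", "R2")))
  tr <- build_forest(sol_of(ccf), eps = 0.05)
  expect_equal(unname(tr$parent[c("B", "C")]), c("A", "A"))
  traj <- classify_trajectory(tr)
  expect_equal(traj$growth_pattern, "branching")
  expect_equal(traj$mrca_pattern, "single_mrca")

  ccf2 <- matrix(c(1, 1, 0.6, 0.5, 0.3, 0.2), 3, 2, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("R1", "R2")))
  tr2 <- build_forest(sol_of(ccf2), eps = 0.05)
  expect_equal(unname(tr2$parent[c("B", "C")]), c("A", "B"))
  expect_equal(classify_trajectory(tr2)$growth_pattern, "linear")
})

test_that("non-nesting clusters become additional roots", {
  ccf <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("R1", "R2")))
  tr <- build_forest(sol_of(ccf), eps = 0.05)
  expect_equal(sum(is.na(tr$parent)), 2)
  expect_equal(classify_trajectory(tr)$mrca_pattern, "multiple_mrca")
})

test_that("noiseless simulated trees reconstruct exactly (regression)", {
  set.seed(17)
  arches <- c("single_mrca_linear", "single_mrca_branching", "multi_mrca")
  for (i in 1:30) {
    arch <- arches[(i %% 3) + 1]
    ncl <- switch(arch, single_mrca_linear = sample(2:4, 1),
                  single_mrca_branching = sample(3:5, 1),
                  multi_mrca = sample(4:6, 1))
    sp <- simulate_clone_tree(arch, ncl, sample(2:6, 1),
                              mutations_per_clone = 50)
    tr <- build_forest(sol_of(sp$ccf, sp$mutations_per_clone), eps = 1e-9)
    expect_equal(unname(tr$parent[sp$nodes]), unname(sp$parent[sp$nodes]),
                 info = paste(arch, i))
    expect_equal(audit_sum_rule(tr, eps = 1e-6), 0L)
  }
})

test_that("subclone fractions are exclusive CCF mass", {
  ccf <- matrix(c(1, 0.6), 2, 1, dimnames = list(c("A", "B"), "R1"))
  tr <- clonescape:::new_clone_tree(c("A", "B"), c(NA, "A"), ccf,
                                    c(A = 10L, B = 5L))
  fr <- subclone_fractions(tr, "R1")
  expect_equal(unname(fr), c(0.4, 0.6))
  # leaf fraction equals its own CCF; totals bounded by clonal CCF
  expect_equal(sum(fr), 1)
  # sum-rule violation beyond eps errors
  bad <- clonescape:::new_clone_tree(c("A", "B"), c(NA, "A"),
                                     matrix(c(0.5, 0.9), 2, 1,
                                            dimnames = list(c("A", "B"), "R1")),
                                     c(A = 1L, B = 1L))
  expect_error(subclone_fractions(bad, "R1", eps = 0.05), "violation")
})

test_that("SV burden comparison groups by growth pattern", {
  lin_ccf <- matrix(c(1, 1, 0.5, 0.4), 2, 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("R1", "R2")))
  br_ccf <- matrix(c(1, 1, 0.6, 0, 0, 0.5), 3, 2, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("R1", "R2")))
  trees <- list(p1 = build_forest(sol_of(lin_ccf)),
                p2 = build_forest(sol_of(br_ccf)))
  sv <- data.frame(case_id = c("p1", "p1", "p2", "p2"),
                   region_id = c("R1", "R2", "R1", "R2"),
                   n_sv = c(10, 10, 10, 10))
  res <- compare_sv_burden_by_pattern(trees, sv, mode = "exact")
  expect_equal(res$test$p_value, 1)      # identical counts -> p = 1
  expect_equal(res$mean_branching, res$mean_linear)
  sv1 <- data.frame(case_id = c("p1", "p2"), region_id = c("R1", "R1"),
                    n_sv = c(5, 50))
  res1 <- compare_sv_burden_by_pattern(trees, sv1, mode = "exact")
  expect_equal(res1$test$p_value, 1)     # single region per group: 2 perms
  expect_error(compare_sv_burden_by_pattern(trees["p1"], sv[1:2, ]),
               "empty")
})

test_that("tree printing and summary report the trajectory", {
  ccf <- matrix(c(1, 0.5), 2, 1, dimnames = list(c("A", "B"), "R1"))
  tr <- clonescape:::new_clone_tree(c("A", "B"), c(NA, "A"), ccf,
                                    c(A = 10L, B = 5L))
  expect_output(print(tr), "single_mrca / linear")
  s <- summary(tr)
  expect_equal(s$sum_rule_violations, 0L)
  expect_output(print(s), "Sum-rule violations: 0")
})
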