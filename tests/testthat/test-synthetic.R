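# Ground-truth generator: archetypes, sum rule, read-count calibration,
# truth completeness, signature channels, expression construction.

test_that("archetypes are realized as specified", {
  lin <- simulate_clone_tree("single_mrca_linear", 3, 2, seed = 1)
  expect_true(all(table(lin$parent[!is.na(lin$parent)]) <= 1))
  expect_equal(sum(is.na(lin$parent)), 1)
  # chain root -> c1 -> c2 with nested CCFs
  expect_true(all(lin$ccf[1, ] >= lin$ccf[2, ]))
  expect_true(all(lin$ccf[2, ] >= lin$ccf[3, ]))

  br <- simulate_clone_tree("single_mrca_branching", 4, 3, seed = 2)
  expect_true(any(table(br$parent[!is.na(br$parent)]) >= 2))

  mm <- simulate_clone_tree("multi_mrca", 2, 2, seed = 7)
  expect_equal(sum(is.na(mm$parent)), 2)
  # roots occupy disjoint region sets
  r <- mm$nodes[is.na(mm$parent)]
  expect_true(all(pmin(mm$ccf[r[1], ], mm$ccf[r[2], ]) < 0.05))

  expect_error(simulate_clone_tree("multi_mrca", 1, 2), "infeasible")
})

test_that("sampled specs satisfy the sum-rule validator (sweep)", {
  set.seed(5)
  arches <- c("single_mrca_linear", "single_mrca_branching", "multi_mrca")
  for (i in 1:60) {
    arch <- arches[(i %% 3) + 1]
    ncl <- switch(arch, single_mrca_linear = sample(2:4, 1),
                  single_mrca_branching = sample(3:5, 1),
                  multi_mrca = sample(4:6, 1))
    sp <- simulate_clone_tree(arch, ncl, sample(2:6, 1),
                              mutations_per_clone = 50)
    expect_silent(validate_tree_spec(sp))
    # crossing identifiability: every non-nested pair crosses by >= 0.08
    expect_true(clonescape:::crossing_ok(sp$ccf, sp$parent, 0.08))
  }
})

test_that("read simulation hits the analytic VAF expectations", {
  # closed form: rho = 0.5, diploid, clonal, m = 1 -> E[VAF] = 0.25
  expect_equal(expected_vaf(1, 0.5, 1, 2), 0.25)
  sp <- simulate_clone_tree("single_mrca_branching", 3, 2, seed = 9,
                            mutations_per_clone = 400)
  rho <- c(0.8, 0.5)
  sim <- simulate_reads(sp, rho, mean_depth = 150, seed = 10)
  # empirical VAF within 3 binomial SEs of expectation per clone x region
  for (k in sp$nodes) {
    rows <- which(sim$truth$clone == k)
    for (d in 1:2) {
      cc <- sim$calls[[d]][rows, ]
      nt <- sim$truth$major[rows] + sim$truth$minor[rows]
      f <- expected_vaf(sp$ccf[k, d], rho[d], sim$truth$multiplicity[rows],
                        pmax(nt, 1))
      ok <- cc$depth > 0
      est <- sum(cc$alt_count[ok]) / sum(cc$depth[ok])
      mu <- sum(f[ok] * cc$depth[ok]) / sum(cc$depth[ok])
      se <- sqrt(sum(f[ok] * (1 - f[ok]) * cc$depth[ok])) / sum(cc$depth[ok])
      expect_lt(abs(est - mu), 3 * se + 1e-9)
    }
  }
})

test_that("truth serialization is complete and consistent with the calls", {
  sp <- simulate_clone_tree("single_mrca_linear", 3, 2, seed = 11,
                            mutations_per_clone = 60)
  out <- tempfile()
  sim <- simulate_reads(sp, c(0.7, 0.6), 80, seed = 12, out_dir = out,
                        patient_id = "pt")
  # every emitted mutation appears in the truth exactly once
  keys <- paste0(sim$calls[[1]]$chrom, ":", sim$calls[[1]]$pos, ":",
                 sim$calls[[1]]$ref, ":", sim$calls[[1]]$alt)
  expect_equal(sort(keys), sort(sim$truth$key))
  expect_false(anyDuplicated(sim$truth$key) > 0)
  expect_true(file.exists(sim$paths$truth))
  tj <- jsonlite::read_json(sim$paths$truth)
  expect_equal(length(tj$truth), nrow(sim$truth))
  # multiplicity never exceeds the major allele count
  expect_true(all(sim$truth$multiplicity <= pmax(sim$truth$major, 1)))
  # non-root clones carry m = 1 (clonal copy events precede subclones)
  roots <- sp$nodes[is.na(sp$parent)]
  expect_true(all(sim$truth$multiplicity[!sim$truth$clone %in% roots] == 1))
})

test_that("signature channel simulation follows the exposure mixture", {
  S <- synthetic_sbs_catalog()
  sp <- simulate_clone_tree("single_mrca_linear", 2, 2, seed = 13,
                            mutations_per_clone = c(5000, 0))
  sp$exposures[1, ] <- 0
  sp$exposures[1, "SBS2"] <- 1
  ctx <- simulate_signature_contexts(sp, S, seed = 14)
  expect_equal(nrow(ctx), 5000)
  expect_true(all(ctx$signature == "SBS2"))
  # chi-square goodness of fit of channel frequencies to the SBS2 column
  obs <- tabulate(ctx$channel + 1L, 96)
  keep <- S[, "SBS2"] > 0
  gof <- suppressWarnings(
    chisq.test(obs[keep], p = S[keep, "SBS2"] / sum(S[keep, "SBS2"])))
  expect_gt(gof$p.value, 0.001)
  # zero-mutation clone contributes no rows
  expect_equal(sum(ctx$clone == "clone2"), 0)
  bad <- sp; bad$exposures <- bad$exposures[, 1:3]
  expect_error(simulate_signature_contexts(bad, S), "mismatch")
})

test_that("channel decomposition writes encodable mutations", {
  set.seed(15)
  ch <- sample(0:95, 300, replace = TRUE)
  dec <- clonescape:::channel_to_mutation(ch)
  expect_equal(encode_sbs96(dec$ref, dec$alt, dec$context), ch)
})

test_that("expression simulation honors fractions, shifts and noise", {
  R <- synthetic_reference_profiles()
  # noiseless single profile at weight 1 reproduces the reference column
  W <- matrix(1, 1, 1, dimnames = list("CAF", "s1"))
  sim <- simulate_expression(W, noise_sd = 0, seed = 1)
  expect_equal(unname(sim$expr[, 1]), unname(R[, "CAF"]))
  # squamous-shifted sample scores higher on the squamous set
  gs <- default_gene_sets()
  W2 <- matrix(0.1, 1, 4, dimnames = list("CAF", NULL))
  sim2 <- simulate_expression(W2, c("squamous", "squamous", "classical",
                                    "classical"), noise_sd = 0, seed = 2)
  g <- gradient_score(sim2$expr, gs$squamous, gs$classical)
  expect_true(all(g[1:2] > g[3:4]))
  # noiseless mixtures deconvolve exactly
  W3 <- matrix(c(0.2, 0.3, 0.1), 3, 1,
               dimnames = list(c("CAF", "CD8_T", "B_cell"), "s1"))
  sim3 <- simulate_expression(W3, noise_sd = 0, seed = 3)
  est <- deconvolve_fractions(sim3$expr[, 1], R)
  got <- unlist(est[1, c("CAF", "CD8_T", "B_cell")])
  expect_equal(unname(got), c(0.2, 0.3, 0.1), tolerance = 1e-6)
  expect_error(simulate_expression(W3 * 10), "sums")
})

test_that("cohort emission passes the readers and records growth truth", {
  out <- tempfile()
  coh <- simulate_cohort(out, n_patients = 2, seed = 3,
                         region_range = c(2, 3))
  man <- read_manifest(coh$manifest)   # validates all referenced paths
  expect_length(man$patients, 2)
  for (p in man$patients) {
    expect_gte(length(p$region_ids), 2)
    calls <- read_vcf(file.path(out, p$vcf[[1]]), p$region_ids[[1]])
    expect_gt(nrow(calls), 50)
    seg <- read_segments(file.path(out, p$segments[[1]]))
    expect_true(all(seg$major >= seg$minor))
    expect_true(all(unlist(p$histology) %in%
                      c("LGD", "HGD", "HGD_microinvasive", "PDAC")))
  }
})
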