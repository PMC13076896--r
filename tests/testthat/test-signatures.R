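# Signature machinery: channel encoders, NNLS refitting, probability
# assignment, branch profiles, NNMF extraction.

test_that("SBS96 encoding collapses strands onto 96 channels", {
  labs <- sbs96_labels()
  expect_length(labs, 96)
  expect_equal(labs[encode_sbs96("C", "T", "ACA") + 1], "A[C>T]A")
  expect_equal(encode_sbs96("G", "A", "TGT"), encode_sbs96("C", "T", "ACA"))
  # all 192 (context, alt) combinations hit exactly 96 channels, each twice
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  all_ch <- integer(0)
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (p5 in bases) for (p3 in bases) {
      all_ch <- c(all_ch, encode_sbs96(ref, alt, paste0(p5, ref, p3)))
    }
  }
  expect_length(all_ch, 192)
  expect_equal(as.vector(table(all_ch)), rep(2L, 96))
  expect_error(encode_sbs96("N", "T", "ANA"), "ambiguous")
  expect_error(encode_sbs96("C", "T", "AAA"), "middle")
})

test_that("ID83 encoding matches the brute-force classifier", {
  labs <- id83_labels()
  expect_length(labs, 83)
  cases <- list(
    list("CT", "C", "GG", "TTTA"),     # 1bp T del in TTTT run -> 1:Del:T:4
    list("C", "CT", "GG", "TTA"),      # 1bp T ins next to TT  -> 1:Ins:T:2
    list("C", "CA", "GG", "CCCC"),     # A ins, no A run       -> 1:Ins:T:0
    list("AGG", "A", "TT", "GGGGGG"),  # GG del in GG repeat
    list("ATCGAT", "A", "GG", "TCGTA"),# 5bp del with TCG... microhomology
    list("AACGT", "A", "CG", "GGGG"),  # 4bp del, no repeat, no MH
    list("A", "ACGCG", "TT", "CGCGCG") # 4bp ins at CG repeats
  )
  for (cs in cases) {
    ch <- encode_id83(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(labs[ch + 1], bf_id83_label(cs[[1]], cs[[2]], cs[[3]], cs[[4]]),
                 info = paste(unlist(cs), collapse = "/"))
  }
  # randomized sweep over synthetic indels
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  for (i in 1:150) {
    L <- sample(1:6, 1)
    motif <- paste(sample(bases, L, replace = TRUE), collapse = "")
    anchor <- sample(bases, 1)
    f5 <- paste(sample(bases, 6, replace = TRUE), collapse = "")
    f3 <- paste(sample(bases, 12, replace = TRUE), collapse = "")
    if (runif(1) < 0.5) { ref <- paste0(anchor, motif); alt <- anchor }
    else { ref <- anchor; alt <- paste0(anchor, motif) }
    ch <- encode_id83(ref, alt, f5, f3)
    expect_equal(labs[ch + 1], bf_id83_label(ref, alt, f5, f3),
                 info = paste(ref, alt, f5, f3))
  }
  # missing flank -> context unavailable
  expect_true(is.na(encode_id83("CT", "C", "", "")))
})

test_that("packaged synthetic catalogs are valid probability matrices", {
  for (cat in list(synthetic_sbs_catalog(), synthetic_id_catalog(),
                   synthetic_cn_catalog())) {
    expect_true(all(cat >= 0))
    expect_equal(unname(colSums(cat)), rep(1, ncol(cat)), tolerance = 1e-8)
  }
})

test_that("NNLS refitting recovers exact and noisy mixtures", {
  S <- synthetic_sbs_catalog()
  e1 <- fit_exposures_nnls(100 * S[, "SBS1"], S)
  expect_equal(unname(e1["SBS1"]), 100, tolerance = 1e-6)
  expect_equal(sum(e1[names(e1) != "SBS1"]), 0, tolerance = 1e-6)

  mix <- 70 * S[, "SBS2"] + 30 * S[, "SBS5"]
  e2 <- fit_exposures_nnls(mix, S)
  expect_equal(unname(e2["SBS2"]), 70, tolerance = 1e-6)
  expect_equal(unname(e2["SBS5"]), 30, tolerance = 1e-6)

  set.seed(9)
  counts <- rmultinom(1, 5000, 0.7 * S[, "SBS1"] + 0.3 * S[, "SBS13"])[, 1]
  e3 <- fit_exposures_nnls(counts, S)
  prop <- e3 / sum(e3)
  expect_lt(sum(abs(prop[c("SBS1", "SBS13")] - c(0.7, 0.3))) +
              sum(prop[!names(prop) %in% c("SBS1", "SBS13")]), 0.05)

  expect_equal(sum(fit_exposures_nnls(rep(0, 96), S)), 0)
})

test_that("NNLS residual beats random perturbations of the exposures", {
  S <- synthetic_sbs_catalog()
  set.seed(10)
  counts <- rmultinom(1, 2000, 0.5 * S[, "SBS5"] + 0.5 * S[, "SBS40"])[, 1]
  e <- fit_exposures_nnls(counts, S, prune_frac = 0)
  res0 <- sum((counts - S %*% e)^2)
  for (i in 1:20) {
    pert <- pmax(e + rnorm(length(e), 0, 20), 0)
    expect_gte(sum((counts - S %*% pert)^2) + 1e-8, res0)
  }
})

test_that("signature probabilities follow the exposure-weighted posterior", {
  S <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2")))
  P <- mutation_signature_probability(0:1, c(s1 = 60, s2 = 40), S)
  expect_equal(unname(P[1, "s1"]), 54 / (54 + 8), tolerance = 1e-12) # 0.871
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
  # single active signature -> probability 1 on covered channels
  P1 <- mutation_signature_probability(0:1, c(s1 = 10, s2 = 0), S)
  expect_equal(unname(P1[, "s1"]), c(1, 1))
  # equal exposure, equal density -> 0.5/0.5
  Seq <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                dimnames = list(c("c1", "c2"), c("s1", "s2")))
  Peq <- mutation_signature_probability(0, c(s1 = 5, s2 = 5), Seq)
  expect_equal(unname(Peq[1, ]), c(0.5, 0.5))
})

test_that("branch profiles recover a planted trunk/branch signature split", {
  S <- synthetic_sbs_catalog()
  ccf <- matrix(c(1, 1, 0.5, 0.4), 2, 2, byrow = TRUE,
                dimnames = list(c("C1", "C2"), c("R1", "R2")))
  tree <- clonescape:::new_clone_tree(c("C1", "C2"), c(NA, "C1"), ccf,
                                      c(C1 = 600L, C2 = 600L))
  set.seed(12)
  ch <- c(sample(0:95, 600, TRUE, prob = S[, "SBS1"]),
          sample(0:95, 600, TRUE, prob = 0.55 * S[, "SBS2"] +
                   0.45 * S[, "SBS13"]))
  cl <- rep(c("C1", "C2"), each = 600)
  pr <- branch_signature_profile(tree, ch, cl, S)
  expect_equal(rowSums(pr), c(C1 = 1, C2 = 1), tolerance = 1e-8)
  truth1 <- setNames(numeric(6), colnames(S)); truth1["SBS1"] <- 1
  truth2 <- setNames(numeric(6), colnames(S))
  truth2[c("SBS2", "SBS13")] <- c(0.55, 0.45)
  expect_gt(cosine_similarity(pr["C1", ], truth1), 0.95)
  expect_gt(cosine_similarity(pr["C2", ], truth2), 0.95)
  # empty branch -> flagged, zero profile rather than NaN
  tree2 <- clonescape:::new_clone_tree(c("C1", "C2", "C3"),
                                       c(NA, "C1", "C1"), rbind(ccf, C3 = c(0.2, 0.1)),
                                       c(C1 = 600L, C2 = 600L, C3 = 0L))
  pr2 <- branch_signature_profile(tree2, ch, cl, S)
  expect_false(any(is.na(pr2)))
  expect_true(attr(pr2, "low_confidence")[["C3"]])
})

test_that("probability-summing branch profiles also recover the split", {
  S <- synthetic_sbs_catalog()
  ccf <- matrix(c(1, 0.5), 2, 1, dimnames = list(c("C1", "C2"), "R1"))
  tree <- clonescape:::new_clone_tree(c("C1", "C2"), c(NA, "C1"), ccf,
                                      c(C1 = 500L, C2 = 500L))
  set.seed(13)
  ch <- c(sample(0:95, 500, TRUE, prob = S[, "SBS1"]),
          sample(0:95, 500, TRUE, prob = S[, "SBS2"]))
  cl <- rep(c("C1", "C2"), each = 500)
  pr <- branch_signature_profile(tree, ch, cl, S, method = "probability")
  expect_gt(pr["C1", "SBS1"], 0.8)
  expect_gt(pr["C2", "SBS2"], 0.8)
})

test_that("KL-NNMF recovers rank-1 structure and planted signatures", {
  S <- synthetic_sbs_catalog()
  # rank-1: single signature, counts proportional to it
  V <- t(sapply(c(500, 1000, 2000), function(n) n * S[, "SBS2"]))
  fit <- extract_denovo_nnmf(V, 1, n_restarts = 2, seed = 3)
  expect_gt(cosine_similarity(fit$signatures[, 1], S[, "SBS2"]), 0.999)
  expect_true(all(diff(fit$objective_trace) <= 1e-6))
  # planted 2-signature cohort
  set.seed(14)
  expo <- cbind(runif(20, 0, 1))
  V2 <- t(sapply(seq_len(20), function(i) {
    rmultinom(1, 3000, expo[i] * S[, "SBS1"] + (1 - expo[i]) * S[, "SBS13"])[, 1]
  }))
  fit2 <- extract_denovo_nnmf(V2, 2, n_restarts = 4, seed = 5)
  sims <- sapply(c("SBS1", "SBS13"), function(s) {
    max(apply(fit2$signatures, 2, cosine_similarity, b = S[, s]))
  })
  expect_true(all(sims >= 0.95))
  expect_error(extract_denovo_nnmf(V2, 50), "rank")
})
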