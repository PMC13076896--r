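# CCF machinery, multiplicity, timing, TMB, SV classes, CN48 channels.

test_that("expected_vaf matches closed forms and inverts compute_ccf", {
  expect_equal(expected_vaf(1, 1, 1, 2), 0.5)
  expect_equal(expected_vaf(1, 0.5, 1, 2), 0.25)
  set.seed(11)
  n <- 500
  ccf <- runif(n, 0, 1.25)
  rho <- runif(n, 0.05, 1)
  m <- sample(1:3, n, replace = TRUE)
  nt <- m + sample(0:3, n, replace = TRUE)
  v <- expected_vaf(ccf, rho, m, nt)
  keep <- v <= 1    # tuples yielding a physical VAF
  ccf <- ccf[keep]; rho <- rho[keep]; m <- m[keep]; nt <- nt[keep]
  v <- v[keep]
  back <- compute_ccf(v, rho, m, nt)
  expect_lt(max(abs(as.numeric(back) - ccf)), 1e-12)
  expect_false(any(attr(back, "capped")))
})

test_that("compute_ccf caps at 1.25 and flags", {
  x <- compute_ccf(0.9, 1.0, 1, 2)
  expect_equal(as.numeric(x), 1.25)
  expect_true(attr(x, "capped"))
  expect_equal(as.numeric(compute_ccf(0.25, 0.5, 1, 2)), 1.0)
  expect_equal(as.numeric(compute_ccf(0.5, 1.0, 2, 4)), 1.0)
})

test_that("estimate_multiplicity rounds half away from zero and clamps", {
  expect_equal(estimate_multiplicity(0.5, 1, 2, 1), 1L)
  expect_equal(estimate_multiplicity(0.66, 1, 3, 2), 2L)  # 0.66*3 = 1.98
  expect_equal(estimate_multiplicity(0.05, 0.5, 2, 2), 1L) # lower clamp
  expect_equal(estimate_multiplicity(0.75, 1, 2, 2), 2L)   # 1.5 rounds up
})

test_that("timing classes follow the gain rules", {
  expect_equal(as.character(classify_timing(TRUE, 2, 2, 1)), "clonal_early")
  expect_equal(as.character(classify_timing(TRUE, 1, 2, 0)), "clonal_late")
  expect_equal(as.character(classify_timing(FALSE, 1, 1, 1)), "subclonal")
  expect_equal(as.character(classify_timing(TRUE, 1, 1, 1)),
               "clonal_unspecified")
  expect_error(classify_timing(TRUE, 3, 2, 1), "exceeds")
})

test_that("TMB is mutations per megabase", {
  expect_equal(compute_tmb(2800, 200, 3000), 1.0)
  expect_equal(compute_tmb(0, 0, 3000), 0)
})

test_that("SV classification follows the strand convention", {
  sv <- data.frame(chrom1 = c("chr1", "chr2", "chr2", "chr2", "chr2"),
                   pos1 = c(100, 100, 100, 100, 900),
                   strand1 = c("+", "+", "-", "+", "-"),
                   chrom2 = c("chr5", "chr2", "chr2", "chr2", "chr2"),
                   pos2 = c(500, 900, 900, 900, 100),
                   strand2 = c("-", "-", "+", "+", "+"),
                   stringsAsFactors = FALSE)
  cls <- classify_sv(sv)
  expect_equal(as.character(cls),
               c("translocation", "deletion", "tandem_duplication",
                 "inversion", "deletion"))  # last: canonicalized swap
  sv$strand1[1] <- NA
  expect_equal(as.character(classify_sv(sv))[1], "unclassified")
})

test_that("CN48 encoding is total, injective and hits all 48 channels", {
  expect_equal(encode_cn48(1, 1, 5e6), 30L)       # het / TCN2 / 1-10Mb
  expect_equal(cn48_labels()[31], "2:het:1Mb-10Mb")
  expect_equal(encode_cn48(0, 0, 5e4), 0L)        # homdel / 0-100kb
  # enumeration oracle: one representative (major, minor, length) per
  # category tuple must map onto each channel exactly once
  reps <- list()
  lens3 <- c(5e4, 5e5, 5e6)
  lens5 <- c(5e4, 5e5, 5e6, 2e7, 8e7)
  for (l in lens3) reps[[length(reps) + 1]] <- c(0, 0, l)
  for (tc in list(c(1, 0), c(2, 0), c(3, 0), c(6, 0), c(9, 0))) {
    for (l in lens5) reps[[length(reps) + 1]] <- c(tc[1], tc[2], l)
  }
  for (tc in list(c(1, 1), c(2, 1), c(4, 2), c(8, 1))) {
    for (l in lens5) reps[[length(reps) + 1]] <- c(tc[1], tc[2], l)
  }
  ch <- vapply(reps, function(r) encode_cn48(r[1], r[2], r[3]), integer(1))
  expect_equal(sort(ch), 0:47)
  # channel counts over a random segment set sum to the number of segments
  set.seed(2)
  mj <- sample(0:6, 200, replace = TRUE)
  mn <- pmin(mj, sample(0:3, 200, replace = TRUE))
  lens <- 10^runif(200, 3, 8)
  tab <- tabulate(encode_cn48(mj, mn, lens) + 1L, 48)
  expect_equal(sum(tab), 200)
})

test_that("mutation_features combines vaf, multiplicity and ccf", {
  mf <- mutation_features(alt_count = c(50, 10), depth = c(100, 100),
                          rho = 1, major = c(1, 1), minor = c(1, 1))
  expect_equal(mf$vaf, c(0.5, 0.1))
  expect_equal(mf$multiplicity, c(1L, 1L))
  expect_equal(mf$ccf, c(1.0, 0.2))
})
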