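# Shared fixture builders and independent brute-force oracles.

# planted multi-region read counts for a set of cluster locations
make_planted_counts <- function(ccf, sizes, purity, depth = 100, seed = 1) {
  set.seed(seed)
  D <- ncol(ccf)
  z <- rep(seq_len(nrow(ccf)), sizes)
  n <- length(z)
  Nm <- matrix(rpois(n * D, depth), n, D)
  cmat <- matrix(rep(purity / 2, each = n), n, D)
  f <- ccf[z, , drop = FALSE] * cmat
  ym <- matrix(rbinom(n * D, as.vector(Nm), pmin(as.vector(f), 1)), n, D)
  list(alt = ym, depth = Nm, purity = purity, truth = z, cmat = cmat)
}

# independent brute-force two-sided Fisher-Pitman p by full enumeration
bf_fisher_pitman <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool); nx <- length(x)
  tobs <- mean(x) - mean(y)
  idx <- utils::combn(n, nx)
  tp <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  mean(abs(tp) >= abs(tobs) - 1e-12)
}

# independent brute-force two-sided Mann-Whitney p (no ties): doubled
# smaller tail of the enumerated U distribution
bf_mann_whitney <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool); nx <- length(x)
  uof <- function(xx, yy) sum(outer(xx, yy, ">")) # U for first group
  uobs <- uof(x, y)
  idx <- utils::combn(n, nx)
  us <- apply(idx, 2, function(i) uof(pool[i], pool[-i]))
  min(1, 2 * min(mean(us <= uobs), mean(us >= uobs)))
}

# independent brute-force Fisher exact two-sided p over fixed margins
bf_fisher_exact <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - m2); hi <- min(c1, m1)
  probs <- vapply(lo:hi, function(aa) {
    exp(lchoose(m1, aa) + lchoose(m2, c1 - aa) - lchoose(m1 + m2, c1))
  }, numeric(1))
  pobs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# independent binomial log-likelihood from first principles (lchoose)
bf_binom_loglik <- function(y, N, f) {
  sum(lchoose(N, y) + y * log(f) + (N - y) * log(1 - f))
}

# brute-force ID83 classification by direct string scanning: builds the
# locus sequence and classifies by searching it, independent of encode_id83
bf_id83_label <- function(ref, alt, flank5, flank3) {
  is_del <- nchar(ref) > nchar(alt)
  long <- if (is_del) ref else alt
  motif <- substr(long, 2, nchar(long))
  L <- nchar(motif)
  reps_after <- function(mot, fl) {
    k <- 0
    while (substr(fl, k * nchar(mot) + 1, (k + 1) * nchar(mot)) == mot &&
           nchar(fl) >= (k + 1) * nchar(mot)) k <- k + 1
    k
  }
  if (L == 1) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    base <- if (motif %in% c("A", "G")) comp[[motif]] else motif
    r <- reps_after(motif, flank3)
    if (is_del) {
      hl <- min(r + 1, 6)
      paste0("1:Del:", base, ":", if (hl >= 6) "6+" else hl)
    } else {
      hl <- min(r, 5)
      paste0("1:Ins:", base, ":", if (hl >= 5) "5+" else hl)
    }
  } else {
    lcl <- if (L >= 5) "5+" else as.character(L)
    r <- reps_after(motif, flank3)
    if (!is_del) {
      u <- min(r, 5)
      paste0(lcl, ":Ins:R:", if (u >= 5) "5+" else u)
    } else if (r >= 1) {
      u <- min(r + 1, 6)
      paste0(lcl, ":Del:R:", if (u >= 6) "6+" else u)
    } else {
      mh <- 0
      for (k in seq_len(L - 1)) {
        if (substr(motif, 1, k) == substr(flank3, 1, k)) mh <- max(mh, k)
        if (substr(motif, L - k + 1, L) ==
            substr(flank5, nchar(flank5) - k + 1, nchar(flank5))) {
          mh <- max(mh, k)
        }
      }
      if (mh >= 1) {
        mhmax <- if (L >= 5) 5 else L - 1
        mh <- min(mh, mhmax)
        mlab <- if (L >= 5 && mh >= 5) "5+" else as.character(mh)
        paste0(lcl, ":Del:M:", mlab)
      } else {
        paste0(lcl, ":Del:R:1")
      }
    }
  }
}

skip_if_no_mclust <- function() {
  testthat::skip_if_not_installed("mclust")
}
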