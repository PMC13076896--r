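# The statistical tests used throughout the analysis, as reusable
# primitives: Fisher-Pitman permutation test (exact enumeration or Monte
# Carlo), Mann-Whitney, Fisher exact 2x2, Pearson/Spearman correlation.

new_test_result <- function(statistic, p_value, method, exact,
                            n_permutations = NA_integer_, estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-8)
  p_value <- min(p_value, 1)   # guard rounding overshoot in exact sums
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 exact = exact, n_permutations = n_permutations,
                 estimate = estimate),
            class = "clone_test")
}

#' @export
print.clone_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", signif(x$statistic, 5),
      " p =", signif(x$p_value, 5),
      if (isTRUE(x$exact)) sprintf(" (exact, %d assignments)", x$n_permutations)
      else if (!is.na(x$n_permutations)) sprintf(" (%d permutations)", x$n_permutations),
      "\n")
  invisible(x)
}

#' Two-sided Fisher-Pitman permutation test
#'
#' Statistic `T = mean(x) - mean(y)`. In exact mode all `choose(n, |x|)`
#' label assignments are enumerated (automatic when at most 200,000);
#' otherwise Monte Carlo with the observed assignment counted in both the
#' numerator and the denominator, guaranteeing `p > 0`. Two-sided p is the
#' fraction of assignments with `|T| >= |T_obs|`.
#'
#' @param x,y numeric group samples (non-empty).
#' @param mode "auto", "exact" or "monte_carlo".
#' @param n_perm Monte Carlo permutations (at least 100).
#' @param seed optional RNG seed for Monte Carlo.
#' @return a `clone_test` result.
#' @export
fisher_pitman <- function(x, y, mode = c("auto", "exact", "monte_carlo"),
                          n_perm = 10000, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  pool <- c(x, y)
  n <- length(pool); nx <- length(x)
  tobs <- mean(x) - mean(y)
  tol <- 1e-12 * max(1, abs(tobs))
  n_exact <- choose(n, nx)
  if (mode == "auto") mode <- if (n_exact <= 2e5) "exact" else "monte_carlo"
  if (mode == "exact") {
    if (n_exact > 2e5) stop("too many assignments for exact enumeration")
    idx <- combn(n, nx)
    tp <- colMeans(matrix(pool[idx], nrow = nx)) * (1 + nx / (n - nx)) -
      sum(pool) / (n - nx)
    p <- mean(abs(tp) >= abs(tobs) - tol)
    new_test_result(tobs, p, "Fisher-Pitman permutation test (two-sided)",
                    TRUE, as.integer(n_exact))
  } else {
    if (n_perm < 100) stop("n_perm must be at least 100")
    if (!is.null(seed)) set.seed(seed)
    tp <- vapply(seq_len(n_perm), function(b) {
      i <- sample.int(n, nx)
      mean(pool[i]) - mean(pool[-i])
    }, numeric(1))
    p <- (1 + sum(abs(tp) >= abs(tobs) - tol)) / (n_perm + 1)
    new_test_result(tobs, p, "Fisher-Pitman permutation test (two-sided)",
                    FALSE, as.integer(n_perm))
  }
}

#' Mann-Whitney U test
#'
#' Delegates to [stats::wilcox.test()]: exact when both groups are small
#' (`min(n) <= 8`) and untied, otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param x,y numeric group samples.
#' @param two_sided two-sided p (default) or greater-alternative.
#' @return a `clone_test` result (statistic = U for the first group).
#' @export
mann_whitney <- function(x, y, two_sided = TRUE) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = if (two_sided) "two.sided" else "greater",
                exact = exact, correct = TRUE))
  new_test_result(unname(wt$statistic), wt$p.value,
                  "Mann-Whitney U test", exact)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities, over tables with
#' the same margins, no larger than the observed table's (delegates to
#' [stats::fisher.test()]). A table with an all-zero margin returns p = 1
#' by convention, flagged via the `degenerate` field of the method string.
#'
#' @param a,b,c,d cell counts, row-wise.
#' @return a `clone_test` result (statistic = odds-ratio estimate).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  tab <- matrix(cells, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(new_test_result(NA_real_, 1,
                           "Fisher exact test (degenerate margin)", TRUE))
  }
  ft <- fisher.test(tab)
  new_test_result(unname(ft$estimate), ft$p.value,
                  "Fisher exact test (two-sided)", TRUE)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlation test (Pearson or Spearman)
#'
#' Pearson p by the t transform of r; Spearman (midrank ties) p by
#' permutation of one variable: exact enumeration for `n <= 7`, seeded
#' Monte Carlo otherwise (observed permutation included).
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @param method "pearson" or "spearman".
#' @param n_perm Monte Carlo permutations for Spearman.
#' @param seed RNG seed for the Monte Carlo path.
#' @return a `clone_test` result (statistic = r).
#' @export
correlation <- function(x, y, method = c("pearson", "spearman"),
                        n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  n <- length(x)
  if (method == "pearson") {
    r <- cor(x, y)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
    new_test_result(r, min(p, 1), "Pearson correlation (t test)", FALSE)
  } else {
    r <- cor(x, y, method = "spearman")
    rx <- rank(x); ry <- rank(y)
    tol <- 1e-12
    if (n <= 7) {
      perms <- all_permutations(n)
      rp <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
      p <- mean(abs(rp) >= abs(r) - tol)
      new_test_result(r, p, "Spearman correlation (exact permutation)",
                      TRUE, nrow(perms))
    } else {
      if (!is.null(seed)) set.seed(seed)
      rp <- vapply(seq_len(n_perm), function(b) cor(rx, ry[sample.int(n)]),
                   numeric(1))
      p <- (1 + sum(abs(rp) >= abs(r) - tol)) / (n_perm + 1)
      new_test_result(r, p, "Spearman correlation (permutation)", FALSE,
                      as.integer(n_perm))
    }
  }
}
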