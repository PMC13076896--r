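# Bulk-expression scoring: gene-set z-scores, the squamous-classical
# gradient score, ssGSEA-style rank enrichment (stromal/immune/ESTIMATE-like
# scores), constrained least-squares cell-fraction deconvolution, and PCA +
# k-means sample clustering.

log_tpm <- function(expr) log2(expr + 1)

#' Mean z-score of a gene set per sample
#'
#' Expression is log2(TPM+1) transformed, each gene z-scored across samples,
#' and the score is the mean z over the set genes present in the matrix.
#' Genes absent from the matrix are ignored; an empty intersection is an
#' error naming the missing genes.
#'
#' @param expr genes x samples TPM matrix.
#' @param set character vector of gene ids.
#' @return named per-sample score vector.
#' @export
gene_set_score <- function(expr, set) {
  present <- intersect(set, rownames(expr))
  if (!length(present)) {
    stop("no set genes present in matrix; missing: ",
         paste(head(set, 5), collapse = ", "))
  }
  lx <- log_tpm(expr[present, , drop = FALSE])
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1, sd)
  z <- (lx - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  colMeans(z)
}

#' Squamous-classical gradient score
#'
#' `gradient = score(squamous set) - score(classical set)`; higher scores
#' indicate squamous-like (more advanced) transcriptional character, lower
#' scores classical/progenitor-like character. Exactly antisymmetric under
#' swapping the two sets.
#'
#' @param expr genes x samples TPM matrix.
#' @param squamous_set,classical_set gene id vectors.
#' @return named per-sample score vector.
#' @export
gradient_score <- function(expr, squamous_set, classical_set) {
  gene_set_score(expr, squamous_set) - gene_set_score(expr, classical_set)
}

#' ssGSEA-style rank enrichment score
#'
#' Per sample, genes are ranked by expression (descending; ties broken by
#' gene-id order) and the score is the difference between the weighted ECDF
#' of set genes (weights `rank^exponent`) and the unweighted ECDF of
#' non-set genes, accumulated over the ranked list: summed by default (the
#' ssGSEA convention that ESTIMATE-style scores build on) or the maximum
#' deviation (`statistic = "max"`). Rank-based, hence invariant to monotone
#' transformations of expression within a sample.
#'
#' @param expr genes x samples matrix.
#' @param set gene id vector.
#' @param exponent rank weight exponent (default 0.25).
#' @param statistic "sum" or "max".
#' @return named per-sample enrichment score.
#' @export
ssgsea_score <- function(expr, set, exponent = 0.25,
                         statistic = c("sum", "max")) {
  statistic <- match.arg(statistic)
  present <- intersect(set, rownames(expr))
  if (!length(present)) stop("no set genes present in matrix")
  G <- nrow(expr)
  vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], rownames(expr))
    inset <- rownames(expr)[ord] %in% present
    r <- seq_len(G)                     # rank from top
    w <- (G - r + 1)^exponent           # high rank -> large weight
    win <- ifelse(inset, w, 0)
    Pin <- cumsum(win) / sum(win)
    Pout <- cumsum(!inset) / sum(!inset)
    dev <- Pin - Pout
    if (statistic == "sum") sum(dev) else dev[which.max(abs(dev))]
  }, numeric(1)) -> s
  setNames(s, colnames(expr))
}

#' Stromal, immune and ESTIMATE-like scores
#'
#' Rank-based enrichment ([ssgsea_score()]) of a stromal and an immune gene
#' set; the ESTIMATE-like score is their sum and summarizes non-tumor
#' content.
#'
#' @param expr genes x samples matrix.
#' @param stromal_set,immune_set gene id vectors.
#' @param ... passed to [ssgsea_score()].
#' @return data.frame with stromal, immune, estimate per sample.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, ...) {
  st <- ssgsea_score(expr, stromal_set, ...)
  im <- ssgsea_score(expr, immune_set, ...)
  data.frame(sample = colnames(expr), stromal = st, immune = im,
             estimate = st + im, row.names = NULL)
}

#' Cell-fraction deconvolution by constrained least squares
#'
#' Minimizes `||R w - g||^2` over `w >= 0`, `sum(w) <= 1` on the
#' reference-gene subspace; the remainder `1 - sum(w)` is reported as the
#' uncharacterized (tumor/epithelial) fraction. Collinear references are
#' ridge-stabilized with a warning.
#'
#' @param expr genes x samples matrix (or a single named vector).
#' @param reference_profiles genes x cell-types reference matrix (same
#'   expression scale as `expr`).
#' @param min_genes warn below this many shared genes.
#' @return data.frame: one row per sample, one column per cell type plus
#'   `uncharacterized`; rows sum to 1.
#' @export
deconvolve_fractions <- function(expr, reference_profiles, min_genes = 50) {
  if (is.null(dim(expr))) expr <- cbind(sample = expr)
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  }
  genes <- intersect(rownames(expr), rownames(reference_profiles))
  if (length(genes) < min_genes) {
    warning("only ", length(genes), " genes shared with the reference")
  }
  if (!length(genes)) stop("no genes shared with the reference")
  R <- as.matrix(reference_profiles[genes, , drop = FALSE])
  if (qr(R)$rank < ncol(R)) {
    warning("collinear reference profiles; ridge-stabilizing")
    R2 <- rbind(R, diag(1e-6 * max(abs(R)), ncol(R)))
  } else R2 <- NULL
  out <- matrix(0, ncol(expr), ncol(R) + 1,
                dimnames = list(colnames(expr),
                                c(colnames(R), "uncharacterized")))
  for (j in seq_len(ncol(expr))) {
    g <- as.numeric(expr[genes, j])
    if (is.null(R2)) {
      w <- pracma::lsqnonneg(R, g)$x
    } else {
      w <- pracma::lsqnonneg(R2, c(g, numeric(ncol(R))))$x
    }
    if (sum(w) > 1) {
      # re-solve with a heavily weighted sum-to-one row and a slack column
      lam <- 1e6 * max(abs(R), 1)
      A <- rbind(cbind(R, 0), lam * rep(1, ncol(R) + 1))
      ws <- pracma::lsqnonneg(A, c(g, lam))$x
      w <- ws[seq_len(ncol(R))]
      if (sum(w) > 1) w <- w / sum(w)
    }
    out[j, ] <- c(w, 1 - sum(w))
  }
  data.frame(sample = rownames(out), out, row.names = NULL,
             check.names = FALSE)
}

#' PCA + k-means clustering of expression samples
#'
#' PCA on z-scored log2(TPM+1) expression, k-means (10 restarts, fixed
#' seed) on the top principal components. When squamous/classical sets are
#' supplied, cluster labels are ordered by decreasing mean gradient score
#' (cluster 1 = most squamous-like); otherwise by decreasing cluster size.
#' Label order is invariant to sample permutation.
#'
#' @param expr genes x samples matrix.
#' @param n_clusters number of clusters (default 2).
#' @param n_pcs principal components to use (reduced with a warning if above
#'   the rank).
#' @param seed RNG seed for k-means.
#' @param squamous_set,classical_set optional gene sets for label ordering.
#' @return named integer cluster labels per sample.
#' @export
pca_cluster <- function(expr, n_clusters = 2, n_pcs = 10, seed = 1,
                        squamous_set = NULL, classical_set = NULL) {
  if (ncol(expr) < n_clusters) stop("fewer samples than clusters")
  orig <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
  expr <- expr[, order(orig), drop = FALSE]   # content-stable sample order
  lx <- log_tpm(expr)
  keep <- apply(lx, 1, sd) > 0
  z <- t(scale(t(lx[keep, , drop = FALSE])))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_pcs > rank) {
    warning("n_pcs reduced to the matrix rank (", rank, ")")
    n_pcs <- rank
  }
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  km <- kmeans(scores, centers = n_clusters, nstart = 10)
  lab <- km$cluster
  if (!is.null(squamous_set) && !is.null(classical_set)) {
    gs <- gradient_score(expr, squamous_set, classical_set)
    ord <- order(-vapply(seq_len(n_clusters),
                         function(k) mean(gs[lab == k]), numeric(1)))
  } else {
    ord <- order(-tabulate(lab, n_clusters),
                 vapply(seq_len(n_clusters), function(k) min(which(lab == k)),
                        numeric(1)))
  }
  relab <- integer(n_clusters); relab[ord] <- seq_len(n_clusters)
  setNames(relab[lab], colnames(expr))[orig]
}
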