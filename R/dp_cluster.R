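# Multi-dimensional Bayesian Dirichlet-process clustering of mutations by
# CCF across tumor regions (truncated stick-breaking, binomial likelihood,
# Gibbs sampling; compiled kernel in src/dp_gibbs.cpp).

#' Sampler controls for [dp_cluster()]
#'
#' @param n_iter,burn_in Gibbs iterations and burn-in.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param max_clusters truncation level of the stick-breaking prior.
#' @param ccf_grid_step grid step for cluster locations on `[0, ccf_max]`.
#' @param ccf_max upper bound of the CCF prior (cap).
#' @param min_cluster_frac clusters smaller than this fraction of mutations
#'   are dissolved and their members reassigned.
#' @param merge_dist consensus clusters whose CCFs differ by less than this
#'   in every region are merged (fragments of one mixture component; kept
#'   below the 0.08 separation that distinguishes real clusters).
#' @param concentration_alpha `"sample"` (Escobar-West update under a
#'   Gamma(1,1) prior) or a fixed positive value.
#' @param alpha_prior shape and rate of the Gamma prior on alpha.
#' @param seed integer seed; all sampler randomness flows from it.
#' @return list of class `dp_control`.
#' @export
dp_control <- function(n_iter = 2000, burn_in = 500, thin = 10,
                       max_clusters = 20, ccf_grid_step = 0.01,
                       ccf_max = 1.25, min_cluster_frac = 0.01,
                       merge_dist = 0.05,
                       concentration_alpha = "sample",
                       alpha_prior = c(1, 1), seed = NULL) {
  stopifnot(burn_in < n_iter, min_cluster_frac > 0, min_cluster_frac < 1,
            ccf_grid_step > 0, max_clusters >= 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 max_clusters = max_clusters, ccf_grid_step = ccf_grid_step,
                 ccf_max = ccf_max, min_cluster_frac = min_cluster_frac,
                 merge_dist = merge_dist,
                 concentration_alpha = concentration_alpha,
                 alpha_prior = alpha_prior, seed = seed),
            class = "dp_control")
}

vaf_coefficient <- function(purity, multiplicity, total_cn, n_normal = 2) {
  purity * multiplicity / (purity * total_cn + (1 - purity) * n_normal)
}

#' Run the Dirichlet-process Gibbs sampler
#'
#' Low-level interface returning the posterior trace; most users want
#' [dp_cluster()]. The likelihood is
#' `y_id ~ Binomial(N_id, pi_kd * c_id)` with
#' `c_id = rho_d m_id / (rho_d n_id + (1 - rho_d) 2)`; cluster locations
#' `pi_kd` live on a grid over `[0, ccf_max]`. Cells with `N = 0`
#' contribute no likelihood.
#'
#' @param y,N alt and total read count matrices (mutations x regions).
#' @param cmat matrix of linear VAF coefficients (same shape).
#' @param control a [dp_control()].
#' @return list of class `dpc_trace` with thinned assignment/location traces,
#'   the averaged co-clustering matrix, alpha trace and occupied-cluster
#'   counts.
#' @export
run_dp_gibbs <- function(y, N, cmat, control = dp_control()) {
  stopifnot(is.matrix(y), is.matrix(N), all(dim(y) == dim(N)),
            all(dim(cmat) == dim(y)))
  if (nrow(y) == 0) stop("no mutations to cluster")
  if (any(y > N)) stop("alt count exceeds depth")
  if (any(!is.finite(cmat))) stop("non-finite VAF coefficient (NaN likelihood)")
  if (!is.null(control$seed)) set.seed(control$seed)
  grid <- seq(0, control$ccf_max, by = control$ccf_grid_step)
  alpha0 <- if (identical(control$concentration_alpha, "sample")) 1
            else control$concentration_alpha
  # over-split, spatially coherent initialization: k-means on naive CCF
  # estimates, so the sampler starts split and only has to merge (truncated
  # Gibbs births new clusters slowly for subtly separated components)
  X <- ifelse(N > 0 & cmat > 0, (y / pmax(N, 1)) / pmax(cmat, 1e-9), 0)
  X <- pmin(X, control$ccf_max)
  ux <- unique(X)
  K0 <- min(control$max_clusters, nrow(ux))
  z0 <- tryCatch({
    ctr <- ux[sample.int(nrow(ux), K0), , drop = FALSE]
    kmeans(X, centers = ctr, iter.max = 30)$cluster - 1L
  }, error = function(e) seq_len(nrow(X)) %% control$max_clusters)
  res <- dp_gibbs_cpp(storage_int(y), storage_int(N), cmat, grid,
                      as.integer(control$max_clusters),
                      as.integer(control$n_iter),
                      as.integer(control$burn_in),
                      as.integer(control$thin),
                      alpha0,
                      identical(control$concentration_alpha, "sample"),
                      control$alpha_prior[1], control$alpha_prior[2],
                      as.integer(z0))
  res$grid <- grid
  res$control <- control
  res$data <- list(y = y, N = N, cmat = cmat)
  class(res) <- "dpc_trace"
  res
}

# Deterministic soft-EM refinement of a partition on the CCF grid.
# memb: 1..K row indices of ccf. Locations are kept as grid indices and the
# binomial terms come from precomputed log tables (the y*log(c) term and the
# binomial coefficient are constant across clusters/configurations and
# omitted, so log-likelihoods are comparable across candidate fits on the
# same data but are shifted relative to dbinom()). Returns the polished
# locations, mixture log-likelihood (shifted), and the hard assignment
# (max responsibility, first-index tie break).
em_polish <- function(y, N, cmat, memb, ccf, grid, max_iter = 30,
                      reg = NULL) {
  n <- nrow(y); D <- ncol(y); K <- nrow(ccf)
  w <- tabulate(memb, K) / n
  G <- length(grid)
  lg <- ifelse(grid > 0, log(pmax(grid, 1e-300)), -1e10)
  if (is.null(reg)) reg <- em_region_tables(y, N, cmat, grid)
  # locations as grid indices (nearest grid point to the supplied ccf)
  gidx <- matrix(pmin(pmax(round(ccf / (grid[2] - grid[1])) + 1L, 1L), G),
                 K, D)
  log_resp <- function(gidx, w) {
    L <- matrix(rep(log(pmax(w, 1e-12)), each = n), n, K)
    for (d in seq_len(D)) {
      r <- reg[[d]]
      if (!length(r$obs)) next
      for (k in seq_len(K)) {
        g <- gidx[k, d]
        L[r$obs, k] <- L[r$obs, k] + r$y * lg[g] + r$nd * r$Td[g, r$uic]
      }
    }
    L
  }
  for (iter in seq_len(max_iter)) {
    L <- log_resp(gidx, w)
    L <- L - L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
    R <- exp(L)
    R <- R / rowSums(R)
    wnew <- colMeans(R)
    gnew <- gidx
    for (d in seq_len(D)) {
      r <- reg[[d]]
      if (!length(r$obs)) next
      for (k in seq_len(K)) {
        if (wnew[k] <= 1e-9) next
        rw <- R[r$obs, k]
        Ysum <- sum(rw * r$y)
        Sv <- rowsum(r$nd * rw, r$uic)[, 1]
        llg <- as.numeric(r$Td %*% Sv) + Ysum * lg
        gnew[k, d] <- which.max(llg)
      }
    }
    moved <- max(abs(gnew - gidx))
    dw <- max(abs(wnew - w))
    gidx <- gnew; w <- wnew
    if (moved == 0 && dw < 1e-3) break
  }
  L <- log_resp(gidx, w)
  mx <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
  loglik <- sum(mx + log(rowSums(exp(L - mx))))
  memb <- max.col(L, ties.method = "first")
  list(memb = memb, ccf = matrix(grid[gidx], K, D), w = w, loglik = loglik,
       k_eff = length(unique(memb)))
}

# Per-region lookup tables shared across em_polish calls on the same data:
# observed rows, alt/ref counts, unique-VAF-coefficient codes and the
# G x U table log1p(-grid * c_u).
em_region_tables <- function(y, N, cmat, grid) {
  lapply(seq_len(ncol(y)), function(d) {
    obs <- which(N[, d] > 0)
    cf <- round(cmat[obs, d], 10)
    fac <- factor(cf)
    uv <- as.numeric(levels(fac))
    list(obs = obs, y = y[obs, d], nd = N[obs, d] - y[obs, d],
         uic = as.integer(fac),
         Td = log1p(-pmin(outer(grid, uv), 1 - 1e-9)))
  })
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Consensus clustering from a posterior trace
#'
#' Average-linkage hierarchical clustering on 1 minus the posterior
#' co-clustering matrix supplies candidate partitions: the cut at
#' dissimilarity 0.5 plus cuts at cluster numbers spanning the posterior
#' range of occupied clusters (single-site Gibbs samplers mix slowly across
#' cluster births, so the posterior can under-split overlapping
#' components). Each candidate is refined by a deterministic soft-EM pass
#' on the location grid and the refined fits are compared by penalized
#' log-likelihood (one location per region plus one weight per cluster).
#' Clusters below `min_cluster_frac` of the mutations are dissolved and
#' their members reassigned; clusters whose locations agree within
#' `merge_dist` in every region are merged. Per-cluster credible intervals
#' come from the posterior location samples of the final members.
#'
#' @param trace a `dpc_trace` from [run_dp_gibbs()].
#' @param control a [dp_control()]; defaults to the one stored in the trace.
#' @return list with assignment, cluster_ccf, cluster_size, ccf_lo, ccf_hi.
#' @export
consense_clusters <- function(trace, control = trace$control) {
  if (!inherits(trace, "dpc_trace")) stop("need a dpc_trace")
  if (trace$n_kept < 1) stop("empty trace")
  co <- trace$coclustering
  n <- nrow(co)
  zt <- trace$z_trace
  pt <- trace$pi_trace
  D <- dim(pt)[3]
  y <- trace$data$y; N <- trace$data$N; cmat <- trace$data$cmat
  grid <- trace$grid

  # posterior location samples of a member set (for credible intervals);
  # capped at 50 members per cluster -- the member-location distribution is
  # already an average over mutations, more adds nothing
  nit <- nrow(zt); K <- dim(pt)[2]
  ci_of <- function(members) {
    mem <- members[unique(round(seq(1, length(members),
                                    length.out = min(50, length(members)))))]
    lin0 <- rep(seq_len(nit), length(mem)) +
      nit * (as.vector(zt[, mem, drop = FALSE]) - 1L)
    t(vapply(seq_len(D), function(d) {
      quantile(pt[lin0 + nit * K * (d - 1L)], c(0.025, 0.975))
    }, numeric(2)))   # D x 2
  }

  # naive per-mutation CCF estimates for centroid initialization
  X <- ifelse(N > 0 & cmat > 0, (y / pmax(N, 1)) / pmax(cmat, 1e-9), NA)
  X <- pmin(X, max(grid))
  centroid0 <- function(memb) {
    ids <- sort(unique(memb))
    cc <- t(vapply(ids, function(k) {
      v <- colMeans(X[memb == k, , drop = FALSE], na.rm = TRUE)
      v[!is.finite(v)] <- 0
      pmin(pmax(v, 0), max(grid))
    }, numeric(D)))
    list(ids = ids, ccf = cc)
  }

  if (n == 1) {
    memb <- 1L
    ccf <- matrix(pmin(ifelse(is.finite(X[1, ]), X[1, ], 0), max(grid)),
                  1, D)
    lo <- hi <- ccf
    size <- 1L
  } else {
    X0 <- X; X0[!is.finite(X0)] <- 0
    # start from the 0.5 co-clustering cut, EM-polish, then hill-climb the
    # penalized likelihood with split and merge moves (EM alone is local;
    # single-site Gibbs under-splits, so both directions are needed).
    # For large n the dendrogram is seeded from a stratified subsample;
    # the EM E-step assigns every mutation regardless.
    if (n > 1500) {
      sub <- unique(round(seq(1, n, length.out = 1500)))
      hc <- hclust(as.dist(1 - co[sub, sub]), method = "average")
      cand_sub <- cutree(hc, h = 0.5)
      ctr <- t(vapply(sort(unique(cand_sub)), function(k) {
        v <- colMeans(X0[sub[cand_sub == k], , drop = FALSE])
        v[!is.finite(v)] <- 0
        v
      }, numeric(D)))
      d2 <- vapply(seq_len(nrow(ctr)), function(k) {
        rowSums(sweep(X0, 2, ctr[k, ])^2)
      }, numeric(n))
      cand <- max.col(-d2, ties.method = "first")
    } else {
      hc <- hclust(as.dist(1 - co), method = "average")
      cand <- cutree(hc, h = 0.5)
    }
    c0 <- centroid0(cand)
    reg <- em_region_tables(y, N, cmat, grid)
    pol <- em_polish(y, N, cmat, match(cand, c0$ids), c0$ccf, grid,
                     reg = reg)
    best <- split_merge_refine(y, N, cmat, X0, pol, grid,
                               penalty_per_cluster(D, n),
                               max_k = control$max_clusters, reg = reg)
    selection <- best$selection
    memb <- best$pol$memb
    ids <- sort(unique(memb))
    ccf <- best$pol$ccf[ids, , drop = FALSE]
    size <- as.integer(table(factor(memb, levels = ids)))
    memb <- match(memb, ids)

    # dissolve small clusters: reassign members to the nearest retained
    # cluster in CCF space (by their naive CCF estimate)
    keep <- size >= control$min_cluster_frac * n
    if (!any(keep)) keep[which.max(size)] <- TRUE
    if (!all(keep)) {
      kept <- which(keep)
      for (i in which(memb %in% which(!keep))) {
        xi <- X[i, ]
        obs <- is.finite(xi)
        d2 <- rowSums((ccf[kept, obs, drop = FALSE] -
                         matrix(xi[obs], length(kept), sum(obs),
                                byrow = TRUE))^2)
        memb[i] <- kept[which.min(d2)]
      }
      ccf <- ccf[keep, , drop = FALSE]
      memb <- match(memb, kept)
      size <- as.integer(table(factor(memb, levels = seq_len(sum(keep)))))
    }

    # merge clusters agreeing within merge_dist in every region (fragments)
    md <- control$merge_dist %||% 0
    if (md > 0) {
      repeat {
        if (nrow(ccf) < 2) break
        dm <- as.matrix(dist(ccf, method = "maximum"))
        diag(dm) <- Inf
        if (min(dm) >= md) break
        w <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        a <- min(w); b <- max(w)
        ccf[a, ] <- (size[a] * ccf[a, ] + size[b] * ccf[b, ]) /
          (size[a] + size[b])
        memb[memb == b] <- a
        size[a] <- size[a] + size[b]
        ccf <- ccf[-b, , drop = FALSE]
        size <- size[-b]
        memb[memb > b] <- memb[memb > b] - 1L
      }
    }

    cis <- lapply(seq_len(nrow(ccf)), function(k) ci_of(which(memb == k)))
    lo <- t(vapply(cis, function(ci) ci[, 1], numeric(D)))
    hi <- t(vapply(cis, function(ci) ci[, 2], numeric(D)))
  }

  # order clusters by decreasing total CCF, relabel C1..CK
  ord <- order(-rowSums(ccf))
  relab <- integer(nrow(ccf)); relab[ord] <- seq_len(nrow(ccf))
  memb <- relab[memb]
  ccf <- ccf[ord, , drop = FALSE]
  lo <- lo[ord, , drop = FALSE]
  hi <- hi[ord, , drop = FALSE]
  size <- size[ord]
  labs <- paste0("C", seq_len(nrow(ccf)))
  rownames(ccf) <- rownames(lo) <- rownames(hi) <- labs
  out <- list(assignment = as.integer(memb),
              cluster_ccf = ccf, ccf_lo = lo, ccf_hi = hi,
              cluster_size = setNames(size, labs))
  if (exists("selection", inherits = FALSE)) out$selection <- selection
  out
}

# per-cluster penalty for candidate-partition selection: each cluster
# carries D grid locations and a weight; the log(n)/2 term guards against
# noise splits surviving the move search (selection over many candidate
# moves inflates spurious likelihood gains beyond the plain AIC charge)
penalty_per_cluster <- function(D, n) (D + 1) + log(n) / 2

# Hill-climb the penalized mixture likelihood with split and merge moves.
# pol: an em_polish() result (memb indexes rows of pol$ccf). Splits use
# 2-means on the members' naive CCF estimates; merges try the closest
# cluster pairs. Deterministic.
split_merge_refine <- function(y, N, cmat, X0, pol, grid, penalty,
                               max_k = 20, max_rounds = 12, reg = NULL) {
  if (is.null(reg)) reg <- em_region_tables(y, N, cmat, grid)
  D <- ncol(y)
  score_of <- function(p) p$loglik - penalty * p$k_eff
  compact <- function(p) {
    # drop empty rows, renumber membership
    ids <- sort(unique(p$memb))
    p$ccf <- p$ccf[ids, , drop = FALSE]
    p$memb <- match(p$memb, ids)
    p$k_eff <- length(ids)
    p
  }
  cur <- compact(pol)
  sel <- list(data.frame(move = "init", k_eff = cur$k_eff,
                         loglik = cur$loglik,
                         score = score_of(cur)))
  for (round in seq_len(max_rounds)) {
    K <- nrow(cur$ccf)
    moves <- list()
    # split candidates: 2-means on each cluster's naive CCFs
    if (K < max_k) {
      for (k in seq_len(K)) {
        mem <- which(cur$memb == k)
        if (length(mem) < 4) next
        ux <- unique(X0[mem, , drop = FALSE])
        if (nrow(ux) < 2) next
        j <- which.max(apply(ux, 2, var))
        ctr <- ux[c(which.min(ux[, j]), which.max(ux[, j])), , drop = FALSE]
        km <- tryCatch(
          kmeans(X0[mem, , drop = FALSE], centers = ctr,
                 iter.max = 20)$cluster,
          error = function(e) NULL)
        if (is.null(km) || length(unique(km)) < 2) next
        memb2 <- cur$memb
        memb2[mem[km == 2]] <- K + 1L
        ccf2 <- rbind(cur$ccf,
                      pmin(pmax(colMeans(X0[mem[km == 2], , drop = FALSE]),
                                0), max(grid)))
        moves[[length(moves) + 1]] <- list(memb = memb2, ccf = ccf2,
                                           move = "split")
      }
    }
    # merge candidates: the closest pairs in max-metric CCF distance
    if (K > 1) {
      dm <- as.matrix(dist(cur$ccf, method = "maximum"))
      dm[upper.tri(dm, diag = TRUE)] <- Inf
      ord <- order(dm)[seq_len(min(3, sum(is.finite(dm))))]
      for (o in ord) {
        ij <- arrayInd(o, dim(dm))
        memb2 <- cur$memb
        memb2[memb2 == ij[1]] <- ij[2]
        moves[[length(moves) + 1]] <- list(memb = memb2, ccf = cur$ccf,
                                           move = "merge")
      }
    }
    if (!length(moves)) break
    cand_best <- NULL
    for (mv in moves) {
      ids <- sort(unique(mv$memb))
      p <- em_polish(y, N, cmat, match(mv$memb, ids),
                     mv$ccf[ids, , drop = FALSE], grid, max_iter = 8,
                     reg = reg)
      p <- compact(p)
      if (is.null(cand_best) || score_of(p) > score_of(cand_best)) {
        cand_best <- p
        cand_best$move <- mv$move
      }
    }
    if (score_of(cand_best) > score_of(cur) + 1e-6) {
      cur <- cand_best
      sel[[length(sel) + 1]] <- data.frame(move = cand_best$move,
                                           k_eff = cur$k_eff,
                                           loglik = cur$loglik,
                                           score = score_of(cur))
    } else break
  }
  # final full polish
  cur <- compact(em_polish(y, N, cmat, cur$memb, cur$ccf, grid, reg = reg))
  list(pol = cur, score = score_of(cur), selection = do.call(rbind, sel))
}

#' Cluster mutations by CCF across regions
#'
#' Fits a truncated Dirichlet-process binomial mixture to multi-region alt/
#' depth counts and returns the consensus clustering. Mutations are
#' internally sorted by content before sampling, so the result is invariant
#' to input row order (same seed). Below 50 mutations the model is not
#' identifiable at typical depths; a single-cluster maximum-likelihood fit
#' is returned with a warning.
#'
#' @param alt,depth mutations x regions matrices of alt and total read
#'   counts (`depth = 0` marks a region where the site was not assessable).
#' @param purity per-region purity vector.
#' @param multiplicity,total_cn mutation multiplicities and locus total copy
#'   numbers (matrices like `alt`, or vectors recycled across regions).
#' @param control a [dp_control()].
#' @return object of class `dpc` with elements assignment, cluster_ccf,
#'   cluster_size, ccf_lo/ccf_hi, alpha trace summary, the input data and
#'   control. Methods: print, summary, coef, logLik, plot.
#' @export
dp_cluster <- function(alt, depth, purity, multiplicity = 1, total_cn = 2,
                       control = dp_control()) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt); D <- ncol(alt)
  if (n == 0) stop("no mutations to cluster")
  if (D < 2) warning("fewer than 2 regions: one-dimensional clustering")
  stopifnot(length(purity) == D)
  expand <- function(x) {
    if (is.matrix(x)) x else matrix(x, n, D)
  }
  m <- expand(multiplicity); nt <- expand(total_cn)
  cmat <- sweep(m / (sweep(nt, 2, purity, "*") +
                       outer(rep(1, n), (1 - purity) * 2)), 2, purity, "*")
  cmat[depth == 0] <- 0
  usable <- rowSums(depth) > 0
  if (!all(usable)) {
    warning(sum(!usable), " mutation(s) with zero depth everywhere dropped")
  }
  ids <- rownames(alt) %||% as.character(seq_len(n))

  if (sum(usable) < 50) {
    warning("fewer than 50 mutations: falling back to a single-cluster fit")
    y <- alt[usable, , drop = FALSE]; N <- depth[usable, , drop = FALSE]
    cm <- cmat[usable, , drop = FALSE]
    pi_hat <- vapply(seq_len(D), function(d) {
      denom <- sum(N[, d] * cm[, d])
      if (denom <= 0) return(0)
      min(sum(y[, d]) / denom, control$ccf_max)
    }, numeric(1))
    ccf <- matrix(pi_hat, 1, D, dimnames = list("C1", colnames(alt)))
    sol <- list(assignment = setNames(rep(1L, sum(usable)), ids[usable]),
                cluster_ccf = ccf, ccf_lo = ccf, ccf_hi = ccf,
                cluster_size = c(C1 = sum(usable)))
  } else {
    y <- alt[usable, , drop = FALSE]; N <- depth[usable, , drop = FALSE]
    cm <- cmat[usable, , drop = FALSE]
    key <- do.call(order, c(as.data.frame(cbind(y, N, round(cm, 10))),
                            list(method = "radix")))
    trace <- run_dp_gibbs(y[key, , drop = FALSE], N[key, , drop = FALSE],
                          cm[key, , drop = FALSE], control)
    sol <- consense_clusters(trace, control)
    inv <- integer(length(key)); inv[key] <- seq_along(key)
    sol$assignment <- setNames(sol$assignment[inv], ids[usable])
    sol$alpha <- c(mean = mean(trace$alpha_trace),
                   sd = sd(trace$alpha_trace))
    sol$k_occupied <- trace$k_occupied
  }
  colnames(sol$cluster_ccf) <- colnames(alt) %||% paste0("R", seq_len(D))
  colnames(sol$ccf_lo) <- colnames(sol$ccf_hi) <- colnames(sol$cluster_ccf)
  sol$data <- list(alt = alt[usable, , drop = FALSE],
                   depth = depth[usable, , drop = FALSE],
                   cmat = cmat[usable, , drop = FALSE])
  sol$control <- control
  class(sol) <- "dpc"
  sol
}

#' Binomial log-likelihood of a cluster solution
#'
#' Sum of binomial log-likelihoods of all observed counts at their assigned
#' cluster CCFs. Deterministic; permutation-invariant.
#'
#' @param solution a `dpc` object (or list with assignment + cluster_ccf).
#' @param data optional list with alt, depth, cmat matrices (defaults to the
#'   data stored in the solution).
#' @return log-likelihood (numeric scalar).
#' @export
solution_loglik <- function(solution, data = solution$data) {
  y <- data$alt; N <- data$depth; cm <- data$cmat
  z <- solution$assignment
  ll <- 0
  for (d in seq_len(ncol(y))) {
    f <- pmin(solution$cluster_ccf[z, d] * cm[, d], 1 - 1e-9)
    obs <- N[, d] > 0
    ll <- ll + sum(dbinom(y[obs, d], N[obs, d], pmax(f[obs], 1e-12), log = TRUE))
  }
  ll
}

#' @export
logLik.dpc <- function(object, ...) {
  structure(solution_loglik(object),
            df = length(object$cluster_size) * ncol(object$cluster_ccf),
            class = "logLik")
}

#' @export
coef.dpc <- function(object, ...) object$cluster_ccf

#' @export
print.dpc <- function(x, ...) {
  cat("Dirichlet-process CCF clustering\n")
  cat(sprintf("  %d mutations, %d regions, %d retained clusters\n",
              length(x$assignment), ncol(x$cluster_ccf),
              nrow(x$cluster_ccf)))
  tab <- cbind(n = x$cluster_size, round(x$cluster_ccf, 3))
  print(tab)
  invisible(x)
}

#' @export
summary.dpc <- function(object, ...) {
  structure(list(ccf = object$cluster_ccf, lo = object$ccf_lo,
                 hi = object$ccf_hi, size = object$cluster_size,
                 alpha = object$alpha, loglik = solution_loglik(object)),
            class = "summary.dpc")
}

#' @export
print.summary.dpc <- function(x, ...) {
  cat("Cluster CCFs (posterior medians, 95% CI):\n")
  for (k in rownames(x$ccf)) {
    cat(" ", k, sprintf("(n=%d):", x$size[[k]]),
        paste(sprintf("%.2f [%.2f,%.2f]", x$ccf[k, ], x$lo[k, ], x$hi[k, ]),
              collapse = "  "), "\n")
  }
  if (!is.null(x$alpha)) {
    cat(sprintf("  alpha: %.2f (sd %.2f)\n", x$alpha[["mean"]], x$alpha[["sd"]]))
  }
  cat(sprintf("  log-likelihood: %.1f\n", x$loglik))
  invisible(x)
}

#' Plot observed CCFs colored by cluster
#'
#' Scatter of per-mutation naive CCF estimates (first two regions) colored
#' by consensus cluster, with cluster centers.
#'
#' @param x a `dpc` object.
#' @param regions indices of the two regions to display.
#' @param ... ignored.
#' @export
plot.dpc <- function(x, regions = c(1, 2), ...) {
  y <- x$data$alt; N <- x$data$depth; cm <- x$data$cmat
  d1 <- regions[1]; d2 <- regions[min(2, length(regions))]
  obs_ccf <- function(d) {
    out <- ifelse(N[, d] > 0 & cm[, d] > 0, (y[, d] / pmax(N[, d], 1)) / cm[, d], 0)
    pmin(out, x$control$ccf_max)
  }
  cols <- hcl.colors(max(x$assignment), "Dark 3")
  plot(obs_ccf(d1), obs_ccf(d2), col = cols[x$assignment], pch = 16,
       cex = 0.6, xlab = colnames(x$cluster_ccf)[d1],
       ylab = colnames(x$cluster_ccf)[d2], main = "CCF clusters")
  points(x$cluster_ccf[, d1], x$cluster_ccf[, d2], pch = 3, cex = 2, lwd = 2)
  invisible(x)
}
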