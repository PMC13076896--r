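# Clone-tree reconstruction from clustered CCFs.
#
# Placement rules: a cluster's candidate parent is the smallest (by total
# CCF) already-placed cluster that dominates it within epsilon in every
# region (pigeonhole/nesting); two clusters whose CCF ordering flips between
# regions beyond epsilon (crossing) are never placed on one lineage; sibling
# CCFs must respect the sum rule (children sum <= parent + epsilon per
# region), enforced greedily by attaching in decreasing total-CCF order and
# escalating to an ancestor when violated.

new_clone_tree <- function(nodes, parent, ccf, size, annotations = NULL,
                           flags = NULL) {
  stopifnot(length(nodes) == nrow(ccf), length(parent) == length(nodes))
  structure(list(nodes = nodes,
                 parent = setNames(parent, nodes),
                 ccf = ccf,
                 size = setNames(size, nodes),
                 annotations = annotations %||%
                   setNames(vector("list", length(nodes)), nodes),
                 flags = flags %||% setNames(rep("", length(nodes)), nodes)),
            class = "clone_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tree_children <- function(tree, node) {
  tree$nodes[!is.na(tree$parent) & tree$parent == node]
}

tree_roots <- function(tree) tree$nodes[is.na(tree$parent)]

tree_ancestors <- function(tree, node) {
  out <- character()
  p <- tree$parent[[node]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[[p]]
  }
  out
}

#' Identify the clonal (trunk) cluster in each region
#'
#' Per region, the cluster with maximal CCF among clusters with CCF at
#' least `1 - clonal_tol`. If no cluster qualifies, the maximal-CCF cluster
#' is returned flagged `pseudo_clonal`.
#'
#' @param solution a [dp_cluster()] solution (or any object with a
#'   `cluster_ccf` matrix, clusters x regions).
#' @param clonal_tol tolerance below CCF 1 (default 0.1).
#' @return data.frame with region, cluster, ccf, pseudo_clonal.
#' @export
identify_clonal_clusters <- function(solution, clonal_tol = 0.1) {
  ccf <- solution$cluster_ccf
  regions <- colnames(ccf) %||% paste0("R", seq_len(ncol(ccf)))
  out <- lapply(seq_len(ncol(ccf)), function(d) {
    qual <- which(ccf[, d] >= 1 - clonal_tol)
    if (length(qual)) {
      k <- qual[which.max(ccf[qual, d])]
      data.frame(region = regions[d], cluster = rownames(ccf)[k],
                 ccf = ccf[k, d], pseudo_clonal = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      k <- which.max(ccf[, d])
      data.frame(region = regions[d], cluster = rownames(ccf)[k],
                 ccf = ccf[k, d], pseudo_clonal = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

sum_rule_ok <- function(ccf, parent_idx, child_idx_set, eps) {
  if (!length(child_idx_set)) return(TRUE)
  kid_sum <- colSums(ccf[child_idx_set, , drop = FALSE])
  all(kid_sum <= ccf[parent_idx, ] + eps)
}

#' Build a clone forest from a cluster solution
#'
#' Applies the nesting (pigeonhole), crossing and sum rules (see file
#' header) to place every retained cluster in a rooted forest. Deterministic
#' given the solution. Clusters for which no consistent placement exists
#' become roots with a warning flag rather than being dropped.
#'
#' @param solution a [dp_cluster()] solution, or a list with elements
#'   `cluster_ccf` (clusters x regions matrix with dimnames) and
#'   `cluster_size` (named counts).
#' @param eps CCF tolerance (default 0.05; comfortably above cluster-level
#'   CCF standard errors at 80X yet below the 0.08 separation the generator
#'   guarantees between crossing clusters).
#' @return a `clone_tree` object.
#' @export
build_forest <- function(solution, eps = 0.05) {
  ccf <- solution$cluster_ccf
  if (is.null(rownames(ccf))) rownames(ccf) <- paste0("C", seq_len(nrow(ccf)))
  size <- solution$cluster_size %||% setNames(rep(1L, nrow(ccf)), rownames(ccf))
  nodes <- rownames(ccf)
  K <- length(nodes)
  parent <- setNames(rep(NA_character_, K), nodes)
  flags <- setNames(rep("", K), nodes)
  ord <- order(-rowSums(ccf), nodes)   # decreasing total CCF, stable
  placed <- character()

  tree_stub <- function() new_clone_tree(nodes, parent, ccf, size)

  for (b in ord) {
    bn <- nodes[b]
    if (!length(placed)) { placed <- c(placed, bn); next }
    # candidates: placed clusters dominating b within eps in every region
    dom <- vapply(placed, function(an) {
      all(ccf[an, ] >= ccf[bn, ] - eps)
    }, logical(1))
    cand <- placed[dom]
    if (!length(cand)) { placed <- c(placed, bn); next }  # new root
    cand <- cand[order(rowSums(ccf[cand, , drop = FALSE]),
                       match(cand, nodes))]  # smallest total CCF first
    chosen <- NA_character_
    for (an in cand) {
      kids <- nodes[!is.na(parent) & parent == an]
      if (sum_rule_ok(ccf, an, match(c(kids, bn), nodes), eps)) {
        chosen <- an; break
      }
      # escalate along ancestors of an that still dominate b
      p <- parent[[an]]
      while (!is.na(p)) {
        kids <- nodes[!is.na(parent) & parent == p]
        if (all(ccf[p, ] >= ccf[bn, ] - eps) &&
            sum_rule_ok(ccf, match(p, nodes), match(c(kids, bn), nodes), eps)) {
          chosen <- p; break
        }
        p <- parent[[p]]
      }
      if (!is.na(chosen)) break
    }
    if (is.na(chosen)) {
      flags[bn] <- "unplaced_root"
      warning("no consistent placement for cluster ", bn,
              "; attached as root", call. = FALSE)
    } else {
      parent[bn] <- chosen
    }
    placed <- c(placed, bn)
  }
  new_clone_tree(nodes, parent, ccf, size, flags = flags)
}

#' Audit the sum (pigeonhole) rule on a clone tree
#'
#' @param tree a `clone_tree`.
#' @param eps tolerance.
#' @return number of (node, region) violations (0 for a valid tree).
#' @export
audit_sum_rule <- function(tree, eps = 0.05) {
  bad <- 0L
  for (nd in tree$nodes) {
    kids <- tree_children(tree, nd)
    if (!length(kids)) next
    kid_sum <- colSums(tree$ccf[kids, , drop = FALSE])
    bad <- bad + sum(kid_sum > tree$ccf[nd, ] + eps)
  }
  bad
}

#' Classify the evolutionary trajectory of a clone tree
#'
#' `multiple_mrca` iff the forest has 2 or more roots; `branching` iff some
#' node has 2 or more children, otherwise `linear`.
#'
#' @param tree a `clone_tree`.
#' @return list with mrca_pattern, growth_pattern, n_roots, root region
#'   support.
#' @export
classify_trajectory <- function(tree) {
  roots <- tree_roots(tree)
  nkid <- vapply(tree$nodes, function(nd) length(tree_children(tree, nd)),
                 integer(1))
  support <- lapply(roots, function(r) {
    colnames(tree$ccf)[tree$ccf[r, ] > 0.05]
  })
  names(support) <- roots
  list(mrca_pattern = if (length(roots) >= 2) "multiple_mrca" else "single_mrca",
       growth_pattern = if (any(nkid >= 2)) "branching" else "linear",
       n_roots = length(roots),
       root_support = support)
}

#' Exclusive subclone fractions in one region (oval-plot fractions)
#'
#' `fraction(node) = CCF(node) - sum(CCF(children))` in the region;
#' negatives within `eps` are clipped to 0.
#'
#' @param tree a `clone_tree`.
#' @param region region id (column of the CCF matrix).
#' @param eps tolerance; sum-rule violations beyond it are an error.
#' @return named vector of exclusive fractions.
#' @export
subclone_fractions <- function(tree, region, eps = 0.05) {
  ccf <- tree$ccf[, region]
  out <- setNames(numeric(length(tree$nodes)), tree$nodes)
  for (nd in tree$nodes) {
    kids <- tree_children(tree, nd)
    f <- ccf[[nd]] - if (length(kids)) sum(ccf[kids]) else 0
    if (f < -eps) stop("sum-rule violation at node ", nd, " in ", region)
    out[nd] <- max(f, 0)
  }
  out
}

#' Compare SV burden between branching and linear cases
#'
#' Groups regions by the growth pattern of their case's tree and compares
#' per-region SV counts with a two-sided Fisher-Pitman permutation test.
#'
#' @param trees named list of `clone_tree` objects (one per case).
#' @param sv_counts data.frame with columns case_id, region_id, n_sv.
#' @param ... passed to [fisher_pitman()].
#' @return list with group means, group sizes and the test result.
#' @export
compare_sv_burden_by_pattern <- function(trees, sv_counts, ...) {
  growth <- vapply(trees, function(t) classify_trajectory(t)$growth_pattern,
                   character(1))
  sv_counts$growth <- growth[sv_counts$case_id]
  x <- sv_counts$n_sv[sv_counts$growth == "branching"]
  y <- sv_counts$n_sv[sv_counts$growth == "linear"]
  if (!length(x) || !length(y)) stop("a growth-pattern group is empty")
  res <- fisher_pitman(x, y, ...)
  list(mean_branching = mean(x), mean_linear = mean(y),
       n_branching = length(x), n_linear = length(y), test = res)
}

#' @export
print.clone_tree <- function(x, ...) {
  traj <- classify_trajectory(x)
  cat("Clone tree:", length(x$nodes), "clusters,",
      traj$n_roots, "root(s);", traj$mrca_pattern, "/",
      traj$growth_pattern, "\n")
  for (r in tree_roots(x)) print_subtree(x, r, 0)
  invisible(x)
}

print_subtree <- function(tree, node, depth) {
  cat(strrep("  ", depth), "- ", node, " (n=", tree$size[[node]], "; CCF ",
      paste(sprintf("%.2f", tree$ccf[node, ]), collapse = "/"), ")",
      if (nzchar(tree$flags[[node]])) paste0(" [", tree$flags[[node]], "]"),
      "\n", sep = "")
  for (k in tree_children(tree, node)) print_subtree(tree, k, depth + 1)
}

#' @export
summary.clone_tree <- function(object, ...) {
  traj <- classify_trajectory(object)
  structure(list(trajectory = traj,
                 n_clusters = length(object$nodes),
                 sizes = object$size,
                 sum_rule_violations = audit_sum_rule(object)),
            class = "summary.clone_tree")
}

#' @export
print.summary.clone_tree <- function(x, ...) {
  cat("Clusters:", x$n_clusters, "\nTrajectory:", x$trajectory$mrca_pattern,
      "/", x$trajectory$growth_pattern,
      "\nSum-rule violations:", x$sum_rule_violations, "\n")
  invisible(x)
}

#' Plot a clone tree
#'
#' Simple layout: depth on the y axis, branch lengths proportional to
#' SNV+indel counts, node labels with cluster ids.
#'
#' @param x a `clone_tree`.
#' @param ... ignored.
#' @export
plot.clone_tree <- function(x, ...) {
  # x positions by leaf order, y by cumulative branch length
  leaves <- x$nodes[vapply(x$nodes, function(n) !length(tree_children(x, n)),
                           logical(1))]
  xs <- setNames(rep(NA_real_, length(x$nodes)), x$nodes)
  xs[leaves] <- seq_along(leaves)
  fill_x <- function(node) {
    kids <- tree_children(x, node)
    if (!length(kids)) return(xs[[node]])
    v <- vapply(kids, fill_x, numeric(1))
    xs[[node]] <<- mean(v)
    xs[[node]]
  }
  for (r in tree_roots(x)) fill_x(r)
  ys <- setNames(rep(0, length(x$nodes)), x$nodes)
  assign_y <- function(node, y0) {
    ys[[node]] <<- y0 + x$size[[node]]
    for (k in tree_children(x, node)) assign_y(k, ys[[node]])
  }
  for (r in tree_roots(x)) assign_y(r, 0)
  plot(NA, xlim = range(xs) + c(-0.5, 0.5), ylim = c(max(ys) * 1.05, 0),
       xlab = "", ylab = "SNVs + indels from root", xaxt = "n",
       main = "Clone tree")
  for (nd in x$nodes) {
    p <- x$parent[[nd]]
    y0 <- if (is.na(p)) 0 else ys[[p]]
    x0 <- if (is.na(p)) xs[[nd]] else xs[[p]]
    segments(x0, y0, xs[[nd]], ys[[nd]])
    points(xs[[nd]], ys[[nd]], pch = 19)
    text(xs[[nd]], ys[[nd]], nd, pos = 4, cex = 0.8)
  }
  invisible(x)
}

# ---- serialization -------------------------------------------------------

newick_subtree <- function(tree, node) {
  kids <- tree_children(tree, node)
  inner <- if (length(kids)) {
    paste0("(", paste(vapply(kids, function(k) newick_subtree(tree, k),
                             character(1)), collapse = ","), ")")
  } else ""
  paste0(inner, node, ":", tree$size[[node]])
}

#' Write a clone tree to Newick or annotated JSON
#'
#' Newick branch lengths are SNV+indel counts (cluster sizes); a forest
#' yields one Newick statement per root. JSON serializes the parent map,
#' per-region CCFs, sizes, annotations, flags and per-region exclusive
#' (oval-plot) fractions; [read_tree_json()] restores the topology exactly.
#'
#' @param tree a `clone_tree`.
#' @param path output file.
#' @param format "newick" or "json".
#' @export
write_tree <- function(tree, path, format = c("newick", "json")) {
  format <- match.arg(format)
  # cycle guard
  for (nd in tree$nodes) {
    seen <- nd; p <- tree$parent[[nd]]
    while (!is.na(p)) {
      if (p %in% seen) stop("cyclic parent links at node ", nd)
      seen <- c(seen, p); p <- tree$parent[[p]]
    }
  }
  if (format == "newick") {
    writeLines(vapply(tree_roots(tree), function(r) {
      paste0(newick_subtree(tree, r), ";")
    }, character(1)), path)
  } else {
    fr <- lapply(colnames(tree$ccf), function(rg) {
      as.list(subclone_fractions(tree, rg, eps = Inf))
    })
    names(fr) <- colnames(tree$ccf)
    obj <- list(nodes = tree$nodes,
                parent = as.list(tree$parent),
                ccf = apply(tree$ccf, 1, as.list),
                regions = colnames(tree$ccf),
                size = as.list(tree$size),
                annotations = tree$annotations,
                flags = as.list(tree$flags),
                fractions = fr)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA)
  }
  invisible(path)
}

#' Read a clone tree from its JSON serialization
#' @param path JSON written by [write_tree()].
#' @return a `clone_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- unlist(obj$nodes)
  regions <- unlist(obj$regions)
  ccf <- matrix(NA_real_, length(nodes), length(regions),
                dimnames = list(nodes, regions))
  for (nd in nodes) ccf[nd, ] <- unlist(obj$ccf[[nd]])
  parent <- vapply(nodes, function(nd) {
    p <- obj$parent[[nd]]
    if (is.null(p)) NA_character_ else as.character(p)
  }, character(1))
  ann <- obj$annotations[nodes]
  new_clone_tree(nodes, parent, ccf, unlist(obj$size)[nodes],
                 annotations = ann,
                 flags = unlist(obj$flags)[nodes])
}
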