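# End-to-end orchestration: ingest a cohort manifest, assemble CCF inputs,
# cluster, build and annotate trees, and emit the per-case and cohort-level
# report files.

#' Ingest one patient from a cohort manifest
#'
#' Reads the per-region VCFs, segment files, BEDPE structural variants and
#' the purity table, and merges calls across regions by mutation key
#' (chrom:pos:ref:alt).
#'
#' @param entry one element of `manifest$patients`.
#' @param base_dir directory paths are relative to.
#' @return list with alt/depth matrices (mutations x regions), per-region
#'   copy-state matrices, purity, SVs, per-mutation metadata and histology.
#' @export
ingest_patient <- function(entry, base_dir = ".") {
  regions <- unlist(entry$region_ids)
  p <- function(x) file.path(base_dir, x)
  calls <- lapply(seq_along(regions), function(d) {
    read_vcf(p(entry$vcf[[d]]), regions[d])
  })
  segs <- lapply(seq_along(regions), function(d) {
    read_segments(p(entry$segments[[d]]), regions[d])
  })
  sv <- do.call(rbind, lapply(seq_along(regions), function(d) {
    read_bedpe(p(entry$bedpe[[d]]), regions[d])
  }))
  rho <- read_purity(p(entry$purity))[regions]
  keys <- sort(unique(unlist(lapply(calls, function(cc) {
    paste0(cc$chrom, ":", cc$pos, ":", cc$ref, ":", cc$alt)
  }))))
  n <- length(keys); D <- length(regions)
  alt <- depth <- major <- minor <- matrix(0L, n, D,
                                           dimnames = list(keys, regions))
  meta <- NULL
  for (d in seq_len(D)) {
    cc <- calls[[d]]
    k <- paste0(cc$chrom, ":", cc$pos, ":", cc$ref, ":", cc$alt)
    alt[k, d] <- cc$alt_count
    depth[k, d] <- cc$depth
    sg <- segs[[d]]
    idx <- match_segment(cc$chrom, cc$pos, sg)
    major[k, d] <- ifelse(is.na(idx), 1L, sg$major[idx])
    minor[k, d] <- ifelse(is.na(idx), 1L, sg$minor[idx])
    if (is.null(meta)) {
      meta <- cc[c("chrom", "pos", "ref", "alt", "context", "gene", "driver")]
      rownames(meta) <- k
    }
  }
  meta <- meta[keys, ]
  meta$is_indel <- nchar(meta$ref) != nchar(meta$alt)
  list(patient_id = entry$patient_id, regions = regions,
       alt = alt, depth = depth, major = major, minor = minor,
       purity = rho, sv = sv, meta = meta,
       histology = unlist(entry$histology)[regions])
}

match_segment <- function(chrom, pos, seg) {
  vapply(seq_along(chrom), function(i) {
    hit <- which(seg$chrom == chrom[i] & seg$start <= pos[i] &
                   seg$end >= pos[i])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Analyze one multi-region case: cluster, build and annotate the tree
#'
#' Estimates per-mutation multiplicities, runs [dp_cluster()], reconstructs
#' the clone forest, classifies the trajectory, computes per-region
#' oval-plot fractions, times every mutation, and attaches driver and SV
#' annotations plus branch signature profiles.
#'
#' @param pat output of [ingest_patient()].
#' @param control a [dp_control()].
#' @param eps CCF tolerance for tree building.
#' @param catalog SBS96 catalog for branch profiles.
#' @return list of class `case_analysis`: fit, tree, trajectory, fractions,
#'   timing, branch_profiles, per-mutation table.
#' @export
analyze_case <- function(pat, control = dp_control(), eps = 0.05,
                         catalog = synthetic_sbs_catalog()) {
  n_t <- pat$major + pat$minor
  vaf <- ifelse(pat$depth > 0, pat$alt / pmax(pat$depth, 1), 0)
  mj <- estimate_multiplicity_joint(vaf, pat$depth, pat$purity,
                                    pmax(n_t, 1), pmax(pat$major, 1))
  m <- matrix(mj, nrow(vaf), ncol(vaf), dimnames = dimnames(vaf))
  fit <- dp_cluster(pat$alt, pat$depth, pat$purity, m, pmax(n_t, 1),
                    control = control)
  tree <- build_forest(fit, eps = eps)
  traj <- classify_trajectory(tree)
  fractions <- lapply(pat$regions, function(rg) {
    subclone_fractions(tree, rg, eps = Inf)
  })
  names(fractions) <- pat$regions

  # timing: truncal = cluster of maximal total CCF among roots
  labs <- paste0("C", fit$assignment)
  roots <- tree_roots(tree)
  trunk <- roots[which.max(rowSums(tree$ccf[roots, , drop = FALSE]))]
  keys <- names(fit$assignment)
  mx <- apply(m[keys, , drop = FALSE], 1, max)
  mjx <- apply(pat$major[keys, , drop = FALSE], 1, max)
  mnx <- apply(pat$minor[keys, , drop = FALSE], 1, max)
  timing <- classify_timing(labs == trunk, pmin(mx, mjx), pmax(mjx, 1), mnx)

  # channels for branch profiles
  meta <- pat$meta[keys, ]
  snv <- !meta$is_indel & !is.na(meta$context)
  channels <- rep(NA_integer_, length(keys))
  if (any(snv)) {
    channels[snv] <- encode_sbs96(meta$ref[snv], meta$alt[snv],
                                  meta$context[snv])
  }
  profiles <- branch_signature_profile(tree, channels, labs, catalog)

  # annotations: drivers by membership, SVs by region-support matching
  ann <- tree$annotations
  for (nd in tree$nodes) {
    drv <- which(meta$driver & labs == nd)
    ann[[nd]]$drivers <- if (length(drv)) {
      paste0(meta$gene[drv], " ", meta$chrom[drv], ":", meta$pos[drv])
    } else character(0)
    ann[[nd]]$signatures <- as.list(profiles[nd, profiles[nd, ] > 0.02])
  }
  if (!is.null(pat$sv) && nrow(pat$sv)) {
    svkey <- paste0(pat$sv$chrom1, ":", pat$sv$pos1, "-", pat$sv$chrom2,
                    ":", pat$sv$pos2, ":", pat$sv$sv_class)
    support <- split(pat$sv$region_id, svkey)
    node_support <- lapply(tree$nodes, function(nd) {
      pat$regions[tree$ccf[nd, ] > 0.1]
    })
    names(node_support) <- tree$nodes
    for (sk in names(support)) {
      regs <- sort(unique(support[[sk]]))
      match_n <- vapply(tree$nodes, function(nd) {
        identical(sort(node_support[[nd]]), regs)
      }, logical(1))
      target <- if (any(match_n)) {
        # smallest matching clone (most recent)
        cand <- tree$nodes[match_n]
        cand[which.min(rowSums(tree$ccf[cand, , drop = FALSE]))]
      } else NA_character_
      if (!is.na(target)) {
        ann[[target]]$svs <- c(ann[[target]]$svs, sk)
      }
    }
  }
  tree$annotations <- ann

  structure(list(patient_id = pat$patient_id, fit = fit, tree = tree,
                 trajectory = traj, fractions = fractions, timing = timing,
                 multiplicity = m, channels = channels,
                 cluster_labels = labs,
                 branch_profiles = profiles, histology = pat$histology,
                 sv = pat$sv),
            class = "case_analysis")
}

#' @export
print.case_analysis <- function(x, ...) {
  cat("Case", x$patient_id, "-", x$trajectory$mrca_pattern, "/",
      x$trajectory$growth_pattern, "\n")
  print(x$tree)
  invisible(x)
}

#' Run the full cohort analysis and write the report
#'
#' `simulate -> ingest -> cluster -> tree -> annotate -> report` over every
#' patient of a manifest: per-case Newick and annotated JSON trees, a
#' cohort trajectory table, oval-plot fraction tables, branch signature
#' profiles, timing tables, the SV-burden comparison between branching and
#' linear cases, and (when expression is present) per-sample score and
#' cell-fraction tables.
#'
#' @param manifest_path cohort manifest YAML (see [read_manifest()]).
#' @param out_dir report output directory.
#' @param control a [dp_control()].
#' @param eps tree-building CCF tolerance.
#' @param seed seed for the per-case sampler streams.
#' @return invisible list of `case_analysis` objects plus cohort tables.
#' @export
run_cohort_analysis <- function(manifest_path, out_dir,
                                control = dp_control(), eps = 0.05,
                                seed = 1) {
  man <- read_manifest(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cases <- list()
  traj_rows <- list()
  sv_rows <- list()
  score_rows <- list()
  frac_rows <- list()
  gs <- default_gene_sets()
  for (i in seq_along(man$patients)) {
    entry <- man$patients[[i]]
    pat <- ingest_patient(entry, man$base_dir)
    control$seed <- (seed * 1000L + i) %% 2147483647L
    res <- analyze_case(pat, control = control, eps = eps)
    cases[[entry$patient_id]] <- res
    write_tree(res$tree, file.path(out_dir, paste0(entry$patient_id, ".nwk")),
               "newick")
    write_tree(res$tree, file.path(out_dir, paste0(entry$patient_id, ".json")),
               "json")
    traj_rows[[i]] <- data.frame(
      patient_id = entry$patient_id,
      mrca_pattern = res$trajectory$mrca_pattern,
      growth_pattern = res$trajectory$growth_pattern,
      n_clusters = length(res$tree$nodes),
      n_roots = res$trajectory$n_roots)
    for (rg in pat$regions) {
      fr <- res$fractions[[rg]]
      frac_rows[[length(frac_rows) + 1]] <- data.frame(
        patient_id = entry$patient_id, region_id = rg,
        cluster = names(fr), fraction = as.numeric(fr))
      nsv <- if (is.null(pat$sv)) 0L else sum(pat$sv$region_id == rg)
      sv_rows[[length(sv_rows) + 1]] <- data.frame(
        patient_id = entry$patient_id, region_id = rg, n_sv = nsv)
    }
    if (!is.null(entry$expression)) {
      expr <- read_expression(file.path(man$base_dir, entry$expression))
      grad <- gradient_score(expr, gs$squamous, gs$classical)
      est <- estimate_scores(expr, gs$stromal, gs$immune)
      fr <- deconvolve_fractions(expr, synthetic_reference_profiles())
      score_rows[[length(score_rows) + 1]] <- cbind(
        patient_id = entry$patient_id, region_id = colnames(expr),
        histology = unlist(entry$histology)[colnames(expr)],
        gradient = grad, est[match(colnames(expr), est$sample), -1],
        fr[match(colnames(expr), fr$sample), -1])
    }
  }
  trajectories <- do.call(rbind, traj_rows)
  sv_counts <- do.call(rbind, sv_rows)
  names(sv_counts)[1] <- "case_id"
  write.table(trajectories, file.path(out_dir, "trajectories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, frac_rows),
              file.path(out_dir, "subclone_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sv_test <- NULL
  trees <- lapply(cases, `[[`, "tree")
  if (length(unique(trajectories$growth_pattern)) == 2) {
    sv_test <- compare_sv_burden_by_pattern(trees, sv_counts)
  }
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else NULL
  if (!is.null(scores)) {
    write.table(scores, file.path(out_dir, "expression_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prof <- do.call(rbind, lapply(names(cases), function(pid) {
    pr <- cases[[pid]]$branch_profiles
    data.frame(patient_id = pid, cluster = rownames(pr), pr,
               check.names = FALSE, row.names = NULL)
  }))
  write.table(prof, file.path(out_dir, "branch_signatures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cases = cases, trajectories = trajectories,
                 sv_counts = sv_counts, sv_test = sv_test,
                 scores = scores, out_dir = out_dir))
}
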