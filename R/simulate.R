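# Synthetic multi-region cohort generator with known ground truth.
#
# Default settings emulate the study conditions: 12 patients, 2-6 regions
# each (mean ~4), 80X tumor depth, purity Uniform(0.3, 0.9), and clone
# trees spanning three archetypes (single-MRCA linear, single-MRCA
# branching, multiple independent MRCAs) in the 3:5:3 proportions of the
# analyzed cases. Branching cases carry ~85 structural variants per region
# against ~30 for single-branch cases.
#
# Identifiability: cluster CCFs are rejection-sampled until every pair of
# clones NOT in an ancestor-descendant relation crosses (each exceeds the
# other by at least `separation` in some region) and every child is
# separated from its parent by at least `separation` in some region.
# Without the crossing condition a nested sibling admits a chain placement
# satisfying every reconstruction rule, and the true topology is not
# recoverable even from exact CCFs.

ARCHETYPES <- c("single_mrca_linear", "single_mrca_branching", "multi_mrca")

spec_children <- function(parent, node) names(parent)[!is.na(parent) & parent == node]

spec_is_ancestor <- function(parent, a, b) {
  # is a an ancestor of b?
  p <- parent[[b]]
  while (!is.na(p)) {
    if (p == a) return(TRUE)
    p <- parent[[p]]
  }
  FALSE
}

#' Validate a clone-tree specification
#'
#' Checks the ground-truth invariants: acyclic parent map, CCFs in
#' `[0, 1]`, the sum rule (`CCF(node) >= sum CCF(children)` in every
#' region, up to `tol`), archetype realization, and non-negative exposures
#' summing to 1.
#'
#' @param spec a `clone_tree_spec` from [simulate_clone_tree()].
#' @param tol numeric slack on the sum rule.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_tree_spec <- function(spec, tol = 1e-9) {
  nodes <- spec$nodes; parent <- spec$parent; ccf <- spec$ccf
  stopifnot(all(names(parent) == nodes), all(rownames(ccf) == nodes))
  if (any(ccf < -tol | ccf > 1 + tol)) stop("CCF outside [0, 1]")
  for (nd in nodes) {
    seen <- nd; p <- parent[[nd]]
    while (!is.na(p)) {
      if (p %in% seen) stop("cycle at ", nd)
      seen <- c(seen, p); p <- parent[[p]]
    }
    kids <- spec_children(parent, nd)
    if (length(kids)) {
      if (any(colSums(ccf[kids, , drop = FALSE]) > ccf[nd, ] + tol)) {
        stop("sum rule violated at ", nd)
      }
    }
  }
  roots <- nodes[is.na(parent)]
  nkid <- vapply(nodes, function(n) length(spec_children(parent, n)), integer(1))
  ok <- switch(spec$archetype,
    single_mrca_linear = length(roots) == 1 && all(nkid <= 1),
    single_mrca_branching = length(roots) == 1 && any(nkid >= 2),
    multi_mrca = length(roots) >= 2)
  if (!ok) stop("archetype not realized: ", spec$archetype)
  if (!is.null(spec$exposures)) {
    if (any(spec$exposures < 0) ||
        any(abs(rowSums(spec$exposures) - 1) > 1e-6)) {
      stop("invalid exposures")
    }
  }
  invisible(TRUE)
}

sample_topology <- function(archetype, n_clones) {
  nodes <- paste0("clone", seq_len(n_clones))
  parent <- setNames(rep(NA_character_, n_clones), nodes)
  if (archetype == "single_mrca_linear") {
    if (n_clones > 1) parent[-1] <- nodes[-n_clones]
  } else if (archetype == "single_mrca_branching") {
    if (n_clones < 3) stop("branching needs at least 3 clones")
    repeat {
      for (i in 2:n_clones) parent[i] <- nodes[sample.int(i - 1, 1)]
      nkid <- table(factor(parent, levels = nodes))
      if (any(nkid >= 2)) break
    }
  } else if (archetype == "multi_mrca") {
    if (n_clones < 2) stop("multi_mrca needs at least 2 clones")
    n_roots <- if (n_clones >= 4) sample(2:3, 1, prob = c(0.8, 0.2)) else 2
    root_of <- sort(sample.int(n_clones, n_roots))
    root_of <- seq_len(n_roots)  # first n_roots nodes are roots
    for (i in seq_len(n_clones)[-seq_len(n_roots)]) {
      # attach to a random earlier node, keeping lineages started at roots
      parent[i] <- nodes[sample.int(i - 1, 1)]
    }
  } else stop("unknown archetype: ", archetype)
  parent
}

crossing_ok <- function(ccf, parent, separation) {
  nodes <- rownames(ccf)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j]
      anc <- spec_is_ancestor(parent, a, b) || spec_is_ancestor(parent, b, a)
      if (anc) next
      if (!(any(ccf[a, ] >= ccf[b, ] + separation) &&
            any(ccf[b, ] >= ccf[a, ] + separation))) {
        return(FALSE)
      }
    }
  }
  # parent-child separation in at least one region
  for (b in nodes) {
    p <- parent[[b]]
    if (is.na(p)) next
    if (!any(ccf[p, ] >= ccf[b, ] + separation)) return(FALSE)
  }
  TRUE
}

sample_ccfs <- function(parent, n_regions, archetype, separation) {
  nodes <- names(parent)
  roots <- nodes[is.na(parent)]
  ccf <- matrix(0, length(nodes), n_regions,
                dimnames = list(nodes, paste0("R", seq_len(n_regions))))
  if (length(roots) == 1) {
    ccf[roots, ] <- 1
  } else {
    # split regions among independent ancestral clones; a root is clonal in
    # its own regions and absent (or rare) elsewhere
    owner <- sort(rep_len(seq_along(roots), n_regions))
    owner <- sample(owner)
    for (r in seq_along(roots)) {
      ccf[roots[r], owner == r] <- runif(sum(owner == r), 0.85, 1)
    }
  }
  # children by stick-breaking from the parent's CCF, per region
  order_nodes <- nodes[order(vapply(nodes, function(n) {
    length(tree_path_to_root(parent, n))
  }, integer(1)))]
  for (nd in order_nodes) {
    kids <- spec_children(parent, nd)
    if (!length(kids)) next
    for (d in seq_len(n_regions)) {
      if (ccf[nd, d] < 0.05) next   # clone absent here; children absent too
      props <- rgamma(length(kids) + 1, 1)
      props <- props / sum(props)
      ccf[kids, d] <- ccf[nd, d] * props[seq_along(kids)]
    }
  }
  # occasionally zero a subclone out of a region (regional restriction)
  subcl <- setdiff(nodes, roots)
  for (nd in subcl) {
    if (n_regions > 2 && runif(1) < 0.3) {
      d <- sample.int(n_regions, 1)
      ccf[nd, d] <- 0
      for (k in nodes) if (spec_is_ancestor(parent, nd, k)) ccf[k, d] <- 0
    }
  }
  ccf
}

tree_path_to_root <- function(parent, node) {
  out <- character()
  p <- parent[[node]]
  while (!is.na(p)) { out <- c(out, p); p <- parent[[p]] }
  out
}

#' Simulate a clone-tree specification with known CCFs
#'
#' Draws a topology of the requested archetype and per-region CCFs
#' satisfying the sum rule exactly, with every non-nested clone pair
#' crossing by at least `separation` in some region (see the file header
#' for why this identifiability condition is enforced).
#'
#' @param archetype one of `"single_mrca_linear"`, `"single_mrca_branching"`,
#'   `"multi_mrca"`.
#' @param n_clones number of clones (`>= 1`; `>= 2` for multi_mrca, `>= 3`
#'   for branching).
#' @param n_regions number of tumor regions (`>= 2`).
#' @param seed RNG seed.
#' @param separation minimum CCF separation for crossing/nesting decisions
#'   (default 0.08, the detectability limit at 80X).
#' @param mutations_per_clone integer vector (recycled) of SNV+indel counts
#'   per clone; default drawn from 100..600 (scaled down from the
#'   thousands of SNVs per sample seen in whole-genome cohorts, keeping
#'   per-cluster counts large enough for CCF accuracy).
#' @param max_tries rejection-sampling budget before redrawing the topology.
#' @return a `clone_tree_spec`: list with nodes, parent, ccf, archetype,
#'   mutations_per_clone, exposures, sv_per_clone.
#' @export
simulate_clone_tree <- function(archetype = ARCHETYPES, n_clones = 4,
                                n_regions = 3, seed = NULL,
                                separation = 0.08,
                                mutations_per_clone = NULL,
                                max_tries = 400) {
  archetype <- match.arg(archetype)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_clones >= 1, n_regions >= 2)
  if (archetype == "multi_mrca" && n_clones < 2) {
    stop("multi_mrca is infeasible with a single clone")
  }
  repeat {
    parent <- sample_topology(archetype, n_clones)
    found <- FALSE
    for (t in seq_len(max_tries)) {
      ccf <- sample_ccfs(parent, n_regions, archetype, separation)
      # drop tries where some clone is everywhere negligible
      if (any(apply(ccf, 1, max) < 0.12)) next
      if (crossing_ok(ccf, parent, separation)) { found <- TRUE; break }
    }
    if (found) break
  }
  nodes <- names(parent)
  if (is.null(mutations_per_clone)) {
    mutations_per_clone <- sample(100:600, n_clones, replace = TRUE)
  }
  mutations_per_clone <- rep_len(as.integer(mutations_per_clone), n_clones)
  spec <- list(nodes = nodes, parent = parent, ccf = ccf,
               archetype = archetype,
               mutations_per_clone = setNames(mutations_per_clone, nodes),
               exposures = default_exposures(parent),
               sv_per_clone = setNames(rep(0L, n_clones), nodes))
  class(spec) <- "clone_tree_spec"
  validate_tree_spec(spec)
  spec
}

# Truncal clones lean on clock-like processes (SBS1/SBS5/SBS40); subclones
# occasionally ignite an APOBEC-like process, mirroring late emergence of
# SBS2/SBS13 in progressing branches.
default_exposures <- function(parent) {
  sigs <- colnames(synthetic_sbs_catalog())
  nodes <- names(parent)
  E <- matrix(0, length(nodes), length(sigs),
              dimnames = list(nodes, sigs))
  for (nd in nodes) {
    e <- setNames(numeric(length(sigs)), sigs)
    base <- rgamma(3, c(3, 5, 2))
    e[c("SBS1", "SBS5", "SBS40")] <- base / sum(base)
    if (!is.na(parent[[nd]]) && runif(1) < 0.3) {
      apo <- runif(1, 0.3, 0.6)
      e <- e * (1 - apo)
      e["SBS2"] <- apo * 0.55
      e["SBS13"] <- apo * 0.45
    }
    E[nd, ] <- e
  }
  E
}

#' Draw SBS96 channels for every mutation of a clone tree
#'
#' The channel of a clone-k mutation is drawn from the mixture
#' `sum_s exposure_ks * catalog[, s]`; the generating signature is recorded
#' per mutation.
#'
#' @param spec a `clone_tree_spec`.
#' @param catalog channels x signatures matrix (columns sum to 1).
#' @param seed RNG seed.
#' @return data.frame with clone, channel (0-based), signature.
#' @export
simulate_signature_contexts <- function(spec, catalog = synthetic_sbs_catalog(),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ncol(spec$exposures) != ncol(catalog)) {
    stop("exposure/catalog dimension mismatch")
  }
  out <- lapply(spec$nodes, function(nd) {
    nmut <- spec$mutations_per_clone[[nd]]
    if (nmut == 0) {
      return(data.frame(clone = character(), channel = integer(),
                        signature = character()))
    }
    sig <- sample(colnames(catalog), nmut, replace = TRUE,
                  prob = spec$exposures[nd, ])
    ch <- vapply(sig, function(s) {
      sample.int(nrow(catalog), 1, prob = catalog[, s]) - 1L
    }, integer(1))
    data.frame(clone = nd, channel = unname(ch), signature = unname(sig),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Decompose an SBS96 channel into ref/alt/context on a random strand.
channel_to_mutation <- function(channel) {
  si <- channel %/% 16L
  p5 <- (channel %% 16L) %/% 4L
  p3 <- channel %% 4L
  sub <- SUBS6[si + 1]
  ref <- substr(sub, 1, 1); alt <- substr(sub, 3, 3)
  ctx <- paste0(BASES[p5 + 1], ref, BASES[p3 + 1])
  flip <- runif(length(channel)) < 0.5
  data.frame(ref = ifelse(flip, unname(COMP[ref]), ref),
             alt = ifelse(flip, unname(COMP[alt]), alt),
             context = ifelse(flip, revcomp(ctx), ctx),
             stringsAsFactors = FALSE)
}

default_copy_profile <- function() {
  c("1,1" = 0.80, "2,1" = 0.10, "2,0" = 0.05, "2,2" = 0.05)
}

DRIVER_GENES <- c("KRAS", "GNAS", "TP53", "SMAD4", "CDKN2A", "RNF43",
                  "ARID1A", "LRP1B", "ATM", "KMT2C")

#' Simulate multi-region read counts and emit the per-patient files
#'
#' For each mutation of clone k in region d, depth is Poisson(`mean_depth`)
#' and the alt count Binomial(depth, f) with
#' `f = expected_vaf(CCF_kd, rho_d, m, n_t)`. Multiplicity is drawn
#' uniformly from `1..major` for truncal (root) clones; mutations arising
#' in descendant clones post-date the (clonal) copy-number events and carry
#' m = 1. Copy-number segments (shared across regions), purity, per-region
#' VCFs, BEDPE structural variants and a truth table are written to
#' `out_dir` when given.
#'
#' @param spec a `clone_tree_spec`.
#' @param purity per-region purity vector in `(0, 1]`.
#' @param mean_depth mean sequencing depth (default 80, the cohort design
#'   depth).
#' @param copy_profile named probabilities over "major,minor" states for
#'   segments.
#' @param seed RNG seed.
#' @param out_dir directory for emitted files (created); NULL keeps
#'   everything in memory.
#' @param patient_id file-name prefix.
#' @param sv_rate_per_region expected SV count per region.
#' @param n_driver_mutations truncal/subclonal driver SNVs to flag.
#' @return invisible list with `calls` (per-region data.frames), `segments`,
#'   `purity`, `sv`, `truth` (per-mutation clone, multiplicity, channel,
#'   signature, copy state), `spec`, and emitted `paths`.
#' @export
simulate_reads <- function(spec, purity, mean_depth = 80,
                           copy_profile = default_copy_profile(),
                           seed = NULL, out_dir = NULL,
                           patient_id = "patient1",
                           sv_rate_per_region = 30,
                           n_driver_mutations = 4) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(purity > 0), all(purity <= 1), mean_depth > 0)
  D <- ncol(spec$ccf)
  stopifnot(length(purity) == D)
  regions <- colnames(spec$ccf)
  names(purity) <- regions

  # clonal segments: 22 chromosomes x 4 segments of 30 Mb
  seg_states <- strsplit(names(copy_profile), ",", fixed = TRUE)
  chroms <- paste0("chr", 1:22)
  seg <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(1, by = 3e7, length.out = 4)
    st <- sample(seq_along(copy_profile), 4, replace = TRUE,
                 prob = copy_profile)
    data.frame(chrom = ch, start = starts, end = starts + 3e7 - 1,
               major = as.integer(vapply(seg_states[st], `[`, "", 1)),
               minor = as.integer(vapply(seg_states[st], `[`, "", 2)),
               stringsAsFactors = FALSE)
  }))

  # mutations: positions, channels, multiplicities
  ctxdf <- simulate_signature_contexts(spec)
  nmut <- nrow(ctxdf)
  is_indel <- runif(nmut) < 0.07
  segi <- sample.int(nrow(seg), nmut, replace = TRUE)
  pos <- seg$start[segi] + floor(runif(nmut) * (seg$end[segi] - seg$start[segi]))
  mutdf <- channel_to_mutation(ctxdf$channel)
  mutdf$ref[is_indel] <- paste0(mutdf$ref[is_indel], "T")
  mutdf$alt[is_indel] <- substr(mutdf$ref[is_indel], 1, 1)
  ctxdf$channel[is_indel] <- NA_integer_
  roots <- spec$nodes[is.na(spec$parent)]
  major <- seg$major[segi]
  m <- ifelse(ctxdf$clone %in% roots,
              1L + floor(runif(nmut) * major), 1L)
  m <- pmin(m, pmax(major, 1L))

  # driver flags on a few truncal/subclonal mutations
  drv <- sample.int(nmut, min(n_driver_mutations, nmut))
  gene <- rep(NA_character_, nmut)
  gene[drv] <- sample(DRIVER_GENES, length(drv), replace = TRUE)

  key <- paste0(seg$chrom[segi], ":", pos, ":", mutdf$ref, ":", mutdf$alt)
  dup <- duplicated(key)
  if (any(dup)) { pos[dup] <- pos[dup] + sample.int(1000, sum(dup)) }
  key <- paste0(seg$chrom[segi], ":", pos, ":", mutdf$ref, ":", mutdf$alt)

  n_t <- seg$major[segi] + seg$minor[segi]
  calls <- list()
  for (d in seq_len(D)) {
    depth <- rpois(nmut, mean_depth)
    f <- expected_vaf(spec$ccf[ctxdf$clone, d], purity[d], m, pmax(n_t, 1))
    alt_count <- rbinom(nmut, depth, pmin(f, 1))
    calls[[regions[d]]] <- data.frame(
      chrom = seg$chrom[segi], pos = pos, ref = mutdf$ref, alt = mutdf$alt,
      alt_count = alt_count, depth = depth, region_id = regions[d],
      context = ifelse(is_indel, NA_character_, mutdf$context),
      gene = gene, driver = !is.na(gene), stringsAsFactors = FALSE)
  }

  # structural variants: clone-attached; present in regions carrying the
  # clone. The total is calibrated so the EXPECTED per-region count equals
  # sv_rate_per_region (an SV appears in every region its clone occupies).
  clone_prob <- (spec$mutations_per_clone + 1) /
    sum(spec$mutations_per_clone + 1)
  presence <- rowMeans(spec$ccf > 0.1)
  p_bar <- max(sum(clone_prob * presence), 0.05)
  sv_total <- rpois(1, sv_rate_per_region / p_bar)
  sv <- NULL
  if (sv_total > 0) {
    sv_clone <- sample(spec$nodes, sv_total, replace = TRUE,
                       prob = spec$mutations_per_clone + 1)
    cls <- sample(c("deletion", "tandem_duplication", "inversion",
                    "translocation"), sv_total, replace = TRUE,
                  prob = c(0.35, 0.25, 0.25, 0.15))
    ch1 <- sample(chroms, sv_total, replace = TRUE)
    p1 <- floor(runif(sv_total, 1e6, 1.1e8))
    len <- floor(runif(sv_total, 1e4, 5e6))
    ch2 <- ifelse(cls == "translocation",
                  sample(chroms, sv_total, replace = TRUE), ch1)
    same <- ch1 == ch2 & cls == "translocation"
    cls[same] <- "inversion"
    p2 <- ifelse(cls == "translocation", floor(runif(sv_total, 1e6, 1.1e8)),
                 p1 + len)
    s1 <- ifelse(cls == "deletion", "+",
                 ifelse(cls == "tandem_duplication", "-",
                        ifelse(cls == "inversion", "+",
                               sample(c("+", "-"), sv_total, TRUE))))
    s2 <- ifelse(cls == "deletion", "-",
                 ifelse(cls == "tandem_duplication", "+",
                        ifelse(cls == "inversion", s1,
                               sample(c("+", "-"), sv_total, TRUE))))
    sv <- data.frame(chrom1 = ch1, pos1 = p1, strand1 = s1,
                     chrom2 = ch2, pos2 = p2, strand2 = s2,
                     clone = sv_clone, sv_class = cls,
                     stringsAsFactors = FALSE)
  }

  truth <- data.frame(key = key, clone = ctxdf$clone, multiplicity = m,
                      major = seg$major[segi], minor = seg$minor[segi],
                      channel = ctxdf$channel, signature = ctxdf$signature,
                      is_indel = is_indel, stringsAsFactors = FALSE)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = character(), bedpe = character(),
                  segments = character())
    for (d in seq_len(D)) {
      rg <- regions[d]
      vp <- file.path(out_dir, paste0(patient_id, "_", rg, ".vcf"))
      write_vcf(calls[[rg]], vp, sample_name = rg)
      sp <- file.path(out_dir, paste0(patient_id, "_", rg, "_segments.tsv"))
      write_segments(cbind(seg, region_id = rg), sp)
      bp <- file.path(out_dir, paste0(patient_id, "_", rg, ".bedpe"))
      svr <- if (!is.null(sv)) {
        sv[spec$ccf[sv$clone, d] > 0.1, , drop = FALSE]
      } else sv
      if (is.null(svr) || !nrow(svr)) {
        writeLines(paste(c("chrom1", "start1", "end1", "chrom2", "start2",
                           "end2", "name", "score", "strand1", "strand2"),
                         collapse = "\t"), bp)
      } else {
        write_bedpe(svr, bp)
      }
      paths$vcf[rg] <- vp; paths$segments[rg] <- sp; paths$bedpe[rg] <- bp
    }
    pp <- file.path(out_dir, paste0(patient_id, "_purity.tsv"))
    write_purity(purity, pp)
    paths$purity <- pp
    tp <- file.path(out_dir, paste0(patient_id, "_truth.json"))
    jsonlite::write_json(list(spec = unclass_spec(spec), truth = truth,
                              purity = as.list(purity),
                              mean_depth = mean_depth),
                         tp, auto_unbox = TRUE, na = "null", digits = NA)
    paths$truth <- tp
  }
  invisible(list(calls = calls, segments = seg, purity = purity, sv = sv,
                 truth = truth, spec = spec, paths = paths))
}

unclass_spec <- function(spec) {
  list(nodes = spec$nodes, parent = as.list(spec$parent),
       ccf = apply(spec$ccf, 1, as.list),
       regions = colnames(spec$ccf),
       archetype = spec$archetype,
       mutations_per_clone = as.list(spec$mutations_per_clone))
}

# ---- expression ----------------------------------------------------------

#' Synthetic cell-type reference profiles
#'
#' Deterministic genes x cell-types matrix (TPM-like scale): each type has
#' a block of marker genes at high expression over a shared low baseline.
#' Squamous/classical epithelial marker genes are included so gradient and
#' deconvolution machinery can be exercised on the same matrix. Synthetic
#' throughout; not derived from any measured reference.
#'
#' @return genes x 7 matrix (epithelial, CAF, endothelial, CD4_T, CD8_T,
#'   B_cell, macrophage).
#' @export
synthetic_reference_profiles <- function() {
  types <- c("epithelial", "CAF", "endothelial", "CD4_T", "CD8_T",
             "B_cell", "macrophage")
  markers <- list(
    epithelial = c("EPCAM", "KRT8", "KRT18", "CDH1", "MUC1",
                   sprintf("EPI%02d", 1:25)),
    CAF = c("ACTA2", "FAP", "PDGFRB", "COL1A1", "COL3A1",
            sprintf("CAF%02d", 1:25)),
    endothelial = c("PECAM1", "VWF", "CDH5", sprintf("END%02d", 1:27)),
    CD4_T = c("CD4", "IL7R", "CD3D", sprintf("CD4G%02d", 1:27)),
    CD8_T = c("CD8A", "CD8B", "GZMK", sprintf("CD8G%02d", 1:27)),
    B_cell = c("CD19", "MS4A1", "CD79A", sprintf("BCG%02d", 1:27)),
    macrophage = c("CD68", "CD163", "CSF1R", sprintf("MAC%02d", 1:27)))
  subtype <- c(default_gene_sets()$squamous, default_gene_sets()$classical)
  genes <- c(unlist(markers, use.names = FALSE), subtype,
             sprintf("HK%03d", 1:100))
  genes <- unique(genes)
  R <- matrix(1, length(genes), length(types),
              dimnames = list(genes, types))
  for (ty in types) R[markers[[ty]], ty] <- 120
  # subtype genes are epithelial-expressed
  R[subtype, "epithelial"] <- 40
  R
}

#' Illustrative gene sets for gradient/stromal/immune scoring
#'
#' Small synthetic sets: squamous and classical epithelial programs (seeded
#' with the canonical marker genes of each subtype plus synthetic fillers),
#' and stromal/immune sets drawn from the reference marker blocks. These
#' are test fixtures, not a reproduction of any published signature.
#'
#' @return named list: squamous, classical, stromal, immune.
#' @export
default_gene_sets <- function() {
  list(squamous = c("TP63", "KRT6A", "S100A2", "KRT5", "KRT14",
                    sprintf("SQG%02d", 1:15)),
       classical = c("GATA6", "HNF4A", "TFF1", "LGALS4", "CTSE",
                     sprintf("CLG%02d", 1:15)),
       stromal = c("ACTA2", "FAP", "PDGFRB", "COL1A1", "COL3A1",
                   "PECAM1", "VWF", "CDH5", sprintf("CAF%02d", 1:10)),
       immune = c("CD4", "IL7R", "CD3D", "CD8A", "CD8B", "GZMK", "CD19",
                  "MS4A1", "CD79A", "CD68", "CD163", "CSF1R",
                  sprintf("CD8G%02d", 1:5)))
}

#' Simulate bulk expression as a cell-type mixture with subtype structure
#'
#' `expression = reference %*% fractions`, plus a multiplicative
#' subtype shift on squamous or classical set genes, times lognormal noise
#' `exp(N(0, noise_sd))`. With `noise_sd = 0` and a single unit fraction
#' the column equals the reference profile exactly.
#'
#' @param true_fractions cell-types x samples matrix of non-negative
#'   fractions with column sums at most 1 (remainder treated as additional
#'   epithelial content).
#' @param subtype per-sample label: "squamous", "classical" or NA (no
#'   shift).
#' @param reference_profiles genes x types matrix.
#' @param gene_sets list with squamous/classical member genes.
#' @param shift log2 shift applied to subtype genes (default 2).
#' @param noise_sd lognormal noise sd.
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples) and `truth` (fractions,
#'   subtype).
#' @export
simulate_expression <- function(true_fractions, subtype = NULL,
                                reference_profiles = synthetic_reference_profiles(),
                                gene_sets = default_gene_sets(),
                                shift = 2, noise_sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- as.matrix(true_fractions)
  if (any(W < 0) || any(colSums(W) > 1 + 1e-9)) {
    stop("fractions must be non-negative with column sums <= 1")
  }
  R <- reference_profiles
  stopifnot(all(rownames(W) %in% colnames(R)))
  # undeclared remainder defaults to extra (uncharacterized) epithelial mass
  rem <- 1 - colSums(W)
  expr <- R[, rownames(W), drop = FALSE] %*% W +
    outer(R[, "epithelial"], rem)
  if (!is.null(subtype)) {
    for (j in seq_len(ncol(expr))) {
      if (is.na(subtype[j])) next
      genes <- gene_sets[[subtype[j]]]
      genes <- intersect(genes, rownames(expr))
      expr[genes, j] <- expr[genes, j] * 2^shift
      other <- intersect(gene_sets[[if (subtype[j] == "squamous")
        "classical" else "squamous"]], rownames(expr))
      expr[other, j] <- expr[other, j] * 2^(-shift / 2)
    }
  }
  if (noise_sd > 0) {
    expr <- expr * matrix(exp(rnorm(length(expr), 0, noise_sd)),
                          nrow(expr))
  }
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  }
  list(expr = expr, truth = list(fractions = W, subtype = subtype))
}

# ---- cohort --------------------------------------------------------------

#' Simulate a full multi-region cohort with manifest and truth
#'
#' Defaults emulate the study conditions: 12 patients, 2-6 regions each,
#' 80X tumor depth, purity Uniform(0.3, 0.9), archetypes in proportions
#' 3 linear : 5 branching : 3 multi-MRCA, branching cases at ~85 SVs per
#' region versus ~30 for linear, and per-region expression with
#' squamous/classical and stromal/immune structure (PDAC-labeled regions
#' shift squamous and stromal-rich). All files are emitted under `out_dir`
#' with a `manifest.yaml`; ground truth is returned and serialized.
#'
#' @param out_dir output directory.
#' @param n_patients cohort size.
#' @param seed master seed; per-patient streams derive deterministically.
#' @param mean_depth tumor depth.
#' @param purity_range uniform purity range.
#' @param region_range inclusive range of regions per patient.
#' @param with_expression also emit expression matrices.
#' @return invisible list with per-patient truth (`patients`), the manifest
#'   path and cohort-level tables.
#' @export
simulate_cohort <- function(out_dir, n_patients = 12, seed = 42,
                            mean_depth = 80, purity_range = c(0.3, 0.9),
                            region_range = c(2, 6),
                            with_expression = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  arch_prob <- c(single_mrca_linear = 3, single_mrca_branching = 5,
                 multi_mrca = 3) / 11
  patients <- list()
  manifest <- list(cohort = basename(out_dir), seed = seed, patients = list())
  for (i in seq_len(n_patients)) {
    pid <- sprintf("case%02d", i)
    pseed <- (seed * 1000L + i) %% 2147483647L
    set.seed(pseed)
    rng <- region_range[1]:region_range[2]
    D <- rng[sample.int(length(rng), 1)]
    arch <- sample(names(arch_prob), 1, prob = arch_prob)
    ncl <- switch(arch,
                  single_mrca_linear = sample(2:4, 1),
                  single_mrca_branching = sample(3:5, 1),
                  multi_mrca = sample(4:6, 1))
    spec <- simulate_clone_tree(arch, ncl, D)
    rho <- runif(D, purity_range[1], purity_range[2])
    growth <- if (any(table(spec$parent[!is.na(spec$parent)]) >= 2)) {
      "branching"
    } else "linear"
    sv_rate <- if (growth == "branching") 85.2 else 29.7
    sim <- simulate_reads(spec, rho, mean_depth = mean_depth,
                          out_dir = out_dir, patient_id = pid,
                          sv_rate_per_region = sv_rate)
    # histology from clone depth composition per region
    depth_of <- vapply(spec$nodes, function(n)
      length(tree_path_to_root(spec$parent, n)), integer(1))
    histology <- vapply(seq_len(D), function(d) {
      present <- spec$nodes[spec$ccf[, d] > 0.3]
      mx <- if (length(present)) max(depth_of[present]) else 0L
      c("LGD", "HGD", "PDAC")[min(mx + 1L, 3L)]
    }, character(1))
    entry <- list(patient_id = pid,
                  region_ids = as.list(colnames(spec$ccf)),
                  vcf = as.list(basename(sim$paths$vcf)),
                  bedpe = as.list(basename(sim$paths$bedpe)),
                  segments = as.list(basename(sim$paths$segments)),
                  purity = basename(sim$paths$purity),
                  truth = basename(sim$paths$truth),
                  histology = as.list(setNames(histology,
                                               colnames(spec$ccf))))
    if (with_expression) {
      types <- setdiff(colnames(synthetic_reference_profiles()), "epithelial")
      W <- vapply(seq_len(D), function(d) {
        pd <- histology[d] == "PDAC"
        caf <- if (pd) runif(1, 0.18, 0.3) else runif(1, 0.02, 0.08)
        imm <- runif(4, 0.005, 0.04)
        endo <- runif(1, 0.01, 0.05)
        w <- c(CAF = caf, endothelial = endo, CD4_T = imm[1],
               CD8_T = imm[2], B_cell = imm[3], macrophage = imm[4])
        w
      }, numeric(6))
      rownames(W) <- c("CAF", "endothelial", "CD4_T", "CD8_T", "B_cell",
                       "macrophage")
      colnames(W) <- colnames(spec$ccf)
      subtype <- ifelse(histology == "PDAC", "squamous",
                        ifelse(histology == "LGD", "classical", NA))
      ex <- simulate_expression(W, subtype, noise_sd = 0.2)
      colnames(ex$expr) <- colnames(spec$ccf)
      ep <- file.path(out_dir, paste0(pid, "_expression.tsv"))
      write_expression(ex$expr, ep)
      entry$expression <- basename(ep)
      sim$expression_truth <- ex$truth
    }
    sim$histology <- histology
    sim$growth <- growth
    patients[[pid]] <- sim
    manifest$patients[[length(manifest$patients) + 1]] <- entry
  }
  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(list(patients = patients, manifest = mp, out_dir = out_dir))
}
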