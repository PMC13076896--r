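# Mutational-signature machinery: SBS96/ID83 channel encoders, NNLS catalog
# refitting with iterative pruning, per-mutation signature probabilities,
# branch-level profiles, and a minimal KL-divergence NNMF extractor.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")
SUBS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(x) paste(rev(COMP[x]), collapse = ""),
         character(1))
}

#' Channel labels of the SBS96 encoding
#'
#' Pyrimidine-strand canonical channels ordered as 6 substitution types
#' (C>A, C>G, C>T, T>A, T>C, T>G) x 4 5' bases x 4 3' bases, e.g.
#' `"A[C>A]A"`.
#'
#' @return character vector of 96 labels.
#' @export
sbs96_labels <- function() {
  out <- character(0)
  for (s in SUBS6) {
    ref <- substr(s, 1, 1)
    for (p5 in BASES) for (p3 in BASES) {
      out <- c(out, paste0(p5, "[", s, "]", p3))
    }
  }
  out
}

#' Encode a single-base substitution into its SBS96 channel
#'
#' The trinucleotide context is the ref base with its 5' and 3' neighbors;
#' purine-reference mutations are reverse-complemented onto the pyrimidine
#' strand, so a mutation and its reverse complement share a channel.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context 3-base string with the middle base equal to `ref`.
#' @return integer channel index in 0..95 (vectorized).
#' @export
encode_sbs96 <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  if (any(!ref %in% BASES) || any(!alt %in% BASES) ||
      any(grepl("[^ACGT]", context))) {
    stop("ambiguous base in ref/alt/context")
  }
  if (any(nchar(context) != 3) || any(substr(context, 2, 2) != ref)) {
    stop("context must be 3 bases with the ref base in the middle")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  pur <- ref %in% c("A", "G")
  ref[pur] <- COMP[ref[pur]]
  alt[pur] <- COMP[alt[pur]]
  context[pur] <- revcomp(context[pur])
  si <- match(paste0(ref, ">", alt), SUBS6) - 1L
  p5 <- match(substr(context, 1, 1), BASES) - 1L
  p3 <- match(substr(context, 3, 3), BASES) - 1L
  si * 16L + p5 * 4L + p3
}

# ---- ID83 ----------------------------------------------------------------

#' Channel labels of the ID83 indel encoding
#'
#' COSMIC-style layout: 1bp deletions (C/T x homopolymer length 1..6+),
#' 1bp insertions (C/T x homopolymer length 0..5+), longer deletions and
#' insertions at repeats (length 2/3/4/5+ x repeat units), and deletions
#' with microhomology.
#'
#' @return character vector of 83 labels.
#' @export
id83_labels <- function() {
  lab <- character(0)
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Del:", b, ":", c(1:5, "6+")))
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Ins:", b, ":", c(0:4, "5+")))
  for (l in c("2", "3", "4", "5+")) {
    lab <- c(lab, paste0(l, ":Del:R:", c(1:5, "6+")))
  }
  for (l in c("2", "3", "4", "5+")) {
    lab <- c(lab, paste0(l, ":Ins:R:", c(0:4, "5+")))
  }
  lab <- c(lab, "2:Del:M:1", paste0("3:Del:M:", 1:2), paste0("4:Del:M:", 1:3),
           paste0("5+:Del:M:", c(1:4, "5+")))
  lab
}

count_prefix_repeats <- function(motif, flank) {
  # how many full copies of `motif` prefix `flank`
  k <- 0L
  L <- nchar(motif)
  while (nchar(flank) >= L * (k + 1) &&
         substr(flank, k * L + 1, (k + 1) * L) == motif) {
    k <- k + 1L
  }
  k
}

microhomology_len <- function(motif, flank5, flank3) {
  # longest proper prefix of motif matching the start of the 3' flank, or
  # proper suffix matching the end of the 5' flank
  L <- nchar(motif)
  best <- 0L
  for (k in seq_len(L - 1)) {
    if (substr(motif, 1, k) == substr(flank3, 1, k)) best <- max(best, k)
    if (substr(motif, L - k + 1, L) ==
        substr(flank5, nchar(flank5) - k + 1, nchar(flank5))) {
      best <- max(best, k)
    }
  }
  best
}

#' Encode an indel into its ID83 channel
#'
#' VCF-style alleles: a deletion has `ref` longer than `alt` (shared leading
#' base), an insertion the reverse. Flanking sequence is required for repeat
#' and microhomology context; with empty flanks the indel is classified as
#' `NA` (context unavailable) and excluded from ID fitting.
#'
#' @param ref,alt VCF ref/alt alleles.
#' @param flank5,flank3 sequence 5' and 3' of the event (the 3' flank starts
#'   immediately after the ref allele).
#' @return integer channel index in 0..82, or NA when context is missing.
#' @export
encode_id83 <- function(ref, alt, flank5 = "", flank3 = "") {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  flank5 <- rep_len(toupper(flank5), n); flank3 <- rep_len(toupper(flank3), n)
  labs <- id83_labels()
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    if (nchar(r) == nchar(a)) stop("not an indel: ", r, ">", a)
    is_del <- nchar(r) > nchar(a)
    long <- if (is_del) r else a
    short <- if (is_del) a else r
    if (substr(long, 1, nchar(short)) != short) {
      stop("alleles must share a leading base: ", r, ">", a)
    }
    motif <- substr(long, nchar(short) + 1, nchar(long))
    L <- nchar(motif)
    if (!nzchar(flank3[i])) next  # context unavailable
    if (L == 1) {
      base <- if (motif %in% c("A", "G")) COMP[[motif]] else motif
      # homopolymer run of the indel base in the 3' flank
      run3 <- count_prefix_repeats(motif, flank3[i])
      if (is_del) {
        hl <- min(run3 + 1L, 6L)         # includes the deleted base
        out[i] <- match(paste0("1:Del:", base, ":",
                               if (hl >= 6) "6+" else hl), labs) - 1L
      } else {
        hl <- min(run3, 5L)
        out[i] <- match(paste0("1:Ins:", base, ":",
                               if (hl >= 5) "5+" else hl), labs) - 1L
      }
    } else {
      lcl <- if (L >= 5) "5+" else as.character(L)
      rep3 <- count_prefix_repeats(motif, flank3[i])
      if (is_del) {
        if (rep3 >= 1) {
          units <- min(rep3 + 1L, 6L)    # includes the deleted copy
          out[i] <- match(paste0(lcl, ":Del:R:",
                                 if (units >= 6) "6+" else units), labs) - 1L
        } else {
          mh <- microhomology_len(motif, flank5[i], flank3[i])
          if (mh >= 1) {
            mhmax <- if (L >= 5) 5L else L - 1L
            mh <- min(mh, mhmax)
            mlab <- if (L >= 5 && mh >= 5) "5+" else as.character(mh)
            out[i] <- match(paste0(lcl, ":Del:M:", mlab), labs) - 1L
          } else {
            out[i] <- match(paste0(lcl, ":Del:R:1"), labs) - 1L
          }
        }
      } else {
        units <- min(rep3, 5L)
        out[i] <- match(paste0(lcl, ":Ins:R:",
                               if (units >= 5) "5+" else units), labs) - 1L
      }
    }
  }
  out
}

# ---- catalogs ------------------------------------------------------------

norm_cols <- function(m) sweep(m, 2, colSums(m), "/")

#' Synthetic SBS96 signature catalog
#'
#' Code-generated stand-in for a COSMIC-style catalog (the real reference
#' matrices are not redistributed here). Shapes are qualitative: an
#' age-related deamination signature with mass on N\[C>T\]G (SBS1-like), two
#' APOBEC-like signatures on T\[C>T/G\]W (SBS2-/SBS13-like), two broad
#' flat-ish signatures (SBS5-/SBS40-like) and a T\[T>G\]T-peaked signature
#' (SBS28-like). Columns sum to 1. Deterministic.
#'
#' @return 96 x 6 matrix with channel rownames and signature colnames.
#' @export
synthetic_sbs_catalog <- function() {
  labs <- sbs96_labels()
  S <- matrix(0, 96, 6, dimnames = list(labs,
    c("SBS1", "SBS2", "SBS5", "SBS13", "SBS28", "SBS40")))
  add <- function(sig, pattern, w) {
    hit <- grepl(pattern, labs)
    S[hit, sig] <<- S[hit, sig] + w / sum(hit)
  }
  add("SBS1", "\\[C>T\\]G$", 0.85); add("SBS1", ".", 0.15)
  add("SBS2", "^T\\[C>T\\][AT]$", 0.80); add("SBS2", "^T\\[C>T\\]", 0.10)
  add("SBS2", ".", 0.10)
  add("SBS13", "^T\\[C>G\\][AT]$", 0.80); add("SBS13", "^T\\[C>G\\]", 0.10)
  add("SBS13", ".", 0.10)
  add("SBS5", "\\[T>C\\]", 0.45); add("SBS5", "\\[C>T\\]", 0.25)
  add("SBS5", ".", 0.30)
  add("SBS28", "^T\\[T>G\\]T$", 0.70); add("SBS28", "\\[T>G\\]", 0.15)
  add("SBS28", ".", 0.15)
  add("SBS40", "\\[C>A\\]", 0.30); add("SBS40", "\\[T>A\\]", 0.20)
  add("SBS40", ".", 0.50)
  norm_cols(S)
}

#' Synthetic ID83 signature catalog
#'
#' Code-generated stand-in with the qualitative structure of the indel
#' signatures reported in IPMN/PDAC cohorts: T-homopolymer insertion
#' slippage (ID1-like), T-homopolymer deletion slippage (ID2-like), a broad
#' deletion signature (ID5-like), microhomology deletions (ID6-/ID8-like),
#' and mixed repeat signatures (ID9-/ID14-like). Columns sum to 1.
#'
#' @return 83 x 7 matrix.
#' @export
synthetic_id_catalog <- function() {
  labs <- id83_labels()
  S <- matrix(0, 83, 7, dimnames = list(labs,
    c("ID1", "ID2", "ID5", "ID6", "ID8", "ID9", "ID14")))
  add <- function(sig, pattern, w) {
    hit <- grepl(pattern, labs)
    S[hit, sig] <<- S[hit, sig] + w / sum(hit)
  }
  add("ID1", "^1:Ins:T:[45]", 0.8); add("ID1", "^1:Ins", 0.15)
  add("ID1", ".", 0.05)
  add("ID2", "^1:Del:T:[56]", 0.8); add("ID2", "^1:Del", 0.15)
  add("ID2", ".", 0.05)
  add("ID5", "^1:Del:T:[123]", 0.6); add("ID5", ".", 0.4)
  add("ID6", ":Del:M:", 0.75); add("ID6", "^5\\+:Del", 0.15); add("ID6", ".", 0.1)
  add("ID8", "^5\\+:Del:R:1", 0.5); add("ID8", ":Del:M:", 0.3); add("ID8", ".", 0.2)
  add("ID9", "^[23]:Del:R:", 0.6); add("ID9", ".", 0.4)
  add("ID14", ":Ins:R:", 0.6); add("ID14", "^1:Ins:C", 0.2); add("ID14", ".", 0.2)
  norm_cols(S)
}

#' Synthetic CN48 signature catalog
#'
#' Code-generated stand-in: a diploid-quiet signature (CN1-like), a
#' chromosomal-instability signature spread over gained states (CN9-like),
#' an amplification-heavy signature (CN24-like), and an LOH-dominated
#' signature (CN48B-like; LOH channels carry most of the mass). Columns sum
#' to 1.
#'
#' @return 48 x 4 matrix.
#' @export
synthetic_cn_catalog <- function() {
  labs <- cn48_labels()
  S <- matrix(0, 48, 4, dimnames = list(labs,
    c("CN1", "CN9", "CN24", "CN48B")))
  add <- function(sig, pattern, w) {
    hit <- grepl(pattern, labs)
    S[hit, sig] <<- S[hit, sig] + w / sum(hit)
  }
  add("CN1", "^2:het:(10Mb-40Mb|>40Mb)", 0.8); add("CN1", "^2:het", 0.2)
  add("CN9", "^3-4:het", 0.5); add("CN9", "^3-4:LOH", 0.2); add("CN9", ".", 0.3)
  add("CN24", "^(5-8|9\\+):", 0.7); add("CN24", ".", 0.3)
  add("CN48B", ":LOH:", 0.85); add("CN48B", "^0:homdel", 0.05)
  add("CN48B", ".", 0.1)
  norm_cols(S)
}

# ---- fitting -------------------------------------------------------------

#' Refit signature exposures by non-negative least squares
#'
#' NNLS of the channel counts on the catalog columns, with iterative
#' pruning: signatures whose activity falls below `prune_frac` of the total
#' are dropped and the remainder refit, until stable. Deterministic.
#'
#' @param channel_counts numeric vector, length = catalog rows.
#' @param catalog channels x signatures probability matrix (columns sum
#'   to 1).
#' @param prune_frac pruning threshold as a fraction of total activity
#'   (default 0.05).
#' @return named exposure vector (mutation-count scale) over all catalog
#'   signatures (pruned ones at 0).
#' @export
fit_exposures_nnls <- function(channel_counts, catalog, prune_frac = 0.05) {
  stopifnot(length(channel_counts) == nrow(catalog))
  sigs <- colnames(catalog)
  expo <- setNames(numeric(ncol(catalog)), sigs)
  if (sum(channel_counts) == 0) return(expo)
  active <- sigs
  repeat {
    fit <- pracma::lsqnonneg(catalog[, active, drop = FALSE],
                             as.numeric(channel_counts))
    x <- setNames(fit$x, active)
    tot <- sum(x)
    drop <- names(x)[x < prune_frac * tot & x < max(x)]
    if (!length(drop) || tot == 0) break
    active <- setdiff(active, drop)
  }
  expo[names(x)] <- x
  expo
}

#' Posterior signature probabilities for a mutation channel
#'
#' `P(s | channel c) = e_s S_cs / sum_s' e_s' S_cs'`. Channels with zero
#' density under every active signature get a uniform row over active
#' signatures, flagged via the `"flat"` attribute. The hard assignment is
#' the row argmax with ties broken by catalog order.
#'
#' @param channel integer channel indices (0-based) or channel labels.
#' @param exposures named exposure vector (see [fit_exposures_nnls()]).
#' @param catalog channels x signatures matrix.
#' @return matrix of probabilities (rows sum to 1) with attribute
#'   `assignment` (signature names) and `flat` (logical).
#' @export
mutation_signature_probability <- function(channel, exposures, catalog) {
  if (sum(exposures) <= 0) stop("exposure total must be positive")
  if (is.character(channel)) channel <- match(channel, rownames(catalog)) - 1L
  act <- names(exposures)[exposures > 0]
  dens <- sweep(catalog[channel + 1L, act, drop = FALSE], 2,
                exposures[act], "*")
  tot <- rowSums(dens)
  flat <- tot <= 0
  P <- matrix(0, length(channel), length(exposures),
              dimnames = list(NULL, names(exposures)))
  P[, act] <- dens / ifelse(tot > 0, tot, 1)
  if (any(flat)) P[flat, act] <- 1 / length(act)
  attr(P, "assignment") <- colnames(P)[apply(P, 1, which.max)]
  attr(P, "flat") <- flat
  P
}

#' Per-branch signature profiles of a clone tree
#'
#' For every cluster (branch) of the tree, either refits exposures on the
#' branch channel counts by NNLS (default) or sums per-mutation posterior
#' probabilities. Proportions sum to 1 per non-empty branch; branches with
#' fewer than `min_mutations` are flagged low-confidence.
#'
#' @param tree a `clone_tree`.
#' @param channels integer vector of SBS96 channels (0-based), one per
#'   mutation.
#' @param cluster cluster label per mutation (matching tree node names).
#' @param catalog channels x signatures matrix.
#' @param method "refit" or "probability".
#' @param prune_frac passed to [fit_exposures_nnls()].
#' @param min_mutations low-confidence flag threshold.
#' @return branches x signatures matrix of proportions, with attribute
#'   `low_confidence`.
#' @export
branch_signature_profile <- function(tree, channels, cluster, catalog,
                                     method = c("refit", "probability"),
                                     prune_frac = 0.05, min_mutations = 20) {
  method <- match.arg(method)
  out <- matrix(0, length(tree$nodes), ncol(catalog),
                dimnames = list(tree$nodes, colnames(catalog)))
  lowconf <- setNames(rep(FALSE, length(tree$nodes)), tree$nodes)
  for (nd in tree$nodes) {
    ch <- channels[cluster == nd & !is.na(channels)]
    if (!length(ch)) { lowconf[nd] <- TRUE; next }
    if (length(ch) < min_mutations) lowconf[nd] <- TRUE
    counts <- tabulate(ch + 1L, nbins = nrow(catalog))
    if (method == "refit") {
      e <- fit_exposures_nnls(counts, catalog, prune_frac)
    } else {
      e0 <- fit_exposures_nnls(counts, catalog, prune_frac)
      if (sum(e0) == 0) { lowconf[nd] <- TRUE; next }
      P <- mutation_signature_probability(ch, e0, catalog)
      e <- colSums(P)
    }
    if (sum(e) > 0) out[nd, ] <- e / sum(e)
  }
  attr(out, "low_confidence") <- lowconf
  out
}

# ---- de novo NNMF --------------------------------------------------------

kl_div <- function(V, WH) {
  ok <- V > 0
  sum(V[ok] * log(V[ok] / WH[ok])) - sum(V) + sum(WH)
}

#' De-novo signature extraction by KL-divergence NNMF
#'
#' Multiplicative-update non-negative matrix factorization minimizing the
#' generalized Kullback-Leibler divergence, best of `n_restarts` random
#' initializations. Signature columns are normalized to sum to 1 (exposures
#' rescaled accordingly).
#'
#' @param count_matrix samples x channels count matrix.
#' @param k number of signatures (rank).
#' @param n_restarts random restarts (best objective kept).
#' @param seed RNG seed.
#' @param max_iter,tol stopping rule for the multiplicative updates.
#' @return list with `signatures` (channels x k, columns sum to 1),
#'   `exposures` (k x samples), `objective` (final KL divergence) and
#'   `objective_trace` of the best run.
#' @export
extract_denovo_nnmf <- function(count_matrix, k, n_restarts = 5, seed = 1,
                                max_iter = 500, tol = 1e-6) {
  V <- t(as.matrix(count_matrix))   # channels x samples
  if (any(V < 0)) stop("counts must be non-negative")
  if (k > min(dim(V))) stop("k exceeds matrix rank bound")
  if (k < 1) stop("k must be >= 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(runif(k * ncol(V), 0.1, 1), k, ncol(V))
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      WH <- W %*% H + 1e-12
      W <- W * ((V / WH) %*% t(H)) / pmax(matrix(rowSums(H), nrow(V), k,
                                                 byrow = TRUE), 1e-12)
      WH <- W %*% H + 1e-12
      H <- H * (t(W) %*% (V / WH)) / pmax(matrix(colSums(W), k, ncol(V)),
                                          1e-12)
      cur <- kl_div(V, W %*% H + 1e-12)
      obj <- c(obj, cur)
      if (is.finite(prev) && prev - cur < tol * max(1, abs(prev))) break
      prev <- cur
    }
    if (is.null(best) || cur < best$objective) {
      best <- list(W = W, H = H, objective = cur, objective_trace = obj)
    }
  }
  scl <- colSums(best$W)
  W <- sweep(best$W, 2, scl, "/")
  H <- sweep(best$H, 1, scl, "*")
  colnames(W) <- rownames(H) <- paste0("DN", seq_len(k))
  if (!is.null(colnames(count_matrix))) rownames(W) <- colnames(count_matrix)
  if (!is.null(rownames(count_matrix))) colnames(H) <- rownames(count_matrix)
  list(signatures = W, exposures = H, objective = best$objective,
       objective_trace = best$objective_trace)
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
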