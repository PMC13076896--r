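# Per-mutation genomic computations: VAF <-> CCF conversion, multiplicity,
# timing class, TMB, SV classification, CN48 channel encoding.

#' Expected variant allele fraction of a mutation
#'
#' For a mutation carried by a fraction `ccf` of tumor cells at multiplicity
#' `m` (mutated copies per carrying cell), in a sample of purity `rho` whose
#' tumor cells have `n_t` total copies at the locus (normal cells `n_normal`),
#' the expected VAF is
#' \deqn{f = \frac{ccf \cdot \rho \cdot m}{\rho \, n_t + (1-\rho) \, n_{normal}}.}
#' Exact inverse of [compute_ccf()].
#'
#' @param ccf cancer cell fraction, in `[0, 1.25]` (values above 1 arise from
#'   noise and are tolerated up to the cap used by [compute_ccf()]).
#' @param rho tumor purity in `(0, 1]`.
#' @param m mutation multiplicity, integer `>= 1`.
#' @param n_t total tumor copy number at the locus, `>= 1`.
#' @param n_normal normal-cell copy number (2 for autosomes).
#' @return expected VAF (vectorized).
#' @export
#' @examples
#' expected_vaf(1, 1, 1, 2)    # 0.5: clonal heterozygous, pure diploid
#' expected_vaf(1, 0.5, 1, 2)  # 0.25
expected_vaf <- function(ccf, rho, m, n_t, n_normal = 2) {
  stopifnot(all(ccf >= 0), all(ccf <= 1.25 + 1e-9),
            all(rho > 0), all(rho <= 1), all(m >= 1), all(n_t >= 1))
  ccf * rho * m / (rho * n_t + (1 - rho) * n_normal)
}

#' Cancer cell fraction from an observed VAF
#'
#' Inverts [expected_vaf()]:
#' `ccf = vaf * (rho * n_t + (1 - rho) * n_normal) / (rho * m)`.
#' Values above `cap` (default 1.25, the upper end of the clustering prior)
#' are capped; the returned vector carries a logical `"capped"` attribute.
#'
#' @inheritParams expected_vaf
#' @param vaf observed variant allele fraction.
#' @param cap upper cap on the returned CCF.
#' @return numeric CCF vector with attribute `capped`.
#' @export
compute_ccf <- function(vaf, rho, m, n_t, n_normal = 2, cap = 1.25) {
  stopifnot(all(rho > 0), all(rho <= 1), all(m >= 1), all(n_t >= 1),
            all(vaf >= 0), all(vaf <= 1))
  ccf <- vaf * (rho * n_t + (1 - rho) * n_normal) / (rho * m)
  capped <- ccf > cap
  ccf[capped] <- cap
  attr(ccf, "capped") <- capped
  ccf
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Estimate mutation multiplicity from an observed VAF
#'
#' `m = clamp(round(vaf * (rho * n_t + (1 - rho) * 2) / rho), 1, major)`,
#' with ties rounded half away from zero. Assumes the mutation is (near-)
#' clonal in the carrying cells; used to fix multiplicities before
#' clustering.
#'
#' @inheritParams compute_ccf
#' @param major major allele copy number at the locus (upper bound on m).
#' @return integer multiplicity in `1..major`.
#' @export
estimate_multiplicity <- function(vaf, rho, n_t, major, n_normal = 2) {
  stopifnot(all(major >= 1))
  raw <- vaf * (rho * n_t + (1 - rho) * n_normal) / rho
  m <- round_half_up(raw)
  pmax(1L, pmin(as.integer(major), as.integer(m)))
}

#' Estimate multiplicities jointly across regions
#'
#' The per-region estimator is noisy at low purity (a VAF fluctuation flips
#' the rounded multiplicity and displaces the implied CCF two-fold). Since
#' copy-number events handled here are clonal, a mutation's multiplicity is
#' shared across regions: this estimator takes the median of the raw
#' per-region mutation copy numbers over regions where the mutation is
#' observed (`alt > 0`), rounds half away from zero, and clamps to
#' `1..major`.
#'
#' @param vaf,depth mutations x regions matrices.
#' @param rho per-region purity vector.
#' @param n_t,major locus copy-number matrices (or vectors recycled).
#' @param n_normal normal copy number.
#' @return integer vector of multiplicities (one per mutation).
#' @export
estimate_multiplicity_joint <- function(vaf, depth, rho, n_t, major,
                                        n_normal = 2) {
  vaf <- as.matrix(vaf); depth <- as.matrix(depth)
  n <- nrow(vaf); D <- ncol(vaf)
  expand <- function(x) if (is.matrix(x)) x else matrix(x, n, D)
  n_t <- expand(n_t); major <- expand(major)
  raw <- sweep(vaf * (sweep(n_t, 2, rho, "*") +
                        matrix(rep((1 - rho) * n_normal, each = n), n, D)),
               2, rho, "/")
  present <- vaf > 0 & depth > 0
  m <- vapply(seq_len(n), function(i) {
    if (!any(present[i, ])) return(1L)
    as.integer(round_half_up(median(raw[i, present[i, ]])))
  }, integer(1))
  pmax(1L, pmin(m, apply(major, 1, max)))
}

#' Timing classes
#' @keywords internal
timing_levels <- c("clonal_early", "clonal_late", "clonal_unspecified", "subclonal")

#' Classify mutation timing relative to copy-number gains
#'
#' Mutations in non-truncal clusters are `subclonal`. Truncal mutations at
#' gained loci (`major >= 2`) are `clonal_early` when present on multiple
#' copies (`m >= 2`, i.e. they preceded the gain) and `clonal_late` when on a
#' single copy; truncal mutations at unamplified loci are
#' `clonal_unspecified`.
#'
#' @param cluster_is_trunk logical; does the mutation belong to the truncal
#'   (MRCA) cluster?
#' @param m multiplicity.
#' @param major,minor allele-specific copy numbers at the locus.
#' @return factor with levels clonal_early, clonal_late, clonal_unspecified,
#'   subclonal.
#' @export
classify_timing <- function(cluster_is_trunk, m, major, minor) {
  if (any(m > major)) stop("multiplicity exceeds major allele copy number")
  out <- rep("clonal_unspecified", length(m))
  out[major >= 2 & m >= 2] <- "clonal_early"
  out[major >= 2 & m == 1] <- "clonal_late"
  out[!cluster_is_trunk] <- "subclonal"
  factor(out, levels = timing_levels)
}

#' Tumor mutation burden
#'
#' @param n_snv,n_indel mutation counts.
#' @param callable_mb callable genome size in megabases (default 3000,
#'   whole genome).
#' @return mutations per megabase.
#' @export
compute_tmb <- function(n_snv, n_indel, callable_mb = 3000) {
  stopifnot(all(callable_mb > 0))
  (n_snv + n_indel) / callable_mb
}

sv_classes <- c("deletion", "tandem_duplication", "inversion",
                "translocation", "unclassified")

#' Canonicalize structural-variant breakpoint records
#'
#' Orders intrachromosomal breakpoints so `pos1 <= pos2` (swapping strands
#' along with positions).
#'
#' @param sv data.frame with columns chrom1, pos1, strand1, chrom2, pos2,
#'   strand2.
#' @return the canonicalized data.frame.
#' @export
canonicalize_sv <- function(sv) {
  swap <- sv$chrom1 == sv$chrom2 & sv$pos1 > sv$pos2
  if (any(swap)) {
    tmp <- sv[swap, c("pos1", "strand1")]
    sv$pos1[swap] <- sv$pos2[swap]
    sv$strand1[swap] <- sv$strand2[swap]
    sv$pos2[swap] <- tmp$pos1
    sv$strand2[swap] <- tmp$strand1
  }
  sv
}

#' Classify structural variants from breakpoint strand pattern
#'
#' Uses the discordant read-pair convention on canonicalized records:
#' different chromosomes give `translocation`; on one chromosome, strands
#' `(+,-)` give `deletion`, `(-,+)` `tandem_duplication`, and `(+,+)`/`(-,-)`
#' `inversion`. Records with missing strands are `unclassified`.
#'
#' @param sv data.frame of breakpoints (see [canonicalize_sv()]).
#' @return factor of SV classes.
#' @export
classify_sv <- function(sv) {
  sv <- canonicalize_sv(sv)
  out <- rep("unclassified", nrow(sv))
  ok <- !is.na(sv$strand1) & !is.na(sv$strand2) &
    sv$strand1 %in% c("+", "-") & sv$strand2 %in% c("+", "-")
  inter <- ok & sv$chrom1 != sv$chrom2
  out[inter] <- "translocation"
  intra <- ok & sv$chrom1 == sv$chrom2
  out[intra & sv$strand1 == "+" & sv$strand2 == "-"] <- "deletion"
  out[intra & sv$strand1 == "-" & sv$strand2 == "+"] <- "tandem_duplication"
  out[intra & sv$strand1 == sv$strand2] <- "inversion"
  factor(out, levels = sv_classes)
}

#' Channel labels of the 48-channel copy-number encoding
#'
#' Homozygous deletions use 3 length classes; LOH segments (minor = 0,
#' total >= 1) use total-copy classes 1/2/3-4/5-8/9+ and het segments
#' (minor >= 1) classes 2/3-4/5-8/9+, each crossed with 5 length classes.
#'
#' @return character vector of 48 labels in channel order.
#' @export
cn48_labels <- function() {
  len3 <- c("0-100kb", "100kb-1Mb", ">1Mb")
  len5 <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
  c(paste0("0:homdel:", len3),
    as.vector(t(outer(c("1", "2", "3-4", "5-8", "9+"),
                      len5, function(a, b) paste0(a, ":LOH:", b)))),
    as.vector(t(outer(c("2", "3-4", "5-8", "9+"),
                      len5, function(a, b) paste0(a, ":het:", b)))))
}

#' Encode a copy-number segment into the 48-channel scheme
#'
#' Deterministic mapping by heterozygosity status (homozygous deletion / LOH
#' / het), total-copy class and segment-length class; see [cn48_labels()]
#' for the layout. Returns 0-based channel indices.
#'
#' @param major,minor allele-specific copy numbers (`major >= minor >= 0`).
#' @param length_bp segment length in base pairs.
#' @return integer channel index in 0..47.
#' @export
encode_cn48 <- function(major, minor, length_bp) {
  stopifnot(all(major >= minor), all(minor >= 0), all(length_bp > 0))
  n <- length(major)
  total <- major + minor
  out <- integer(n)
  len3 <- findInterval(length_bp, c(0, 1e5, 1e6) + 1)        # 1..3
  len5 <- findInterval(length_bp, c(0, 1e5, 1e6, 1e7, 4e7) + 1) # 1..5
  tcl_loh <- findInterval(total, c(1, 2, 3, 5, 9))           # 1..5
  tcl_het <- findInterval(total, c(2, 3, 5, 9))              # 1..4
  homdel <- total == 0
  loh <- !homdel & minor == 0
  het <- minor >= 1
  out[homdel] <- len3[homdel] - 1L
  out[loh] <- 3L + (tcl_loh[loh] - 1L) * 5L + (len5[loh] - 1L)
  out[het] <- 28L + (tcl_het[het] - 1L) * 5L + (len5[het] - 1L)
  out
}

#' Per-mutation feature table
#'
#' Convenience wrapper combining VAF, multiplicity estimation and CCF for a
#' set of mutations in one region.
#'
#' @param alt_count,depth read counts.
#' @param rho purity of the region.
#' @param major,minor locus allele-specific copy numbers.
#' @return data.frame with vaf, multiplicity, ccf, ccf_capped.
#' @export
mutation_features <- function(alt_count, depth, rho, major, minor) {
  stopifnot(all(alt_count <= depth))
  vaf <- ifelse(depth > 0, alt_count / depth, NA_real_)
  n_t <- major + minor
  m <- estimate_multiplicity(ifelse(is.na(vaf), 0, vaf), rho, n_t, pmax(1, major))
  ccf <- compute_ccf(ifelse(is.na(vaf), 0, vaf), rho, m, pmax(1, n_t))
  data.frame(vaf = vaf, multiplicity = m, ccf = as.numeric(ccf),
             ccf_capped = attr(ccf, "capped"))
}
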