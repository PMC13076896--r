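# Readers/writers for the formats the pipeline touches: VCF (via vcfR),
# BEDPE, Battenberg-style segment and purity tables, expression TSV, GMT
# gene sets, YAML cohort manifests.
#
# Coordinate conventions: 1-based inclusive internally; BEDPE is read as
# 0-based half-open and converted on ingest.

#' Read somatic calls from a VCF
#'
#' One row per PASS record and alt allele (multi-allelic records are split).
#' Alt/ref depths are taken from the `AD` FORMAT field (first sample);
#' records without usable depths are skipped with a message. An optional
#' `TNC=` INFO key (trinucleotide context), `GENE=` and `DRIVER` flags are
#' carried through when present.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param region_id label attached to every returned call.
#' @return data.frame with columns chrom, pos, ref, alt, alt_count, depth,
#'   region_id, context, gene, driver.
#' @export
read_vcf <- function(path, region_id) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fixm))) fixm <- matrix(fixm, nrow = 1,
                                         dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alt_count = integer(),
                      depth = integer(), region_id = character(),
                      context = character(), gene = character(),
                      driver = logical(), stringsAsFactors = FALSE))
  }
  gt <- v@gt
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  if (is.null(gt) || ncol(gt) < 2) stop("VCF has no sample column: ", path)
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  smp <- strsplit(gt[, 2], ":", fixed = TRUE)
  info <- fix$INFO
  grab <- function(key) {
    vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]*"), info)),
           function(x) {
             if (length(x)) sub(paste0(".*", key, "="), "", x[[1]])
             else NA_character_
           }, character(1))
  }
  ctx <- grab("TNC")
  gene <- grab("GENE")
  driver <- grepl("(^|;)DRIVER(;|$)", info)
  pass <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    if (!pass[i]) next
    adx <- match("AD", fmt[[i]])
    if (is.na(adx) || adx > length(smp[[i]])) {
      stop("record ", fix$CHROM[i], ":", fix$POS[i], " has no AD depth field")
    }
    ad <- suppressWarnings(as.integer(strsplit(smp[[i]][adx], ",", fixed = TRUE)[[1]]))
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (any(is.na(ad)) || length(ad) < 1 + length(alts)) { skipped <- skipped + 1L; next }
    dpx <- match("DP", fmt[[i]])
    dp <- if (!is.na(dpx) && dpx <= length(smp[[i]])) {
      suppressWarnings(as.integer(smp[[i]][dpx]))
    } else sum(ad)
    if (is.na(dp)) dp <- sum(ad)
    for (a in seq_along(alts)) {
      if (ad[1 + a] > dp) {
        stop("alt_count exceeds depth at ", fix$CHROM[i], ":", fix$POS[i])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        alt_count = ad[1 + a], depth = dp, region_id = region_id,
        context = ctx[i], gene = gene[i], driver = driver[i],
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) message(skipped, " record(s) without usable depths skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write somatic calls as a minimal VCF 4.2 file
#'
#' Single-sample VCF with `AD` and `DP` FORMAT fields and optional `TNC`,
#' `GENE`, `DRIVER` INFO keys; the exact inverse of [read_vcf()] on files it
#' writes.
#'
#' @param calls data.frame as returned by [read_vcf()] (ref_count implied by
#'   depth - alt_count).
#' @param path output path.
#' @param sample_name sample column header.
#' @export
write_vcf <- function(calls, path, sample_name = "TUMOR") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context of the ref base\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=DRIVER,Number=0,Type=Flag,Description=\"Driver mutation\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  info <- rep(".", nrow(calls))
  if (nrow(calls)) {
    parts <- mapply(function(ctx, gene, drv) {
      p <- character()
      if (!is.na(ctx)) p <- c(p, paste0("TNC=", ctx))
      if (!is.na(gene)) p <- c(p, paste0("GENE=", gene))
      if (isTRUE(drv)) p <- c(p, "DRIVER")
      if (length(p)) paste(p, collapse = ";") else "."
    }, calls$context, calls$gene, calls$driver)
    info <- unname(parts)
  }
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          info, "AD:DP",
          paste0(calls$depth - calls$alt_count, ",", calls$alt_count, ":",
                 calls$depth),
          sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Tab-separated with header columns chrom, start, end, major, minor (and
#' optionally region_id). Coordinates are 1-based inclusive. Overlapping
#' segments within a region are an error.
#'
#' @param path segment TSV.
#' @param region_id region label if the file lacks a region_id column.
#' @return data.frame of segments.
#' @export
read_segments <- function(path, region_id = NULL) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  seg <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "major", "minor")
  if (!all(need %in% names(seg))) {
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  }
  if (!("region_id" %in% names(seg))) {
    seg$region_id <- if (is.null(region_id)) NA_character_ else region_id
  }
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  if (any(is.na(seg$start)) || any(is.na(seg$end))) stop("coordinate parse failure")
  if (any(seg$start > seg$end)) stop("segment with start > end")
  if (any(seg$major < 0 | seg$minor < 0)) stop("negative copy numbers")
  if (any(seg$major < seg$minor)) stop("major < minor in segment file")
  for (rg in unique(seg$region_id)) {
    for (ch in unique(seg$chrom[seg$region_id %in% rg])) {
      s <- seg[seg$region_id %in% rg & seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop("overlapping segments on ", ch, " in region ", rg)
      }
    }
  }
  seg
}

#' Write a segment table
#' @param seg data.frame of segments.
#' @param path output TSV.
#' @export
write_segments <- function(seg, path) {
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read structural variants from BEDPE
#'
#' BEDPE is 0-based half-open; breakpoint positions are converted to the
#' 1-based end coordinate of each interval on ingest. Records are
#' canonicalized ([canonicalize_sv()]) and classified ([classify_sv()]).
#'
#' @param path BEDPE file (chrom1 start1 end1 chrom2 start2 end2 name score
#'   strand1 strand2).
#' @param region_id region label.
#' @return data.frame with chrom1, pos1, strand1, chrom2, pos2, strand2,
#'   sv_class, region_id.
#' @export
read_bedpe <- function(path, region_id) {
  if (!file.exists(path)) stop("BEDPE not found: ", path)
  first <- readLines(path, n = 1)
  bp <- read.table(path, header = grepl("^#?chrom1", first),
                   sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "")
  if (nrow(bp) && is.character(bp[[2]])) stop("coordinate parse failure in BEDPE")
  if (ncol(bp) < 10) stop("BEDPE needs 10 columns")
  names(bp)[1:10] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                       "name", "score", "strand1", "strand2")
  sv <- data.frame(chrom1 = as.character(bp$chrom1), pos1 = bp$end1,
                   strand1 = bp$strand1,
                   chrom2 = as.character(bp$chrom2), pos2 = bp$end2,
                   strand2 = bp$strand2,
                   region_id = region_id, stringsAsFactors = FALSE)
  sv <- canonicalize_sv(sv)
  sv$sv_class <- classify_sv(sv)
  sv
}

#' Write structural variants as BEDPE
#' @param sv data.frame as from [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(sv, path) {
  bp <- data.frame(chrom1 = sv$chrom1, start1 = sv$pos1 - 1L, end1 = sv$pos1,
                   chrom2 = sv$chrom2, start2 = sv$pos2 - 1L, end2 = sv$pos2,
                   name = seq_len(nrow(sv)), score = ".",
                   strand1 = sv$strand1, strand2 = sv$strand2)
  write.table(bp, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("chrom1", "start1", "end1", "chrom2", "start2",
                            "end2", "name", "score", "strand1", "strand2"))
  invisible(path)
}

#' Read a purity file
#'
#' Tab-separated with columns region_id, purity (one row per region), or a
#' single purity value.
#'
#' @param path purity TSV.
#' @return named numeric vector of purities.
#' @export
read_purity <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  rho <- setNames(as.numeric(tb$purity), tb$region_id)
  if (any(rho <= 0 | rho > 1)) stop("purity must be in (0, 1]")
  rho
}

#' Write a purity file
#' @param rho named numeric vector (names = region ids).
#' @param path output TSV.
#' @export
write_purity <- function(rho, path) {
  write.table(data.frame(region_id = names(rho), purity = as.numeric(rho)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix (TPM scale)
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (any(m < 0)) stop("negative expression values")
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix
#' @param expr genes x samples matrix.
#' @param path output TSV.
#' @export
write_expression <- function(expr, path) {
  tb <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT-style gene sets
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  if (any(!lengths(sets))) stop("empty gene set in ", path)
  sets
}

#' Write GMT-style gene sets
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' YAML listing patients, their regions, per-region file paths (vcf, bedpe,
#' segments), a purity file, optional expression path and per-region
#' histology labels (LGD, HGD, HGD_microinvasive, PDAC). Region ids must be
#' unique within a patient and every referenced path must resolve;
#' multi-region clustering requires at least 2 regions.
#'
#' @param path manifest YAML.
#' @param check_paths verify that referenced files exist (default TRUE).
#' @return list of per-patient entries.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  histologies <- c("LGD", "HGD", "HGD_microinvasive", "PDAC")
  for (p in man$patients) {
    if (anyDuplicated(p$region_ids)) {
      stop("duplicate region ids for patient ", p$patient_id)
    }
    if (length(p$region_ids) < 2) {
      stop("patient ", p$patient_id, " has < 2 regions")
    }
    if (!all(unlist(p$histology) %in% histologies)) {
      stop("unknown histology label for patient ", p$patient_id)
    }
    if (check_paths) {
      paths <- c(unlist(p$vcf), unlist(p$bedpe), unlist(p$segments), p$purity,
                 p$expression)
      paths <- file.path(base, paths)
      miss <- paths[!file.exists(paths)]
      if (length(miss)) stop("missing files for patient ", p$patient_id, ": ",
                             paste(miss, collapse = ", "))
    }
  }
  man$base_dir <- base
  man
}
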