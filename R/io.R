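## Containers and text-format I/O shared by the phasing and popgen stages.

#' Variant table container
#'
#' Desk-scale in-memory representation of a set of biallelic (or
#' multi-allelic, pre-filtering) variant sites with per-sample genotypes and
#' depths, as produced by a short-read genotyper. Positions follow the VCF
#' convention (1-based).
#'
#' @param sites data.frame with at least `scaffold`, `pos`, `ref`, `alt`
#'   (comma-separated for multi-allelic sites) and `qual`; strand/placement
#'   support counts `SAF`, `SAR`, `RPL`, `RPR` are required by
#'   [filter_variants()].
#' @param gt character matrix (sites x samples) of genotypes written with
#'   allele letters, e.g. `"A/C"` (diploid) or `"A"` (haploid); `NA` =
#'   missing.
#' @param dp numeric matrix (sites x samples) of genotype depths.
#' @param samples data.frame with `sample_id` and `sex` ("M"/"F").
#' @return list of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp, samples) {
  .ns_assert(nrow(gt) == nrow(sites) && nrow(dp) == nrow(sites),
             "gt/dp must have one row per site")
  .ns_assert(ncol(gt) == nrow(samples) && ncol(dp) == nrow(samples),
             "gt/dp must have one column per sample")
  .ns_assert(all(samples$sex %in% c("M", "F")), "sample sex must be 'M' or 'F'")
  colnames(gt) <- colnames(dp) <- samples$sample_id
  structure(list(sites = sites, gt = gt, dp = dp, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%d F, %d M)\n",
              nrow(x$sites), nrow(x$samples),
              sum(x$samples$sex == "F"), sum(x$samples$sex == "M")))
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt a [variant_table()].
#' @export
n_sites <- function(vt) nrow(vt$sites)

## subset a variant_table by site index, preserving structure
vt_subset <- function(vt, idx) {
  variant_table(vt$sites[idx, , drop = FALSE],
                vt$gt[idx, , drop = FALSE],
                vt$dp[idx, , drop = FALSE],
                vt$samples)
}

#' Write a variant table as VCF text
#'
#' Emits a minimal VCF 4.2 file with `SAF/SAR/RPL/RPR` INFO fields (when
#' present) and `GT:DP` genotype fields. Genotype allele letters are
#' converted to VCF allele indices.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  s <- vt$sites
  info_keys <- intersect(c("SAF", "SAR", "RPL", "RPR"), names(s))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=neosex",
           sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"%s\">",
                   info_keys, info_keys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples$sample_id), collapse = "\t"))
  rows <- vapply(seq_len(nrow(s)), function(i) {
    alleles <- c(s$ref[i], strsplit(s$alt[i], ",", fixed = TRUE)[[1]])
    info <- if (length(info_keys))
      paste(sprintf("%s=%s", info_keys,
                    vapply(info_keys, function(k) as.character(s[[k]][i]), "")),
            collapse = ";") else "."
    gts <- vapply(seq_len(ncol(vt$gt)), function(j) {
      g <- vt$gt[i, j]
      gt <- if (is.na(g)) {
        "./."
      } else {
        idx <- match(strsplit(g, "/", fixed = TRUE)[[1]], alleles) - 1L
        if (anyNA(idx)) .ns_stop("genotype allele not in REF/ALT at row ", i)
        paste(idx, collapse = "/")
      }
      paste0(gt, ":", vt$dp[i, j])
    }, "")
    paste(c(s$scaffold[i], s$pos[i], ".", s$ref[i], s$alt[i],
            format(s$qual[i]), "PASS", info, "GT:DP", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a VCF into a variant table
#'
#' Parses a VCF with `vcfR` and converts genotype indices back to allele
#' letters. Non-SNP records are accepted here; [filter_variants()] handles
#' their removal and [validate_snps()] can reject them outright.
#'
#' @param path VCF path (plain text or gzipped).
#' @param sexes data.frame with `sample_id`, `sex`, covering all VCF samples.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, sexes) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .ns_stop("read_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- data.frame(scaffold = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      qual = as.numeric(fix$QUAL), stringsAsFactors = FALSE)
  for (k in c("SAF", "SAR", "RPL", "RPR")) {
    val <- suppressWarnings(vcfR::extract.info(v, element = k, as.numeric = TRUE))
    if (!all(is.na(val))) sites[[k]] <- val
  }
  gt_idx <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  dp[is.na(dp)] <- 0
  samp <- colnames(gt_idx)
  sex_map <- setNames(sexes$sex, sexes$sample_id)
  if (anyNA(sex_map[samp]))
    .ns_stop("sexes table is missing sample(s): ",
             paste(samp[is.na(sex_map[samp])], collapse = ", "))
  gt <- matrix(NA_character_, nrow(sites), length(samp))
  for (i in seq_len(nrow(sites))) {
    alleles <- c(sites$ref[i], strsplit(sites$alt[i], ",", fixed = TRUE)[[1]])
    for (j in seq_along(samp)) {
      g <- gt_idx[i, j]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
      if (anyNA(idx)) next
      gt[i, j] <- paste(alleles[idx], collapse = "/")
    }
  }
  variant_table(sites, gt, dp,
                data.frame(sample_id = samp, sex = unname(sex_map[samp]),
                           stringsAsFactors = FALSE))
}

#' Read CDS intervals from a GFF3 file
#'
#' Extracts CDS features for one gene (or all genes) from a GFF3 annotation
#' using `rtracklayer`, returning 1-based inclusive intervals in
#' transcription order.
#'
#' @param path GFF3 path.
#' @param gene_id optional gene identifier to filter on (matched against the
#'   `Parent` or `gene_id` attribute).
#' @return data.frame with `gene_id`, `scaffold`, `start`, `end`, `strand`.
#' @export
read_cds_gff3 <- function(path, gene_id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    .ns_stop("read_cds_gff3() requires the rtracklayer package")
  g <- rtracklayer::import(path)
  g <- g[g$type == "CDS"]
  parent <- if (!is.null(g$Parent)) vapply(g$Parent, function(p) p[1] %||% NA_character_, "")
            else if (!is.null(g$gene_id)) g$gene_id else rep(NA_character_, length(g))
  df <- data.frame(gene_id = sub("^transcript:", "", parent),
                   scaffold = as.character(GenomicRanges::seqnames(g)),
                   start = GenomicRanges::start(g), end = GenomicRanges::end(g),
                   strand = as.character(GenomicRanges::strand(g)),
                   stringsAsFactors = FALSE)
  if (!is.null(gene_id)) df <- df[df$gene_id == gene_id, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

#' Read / write alignments as FASTA
#'
#' Alignments are plain uppercase character matrices (rows = sequences,
#' rownames = labels). FASTA parsing and writing is delegated to `ape`.
#'
#' @param path FASTA path.
#' @return `read_alignment()`: a character matrix.
#' @export
read_alignment <- function(path) {
  x <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(x)))
  rownames(m) <- names(x)
  m
}

#' @rdname read_alignment
#' @param aln character matrix alignment.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(ape::as.DNAbin(aln), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open, first three columns used).
#' @return data.frame with `scaffold`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    b <- rtracklayer::import.bed(path)
    data.frame(scaffold = as.character(GenomicRanges::seqnames(b)),
               start = GenomicRanges::start(b) - 1L, end = GenomicRanges::end(b),
               stringsAsFactors = FALSE)
  } else {
    b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
    names(b) <- c("scaffold", "start", "end")
    b
  }
}

## merge possibly-overlapping half-open intervals within one scaffold
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

## total overlap (bp) of merged intervals with window [ws, we)
interval_overlap_bp <- function(ivs, ws, we) {
  if (nrow(ivs) == 0L) return(0)
  s <- pmax(ivs$start, ws); e <- pmin(ivs$end, we)
  sum(pmax(0, e - s))
}
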