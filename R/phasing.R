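## Phasing of coding sequence into Z and W haplotypes from male/female
## genotypes called against a W-depleted reference.
##
## Mapping contract: the reference carries no W scaffolds, so female reads
## from the W gametolog co-map onto the Z scaffold. ZZ males are then
## informative about the Z allele, and the female-specific allele is the W.

#' Phase one site into a (Z, W) allele pair
#'
#' Applies the sex-hemizygosity truth table to the genotypes at a single
#' site of a Z-linked CDS:
#' \itemize{
#'   \item site quality below `phase_min_q`, or any used sample depth below
#'     `phase_min_depth`, masks the site: `(N, N)`;
#'   \item all samples homozygous for one allele `a`: invariant, `(a, a)`;
#'   \item every male homozygous `a` and every female carrying one shared
#'     second allele `b` (heterozygous `a/b` or homozygous `b`): `(a, b)` -
#'     the female-specific allele is the co-mapped W copy;
#'   \item anything else (male heterozygosity = Z polymorphism, conflicting
#'     or multiple female-specific alleles): `(N, N)`.
#' }
#'
#' @param genotypes data.frame with one row per sample: `sex` ("M"/"F"),
#'   `allele1`, `allele2` (single characters, `NA` = missing genotype) and
#'   `depth`.
#' @param qual numeric site quality.
#' @param cfg a [pipeline_config()]; uses `phase_min_q`, `phase_min_depth`.
#' @return character vector `c(z, w)` with attribute `reason` describing
#'   which rule fired.
#' @examples
#' g <- data.frame(sex = c("M", "M", "F", "F"),
#'                 allele1 = c("A", "A", "A", "A"),
#'                 allele2 = c("A", "A", "C", "C"), depth = 30)
#' phase_site(g, qual = 50)  # c("A", "C")
#' @export
phase_site <- function(genotypes, qual, cfg = pipeline_config()) {
  .ns_assert(all(c("sex", "allele1", "allele2", "depth") %in% names(genotypes)),
             "genotypes needs columns sex, allele1, allele2, depth")
  if (!any(genotypes$sex == "F"))
    .ns_stop("phasing is undefined without female samples")
  if (!any(genotypes$sex == "M"))
    .ns_stop("phasing is undefined without male samples")

  res <- function(z, w, reason) structure(c(z = z, w = w), reason = reason)
  if (qual < cfg$phase_min_q) return(res("N", "N", "low_quality"))

  called <- !is.na(genotypes$allele1) & !is.na(genotypes$allele2)
  used <- genotypes[called, , drop = FALSE]
  if (nrow(used) == 0L) return(res("N", "N", "no_genotypes"))
  if (any(used$depth < cfg$phase_min_depth)) return(res("N", "N", "low_depth"))
  if (!any(used$sex == "F") || !any(used$sex == "M"))
    return(res("N", "N", "sex_missing_after_call"))

  m <- used[used$sex == "M", , drop = FALSE]
  f <- used[used$sex == "F", , drop = FALSE]
  male_alleles <- unique(c(m$allele1, m$allele2))
  if (length(male_alleles) != 1L || any(m$allele1 != m$allele2))
    return(res("N", "N", "male_polymorphism"))
  a <- male_alleles

  fem_alleles <- unique(c(f$allele1, f$allele2))
  if (identical(fem_alleles, a)) return(res(a, a, "invariant"))
  b <- setdiff(fem_alleles, a)
  if (length(b) > 1L) return(res("N", "N", "multiallelic_female"))
  carries_b <- f$allele1 == b | f$allele2 == b
  if (all(carries_b)) return(res(a, b, "female_specific"))
  res("N", "N", "inconsistent_female")
}

#' Phase every site of a variant table
#'
#' Convenience wrapper applying [phase_site()] to each row of a
#' [variant_table()].
#'
#' @param vt a [variant_table()].
#' @param cfg a [pipeline_config()].
#' @return data.frame with `scaffold`, `pos`, `z`, `w`, `reason`.
#' @export
phase_sites <- function(vt, cfg = pipeline_config()) {
  n <- n_sites(vt)
  z <- w <- reason <- character(n)
  sex <- vt$samples$sex
  for (i in seq_len(n)) {
    parts <- strsplit(vt$gt[i, ], "/", fixed = TRUE)
    a1 <- vapply(parts, function(p) p[1] %||% NA_character_, "")
    a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1] %||% NA_character_, "")
    g <- data.frame(sex = sex, allele1 = a1, allele2 = a2,
                    depth = vt$dp[i, ], stringsAsFactors = FALSE)
    r <- phase_site(g, vt$sites$qual[i], cfg)
    z[i] <- r[["z"]]; w[i] <- r[["w"]]; reason[i] <- attr(r, "reason")
  }
  data.frame(scaffold = vt$sites$scaffold, pos = vt$sites$pos,
             z = z, w = w, reason = reason, stringsAsFactors = FALSE)
}

#' Assemble phased Z and W CDS sequences for one gene
#'
#' Splices per-site phased alleles into the reference CDS: exons are
#' concatenated in genomic order, phased alleles replace the reference base
#' at their transcript coordinate, and minus-strand genes are
#' reverse-complemented so both haplotypes read in transcription order.
#' Sites outside the CDS intervals are ignored.
#'
#' @param phased data.frame of phased sites (`pos`, `z`, `w`), e.g. from
#'   [phase_sites()]; positions are 1-based scaffold coordinates.
#' @param cds_intervals data.frame with `start`, `end` (1-based inclusive,
#'   GFF convention), non-overlapping and ordered by `start`.
#' @param strand `"+"` or `"-"`.
#' @param ref_seq reference scaffold sequence: single string or character
#'   vector of bases.
#' @param gene_id gene identifier carried into the result.
#' @return list of class `phased_gametolog`: `gene_id`, `z`, `w` (strings of
#'   equal CDS length), `n_masked` (sites phased to N) and `n_w_specific`
#'   (sites where W differs from Z).
#' @export
phase_gene <- function(phased, cds_intervals, strand, ref_seq,
                       gene_id = "gene") {
  .ns_assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  ci <- cds_intervals[order(cds_intervals$start), , drop = FALSE]
  .ns_assert(all(ci$end >= ci$start), "CDS intervals need end >= start")
  if (nrow(ci) > 1L)
    .ns_assert(all(ci$start[-1] > ci$end[-nrow(ci)]),
               "CDS intervals must be non-overlapping")
  if (length(ref_seq) == 1L) ref_seq <- strsplit(ref_seq, "")[[1]]
  .ns_assert(max(ci$end) <= length(ref_seq),
             "CDS interval outside the reference scaffold")

  gpos <- unlist(lapply(seq_len(nrow(ci)), function(i) ci$start[i]:ci$end[i]))
  z <- w <- toupper(ref_seq[gpos])
  n_masked <- 0L
  if (nrow(phased)) {
    hit <- match(phased$pos, gpos)
    keep <- !is.na(hit)
    for (k in which(keep)) {
      z[hit[k]] <- phased$z[k]
      w[hit[k]] <- phased$w[k]
      if (phased$z[k] == "N") n_masked <- n_masked + 1L
    }
  }
  if (strand == "-") {
    z <- rev_comp(z); w <- rev_comp(w)
  }
  structure(list(gene_id = gene_id,
                 z = paste(z, collapse = ""), w = paste(w, collapse = ""),
                 n_masked = n_masked,
                 n_w_specific = sum(z != w & z != "N" & w != "N")),
            class = "phased_gametolog")
}

#' @export
print.phased_gametolog <- function(x, ...) {
  cat(sprintf("phased_gametolog %s: %d bp CDS, %d masked, %d W-specific sites\n",
              x$gene_id, nchar(x$z), x$n_masked, x$n_w_specific))
  invisible(x)
}

## reverse complement of a character vector of bases (N preserved)
rev_comp <- function(x) {
  rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]))
}

#' Screen genes for W-copy deletions
#'
#' Hemizygous deletion of the W copy halves the relative female read dose on
#' the co-mapped Z exon and removes female-specific (private) alleles. An
#' exon is flagged \emph{deleted} when its normalised female coverage drops
#' below `wdel_cov_drop` times the male coverage \emph{and} female private
#' alleles fall below `wdel_min_private`; it is \emph{ambiguous} when
#' exactly one of the two signs is present. A gene is `W_DELETED` if any
#' exon is deleted, `AMBIGUOUS` if any exon is ambiguous (and none deleted),
#' otherwise `INTACT`. Downstream gametolog sets exclude `W_DELETED` genes.
#'
#' @param evidence data.frame with `gene_id`, `exon`, `cov_f`, `cov_m`
#'   (per-sex mean coverage, each normalised to that sex's autosomal
#'   median) and `private_f` (female private-allele count).
#' @param cfg a [pipeline_config()].
#' @return data.frame with `gene_id`, `flag` in
#'   `{INTACT, W_DELETED, AMBIGUOUS}`, `n_deleted`, `n_ambiguous`.
#' @export
screen_w_deletion <- function(evidence, cfg = pipeline_config()) {
  need <- c("gene_id", "exon", "cov_f", "cov_m", "private_f")
  miss <- setdiff(need, names(evidence))
  if (length(miss))
    .ns_stop("evidence is missing column(s): ", paste(miss, collapse = ", "))
  .ns_assert(all(evidence$private_f >= 0), "private-allele counts must be >= 0")

  cov_hit  <- evidence$cov_f < cfg$wdel_cov_drop * evidence$cov_m
  priv_hit <- evidence$private_f < cfg$wdel_min_private
  status <- ifelse(cov_hit & priv_hit, "DELETED",
            ifelse(cov_hit | priv_hit, "AMBIGUOUS", "INTACT"))
  out <- lapply(split(seq_len(nrow(evidence)), evidence$gene_id), function(idx) {
    st <- status[idx]
    data.frame(gene_id = evidence$gene_id[idx[1]],
               flag = if (any(st == "DELETED")) "W_DELETED"
                      else if (any(st == "AMBIGUOUS")) "AMBIGUOUS" else "INTACT",
               n_deleted = sum(st == "DELETED"),
               n_ambiguous = sum(st == "AMBIGUOUS"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
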