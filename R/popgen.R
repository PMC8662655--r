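## Variant filtering, callable-site computation, windowed nucleotide
## diversity with sex/ploidy awareness, and repeat-fraction summaries.

## depth threshold per sample for a given analysis context
context_depth_thresholds <- function(samples, context, cfg) {
  .ns_assert(context %in% c("autosomal", "sex_linked"),
             "context must be 'autosomal' or 'sex_linked'")
  ifelse(context == "sex_linked" & samples$sex == "F",
         cfg$dp_hap_female, cfg$dp_diploid)
}

## TRUE for sites overlapping the (0-based half-open) repeat mask
in_repeats <- function(scaffold, pos, repeat_mask) {
  hit <- rep(FALSE, length(pos))
  if (is.null(repeat_mask) || nrow(repeat_mask) == 0L) return(hit)
  for (sc in unique(repeat_mask$scaffold)) {
    rm <- repeat_mask[repeat_mask$scaffold == sc, , drop = FALSE]
    idx <- which(scaffold == sc)
    if (!length(idx)) next
    p0 <- pos[idx] - 1L                       # 0-based site coordinate
    for (r in seq_len(nrow(rm)))
      hit[idx] <- hit[idx] | (p0 >= rm$start[r] & p0 < rm$end[r])
  }
  hit
}

#' Filter variant sites with the resequencing-study rules
#'
#' Applies, in order: repeat-overlap removal; removal of sites whose mean
#' coverage is at least `cov_cap_mult` times the median of per-site mean
#' coverages (computed on the post-repeat set for this context); site
#' quality strictly greater than `pop_q`; strand support (`SAF > 0` and
#' `SAR > 0`); placement support (`RPL > 0` and `RPR > 0`); per-genotype
#' depth masking (genotypes below 10x set missing, 5x for females on
#' sex-linked scaffolds); site call rate of at least `call_rate`; and
#' finally restriction to biallelic SNPs. Every dropped record is counted
#' in the attached `droplog`.
#'
#' @param vt a [variant_table()].
#' @param repeat_mask data.frame `scaffold`, `start`, `end` (0-based
#'   half-open), or `NULL`.
#' @param cfg a [pipeline_config()].
#' @param context `"autosomal"` or `"sex_linked"` (females hemizygous).
#' @param cov_cap optional precomputed coverage cap; when `NULL` the cap is
#'   derived from the data as described above.
#' @return the filtered [variant_table()] with attributes `droplog`
#'   (data.frame `filter`, `n_dropped`) and `cov_cap`.
#' @export
filter_variants <- function(vt, repeat_mask = NULL, cfg = pipeline_config(),
                            context = "autosomal", cov_cap = NULL) {
  for (k in c("SAF", "SAR", "RPL", "RPR"))
    if (is.null(vt$sites[[k]]))
      .ns_stop("variant table is missing the required field: ", k)
  log <- data.frame(filter = character(), n_dropped = integer(),
                    stringsAsFactors = FALSE)
  note <- function(name, n) rbind(log, data.frame(filter = name, n_dropped = n,
                                                  stringsAsFactors = FALSE))

  keep <- !in_repeats(vt$sites$scaffold, vt$sites$pos, repeat_mask)
  log <- note("repeat_overlap", sum(!keep)); vt <- vt_subset(vt, keep)

  mean_cov <- rowMeans(vt$dp)
  if (is.null(cov_cap)) cov_cap <- cfg$cov_cap_mult * median(mean_cov)
  keep <- mean_cov < cov_cap
  log <- note("coverage_cap", sum(!keep)); vt <- vt_subset(vt, keep)

  keep <- vt$sites$qual > cfg$pop_q
  log <- note("quality", sum(!keep)); vt <- vt_subset(vt, keep)

  keep <- vt$sites$SAF > 0 & vt$sites$SAR > 0
  log <- note("strand_support", sum(!keep)); vt <- vt_subset(vt, keep)

  keep <- vt$sites$RPL > 0 & vt$sites$RPR > 0
  log <- note("placement_support", sum(!keep)); vt <- vt_subset(vt, keep)

  thr <- context_depth_thresholds(vt$samples, context, cfg)
  low <- sweep(vt$dp, 2, thr, `<`)
  vt$gt[low] <- NA_character_

  called <- rowMeans(!is.na(vt$gt))
  keep <- called >= cfg$call_rate
  log <- note("call_rate", sum(!keep)); vt <- vt_subset(vt, keep)

  n_alt <- lengths(strsplit(vt$sites$alt, ",", fixed = TRUE))
  keep <- n_alt == 1L & nchar(vt$sites$ref) == 1L & nchar(vt$sites$alt) == 1L
  log <- note("biallelic_snp", sum(!keep)); vt <- vt_subset(vt, keep)

  attr(vt, "droplog") <- log
  attr(vt, "cov_cap") <- cov_cap
  vt
}

#' Reject non-SNP variant records
#'
#' Inputs are expected pre-decomposed (complex variants already split into
#' primitives); this validation pass fails loudly when they are not.
#'
#' @param vt a [variant_table()].
#' @return `vt`, invisibly, if all records are SNPs.
#' @export
validate_snps <- function(vt) {
  alts <- strsplit(vt$sites$alt, ",", fixed = TRUE)
  bad <- nchar(vt$sites$ref) != 1L |
    vapply(alts, function(a) any(nchar(a) != 1L), TRUE)
  if (any(bad))
    .ns_stop("non-SNP record(s) at ",
             paste(head(paste0(vt$sites$scaffold[bad], ":", vt$sites$pos[bad]), 5),
                   collapse = ", "),
             "; decompose complex variants upstream")
  invisible(vt)
}

#' Compute the callable-site mask for a context
#'
#' A site is callable when at least `call_rate` of the context's samples
#' meet the depth threshold (10x, or 5x for females on sex-linked
#' scaffolds), its mean coverage is below the coverage cap, and it lies
#' outside annotated repeats - the same thresholds as the variant filter,
#' so callable bp is a valid denominator for diversity.
#'
#' @param depths list with `scaffold`, `pos` (1-based) and `dp` (sites x
#'   samples depth matrix), covering every position of the region.
#' @param samples data.frame `sample_id`, `sex` matching `dp` columns.
#' @param repeat_mask data.frame `scaffold`, `start`, `end` or `NULL`.
#' @param cfg a [pipeline_config()].
#' @param context `"autosomal"` or `"sex_linked"`.
#' @param cov_cap optional precomputed cap; `NULL` derives
#'   `cov_cap_mult * median(per-site mean depth)`.
#' @return data.frame of class `callable_mask`: `scaffold`, `start`, `end`
#'   (0-based half-open, merged).
#' @export
callable_sites <- function(depths, samples, repeat_mask = NULL,
                           cfg = pipeline_config(), context = "autosomal",
                           cov_cap = NULL) {
  thr <- context_depth_thresholds(samples, context, cfg)
  enough <- rowMeans(sweep(depths$dp, 2, thr, `>=`)) >= cfg$call_rate
  mean_cov <- rowMeans(depths$dp)
  if (is.null(cov_cap)) cov_cap <- cfg$cov_cap_mult * median(mean_cov)
  ok <- enough & mean_cov < cov_cap &
    !in_repeats(depths$scaffold, depths$pos, repeat_mask)
  out <- lapply(unique(depths$scaffold), function(sc) {
    p <- sort(depths$pos[ok & depths$scaffold == sc])
    if (!length(p)) return(NULL)
    iv <- merge_intervals(p - 1L, p)          # single-site intervals, merged
    data.frame(scaffold = sc, start = iv$start, end = iv$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  class(out) <- c("callable_mask", "data.frame")
  out
}

## per-site unbiased pi from a genotype matrix row
## k = called allele copies, j = alternate copies: pi = 2 j (k-j) / (k (k-1))
site_pi <- function(gt_row, ref) {
  alleles <- unlist(strsplit(gt_row[!is.na(gt_row)], "/", fixed = TRUE))
  k <- length(alleles)
  if (k < 2) return(NA_real_)
  j <- sum(alleles != ref)
  2 * j * (k - j) / (k * (k - 1))
}

#' Windowed nucleotide diversity over callable sites
#'
#' Per-site unbiased pi with `k` observed allele copies and `j` alternate
#' copies is `2 j (k - j) / (k (k - 1))`; window estimates divide the sum
#' of per-site pi by the callable bp in the window (sites at which no SNP
#' was called contribute zero difference but count in the denominator).
#' Haploid genotypes ("A") contribute one allele copy, diploid ("A/C")
#' two, so the female sex-linked (haploid) and autosomal (diploid)
#' analyses use the same code path.
#'
#' @param vt a filtered [variant_table()] of biallelic SNPs.
#' @param mask a `callable_mask` from [callable_sites()] for the same
#'   context.
#' @param window window size in bp (default 100000); windows are half-open
#'   multiples of the window size from scaffold start.
#' @return data.frame of `DiversityWindow` rows: `scaffold`, `start`,
#'   `end`, `pi_sum`, `callable_bp`, `n_snps`, `pi` (`NA` when no callable
#'   bp).
#' @export
pi_windows <- function(vt, mask, window = 100000) {
  s <- vt$sites
  pis <- vapply(seq_len(nrow(s)), function(i) site_pi(vt$gt[i, ], s$ref[i]),
                1)
  pis[is.na(pis)] <- 0
  inside <- in_repeats(s$scaffold, s$pos,
                       mask)  # mask shares the half-open convention
  if (nrow(s) && !all(inside))
    .ns_stop("variant site(s) outside the callable mask: ",
             paste(head(paste0(s$scaffold, ":", s$pos)[!inside], 5),
                   collapse = ", "))
  scaffolds <- unique(c(s$scaffold, mask$scaffold))
  out <- lapply(scaffolds, function(sc) {
    mv <- mask[mask$scaffold == sc, , drop = FALSE]
    if (nrow(mv) == 0L) return(NULL)
    idx <- which(s$scaffold == sc)
    w_hi <- max(mv$end, if (length(idx)) s$pos[idx] else 0)
    starts <- seq(0L, by = window, length.out = ceiling(w_hi / window))
    do.call(rbind, lapply(starts, function(ws) {
      we <- ws + window
      callable <- interval_overlap_bp(mv, ws, we)
      in_w <- idx[s$pos[idx] - 1L >= ws & s$pos[idx] - 1L < we]
      data.frame(scaffold = sc, start = ws, end = we,
                 pi_sum = sum(pis[in_w]), callable_bp = callable,
                 n_snps = length(in_w),
                 pi = if (callable > 0) sum(pis[in_w]) / callable else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Repeat fraction per window or region
#'
#' Overlapping repeat records are merged before counting; repeats are
#' clipped to window bounds. Region aggregates over several windows are
#' length-weighted means (i.e. total masked bp / total bp).
#'
#' @param windows data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open windows or regions).
#' @param repeats data.frame with `scaffold`, `start`, `end` repeat
#'   annotation records.
#' @return `windows` with a `repeat_fraction` column.
#' @export
repeat_fraction <- function(windows, repeats) {
  frac <- vapply(seq_len(nrow(windows)), function(i) {
    rm <- repeats[repeats$scaffold == windows$scaffold[i], , drop = FALSE]
    merged <- merge_intervals(rm$start, rm$end)
    interval_overlap_bp(merged, windows$start[i], windows$end[i]) /
      (windows$end[i] - windows$start[i])
  }, 1)
  windows$repeat_fraction <- frac
  windows
}
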