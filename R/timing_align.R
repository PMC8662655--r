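## Alignment preparation for the recombination-suppression timing stage:
## column trimming, gene-conversion tract masking, and the minimum-length
## filter.

#' Remove alignment columns with gaps or ambiguous bases
#'
#' Drops every column in which any sequence carries a character outside
#' `{A,C,G,T}` (gaps, N, IUPAC ambiguity codes). Row order is preserved; the
#' result may have zero columns (the caller applies the minimum-length
#' filter).
#'
#' @param aln character matrix alignment (rows = sequences).
#' @return the trimmed character matrix.
#' @export
trim_alignment <- function(aln) {
  .ns_assert(is.matrix(aln), "alignment must be a character matrix")
  if (ncol(aln) == 0L) return(aln)
  clean <- colSums(matrix(aln %in% c("A", "C", "G", "T"), nrow(aln))) == nrow(aln)
  aln[, clean, drop = FALSE]
}

#' Drop alignments too short for timing analysis
#'
#' @param alns list of (trimmed) character-matrix alignments.
#' @param min_aln minimum number of columns (default 700; alignments
#'   strictly shorter are removed).
#' @return the filtered list.
#' @export
filter_alignments_for_timing <- function(alns, min_aln = 700) {
  alns[vapply(alns, ncol, 1L) >= min_aln]
}

#' Flag putative gene-conversion tracts between Z and W sequences
#'
#' Simplified inner/outer-fragment run-length test in the spirit of Sawyer's
#' statistic: for each within-species Z/W row pair, the maximal runs of
#' identical columns (between consecutive mismatches, including the leading
#' and trailing runs) are scored by their length given the pair's overall
#' mismatch density. The null distribution is obtained by permuting the
#' positions of the mismatching columns uniformly over the alignment
#' (`geneconv_perms` seeded permutations); a run is reported as a tract when
#' the permutation max-run exceeds it in fewer than `geneconv_alpha` of
#' permutations. This is an approximation of the full GENECONV procedure,
#' not a re-implementation.
#'
#' @param aln trimmed character matrix alignment.
#' @param zw_pairs list of two-element character vectors
#'   `c(z_row_name, w_row_name)`, one per species with both copies.
#' @param cfg a [pipeline_config()]; uses `geneconv_perms`,
#'   `geneconv_alpha`.
#' @param seed integer seed for the permutation null.
#' @return list of class `conversion_mask`: `tracts` (data.frame with
#'   `pair`, `start`, `end` 0-based half-open alignment columns, `length`,
#'   `p`) and `mask` (merged flagged intervals over all pairs).
#' @export
mask_gene_conversion <- function(aln, zw_pairs, cfg = pipeline_config(),
                                 seed = 1L) {
  L <- ncol(aln)
  tracts <- data.frame(pair = character(), start = integer(), end = integer(),
                       length = integer(), p = numeric(), stringsAsFactors = FALSE)
  set.seed(seed)
  for (pr in zw_pairs) {
    .ns_assert(all(pr %in% rownames(aln)),
               paste0("pair rows not in alignment: ", paste(pr, collapse = "/")))
    z <- aln[pr[1], ]; w <- aln[pr[2], ]
    mism <- which(z != w)
    d <- length(mism)
    if (d == 0L) next  # identical rows carry no tract signal here
    # observed identical runs (0-based half-open), incl. leading/trailing
    bounds <- c(0L, mism, L + 1L)
    run_start <- bounds[-length(bounds)]            # mismatch col (or 0)
    run_end <- bounds[-1] - 1L                      # next mismatch col - 1
    run_len <- run_end - run_start
    # permutation null for the maximum identical run length
    nperm <- cfg$geneconv_perms
    max_null <- vapply(seq_len(nperm), function(b) {
      mm <- sort(sample.int(L, d))
      max(diff(c(0L, mm, L + 1L)) - 1L)
    }, 1L)
    for (k in seq_along(run_len)) {
      p <- (1 + sum(max_null >= run_len[k])) / (nperm + 1)
      if (p < cfg$geneconv_alpha) {
        tracts <- rbind(tracts, data.frame(
          pair = paste(pr, collapse = "|"),
          start = run_start[k], end = run_end[k],  # half-open: cols start..end-1
          length = run_len[k], p = p, stringsAsFactors = FALSE))
      }
    }
  }
  mask <- if (nrow(tracts)) merge_intervals(tracts$start, tracts$end)
          else data.frame(start = integer(), end = integer())
  structure(list(tracts = tracts, mask = mask, n_col = L),
            class = "conversion_mask")
}

#' @export
print.conversion_mask <- function(x, ...) {
  cat(sprintf("conversion_mask: %d tract(s) over %d columns\n",
              nrow(x$tracts), x$n_col))
  invisible(x)
}

#' Remove flagged gene-conversion columns from an alignment
#'
#' @param aln character matrix alignment.
#' @param mask a `conversion_mask` from [mask_gene_conversion()].
#' @return the alignment minus the flagged columns.
#' @export
apply_conversion_mask <- function(aln, mask) {
  if (nrow(mask$mask) == 0L) return(aln)
  drop <- unlist(lapply(seq_len(nrow(mask$mask)), function(i)
    seq.int(mask$mask$start[i] + 1L, mask$mask$end[i])))
  aln[, -drop, drop = FALSE]
}
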