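## Sex-linkage classification of assembly scaffolds from sex-stratified
## coverage and heterozygosity, and ancestral/added region assignment from
## dual-reference homology ranges.

#' Classify scaffolds as W-linked, Z-linked or autosomal
#'
#' Applies the coverage/heterozygosity rules for a ZW system to per-scaffold,
#' per-sample profiles computed from mismatch-free read alignments:
#' \itemize{
#'   \item \strong{W}: median female coverage strictly above `w_fem_min`
#'     (default 25x) while median male coverage is zero (females carry the
#'     only W copy; males have none).
#'   \item \strong{Z}: either the female/male coverage ratio is strictly
#'     below `z_ratio_1` (0.55), or the ratio is strictly below `z_ratio_2`
#'     (0.65) and the absolute male-female heterozygosity difference is
#'     strictly above `het_diff_min` (0.1) (hemizygous females lose
#'     heterozygosity on Z).
#'   \item \strong{AUTOSOME}: neither rule fires.
#'   \item \strong{UNASSIGNED}: male median coverage is zero but the W rule
#'     does not fire (ratio undefined), or a sex has no samples.
#' }
#' Precedence is W > Z > AUTOSOME. All inequalities are strict, exactly as
#' the rules are stated; boundary values fail.
#'
#' @param profiles data.frame with columns `scaffold_id`, `sample_id`,
#'   `sex` ("M"/"F"), `median_coverage` (x-fold, computed from
#'   mismatch-free alignments) and `heterozygosity` (fraction in `[0,1]`).
#'   A `length_bp` column is carried through if present.
#' @param cfg a [pipeline_config()].
#' @return data.frame, one row per scaffold: `scaffold_id`, `class`
#'   (`W`/`Z`/`AUTOSOME`/`UNASSIGNED`), the evidence values `fem_median`,
#'   `male_median`, `cov_ratio`, `het_f`, `het_m`, `het_diff`, and
#'   `rule_fired`.
#' @examples
#' prof <- data.frame(
#'   scaffold_id = "s1", sample_id = c("f1", "f2", "m1", "m2"),
#'   sex = c("F", "F", "M", "M"),
#'   median_coverage = c(30, 32, 0, 0), heterozygosity = c(0.01, 0.02, 0, 0))
#' classify_scaffolds(prof)$class
#' @export
classify_scaffolds <- function(profiles, cfg = pipeline_config()) {
  need <- c("scaffold_id", "sample_id", "sex", "median_coverage", "heterozygosity")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    .ns_stop("profiles is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(profiles$sex) || !all(profiles$sex %in% c("M", "F")))
    .ns_stop("every sample must carry a sex label 'M' or 'F'")
  .ns_assert(all(profiles$median_coverage >= 0), "median_coverage must be >= 0")
  .ns_assert(all(profiles$heterozygosity >= 0 & profiles$heterozygosity <= 1),
             "heterozygosity must lie in [0, 1]")

  summ <- match.fun(cfg$het_summary) # median or mean across samples of a sex
  out <- lapply(split(profiles, profiles$scaffold_id), function(p) {
    fem  <- p[p$sex == "F", , drop = FALSE]
    male <- p[p$sex == "M", , drop = FALSE]
    row <- data.frame(scaffold_id = p$scaffold_id[[1]],
                      class = "UNASSIGNED", fem_median = NA_real_,
                      male_median = NA_real_, cov_ratio = NA_real_,
                      het_f = NA_real_, het_m = NA_real_, het_diff = NA_real_,
                      rule_fired = "none", stringsAsFactors = FALSE)
    if (nrow(fem) == 0L || nrow(male) == 0L) {
      warning("scaffold ", row$scaffold_id,
              ": no samples of one sex; call is UNASSIGNED", call. = FALSE)
      return(row)
    }
    row$fem_median  <- median(fem$median_coverage)
    row$male_median <- median(male$median_coverage)
    row$het_f <- summ(fem$heterozygosity)
    row$het_m <- summ(male$heterozygosity)
    row$het_diff <- abs(row$het_m - row$het_f)
    if (row$male_median <= cfg$w_male_eps) {
      if (row$fem_median > cfg$w_fem_min) {
        row$class <- "W"; row$rule_fired <- "W:fem>25,male=0"
      } # else: ratio undefined -> UNASSIGNED
      return(row)
    }
    row$cov_ratio <- row$fem_median / row$male_median
    if (row$cov_ratio < cfg$z_ratio_1) {
      row$class <- "Z"; row$rule_fired <- "Z1:ratio<0.55"
    } else if (row$cov_ratio < cfg$z_ratio_2 && row$het_diff > cfg$het_diff_min) {
      row$class <- "Z"; row$rule_fired <- "Z2:ratio<0.65&hetdiff>0.1"
    } else {
      row$class <- "AUTOSOME"; row$rule_fired <- "default"
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[match(unique(profiles$scaffold_id), out$scaffold_id), , drop = FALSE]
}

#' Assign homology ranges to the ancestral or added sex-chromosome region
#'
#' A genomic range (from whole-genome alignment against two outgroup
#' reference assemblies) belongs to the \emph{ancestral} sex chromosome if it
#' aligns to chromosome Z (or Z_random) in both references, or to Z in one
#' and an unplaced scaffold in the other; \emph{added} analogously for
#' chromosome 4A (or 4A_random). Ranges shorter than `cfg$min_range_bp`
#' (10 kb) are dropped; contradictory targets (Z in one reference, 4A in the
#' other) are reported as UNASSIGNED.
#'
#' @param ranges data.frame with columns `scaffold_id`, `start`, `end`
#'   (0-based half-open) and target chromosome names `target_A`, `target_B`.
#' @param cfg a [pipeline_config()].
#' @param unplaced_regex regular expression identifying unplaced-scaffold
#'   target names.
#' @return `ranges` minus the sub-threshold rows, with a `region` column in
#'   `{ANCESTRAL, ADDED, UNASSIGNED}`.
#' @export
assign_region_homology <- function(ranges, cfg = pipeline_config(),
                                   unplaced_regex = "^(scaffold|contig|chrUn|random_)") {
  need <- c("scaffold_id", "start", "end", "target_A", "target_B")
  miss <- setdiff(need, names(ranges))
  if (length(miss))
    .ns_stop("ranges is missing column(s): ", paste(miss, collapse = ", "))
  .ns_assert(all(ranges$end > ranges$start), "ranges must satisfy end > start")

  keep <- (ranges$end - ranges$start) >= cfg$min_range_bp
  ranges <- ranges[keep, , drop = FALSE]
  norm <- function(x) sub("^chr", "", trimws(x))
  a <- norm(ranges$target_A); b <- norm(ranges$target_B)
  is_anc <- function(x) x %in% c("Z", "Z_random")
  is_add <- function(x) x %in% c("4A", "4A_random")
  is_unp <- function(x) grepl(unplaced_regex, x, ignore.case = TRUE)

  region <- rep("UNASSIGNED", nrow(ranges))
  anc <- (is_anc(a) & is_anc(b)) | (is_anc(a) & is_unp(b)) | (is_unp(a) & is_anc(b))
  add <- (is_add(a) & is_add(b)) | (is_add(a) & is_unp(b)) | (is_unp(a) & is_add(b))
  conflict <- (is_anc(a) & is_add(b)) | (is_add(a) & is_anc(b))
  region[anc] <- "ANCESTRAL"
  region[add] <- "ADDED"
  region[conflict] <- "UNASSIGNED"
  if (any(conflict))
    message(sum(conflict), " range(s) with conflicting targets left UNASSIGNED")
  ranges$region <- region
  rownames(ranges) <- NULL
  ranges
}

#' Read and write scaffold profile / call tables
#'
#' TSV interchange for the classifier: profiles have columns `scaffold_id`,
#' `length_bp` (optional), `sample_id`, `sex`, `median_coverage`,
#' `heterozygosity`. Callers of [read_profiles()] assert that coverage was
#' computed from mismatch-free alignments upstream.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_profiles <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#")
}

#' @rdname read_profiles
#' @param x a data.frame (calls or profiles).
#' @param ... header comment lines to prepend (each prefixed with `#`).
#' @export
write_calls <- function(x, path, ...) {
  hdr <- c(...)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(paste0("# ", hdr), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
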