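#' Pipeline configuration with literature-default thresholds
#'
#' Builds the configuration list used by every stage of the pipeline. Each
#' default is the threshold used in the source study of the Sylvioidea
#' neo-sex chromosome; all are overridable either here or through a YAML file
#' ([read_config()]).
#'
#' Thresholds and their meaning:
#' \describe{
#'   \item{w_fem_min}{W rule: median female coverage must exceed this
#'     (x-fold) while median male coverage is zero. Default 25.}
#'   \item{w_male_eps}{Tolerance on "male coverage is zero" (default 0,
#'     i.e. exact equality on mismatch-free-filtered coverage).}
#'   \item{z_ratio_1}{Z rule 1: female/male coverage ratio strictly below
#'     this. Default 0.55.}
#'   \item{z_ratio_2, het_diff_min}{Z rule 2: ratio strictly below
#'     \code{z_ratio_2} (0.65) and absolute male-female heterozygosity
#'     difference strictly above \code{het_diff_min} (0.1).}
#'   \item{het_summary}{How per-sample heterozygosity is summarised within a
#'     sex before the difference test: "median" (default) or "mean".}
#'   \item{min_range_bp}{Dual-reference homology ranges shorter than this are
#'     ignored (10 kb).}
#'   \item{phase_min_q, phase_min_depth}{Site quality and per-sample depth
#'     below which a phased site is masked to N (both 20).}
#'   \item{wdel_cov_drop, wdel_min_private}{W-deletion screen: an exon is
#'     flagged when normalised female coverage < \code{wdel_cov_drop} times
#'     male coverage and female private alleles < \code{wdel_min_private}.}
#'   \item{tau}{Minimum bootstrap support (percent) for a gene-tree node to
#'     constrain suppression timing. Default 70.}
#'   \item{min_aln}{Minimum trimmed alignment length for the timing analysis
#'     (700 bp).}
#'   \item{nj_bootstrap}{Bootstrap replicates for the internal NJ tree
#'     builder (100).}
#'   \item{sat_cap}{Distance (substitutions/site) substituted for saturated
#'     pairwise distances (p >= 3/4).}
#'   \item{geneconv_perms, geneconv_alpha}{Permutations and alpha for the
#'     gene-conversion tract test.}
#'   \item{rates_min_len, rates_max_ds}{Rate-table filter: minimum aligned
#'     length (500 bp, inclusive) and maximum dS (3, exclusive).}
#'   \item{pop_q}{Variant quality must be strictly greater than this (20).}
#'   \item{dp_diploid, dp_hap_female}{Genotype depth thresholds: 10x for
#'     males and autosomal females, 5x for females on sex-linked scaffolds.}
#'   \item{call_rate}{Minimum fraction of called genotypes per site (0.8).}
#'   \item{cov_cap_mult}{Sites with mean coverage at least this multiple of
#'     the median of per-site means are dropped (2).}
#'   \item{window}{Diversity/repeat window size in bp (100000).}
#' }
#'
#' @param ... named overrides of any default.
#' @return A named list of class `neosex_config`.
#' @examples
#' cfg <- pipeline_config(tau = 80)
#' cfg$tau
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # sexlink
    w_fem_min    = 25,
    w_male_eps   = 0,
    z_ratio_1    = 0.55,
    z_ratio_2    = 0.65,
    het_diff_min = 0.1,
    het_summary  = "median",
    normalize_coverage = FALSE,
    min_range_bp = 10000,
    # phasing
    phase_min_q     = 20,
    phase_min_depth = 20,
    wdel_cov_drop   = 0.75,
    wdel_min_private = 1,
    # timing
    tau          = 70,
    min_aln      = 700,
    nj_bootstrap = 100,
    sat_cap      = 5,
    geneconv_perms = 10000,
    geneconv_alpha = 0.05,
    # rates
    rates_min_len = 500,
    rates_max_ds  = 3,
    # popgen
    pop_q         = 20,
    dp_diploid    = 10,
    dp_hap_female = 5,
    call_rate     = 0.8,
    cov_cap_mult  = 2,
    window        = 100000,
    seed          = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    .ns_assert(!is.null(names(dots)) && all(nzchar(names(dots))),
               "all configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      .ns_stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "neosex_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Fields absent from the file are filled from [pipeline_config()] defaults
#' (reported via `message()`); unknown fields are rejected. The
#' write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_config()` returns a `neosex_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  .ns_assert(file.exists(path), paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- pipeline_config()
  missing <- setdiff(names(defaults), names(raw))
  if (length(missing))
    message("config: using defaults for ", paste(missing, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a `neosex_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

#' @export
print.neosex_config <- function(x, ...) {
  cat("neosex pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(val)) "NULL" else paste(val, collapse = ", ")))
  }
  invisible(x)
}
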