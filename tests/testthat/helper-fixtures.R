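# Deterministic fixtures built in code.

# profile rows for one scaffold from per-sex coverage/het vectors
make_profile <- function(scaffold, cov_f, cov_m, het_f = 0.2, het_m = 0.2) {
  data.frame(
    scaffold_id = scaffold,
    sample_id = c(sprintf("f%d", seq_along(cov_f)), sprintf("m%d", seq_along(cov_m))),
    sex = c(rep("F", length(cov_f)), rep("M", length(cov_m))),
    median_coverage = c(cov_f, cov_m),
    heterozygosity = c(rep_len(het_f, length(cov_f)), rep_len(het_m, length(cov_m))),
    stringsAsFactors = FALSE)
}

# one-site genotype frame for phase_site()
make_site <- function(male_gt, female_gt, depth = 30) {
  split_gt <- function(g) strsplit(g, "/", fixed = TRUE)
  m <- split_gt(male_gt); f <- split_gt(female_gt)
  data.frame(
    sex = c(rep("M", length(m)), rep("F", length(f))),
    allele1 = c(vapply(m, `[`, "", 1), vapply(f, `[`, "", 1)),
    allele2 = c(vapply(m, `[`, "", 2), vapply(f, `[`, "", 2)),
    depth = rep_len(depth, length(m) + length(f)),
    stringsAsFactors = FALSE)
}

# 100-site variant fixture with a known fate for every filter, 5M + 5F,
# autosomal context. Truth: 10 repeat, 5 coverage-cap, 5 quality, 4 strand,
# 4 placement, 7 call-rate, 5 non-biallelic -> 60 survivors.
make_filter_fixture <- function() {
  n <- 100
  samples <- data.frame(sample_id = c(sprintf("m%d", 1:5), sprintf("f%d", 1:5)),
                        sex = c(rep("M", 5), rep("F", 5)),
                        stringsAsFactors = FALSE)
  sites <- data.frame(scaffold = "s1", pos = seq_len(n) * 10L,
                      ref = "A", alt = "C", qual = 50,
                      SAF = 10L, SAR = 10L, RPL = 10L, RPR = 10L,
                      stringsAsFactors = FALSE)
  gt <- matrix("A/C", n, 10)
  dp <- matrix(30, n, 10)
  fate <- rep("keep", n)
  fate[1:10] <- "repeat"               # pos 10..100 inside repeat below
  dp[11:15, ] <- 100; fate[11:15] <- "coverage_cap"
  sites$qual[16:20] <- 20; fate[16:20] <- "quality"        # strict > 20
  sites$SAF[21:22] <- 0L; sites$SAR[23:24] <- 0L; fate[21:24] <- "strand"
  sites$RPL[25:26] <- 0L; sites$RPR[27:28] <- 0L; fate[25:28] <- "placement"
  dp[29:35, 1:3] <- 5; fate[29:35] <- "call_rate"          # 7/10 called
  sites$alt[36:38] <- "C,T"; sites$ref[39:40] <- "AT"
  fate[36:40] <- "biallelic"
  repeats <- data.frame(scaffold = "s1", start = 0L, end = 105L)  # pos <= 105
  list(vt = neosex::variant_table(sites, gt, dp, samples),
       repeats = repeats, fate = fate,
       expected_drops = c(repeat_overlap = 10, coverage_cap = 5, quality = 5,
                          strand_support = 4, placement_support = 4,
                          call_rate = 7, biallelic_snp = 5),
       n_survivors = 60)
}

# convert a diploid variant table into the equivalent table of 2n phased
# haploid "samples" (for the pi consistency property)
diploid_to_haploid_vt <- function(vt) {
  n <- nrow(vt$samples)
  gt <- matrix(NA_character_, nrow(vt$gt), 2 * n)
  for (j in seq_len(n)) {
    parts <- strsplit(vt$gt[, j], "/", fixed = TRUE)
    gt[, 2 * j - 1] <- vapply(parts, `[`, "", 1)
    gt[, 2 * j] <- vapply(parts, `[`, "", 2)
  }
  samples <- data.frame(
    sample_id = paste0(rep(vt$samples$sample_id, each = 2), c("_a", "_b")),
    sex = rep(vt$samples$sex, each = 2), stringsAsFactors = FALSE)
  neosex::variant_table(vt$sites, gt,
                        vt$dp[, rep(seq_len(n), each = 2), drop = FALSE],
                        samples)
}
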