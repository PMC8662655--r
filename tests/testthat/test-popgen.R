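test_that("per-site and per-window pi match hand computations", {
  # 5 haploid samples, one site with 2 alternate copies:
  # pi = 2*2*3/(5*4) = 0.6; over 100 callable bp the window pi is 0.006
  samples <- data.frame(sample_id = paste0("f", 1:5), sex = "F")
  sites <- data.frame(scaffold = "s", pos = 50L, ref = "A", alt = "C",
                      qual = 60, SAF = 5L, SAR = 5L, RPL = 5L, RPR = 5L)
  gt <- matrix(c("C", "C", "A", "A", "A"), 1, 5)
  vt <- variant_table(sites, gt, matrix(30, 1, 5), samples)
  mask <- data.frame(scaffold = "s", start = 0L, end = 100L)
  w <- pi_windows(vt, mask, window = 100)
  expect_equal(w$pi_sum, 0.6)
  expect_equal(w$pi, 0.006)
  expect_equal(w$n_snps, 1L)

  # 5 diploids all heterozygous: j = 5 of k = 10 -> pi = 50/90
  gt2 <- matrix("A/C", 1, 5)
  vt2 <- variant_table(sites, gt2, matrix(30, 1, 5), samples)
  w2 <- pi_windows(vt2, mask, window = 100)
  expect_equal(w2$pi_sum, 2 * 5 * 5 / 90)

  # no SNPs but callable sequence: pi = 0; no callable bp: pi undefined
  w0 <- pi_windows(vt_subsettable <- variant_table(sites[0, ], gt[0, , drop = FALSE],
                                                   matrix(30, 0, 5), samples),
                   mask, window = 100)
  expect_equal(w0$pi, 0)
  expect_error(pi_windows(vt, data.frame(scaffold = "s", start = 60L, end = 100L),
                          window = 100), "outside")
})

test_that("diploid pi equals haploid pi on the phased haplotypes", {
  d <- simulate_diversity(sim_config(seed = 17, theta = 0.004,
                                     scaffold_length = 5e4))
  w_dip <- pi_windows(d$vt, d$mask, window = 5e4)
  w_hap <- pi_windows(diploid_to_haploid_vt(d$vt), d$mask, window = 5e4)
  expect_equal(w_hap$pi, w_dip$pi)
})

test_that("simulated diversity recovers theta", {
  d <- simulate_diversity(sim_config(seed = 19, theta = 0.003,
                                     scaffold_length = 1e6))
  w <- pi_windows(d$vt, d$mask, window = 1e5)
  expect_equal(mean(w$pi), 0.003, tolerance = 0.1)
})

test_that("the variant filters drop exactly the constructed fates, in order", {
  fx <- make_filter_fixture()
  out <- filter_variants(fx$vt, fx$repeats)
  log <- attr(out, "droplog")
  expect_equal(setNames(log$n_dropped, log$filter), fx$expected_drops)
  expect_equal(n_sites(out), fx$n_survivors)
  expect_equal(out$sites$pos, fx$vt$sites$pos[fx$fate == "keep"])

  # idempotence: re-filtering the survivors drops nothing
  again <- filter_variants(out, fx$repeats)
  expect_equal(sum(attr(again, "droplog")$n_dropped), 0)
  expect_equal(again$sites, out$sites)

  # boundary: qual exactly 20 is dropped ("larger than 20" is strict)
  expect_true(all(fx$vt$sites$qual[16:20] == 20))
  expect_false(any(out$sites$pos %in% fx$vt$sites$pos[16:20]))

  # missing support fields are an error naming the field
  vt_bad <- fx$vt; vt_bad$sites$SAR <- NULL
  expect_error(filter_variants(vt_bad, fx$repeats), "SAR")
})

test_that("female sex-linked genotypes use the 5x depth threshold", {
  samples <- data.frame(sample_id = c(paste0("m", 1:5), paste0("f", 1:5)),
                        sex = rep(c("M", "F"), each = 5))
  sites <- data.frame(scaffold = "s", pos = c(10L, 20L), ref = "A", alt = "C",
                      qual = 60, SAF = 5L, SAR = 5L, RPL = 5L, RPR = 5L)
  gt <- matrix("A/C", 2, 10)
  dp <- matrix(30, 2, 10); dp[, 6:10] <- 7   # females at 7x
  vt <- variant_table(sites, gt, dp, samples)
  # autosomal: female genotypes < 10x go missing -> 50% called -> dropped
  auto <- filter_variants(vt, NULL, context = "autosomal")
  expect_equal(n_sites(auto), 0)
  # sex-linked: 7x exceeds the 5x female threshold -> retained
  sl <- filter_variants(vt, NULL, context = "sex_linked")
  expect_equal(n_sites(sl), 2)
})

test_that("callable mask applies depth, cap, call-rate and repeat rules", {
  samples <- data.frame(sample_id = c(paste0("m", 1:5), paste0("f", 1:5)),
                        sex = rep(c("M", "F"), each = 5))
  n <- 1000L
  dp <- matrix(30, n, 10)
  depths <- list(scaffold = rep("s", n), pos = 1:n, dp = dp)
  mask <- callable_sites(depths, samples)
  expect_equal(sum(mask$end - mask$start), n)  # uniform depth: all callable

  # a 100 bp repeat removes exactly its span
  rep_iv <- data.frame(scaffold = "s", start = 100L, end = 200L)
  mask2 <- callable_sites(depths, samples, rep_iv)
  expect_equal(sum(mask2$end - mask2$start), n - 100L)

  # female depth 4 fails the 5x sex-linked threshold
  dp3 <- dp; dp3[1:50, 6:10] <- 4
  depths3 <- list(scaffold = rep("s", n), pos = 1:n, dp = dp3)
  mask3 <- callable_sites(depths3, samples, cfg = pipeline_config(),
                          context = "sex_linked")
  expect_equal(sum(mask3$end - mask3$start), n - 50L)
  # ...but with cov_cap fixed high, depth 4 still passes in no context
  mask4 <- callable_sites(depths3, samples, context = "autosomal")
  expect_equal(sum(mask4$end - mask4$start), n - 50L)
})

test_that("repeat fractions merge overlaps and clip to windows", {
  win <- data.frame(scaffold = "s", start = 0L, end = 100000L)
  # fully covered window
  expect_equal(repeat_fraction(win, data.frame(scaffold = "s", start = 0L,
                                               end = 2e5))$repeat_fraction, 1)
  # two adjacent 10 kb repeats -> 0.2
  reps <- data.frame(scaffold = "s", start = c(0L, 10000L),
                     end = c(10000L, 20000L))
  expect_equal(repeat_fraction(win, reps)$repeat_fraction, 0.2)
  # overlapping 50 kb + 50 kb sharing 25 kb -> 75 kb union
  reps2 <- data.frame(scaffold = "s", start = c(0L, 25000L),
                      end = c(50000L, 75000L))
  expect_equal(repeat_fraction(win, reps2)$repeat_fraction, 0.75)
  expect_equal(75000, oracle_union_bp(reps2$start, reps2$end, 0, 100000))

  # random intervals against the per-basepair union oracle
  set.seed(55)
  for (rep in 1:10) {
    st <- sample(0:900, 20, TRUE); en <- st + sample(1:100, 20, TRUE)
    rr <- data.frame(scaffold = "s", start = st, end = en)
    w <- data.frame(scaffold = "s", start = 0L, end = 1000L)
    expect_equal(repeat_fraction(w, rr)$repeat_fraction * 1000,
                 oracle_union_bp(st, en, 0, 1000))
  }
})

test_that("non-SNP records are rejected by validation", {
  fx <- make_filter_fixture()
  expect_error(validate_snps(fx$vt), "decompose")
  ok <- vt_ok <- filter_variants(fx$vt, fx$repeats)
  expect_silent(validate_snps(ok))
})
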