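test_that("phase_site implements the sex-hemizygosity truth table", {
  # female-specific allele becomes the W copy
  expect_equal(as.vector(phase_site(make_site(c("A/A", "A/A"), c("A/C", "A/C")),
                                 qual = 50)), c("A", "C"))
  # invariant site
  expect_equal(as.vector(phase_site(make_site("A/A", "A/A"), qual = 50)),
               c("A", "A"))
  # female homozygous for the W allele still phases
  expect_equal(as.vector(phase_site(make_site("A/A", c("C/C", "A/C")), qual = 50)),
               c("A", "C"))
  # male heterozygosity is Z polymorphism: masked, never phased
  expect_equal(as.vector(phase_site(make_site(c("A/C", "A/A"), "A/C"), qual = 50)),
               c("N", "N"))
  # two different female-specific alleles: masked
  expect_equal(as.vector(phase_site(make_site("A/A", c("A/C", "A/G")), qual = 50)),
               c("N", "N"))
  # a female without the W allele conflicts
  expect_equal(as.vector(phase_site(make_site("A/A", c("A/C", "A/A")), qual = 50)),
               c("N", "N"))
})

test_that("quality and depth masking follows the 20/20 rule", {
  g <- make_site("A/A", "A/C", depth = c(30, 15))
  expect_equal(as.vector(phase_site(g, qual = 50)), c("N", "N"))
  expect_equal(as.vector(phase_site(make_site("A/A", "A/C"), qual = 19)),
               c("N", "N"))
  expect_equal(as.vector(phase_site(make_site("A/A", "A/C", depth = 20),
                                 qual = 20)), c("A", "C"))
  expect_error(phase_site(make_site("A/A", character(0)), qual = 50),
               "female")
})

test_that("masking is monotone in the depth threshold", {
  set.seed(5)
  gen <- simulate_genotypes(sim_config(seed = 5, gene_length = 500,
                                       depth_mean = 30, depth_dispersion = 5))
  masked_at <- function(min_depth) {
    ph <- phase_sites(gen$vt, pipeline_config(phase_min_depth = min_depth))
    ph$pos[ph$z == "N"]
  }
  m20 <- masked_at(20); m25 <- masked_at(25); m30 <- masked_at(30)
  expect_true(all(m20 %in% m25))
  expect_true(all(m25 %in% m30))
})

test_that("phasing is symmetric under sample relabeling within a sex", {
  gen <- simulate_genotypes(sim_config(seed = 8, gene_length = 800,
                                       male_poly_rate = 0.002))
  vt <- gen$vt
  fem <- which(vt$samples$sex == "F")
  perm <- c(which(vt$samples$sex == "M"), rev(fem))
  vt2 <- variant_table(vt$sites, vt$gt[, perm, drop = FALSE],
                       vt$dp[, perm, drop = FALSE], vt$samples[perm, ])
  expect_equal(phase_sites(vt2)[, c("z", "w")], phase_sites(vt)[, c("z", "w")])
})

test_that("phase_gene splices sites into transcript coordinates", {
  ref <- strsplit("AAAACCCCGGGGTTTT", "")[[1]]
  cds <- data.frame(start = c(2, 9), end = c(5, 12))  # exons AAAC + GGGG
  phased <- data.frame(pos = c(3, 10), z = c("A", "G"), w = c("T", "C"),
                       stringsAsFactors = FALSE)
  pg <- phase_gene(phased, cds, "+", ref, gene_id = "g1")
  expect_equal(pg$z, "AAACGGGG")
  expect_equal(pg$w, "ATACGCGG")   # site 3 -> exon1 offset 2, site 10 -> exon2 offset 2
  expect_equal(pg$n_w_specific, 2L)
  expect_equal(pg$n_masked, 0L)

  # empty site list: both haplotypes equal the reference CDS
  pg0 <- phase_gene(phased[0, ], cds, "+", ref)
  expect_equal(pg0$z, pg0$w)
  expect_equal(pg0$z, "AAACGGGG")

  # minus strand: complemented allele at the mirrored position
  pg_m <- phase_gene(phased, cds, "-", ref)
  expect_equal(pg_m$z, paste(oracle_revcomp(strsplit(pg$z, "")[[1]]),
                             collapse = ""))
  expect_equal(pg_m$w, paste(oracle_revcomp(strsplit(pg$w, "")[[1]]),
                             collapse = ""))

  # off-CDS sites ignored; masked sites are N in both copies
  phased2 <- data.frame(pos = c(1, 4), z = c("C", "N"), w = c("C", "N"))
  pg2 <- phase_gene(phased2, cds, "+", ref)
  expect_equal(pg2$n_masked, 1L)
  expect_equal(substr(pg2$z, 3, 3), "N")
  expect_equal(substr(pg2$w, 3, 3), "N")

  expect_error(phase_gene(phased, data.frame(start = 2, end = 99), "+", ref),
               "outside")
})

test_that("W-deletion screen combines dose and private-allele evidence", {
  ev <- data.frame(gene_id = c("del", "del", "ok", "amb"),
                   exon = c(1, 2, 1, 1),
                   cov_f = c(0.5, 1.0, 1.0, 0.7),
                   cov_m = c(1.0, 1.0, 1.0, 1.0),
                   private_f = c(0, 6, 8, 5))
  out <- screen_w_deletion(ev)
  expect_equal(setNames(out$flag, out$gene_id),
               c(amb = "AMBIGUOUS", del = "W_DELETED", ok = "INTACT"))
  expect_error(screen_w_deletion(ev[, -3]), "missing")
})

test_that("VCF writing and reading round-trips genotypes and supports", {
  gen <- simulate_genotypes(sim_config(seed = 12, gene_length = 400))
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gen$vt, path)
  back <- read_vcf(path, gen$vt$samples)
  expect_equal(back$sites$pos, gen$vt$sites$pos)
  expect_equal(back$sites$SAF, gen$vt$sites$SAF)
  expect_equal(unname(back$dp), unname(gen$vt$dp))
  norm_gt <- function(m) apply(m, c(1, 2), function(g)
    if (is.na(g)) NA_character_
    else paste(sort(strsplit(g, "/", fixed = TRUE)[[1]]), collapse = "/"))
  expect_equal(unname(norm_gt(back$gt)), unname(norm_gt(gen$vt$gt)))
  ph1 <- phase_sites(gen$vt); ph2 <- phase_sites(back)
  expect_equal(ph2[, c("z", "w")], ph1[, c("z", "w")])
})
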