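## Seeded generators for every input the pipeline consumes, with truth
## emitted alongside. All generators are pure functions of their
## configuration: the same seed reproduces every artifact bit for bit.

#' Simulation configuration
#'
#' @param seed integer seed fixing all generator output.
#' @param tree a [dated_species_tree()]; the default Sylvioidea-like ladder
#'   (splits 21, 17, 7, 5, 3 Ma; fusion 24 Ma; outgroup 44 Ma).
#' @param mu substitution rate (substitutions/site/My, Jukes-Cantor).
#' @param gene_length simulated CDS/alignment length in bp.
#' @param n_genes genes per scenario.
#' @param coverage_mean diploid autosomal coverage (x-fold). Single-copy
#'   regions (Z and W in females) get half of this; the default 60 places
#'   the female W at ~30x, the regime in which the 25x W-detection rule
#'   operates.
#' @param coverage_dispersion negative-binomial size for per-site depth
#'   draws; `0` selects the degenerate mode (exact class means).
#' @param coverage_sites per-site draws summarised into each per-sample
#'   median coverage.
#' @param het_diploid,het_hemizygous,het_sd heterozygosity means for
#'   diploid and hemizygous contexts, and their between-sample sd.
#' @param n_males,n_females resequenced sample counts.
#' @param depth_mean,depth_dispersion genotype depth model (NB mean/size;
#'   dispersion `0` = exact).
#' @param qual_mean site quality in the generated genotype tables.
#' @param zw_divergence per-site Z/W difference rate used when genotypes
#'   are generated without an explicit haplotype pair.
#' @param male_poly_rate per-site Z polymorphism rate among male
#'   haplotypes.
#' @param theta population-scaled mutation rate for diversity simulation.
#' @param scaffold_length scaffold length for diversity simulation (bp).
#' @param conv_tract optional gene-conversion spec:
#'   `list(species =, length =, prob =)`; a Z segment of `length` bp is
#'   copied onto that species' W with probability `prob` per gene.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = dated_species_tree(),
                       mu = 0.002, gene_length = 3000, n_genes = 10,
                       coverage_mean = 60, coverage_dispersion = 10,
                       coverage_sites = 2000,
                       het_diploid = 0.2, het_hemizygous = 0.01,
                       het_sd = 0.02,
                       n_males = 5, n_females = 5,
                       depth_mean = 30, depth_dispersion = 0,
                       qual_mean = 60,
                       zw_divergence = 0.02, male_poly_rate = 0,
                       theta = 0.003, scaffold_length = 1e6,
                       conv_tract = NULL) {
  structure(as.list(environment()), class = "sim_config")
}

## NB draw that degrades to the exact mean when dispersion (size) is 0
nb_draw <- function(n, mu, size) {
  if (size <= 0) rep(mu, n) else rnbinom(n, mu = mu, size = size)
}

## random DNA as a character vector
random_seq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## mutate each position with probability p to one of the other three bases
mutate_seq <- function(x, p) {
  hit <- which(runif(length(x)) < p)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  x
}

## ---- gametolog sequence simulation ------------------------------------

## newick join of two dated subtrees at age `at`
tree_join <- function(a, b, at) {
  list(str = sprintf("(%s:%g,%s:%g)", a$str, at - a$age, b$str, at - b$age),
       age = at)
}

## genealogy of one added-region gene: Z ladder following the species tree,
## a shared W clade detaching from the focal Z lineage at t_s (covering
## species that split after t_s), and species-specific W detachment for the
## older species (at half their own terminal window)
gene_genealogy <- function(dated, t_s) {
  splits <- dated$splits
  tip <- function(label) list(str = label, age = 0)
  own_t <- function(s) 0.5 * min(t_s, splits[[s]])

  d_species <- names(splits)[splits < t_s]
  z <- tip(paste0(dated$focal, "|Z"))
  w <- tip(paste0(dated$focal, "|W"))
  events <- sort(c(unname(splits), t_s), na.last = NA)
  for (a in events) {
    if (a == t_s) {
      # unsuppressed (t_s = 0): W still detaches, at effectively zero depth
      z <- tree_join(z, w, max(t_s, 1e-9))
      next
    }
    s <- names(splits)[match(a, splits)]
    if (s %in% d_species) {
      z <- tree_join(z, tip(paste0(s, "|Z")), a)
      w <- tree_join(w, tip(paste0(s, "|W")), a)
    } else {
      t0 <- max(own_t(s), 1e-9)   # W leaf always present; 0 = identical to Z
      sp <- tree_join(tip(paste0(s, "|Z")), tip(paste0(s, "|W")), t0)
      z <- tree_join(z, sp, a)
    }
  }
  z <- tree_join(z, tip("outgroup|OUT"), dated$outgroup_age)
  ape::read.tree(text = paste0(z$str, ";"))
}

#' Simulate gametolog alignments on a dated species tree
#'
#' For each gene an ancestral sequence evolves by Jukes-Cantor at rate `mu`
#' along a genealogy in which the W lineage detaches from the Z lineage at
#' the gene's recombination-suppression time: species splitting after that
#' time share one W clade, older species suppress on their own terminal
#' branches (before detachment the Z and W histories are identical).
#' Suppression times are drawn uniformly within the truth branch. Optional
#' gene conversion copies a Z segment onto the W after simulation.
#'
#' @param cfg a [sim_config()].
#' @param branches character vector of truth branch ids (see
#'   [focal_branches()]); recycled over `cfg$n_genes` genes. `"none"`
#'   simulates no suppression (Z equals W everywhere).
#' @return list with `alignments` (named list of character matrices with
#'   `species|tag` rows), `truth` (data.frame `gene_id`, `branch`, `t_s`,
#'   conversion-tract coordinates) and `tree` (the dated species tree).
#' @export
simulate_gametologs <- function(cfg = sim_config(), branches = "b3") {
  set.seed(cfg$seed)
  dated <- cfg$tree
  br <- focal_branches(dated)
  branches <- rep(branches, length.out = cfg$n_genes)
  alns <- vector("list", cfg$n_genes)
  truth <- data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
                      branch = branches, t_s = NA_real_,
                      conv_species = NA_character_,
                      conv_start = NA_integer_, conv_end = NA_integer_,
                      stringsAsFactors = FALSE)
  for (g in seq_len(cfg$n_genes)) {
    t_s <- if (branches[g] == "none") 0 else {
      row <- br[br$branch == branches[g], ]
      .ns_assert(nrow(row) == 1, paste0("unknown branch id: ", branches[g]))
      runif(1, row$child_age, row$parent_age)
    }
    truth$t_s[g] <- t_s
    phy <- gene_genealogy(dated, t_s)
    phy$edge.length <- phy$edge.length * cfg$mu
    sim <- phangorn::simSeq(phy, l = cfg$gene_length)
    m <- toupper(as.character(sim))
    if (!is.null(cfg$conv_tract) && runif(1) < cfg$conv_tract$prob) {
      sp <- cfg$conv_tract$species
      zr <- paste0(sp, "|Z"); wr <- paste0(sp, "|W")
      if (all(c(zr, wr) %in% rownames(m))) {
        len <- min(cfg$conv_tract$length, cfg$gene_length)
        start <- sample.int(cfg$gene_length - len + 1L, 1)
        m[wr, start:(start + len - 1L)] <- m[zr, start:(start + len - 1L)]
        truth$conv_species[g] <- sp
        truth$conv_start[g] <- start - 1L       # 0-based half-open
        truth$conv_end[g] <- start + len - 1L
      }
    }
    alns[[g]] <- m
  }
  names(alns) <- truth$gene_id
  list(alignments = alns, truth = truth, tree = dated)
}

## ---- scaffold profile simulation --------------------------------------

#' Simulate sex-stratified scaffold coverage/heterozygosity profiles
#'
#' Emulates the per-scaffold, per-sample evidence the sex-linkage
#' classifier consumes. Per-sample median coverage is the median of
#' `coverage_sites` negative-binomial per-site depth draws around the class
#' mean (autosome and PAR: full coverage in both sexes; Z: half coverage in
#' females; W: half coverage in females and exactly zero in males - the
#' coverage is computed from mismatch-free alignments, so male reads never
#' touch W scaffolds). Heterozygosity is normal around the diploid or
#' hemizygous mean, truncated to `[0, 1]`. Dispersion `0` yields exact
#' class means.
#'
#' @param cfg a [sim_config()].
#' @param n_per_class scaffolds per class.
#' @param classes simulated truth classes; `PAR` scaffolds have autosomal
#'   signal and are expected to be called `AUTOSOME`.
#' @return list with `profiles` (classifier input data.frame) and `truth`
#'   (`scaffold_id`, `class_true`, `expected_call`).
#' @export
simulate_profiles <- function(cfg = sim_config(), n_per_class = 50,
                              classes = c("AUTOSOME", "Z", "W", "PAR")) {
  set.seed(cfg$seed)
  c_full <- cfg$coverage_mean
  cov_mean <- function(class, sex) {
    switch(class,
           AUTOSOME = c_full, PAR = c_full,
           Z = if (sex == "F") c_full / 2 else c_full,
           W = if (sex == "F") c_full / 2 else 0)
  }
  het_mean <- function(class, sex) {
    hemi <- (class == "Z" && sex == "F") || class == "W"
    if (class == "W" && sex == "M") return(0)
    if (hemi) cfg$het_hemizygous else cfg$het_diploid
  }
  samples <- data.frame(
    sample_id = c(sprintf("F%02d", seq_len(cfg$n_females)),
                  sprintf("M%02d", seq_len(cfg$n_males))),
    sex = c(rep("F", cfg$n_females), rep("M", cfg$n_males)),
    stringsAsFactors = FALSE)
  rows <- list(); truth <- list(); k <- 0
  for (cl in classes) for (i in seq_len(n_per_class)) {
    k <- k + 1
    sid <- sprintf("scaf_%s_%03d", cl, i)
    for (r in seq_len(nrow(samples))) {
      mu <- cov_mean(cl, samples$sex[r])
      cov <- if (mu == 0) 0
             else median(nb_draw(cfg$coverage_sites, mu, cfg$coverage_dispersion))
      hm <- het_mean(cl, samples$sex[r])
      het <- if (cfg$coverage_dispersion <= 0) hm
             else min(1, max(0, rnorm(1, hm, cfg$het_sd)))
      rows[[length(rows) + 1]] <- data.frame(
        scaffold_id = sid, sample_id = samples$sample_id[r],
        sex = samples$sex[r], median_coverage = cov, heterozygosity = het,
        stringsAsFactors = FALSE)
    }
    truth[[k]] <- data.frame(scaffold_id = sid, class_true = cl,
                             expected_call = if (cl == "PAR") "AUTOSOME" else cl,
                             stringsAsFactors = FALSE)
  }
  list(profiles = do.call(rbind, rows), truth = do.call(rbind, truth))
}

## ---- genotype simulation ----------------------------------------------

sim_samples <- function(cfg) {
  data.frame(
    sample_id = c(sprintf("M%02d", seq_len(cfg$n_males)),
                  sprintf("F%02d", seq_len(cfg$n_females))),
    sex = c(rep("M", cfg$n_males), rep("F", cfg$n_females)),
    stringsAsFactors = FALSE)
}

## support fields consistent with a depth (strictly positive when dp >= 2)
support_fields <- function(dp) {
  saf <- pmax(1L, round(dp / 2)); sar <- pmax(1L, dp - saf)
  data.frame(SAF = saf, SAR = sar, RPL = saf, RPR = sar)
}

#' Simulate male/female genotype tables from a Z/W haplotype pair
#'
#' Projects known Z and W haplotypes onto a VCF-convention site table:
#' males carry two Z copies (each independently mutated at
#' `male_poly_rate` to model standing Z polymorphism), females one Z and
#' one W copy co-mapped to the Z reference. Sites are emitted wherever any
#' sampled allele differs from the Z reference. Depth, site quality and
#' strand/placement supports are populated so every downstream filter is
#' exercisable; with `depth_dispersion = 0` and default quality the table
#' is error-free.
#'
#' @param cfg a [sim_config()].
#' @param z_seq,w_seq optional haplotypes (character vectors of equal
#'   length); generated from `cfg$gene_length` and `cfg$zw_divergence`
#'   when omitted.
#' @param scaffold scaffold name for the emitted sites.
#' @return list with `vt` (a [variant_table()]), `truth` (data.frame
#'   `pos`, `z`, `w`, `informative`) and the haplotypes used.
#' @export
simulate_genotypes <- function(cfg = sim_config(), z_seq = NULL, w_seq = NULL,
                               scaffold = "scafZ") {
  set.seed(cfg$seed)
  if (is.null(z_seq)) z_seq <- random_seq(cfg$gene_length)
  if (is.null(w_seq)) w_seq <- mutate_seq(z_seq, cfg$zw_divergence)
  .ns_assert(length(z_seq) == length(w_seq), "haplotypes must match in length")
  L <- length(z_seq)
  samples <- sim_samples(cfg)
  n_m <- cfg$n_males; n_f <- cfg$n_females

  ## male Z haplotypes with optional polymorphism
  zhap <- replicate(2 * n_m + n_f, mutate_seq(z_seq, cfg$male_poly_rate),
                    simplify = FALSE)
  seg <- which(vapply(seq_len(L), function(i) {
    alleles <- c(vapply(zhap, `[[`, "", i), w_seq[i])
    any(alleles != z_seq[i])
  }, TRUE))

  n <- length(seg)
  gt <- matrix(NA_character_, n, nrow(samples))
  for (j in seq_len(n_m))
    gt[, j] <- paste(vapply(seg, function(i) zhap[[2 * j - 1]][i], ""),
                     vapply(seg, function(i) zhap[[2 * j]][i], ""), sep = "/")
  for (j in seq_len(n_f))
    gt[, n_m + j] <- paste(vapply(seg, function(i) zhap[[2 * n_m + j]][i], ""),
                           w_seq[seg], sep = "/")
  dp <- matrix(nb_draw(n * nrow(samples), cfg$depth_mean,
                       cfg$depth_dispersion), n, nrow(samples))
  ref <- z_seq[seg]
  alt <- vapply(seq_len(n), function(i) {
    alleles <- setdiff(unique(strsplit(paste(gt[i, ], collapse = "/"),
                                       "/", fixed = TRUE)[[1]]), ref[i])
    paste(alleles, collapse = ",")
  }, "")
  sup <- support_fields(round(rowMeans(dp)))
  sites <- data.frame(scaffold = scaffold, pos = seg, ref = ref, alt = alt,
                      qual = cfg$qual_mean, sup, stringsAsFactors = FALSE)
  vt <- variant_table(sites, gt, dp, samples)
  truth <- data.frame(pos = seg, z = z_seq[seg], w = w_seq[seg],
                      informative = z_seq[seg] != w_seq[seg],
                      stringsAsFactors = FALSE)
  list(vt = vt, truth = truth, z_seq = z_seq, w_seq = w_seq)
}

#' Simulate a neutral diversity panel at a given theta
#'
#' Direct (coalescent-free) simulation: the number of segregating sites is
#' Poisson with mean `theta * L * a_k` (Watterson's constant
#' `a_k = sum_{j=1}^{k-1} 1/j` for `k` sampled allele copies) and each
#' site's alternate-allele count `j` is drawn from the neutral site
#' frequency spectrum `P(j) \propto 1/j`, which makes the expected per-site
#' pairwise diversity equal `theta` exactly. Alternate alleles are assigned
#' to copies uniformly. Depth, quality and support fields are populated to
#' pass the variant filters; optional missingness can be injected at known
#' sites.
#'
#' @param cfg a [sim_config()]; uses `theta`, `scaffold_length`,
#'   `n_males`, `n_females`, `depth_mean`, `qual_mean`.
#' @param ploidy `"diploid"` (k = 2n copies) or `"haploid"` (k = n,
#'   e.g. females on sex-linked scaffolds).
#' @param missing_pos positions at which to inject missing genotypes.
#' @param missing_frac fraction of samples set missing at those positions.
#' @param scaffold scaffold name.
#' @return list with `vt` (a [variant_table()]), `truth` (`theta`, per-site
#'   `pos`, `j`, `k`) and `mask` (full-scaffold `callable_mask`).
#' @export
simulate_diversity <- function(cfg = sim_config(), ploidy = "diploid",
                               missing_pos = integer(0), missing_frac = 0.3,
                               scaffold = "sim1") {
  set.seed(cfg$seed)
  samples <- sim_samples(cfg)
  n_samp <- nrow(samples)
  copies <- if (ploidy == "diploid") 2L else 1L
  k <- copies * n_samp
  .ns_assert(k >= 2, "need at least two allele copies")
  L <- cfg$scaffold_length
  a_k <- sum(1 / seq_len(k - 1))
  S <- min(rpois(1, cfg$theta * L * a_k), L)
  pos <- sort(sample.int(L, S))
  j <- sample.int(k - 1, S, replace = TRUE, prob = 1 / seq_len(k - 1))

  base_pair <- function() sample(c("A", "C", "G", "T"), 2)
  gt <- matrix(NA_character_, S, n_samp)
  ref <- alt <- character(S)
  for (i in seq_len(S)) {
    ra <- base_pair(); ref[i] <- ra[1]; alt[i] <- ra[2]
    carriers <- sample.int(k, j[i])
    hap <- rep(ref[i], k); hap[carriers] <- alt[i]
    gt[i, ] <- vapply(seq_len(n_samp), function(s) {
      paste(hap[((s - 1) * copies + 1):(s * copies)], collapse = "/")
    }, "")
  }
  if (length(missing_pos)) {
    n_miss <- max(1L, ceiling(missing_frac * n_samp))
    for (p in missing_pos) {
      i <- match(p, pos)
      if (!is.na(i)) gt[i, seq_len(n_miss)] <- NA_character_
    }
  }
  dp <- matrix(cfg$depth_mean, S, n_samp)
  sup <- support_fields(rep(cfg$depth_mean, S))
  sites <- data.frame(scaffold = rep(scaffold, S), pos = pos, ref = ref,
                      alt = alt, qual = rep(cfg$qual_mean, S), sup,
                      stringsAsFactors = FALSE)
  mask <- data.frame(scaffold = scaffold, start = 0L, end = L,
                     stringsAsFactors = FALSE)
  class(mask) <- c("callable_mask", "data.frame")
  list(vt = variant_table(sites, gt, dp, samples),
       truth = list(theta = cfg$theta, pos = pos, j = j, k = k),
       mask = mask)
}
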