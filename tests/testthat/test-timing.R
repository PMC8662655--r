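# The quoted scenario tree: focal-lineage splits at 21, 17 and 7 Ma,
# fusion at 24 Ma, so the focal branches are b1:24-21, b2:21-17, b3:17-7,
# b4:7-0.
scenario_tree <- function() {
  dated_species_tree(splits = c(panurus = 21, locustella = 17, acro = 7),
                     focal = "warbler", fusion_age = 24, outgroup_age = 44)
}

# gene tree over the scenario taxa with chosen support values
scenario_gene_tree <- function(panurus_pair = 0, w_clade4 = 0,
                               locustella_w_in_clade = FALSE,
                               locustella_pair = 0) {
  w_core <- "(warbler|W:3,acro|W:3)%W%"
  if (locustella_w_in_clade)
    w_core <- sprintf("(%s:2,locustella|W:5)%%W%%", w_core)
  z_core <- "(warbler|Z:3,acro|Z:3)60"
  if (locustella_pair > 0) {
    mid <- sprintf("((%s:6,%s:9)50:3,(locustella|Z:5,locustella|W:5)%d:7)55",
                   z_core, w_core, locustella_pair)
  } else if (locustella_w_in_clade) {
    mid <- sprintf("((%s:9,%s:7)50:5,locustella|Z:12)55", z_core, w_core)
  } else {
    mid <- sprintf("(((%s:6,%s:6)50:3,locustella|Z:9)50:3,locustella|W:12)55",
                   z_core, w_core)
  }
  nw <- sprintf("((%s:9,(panurus|Z:2,panurus|W:2)%d:19)50:23,outgroup|OUT:44);",
                mid, panurus_pair)
  nw <- gsub("%W%", as.character(w_clade4), nw, fixed = TRUE)
  ape::read.tree(text = nw)
}

test_that("trimming removes exactly the columns with gaps or ambiguity", {
  aln <- rbind(a = c("A", "C", "G", "T", "A"),
               b = c("A", "C", "N", "T", "-"),
               c = c("A", "C", "G", "T", "A"))
  out <- trim_alignment(aln)
  expect_equal(ncol(out), 3)
  expect_equal(rownames(out), c("a", "b", "c"))
  clean <- rbind(a = c("A", "C"), b = c("G", "T"))
  expect_identical(trim_alignment(clean), clean)
  allgap <- rbind(a = c("A", "C"), b = c("-", "-"))
  expect_equal(ncol(trim_alignment(allgap)), 0)
})

test_that("the 700 bp length filter is strict", {
  mk <- function(n) matrix("A", 2, n)
  alns <- list(short = mk(699), exact = mk(700), mixed = mk(1200), tiny = mk(500))
  expect_equal(names(filter_alignments_for_timing(alns)), c("exact", "mixed"))
  expect_equal(length(filter_alignments_for_timing(list())), 0)
})

test_that("gene-conversion masking flags dense identity runs, not uniform divergence", {
  set.seed(1)
  z <- sample(c("A", "C", "G", "T"), 1000, TRUE)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  cfg <- pipeline_config(geneconv_perms = 2000)

  # ~10% divergence uniformly spaced: nothing flagged
  w_uni <- z
  for (i in seq(10, 1000, by = 10)) w_uni[i] <- other(z[i])
  aln <- rbind(z, w_uni); rownames(aln) <- c("sp|Z", "sp|W")
  m_uni <- mask_gene_conversion(aln, list(c("sp|Z", "sp|W")), cfg, seed = 2)
  expect_equal(nrow(m_uni$tracts), 0)

  # 300 identical leading columns then ~10% divergence: leading tract flagged
  w_lead <- z
  for (i in seq(301, 1000, by = 10)) w_lead[i] <- other(z[i])
  aln2 <- rbind(z, w_lead); rownames(aln2) <- c("sp|Z", "sp|W")
  m_lead <- mask_gene_conversion(aln2, list(c("sp|Z", "sp|W")), cfg, seed = 2)
  expect_gte(nrow(m_lead$tracts), 1)
  expect_equal(m_lead$tracts$start[1], 0)
  expect_equal(m_lead$tracts$length[1], 300)
  expect_lt(m_lead$tracts$p[1], 0.05)
  trimmed <- apply_conversion_mask(aln2, m_lead)
  expect_equal(ncol(trimmed), 1000 - sum(m_lead$mask$end - m_lead$mask$start))

  # identical rows: empty mask
  aln3 <- rbind(z, z); rownames(aln3) <- c("sp|Z", "sp|W")
  expect_equal(nrow(mask_gene_conversion(aln3, list(c("sp|Z", "sp|W")),
                                         cfg, seed = 2)$tracts), 0)
})

test_that("simulated conversion tracts are recovered", {
  cfg <- sim_config(seed = 31, n_genes = 4, gene_length = 2000,
                    conv_tract = list(species = "warbler", length = 500,
                                      prob = 1))
  g <- simulate_gametologs(cfg, branches = "b2")
  pcfg <- pipeline_config(geneconv_perms = 2000)
  hits <- 0
  for (i in seq_len(4)) {
    m <- mask_gene_conversion(g$alignments[[i]],
                              list(c("warbler|Z", "warbler|W")), pcfg, seed = i)
    truth <- g$truth[i, ]
    if (nrow(m$tracts) &&
        any(m$tracts$start < truth$conv_end & m$tracts$end > truth$conv_start))
      hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("NJ builder recovers additive quartets and is deterministic", {
  set.seed(9)
  # quartet with clear structure: (a,b) vs (c,out)
  anc <- sample(c("A", "C", "G", "T"), 2000, TRUE)
  mut <- function(x, p) {
    hit <- which(runif(length(x)) < p)
    for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    x
  }
  inner1 <- mut(anc, 0.05); inner2 <- mut(anc, 0.05)
  aln <- rbind("a|Z" = mut(inner1, 0.02), "b|W" = mut(inner1, 0.02),
               "c|Z" = mut(inner2, 0.05), "d|OUT" = mut(inner2, 0.1))
  tr <- build_tree_nj(aln, n_bootstrap = 100, seed = 4)
  expect_true(ape::is.monophyletic(tr, c("a|Z", "b|W")))
  tr2 <- build_tree_nj(aln, n_bootstrap = 100, seed = 4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  # identical sequences pair at 100% with zero terminal branch lengths
  aln2 <- rbind("a|Z" = anc, "b|W" = anc, "c|Z" = mut(anc, 0.1),
                "d|OUT" = mut(anc, 0.2))
  tr3 <- build_tree_nj(aln2, n_bootstrap = 50, seed = 4)
  node <- ape::getMRCA(tr3, c("a|Z", "b|W"))
  expect_equal(as.numeric(tr3$node.label[node - ape::Ntip(tr3)]), 100)
  term <- tr3$edge.length[tr3$edge[, 2] %in% match(c("a|Z", "b|W"), tr3$tip.label)]
  expect_equal(term, c(0, 0))
})

test_that("added-region inference reproduces the three reference placements", {
  dst <- scenario_tree()
  br <- focal_branches(dst)
  expect_equal(br$parent_age, c(24, 21, 17, 7))

  # bearded-reedling pair + reed-warbler W clade supported, middle species
  # unresolved: interval 21-7 Ma
  t1 <- scenario_gene_tree(panurus_pair = 95, w_clade4 = 92)
  c1 <- infer_suppression_added(t1, dst)
  expect_equal(c1$branches$branch, c("b2", "b3"))
  expect_equal(c1$status, "INTERVAL")

  # middle species' W inside the supported W clade: resolved to 21-17
  t2 <- scenario_gene_tree(panurus_pair = 95, w_clade4 = 92,
                           locustella_w_in_clade = TRUE)
  c2 <- infer_suppression_added(t2, dst)
  expect_equal(c2$branches$branch, "b2")
  expect_equal(c2$status, "RESOLVED")

  # middle species' Z+W pair supported instead: resolved to 17-7
  t3 <- scenario_gene_tree(panurus_pair = 95, w_clade4 = 92,
                           locustella_pair = 88)
  c3 <- infer_suppression_added(t3, dst)
  expect_equal(c3$branches$branch, "b3")

  # no supported nodes: all four branches remain
  t4 <- scenario_gene_tree()
  c4 <- infer_suppression_added(t4, dst)
  expect_equal(c4$branches$branch, paste0("b", 1:4))
  expect_equal(c4$status, "INTERVAL")

  expect_error(infer_suppression_added(
    ape::drop.tip(t1, "warbler|W"), dst), "focal")
})

test_that("adding a supported constraint never enlarges the candidate set", {
  dst <- scenario_tree()
  base <- infer_suppression_added(scenario_gene_tree(panurus_pair = 95), dst)
  more <- infer_suppression_added(
    scenario_gene_tree(panurus_pair = 95, w_clade4 = 92), dst)
  expect_true(all(more$branches$branch %in% base$branches$branch))
  # candidates always form a contiguous segment of the lineage path
  for (call in list(base, more)) {
    idx <- match(call$branches$branch, focal_branches(dst)$branch)
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("ancestral-region inference brackets the W-clade attachment", {
  dst <- dated_species_tree()
  # supported flanks on both sides: single branch
  nw <- paste0("((((((((warbler|Z:1,panurus|Z:1)90:1,greattit|Z:2)95:1,",
               "zebrafinch|Z:3)85:1,(warbler|W:2,panurus|W:2)99:2)80:1,",
               "manakin|Z:5)75:1,budgerigar|Z:6)88:1,chicken|Z:7)60:1,",
               "(emu|Z:8,anolis|OUT:8)50:1);")
  c1 <- infer_suppression_ancestral(ape::read.tree(text = nw), dst)
  expect_equal(c1$status, "RESOLVED")
  expect_equal(c1$branches$parent_age, 41)
  expect_equal(c1$branches$child_age, 33)

  # no supported flanks: interval widens to the root on the old side and to
  # the attachment's own dated position on the young side
  nw50 <- gsub("\\)\\d+:", ")50:", nw)
  c2 <- infer_suppression_ancestral(ape::read.tree(text = nw50), dst)
  expect_equal(c2$status, "INTERVAL")
  expect_equal(max(c2$branches$parent_age), 312)
  expect_equal(min(c2$branches$child_age), 33)

  # supported non-monophyly of the W leaves is inconclusive
  nw_para <- paste0("(((((warbler|Z:1,panurus|W:1)90:1,greattit|Z:2)95:1,",
                    "warbler|W:3)85:1,chicken|Z:7)60:1,anolis|OUT:8);")
  c3 <- infer_suppression_ancestral(ape::read.tree(text = nw_para), dst)
  expect_equal(c3$status, "INCONCLUSIVE")
  expect_match(c3$note, "monophyletic")
})

test_that("suppression_table summarises calls", {
  dst <- scenario_tree()
  calls <- list(infer_suppression_added(scenario_gene_tree(95, 92), dst,
                                        gene_id = "g1"))
  tab <- suppression_table(calls)
  expect_equal(tab$gene_id, "g1")
  expect_equal(tab$branches, "b2,b3")
  expect_equal(tab$oldest, 21)
  expect_equal(tab$youngest, 7)
})
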