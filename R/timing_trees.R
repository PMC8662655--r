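## Dating recombination suppression per gene from bootstrap-annotated gene
## trees read against a dated species phylogeny.
##
## Leaf naming convention throughout: "<species>|Z", "<species>|W" for
## gametolog copies and "<species>|OUT" for outgroup sequences used only for
## rooting.

#' Dated species tree for suppression timing
#'
#' Holds the dated backbone the gene-tree topology is read against: the
#' split age of every Sylvioidea-like species from the focal lineage, the
#' Z-autosome fusion age bounding the added-region analysis, and (for the
#' ancestral-region analysis) the split ages of the avian backbone species
#' from the focal Z lineage.
#'
#' @param splits named numeric vector: split age (Ma) of each non-focal
#'   ingroup species from the focal lineage. Defaults to a Sylvioidea-like
#'   ladder (bearded-reedling analogue 21, grassbird analogue 17, and a
#'   reed-warbler radiation at 7, 5 and 3 Ma).
#' @param focal name of the focal species (a leaf).
#' @param fusion_age age (Ma) of the autosome fusion creating the added
#'   region; must exceed all ingroup splits.
#' @param outgroup_age split age of the rooting outgroup for added-region
#'   gene trees.
#' @param backbone named numeric vector of split ages of non-Sylvioidea
#'   backbone species from the focal Z lineage (oldest = root), used by
#'   [infer_suppression_ancestral()].
#' @return list of class `dated_species_tree`.
#' @export
dated_species_tree <- function(splits = c(panurus = 21, locustella = 17,
                                          acro_a = 7, acro_b = 5, iduna = 3),
                               focal = "warbler",
                               fusion_age = 24,
                               outgroup_age = 44,
                               backbone = c(anolis = 312, emu = 93,
                                            chicken = 75, budgerigar = 60,
                                            manakin = 41, zebrafinch = 33,
                                            greattit = 24)) {
  .ns_assert(!is.null(names(splits)) && all(nzchar(names(splits))),
             "splits must be a named vector")
  .ns_assert(all(splits > 0), "split ages must be positive")
  .ns_assert(fusion_age > max(splits),
             "fusion age must predate all ingroup splits")
  if (!is.null(backbone)) {
    backbone <- sort(backbone, decreasing = TRUE)
    .ns_assert(min(backbone) >= max(splits),
               "backbone splits must predate the ingroup radiation")
  }
  structure(list(splits = sort(splits, decreasing = TRUE), focal = focal,
                 fusion_age = fusion_age, outgroup_age = outgroup_age,
                 backbone = backbone),
            class = "dated_species_tree")
}

#' @export
print.dated_species_tree <- function(x, ...) {
  cat("dated_species_tree\n")
  cat("  focal:", x$focal, "  fusion:", x$fusion_age, "Ma\n")
  cat("  ingroup splits:",
      paste(sprintf("%s=%g", names(x$splits), x$splits), collapse = ", "), "\n")
  if (!is.null(x$backbone))
    cat("  backbone:",
        paste(sprintf("%s=%g", names(x$backbone), x$backbone), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate dated branches along the focal lineage (added region)
#'
#' Branches run from the fusion age to the present, delimited by the
#' ingroup split ages.
#'
#' @param dated a [dated_species_tree()].
#' @return data.frame with `branch`, `parent_age`, `child_age`
#'   (`parent_age > child_age >= 0`).
#' @export
focal_branches <- function(dated) {
  bounds <- c(dated$fusion_age, sort(unique(unname(dated$splits)),
                                     decreasing = TRUE), 0)
  data.frame(branch = paste0("b", seq_len(length(bounds) - 1)),
             parent_age = bounds[-length(bounds)],
             child_age = bounds[-1], stringsAsFactors = FALSE)
}

#' Enumerate dated branches along the avian backbone (ancestral region)
#'
#' Branches are delimited by the backbone split ages, extended tipward to
#' the ingroup crown (the oldest Sylvioidea split).
#'
#' @param dated a [dated_species_tree()] with a `backbone`.
#' @return data.frame with `branch`, `parent_age`, `child_age`.
#' @export
backbone_branches <- function(dated) {
  .ns_assert(!is.null(dated$backbone), "dated tree has no backbone")
  bounds <- c(sort(unique(unname(dated$backbone)), decreasing = TRUE),
              max(dated$splits))
  data.frame(branch = paste0("a", seq_len(length(bounds) - 1)),
             parent_age = bounds[-length(bounds)],
             child_age = bounds[-1], stringsAsFactors = FALSE)
}

## split age of species s from the focal lineage; the focal species itself
## "splits" at its most recent divergence
species_split_age <- function(dated, s) {
  if (s == dated$focal) return(min(dated$splits))
  a <- dated$splits[s]
  if (is.na(a)) .ns_stop("species not in dated tree: ", s)
  unname(a)
}

## crown age of a species set containing the focal species
crown_age <- function(dated, species_set) {
  others <- setdiff(species_set, dated$focal)
  .ns_assert(length(others) >= 1, "crown age needs at least two species")
  max(vapply(others, function(s) species_split_age(dated, s), 1))
}

## ---- gene-tree helpers -----------------------------------------------

split_leaf <- function(labels) {
  m <- regmatches(labels, regexpr("\\|(Z|W|OUT)$", labels))
  .ns_assert(length(m) == length(labels),
             "leaf labels must end in |Z, |W or |OUT")
  data.frame(label = labels,
             species = sub("\\|(Z|W|OUT)$", "", labels),
             tag = sub("^\\|", "", m), stringsAsFactors = FALSE)
}

node_support <- function(tree, node) {
  lab <- tree$node.label[node - ape::Ntip(tree)]
  suppressWarnings(as.numeric(lab))
}

clade_tips <- function(tree, node) {
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

## MRCA node of a tip set; NA support treated as unsupported
is_supported_clade <- function(tree, tips, tau) {
  if (length(tips) < 2) return(FALSE)
  node <- ape::getMRCA(tree, tips)
  if (is.null(node)) return(FALSE)
  if (!setequal(clade_tips(tree, node), tips)) return(FALSE)
  s <- node_support(tree, node)
  isTRUE(!is.na(s) && s >= tau)
}

## ---- NJ + bootstrap stand-in ------------------------------------------

## Jukes-Cantor distance matrix from an integer-coded alignment;
## saturated pairs (p >= 3/4) are set to `cap`
jc_dist <- function(codes, cap = 5, warn = TRUE) {
  n <- nrow(codes)
  D <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    xi <- codes[i, ]
    for (j in seq.int(i + 1, n)) {
      p <- mean(xi != codes[j, ])
      d <- if (p >= 0.75) { saturated <- TRUE; cap }
           else -0.75 * log(1 - 4 * p / 3)
      D[i, j] <- D[j, i] <- d
    }
  }
  if (saturated && warn)
    warning("saturated pairwise distance(s) set to cap = ", cap, call. = FALSE)
  D
}

#' Neighbor-joining gene tree with bootstrap supports
#'
#' Desk-scale stand-in for an external maximum-likelihood tree search:
#' neighbor joining on Jukes-Cantor distances, rooted on the `|OUT`
#' leaves, with clade supports from seeded alignment-column bootstrap
#' resampling (percent of replicates containing each clade). Externally
#' built Newick trees with support labels are equally accepted by the
#' inference functions, so this builder is pluggable.
#'
#' @param aln trimmed character-matrix alignment; rownames follow the
#'   `species|tag` convention and must include at least one `|OUT` leaf.
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @param cfg a [pipeline_config()]; uses `sat_cap` for saturated
#'   distances.
#' @return a rooted `ape::phylo` with `node.label` bootstrap percentages.
#' @export
build_tree_nj <- function(aln, n_bootstrap = 100, seed = 1L,
                          cfg = pipeline_config()) {
  .ns_assert(nrow(aln) >= 4, "need at least 4 sequences")
  out_tips <- grep("\\|OUT$", rownames(aln), value = TRUE)
  .ns_assert(length(out_tips) >= 1, "need at least one |OUT leaf for rooting")
  codes <- matrix(match(aln, c("A", "C", "G", "T")), nrow(aln),
                  dimnames = dimnames(aln))
  .ns_assert(!anyNA(codes), "alignment must be trimmed to {A,C,G,T} first")

  build <- function(cd, warn) {
    phy <- ape::nj(stats::as.dist(jc_dist(cd, cap = cfg$sat_cap, warn = warn)))
    phy$edge.length[phy$edge.length < 0] <- 0
    ape::root(phy, outgroup = out_tips, resolve.root = TRUE)
  }
  tr <- build(codes, warn = TRUE)
  set.seed(seed)
  L <- ncol(codes)
  boots <- lapply(seq_len(n_bootstrap), function(b)
    build(codes[, sample.int(L, replace = TRUE), drop = FALSE], warn = FALSE))
  counts <- ape::prop.clades(tr, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  tr$node.label <- as.character(round(100 * counts / n_bootstrap))
  tr
}

## ---- suppression inference --------------------------------------------

new_suppression_call <- function(gene_id, branches, status, constraints,
                                 note = NA_character_) {
  structure(list(gene_id = gene_id, branches = branches, status = status,
                 constraints = constraints, note = note),
            class = "suppression_call")
}

#' @export
print.suppression_call <- function(x, ...) {
  cat(sprintf("suppression_call %s: %s", x$gene_id, x$status))
  if (nrow(x$branches))
    cat(sprintf(" [%s; %g-%g Ma]", paste(x$branches$branch, collapse = ","),
                max(x$branches$parent_age), min(x$branches$child_age)))
  if (!is.na(x$note)) cat("  (", x$note, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Date recombination suppression for an added-region gene
#'
#' Reads a bootstrap-annotated, outgroup-rooted gene tree against the dated
#' species tree. Starting from all focal-lineage branches between the
#' fusion age and the present:
#' \itemize{
#'   \item a supported (`>= tau`) clade pairing one species' Z and W
#'     copies means recombination continued past that species' split, so
#'     branches older than the split are removed;
#'   \item a supported clade of only W copies that includes the focal
#'     species' W means suppression predates that species set's radiation,
#'     so branches younger than its crown age (on the dated tree, not the
#'     gene tree) are removed.
#' }
#' One remaining branch is `RESOLVED`, several are an `INTERVAL`, and an
#' empty set (conflicting constraints) is `INCONCLUSIVE` - reported, not
#' dropped. Nodes below `tau` are treated as absent (polytomy semantics).
#'
#' @param tree rooted `ape::phylo` with `species|tag` leaves and bootstrap
#'   `node.label`s.
#' @param dated a [dated_species_tree()].
#' @param tau bootstrap support threshold (percent), default 70.
#' @param gene_id identifier carried into the call.
#' @return a `suppression_call`.
#' @export
infer_suppression_added <- function(tree, dated, tau = 70, gene_id = "gene") {
  leaves <- split_leaf(tree$tip.label)
  focal_w <- leaves$label[leaves$species == dated$focal & leaves$tag == "W"]
  if (length(focal_w) != 1L)
    .ns_stop("focal species W leaf absent from gene tree")

  br <- focal_branches(dated)
  keep <- rep(TRUE, nrow(br))
  cons <- data.frame(type = character(), species = character(),
                     age = numeric(), stringsAsFactors = FALSE)

  ingroup <- c(dated$focal, names(dated$splits))
  for (s in intersect(ingroup, unique(leaves$species))) {
    zt <- leaves$label[leaves$species == s & leaves$tag == "Z"]
    wt <- leaves$label[leaves$species == s & leaves$tag == "W"]
    if (length(zt) == 1L && length(wt) == 1L &&
        is_supported_clade(tree, c(zt, wt), tau)) {
      a <- species_split_age(dated, s)
      keep <- keep & (br$child_age < a)
      cons <- rbind(cons, data.frame(type = "zw_pair", species = s, age = a,
                                     stringsAsFactors = FALSE))
    }
  }

  ntip <- ape::Ntip(tree)
  for (node in seq.int(ntip + 1, ntip + tree$Nnode)) {
    s <- node_support(tree, node)
    if (is.na(s) || s < tau) next
    tips <- clade_tips(tree, node)
    info <- leaves[match(tips, leaves$label), ]
    if (all(info$tag == "W") && focal_w %in% tips && length(tips) >= 2) {
      cr <- crown_age(dated, info$species)
      keep <- keep & (br$parent_age > cr)
      cons <- rbind(cons, data.frame(type = "w_clade",
                                     species = paste(sort(info$species),
                                                     collapse = "+"),
                                     age = cr, stringsAsFactors = FALSE))
    }
  }

  cand <- br[keep, , drop = FALSE]
  rownames(cand) <- NULL
  status <- if (nrow(cand) == 0L) "INCONCLUSIVE"
            else if (nrow(cand) == 1L) "RESOLVED" else "INTERVAL"
  new_suppression_call(gene_id, cand, status, cons)
}

#' Date recombination suppression for an ancestral-region gene
#'
#' On the ancestral sex chromosome all ingroup W copies are expected to form
#' one clade attached deep in the avian backbone. The candidate interval is
#' bounded by the closest supported nodes flanking the W-clade attachment on
#' the backbone spine: the youngest supported node above it (default: the
#' root) and the oldest supported node at or below it (default: the
#' attachment's own dated position, i.e. the crown age of the Z subtree the
#' W clade is sister to). Unsupported flanking nodes widen the interval.
#' Non-monophyletic W copies make the gene `INCONCLUSIVE` and are reported.
#'
#' @inheritParams infer_suppression_added
#' @return a `suppression_call`.
#' @export
infer_suppression_ancestral <- function(tree, dated, tau = 70,
                                        gene_id = "gene") {
  .ns_assert(!is.null(dated$backbone),
             "dated tree needs a backbone for the ancestral analysis")
  leaves <- split_leaf(tree$tip.label)
  w_tips <- leaves$label[leaves$tag == "W"]
  .ns_assert(length(w_tips) >= 2, "need at least two W leaves")
  br <- backbone_branches(dated)
  ntip <- ape::Ntip(tree)

  ## dated age of the MRCA of a Z/OUT species set
  set_age <- function(species) {
    bb <- intersect(species, names(dated$backbone))
    if (length(bb)) return(max(dated$backbone[bb]))
    crown_age(dated, species)
  }

  w_mrca <- ape::getMRCA(tree, w_tips)
  if (!setequal(clade_tips(tree, w_mrca), w_tips))
    return(new_suppression_call(gene_id, br[0, ], "INCONCLUSIVE",
                                data.frame(), note = "W leaves not monophyletic"))

  syl_z <- leaves$label[leaves$tag == "Z" & leaves$species %in%
                          c(dated$focal, names(dated$splits))]
  .ns_assert(length(syl_z) >= 1, "no ingroup Z leaves present")
  z_end <- if (length(syl_z) > 1) ape::getMRCA(tree, syl_z)
           else match(syl_z, tree$tip.label)
  root <- ntip + 1L
  spine <- ape::nodepath(tree, root, z_end)
  spine <- spine[spine > ntip]                     # internal nodes only

  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  n_w <- parent_of(w_mrca)
  if (!(n_w %in% spine))
    return(new_suppression_call(gene_id, br[0, ], "INCONCLUSIVE",
                                data.frame(),
                                note = "W clade attaches off the backbone spine"))

  spine_z_age <- function(node) {
    tips <- clade_tips(tree, node)
    info <- leaves[match(tips, leaves$label), ]
    set_age(unique(info$species[info$tag != "W"]))
  }
  i_w <- match(n_w, spine)
  above <- if (i_w > 1) spine[seq_len(i_w - 1)] else integer(0)
  below <- spine[seq.int(i_w, length(spine))]      # n_w acts as its own floor

  sup <- function(nodes) {
    s <- vapply(nodes, function(n) node_support(tree, n), 1)
    nodes[!is.na(s) & s >= tau]
  }
  up_sup <- sup(above)
  A <- if (length(up_sup)) min(vapply(up_sup, spine_z_age, 1))
       else max(dated$backbone)
  dn_sup <- sup(below)
  B <- if (length(dn_sup)) max(vapply(dn_sup, spine_z_age, 1))
       else spine_z_age(n_w)

  cand <- br[br$parent_age <= A & br$child_age >= B, , drop = FALSE]
  rownames(cand) <- NULL
  status <- if (nrow(cand) == 0L) "INCONCLUSIVE"
            else if (nrow(cand) == 1L) "RESOLVED" else "INTERVAL"
  cons <- data.frame(type = c("upper", "lower"), species = NA_character_,
                     age = c(A, B), stringsAsFactors = FALSE)
  new_suppression_call(gene_id, cand, status, cons)
}

#' Tabulate suppression calls
#'
#' @param calls list of `suppression_call` objects.
#' @return data.frame with one row per gene: branch ids, age bounds and
#'   status, suitable for a timing heatmap.
#' @export
suppression_table <- function(calls) {
  out <- lapply(calls, function(x) {
    data.frame(gene_id = x$gene_id,
               branches = paste(x$branches$branch, collapse = ","),
               oldest = if (nrow(x$branches)) max(x$branches$parent_age) else NA_real_,
               youngest = if (nrow(x$branches)) min(x$branches$child_age) else NA_real_,
               status = x$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
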