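## Pairwise synonymous/nonsynonymous divergence by Nei-Gojobori (1986)
## counting with Jukes-Cantor correction, the gametolog filters, and the
## nonparametric group contrasts used on the resulting rate tables.

.ng_env <- new.env(parent = emptyenv())

ng_bases <- c("A", "C", "G", "T")

## standard genetic code, codons in ACGT x ACGT x ACGT order
ng_code <- function() {
  if (!is.null(.ng_env$code)) return(.ng_env$code)
  aa <- c(
    "K","N","K","N","T","T","T","T","R","S","R","S","I","I","M","I",
    "Q","H","Q","H","P","P","P","P","R","R","R","R","L","L","L","L",
    "E","D","E","D","A","A","A","A","G","G","G","G","V","V","V","V",
    "*","Y","*","Y","S","S","S","S","*","C","W","C","L","F","L","F")
  codons <- as.vector(t(outer(
    as.vector(t(outer(ng_bases, ng_bases, paste0))), ng_bases, paste0)))
  .ng_env$code <- setNames(aa, codons)
  .ng_env$code
}

## fractional synonymous sites per codon (stops excluded from the
## mutational opportunity; S + N = 3 for every codon)
ng_site_table <- function() {
  if (!is.null(.ng_env$sites)) return(.ng_env$sites)
  code <- ng_code()
  codons <- names(code)
  s <- setNames(numeric(64), codons)
  for (cd in codons) {
    if (code[[cd]] == "*") { s[cd] <- NA_real_; next }
    tot <- 0
    for (pos in 1:3) {
      nts <- setdiff(ng_bases, substr(cd, pos, pos))
      syn <- valid <- 0
      for (nt in nts) {
        mut <- cd
        substr(mut, pos, pos) <- nt
        if (code[[mut]] == "*") next
        valid <- valid + 1
        if (code[[mut]] == code[[cd]]) syn <- syn + 1
      }
      if (valid > 0) tot <- tot + syn / valid
    }
    s[cd] <- tot
  }
  .ng_env$sites <- s
  s
}

## average (syn, nonsyn) difference counts between two codons over all
## orderings of single-step mutational pathways; pathways through stop
## codons are excluded (all-blocked pairs fall back to all pathways)
ng_pair_diffs <- function(c1, c2) {
  code <- ng_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(0, 0))
  perms <- if (length(pos) == 1L) list(pos)
           else if (length(pos) == 2L) list(pos, rev(pos))
           else { p <- pos; list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                                 p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)]) }
  walk <- function(order) {
    cur <- c1; syn <- non <- 0; blocked <- FALSE
    for (k in order) {
      nxt <- cur
      substr(nxt, k, k) <- substr(c2, k, k)
      if (code[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (code[[nxt]] == code[[cur]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    list(syn = syn, non = non, blocked = blocked)
  }
  paths <- lapply(perms, walk)
  ok <- !vapply(paths, `[[`, TRUE, "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(mean(vapply(paths[ok], `[[`, 1, "syn")),
    mean(vapply(paths[ok], `[[`, 1, "non")))
}

## 64 x 64 lookup tables of average syn / nonsyn differences
ng_diff_tables <- function() {
  if (!is.null(.ng_env$sd)) return(list(sd = .ng_env$sd, nd = .ng_env$nd))
  code <- ng_code()
  codons <- names(code)
  sd <- nd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  for (i in 1:64) {
    if (code[[codons[i]]] == "*") next
    for (j in 1:64) {
      if (code[[codons[j]]] == "*") next
      d <- ng_pair_diffs(codons[i], codons[j])
      sd[i, j] <- d[1]; nd[i, j] <- d[2]
    }
  }
  .ng_env$sd <- sd; .ng_env$nd <- nd
  list(sd = sd, nd = nd)
}

jc_correct <- function(p) {
  x <- 1 - 4 * p / 3
  ifelse(x <= 0, NA_real_, -0.75 * log(x))
}

#' Nei-Gojobori pairwise substitution rates
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' in-frame coding sequences by the unweighted Nei-Gojobori (NG86) method:
#' per-codon synonymous site fractions by mutational opportunity (changes
#' creating stop codons are excluded from the opportunity, so S + N = 3 per
#' codon), multi-substitution codons averaged over all orderings of
#' single-step pathways with stop-codon intermediates excluded, and
#' Jukes-Cantor distance correction `d = -3/4 log(1 - 4p/3)`. Codons
#' containing any character outside `{A,C,G,T}` in either sequence are
#' dropped pairwise; `aligned_bp` counts retained codons only. Estimates
#' with `dS > rates_max_ds` or in the saturated log domain are flagged; a
#' pair with `dS = 0` carries an undefined omega.
#'
#' This counting estimator deliberately stands in for maximum-likelihood
#' codon models: it is deterministic and desk-scale, and its group
#' contrasts do not depend on the absolute rate scale.
#'
#' @param seq1,seq2 equal-length coding sequences (strings or character
#'   vectors), length divisible by 3, no internal stop codons among
#'   retained codons.
#' @param gene_id,pair identifiers carried into the result row.
#' @param cfg a [pipeline_config()]; `rates_max_ds` sets the saturation
#'   flag threshold.
#' @param on_stop `"error"` (default) rejects internal stop codons, as
#'   expected for curated coding alignments; `"drop"` removes the affected
#'   codon pairs, for sequence input without enforced codon structure.
#' @return one-row data.frame: `gene_id`, `pair`, `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `aligned_bp`,
#'   `saturated`, `omega_undefined`.
#' @export
ng86_rates <- function(seq1, seq2, gene_id = "gene", pair = "Z-W",
                       cfg = pipeline_config(),
                       on_stop = c("error", "drop")) {
  on_stop <- match.arg(on_stop)
  to_vec <- function(x) if (length(x) == 1L) strsplit(toupper(x), "")[[1]] else toupper(x)
  s1 <- to_vec(seq1); s2 <- to_vec(seq2)
  .ns_assert(length(s1) == length(s2), "sequences must have equal length")
  if (length(s1) %% 3 != 0) .ns_stop("sequence length must be divisible by 3")

  n_cod <- length(s1) / 3
  cod1 <- vapply(seq_len(n_cod), function(i)
    paste(s1[(3 * i - 2):(3 * i)], collapse = ""), "")
  cod2 <- vapply(seq_len(n_cod), function(i)
    paste(s2[(3 * i - 2):(3 * i)], collapse = ""), "")
  clean <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2)
  cod1 <- cod1[clean]; cod2 <- cod2[clean]
  if (length(cod1) == 0L) .ns_stop("no codons left after masking")
  code <- ng_code()
  stops <- code[cod1] == "*" | code[cod2] == "*"
  if (any(stops)) {
    if (on_stop == "error") .ns_stop("internal stop codon in input")
    cod1 <- cod1[!stops]; cod2 <- cod2[!stops]
    if (length(cod1) == 0L) .ns_stop("no codons left after masking")
  }

  sites <- ng_site_table()
  S <- (sum(sites[cod1]) + sum(sites[cod2])) / 2
  N <- 3 * length(cod1) - S
  tabs <- ng_diff_tables()
  Sd <- sum(tabs$sd[cbind(cod1, cod2)])
  Nd <- sum(tabs$nd[cbind(cod1, cod2)])

  pS <- Sd / S; pN <- Nd / N
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  saturated <- is.na(dS) || is.na(dN) || dS > cfg$rates_max_ds
  omega_undefined <- !is.na(dS) && dS == 0
  omega <- if (!saturated && !omega_undefined && !is.na(dN)) dN / dS else NA_real_
  data.frame(gene_id = gene_id, pair = pair, S_sites = S, N_sites = N,
             Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
             omega = omega, aligned_bp = 3L * length(cod1),
             saturated = saturated, omega_undefined = omega_undefined,
             stringsAsFactors = FALSE)
}

#' Filter a rate table on alignment length and saturation
#'
#' Keeps rows with `aligned_bp >= min_len` (inclusive) and `dS < max_ds`
#' (saturated and flagged rows are dropped). Idempotent.
#'
#' @param rates data.frame of [ng86_rates()] rows.
#' @param min_len minimum aligned length in bp (default 500).
#' @param max_ds maximum synonymous divergence (default 3, exclusive).
#' @return the filtered data.frame.
#' @export
filter_rates <- function(rates, min_len = 500, max_ds = 3) {
  keep <- rates$aligned_bp >= min_len & !rates$saturated &
    !is.na(rates$dS) & rates$dS < max_ds
  out <- rates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group rank tests for rate contrasts
#'
#' Thin wrapper around [stats::wilcox.test()] reporting the conventions of
#' the rate contrasts: the Mann-Whitney U statistic is computed for the
#' first group (`U(a,b) + U(b,a) = |a||b|`), the Wilcoxon signed-rank V for
#' the paired differences `a - b`. Tests are two-sided; p-values are exact
#' for small untied samples and use the tie-corrected normal approximation
#' otherwise (base R behaviour).
#'
#' @param a,b numeric vectors; `wilcoxon_signed` requires equal lengths
#'   (paired).
#' @param test `"mann_whitney"` or `"wilcoxon_signed"`.
#' @return list with `statistic`, `p`, `method`, `n`.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "wilcoxon_signed")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (test == "wilcoxon_signed") {
    .ns_assert(length(a) == length(b),
               "wilcoxon_signed requires paired, equal-length inputs")
    ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = test, n = c(length(a), length(b)))
}

#' Spearman rank correlation of omega sets
#'
#' Rank correlation with average ranks on ties; exact p-value for n <= 9
#' without ties, t approximation otherwise (base R behaviour).
#'
#' @param x,y numeric vectors of per-gene omega (dN/dS) values.
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_omega <- function(x, y) {
  keep <- complete.cases(x, y)
  ht <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman"))
  list(rho = unname(ht$estimate), p = ht$p.value, n = sum(keep))
}

#' Kruskal-Wallis with Dunn post hoc tests and Benjamini-Hochberg control
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]) followed
#' by Dunn z tests for every group pair, with Benjamini-Hochberg adjustment
#' over all pairs.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return list with `H`, `p_global`, and `pairs` (data.frame: `group1`,
#'   `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn_bh <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  kw <- kruskal.test(values, factor(groups))
  N <- length(values)
  r <- rank(values)
  gm <- tapply(r, groups, mean)
  gn <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combos <- combn(names(gm), 2)
  z <- p <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / gn[[g1]] + 1 / gn[[g2]]))
    z[k] <- (gm[[g1]] - gm[[g2]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  list(H = unname(kw$statistic), p_global = kw$p.value,
       pairs = data.frame(group1 = combos[1, ], group2 = combos[2, ],
                          z = z, p = p, p_adj = p.adjust(p, "BH"),
                          stringsAsFactors = FALSE))
}

#' Summary contrast of a per-gene rate table between two groups
#'
#' Recomputes the headline contrast statistics from a per-gene table:
#' group medians and the two-group Mann-Whitney U (or paired Wilcoxon V)
#' with its p-value, for each requested value column.
#'
#' @param tab data.frame with a `group` column and numeric value columns.
#' @param value_cols names of the value columns to contrast.
#' @param groups length-2 character vector selecting and ordering the two
#'   groups (first group defines the U statistic).
#' @param paired use the signed-rank test (rows must be aligned pairs).
#' @return data.frame: one row per value column with `median_<g1>`,
#'   `median_<g2>`, `statistic`, `p`, `n1`, `n2`.
#' @export
contrast_table <- function(tab, value_cols, groups, paired = FALSE) {
  .ns_assert(length(groups) == 2, "exactly two groups required")
  out <- lapply(value_cols, function(v) {
    a <- tab[[v]][tab$group == groups[1]]
    b <- tab[[v]][tab$group == groups[2]]
    ct <- compare_groups(a, b,
                         if (paired) "wilcoxon_signed" else "mann_whitney")
    data.frame(value = v,
               median_1 = median(a, na.rm = TRUE),
               median_2 = median(b, na.rm = TRUE),
               statistic = ct$statistic, p = ct$p,
               n1 = ct$n[1], n2 = ct$n[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[2:3] <- paste0("median_", groups)
  out
}
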