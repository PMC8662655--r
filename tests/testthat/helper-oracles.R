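# Independent oracles used to freeze expected values. These deliberately
# avoid the package's lookup tables and code paths: the genetic code comes
# from Biostrings, pathway enumeration is a recursive DFS, and interval
# arithmetic is per-basepair.

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# fractional synonymous sites of one codon (stop targets excluded from the
# mutational opportunity)
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (oracle_translate(mut) == "*") next
      valid <- valid + 1
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# recursive DFS over single-step pathways between two codons; returns the
# per-path (syn, nonsyn) counts with stop-intermediate paths marked
oracle_paths <- function(from, to) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(diff_pos) == 0) return(list())
  acc <- list()
  recurse <- function(cur, remaining, syn, non, blocked) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- c(syn = syn, non = non, blocked = blocked)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      step_syn <- oracle_translate(nxt) == oracle_translate(cur)
      recurse(nxt, setdiff(remaining, pos),
              syn + step_syn, non + !step_syn,
              blocked || (oracle_translate(nxt) == "*" && nxt != to))
    }
  }
  recurse(from, diff_pos, 0, 0, FALSE)
  acc
}

# full NG86 oracle for two codon-vector sequences (no masking logic; inputs
# must be clean sense codons)
oracle_ng86 <- function(cod1, cod2) {
  S <- (sum(vapply(cod1, oracle_syn_sites, 1)) +
          sum(vapply(cod2, oracle_syn_sites, 1))) / 2
  N <- 3 * length(cod1) - S
  Sd <- Nd <- 0
  for (i in seq_along(cod1)) {
    paths <- oracle_paths(cod1[i], cod2[i])
    if (length(paths) == 0) next
    m <- do.call(rbind, paths)
    ok <- m[, "blocked"] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(m))
    Sd <- Sd + mean(m[ok, "syn"])
    Nd <- Nd + mean(m[ok, "non"])
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

sense_codons <- function() {
  all <- names(Biostrings::GENETIC_CODE)
  all[Biostrings::GENETIC_CODE != "*"]
}

random_codon_seq <- function(n_codons) {
  sample(sense_codons(), n_codons, replace = TRUE)
}

# per-basepair union size of intervals clipped to a window
oracle_union_bp <- function(starts, ends, ws, we) {
  covered <- logical(we - ws)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], ws); hi <- min(ends[i], we)
    if (hi > lo) covered[(lo - ws + 1):(hi - ws)] <- TRUE
  }
  sum(covered)
}

oracle_revcomp <- function(x) {
  out <- rev(x)
  chartr("ACGTN", "TGCAN", out)
}

# Mann-Whitney U of a over b by direct pair counting (ties count 1/2)
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Wilcoxon signed-rank V: sum of ranks of |d| for positive d (zeros dropped)
oracle_v <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  sum(rank(abs(d))[d > 0])
}
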