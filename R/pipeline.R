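## Stage orchestration behind the command-line entry point. Each stage is a
## thin file-in/file-out wrapper over the package functions; outputs are
## TSVs with header comments recording the thresholds used, so that a rerun
## with identical inputs and seed is byte-identical.

stage_header <- function(cfg, used) {
  c(paste0("neosex ", as.character(utils::packageVersion("neosex"))),
    paste0("seed=", cfg$seed %||% "NA"),
    vapply(used, function(k) paste0(k, "=", paste(cfg[[k]], collapse = ",")),
           ""))
}

#' Run one pipeline stage on files
#'
#' File-level entry point used by the `neosex` command-line script. Stages:
#' \describe{
#'   \item{simulate}{writes a full synthetic input set (profiles,
#'     gametolog FASTAs, species tree, genotype VCF, truth tables) under
#'     `args$out`.}
#'   \item{sexlink}{`args$profiles` (TSV) to scaffold calls TSV.}
#'   \item{phase}{`args$vcf` + `args$sexes` (TSV) to a phased-site TSV.}
#'   \item{timing}{directory of alignment FASTAs to a suppression-timing
#'     TSV (trim, length filter, NJ bootstrap, added-region inference).}
#'   \item{rates}{directory of gametolog FASTAs to a Z/W rate TSV.}
#'   \item{diversity}{`args$vcf` + `args$sexes` (+ optional `args$repeats`
#'     BED, `args$mask` BED) to a windowed-diversity TSV.}
#' }
#'
#' @param stage stage name.
#' @param cfg a [pipeline_config()].
#' @param args named list of stage arguments (file paths; `out` required).
#' @return the stage's primary result, invisibly.
#' @export
run_stage <- function(stage, cfg = pipeline_config(), args = list()) {
  stages <- c("simulate", "sexlink", "phase", "timing", "rates", "diversity")
  if (!stage %in% stages)
    .ns_stop("unknown stage '", stage, "'; expected one of: ",
             paste(stages, collapse = ", "))
  .ns_assert(!is.null(args$out), "args$out is required")
  switch(stage,
         simulate = stage_simulate(cfg, args),
         sexlink = stage_sexlink(cfg, args),
         phase = stage_phase(cfg, args),
         timing = stage_timing(cfg, args),
         rates = stage_rates(cfg, args),
         diversity = stage_diversity(cfg, args))
}

stage_simulate <- function(cfg, args) {
  dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
  scfg <- sim_config(seed = cfg$seed %||% 1L,
                     n_genes = args$n_genes %||% 5)
  prof <- simulate_profiles(scfg, n_per_class = args$n_per_class %||% 5)
  write_calls(prof$profiles, file.path(args$out, "profiles.tsv"),
              stage_header(cfg, character(0)))
  write_calls(prof$truth, file.path(args$out, "profiles_truth.tsv"))
  gam <- simulate_gametologs(scfg, branches = args$branches %||% "b3")
  dir.create(file.path(args$out, "alignments"), showWarnings = FALSE)
  for (g in names(gam$alignments))
    write_alignment(gam$alignments[[g]],
                    file.path(args$out, "alignments", paste0(g, ".fasta")))
  write_calls(gam$truth, file.path(args$out, "gametolog_truth.tsv"))
  gen <- simulate_genotypes(scfg)
  write_vcf(gen$vt, file.path(args$out, "genotypes.vcf"))
  write_calls(gen$vt$samples, file.path(args$out, "sexes.tsv"))
  write_calls(gen$truth, file.path(args$out, "phase_truth.tsv"))
  message("simulate: wrote synthetic inputs to ", args$out)
  invisible(args$out)
}

stage_sexlink <- function(cfg, args) {
  prof <- read_profiles(args$profiles)
  calls <- classify_scaffolds(prof, cfg)
  for (cl in c("W", "Z", "AUTOSOME", "UNASSIGNED"))
    message("sexlink: ", sum(calls$class == cl), " scaffold(s) ", cl)
  write_calls(calls, args$out,
              stage_header(cfg, c("w_fem_min", "z_ratio_1", "z_ratio_2",
                                  "het_diff_min")))
  invisible(calls)
}

stage_phase <- function(cfg, args) {
  sexes <- read_profiles(args$sexes)
  vt <- read_vcf(args$vcf, sexes)
  phased <- phase_sites(vt, cfg)
  n_masked <- sum(phased$z == "N")
  message("phase: ", nrow(phased), " site(s), ", n_masked, " masked")
  write_calls(phased, args$out,
              stage_header(cfg, c("phase_min_q", "phase_min_depth")))
  invisible(phased)
}

stage_timing <- function(cfg, args) {
  dated <- args$tree %||% dated_species_tree()
  files <- list.files(args$alignments, pattern = "\\.fa(sta)?$",
                      full.names = TRUE)
  .ns_assert(length(files) > 0, "no FASTA alignments found")
  alns <- lapply(files, read_alignment)
  names(alns) <- sub("\\.fa(sta)?$", "", basename(files))
  alns <- lapply(alns, trim_alignment)
  alns <- filter_alignments_for_timing(alns, cfg$min_aln)
  message("timing: ", length(alns), " alignment(s) pass the ",
          cfg$min_aln, " bp filter")
  calls <- lapply(names(alns), function(g) {
    tr <- build_tree_nj(alns[[g]], n_bootstrap = cfg$nj_bootstrap,
                        seed = cfg$seed %||% 1L, cfg = cfg)
    infer_suppression_added(tr, dated, tau = cfg$tau, gene_id = g)
  })
  tab <- suppression_table(calls)
  write_calls(tab, args$out, stage_header(cfg, c("tau", "min_aln",
                                                 "nj_bootstrap")))
  invisible(tab)
}

stage_rates <- function(cfg, args) {
  files <- list.files(args$alignments, pattern = "\\.fa(sta)?$",
                      full.names = TRUE)
  .ns_assert(length(files) > 0, "no FASTA alignments found")
  rows <- lapply(files, function(f) {
    aln <- trim_alignment(read_alignment(f))
    gene <- sub("\\.fa(sta)?$", "", basename(f))
    pairs <- grep("\\|(Z|W)$", rownames(aln), value = TRUE)
    zs <- grep("\\|Z$", pairs, value = TRUE)
    ws <- grep("\\|W$", pairs, value = TRUE)
    if (!length(zs) || !length(ws)) return(NULL)
    ## simulated/unverified CDS input: codon pairs hitting stops are dropped
    ng86_rates(aln[zs[1], ], aln[ws[1], ], gene_id = gene, pair = "Z-W",
               cfg = cfg, on_stop = "drop")
  })
  rates <- do.call(rbind, rows)
  filtered <- filter_rates(rates, cfg$rates_min_len, cfg$rates_max_ds)
  message("rates: ", nrow(filtered), "/", nrow(rates),
          " gene(s) pass the length/dS filters")
  write_calls(filtered, args$out,
              stage_header(cfg, c("rates_min_len", "rates_max_ds")))
  invisible(filtered)
}

stage_diversity <- function(cfg, args) {
  sexes <- read_profiles(args$sexes)
  vt <- read_vcf(args$vcf, sexes)
  repeats <- if (!is.null(args$repeats)) read_bed(args$repeats) else NULL
  context <- args$context %||% "autosomal"
  fv <- filter_variants(vt, repeats, cfg, context = context)
  log <- attr(fv, "droplog")
  for (i in seq_len(nrow(log)))
    message("diversity: ", log$n_dropped[i], " site(s) dropped by ",
            log$filter[i])
  mask <- if (!is.null(args$mask)) {
    m <- read_bed(args$mask)
    class(m) <- c("callable_mask", "data.frame")
    m
  } else {
    ## no depth data: assume the full span of each scaffold is callable
    do.call(rbind, lapply(unique(fv$sites$scaffold), function(sc) {
      data.frame(scaffold = sc, start = 0L,
                 end = as.integer(ceiling(max(fv$sites$pos[
                   fv$sites$scaffold == sc]) / cfg$window) * cfg$window),
                 stringsAsFactors = FALSE)
    }))
  }
  win <- pi_windows(fv, mask, window = cfg$window)
  if (!is.null(repeats)) win <- repeat_fraction(win, repeats)
  write_calls(win, args$out,
              stage_header(cfg, c("pop_q", "dp_diploid", "dp_hap_female",
                                  "call_rate", "cov_cap_mult", "window")))
  invisible(win)
}
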