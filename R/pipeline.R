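#' Write a complete synthetic study to a directory
#'
#' Generates one seeded synthetic dataset exercising every pipeline stage
#' and writes it as plain-text interchange files: a bacterial contig with
#' an embedded prophage (FASTA + GFF3 ORFs), a VLP depth profile over the
#' contig, a phage genome carrying a planted DGR (FASTA), a cognate-genome
#' alignment (aligned FASTA), a pileup table, CRISPR spacers (FASTA), a
#' split-read junction table, an ANI table, and `truth.json` recording all
#' planted coordinates and parameters.
#'
#' @param seed integer RNG seed; stage seeds are derived deterministically.
#' @param dir output directory (created if needed).
#' @param host_len,prophage_len contig geometry (defaults 120 kb / 40 kb).
#' @param coverage_ratio planted induction coverage ratio (default 50).
#' @param n_cognates,vr_adenine_rate,background_rate cognate-set
#'   parameters (defaults 30 / 0.3 / 0.002).
#' @param minor_fraction pileup minor-allele fraction at VR adenine
#'   targets (default 0.3).
#' @return Invisibly, a list of file paths plus the assembled truth.
#' @export
simulate_study <- function(seed, dir, host_len = 120000L,
                           prophage_len = 40000L, coverage_ratio = 50,
                           n_cognates = 30L, vr_adenine_rate = 0.3,
                           background_rate = 0.002, minor_fraction = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  p <- function(...) file.path(dir, paste0(...))

  host <- simulate_host_with_prophage(seed, host_len = host_len,
                                      prophage_len = prophage_len)
  depth <- simulate_depth_profile(seed + 1L, host_len,
                                  prophage = host$truth$prophage,
                                  base_depth = 5, ratio = coverage_ratio)

  ## phage genome: the prophage region excised, with a DGR planted
  phage_seq <- setNames(substr(host$genome, host$truth$prophage$start,
                               host$truth$prophage$end), "sim_phage")
  dgr <- plant_dgr(seed + 2L, phage_seq, tr_len = 120L, n_vr = 1L,
                   adenine_sub_count = 12L)
  cog <- simulate_cognate_set(seed + 3L, dgr$genome, dgr$truth,
                              n = n_cognates,
                              vr_adenine_rate = vr_adenine_rate,
                              background_rate = background_rate)
  pile <- simulate_pileup(seed + 4L, dgr$genome, depth = 100,
                          vr_positions = cog$truth$vr_a_positions,
                          minor_fraction = minor_fraction)
  spac <- simulate_spacers(seed + 5L, dgr$genome, n = 5L)
  junc <- simulate_junctions(seed + 6L,
                             borders = c(host$truth$prophage$start,
                                         host$truth$prophage$end),
                             n = 2000L, noise_fraction = 0.1,
                             contig_len = host_len)

  write_genome_fasta(host$genome, p("contig.fasta"))
  write_orfs_gff3(host$orfs, p("orfs.gff3"))
  write_depth_tsv(setNames(list(depth$depth), names(host$genome)),
                  p("depth.tsv"))
  write_genome_fasta(dgr$genome, p("phage.fasta"))
  write_genome_fasta(cog$msa, p("cognates_aln.fasta"))
  write_pileup_tsv(pile$pileup, p("pileup.tsv"), names(dgr$genome))
  write_genome_fasta(spac$spacers, p("spacers.fasta"))
  utils::write.table(
    data.frame(contig = names(host$genome),
               position = junc$junctions$position,
               count = junc$junctions$count),
    p("junctions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(id_a = "sim_phage", id_b = "sim_phage_cognate",
               ani = 99.0, tcov = 96.0),
    p("ani.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(seed = seed, host = host$truth, depth = depth$truth,
                dgr = dgr$truth, cognates = cog$truth,
                pileup = pile$truth, spacers = spac$truth,
                junctions = junc$truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(dir = dir, truth = truth))
}

#' Run the full analysis pipeline on a directory of inputs
#'
#' Executes the stages in study order on the files written by
#' [simulate_study()] (or real data in the same layout): prophage scan of
#' the bacterial contig, DGR repeat detection on the phage genome, DGR
#' activity from the cognate alignment and the pileup, and host linking
#' via spacer matches plus species clustering. Writes per-stage TSVs and a
#' consolidated `report.json` under the output prefix.
#'
#' @param dir input directory (see [simulate_study()] for the layout).
#' @param out_prefix path prefix for outputs (directory part is created).
#' @param thr thresholds from [dgr_thresholds()].
#' @param region_cutoff,min_region_len candidate-region caller settings.
#' @return The consolidated report, invisibly.
#' @export
run_pipeline <- function(dir, out_prefix, thr = dgr_thresholds(),
                         region_cutoff = 3.0, min_region_len = 15000L) {
  if (!dir.exists(dir)) stop("input directory not found: ", dir)
  need <- c("contig.fasta", "orfs.gff3", "depth.tsv", "phage.fasta",
            "cognates_aln.fasta", "pileup.tsv", "spacers.fasta",
            "junctions.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing input file(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
  }
  out_dir <- dirname(out_prefix)
  if (nzchar(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  op <- function(...) paste0(out_prefix, ...)

  ## --- prophage scan -------------------------------------------------
  contig <- read_genome_fasta(file.path(dir, "contig.fasta"))
  contig_id <- names(contig)[1L]
  contig_len <- nchar(contig[[1L]])
  orfs <- read_orfs_gff3(file.path(dir, "orfs.gff3"))
  depths <- read_depth_tsv(file.path(dir, "depth.tsv"),
                           setNames(contig_len, contig_id))
  spec <- bacterial_window_spec()
  nt <- nucleotide_content_track(contig[1L], spec)
  og <- orf_organization_track(orfs, contig_len, spec)
  db <- depth_breadth_tracks(depths[[contig_id]], spec)
  tracks <- data.frame(start = nt$start, end = nt$end,
                       gc = nt$G + nt$C,
                       median_orf_len = og$median_orf_len,
                       strand_switches = og$strand_switches,
                       mean_depth = db$mean_depth, breadth = db$breadth)
  regions <- call_candidate_regions(
    tracks,
    directions = c(gc = -1, median_orf_len = -1, strand_switches = -1,
                   mean_depth = 1, breadth = 1),
    cutoff = region_cutoff, min_region_len = min_region_len)
  write_track_tsv(tracks, op("tracks.tsv"), contig_id)
  write_track_tsv(regions, op("regions.tsv"), contig_id)
  write_regions_bed(regions, op("regions.bed"), contig_id)

  ratios <- lapply(seq_len(nrow(regions)), function(i) {
    coverage_ratio(depths[[contig_id]], regions[i, ])
  })
  junc <- read_junction_table(file.path(dir, "junctions.tsv"))
  termini <- call_transposable_termini(junc)

  ## --- DGR detection -------------------------------------------------
  phage <- read_genome_fasta(file.path(dir, "phage.fasta"))
  alns <- find_repeat_alignments(phage[1L], thr)
  pairs <- Filter(function(x) inherits(x, "repeat_pair"),
                  lapply(alns, classify_dgr_pair, thr = thr))
  phage_len <- nchar(phage[[1L]])
  loci <- suppressWarnings(assemble_loci(pairs, rt_orfs = NULL, orfs = NULL,
                                         genome_len = phage_len))

  ## --- DGR activity --------------------------------------------------
  msa <- read_msa_fasta(file.path(dir, "cognates_aln.fasta"))
  stats <- msa_column_stats(msa, names(phage)[1L], thr)
  vtrack <- variation_track(stats)
  atrack <- adenine_conservation_track(stats)
  pile <- read_pileup_tsv(file.path(dir, "pileup.tsv"), phage_len)
  incl <- sample_inclusion(pile, thr)
  ptrack <- variation_track(pileup_variation(pile))
  vr_ivs <- if (length(loci)) loci[[1L]]$vrs else list()
  activity <- if (length(vr_ivs)) {
    list(msa = vr_activity_call(vtrack, vr_ivs),
         pileup = if (incl$include) vr_activity_call(ptrack, vr_ivs))
  }
  write_track_tsv(vtrack, op("msa_variation.tsv"), names(phage)[1L])
  write_track_tsv(atrack, op("adenine_conservation.tsv"), names(phage)[1L])
  write_track_tsv(ptrack, op("pileup_variation.tsv"), names(phage)[1L])

  ## --- host linking --------------------------------------------------
  spacers <- read_genome_fasta(file.path(dir, "spacers.fasta"))
  sp_matches <- match_spacers(spacers, phage[1L], thr)

  report <- list(
    contig = list(id = contig_id, length = contig_len),
    candidate_regions = regions,
    coverage_ratios = lapply(ratios, function(r) r[c("ratio", "infinite")]),
    termini = termini,
    dgr_loci = lapply(loci, function(l) list(
      tr = l$tr, vrs = l$vrs, n_vr = length(l$vrs))),
    pileup_sample_included = incl,
    vr_activity = activity,
    spacer_matches = sp_matches,
    n_spacer_links = nrow(sp_matches))
  jsonlite::write_json(report, op("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
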