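## Seeded synthetic-data generators. Every generator takes an explicit seed,
## restores the caller's RNG state on exit, and returns the full ground
## truth alongside the data so recovery can be asserted in tests.

with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a bacterial contig with an embedded prophage
#'
#' Generates an i.i.d. nucleotide sequence in which a prophage region of
#' distinct GC content is embedded, plus non-overlapping ORFs drawn from
#' contrasting regimes: host genes are longer with longer intergenic gaps
#' and switch coding strand often, prophage genes are shorter, tightly
#' packed, and rarely switch strand. These are the qualitative contrasts
#' the prophage evidence tracks are designed to expose.
#'
#' Distribution defaults (nt): host gene length ~ Normal(900, 300)
#' truncated at 150, prophage ~ Normal(450, 150) truncated at 150; host
#' intergenic gap ~ Exponential(mean 120), prophage ~ Exponential(mean 40);
#' strand-switch probability between consecutive genes 0.35 (host) and 0.08
#' (prophage). Gene lengths are rounded to codon multiples.
#'
#' @param seed integer RNG seed.
#' @param host_len,prophage_len contig and prophage lengths in nt
#'   (`prophage_len < host_len`).
#' @param host_gc,prophage_gc GC fractions of the two regimes.
#' @param prophage_start prophage start position; `NULL` places it at a
#'   random feasible position.
#' @param gene_len_mean,gene_len_sd,gap_mean,switch_prob length-2 numeric
#'   vectors `(host, prophage)` overriding the regime defaults.
#' @param contig_id contig identifier.
#' @return A list with `genome` (named character), `orfs` (data.frame with
#'   `contig_id`, `start`, `end`, `strand`), and `truth` (seed, prophage
#'   interval, regime parameters).
#' @export
simulate_host_with_prophage <- function(seed, host_len = 120000L,
                                        prophage_len = 40000L,
                                        host_gc = 0.56, prophage_gc = 0.46,
                                        prophage_start = NULL,
                                        gene_len_mean = c(900, 450),
                                        gene_len_sd = c(300, 150),
                                        gap_mean = c(120, 40),
                                        switch_prob = c(0.35, 0.08),
                                        contig_id = "sim_contig") {
  host_len <- as.integer(host_len); prophage_len <- as.integer(prophage_len)
  if (prophage_len >= host_len) stop("prophage_len must be < host_len")
  with_seed(seed, {
    if (is.null(prophage_start)) {
      lo <- max(1L, round(0.15 * host_len))
      hi <- host_len - prophage_len - max(1L, round(0.15 * host_len))
      if (hi < lo) stop("prophage does not fit with flanking host sequence")
      prophage_start <- sample(lo:hi, 1L)
    }
    prophage_start <- as.integer(prophage_start)
    prophage_end <- prophage_start + prophage_len - 1L
    if (prophage_end >= host_len) stop("prophage extends past the contig")

    seqs <- c(random_seq(prophage_start - 1L, host_gc),
              random_seq(prophage_len, prophage_gc),
              random_seq(host_len - prophage_end, host_gc))
    genome <- setNames(paste(seqs, collapse = ""), contig_id)

    gen_orfs <- function(lo, hi, regime) {
      mu <- gene_len_mean[regime]; sdv <- gene_len_sd[regime]
      gmu <- gap_mean[regime]; sw <- switch_prob[regime]
      starts <- ends <- integer(0); strands <- character(0)
      strand <- sample(c("+", "-"), 1L)
      pos <- lo + round(rexp(1L, 1 / gmu))
      repeat {
        len <- round(max(150, rnorm(1L, mu, sdv)))
        len <- 3L * ceiling(len / 3)
        if (pos + len - 1L > hi) break
        starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
        strands <- c(strands, strand)
        if (runif(1L) < sw) strand <- if (strand == "+") "-" else "+"
        pos <- pos + len + round(rexp(1L, 1 / gmu)) + 1L
      }
      data.frame(contig_id = contig_id, start = starts, end = ends,
                 strand = strands)
    }
    orfs <- rbind(
      if (prophage_start > 300L) gen_orfs(1L, prophage_start - 1L, 1L),
      gen_orfs(prophage_start, prophage_end, 2L),
      if (host_len - prophage_end > 300L) {
        gen_orfs(prophage_end + 1L, host_len, 1L)
      })
    list(genome = genome, orfs = orfs,
         truth = list(seed = seed, contig_id = contig_id,
                      prophage = interval(contig_id, prophage_start,
                                          prophage_end),
                      host_gc = host_gc, prophage_gc = prophage_gc,
                      gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
                      gap_mean = gap_mean, switch_prob = switch_prob))
  })
}

#' Plant a DGR (template repeat, variable repeats, RT gene) in a genome
#'
#' Copies a template repeat (TR) taken from the genome itself to one or
#' more variable-repeat (VR) sites, substituting a requested number of
#' positions in each VR -- only at positions where the TR holds adenine, to
#' C, G or T uniformly. This is the mutational signature of DGR
#' retrohoming. Optionally records an RT gene placeholder ORF next to the
#' TR. The TR site is chosen among windows holding at least the requested
#' number of adenines.
#'
#' @param seed integer RNG seed.
#' @param genome nucleotide sequence (named character or `DNAStringSet`).
#' @param tr_len TR length in nt (at least 90).
#' @param n_vr number of VR copies to plant.
#' @param adenine_sub_count substitutions per VR, all at TR adenine
#'   positions.
#' @param rt_orf record an RT ORF placeholder downstream of the TR.
#' @param min_separation minimum distance between planted elements (nt).
#' @return A list with `genome` (modified, named character) and `truth`:
#'   `tr` interval, list of `vrs` intervals, per-VR substitution positions
#'   (genome coordinates and TR-relative offsets), `tr_a_offsets`, and
#'   `rt_orf` (or NULL).
#' @export
plant_dgr <- function(seed, genome, tr_len = 120L, n_vr = 1L,
                      adenine_sub_count = 10L, rt_orf = TRUE,
                      min_separation = 400L) {
  seq <- as_genome_seq(genome)
  id <- names(seq)
  glen <- nchar(seq)
  tr_len <- as.integer(tr_len)
  if (tr_len < 90L) stop("tr_len must be at least 90")
  m <- as.integer(adenine_sub_count)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    ## choose a TR window with enough adenines
    is_a <- chars == "A"
    csum <- c(0L, cumsum(is_a))
    cand_starts <- seq_len(glen - tr_len + 1L)
    a_counts <- csum[cand_starts + tr_len] - csum[cand_starts]
    ok <- cand_starts[a_counts >= max(m, 1L)]
    if (!length(ok)) {
      stop("no TR window with at least ", m, " adenines")
    }
    tr_start <- sample(ok, 1L)
    tr_end <- tr_start + tr_len - 1L
    tr_seq <- chars[tr_start:tr_end]
    tr_a_offsets <- which(tr_seq == "A")

    ## place VRs away from the TR and one another
    occupied <- matrix(c(tr_start, tr_end), ncol = 2L)
    too_close <- function(s, e) {
      any(occupied[, 1L] - min_separation <= e &
            occupied[, 2L] + min_separation >= s)
    }
    vrs <- list(); subs <- list()
    for (v in seq_len(n_vr)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        vs <- sample.int(glen - tr_len + 1L, 1L)
        ve <- vs + tr_len - 1L
        if (too_close(vs, ve)) next
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place VR ", v, " after 1000 attempts")
      occupied <- rbind(occupied, c(vs, ve))
      vr_seq <- tr_seq
      off <- if (m > 0L) sort(sample(tr_a_offsets, m)) else integer(0)
      for (p in off) {
        vr_seq[p] <- sample(c("C", "G", "T"), 1L)
      }
      chars[vs:ve] <- vr_seq
      vrs[[v]] <- interval(id, vs, ve)
      subs[[v]] <- list(genome_pos = vs - 1L + off, tr_offsets = off)
    }

    rt <- NULL
    if (isTRUE(rt_orf)) {
      rt_len <- 900L
      rs <- min(glen - rt_len + 1L, tr_end + 51L)
      rt <- data.frame(contig_id = id, start = rs, end = rs + rt_len - 1L,
                       strand = "+")
    }
    list(genome = setNames(paste(chars, collapse = ""), id),
         truth = list(seed = seed, tr = interval(id, tr_start, tr_end),
                      vrs = vrs, substitutions = subs,
                      tr_a_offsets = tr_a_offsets,
                      adenine_sub_count = m, rt_orf = rt))
  })
}

#' Simulate a substitution-only cognate genome set
#'
#' Emits `n` copies of a genome carrying a planted DGR: background
#' substitutions fall i.i.d. genome-wide at `background_rate`, and at VR
#' positions corresponding to TR adenines each genome is independently
#' substituted at `vr_adenine_rate` (to C/G/T uniformly). Because only
#' substitutions are introduced, the identity alignment is the true MSA and
#' no aligner is needed. The unmutated genome itself is included as the
#' reference row.
#'
#' @param seed integer RNG seed.
#' @param genome genome carrying the DGR (named character).
#' @param dgr_truth the `truth` element returned by [plant_dgr()].
#' @param n number of cognate genomes (at least 2).
#' @param vr_adenine_rate per-position substitution probability at VR
#'   adenine-target positions.
#' @param background_rate genome-wide background substitution probability.
#' @param reference_id name for the reference row (default the genome name).
#' @return A list with `msa` (named character vector, reference first) and
#'   `truth` (parameters plus the VR adenine-target genome positions).
#' @export
simulate_cognate_set <- function(seed, genome, dgr_truth, n = 30L,
                                 vr_adenine_rate = 0.3,
                                 background_rate = 0.002,
                                 reference_id = NULL) {
  seq <- as_genome_seq(genome)
  if (n < 2L) stop("n must be at least 2")
  if (vr_adenine_rate < 0 || vr_adenine_rate > 1 ||
      background_rate < 0 || background_rate > 1) {
    stop("substitution rates must lie in [0, 1]")
  }
  if (is.null(reference_id)) reference_id <- names(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  glen <- length(chars)
  vr_a_pos <- unlist(lapply(dgr_truth$vrs, function(vr) {
    vr$start - 1L + dgr_truth$tr_a_offsets
  }))
  vr_a_pos <- vr_a_pos[vr_a_pos >= 1L & vr_a_pos <= glen]
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rows <- vector("list", n)
    for (g in seq_len(n)) {
      gc <- chars
      nb <- rbinom(1L, glen, background_rate)
      if (nb > 0L) {
        pos <- sample.int(glen, nb)
        for (p in pos) gc[p] <- sample(setdiff(bases, gc[p]), 1L)
      }
      hit <- vr_a_pos[runif(length(vr_a_pos)) < vr_adenine_rate]
      for (p in hit) gc[p] <- sample(c("C", "G", "T"), 1L)
      rows[[g]] <- paste(gc, collapse = "")
    }
    msa <- c(setNames(seq, reference_id),
             setNames(unlist(rows), paste0("cognate_", seq_len(n))))
    list(msa = msa,
         truth = list(seed = seed, n = n, vr_adenine_rate = vr_adenine_rate,
                      background_rate = background_rate,
                      vr_a_positions = sort(vr_a_pos),
                      vrs = dgr_truth$vrs))
  })
}

#' Simulate a per-position depth profile with an induced prophage
#'
#' Depth is Poisson with mean `base_depth` outside the prophage region and
#' `base_depth * ratio` inside, emulating the sharp rise of VLP read
#' coverage over an actively replicating prophage.
#'
#' @param seed integer RNG seed.
#' @param contig_len contig length in nt.
#' @param prophage interval with `start`/`end`, or NULL for a flat profile.
#' @param base_depth mean depth outside the prophage.
#' @param ratio inside/outside depth ratio.
#' @return A list with `depth` (integer vector) and `truth`.
#' @export
simulate_depth_profile <- function(seed, contig_len, prophage = NULL,
                                   base_depth = 5, ratio = 1) {
  contig_len <- as.integer(contig_len)
  with_seed(seed, {
    depth <- rpois(contig_len, base_depth)
    if (!is.null(prophage)) {
      s <- as.integer(prophage$start); e <- as.integer(prophage$end)
      depth[s:e] <- rpois(e - s + 1L, base_depth * ratio)
    }
    list(depth = depth,
         truth = list(seed = seed, contig_len = contig_len,
                      prophage = prophage, base_depth = base_depth,
                      ratio = ratio))
  })
}

#' Simulate a read pileup over a genome
#'
#' Base counts per position follow the reference base at the local depth,
#' with a uniform per-base sequencing error (default 0.2 percent spread
#' over the three non-reference bases). At VR adenine-target positions a
#' single planted alternative base additionally appears at
#' `minor_fraction`, emulating a population in which a fraction of genomes
#' carries a DGR-substituted variable repeat.
#'
#' @param seed integer RNG seed.
#' @param genome genome sequence (named character).
#' @param depth per-position depth vector, or a single mean depth (Poisson
#'   sampled per position).
#' @param vr_positions genome positions eligible for the planted minor
#'   allele (typically `truth$vr_a_positions` from the cognate simulator or
#'   VR adenine targets from [plant_dgr()]).
#' @param minor_fraction expected minor-allele fraction at `vr_positions`.
#' @param error_rate per-base error rate (default 0.002).
#' @return A list with `pileup` (data.frame `position`, `A`, `C`, `G`, `T`)
#'   and `truth` (including the planted alternative base per VR position).
#' @export
simulate_pileup <- function(seed, genome, depth = 100, vr_positions = integer(0),
                            minor_fraction = 0, error_rate = 0.002) {
  seq <- as_genome_seq(genome)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  glen <- length(chars)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    d <- if (length(depth) == 1L) rpois(glen, depth) else as.integer(depth)
    if (length(d) != glen) stop("depth length must match the genome")
    counts <- matrix(0L, nrow = glen, ncol = 4L,
                     dimnames = list(NULL, bases))
    ref_idx <- match(chars, bases)
    ## sequencing errors: binomial per position, split uniformly
    n_err <- rbinom(glen, d, error_rate)
    alt <- setNames(rep(NA_character_, length(vr_positions)),
                    as.character(vr_positions))
    n_minor <- rep(0L, glen)
    if (length(vr_positions) && minor_fraction > 0) {
      for (i in seq_along(vr_positions)) {
        p <- vr_positions[i]
        a <- sample(bases[-ref_idx[p]], 1L)
        alt[i] <- a
        k <- rbinom(1L, max(d[p] - n_err[p], 0L), minor_fraction)
        n_minor[p] <- k
        counts[p, a] <- counts[p, a] + k
      }
    }
    for (p in which(n_err > 0L)) {
      errs <- sample(bases[-ref_idx[p]], n_err[p], replace = TRUE)
      for (a in errs) counts[p, a] <- counts[p, a] + 1L
    }
    ref_n <- pmax(d - n_err - n_minor, 0L)
    ok <- !is.na(ref_idx)
    counts[cbind(which(ok), ref_idx[ok])] <-
      counts[cbind(which(ok), ref_idx[ok])] + ref_n[ok]
    list(pileup = data.frame(position = seq_len(glen),
                             A = counts[, "A"], C = counts[, "C"],
                             G = counts[, "G"], T = counts[, "T"]),
         truth = list(seed = seed, minor_fraction = minor_fraction,
                      error_rate = error_rate, vr_positions = vr_positions,
                      alt_bases = alt))
  })
}

#' Simulate CRISPR spacers excised from a genome
#'
#' Cuts `n` spacers from recorded positions and strands, introducing
#' exactly `mismatches` substitutions into each spacer sequence.
#'
#' @param seed integer RNG seed.
#' @param genome source genome (named character).
#' @param n number of spacers.
#' @param spacer_len spacer length in nt.
#' @param mismatches exact substitution count per spacer.
#' @return A list with `spacers` (named character vector) and `truth`
#'   (data.frame of planted `position` and `strand` per spacer).
#' @export
simulate_spacers <- function(seed, genome, n = 10L, spacer_len = 34L,
                             mismatches = 0L) {
  seq <- as_genome_seq(genome)
  glen <- nchar(seq)
  spacer_len <- as.integer(spacer_len)
  with_seed(seed, {
    pos <- sample.int(glen - spacer_len + 1L, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    sp <- character(n)
    for (i in seq_len(n)) {
      s <- substr(seq, pos[i], pos[i] + spacer_len - 1L)
      if (strand[i] == "-") s <- revcomp_chr(s)
      if (mismatches > 0L) {
        chars <- strsplit(s, "", fixed = TRUE)[[1L]]
        at <- sample.int(spacer_len, mismatches)
        for (p in at) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        }
        s <- paste(chars, collapse = "")
      }
      sp[i] <- s
    }
    names(sp) <- sprintf("spacer_%02d", seq_len(n))
    list(spacers = sp,
         truth = data.frame(spacer_id = names(sp), position = pos,
                            strand = strand, mismatches = mismatches))
  })
}

#' Simulate split-read junction positions
#'
#' Draws `n` junction positions: with probability `1 - noise_fraction` a
#' planted border (left or right with equal probability), else a uniform
#' position along the contig -- the background of spurious split
#' alignments.
#'
#' @param seed integer RNG seed.
#' @param borders length-2 integer vector of the planted termini.
#' @param n number of junction records.
#' @param noise_fraction fraction of uniformly placed noise junctions.
#' @param contig_len contig length for the noise distribution.
#' @return A list with `junctions` (data.frame `position`, `count`,
#'   aggregated) and `truth`.
#' @export
simulate_junctions <- function(seed, borders, n = 2000L, noise_fraction = 0.1,
                               contig_len = 100000L) {
  borders <- sort(as.integer(borders))
  if (length(borders) != 2L) stop("borders must have length 2")
  with_seed(seed, {
    is_noise <- runif(n) < noise_fraction
    pos <- integer(n)
    pos[!is_noise] <- sample(borders, sum(!is_noise), replace = TRUE)
    pos[is_noise] <- sample.int(contig_len, sum(is_noise), replace = TRUE)
    tab <- table(pos)
    list(junctions = data.frame(position = as.integer(names(tab)),
                                count = as.integer(tab)),
         truth = list(seed = seed, borders = borders, n = n,
                      noise_fraction = noise_fraction,
                      contig_len = contig_len))
  })
}
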