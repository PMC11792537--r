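## Readers and writers for the plain-text interchange formats. Coordinates
## are 1-based inclusive everywhere except BED output, which follows the
## BED standard (0-based half-open); the conversion lives only in
## write_regions_bed / regions_to_bed.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors, the sequence representation used across this package.
#' `read_msa_fasta` keeps gap characters (aligned FASTA).
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param width line-wrap width for output.
#' @return `read_genome_fasta` and `read_msa_fasta` return a named
#'   character vector; `write_genome_fasta` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_genome_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read ORFs from a GFF3 file
#'
#' Parses a GFF3 annotation and returns the ORF table used by the track and
#' locus functions. Lines are pre-validated so coordinate errors are
#' reported with their file and line number.
#'
#' @param path GFF3 file path.
#' @param feature_types feature types retained (default CDS and gene-like
#'   records); NULL keeps everything.
#' @return data.frame with `contig_id`, `start`, `end`, `strand`.
#' @export
read_orfs_gff3 <- function(path, feature_types = c("CDS", "gene", "ORF")) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      stop(path, " line ", i, ": fewer than 8 GFF3 fields")
    }
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e) || s > e || s < 1L) {
      stop(path, " line ", i, ": invalid coordinates '", f[4L], "'-'",
           f[5L], "'")
    }
  }
  g <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types)) {
    keep <- as.character(g$type) %in% feature_types
    if (any(keep)) g <- g[keep]
  }
  data.frame(contig_id = as.character(GenomeInfoDb::seqnames(g)),
             start = BiocGenerics::start(g), end = BiocGenerics::end(g),
             strand = ifelse(as.character(BiocGenerics::strand(g)) == "-",
                             "-", "+"))
}

#' Write ORFs as GFF3
#'
#' @param orfs data.frame with `contig_id`, `start`, `end`, `strand`.
#' @param path output path.
#' @param source,type GFF3 source and type fields.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path, source = "dgrscan", type = "CDS") {
  orfs <- as.data.frame(orfs)
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\tID=orf%04d",
                     orfs$contig_id, source, type,
                     as.integer(orfs$start), as.integer(orfs$end),
                     orfs$strand, seq_len(nrow(orfs))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns (contig, 1-based position, depth), as
#' produced by standard depth utilities. Positions absent from the file are
#' depth 0; the full profile length comes from `contig_lengths`.
#'
#' @param path file path.
#' @param contig_lengths named integer vector of contig lengths.
#' @return Named list of per-contig integer depth vectors.
#' @export
read_depth_tsv <- function(path, contig_lengths) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "position", "depth"),
                          colClasses = c("character", "integer", "integer"))
  out <- lapply(contig_lengths, function(n) integer(n))
  for (id in unique(tb$contig)) {
    if (!(id %in% names(out))) {
      stop(path, ": depth rows for unknown contig '", id, "'")
    }
    rows <- tb[tb$contig == id, ]
    if (any(rows$position < 1L) || any(rows$position > length(out[[id]]))) {
      stop(path, ": position outside contig '", id, "'")
    }
    out[[id]][rows$position] <- rows$depth
  }
  out
}

#' @rdname read_depth_tsv
#' @param depths named list of per-contig depth vectors.
#' @export
write_depth_tsv <- function(depths, path) {
  rows <- lapply(names(depths), function(id) {
    d <- depths[[id]]
    nz <- which(d > 0)
    if (!length(nz)) return(NULL)
    data.frame(contig = id, position = nz, depth = d[nz])
  })
  tb <- do.call(rbind, rows)
  if (is.null(tb)) tb <- data.frame(contig = character(), position = integer(),
                                    depth = integer())
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write per-position pileup nucleotide-count tables
#'
#' Tab-separated with header: genome, 1-based position, A, C, G, T counts.
#' Positions absent from the file get zero counts.
#'
#' @param path file path.
#' @param genome_length full genome length.
#' @return data.frame with `position`, `A`, `C`, `G`, `T`.
#' @export
read_pileup_tsv <- function(path, genome_length) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("position", "A", "C", "G", "T")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    stop(path, ": pileup lacks column(s) ", paste(miss, collapse = ", "))
  }
  out <- data.frame(position = seq_len(genome_length),
                    A = 0L, C = 0L, G = 0L, T = 0L)
  if (any(tb$position < 1L) || any(tb$position > genome_length)) {
    stop(path, ": pileup position outside the genome")
  }
  out[tb$position, c("A", "C", "G", "T")] <- tb[, c("A", "C", "G", "T")]
  out
}

#' @rdname read_pileup_tsv
#' @param pileup data.frame with `position`, `A`, `C`, `G`, `T`.
#' @param genome_id genome identifier written in the first column.
#' @export
write_pileup_tsv <- function(pileup, path, genome_id = "genome") {
  tb <- cbind(genome = genome_id,
              pileup[, c("position", "A", "C", "G", "T")])
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular alignment hit file
#'
#' The conventional pairwise-hit format: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore. Subject
#' coordinates of reversed hits are normalized to `sstart <= send` with a
#' `sstrand` flag.
#'
#' @param path file path.
#' @return data.frame with the 12 standard columns plus `sstrand`.
#' @export
read_hit_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols,
                          colClasses = c("character", "character",
                                         rep("numeric", 10L)))
  rev <- tb$sstart > tb$send
  tmp <- tb$sstart[rev]
  tb$sstart[rev] <- tb$send[rev]
  tb$send[rev] <- tmp
  tb$sstrand <- ifelse(rev, "-", "+")
  tb
}

#' Read a per-domain profile-search table
#'
#' Parses the standard whitespace-delimited per-domain tabular output of
#' profile searches (one row per domain hit; target sequence in column 1,
#' profile in column 4, independent e-value in column 13, envelope
#' coordinates in columns 20-21).
#'
#' @param path file path.
#' @return data.frame with `protein_id`, `profile_id`, `evalue`,
#'   `env_start`, `env_end`.
#' @export
read_domain_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(protein_id = character(), profile_id = character(),
                      evalue = numeric(), env_start = integer(),
                      env_end = integer()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  short <- which(lengths(parts) < 21L)
  if (length(short)) {
    stop(path, ": domain-table row ", short[1L], " has fewer than 21 fields")
  }
  data.frame(
    protein_id = vapply(parts, `[`, "", 1L),
    profile_id = vapply(parts, `[`, "", 4L),
    evalue = as.numeric(vapply(parts, `[`, "", 13L)),
    env_start = as.integer(vapply(parts, `[`, "", 20L)),
    env_end = as.integer(vapply(parts, `[`, "", 21L)))
}

#' Read an ANI table
#'
#' Tab-separated with header: id_a, id_b, ani, tcov (percent values; tcov
#' is alignment coverage of the shorter genome).
#'
#' @param path file path.
#' @return data.frame with those four columns.
#' @export
read_ani_table <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("id_a", "id_b", "ani", "tcov")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    stop(path, ": ANI table lacks column(s) ", paste(miss, collapse = ", "))
  }
  tb
}

#' Read a split-read junction table
#'
#' Tab-separated: contig, position, count.
#'
#' @param path file path.
#' @return data.frame with `contig`, `position`, `count`.
#' @export
read_junction_table <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("contig", "position", "count"),
                    colClasses = c("character", "integer", "integer"))
}

#' Write a window track as TSV
#'
#' @param track data.frame with `start`, `end` and value columns.
#' @param path output path.
#' @param contig_id contig identifier written as the first column.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path, contig_id = "contig") {
  tb <- cbind(contig = contig_id,
              win_start = track$start, win_end = track$end,
              track[, setdiff(names(track), c("start", "end")), drop = FALSE])
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive regions to BED fields
#'
#' @param regions data.frame with `start`, `end` (1-based inclusive).
#' @param contig_id contig name for the BED chrom column.
#' @param names optional region names.
#' @return data.frame with `chrom`, `chromStart` (0-based), `chromEnd`
#'   (exclusive), `name`.
#' @export
regions_to_bed <- function(regions, contig_id = "contig", names = NULL) {
  if (is.null(names)) {
    names <- sprintf("region_%d", seq_len(nrow(regions)))
  }
  data.frame(chrom = contig_id,
             chromStart = as.integer(regions$start) - 1L,
             chromEnd = as.integer(regions$end),
             name = names)
}

#' @rdname regions_to_bed
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path, contig_id = "contig",
                              names = NULL) {
  bed <- regions_to_bed(regions, contig_id, names)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
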