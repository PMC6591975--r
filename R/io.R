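#' Read a (multi-)FASTA genome
#'
#' Wraps `Biostrings::readDNAStringSet()`. Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences, ready for
#'   [scan_genome()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty input: ", path, " holds no FASTA records")
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA header with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(x)), ids)
}

# forward-strand interval of the terminal motif (core + level-0 target T)
.motif_span <- function(d) {
  extra <- nchar(d$end3_motif) - 4L
  start <- ifelse(d$strand == "+", d$end3_pos - 3L, d$end3_pos - extra)
  end <- ifelse(d$strand == "+", d$end3_pos + extra, d$end3_pos + 3L)
  data.frame(start = start, end = end)
}

# nearest 5' end on the forward strand, NA when absent
.nearest5 <- function(d) {
  vapply(d$five_prime, function(p) if (length(p)) p[[1L]] else NA_integer_,
         integer(1))
}

# full-length span: nearest 5' end to the 3' core end; hairpin start fallback
.full_span <- function(d) {
  p5 <- .nearest5(d)
  plus <- d$strand == "+"
  start <- ifelse(plus, ifelse(is.na(p5), d$hp_left_start, p5), d$end3_pos)
  end <- ifelse(plus, d$end3_pos, ifelse(is.na(p5), d$hp_left_end, p5))
  data.frame(start = start, end = end, has5 = !is.na(p5))
}

.extract_stranded <- function(records, seqid, start, end, strand) {
  s <- substr(records[[seqid]], start, end)
  if (strand == "-") s <- revcomp_cpp(s) else toupper(s)
}

.write_fasta <- function(seqs, path) {
  # seqs: named character; wrapped at 60 columns
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  path
}

#' Write the scanner's four output files
#'
#' Produces, under a common prefix, the 3' terminal regions
#' (`<prefix>.3.txt`: hairpin start through motif end plus a downstream
#' flank), all 5' ends (`<prefix>.5.fa`), putative full-length elements
#' (`<prefix>.full.fa`, nearest 5' end through the 3' terminus; candidates
#' with no 5' end are omitted) and a GFF3 annotation (`<prefix>.gff3`, one
#' feature per candidate spanning nearest 5' end -- or hairpin start -- to
#' the 3' terminus). Sequences are written on the candidate strand, wrapped
#' at 60 columns.
#'
#' @param candidates Candidates from [scan_genome()].
#' @param records The scanned sequences (named character vector or
#'   `DNAStringSet`).
#' @param out_prefix Output path prefix.
#' @param flank3 Downstream flank, in bases, appended to each 3' terminal
#'   record (clipped at the sequence end).
#' @param flank5 Length of each 5' end record, in bases.
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_helitron_outputs <- function(candidates, records, out_prefix,
                                   flank3 = 30L, flank5 = 30L) {
  records <- .coerce_records(records)
  if (!all(candidates$seqid %in% names(records)))
    stop("candidates refer to sequences missing from 'records'")
  d <- candidates
  n <- nrow(d)
  lens <- nchar(records)[d$seqid]
  ms <- .motif_span(d)
  fs <- .full_span(d)

  paths <- c(end3 = paste0(out_prefix, ".3.txt"),
             end5 = paste0(out_prefix, ".5.fa"),
             full = paste0(out_prefix, ".full.fa"),
             gff3 = paste0(out_prefix, ".gff3"))

  # 3' terminal regions: hairpin through motif end + flank, candidate strand
  s3 <- character(n)
  h3 <- character(n)
  for (i in seq_len(n)) {
    if (d$strand[i] == "+") {
      a <- d$hp_left_start[i]; b <- min(ms$end[i] + flank3, lens[i])
    } else {
      a <- max(ms$start[i] - flank3, 1L); b <- d$hp_left_end[i]
    }
    s3[i] <- .extract_stranded(records, d$seqid[i], a, b, d$strand[i])
    h3[i] <- sprintf("%s %s:%d..%d %s", d$id[i], d$seqid[i], a, b, d$strand[i])
  }
  .write_fasta(setNames(s3, h3), paths[["end3"]])

  # all 5' ends, one record each
  s5 <- character(0); h5 <- character(0)
  for (i in seq_len(n)) {
    fp <- d$five_prime[[i]]
    for (j in seq_along(fp)) {
      if (d$strand[i] == "+") {
        a <- fp[j]; b <- min(fp[j] + flank5 - 1L, lens[i])
      } else {
        a <- max(fp[j] - flank5 + 1L, 1L); b <- fp[j]
      }
      s5 <- c(s5, .extract_stranded(records, d$seqid[i], a, b, d$strand[i]))
      h5 <- c(h5, sprintf("%s.5_%d %s:%d..%d %s", d$id[i], j, d$seqid[i],
                          a, b, d$strand[i]))
    }
  }
  .write_fasta(setNames(s5, h5), paths[["end5"]])

  # full-length: nearest 5' end through 3' terminus; needs a 5' end
  keep <- which(fs$has5)
  sf <- character(length(keep)); hf <- character(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    sf[k] <- .extract_stranded(records, d$seqid[i], fs$start[i], fs$end[i],
                               d$strand[i])
    hf[k] <- sprintf("%s %s:%d..%d %s", d$id[i], d$seqid[i], fs$start[i],
                     fs$end[i], d$strand[i])
  }
  .write_fasta(setNames(sf, hf), paths[["full"]])

  write_helitron_gff3(candidates, paths[["gff3"]])
  invisible(paths)
}

#' Write candidates as GFF3
#'
#' One `Helitron` feature per candidate, 1-based inclusive forward-strand
#' coordinates, spanning the nearest 5' end (or the hairpin when no 5' end
#' exists) through the 3' terminus. Attributes carry the candidate id, the
#' matched 3' motif, the hairpin span and the number of 5' ends.
#'
#' @param candidates Candidates from [scan_genome()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_helitron_gff3 <- function(candidates, path) {
  d <- candidates
  fs <- .full_span(d)
  gr <- GenomicRanges::GRanges(
    seqnames = d$seqid,
    ranges = IRanges::IRanges(start = fs$start, end = fs$end),
    strand = d$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "helscan", type = "Helitron",
    ID = d$id, end3_motif = d$end3_motif,
    hairpin_start = pmin(d$hp_left_start, d$hp_right_start),
    hairpin_end = pmax(d$hp_left_end, d$hp_right_end),
    n_five_prime = d$n_five_prime)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 of Helitron candidates
#'
#' Reads a file written by [write_helitron_gff3()] (or any GFF3 of Helitron
#' features) into a data frame of intervals.
#'
#' @param path GFF3 file.
#' @return Data frame with `seqid`, `start`, `end`, `strand`, `id`.
#' @export
read_helitron_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             id = if (!is.null(gr$ID)) as.character(gr$ID) else
               as.character(seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Per-genome scan summary
#'
#' One row per genome: number of sequences, total bases (N included),
#' number of distinct 3' termini and Helitron density (termini per Mb).
#'
#' @param candidates Candidates from [scan_genome()].
#' @param records The scanned sequences.
#' @param genome Label for the summary row.
#' @return A one-row data frame: `genome`, `n_sequences`, `total_bases`,
#'   `n_helitrons`, `density`.
#' @export
helitron_summary <- function(candidates, records, genome = "genome") {
  records <- .coerce_records(records)
  total <- sum(as.numeric(nchar(records)))
  n <- nrow(unique(as.data.frame(candidates[, c("seqid", "strand", "end3_pos")])))
  data.frame(genome = genome, n_sequences = length(records),
             total_bases = total, n_helitrons = n,
             density = helitron_density(n, total / 1e6),
             stringsAsFactors = FALSE)
}

#' Read a genome feature table
#'
#' Tab-separated table of per-genome features used by the classification and
#' clustering operations: columns `genome` (label), `genome_size` (Mb),
#' `helitron_count`, `density` (Helitrons per Mb) and optionally `group`
#' (class label). Density is recomputed from count and size when absent.
#'
#' @param path TSV file.
#' @return A data frame.
#' @export
read_feature_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome", "genome_size")
  if (!all(need %in% names(d)))
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  if (is.null(d$density) && !is.null(d$helitron_count))
    d$density <- d$helitron_count / d$genome_size
  d
}
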