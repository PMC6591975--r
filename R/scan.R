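#' Reverse complement of a nucleotide sequence
#'
#' Complements A<->T, C<->G (N maps to N) and reverses. Input is normalized
#' to upper case; any character outside the A/C/G/T/N alphabet is an error
#' naming the offending position.
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complemented string, upper case.
#' @examples
#' reverse_complement("AACGT")  # "ACGTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  revcomp_cpp(seq)
}

.coerce_records <- function(records) {
  if (methods::is(records, "DNAStringSet") || methods::is(records, "XStringSet"))
    records <- setNames(as.character(records), names(records))
  if (!is.character(records))
    stop("records must be a named character vector or a DNAStringSet")
  if (length(records) == 0L) stop("empty input: no sequence records")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("every sequence record needs a non-empty id")
  if (anyDuplicated(names(records)))
    stop("duplicate sequence ids: ",
         paste(unique(names(records)[duplicated(names(records))]), collapse = ", "))
  records
}

#' Find GC-rich palindromic hairpins in a sequence
#'
#' Left-anchored greedy search: for every admissible left-arm start the
#' longest arm is taken, then the shortest loop, and at most one hairpin is
#' reported per left-arm start. An arm is a run of `arm_min`--`arm_max`
#' bases beginning and ending with G/C with at least `ceiling(gc_min * len)`
#' G/C bases; the right arm must be the exact reverse complement of the left
#' arm, separated by a loop of at most `loop_max` bases. Windows containing
#' N never match. Only maximal stems are reported: a match whose arms extend
#' outward by one complementary base into another admissible arm is dropped
#' in favour of the longer match.
#'
#' @param seq A single nucleotide string.
#' @param params A [helitron_params()] object.
#' @return A data frame of hairpins ordered by `left_start` (1-based
#'   inclusive coordinates): `left_start`, `left_end`, `loop_len`,
#'   `right_start`, `right_end`, `arm_seq`.
#' @examples
#' find_hairpins(paste0("AAAA", "GCGGCGGC", "ATAT", "GCCGCCGC", "AAAA"),
#'               helitron_params())
#' @export
find_hairpins <- function(seq, params = helitron_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  params <- as_helitron_params(params)
  h <- find_hairpins_cpp(seq, params$arm_min, params$arm_max,
                         params$loop_max, params$gc_min)
  data.frame(left_start = as.integer(h$left_start),
             left_end = as.integer(h$left_end),
             loop_len = as.integer(h$loop_len),
             right_start = as.integer(h$right_start),
             right_end = as.integer(h$right_end),
             arm_seq = as.character(h$arm_seq),
             stringsAsFactors = FALSE)
}

# Core per-record scan; returns the candidate data.frame for one sequence.
.scan_record <- function(seq, seqid, params, want_five = TRUE,
                         both_strands = TRUE) {
  r <- scan_sequence_cpp(seq, params$fuzzy_level, params$arm_min,
                         params$arm_max, params$loop_max, params$spacer_min,
                         params$spacer_max, params$upstream_window,
                         params$gc_min, want_five, both_strands)
  d <- data.frame(seqid = rep(seqid, length(r$strand)),
                  strand = as.character(r$strand),
                  end3_pos = as.integer(r$end3_pos),
                  end3_motif = as.character(r$end3_motif),
                  hp_left_start = as.integer(r$hp_left_start),
                  hp_left_end = as.integer(r$hp_left_end),
                  loop_len = as.integer(r$loop_len),
                  hp_right_start = as.integer(r$hp_right_start),
                  hp_right_end = as.integer(r$hp_right_end),
                  arm_seq = as.character(r$arm_seq),
                  n_five_prime = as.integer(r$n_five_prime),
                  target_site_ok = as.logical(r$target_site_ok),
                  stringsAsFactors = FALSE)
  d$five_prime <- lapply(r$five_prime, as.integer)
  # order by forward-strand terminus position, '+' before '-' on ties
  d <- d[order(d$end3_pos, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  if (params$target_site_filter && nrow(d))
    d <- d[!is.na(d$target_site_ok) & d$target_site_ok, , drop = FALSE]
  d
}

.assign_ids <- function(d) {
  d$id <- rep(NA_character_, nrow(d))
  for (sq in unique(d$seqid)) {
    for (st in c("+", "-")) {
      i <- which(d$seqid == sq & d$strand == st)
      if (!length(i)) next
      i <- i[order(d$end3_pos[i])]
      pre <- if (st == "+") "" else "tr"
      d$id[i] <- paste0(pre, sq, "H", seq_along(i))
    }
  }
  d[, c("id", setdiff(names(d), "id")), drop = FALSE]
}

#' Find Helitron 3' termini (without 5' ends)
#'
#' Scans one sequence on both strands for the hairpin + terminal-motif
#' signature. For each motif occurrence the nearest admissible hairpin is
#' taken (smallest spacer, then longest arm, then shortest loop) and at most
#' one candidate is kept per distinct 3' end position and strand. The
#' forward scan is followed by an identical scan of the reverse complement
#' with all coordinates mapped back to the forward strand.
#'
#' @inheritParams find_hairpins
#' @param seqid Identifier used for the record in the output.
#' @return A candidate data frame (see [scan_genome()]) with empty
#'   `five_prime` lists.
#' @export
find_3prime_termini <- function(seq, params = helitron_params(),
                                seqid = "seq1") {
  stopifnot(is.character(seq), length(seq) == 1L)
  params <- as_helitron_params(params)
  .assign_ids(.scan_record(seq, seqid, params, want_five = FALSE))
}

#' Populate candidate 5' TC ends for scanned termini
#'
#' For every candidate, all `TC` occurrences on the candidate strand that lie
#' upstream of the hairpin left arm and within `upstream_window` bases of the
#' 3' end are recorded, nearest first. Candidates with no 5' end are
#' retained with an empty list. `target_site_ok` reports whether the base
#' 3'-adjacent to the terminal motif is T and the base 5'-adjacent to the
#' nearest 5' end is A (NA when there is no 5' end).
#'
#' @param candidates A candidate data frame from [find_3prime_termini()].
#' @param seq The sequence the candidates were found in.
#' @param params The same [helitron_params()] used for the scan.
#' @return The candidate data frame with `five_prime`, `n_five_prime` and
#'   `target_site_ok` populated.
#' @export
find_5prime_ends <- function(candidates, seq, params = helitron_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  params <- as_helitron_params(params)
  if (!nrow(candidates)) return(candidates)
  seqid <- candidates$seqid[1L]
  full <- .scan_record(seq, seqid, params, want_five = TRUE)
  key <- function(d) paste(d$strand, d$end3_pos)
  i <- match(key(candidates), key(full))
  if (anyNA(i))
    stop("candidates do not match this sequence/parameter combination")
  for (col in c("five_prime", "n_five_prime", "target_site_ok"))
    candidates[[col]] <- full[[col]][i]
  candidates
}

#' Scan a genome for structural Helitron candidates
#'
#' Runs the 3' terminus scan plus 5' TC search on every record and
#' concatenates the per-record results in input order. Candidate ids follow
#' the naming scheme `<seqid>H<k>` on the forward strand and `tr<seqid>H<k>`
#' on the reverse strand, with `k` counting per sequence and strand in
#' forward-coordinate order. Output is identical for any `worker_count`.
#'
#' @param records Named character vector of sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from [read_genome()]).
#' @param params A [helitron_params()] object.
#' @param with_five_prime Populate 5' TC ends (default) or skip them.
#' @return A data frame of class `helitron_candidates`, one row per
#'   candidate 3' terminus: `id`, `seqid`, `strand`, `end3_pos` (1-based
#'   forward-strand position of the last base of the CTRR core),
#'   `end3_motif`, hairpin coordinates (`hp_left_*`, `hp_right_*` are the
#'   scanned-strand left/right arms in forward coordinates), `loop_len`,
#'   `arm_seq`, `n_five_prime`, `five_prime` (list of 1-based positions,
#'   nearest first) and `target_site_ok`. The scan parameters are attached
#'   as attribute `params`.
#' @examples
#' g <- make_planted_genome(n_cassettes = 2, background_length = 4000, seed = 1)
#' scan_genome(g$records)
#' @export
scan_genome <- function(records, params = helitron_params(),
                        with_five_prime = TRUE) {
  records <- .coerce_records(records)
  params <- as_helitron_params(params)
  scan1 <- function(i) .scan_record(records[[i]], names(records)[i], params,
                                    want_five = with_five_prime)
  idx <- seq_along(records)
  if (params$worker_count > 1L && .Platform$OS.type == "unix") {
    parts <- parallel::mclapply(idx, scan1, mc.cores = params$worker_count,
                                mc.preschedule = TRUE)
  } else {
    parts <- lapply(idx, scan1)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- .assign_ids(out)
  attr(out, "params") <- params
  class(out) <- c("helitron_candidates", class(out))
  out
}

#' @export
print.helitron_candidates <- function(x, ...) {
  cat(sprintf("Helitron candidates: %d termini on %d sequence(s) (+: %d, -: %d)\n",
              nrow(x), length(unique(x$seqid)), sum(x$strand == "+"),
              sum(x$strand == "-")))
  if (nrow(x)) {
    show <- as.data.frame(head(x[, c("id", "seqid", "strand", "end3_pos",
                                     "end3_motif", "loop_len", "n_five_prime")],
                               10L))
    print(show, ...)
    if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}
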