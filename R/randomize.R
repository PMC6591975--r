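#' Base composition of sequence records
#'
#' Counts A/C/G/T/N over all records. N (and any other ambiguity code) is
#' excluded from the frequency denominator but included in the total length.
#'
#' @param records Named character vector of sequences or a `DNAStringSet`.
#' @return A list: `counts` (A, C, G, T, N, other), `freq` (A, C, G, T;
#'   `NaN` with `defined = FALSE` when no unambiguous base exists), `length`
#'   (total bases) and `defined`.
#' @examples
#' count_composition(c(chr1 = "AATG"))$freq
#' @export
count_composition <- function(records) {
  records <- .coerce_records(records)
  tot <- Reduce(`+`, lapply(records, base_counts_cpp))
  acgt <- tot[c("A", "C", "G", "T")]
  denom <- sum(acgt)
  list(counts = tot[c("A", "C", "G", "T", "N", "other")],
       freq = acgt / denom,
       length = unname(tot[["length"]]),
       defined = denom > 0)
}

#' Specification of a composition-matched random genome
#'
#' @param freq_A,freq_T,freq_G,freq_C Base frequencies. They are normalized
#'   to sum to 1 (published compositions measured over a genome that
#'   contains N can sum to slightly less); a deviation beyond 1% is an
#'   error.
#' @param length Sequence length in bases.
#' @param seed RNG seed; the same spec always yields the same sequence.
#' @return An object of class `composition_spec`.
#' @export
composition_spec <- function(freq_A, freq_T, freq_G, freq_C, length,
                             seed = 1L) {
  f <- c(A = freq_A, C = freq_C, G = freq_G, T = freq_T)
  if (any(f < 0)) stop("frequencies must be non-negative")
  s <- sum(f)
  if (abs(s - 1) > 0.01)
    stop("frequencies must sum to 1 (got ", format(s), ")")
  structure(list(freq = f / s, length = as.numeric(length),
                 seed = as.integer(seed)),
            class = "composition_spec")
}

#' Generate a random genome from a composition spec
#'
#' Bases are drawn i.i.d. from the categorical distribution over A/C/G/T at
#' the spec's frequencies, using R's RNG seeded from the spec, so identical
#' specs give byte-identical sequences.
#'
#' @param spec A [composition_spec()].
#' @param id Record id of the generated sequence.
#' @return Named character vector of length 1.
#' @export
random_genome <- function(spec, id = "random") {
  stopifnot(inherits(spec, "composition_spec"))
  set.seed(spec$seed)
  setNames(random_dna_cpp(spec$length, unname(spec$freq)), id)
}

#' Estimate the scanner's false-positive rate on random genomes
#'
#' Generates `n_genomes` composition-matched random genomes, scans each at
#' the given parameters, and reports
#' `FPR = 100 * mean(candidate count) / reference_count`, where the
#' reference count is the number of candidates the scanner predicts in the
#' real genome the composition was measured from. Candidates found in
#' random sequence cannot be genuine Helitrons, so the mean random yield
#' relative to the real yield estimates the fraction of false calls.
#'
#' @param freq Base frequencies, named A/C/G/T (normalized internally).
#' @param length Length of each random genome, bases.
#' @param n_genomes Number of random genomes (>= 1).
#' @param params A [helitron_params()] object.
#' @param reference_count Candidate count in the real genome (> 0).
#' @param seed Base seed; genome `i` uses `seed + i - 1`.
#' @param scale_to Optionally, a genome length the counts are linearly
#'   extrapolated to before forming the rate (e.g. scan genomes of
#'   `length = L/10` and set `scale_to = L`). Default: no scaling.
#' @return A list: `fpr` (percent), `mean_count`, `counts` (per genome),
#'   `reference_count`, `length`, `n_genomes`.
#' @export
estimate_fpr <- function(freq, length, n_genomes, params = helitron_params(),
                         reference_count, seed = 1L, scale_to = NULL) {
  if (n_genomes < 1) stop("n_genomes must be at least 1")
  if (reference_count <= 0) stop("reference_count must be positive")
  f <- freq[c("A", "T", "G", "C")]
  counts <- vapply(seq_len(n_genomes), function(i) {
    spec <- composition_spec(f[["A"]], f[["T"]], f[["G"]], f[["C"]],
                             length = length, seed = seed + i - 1L)
    g <- random_genome(spec, id = paste0("rand", i))
    nrow(scan_genome(g, params, with_five_prime = FALSE))
  }, numeric(1))
  scale <- if (is.null(scale_to)) 1 else scale_to / length
  mean_count <- mean(counts) * scale
  list(fpr = 100 * mean_count / reference_count, mean_count = mean_count,
       counts = counts, reference_count = reference_count,
       length = length, n_genomes = n_genomes)
}
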