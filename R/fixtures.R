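#' Synthetic genome with planted Helitron cassettes
#'
#' Generates a background sequence (A/T-only by default, so no hairpin arm
#' or CTAG motif can arise by chance) and plants non-overlapping canonical
#' cassettes `A | TC ... [arm][loop][rc-arm] (spacer) CTAG | T`, i.e. a 5'
#' TC end in an AT target site, a GC-only palindromic hairpin, and the CTAG
#' 3' terminus. The returned truth table gives the planted coordinates in
#' the exact representation [scan_genome()] reports, so recovery can be
#' checked field by field.
#'
#' @param n_cassettes Number of cassettes (0 allowed).
#' @param background_length Total genome length, bases.
#' @param arm_len,loop_len,spacer_len Cassette geometry, bases.
#' @param five_prime_distance Distance from the 5' T to the hairpin start.
#' @param include_five_prime Plant the 5' `A|TC` head (default) or start
#'   cassettes at the hairpin.
#' @param composition Background base probabilities, named A/C/G/T.
#' @param strands Strand per cassette, recycled (`"+"`/`"-"`).
#' @param seqid Record id.
#' @param seed RNG seed; generation is a pure function of the arguments.
#' @return A list: `records` (named character vector of length 1) and
#'   `truth` (data frame with `id`, `strand`, `end3_pos`, `hp_left_start`,
#'   `hp_left_end`, `hp_right_start`, `hp_right_end`, `loop_len`,
#'   `five_prime` -- NA when not planted -- and the cassette `start`/`end`).
#' @examples
#' g <- make_planted_genome(n_cassettes = 3, background_length = 6000, seed = 7)
#' nrow(scan_genome(g$records))  # 3
#' @export
make_planted_genome <- function(n_cassettes = 5, background_length = 10000,
                                arm_len = 8, loop_len = 4, spacer_len = 3,
                                five_prime_distance = 150,
                                include_five_prime = TRUE,
                                composition = c(A = 0.5, C = 0, G = 0, T = 0.5),
                                strands = "+", seqid = "chr1", seed = 1) {
  stopifnot(n_cassettes >= 0, arm_len >= 1, loop_len >= 0, spacer_len >= 0,
            five_prime_distance >= 3)
  set.seed(seed)
  bg <- random_dna_cpp(background_length,
                       unname(composition[c("A", "C", "G", "T")] /
                                sum(composition)))
  w_str <- function(k) paste(sample(c("A", "T"), k, replace = TRUE),
                             collapse = "")
  filler_len <- five_prime_distance - 2L
  head_len <- if (include_five_prime) 3L + filler_len else 0L
  cass_len <- head_len + 2L * arm_len + loop_len + spacer_len + 5L
  if (n_cassettes * cass_len >= background_length)
    stop("overcrowded: ", n_cassettes, " cassettes of ", cass_len,
         " bp do not fit in ", background_length, " bp")
  strands <- rep_len(strands, max(n_cassettes, 1L))

  slot <- if (n_cassettes) background_length %/% n_cassettes else 0L
  truth <- vector("list", n_cassettes)
  seq_chars <- strsplit(bg, "", fixed = TRUE)[[1L]]
  for (k in seq_len(n_cassettes)) {
    arm <- paste(sample(c("G", "C"), arm_len, replace = TRUE), collapse = "")
    rc_arm <- revcomp_cpp(arm)
    # filler ends in A so a GC arm start cannot form a spurious upstream TC
    head_part <- if (include_five_prime)
      paste0("A", "TC", w_str(filler_len - 1L), "A") else ""
    cass <- paste0(head_part, arm, w_str(loop_len), rc_arm,
                   w_str(spacer_len), "CTAG", "T")
    # place inside slot k, away from the slot edges
    lo <- (k - 1L) * slot + 1L
    hi <- k * slot - cass_len
    start <- lo + sample.int(max(hi - lo, 1L), 1L) - 1L
    pos <- function(off) start + off - 1L  # cassette-local 1-based -> genome
    # cassette-local coordinates (on the cassette strand)
    hp_l <- head_len + 1L
    hp_r <- head_len + arm_len + loop_len + 1L
    e3 <- head_len + 2L * arm_len + loop_len + spacer_len + 4L
    if (strands[k] == "-") cass <- revcomp_cpp(cass)
    seq_chars[start:(start + cass_len - 1L)] <-
      strsplit(cass, "", fixed = TRUE)[[1L]]
    flip <- function(p) start + cass_len - p  # local -> genome, minus strand
    if (strands[k] == "+") {
      tr <- data.frame(strand = "+", end3_pos = pos(e3),
                       hp_left_start = pos(hp_l),
                       hp_left_end = pos(hp_l + arm_len - 1L),
                       hp_right_start = pos(hp_r),
                       hp_right_end = pos(hp_r + arm_len - 1L),
                       loop_len = loop_len,
                       five_prime = if (include_five_prime) pos(2L) else NA,
                       start = start, end = start + cass_len - 1L)
    } else {
      tr <- data.frame(strand = "-", end3_pos = flip(e3),
                       hp_left_start = flip(hp_l + arm_len - 1L),
                       hp_left_end = flip(hp_l),
                       hp_right_start = flip(hp_r + arm_len - 1L),
                       hp_right_end = flip(hp_r),
                       loop_len = loop_len,
                       five_prime = if (include_five_prime) flip(2L) else NA,
                       start = start, end = start + cass_len - 1L)
    }
    truth[[k]] <- tr
  }
  truth <- if (n_cassettes) do.call(rbind, truth) else
    data.frame(strand = character(0), end3_pos = integer(0),
               hp_left_start = integer(0), hp_left_end = integer(0),
               hp_right_start = integer(0), hp_right_end = integer(0),
               loop_len = integer(0), five_prime = integer(0),
               start = integer(0), end = integer(0))
  if (n_cassettes) {
    truth <- truth[order(truth$end3_pos), , drop = FALSE]
    rownames(truth) <- NULL
    ids <- integer(nrow(truth))
    for (st in c("+", "-")) {
      i <- which(truth$strand == st)
      ids[i] <- seq_along(i)
    }
    truth$id <- paste0(ifelse(truth$strand == "-", "tr", ""), seqid, "H", ids)
    truth <- truth[, c("id", setdiff(names(truth), "id"))]
  }
  list(records = setNames(paste(seq_chars, collapse = ""), seqid),
       truth = truth)
}

#' Toy gene annotation
#'
#' Builds a [gene_models] object from gene spans, placing one centred CDS
#' interval per gene covering `cds_fraction` of the span.
#'
#' @param spans Data frame with `seqid`, `start`, `end` and optionally
#'   `strand` and `gene_id`.
#' @param cds_fraction Fraction of each span covered by CDS (0 for none).
#' @return A [gene_models] object.
#' @export
make_toy_annotation <- function(spans, cds_fraction = 0.6) {
  stopifnot(all(c("seqid", "start", "end") %in% names(spans)),
            cds_fraction >= 0, cds_fraction <= 1)
  if (any(spans$start > spans$end)) stop("invalid span: start > end")
  g <- data.frame(gene_id = if (!is.null(spans$gene_id)) spans$gene_id else
    sprintf("gene%03d", seq_len(nrow(spans))),
    seqid = spans$seqid,
    strand = if (!is.null(spans$strand)) spans$strand else "+",
    start = spans$start, end = spans$end, stringsAsFactors = FALSE)
  if (cds_fraction > 0) {
    len <- g$end - g$start + 1L
    cdslen <- pmax(1L, as.integer(round(len * cds_fraction)))
    cs <- g$start + (len - cdslen) %/% 2L
    cds <- data.frame(gene_id = g$gene_id, seqid = g$seqid, start = cs,
                      end = cs + cdslen - 1L, stringsAsFactors = FALSE)
  } else {
    cds <- data.frame(gene_id = character(0), seqid = character(0),
                      start = integer(0), end = integer(0))
  }
  gene_models(g, cds)
}

#' Synthetic ecotype x locus matrix with planted associations
#'
#' Builds a presence/absence matrix over ecotypes whose phenotype classes
#' have exactly the requested margins, with loci planted to carry exact
#' association patterns (e.g. "present in 3 ecotypes, all of class late")
#' plus optional independent random loci.
#'
#' Each planted spec is a list with `name`, `n`, `class` and `state`:
#' exactly `n` ecotypes of phenotype `class` carry value `state` (0 or 1)
#' at that locus, every other ecotype carries `1 - state`. The carriers
#' are drawn (seeded) from the ecotypes of that class.
#'
#' @param class_counts Named integer vector: ecotypes per phenotype class.
#' @param planted List of planted locus specs (see above).
#' @param n_random_loci Number of additional loci with i.i.d.
#'   `Bernoulli(p_random)` presence, independent of the phenotype.
#' @param p_random Presence probability of the random loci.
#' @param seed RNG seed.
#' @return A list: `presence` (ecotype x locus 0/1 matrix), `phenotype`
#'   (character vector), and `transactions` (ready-made
#'   [as_transactions()] object).
#' @examples
#' m <- make_ecotype_matrix(c(late = 5, intermediate = 13),
#'        planted = list(list(name = "LOC384", n = 3, class = "late",
#'                            state = 1)))
#' mine_rules(m$transactions)
#' @export
make_ecotype_matrix <- function(class_counts, planted = list(),
                                n_random_loci = 0, p_random = 0.5,
                                seed = 1) {
  stopifnot(!is.null(names(class_counts)), all(class_counts >= 0))
  n <- sum(class_counts)
  if (n < 2L) stop("need at least two ecotypes")
  phen <- rep(names(class_counts), class_counts)
  eco <- sprintf("E%02d", seq_len(n))
  set.seed(seed)
  cols <- list()
  for (sp in planted) {
    stopifnot(all(c("name", "n", "class", "state") %in% names(sp)))
    pool <- which(phen == sp$class)
    if (sp$n > length(pool))
      stop("infeasible planted locus ", sp$name, ": ", sp$n, " > ",
           length(pool), " ecotypes of class ", sp$class)
    pick <- if (sp$n) pool[sample.int(length(pool), sp$n)] else integer(0)
    v <- rep(1L - sp$state, n)
    v[pick] <- sp$state
    cols[[sp$name]] <- v
  }
  for (j in seq_len(n_random_loci)) {
    cols[[sprintf("RND%03d", j)]] <- as.integer(stats::runif(n) < p_random)
  }
  pres <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(0), nrow = n, ncol = 0)
  rownames(pres) <- eco
  list(presence = pres, phenotype = phen,
       transactions = as_transactions(pres, phen))
}
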