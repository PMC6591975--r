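test_that("reverse_complement follows the complement rule and flags bad input", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("TC"), "GA")
  expect_identical(reverse_complement("AACGT"), "ACGTT")
  expect_identical(reverse_complement("acgnt"), "ANCGT")
  expect_error(reverse_complement("ACXGT"), "position 3")
  # agreement with Biostrings on random sequences
  set.seed(11)
  for (k in 1:5) {
    s <- random_seq(200, gc = 0.4)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("find_hairpins reports maximal stems with greedy arm/loop choice", {
  p <- helitron_params()
  h <- find_hairpins(paste0("AAAA", "GCGGCGGC", "ATAT", "GCCGCCGC", "AAAA"), p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$arm_seq, "GCGGCGGC")
  expect_equal(h$loop_len, 4L)
  expect_equal(h$left_start, 5L)
  expect_equal(h$right_end, 24L)
  # no G/C at all -> nothing
  expect_equal(nrow(find_hairpins(strrep("A", 1000), p)), 0L)
  # too short for two arms
  expect_equal(nrow(find_hairpins(strrep("G", 2 * p$arm_min - 1), p)), 0L)
  # N inside the loop blocks the match
  expect_equal(nrow(find_hairpins(paste0("GCGGCGGC", "ANAT", "GCCGCCGC"), p)), 0L)
})

test_that("3' terminus detection honours the spacer bound and strand mapping", {
  p <- helitron_params()
  arm <- "GCGGCGGC"
  cass <- function(spacer) paste0(arm, "ATAT", reverse_complement(arm),
                                  strrep("T", spacer), "CTAG")
  bg <- function(x) paste0(strrep("A", 100), x, strrep("T", 100))
  one <- find_3prime_termini(bg(cass(3)), p)
  expect_equal(nrow(one), 1L)
  expect_equal(one$strand, "+")
  expect_equal(one$end3_motif, "CTAG")
  # 11-nt spacer exceeds spacer_max = 10
  expect_equal(nrow(find_3prime_termini(bg(cass(11)), p)), 0L)
  # reverse complement of the fixture: same terminus on the minus strand,
  # forward-strand interval preserved under coordinate reflection
  s <- bg(cass(3))
  rc <- reverse_complement(s)
  two <- find_3prime_termini(rc, p)
  expect_equal(nrow(two), 1L)
  expect_equal(two$strand, "-")
  n <- nchar(s)
  expect_equal(two$end3_pos, n - one$end3_pos + 1L)
  expect_equal(two$hp_left_start, n - one$hp_left_end + 1L)
  expect_equal(two$hp_left_end, n - one$hp_left_start + 1L)
})

test_that("5' TC search is exhaustive, nearest-first, window-bounded", {
  p <- helitron_params()
  arm <- "GCCGGCGC"
  tail3 <- paste0(arm, "TTAA", reverse_complement(arm), "ATT", "CTAG", "T")
  # exactly one ATC, the TC 150 bases upstream of the hairpin start
  s1 <- paste0(strrep("A", 50), "ATC", strrep("A", 148), tail3, strrep("A", 40))
  c1 <- find_3prime_termini(s1, p)
  c1 <- find_5prime_ends(c1, s1, p)
  expect_equal(c1$five_prime[[1]], 52L)
  expect_equal(c1$hp_left_start - c1$five_prime[[1]], 150L)
  expect_true(c1$target_site_ok)
  # no TC in the window: empty list, candidate retained
  s2 <- paste0(strrep("A", 200), tail3, strrep("A", 40))
  c2 <- find_5prime_ends(find_3prime_termini(s2, p), s2, p)
  expect_equal(nrow(c2), 1L)
  expect_equal(c2$n_five_prime, 0L)
  expect_identical(c2$five_prime[[1]], integer(0))
  expect_true(is.na(c2$target_site_ok))
  # three TCs: three positions, nearest first, equal to exhaustive window scan
  s3 <- paste0(strrep("A", 30), "TC", strrep("A", 40), "TC", strrep("A", 50),
               "TC", strrep("A", 60), tail3)
  c3 <- find_5prime_ends(find_3prime_termini(s3, p), s3, p)
  exp <- oracle_five_prime(s3, c3$hp_left_start, c3$end3_pos,
                           p$upstream_window)
  expect_equal(length(exp), 3L)
  expect_equal(c3$five_prime[[1]], exp)
  expect_true(all(diff(c3$five_prime[[1]]) < 0))
})

test_that("scanner equals the brute-force enumerator on seeded sequences", {
  p <- helitron_params()
  set.seed(42)
  cases <- list()
  for (gc in c(0.4, 0.6, 0.75)) {
    for (len in c(400, 1200, 2000)) {
      cases[[length(cases) + 1L]] <- random_seq(len, gc = gc)
    }
  }
  # also a planted genome so at least one true positive is present
  cases[[length(cases) + 1L]] <-
    make_planted_genome(n_cassettes = 2, background_length = 1500,
                        seed = 4)$records[[1L]]
  n_hits <- 0L
  for (s in cases) {
    got <- find_3prime_termini(s, p)
    want <- oracle_termini(s, p)
    expect_equal(nrow(got), nrow(want))
    for (col in c("strand", "end3_pos", "hp_left_start", "hp_left_end",
                  "loop_len", "hp_right_start", "hp_right_end"))
      expect_equal(got[[col]], want[[col]], info = col)
    n_hits <- n_hits + nrow(want)
  }
  expect_gt(n_hits, 0L)  # the comparison must have exercised real matches
})

test_that("fuzzy levels are nested and stricter levels imply looser hits", {
  set.seed(7)
  seqs <- c(replicate(4, random_seq(1500, gc = 0.6)),
            make_planted_genome(3, 4000, seed = 2)$records[[1L]])
  for (s in seqs) {
    keys <- lapply(0:3, function(u) {
      d <- find_3prime_termini(s, helitron_params(fuzzy_level = u))
      paste(d$strand, d$end3_pos)
    })
    for (u in 1:3)
      expect_true(all(keys[[u]] %in% keys[[u + 1L]]),
                  info = paste("level", u - 1, "subset of", u))
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  p <- helitron_params()
  set.seed(13)
  for (k in 1:4) {
    s <- random_seq(1500, gc = 0.65)
    n <- nchar(s)
    a <- find_3prime_termini(s, p)
    b <- find_3prime_termini(reverse_complement(s), p)
    expect_equal(nrow(a), nrow(b))
    expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
    key_a <- sort(paste(a$strand, a$end3_pos))
    key_b <- sort(paste(ifelse(b$strand == "+", "-", "+"),
                        n - b$end3_pos + 1L))
    expect_equal(key_a, key_b)
  }
})

test_that("scan_genome concatenates records, names ids, is worker-invariant", {
  g1 <- make_planted_genome(1, 3000, seed = 1)
  g2 <- make_planted_genome(1, 3000, seed = 2, seqid = "chr2")
  recs <- c(g1$records, g2$records)
  cand <- scan_genome(recs)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$seqid, c("chr1", "chr2"))
  expect_equal(cand$id, c("chr1H1", "chr2H1"))
  # ten records, one cassette each
  recs10 <- setNames(
    vapply(1:10, function(i)
      make_planted_genome(1, 2500, seed = i)$records[[1L]], character(1)),
    paste0("c", 1:10))
  c10 <- scan_genome(recs10)
  expect_equal(nrow(c10), 10L)
  expect_equal(c10$seqid, paste0("c", 1:10))
  # byte-identical output across worker counts
  s1 <- scan_genome(recs10, helitron_params(worker_count = 1))
  s4 <- scan_genome(recs10, helitron_params(worker_count = 4))
  attr(s1, "params") <- attr(s4, "params") <- NULL
  expect_identical(s1, s4)
  # all-N record yields nothing; empty input errors
  expect_equal(nrow(scan_genome(c(nn = strrep("N", 5000)))), 0L)
  expect_error(scan_genome(character(0)), "empty input")
})

test_that("target-site filter keeps only AT-flanked candidates", {
  g <- make_planted_genome(3, 9000, seed = 6)
  all_c <- scan_genome(g$records)
  kept <- scan_genome(g$records, helitron_params(target_site_filter = TRUE))
  expect_true(all(kept$id %in% all_c$id))
  expect_true(all(kept$target_site_ok))
  expect_equal(nrow(kept), sum(!is.na(all_c$target_site_ok) &
                                 all_c$target_site_ok))
})
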