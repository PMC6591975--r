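toy_genes <- function() {
  gene_models(
    genes = data.frame(gene_id = c("g1", "g2"), seqid = "chr1",
                       strand = c("+", "-"), start = c(1000L, 8000L),
                       end = c(2000L, 9000L)),
    cds = data.frame(gene_id = c("g1", "g2"), seqid = "chr1",
                     start = c(1200L, 8200L), end = c(1800L, 8800L)))
}

fake_cand <- function(pos, seqid = "chr1") {
  data.frame(id = paste0("H", seq_along(pos)), seqid = seqid, strand = "+",
             end3_pos = as.integer(pos), stringsAsFactors = FALSE)
}

test_that("insertion typing partitions candidates by 3' end position", {
  g <- toy_genes()
  calls <- classify_insertions(fake_cand(c(1500, 1100, 5000)), g)
  expect_equal(calls$category, c("CDS", "intron/UTR", "intergenic"))
  expect_equal(calls$host_gene_id, c("g1", "g1", ""))
  # boundary positions: CDS edges are CDS, gene edges are genic
  calls2 <- classify_insertions(fake_cand(c(1200, 1800, 1000, 2000, 999,
                                            2001)), g)
  expect_equal(calls2$category,
               c("CDS", "CDS", "intron/UTR", "intron/UTR", "intergenic",
                 "intergenic"))
  # genes on either strand count as genic
  expect_equal(classify_insertions(fake_cand(8500), g)$category, "CDS")
  # categories partition: counts sum to total
  set.seed(5)
  pos <- sample.int(10000, 200)
  sm <- insertion_summary(classify_insertions(fake_cand(pos), g))
  expect_equal(sum(sm$n), 200L)
  expect_equal(sum(sm$percent), 100)
})

test_that("insertion typing ignores gene input order and flags bad seqids", {
  g <- toy_genes()
  gr <- gene_models(g$genes[2:1, ], g$cds[2:1, ])
  pos <- c(1500, 1100, 5000, 8500, 100)
  expect_equal(classify_insertions(fake_cand(pos), g),
               classify_insertions(fake_cand(pos), gr))
  expect_warning(
    calls <- classify_insertions(fake_cand(500, seqid = "chrX"), g),
    "absent")
  expect_equal(calls$category, "intergenic")
})

test_that("insertion summary percentages", {
  calls <- data.frame(candidate_id = paste0("H", 1:10),
                      category = c("CDS", rep("intron/UTR", 2),
                                   rep("intergenic", 7)))
  sm <- insertion_summary(calls)
  expect_equal(sm$percent, c(10, 20, 70))
  all_int <- insertion_summary(data.frame(candidate_id = "a",
                                          category = "intergenic"))
  expect_equal(all_int$percent, c(0, 0, 100))
  empty <- insertion_summary(data.frame(candidate_id = character(0),
                                        category = character(0)))
  expect_equal(empty$n, c(0L, 0L, 0L))
  expect_true(isTRUE(attr(empty, "empty")))
})

test_that("nearest downstream gene marker uses the first start at/after 3' end", {
  g <- gene_models(
    genes = data.frame(gene_id = c("a", "b"), seqid = "chr1", strand = "+",
                       start = c(1200L, 5000L), end = c(1400L, 5100L)),
    cds = data.frame(gene_id = character(0), seqid = character(0),
                     start = integer(0), end = integer(0)))
  expect_equal(nearest_downstream_gene(fake_cand(1000), g), "a")
  # gene starting exactly at the end position qualifies
  expect_equal(nearest_downstream_gene(fake_cand(1200), g), "a")
  # past the last gene: empty marker
  expect_equal(nearest_downstream_gene(fake_cand(6000), g), "")
  # max_distance bounds the search
  expect_equal(nearest_downstream_gene(fake_cand(100), g,
                                       max_distance = 500), "")
  expect_equal(nearest_downstream_gene(fake_cand(100), g,
                                       max_distance = 2000), "a")
})

test_that("LOC matrix: union of markers, sorted ids, polymorphism flags", {
  lm <- build_loc_matrix(list(e1 = c("a", "b"), e2 = "a", e3 = c("a", "c")))
  expect_equal(nrow(lm), 3L)
  expect_equal(lm$marker_gene_id, c("a", "b", "c"))
  expect_equal(lm$loc_id, c("LOC001", "LOC002", "LOC003"))
  expect_equal(lm$polymorphic, c(FALSE, TRUE, TRUE))
  expect_equal(unlist(lm[1, c("e1", "e2", "e3")], use.names = FALSE),
               c(1L, 1L, 1L))
  # identical marker sets: zero polymorphic loci
  lm2 <- build_loc_matrix(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(sum(lm2$polymorphic), 0L)
  # polymorphic + monomorphic = total
  expect_equal(sum(lm$polymorphic) + sum(!lm$polymorphic), nrow(lm))
  # 18 ecotypes, one locus absent from exactly two: row sums to 16
  sets <- c(lapply(1:16, function(i) "m"), list(character(0), character(0)))
  names(sets) <- sprintf("E%02d", 1:18)
  lm3 <- build_loc_matrix(sets)
  expect_equal(sum(lm3[1, sprintf("E%02d", 1:18)]), 16L)
})

test_that("gene models validate CDS nesting and round-trip through GFF3", {
  expect_error(gene_models(
    genes = data.frame(gene_id = "g", seqid = "c", start = 10L, end = 20L),
    cds = data.frame(gene_id = "g", seqid = "c", start = 5L, end = 15L)),
    "nest")
  # round-trip a toy annotation through a GFF3 file
  tmp <- withr::local_tempdir()
  gm <- make_toy_annotation(data.frame(seqid = "chr1",
                                       start = c(1000L, 4000L),
                                       end = c(2000L, 5000L)),
                            cds_fraction = 0.5)
  path <- file.path(tmp, "genes.gff3")
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(gm$genes$start, gm$cds$start),
                           c(gm$genes$end, gm$cds$end)))
  gr$type <- c("gene", "gene", "CDS", "CDS")
  gr$ID <- c(gm$genes$gene_id, paste0(gm$cds$gene_id, ".cds"))
  gr$Parent <- IRanges::CharacterList(list(character(0), character(0),
                                           gm$cds$gene_id[1],
                                           gm$cds$gene_id[2]))
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  gm2 <- read_gene_models(path)
  expect_equal(gm2$genes$start, gm$genes$start)
  expect_equal(gm2$cds$gene_id, gm$cds$gene_id)
})
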