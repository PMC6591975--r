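#' Gene models for insertion typing
#'
#' A light container of gene spans and their CDS intervals used to classify
#' Helitron insertion sites: a list with `genes` (data frame `gene_id`,
#' `seqid`, `strand`, `start`, `end`) and `cds` (data frame `gene_id`,
#' `seqid`, `start`, `end`).
#'
#' @param genes,cds Data frames as above; every CDS interval must lie inside
#'   its gene span.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, cds) {
  need_g <- c("gene_id", "seqid", "start", "end")
  stopifnot(all(need_g %in% names(genes)))
  if (is.null(genes$strand)) genes$strand <- "+"
  if (nrow(cds)) {
    stopifnot(all(c("gene_id", "seqid", "start", "end") %in% names(cds)))
    i <- match(cds$gene_id, genes$gene_id)
    if (anyNA(i)) stop("CDS rows refer to unknown gene ids")
    bad <- cds$start < genes$start[i] | cds$end > genes$end[i] |
      cds$start > cds$end
    if (any(bad))
      stop("CDS intervals must nest inside their gene span (",
           paste(unique(cds$gene_id[bad]), collapse = ", "), ")")
  }
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d CDS intervals on %d sequence(s)\n",
              nrow(x$genes), nrow(x$cds), length(unique(x$genes$seqid))))
  invisible(x)
}

#' Read gene models from GFF3/GTF
#'
#' Imports an annotation with `rtracklayer` and extracts gene spans plus CDS
#' intervals. For GTF the `gene_id` attribute keys everything; for GFF3 gene
#' ids come from the gene features' `ID` and CDS are resolved to their gene
#' through the `Parent` chain (CDS -> mRNA -> gene) when necessary.
#'
#' @param path Annotation file (`.gff3`, `.gff`, `.gtf`).
#' @param gene_types Feature types treated as genes.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path, gene_types = "gene") {
  gr <- rtracklayer::import(path)
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  id_of <- function(i) {
    if (!is.null(m$gene_id)) return(as.character(m$gene_id)[i])
    as.character(m$ID)[i]
  }
  gi <- which(type %in% gene_types)
  if (!length(gi)) stop("no gene features in ", path)
  genes <- data.frame(gene_id = id_of(gi), seqid = seqid[gi],
                      strand = as.character(GenomicRanges::strand(gr))[gi],
                      start = GenomicRanges::start(gr)[gi],
                      end = GenomicRanges::end(gr)[gi],
                      stringsAsFactors = FALSE)
  ci <- which(type == "CDS")
  if (length(ci)) {
    if (!is.null(m$gene_id)) {
      cgene <- as.character(m$gene_id)[ci]
    } else {
      # GFF3: map Parent (transcript or gene) back to a gene ID
      parent_of <- vapply(m$Parent[ci], function(p)
        if (length(p)) as.character(p)[1L] else NA_character_, character(1))
      tx <- which(!is.null(m$ID) & !(type %in% gene_types) & type != "CDS")
      tx_parent <- setNames(vapply(m$Parent[tx], function(p)
        if (length(p)) as.character(p)[1L] else NA_character_, character(1)),
        as.character(m$ID)[tx])
      cgene <- ifelse(parent_of %in% genes$gene_id, parent_of,
                      unname(tx_parent[parent_of]))
    }
    cds <- data.frame(gene_id = cgene, seqid = seqid[ci],
                      start = GenomicRanges::start(gr)[ci],
                      end = GenomicRanges::end(gr)[ci],
                      stringsAsFactors = FALSE)
    cds <- cds[!is.na(cds$gene_id), , drop = FALSE]
  } else {
    cds <- data.frame(gene_id = character(0), seqid = character(0),
                      start = integer(0), end = integer(0))
  }
  gene_models(genes, cds)
}

#' Classify Helitron insertions against gene annotation
#'
#' Assigns each candidate to exactly one category from the position of its
#' 3' terminus: `CDS` when it falls inside a CDS interval, `intron/UTR`
#' when inside a gene span but outside CDS, otherwise `intergenic`. Genes
#' on either strand count. Candidates on sequences absent from the
#' annotation are typed intergenic with a warning.
#'
#' @param candidates Candidates from [scan_genome()] (needs `id`, `seqid`,
#'   `end3_pos`).
#' @param genes A [gene_models] object.
#' @return Data frame: `candidate_id`, `category`, `host_gene_id` (empty
#'   for intergenic; ties broken by lexicographic gene id).
#' @export
classify_insertions <- function(candidates, genes) {
  stopifnot(inherits(genes, "gene_models"))
  d <- candidates
  n <- nrow(d)
  unknown <- !(d$seqid %in% genes$genes$seqid)
  if (any(unknown))
    warning(sum(unknown), " candidate(s) on sequences absent from the ",
            "annotation; typed intergenic")
  cat_out <- rep("intergenic", n)
  host <- rep("", n)
  if (n) {
    pts <- GenomicRanges::GRanges(d$seqid,
                                  IRanges::IRanges(d$end3_pos, d$end3_pos))
    gg <- GenomicRanges::GRanges(genes$genes$seqid,
                                 IRanges::IRanges(genes$genes$start,
                                                  genes$genes$end))
    hit_g <- suppressWarnings(
      GenomicRanges::findOverlaps(pts, gg, ignore.strand = TRUE))
    if (length(hit_g)) {
      qh <- S4Vectors::queryHits(hit_g)
      ids <- genes$genes$gene_id[S4Vectors::subjectHits(hit_g)]
      best <- tapply(ids, qh, function(v) sort(v)[1L])
      idx <- as.integer(names(best))
      cat_out[idx] <- "intron/UTR"
      host[idx] <- unname(best)
    }
    if (nrow(genes$cds)) {
      cc <- GenomicRanges::GRanges(genes$cds$seqid,
                                   IRanges::IRanges(genes$cds$start,
                                                    genes$cds$end))
      hit_c <- suppressWarnings(
        GenomicRanges::findOverlaps(pts, cc, ignore.strand = TRUE))
      if (length(hit_c)) {
        qh <- S4Vectors::queryHits(hit_c)
        ids <- genes$cds$gene_id[S4Vectors::subjectHits(hit_c)]
        best <- tapply(ids, qh, function(v) sort(v)[1L])
        idx <- as.integer(names(best))
        cat_out[idx] <- "CDS"
        host[idx] <- unname(best)
      }
    }
  }
  data.frame(candidate_id = d$id, category = cat_out, host_gene_id = host,
             stringsAsFactors = FALSE)
}

#' Summarize insertion categories
#'
#' @param calls Output of [classify_insertions()].
#' @return Data frame with one row per category (`CDS`, `intron/UTR`,
#'   `intergenic`): `n` and `percent` (percentages sum to 100). For an
#'   empty input all counts are zero and attribute `empty` is set.
#' @export
insertion_summary <- function(calls) {
  cats <- c("CDS", "intron/UTR", "intergenic")
  n <- vapply(cats, function(k) sum(calls$category == k), integer(1))
  tot <- sum(n)
  out <- data.frame(category = cats, n = n,
                    percent = if (tot) 100 * n / tot else rep(0, 3),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!tot) attr(out, "empty") <- TRUE
  out
}

#' Nearest gene downstream of each 3' terminus
#'
#' For each candidate, the first gene whose span starts at or after the 3'
#' end position on the forward strand of the assembly, within
#' `max_distance` bases. Used to derive locus (LOC) markers that are
#' comparable across assemblies of different ecotypes.
#'
#' @param candidates Candidates from [scan_genome()].
#' @param genes A [gene_models] object.
#' @param max_distance Maximum distance from the 3' end to the gene start.
#' @return Character vector of marker gene ids (`""` when no gene
#'   qualifies), one per candidate.
#' @export
nearest_downstream_gene <- function(candidates, genes, max_distance = 500) {
  stopifnot(inherits(genes, "gene_models"))
  g <- genes$genes[order(genes$genes$seqid, genes$genes$start), , drop = FALSE]
  out <- character(nrow(candidates))
  for (sq in unique(candidates$seqid)) {
    gi <- which(g$seqid == sq)
    ci <- which(candidates$seqid == sq)
    if (!length(gi)) next
    starts <- g$start[gi]
    for (i in ci) {
      pos <- candidates$end3_pos[i]
      j <- which(starts >= pos & starts - pos <= max_distance)
      if (length(j)) out[i] <- g$gene_id[gi[j[1L]]]
    }
  }
  out
}

#' Build a locus presence/absence matrix across ecotypes
#'
#' Takes, per ecotype, the set of nearest-downstream-gene markers of its
#' Helitrons, forms the union of marker genes, assigns locus ids
#' (`LOC001`, ...) in sorted gene-id order and records presence (1) or
#' absence (0) of each locus in each ecotype. A locus is polymorphic when
#' its presence vector is neither all 0 nor all 1; all-1 rows are the loci
#' shared by every ecotype.
#'
#' @param marker_sets Named list (>= 2 ecotypes) of character vectors of
#'   marker gene ids.
#' @return Data frame: `loc_id`, `marker_gene_id`, one 0/1 column per
#'   ecotype, and `polymorphic`.
#' @export
build_loc_matrix <- function(marker_sets) {
  stopifnot(is.list(marker_sets), length(marker_sets) >= 2L,
            !is.null(names(marker_sets)))
  sets <- lapply(marker_sets, function(s) unique(s[nzchar(s)]))
  all_genes <- sort(unique(unlist(sets)))
  pres <- vapply(sets, function(s) as.integer(all_genes %in% s),
                 integer(length(all_genes)))
  pres <- matrix(pres, nrow = length(all_genes),
                 dimnames = list(NULL, names(sets)))
  out <- data.frame(loc_id = sprintf("LOC%03d", seq_along(all_genes)),
                    marker_gene_id = all_genes, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pres))
  rs <- rowSums(pres)
  out$polymorphic <- rs > 0 & rs < length(sets)
  out
}
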