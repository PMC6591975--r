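# Independent brute-force oracles, written against the rules directly and
# kept free of the package's scanning code paths (only reverse_complement is
# cross-checked against Biostrings).

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1L]]
.is_acgt <- function(ch) ch %in% c("A", "C", "G", "T")
.is_s <- function(ch) ch %in% c("G", "C")
.comp <- c(A = "T", C = "G", G = "C", T = "A")

# arm admissibility on ch[a..b]
.arm_ok <- function(ch, a, b, gc_min) {
  v <- ch[a:b]
  all(.is_acgt(v)) && .is_s(v[1L]) && .is_s(v[length(v)]) &&
    sum(.is_s(v)) >= ceiling(gc_min * length(v) - 1e-9)
}

# all admissible hairpins with right arm ending at re (inclusive, 1-based)
.hairpins_ending_at <- function(ch, re, p) {
  out <- list()
  for (L in p$arm_min:p$arm_max) {
    rs <- re - L + 1L
    if (rs < 1L) next
    if (!.arm_ok(ch, rs, re, p$gc_min)) next
    for (loop in 0:p$loop_max) {
      le <- rs - loop - 1L
      ls <- le - L + 1L
      if (ls < 1L) next
      if (loop > 0 && !all(.is_acgt(ch[(le + 1L):(rs - 1L)]))) next
      left <- ch[ls:le]
      right <- ch[rs:re]
      if (!all(.is_acgt(left))) next
      if (!identical(paste(left, collapse = ""),
                     oracle_revcomp(paste(right, collapse = ""))))
        next
      out[[length(out) + 1L]] <- c(ls = ls, le = le, loop = loop,
                                   rs = rs, re = re, L = L)
    }
  }
  out
}

.motif_hit <- function(ch, i, fuzzy) {
  n <- length(ch)
  if (i + 3L > n) return(FALSE)
  if (ch[i] != "C" || ch[i + 1L] != "T") return(FALSE)
  a <- ch[i + 2L]; b <- ch[i + 3L]
  switch(as.character(fuzzy),
         "0" = a == "A" && b == "G" && i + 4L <= n && ch[i + 4L] == "T",
         "1" = a == "A" && b == "G",
         "2" = a %in% c("A", "G") && b %in% c("A", "G"),
         "3" = .is_acgt(a) && .is_acgt(b))
}

# full enumeration on one scanned strand; returns scanned-strand 1-based rows
.oracle_strand <- function(s, p) {
  ch <- .chars(s)
  n <- length(ch)
  rows <- list()
  for (i in seq_len(max(n - 3L, 0L))) {
    if (!.motif_hit(ch, i, p$fuzzy_level)) next
    hits <- list()
    for (sp in p$spacer_min:p$spacer_max) {
      re <- i - sp - 1L  # right arm end = motif start - spacer - 1
      if (re < 1L) next
      if (sp > 0 && !all(.is_acgt(ch[(re + 1L):(i - 1L)]))) next
      hp <- .hairpins_ending_at(ch, re, p)
      for (h in hp) hits[[length(hits) + 1L]] <- c(h, sp = sp)
    }
    if (!length(hits)) next
    m <- do.call(rbind, hits)
    # tie-break: min spacer, then max arm, then min loop
    m <- m[order(m[, "sp"], -m[, "L"], m[, "loop"]), , drop = FALSE]
    best <- m[1L, ]
    rows[[length(rows) + 1L]] <-
      data.frame(e3 = i + 3L, ls = best[["ls"]], le = best[["le"]],
                 loop = best[["loop"]], rs = best[["rs"]], re = best[["re"]])
  }
  if (!length(rows))
    return(data.frame(e3 = integer(0), ls = integer(0), le = integer(0),
                      loop = integer(0), rs = integer(0), re = integer(0)))
  do.call(rbind, rows)
}

# both strands, mapped to forward 1-based coordinates like the scanner
oracle_termini <- function(s, p) {
  n <- nchar(s)
  fw <- .oracle_strand(s, p)
  fw <- data.frame(strand = rep("+", nrow(fw)), end3_pos = fw$e3,
                   hp_left_start = fw$ls, hp_left_end = fw$le,
                   loop_len = fw$loop, hp_right_start = fw$rs,
                   hp_right_end = fw$re)
  rv <- .oracle_strand(oracle_revcomp(s), p)
  rv <- data.frame(strand = rep("-", nrow(rv)),
                   end3_pos = n - rv$e3 + 1L,
                   hp_left_start = n - rv$le + 1L,
                   hp_left_end = n - rv$ls + 1L,
                   loop_len = rv$loop,
                   hp_right_start = n - rv$re + 1L,
                   hp_right_end = n - rv$rs + 1L)
  out <- rbind(fw, rv)
  out <- out[order(out$end3_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive 5' TC scan on the scanned strand for a single '+' candidate
oracle_five_prime <- function(s, hp_left_start, end3_pos, window) {
  ch <- .chars(s)
  lo <- max(1L, end3_pos - window)
  hits <- integer(0)
  p <- hp_left_start - 1L
  while (p >= lo) {
    if (p + 1L <= length(ch) && ch[p] == "T" && ch[p + 1L] == "C")
      hits <- c(hits, p)
    p <- p - 1L
  }
  hits
}

# random test sequence with controllable GC content
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# direct-count rule miner over a transaction item matrix (antecedents of
# size 1 and 2 over locus items, consequent one phenotype item)
oracle_rules <- function(items, ft_items, min_support, min_confidence,
                         min_lift) {
  loc_items <- setdiff(colnames(items), ft_items)
  n <- nrow(items)
  antecedents <- c(as.list(loc_items), {
    prs <- list()
    if (length(loc_items) >= 2L)
      for (a in seq_along(loc_items))
        for (b in seq_along(loc_items))
          if (a < b &&
              sub("=[01]$", "", loc_items[a]) !=
              sub("=[01]$", "", loc_items[b]))
            prs[[length(prs) + 1L]] <- c(loc_items[a], loc_items[b])
    prs
  })
  rows <- list()
  for (a in antecedents) {
    for (cns in ft_items) {
      n_a <- 0L; n_ac <- 0L; n_c <- 0L
      for (t in seq_len(n)) {
        in_a <- all(items[t, a])
        in_c <- items[t, cns]
        if (in_a) n_a <- n_a + 1L
        if (in_c) n_c <- n_c + 1L
        if (in_a && in_c) n_ac <- n_ac + 1L
      }
      if (n_a == 0L) next
      supp <- n_ac / n
      conf <- n_ac / n_a
      lift <- conf / (n_c / n)
      if (supp > min_support && conf > min_confidence && lift > min_lift)
        rows[[length(rows) + 1L]] <-
          data.frame(antecedent = paste(sort(a), collapse = ","),
                     consequent = cns, support = supp, confidence = conf,
                     lift = lift)
    }
  }
  if (!length(rows))
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$lift, -out$support, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  out
}
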