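#' Build a transaction set from a locus matrix and a phenotype
#'
#' Materializes, per ecotype, one item per locus state (`LOC006=1` when the
#' locus is present, `LOC006=0` when absent -- absence items are explicit so
#' rule mining sees both states) plus exactly one phenotype item
#' (`FT=<class>`).
#'
#' @param presence Ecotype x locus 0/1 matrix (ecotypes in rows, locus ids
#'   as column names), or the data frame from [build_loc_matrix()] (loci in
#'   rows; it is transposed internally).
#' @param phenotype Character/factor vector of phenotype classes, one per
#'   ecotype, in the ecotype order of `presence`.
#' @return An object of class `transaction_set`: a logical item matrix
#'   (transactions x items) with the phenotype classes as attribute.
#' @export
as_transactions <- function(presence, phenotype) {
  if (is.data.frame(presence) && all(c("loc_id", "marker_gene_id") %in%
                                     names(presence))) {
    eco <- setdiff(names(presence), c("loc_id", "marker_gene_id",
                                      "polymorphic"))
    m <- t(as.matrix(presence[, eco]))
    colnames(m) <- presence$loc_id
    presence <- m
  }
  presence <- as.matrix(presence)
  if (is.null(colnames(presence)))
    colnames(presence) <- sprintf("LOC%03d", seq_len(ncol(presence)))
  if (length(phenotype) != nrow(presence))
    stop("phenotype must have one class per ecotype (schema error)")
  if (anyNA(phenotype)) stop("phenotype classes may not be missing")
  phenotype <- as.character(phenotype)
  cls <- unique(phenotype)
  items <- cbind(presence == 1, presence == 0)
  colnames(items) <- c(paste0(colnames(presence), "=1"),
                       paste0(colnames(presence), "=0"))
  ft <- vapply(cls, function(k) phenotype == k,
               logical(length(phenotype)))
  ft <- matrix(ft, nrow = length(phenotype),
               dimnames = list(NULL, paste0("FT=", cls)))
  out <- cbind(items, ft)
  structure(out, class = c("transaction_set", class(out)),
            phenotype_items = paste0("FT=", cls))
}

#' Mine association rules between loci and a phenotype
#'
#' Exhaustive enumeration of rules `{antecedent} -> {FT=<class>}` with
#' antecedents of one or two locus items (an apriori search with
#' `maxlen = 3` counting the consequent). Metrics are the usual ones:
#' support = P(antecedent and consequent), confidence = support /
#' P(antecedent), lift = confidence / P(consequent). A rule is kept only
#' when it strictly exceeds all three thresholds.
#'
#' @param transactions A [as_transactions()] object.
#' @param min_support,min_confidence,min_lift Strict lower bounds.
#' @param maxlen Maximum rule length including the consequent (2 or 3).
#' @return Data frame sorted by (lift desc, support desc, antecedent):
#'   `antecedent` (items joined by `,`), `consequent`, `support`,
#'   `confidence`, `lift`.
#' @export
mine_rules <- function(transactions, min_support = 0.1,
                       min_confidence = 0.8, min_lift = 1.1, maxlen = 3) {
  stopifnot(inherits(transactions, "transaction_set"), maxlen %in% 2:3)
  items <- unclass(transactions)
  ft_items <- attr(transactions, "phenotype_items")
  loc_items <- setdiff(colnames(items), ft_items)
  n <- nrow(items)
  if (n < 2L) stop("need at least two transactions")
  p_cons <- colMeans(items[, ft_items, drop = FALSE])

  ante_list <- as.list(loc_items)
  if (maxlen >= 3L && length(loc_items) >= 2L) {
    # pairs of items from distinct loci (same-locus pairs have support 0)
    locus_of <- sub("=[01]$", "", loc_items)
    idx <- utils::combn(seq_along(loc_items), 2L)
    keep <- locus_of[idx[1L, ]] != locus_of[idx[2L, ]]
    idx <- idx[, keep, drop = FALSE]
    ante_list <- c(ante_list,
                   lapply(seq_len(ncol(idx)), function(j)
                     loc_items[idx[, j]]))
  }

  rows <- vector("list", length(ante_list) * length(ft_items))
  r <- 0L
  for (a in ante_list) {
    in_a <- if (length(a) == 1L) items[, a] else
      items[, a[1L]] & items[, a[2L]]
    p_a <- mean(in_a)
    if (p_a == 0) next
    for (cns in ft_items) {
      supp <- mean(in_a & items[, cns])
      conf <- supp / p_a
      lift <- conf / p_cons[[cns]]
      if (supp > min_support && conf > min_confidence && lift > min_lift) {
        r <- r + 1L
        rows[[r]] <- data.frame(antecedent = paste(sort(a), collapse = ","),
                                consequent = cns, support = supp,
                                confidence = conf, lift = lift,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (r) do.call(rbind, rows[seq_len(r)]) else
    data.frame(antecedent = character(0), consequent = character(0),
               support = numeric(0), confidence = numeric(0),
               lift = numeric(0))
  out <- out[order(-out$lift, -out$support, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loci with passing rules for both presence and absence
#'
#' Extracts, from a mined rule set, the loci for which both the `=1` and
#' the `=0` single-item rule pass all filters (possibly toward different
#' phenotype classes).
#'
#' @param rules Output of [mine_rules()].
#' @return Data frame with one row per paired locus: `locus`,
#'   `consequent_absent`, `consequent_present`, and the support /
#'   confidence / lift of each side (`*_0`, `*_1`).
#' @export
paired_rules <- function(rules) {
  single <- rules[!grepl(",", rules$antecedent), , drop = FALSE]
  st <- sub("^.*=", "", single$antecedent)
  locus <- sub("=[01]$", "", single$antecedent)
  have0 <- unique(locus[st == "0"])
  have1 <- unique(locus[st == "1"])
  both <- sort(intersect(have0, have1))
  rows <- lapply(both, function(l) {
    r0 <- single[locus == l & st == "0", ][1L, ]
    r1 <- single[locus == l & st == "1", ][1L, ]
    data.frame(locus = l,
               consequent_absent = r0$consequent,
               consequent_present = r1$consequent,
               support_0 = r0$support, confidence_0 = r0$confidence,
               lift_0 = r0$lift,
               support_1 = r1$support, confidence_1 = r1$confidence,
               lift_1 = r1$lift, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(locus = character(0), consequent_absent = character(0),
                      consequent_present = character(0), support_0 = numeric(0),
                      confidence_0 = numeric(0), lift_0 = numeric(0),
                      support_1 = numeric(0), confidence_1 = numeric(0),
                      lift_1 = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
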