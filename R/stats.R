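#' Helitron density
#'
#' Number of distinct 3' termini divided by genome size in Mb (units:
#' Helitrons per Mb). Genome size counts all bases, N included.
#'
#' @param count Number of 3' termini (non-negative).
#' @param size_mb Genome size in Mb (> 0).
#' @return Density in Helitrons per Mb.
#' @examples
#' helitron_density(665, 121)   # 5.4959
#' @export
helitron_density <- function(count, size_mb) {
  if (any(size_mb <= 0)) stop("genome size must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / size_mb
}

#' Mean, standard deviation and coefficient of variation
#'
#' @param values Numeric vector, length >= 2.
#' @param population Use the population (n) divisor instead of the sample
#'   (n-1) divisor. Sample SD is the default; some published dispersion
#'   figures for these genome tables use the n divisor, so it is exposed.
#' @return A list with `mean`, `sd` and `cv` (percent).
#' @examples
#' dispersion(c(7.3599, 7.239))$cv   # 1.17 %
#' @export
dispersion <- function(values, population = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  s <- sd(values)
  if (population) s <- s * sqrt((length(values) - 1) / length(values))
  if (m == 0) stop("CV undefined: mean is zero")
  list(mean = m, sd = s, cv = 100 * s / m)
}

#' Pearson correlation with BCa bootstrap interval
#'
#' Product-moment correlation with the usual t-distribution p value and
#' Fisher-z confidence interval, plus a seeded nonparametric bootstrap:
#' pairs are resampled `n_boot` times, the BCa interval of r is taken, and a
#' two-sided bootstrap p value is computed as twice the smaller tail
#' fraction of resampled r values at or across zero.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, no missing values.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @param conf Confidence level.
#' @return A list: `r`, `p`, `conf_int` (Fisher-z), `bca` (bootstrap BCa
#'   interval), `boot_p`, `n_boot`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 1000, seed = 1234, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant vector")
  ct <- cor.test(x, y, method = "pearson", conf.level = conf)
  dat <- data.frame(x = x, y = y)
  stat <- function(d, i) {
    xi <- d$x[i]; yi <- d$y[i]
    if (sd(xi) == 0 || sd(yi) == 0) return(NA_real_)
    cor(xi, yi)
  }
  set.seed(seed)
  b <- boot::boot(dat, stat, R = n_boot)
  bca <- tryCatch({
    # small samples put the BCa endpoints on extreme order statistics, and
    # degenerate resamples (all r identical) make boot print a notice; both
    # are uninformative here
    log <- utils::capture.output(
      ci <- suppressWarnings(boot::boot.ci(b, conf = conf, type = "bca")))
    if (is.null(ci)) c(NA_real_, NA_real_) else ci$bca[1L, 4:5]
  }, error = function(e) c(NA_real_, NA_real_))
  t0 <- b$t[!is.na(b$t)]
  boot_p <- min(1, 2 * min(mean(t0 <= 0), mean(t0 >= 0)))
  list(r = unname(ct$estimate), p = ct$p.value,
       conf_int = unname(ct$conf.int), bca = unname(bca),
       boot_p = boot_p, n_boot = n_boot)
}

#' Sliding-window Helitron and gene densities
#'
#' Tiles every sequence with windows of `window` bases advancing by `step`
#' (the last partial window is retained) and counts, per window, Helitron 3'
#' termini and gene starts falling inside it. A feature belongs to a window
#' when its representative point (Helitron: `end3_pos`; gene: `start`) lies
#' in `[window_start, window_end]`; because windows overlap, a feature can
#' be counted in up to `window/step` windows.
#'
#' @param candidates Candidates from [scan_genome()], or any data frame with
#'   `seqid` and `end3_pos`.
#' @param genes Data frame with `seqid` and `start` (gene starts), a
#'   [gene_models] object, or `NULL`.
#' @param seq_lengths Named vector of sequence lengths.
#' @param window,step Window and step size in bases.
#' @return Data frame: `seqid`, `window_start`, `window_end`,
#'   `n_helitrons`, `n_genes`.
#' @export
sliding_windows <- function(candidates, genes, seq_lengths,
                            window = 1e6, step = 5e5) {
  stopifnot(window >= 1, step >= 1, !is.null(names(seq_lengths)))
  if (inherits(genes, "gene_models")) genes <- genes$genes
  rows <- lapply(names(seq_lengths), function(sq) {
    len <- seq_lengths[[sq]]
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window - 1, len)
    hp <- candidates$end3_pos[candidates$seqid == sq]
    gs <- if (is.null(genes)) integer(0) else genes$start[genes$seqid == sq]
    data.frame(seqid = sq, window_start = starts, window_end = ends,
               n_helitrons = vapply(seq_along(starts), function(i)
                 sum(hp >= starts[i] & hp <= ends[i]), integer(1)),
               n_genes = vapply(seq_along(starts), function(i)
                 sum(gs >= starts[i] & gs <= ends[i]), integer(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify genomes by species group from (genome size, Helitron density)
#'
#' Classic linear discriminant analysis (pooled within-class covariance,
#' class-proportional priors) on the two genome characteristics, as used to
#' assign de novo assemblies to a species group.
#'
#' @param train Data frame with `genome_size`, `density` and `group` (the
#'   class label; at least two classes, each non-empty).
#' @param newdata Data frame with `genome_size` and `density` to classify;
#'   defaults to the training rows (self-prediction).
#' @return A list: `class` (predicted labels, character), `posterior`
#'   (matrix), `model` (the underlying fit).
#' @export
lda_classify <- function(train, newdata = train) {
  need <- c("genome_size", "density")
  stopifnot(all(need %in% names(train)), all(need %in% names(newdata)),
            "group" %in% names(train))
  grp <- factor(train$group, levels = unique(train$group))
  if (nlevels(grp) < 2L) stop("need at least two classes to train")
  if (any(table(grp) < 1L)) stop("every class needs at least one row")
  fit <- tryCatch(
    MASS::lda(x = train[, need], grouping = grp),
    error = function(e)
      stop("degenerate model (singular pooled covariance?): ",
           conditionMessage(e), "; consider jittering the features"))
  pr <- predict(fit, newdata[, need])
  list(class = as.character(pr$class), posterior = pr$posterior, model = fit)
}

#' Median-linkage clustering of genome features
#'
#' Hierarchical agglomeration with the median (WPGMC) linkage on the
#' Euclidean distance over (genome size, Helitron density).
#'
#' @param rows Data frame with `genome`, `genome_size`, `density`.
#' @param features Feature columns used for the distance.
#' @return An `hclust` object labelled by `genome`.
#' @export
median_cluster <- function(rows, features = c("genome_size", "density")) {
  stopifnot(all(features %in% names(rows)), nrow(rows) >= 2L)
  m <- as.matrix(rows[, features])
  rownames(m) <- if (!is.null(rows$genome)) rows$genome else
    as.character(seq_len(nrow(rows)))
  hclust(dist(m), method = "median")
}

#' Chi-square test of insertion-site counts against genome composition
#'
#' Pearson chi-square of observed Helitron insertion counts per category
#' (CDS, intron/UTR, intergenic) against expected counts proportional to
#' the genomic fraction of each category.
#'
#' @param observed Named non-negative counts per category.
#' @param expected_fractions Fractions of the genome per category; must sum
#'   to 1 and be positive.
#' @return The `htest` object from [stats::chisq.test()].
#' @export
chisq_insertion_test <- function(observed, expected_fractions) {
  stopifnot(length(observed) == length(expected_fractions))
  if (any(expected_fractions <= 0))
    stop("expected fractions must be positive (zero expected cell)")
  if (abs(sum(expected_fractions) - 1) > 1e-8)
    stop("expected fractions must sum to 1")
  suppressWarnings(chisq.test(x = observed, p = expected_fractions))
}
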