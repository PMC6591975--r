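test_that("density arithmetic matches the published genome tables", {
  expect_equal(round(helitron_density(665, 121), 4), 5.4959)
  expect_equal(round(helitron_density(7056, 314.2), 4), 22.4570)
  expect_equal(helitron_density(0, 100), 0)
  expect_error(helitron_density(10, 0), "positive")
  expect_error(helitron_density(-1, 10), "non-negative")
})

test_that("dispersion reproduces the published CVs of density pairs", {
  expect_equal(round(dispersion(c(7.3599, 7.2390))$cv, 2), 1.17)
  d <- dispersion(c(13.7903, 14.0141))
  expect_equal(round(d$sd, 2), 0.16)
  expect_equal(round(d$cv, 2), 1.14)
  expect_equal(dispersion(c(5, 5, 5))$sd, 0)
  expect_equal(dispersion(c(5, 5, 5))$cv, 0)
  expect_error(dispersion(5), "two values")
  expect_error(dispersion(c(-1, 1)), "mean is zero")
  # population divisor reduces the sample SD by sqrt((n-1)/n)
  v <- c(1, 4, 9, 16)
  expect_equal(dispersion(v, population = TRUE)$sd,
               sd(v) * sqrt(3 / 4))
})

test_that("pearson_bootstrap matches the closed form and is seed-stable", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.2, 2.9, 5.1, 6.8, 12.3)
  res <- pearson_bootstrap(x, y, n_boot = 200, seed = 99)
  # direct formula oracle
  mx <- mean(x); my <- mean(y)
  r_hand <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t_hand <- r_hand * sqrt((length(x) - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(x) - 2)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # identical seed, identical BCa bounds
  res2 <- pearson_bootstrap(x, y, n_boot = 200, seed = 99)
  expect_identical(res$bca, res2$bca)
  expect_identical(res$boot_p, res2$boot_p)
  # exact linear relation: r = 1
  ylin <- 2 * x
  expect_equal(pearson_bootstrap(x, ylin, n_boot = 50, seed = 1)$r, 1)
  expect_error(pearson_bootstrap(x, rep(3, 5)), "constant")
})

test_that("sliding windows advance by step and keep the last partial window", {
  cand <- data.frame(seqid = "chr1", end3_pos = 1200000L)
  win <- sliding_windows(cand, NULL, c(chr1 = 2e6))
  expect_equal(win$window_start, c(1, 500001, 1000001, 1500001))
  expect_equal(win$window_end, c(1e6, 15e5, 2e6, 2e6))
  hit <- win$window_start[win$n_helitrons > 0]
  expect_equal(hit, c(500001, 1000001))
  # empty genome: rows exist, all counts zero
  win0 <- sliding_windows(cand[0, ], NULL, c(chr1 = 2e6))
  expect_equal(sum(win0$n_helitrons), 0L)
  expect_equal(nrow(win0), 4L)
  # anti-correlated fixture: genes in the left half, Helitrons in the right
  genes <- data.frame(seqid = "chr1", start = seq(1e4, 9e5, by = 2e4))
  helis <- data.frame(seqid = "chr1",
                      end3_pos = seq(1.1e6, 1.95e6, by = 2e4))
  w <- sliding_windows(helis, genes, c(chr1 = 2e6))
  expect_lt(cor(w$n_genes, w$n_helitrons), 0)
})

test_that("LDA agrees with a nearest-centroid oracle on separated classes", {
  set.seed(31)
  tr <- data.frame(
    genome_size = c(rnorm(20, 120, 2), rnorm(20, 400, 2)),
    density = c(rnorm(20, 5, 0.1), rnorm(20, 14, 0.1)),
    group = rep(c("small", "big"), each = 20))
  te <- data.frame(genome_size = c(118, 402, 130, 390),
                   density = c(5.1, 13.8, 4.8, 14.2))
  fit <- lda_classify(tr, te)
  centroid <- function(g) colMeans(tr[tr$group == g, 1:2])
  pred_nc <- vapply(seq_len(nrow(te)), function(i) {
    d <- vapply(c("small", "big"), function(g)
      sum((unlist(te[i, 1:2]) - centroid(g))^2), numeric(1))
    names(which.min(d))
  }, character(1))
  expect_equal(fit$class, unname(pred_nc))
  # single-class training is rejected
  expect_error(lda_classify(transform(tr, group = "one")), "two classes")
})

test_that("median-linkage clustering follows hand agglomeration", {
  two <- data.frame(genome = c("a", "b"), genome_size = c(0, 3),
                    density = c(0, 4))
  h2 <- median_cluster(two)
  expect_equal(h2$height, 5)  # single merge at the Euclidean distance
  # three collinear 1-D points 0, 1, 10: first merge is {0, 1}
  three <- data.frame(genome = c("p", "q", "r"),
                      genome_size = c(0, 1, 10), density = 0)
  h3 <- median_cluster(three)
  expect_equal(sort(h3$merge[1, ]), c(-2, -1))
  # permuting the input preserves the topology (cophenetic distances)
  perm <- three[c(3, 1, 2), ]
  hp <- median_cluster(perm)
  co1 <- as.matrix(stats::cophenetic(h3))
  co2 <- as.matrix(stats::cophenetic(hp))
  expect_equal(co1[rownames(co2), colnames(co2)], co2)
})

test_that("chi-square insertion test against genomic fractions", {
  # observed exactly proportional to expected
  r0 <- chisq_insertion_test(c(CDS = 10, `intron/UTR` = 20,
                               intergenic = 70), c(0.1, 0.2, 0.7))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)
  # hand formula
  obs <- c(CDS = 10, `intron/UTR` = 10, intergenic = 80)
  exp_frac <- rep(1 / 3, 3)
  r1 <- chisq_insertion_test(obs, exp_frac)
  e <- sum(obs) * exp_frac
  expect_equal(unname(r1$statistic), sum((obs - e)^2 / e))
  expect_equal(unname(r1$parameter), 2)
  # strongly skewed fixture is significant far below 1e-4
  r2 <- chisq_insertion_test(c(CDS = 60, `intron/UTR` = 20, intergenic = 20),
                             c(0.02, 0.05, 0.93))
  expect_lt(r2$p.value, 1e-4)
  expect_error(chisq_insertion_test(obs, c(0, 0.5, 0.5)), "positive")
  expect_error(chisq_insertion_test(obs, c(0.2, 0.2, 0.2)), "sum to 1")
})
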