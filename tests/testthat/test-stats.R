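test_that("significance tiers match the caption bands on boundaries", {
  expect_equal(p_tier(c(0.06, 0.05, 0.011, 0.01, 0.001, 0.0001, 1e-6)),
               c("ns", "*", "*", "**", "***", "****", "****"))
  expect_equal(p_tier(0.0011), "**")
})

test_that("Student's t handles identical, degenerate and separated samples", {
  x <- c(1, 2, 3, 4)
  res <- student_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  const <- student_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)
  deg <- student_t(c(2, 2, 2), c(3, 3, 3))
  expect_true(is.infinite(deg$statistic))
  expect_true(deg$p_value < 1e-100)

  set.seed(4)
  big <- student_t(rnorm(1000, 0), rnorm(1000, 2))
  expect_lt(big$p_value, 1e-4)
  expect_equal(big$tier, "****")
  expect_error(student_t(1, c(1, 2)), "n >= 2")

  # matches stats::t.test in both pooled and Welch forms
  y <- c(2, 4, 4.5, 7, 1)
  expect_equal(student_t(x, y)$p_value,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(student_t(x, y, pooled = FALSE)$p_value,
               t.test(x, y)$p.value)
})

test_that("t-test p-values are uniform under the null", {
  set.seed(101)
  ps <- replicate(1000, student_t(rnorm(10), rnorm(10))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("one-way ANOVA matches F = t^2 and detects planted shifts", {
  set.seed(6)
  x <- rnorm(15); y <- rnorm(15)
  a <- one_way_anova(list(x, y))
  t2 <- student_t(x, y)$statistic^2
  expect_equal(a$statistic, t2, tolerance = 1e-9)
  expect_equal(a$group_stats$mean, c(mean(x), mean(y)))

  # power: 3 groups, delta = 1.5 sd, n = 50
  set.seed(7)
  rejections <- mean(replicate(60, {
    g <- list(rnorm(50), rnorm(50), rnorm(50, 1.5))
    one_way_anova(g)$p_value < 0.05
  }))
  expect_gt(rejections, 0.9)

  # zero within-group variance
  inf_f <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(is.infinite(inf_f$statistic))
  expect_true(inf_f$p_value <= .Machine$double.xmin)
  flat <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(flat$p_value, 1)
})

test_that("PCA explains correlated data and reconstructs the input", {
  set.seed(9)
  x <- rnorm(30)
  f2 <- cbind(a = x, b = 2 * x)   # perfectly correlated
  rownames(f2) <- sprintf("s%02d", 1:30)
  p2 <- pca(f2)
  expect_equal(p2$explained_variance[1], 1, tolerance = 1e-12)

  m <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(sprintf("s%02d", 1:40), paste0("f", 1:5)))
  p <- pca(m)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)
  recon <- p$scores %*% t(p$loadings) + rep(1, 40) %o% p$center
  expect_equal(recon, m, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: dominant loading of each component positive
  for (j in 1:5) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("phylogenetic PCA reduces to PCA on a star tree and matches phyl.pca", {
  set.seed(12)
  n <- 16
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- sprintf("s%02d", 1:n)
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(star$tip.label, paste0("f", 1:4)))
  pp <- phylo_pca(m, star)
  p0 <- pca(m)
  expect_equal(pp$scores, p0$scores, tolerance = 1e-8)
  expect_equal(pp$explained_variance, p0$explained_variance, tolerance = 1e-8)

  # non-trivial tree: eigenvalues agree with phytools' BM pPCA
  tr <- ape::rcoal(n)
  tr$tip.label <- rownames(m)
  pp2 <- phylo_pca(m, tr)
  ref <- phytools::phyl.pca(tr, m, method = "BM", mode = "cov")
  expect_equal(pp2$explained_variance,
               diag(ref$Eval) / sum(diag(ref$Eval)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # permutation equivariance of score rows
  perm <- sample(n)
  pp3 <- phylo_pca(m[perm, ], tr)
  expect_equal(abs(pp3$scores), abs(pp2$scores[perm, ]), tolerance = 1e-8)
})

test_that("PERMANOVA pseudo-F matches direct sums of squares and vegan", {
  set.seed(15)
  pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 3), 10))
  rownames(pts) <- sprintf("s%02d", 1:20)
  d <- as.matrix(dist(pts))
  g <- stats::setNames(rep(c("a", "b"), each = 10), rownames(pts))
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$statistic, permanova_f_direct(d, g), tolerance = 1e-9)
  ref <- vegan::adonis2(as.dist(d) ~ grp,
                        data = data.frame(grp = g), permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-9)

  # planted strong separation: p at the permutation floor
  expect_equal(res$p_value, 1 / 200)
  res999 <- permanova(d, g, n_perm = 999, seed = 2)
  expect_equal(res999$p_value, 0.001)

  expect_error(permanova(d, stats::setNames(c("a", rep("b", 19)), rownames(pts))),
               ">= 2 members")
})

test_that("enrichment scan flags planted effects and marks untestable cells", {
  set.seed(33)
  n <- 50
  ids <- sprintf("s%03d", 1:(4 * n))
  hab <- stats::setNames(rep(c("LA", "SA"), each = 2 * n), ids)
  tax <- stats::setNames(rep(c("K1", "K2", "K1", "K2"), each = n), ids)
  # GH enriched 2x in SA within K1 only; GT flat; PL all zero
  gh_rate <- ifelse(hab == "SA" & tax == "K1", 40, 20)
  m <- cbind(GH = rpois(4 * n, gh_rate), GT = rpois(4 * n, 15),
             PL = rep(0L, 4 * n))
  rownames(m) <- ids
  scan <- enrichment_scan(m, hab, tax)
  planted <- scan[scan$scan == "LA_vs_SA_t" & scan$group == "K1" & scan$class == "GH", ]
  expect_lt(planted$p_value, 0.05)
  expect_false(scan$testable[scan$class == "PL" & scan$scan == "LA_vs_SA_t"][1])
  expect_true(all(is.na(scan$p_value[!scan$testable])))
  # BH column only where testable, raw p retained
  expect_true(all(!is.na(scan$p_bh[scan$testable])))
})
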