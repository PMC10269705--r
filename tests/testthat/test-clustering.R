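test_that("PAM solves the two-blob instance and the degenerate k", {
  d <- dist_1d(c(0, 1, 10, 11), c("a", "b", "c", "d"))
  fit <- pam_cluster(d, 2)
  expect_equal(fit$objective, 2)
  expect_equal(unname(fit$cluster), c(1, 1, 2, 2))

  fit_n <- pam_cluster(d, 4)
  expect_equal(fit_n$objective, 0)
  expect_setequal(fit_n$medoids, c("a", "b", "c", "d"))

  fit_1 <- pam_cluster(d, 1)
  expect_equal(fit_1$medoids, names(which.min(colSums(d))))
  expect_equal(fit_1$objective, min(colSums(d)))

  expect_error(pam_cluster(d, 0), "k must lie")
  expect_error(pam_cluster(d, 5), "k must lie")
})

test_that("PAM output is swap-optimal, matches the reference implementation, and never beats brute force", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    fit <- pam_cluster(d, k)
    # defining property of BUILD+SWAP output: no single medoid exchange improves
    med_idx <- match(fit$medoids, rownames(d))
    for (m in med_idx) {
      for (h in setdiff(seq_len(n), med_idx)) {
        trial <- c(setdiff(med_idx, m), h)
        obj <- sum(apply(d[, trial, drop = FALSE], 1, min))
        expect_gte(obj, fit$objective - 1e-10)
      }
    }
    # agrees with the canonical PAM implementation
    ref <- cluster::pam(stats::as.dist(d), k)
    expect_equal(fit$objective, ref$objective[["swap"]] * n, tolerance = 1e-9)
    # sanity against the exhaustive optimum: a local optimum can never beat it
    expect_gte(fit$objective, brute_pam_objective(d, k) - 1e-10)
    # medoids belong to their own clusters
    expect_true(all(fit$cluster[fit$medoids] == seq_len(k)))
  }
})

test_that("mean silhouette matches the direct formula and its bounds", {
  d <- dist_1d(c(0, 1, 10, 11), c("a", "b", "c", "d"))
  fit <- pam_cluster(d, 2)
  # per-point: (9.5/10.5 + 8.5/9.5 + 8.5/9.5 + 9.5/10.5) / 4
  expect_equal(mean_silhouette(d, fit), (9.5 / 10.5 + 8.5 / 9.5) / 2,
               tolerance = 1e-12)
  expect_error(mean_silhouette(d, pam_cluster(d, 1)), "undefined")

  # all pairwise distances equal -> exactly 0
  deq <- matrix(1, 6, 6) - diag(6)
  dimnames(deq) <- list(letters[1:6], letters[1:6])
  cl <- stats::setNames(rep(1:2, each = 3), letters[1:6])
  expect_equal(mean_silhouette(deq, cl), 0)

  # always within [-1, 1], and agrees with cluster::silhouette
  set.seed(5)
  for (i in 1:10) {
    pts <- rnorm(12)
    d2 <- dist_1d(pts)
    cl2 <- stats::setNames(sample(1:3, 12, replace = TRUE), rownames(d2))
    if (length(unique(cl2)) < 2) next
    s <- mean_silhouette(d2, cl2)
    expect_true(s >= -1 && s <= 1)
    ref <- mean(cluster::silhouette(cl2, stats::as.dist(d2))[, "sil_width"])
    expect_equal(s, ref, tolerance = 1e-10)
  }
})

test_that("silhouette scan recovers the planted number of clusters", {
  recovered <- vapply(1:10, function(s) {
    tr <- simulate_clade_tree(c(8, 8, 8, 8), seed = 100 + s, separation = 4)
    d <- cophenetic_matrix(tr)
    select_k(d, 2, 8, seed = s)$k_best
  }, 0L)
  expect_gte(sum(recovered == 4), 9)

  tr2 <- simulate_clade_tree(c(10, 10), seed = 42, separation = 4)
  expect_equal(select_k(cophenetic_matrix(tr2), 2, 6)$k_best, 2)

  # k_max clipping
  d5 <- dist_1d(c(0, 1, 2, 10, 12))
  expect_warning(res <- select_k(d5, 2, 20), "clipped")
  expect_equal(max(res$curve$k), 4)
})

test_that("complete-linkage clustering splits planted blobs deterministically", {
  set.seed(8)
  f <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 12), 10))
  rownames(f) <- sprintf("s%02d", 1:20)
  colnames(f) <- c("GH", "GT")
  fit <- hclust_complete(f, 2)
  expect_equal(length(unique(fit$cluster[1:10])), 1)
  expect_equal(length(unique(fit$cluster[11:20])), 1)
  expect_false(fit$cluster[1] == fit$cluster[20])
  expect_equal(unique(hclust_complete(f, 1)$cluster), 1L)
  # complete-linkage merge heights are non-decreasing
  expect_true(all(diff(fit$hclust$height) >= -1e-12))
  expect_error(hclust_complete(rbind(f, NA), 2), "non-finite")
})

# strain-level labels reconstructed from the printed cluster-by-habitat table
table1_fixture <- function() {
  counts <- rbind(K1 = c(LA = 174, SA = 95, OA = 16),
                  K2 = c(LA = 4, SA = 34, OA = 40),
                  K3 = c(LA = 9, SA = 66, OA = 33),
                  K4 = c(LA = 8, SA = 88, OA = 6))
  cl <- rep(rep(1:4, times = rowSums(counts)))
  hab <- unlist(lapply(1:4, function(i) rep(colnames(counts), counts[i, ])))
  ids <- sprintf("s%03d", seq_along(cl))
  list(cluster = stats::setNames(cl, ids), habitats = stats::setNames(hab, ids),
       counts = counts)
}

test_that("cluster composition reproduces printed habitat shares", {
  fx <- table1_fixture()
  expect_equal(sum(fx$counts), 573)
  comp <- cluster_composition(fx$cluster, fx$habitats)
  pick <- function(k, h) comp$pct[comp$cluster == k & comp$habitat == h]
  expect_equal(pick(1, "LA"), 61.05)
  expect_equal(pick(1, "SA"), 33.33)
  expect_equal(pick(2, "OA"), 51.28)
  expect_equal(pick(3, "SA"), 61.11)
  expect_equal(pick(4, "SA"), 86.27)
  # shares within each cluster sum to 100 within rounding slack
  sums <- tapply(comp$pct, comp$cluster, sum)
  expect_true(all(abs(sums - 100) <= 0.02))

  single <- cluster_composition(stats::setNames(c(1, 1), c("a", "b")),
                                stats::setNames(c("LA", "LA"), c("a", "b")))
  expect_equal(single$pct[single$n > 0], 100.00)
})

test_that("habitat concordance counts majority-habitat strains over the whole cohort", {
  expect_equal(share_pct(c(168, 251, 81), 573), c(29.32, 43.80, 14.14))

  one <- habitat_concordance(stats::setNames(rep(1, 4), letters[1:4]),
                             stats::setNames(rep("LA", 4), letters[1:4]))
  expect_equal(one$pct, 100)

  # random balanced labels: concordance tracks the majority-rule baseline
  set.seed(13)
  rate <- mean(replicate(40, {
    ids <- sprintf("s%02d", 1:40)
    cl <- stats::setNames(sample(1:2, 40, TRUE), ids)
    hab <- stats::setNames(sample(c("LA", "SA"), 40, TRUE), ids)
    sum(habitat_concordance(cl, hab)$concordant) / 40
  }))
  expect_gt(rate, 0.45)   # majority rule can't fall below half on average
  expect_lt(rate, 0.75)
})
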