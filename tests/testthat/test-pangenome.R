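test_that("partition recovers planted class counts exactly across random configs", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    ids <- sprintf("s%02d", 1:n)
    units <- stats::setNames(paste0("U", sample(1:4, n, TRUE)), ids)
    if (length(unique(units)) < 2) units[1:2] <- c("U1", "U2")
    nc <- sample(1:20, 1); na <- sample(0:30, 1); ns <- sample(0:20, 1)
    m <- simulate_orthogroups(ids, units, nc, na, ns, seed = i)
    part <- partition_pangenome(m, units)
    expect_equal(part$summary$n_core, nc)
    expect_equal(part$summary$n_accessory, na)
    expect_equal(part$summary$n_specific, ns)
    expect_equal(part$class_of[names(attr(m, "truth"))],
                 attr(m, "truth"))
    # classes disjoint and exhaustive by construction of class_of
    expect_equal(sum(table(part$class_of)), ncol(m))
  }
})

test_that("partition is invariant to strain and family permutation", {
  co <- simulate_cohort(small_config(seed = 31))
  m <- co$ortho
  units <- co$truth$unit
  p0 <- partition_pangenome(m, units)
  set.seed(1)
  m2 <- m[sample(nrow(m)), sample(ncol(m))]
  p2 <- partition_pangenome(m2, units)
  expect_equal(p0$summary, p2$summary)
  expect_equal(p0$class_of[colnames(m2)], p2$class_of)
})

test_that("edge families classify by the unit-confinement rule", {
  ids <- c("a", "b", "c", "d")
  units <- stats::setNames(c("U1", "U1", "U2", "U2"), ids)
  m <- matrix(c(1, 1, 1, 1,   # core
                1, 0, 0, 0,   # one strain, one unit -> specific
                1, 1, 0, 0,   # both carriers in U1 -> specific
                1, 0, 1, 0),  # spans two units, not all -> accessory
              4, 4, dimnames = list(ids, c("F1", "F2", "F3", "F4")))
  cls <- partition_pangenome(m, units)$class_of
  expect_equal(unname(cls), c("core", "specific", "specific", "accessory"))
})

test_that("partition shares reproduce printed pan-genome arithmetic", {
  sh <- partition_shares(163, 37784, 21240)
  expect_equal(sh$core_pct, 0.28)
  expect_equal(sh$specific_pct, 35.89)
  expect_equal(163 + 37784 + 21240, 59187)
  expect_equal(partition_shares(1, 0, 0)$core_pct, 100.00)
})

test_that("matched subsampling centres panels on the reference habitat", {
  # SA pool contains a planted outlier clade (x1, x2) on a long stem:
  # the most deviant candidates must be excluded first
  tr <- parse_newick(paste0(
    "((((o1:1,o2:1):1,(o3:1,o4:1):1):1,((s1:1,s2:1):1,(s3:1,s4:1):1):1):1,",
    "(x1:1,x2:1):20);"))
  d <- cophenetic_matrix(tr)
  hab <- stats::setNames(c(rep("OA", 4), rep("SA", 6)),
                         c(paste0("o", 1:4), paste0("s", 1:4), "x1", "x2"))
  sel <- matched_subsample(d, hab, "OA", n_per_group = 4, seed = 1)
  expect_setequal(sel$SA, paste0("s", 1:4))
  expect_setequal(sel$OA, paste0("o", 1:4))

  # n_per_group equal to the pool takes the whole pool
  inner <- c(paste0("o", 1:4), paste0("s", 1:4))
  sel_all <- matched_subsample(d[inner, inner], hab[inner], "OA",
                               n_per_group = 4, seed = 1)
  expect_setequal(sel_all$SA, paste0("s", 1:4))
  expect_error(matched_subsample(d, hab, "OA", n_per_group = 50),
               "exceeds pool size")
  # determinism
  expect_identical(sel, matched_subsample(d, hab, "OA", 4, seed = 1))
})

test_that("matched subsampling reduces variance of mean distance to reference", {
  matched_var <- numeric(20); random_var <- numeric(20)
  for (s in 1:20) {
    tr <- simulate_tree(36, seed = 200 + s, habitat_assortativity = 0)
    hab <- attr(tr, "habitat")
    d <- cophenetic_matrix(tr)
    npg <- min(table(hab)) - 1
    if (npg < 3) next
    sel <- matched_subsample(d, hab, "OA", npg, seed = s)
    ref <- sel$OA
    md <- function(ids) rowMeans(d[ids, ref, drop = FALSE])
    others <- setdiff(names(sel), "OA")
    matched_var[s] <- mean(vapply(others, function(h) var(md(sel[[h]])), 0))
    random_var[s] <- mean(vapply(others, function(h) {
      pool <- rownames(d)[hab == h]
      set.seed(1000 + s)
      var(md(sample(pool, npg)))
    }, 0))
  }
  expect_lt(mean(matched_var), mean(random_var))
})

test_that("family abundance tables report group means, SDs and sizes", {
  ids <- sprintf("s%02d", 1:6)
  m <- matrix(c(2, 2, 2, 4, 4, 4,
                1, 2, 3, 1, 2, 3), 6, 2,
              dimnames = list(ids, c("F1", "F2")))
  grp <- stats::setNames(rep(c("LA", "SA"), each = 3), ids)
  ab <- family_abundance_by_group(m, c("F1", "F2"), grp)
  f1 <- ab[ab$family == "F1", ]
  expect_equal(f1$mean, c(2, 4))
  expect_equal(f1$sd, c(0, 0))
  expect_equal(f1$n, c(3L, 3L))
  # single-strain group: SD reported missing
  grp2 <- stats::setNames(c("LA", rep("SA", 5)), ids)
  ab2 <- family_abundance_by_group(m, "F1", grp2)
  expect_true(is.na(ab2$sd[ab2$group == "LA"]))
  expect_error(family_abundance_by_group(m, "nope", grp), "unknown families")
})
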