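#' Significance tier stars for a p-value
#'
#' Bands: `*` 0.01 < p <= 0.05; `**` 0.001 < p <= 0.01; `***` 0.0001 < p
#' <= 0.001; `****` p <= 0.0001; `ns` p > 0.05.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of tiers.
#' @export
p_tier <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_character_, length(p))
  out[!is.na(p)] <- "ns"
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out[!is.na(p) & p <= 0.0001] <- "****"
  out
}

.stat_result <- function(method, statistic, df, p, n_perm = NA_integer_, extra = NULL) {
  res <- list(method = method, statistic = unname(statistic), df = unname(df),
              p_value = unname(p), n_perm = n_perm, tier = p_tier(p))
  c(res, extra)
}

#' Two-sample Student's t test
#'
#' Two-sided; pooled-variance (classic Student) by default, Welch when
#' `pooled = FALSE`. Degenerate inputs with zero variance in both samples
#' return t = 0, p = 1 when the means are equal, and t = +/-Inf, p ~ 0
#' (flagged `degenerate`) when they differ.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param pooled use the pooled-variance statistic (default TRUE).
#' @return list with method, statistic, df, p_value, tier.
#' @export
student_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) .fail("each sample needs n >= 2")
  if (any(!is.finite(c(x, y)))) .fail("samples must be finite")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(.stat_result("student_t", 0, length(x) + length(y) - 2, 1))
    }
    res <- .stat_result("student_t", sign(mean(x) - mean(y)) * Inf,
                        length(x) + length(y) - 2, .Machine$double.xmin,
                        extra = list(degenerate = TRUE))
    return(res)
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  .stat_result("student_t", tt$statistic, tt$parameter, tt$p.value)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects F test, F = MS_between / MS_within. Group means
#' and SDs are reported alongside for bar-chart style summaries.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return list with method, statistic (F), df (df1, df2), p_value, tier,
#'   and `group_stats` (data.frame of n, mean, sd per group).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) .fail("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) .fail("each group needs n >= 2")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  gs <- data.frame(group = levels(g),
                   n = as.integer(table(g)),
                   mean = vapply(groups, mean, 0),
                   sd = vapply(groups, stats::sd, 0))
  df1 <- nlevels(g) - 1L
  df2 <- length(v) - nlevels(g)
  ss_w <- sum((v - stats::ave(v, g))^2)
  if (ss_w == 0) {
    ss_b <- sum(tapply(v, g, length) * (tapply(v, g, mean) - mean(v))^2)
    if (ss_b == 0) {
      return(.stat_result("anova", 0, c(df1 = df1, df2 = df2), 1,
                          extra = list(group_stats = gs)))
    }
    return(.stat_result("anova", Inf, c(df1 = df1, df2 = df2),
                        .Machine$double.xmin, extra = list(group_stats = gs)))
  }
  a <- stats::anova(stats::lm(v ~ g))
  .stat_result("anova", a$`F value`[1], c(df1 = a$Df[1], df2 = a$Df[2]),
               a$`Pr(>F)`[1], extra = list(group_stats = gs))
}

# flip component signs so the largest-magnitude loading is positive
.fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal-component analysis of a feature table
#'
#' Column-centred SVD (no scaling). Component signs follow the convention
#' that the largest-magnitude loading of each component is positive.
#'
#' @param features strains x classes numeric matrix.
#' @return list with `scores`, `loadings`, `explained_variance` (fractions
#'   summing to 1), and `center`.
#' @export
pca <- function(features) {
  m <- as.matrix(features)
  if (nrow(m) < 2 || ncol(m) < 2) .fail("need >= 2 strains and >= 2 features")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  fixed <- .fix_signs(pc$rotation, pc$x)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = fixed$scores, loadings = fixed$loadings,
       explained_variance = ev, center = pc$center)
}

#' Phylogenetic principal-component analysis
#'
#' PCA corrected for phylogenetic non-independence under a Brownian-motion
#' model: the trait covariance is estimated by generalised least squares
#' with the tree covariance C (C_ij = shared root-to-MRCA path length of
#' tips i and j), i.e. a GLS mean, C^-1-weighted covariance and its
#' eigen-decomposition. For a star phylogeny with unit tip branches C = I
#' and the result equals ordinary [pca()].
#'
#' @param features strains x classes matrix; rownames must match the tree
#'   tips.
#' @param tree `phylo` object over the same strains.
#' @return list with `scores`, `loadings`, `explained_variance`, `center`.
#' @export
phylo_pca <- function(features, tree) {
  m <- as.matrix(features)
  if (!setequal(rownames(m), tree$tip.label)) {
    .fail("feature-table strains and tree tips differ")
  }
  C <- ape::vcv(tree)[rownames(m), rownames(m)]
  Cinv <- tryCatch(solve(C), error = function(e)
    .fail("singular phylogenetic covariance; jitter zero branch lengths"))
  one <- matrix(1, nrow(m), 1)
  a <- solve(t(one) %*% Cinv %*% one) %*% t(one) %*% Cinv %*% m
  Xc <- m - one %*% a
  R <- t(Xc) %*% Cinv %*% Xc / (nrow(m) - 1)
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  scores <- Xc %*% eig$vectors
  colnames(scores) <- colnames(eig$vectors) <- paste0("PC", seq_len(ncol(m)))
  rownames(eig$vectors) <- colnames(m)
  fixed <- .fix_signs(eig$vectors, scores)
  ev <- pmax(eig$values, 0)
  list(scores = fixed$scores, loadings = fixed$loadings,
       explained_variance = ev / sum(ev), center = drop(a))
}

#' PERMANOVA (Adonis) on a distance matrix
#'
#' Anderson's permutational multivariate ANOVA: the squared distance matrix
#' is Gower-centred, the pseudo-F contrasts among-group and within-group
#' sums of squares, and the p-value is the permutation fraction with the +1
#' convention, p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), so the
#' smallest attainable p is 1 / (n_perm + 1) (0.001 at 999 permutations).
#'
#' @param dist symmetric distance matrix.
#' @param labels named vector, strain id -> group; >= 2 groups, each with
#'   >= 2 members.
#' @param n_perm number of label permutations (>= 99), default 999.
#' @param seed integer seed for the permutations.
#' @return list with method, statistic (pseudo-F), df, p_value, n_perm,
#'   tier, and `ss` (among, within, total).
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  g <- factor(labels[rownames(d)])
  if (nlevels(g) < 2) .fail("need >= 2 groups")
  if (any(table(g) < 2)) .fail("every group needs >= 2 members")
  if (n_perm < 99) .fail("n_perm must be >= 99")
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  a <- nlevels(g)
  f_stat <- function(Gm) {
    ss_a <- sum(H * Gm)          # tr(H G); G is centred so intercept drops
    ss_t <- sum(diag(Gm))
    ss_w <- ss_t - ss_a
    (ss_a / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(G)
  ss_a <- sum(H * G); ss_t <- sum(diag(G))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      f_stat(G[p, p]) >= f_obs
    }, NA))
  })
  p <- (1 + exceed) / (1 + n_perm)
  .stat_result("permanova", f_obs, c(df1 = a - 1L, df2 = n - a), p,
               n_perm = as.integer(n_perm),
               extra = list(ss = c(among = ss_a, within = ss_t - ss_a,
                                   total = ss_t)))
}

#' Habitat-enrichment scan over feature classes
#'
#' For every (taxon cluster, feature class): a pooled two-sample Student's
#' t test of LA vs SA strains. For every (habitat, feature class): a
#' one-way ANOVA across taxon clusters. Cells whose groups are too small or
#' whose values are all zero are marked untestable rather than dropped.
#' Raw p-values are primary; a Benjamini-Hochberg column is appended per
#' scan for reuse.
#'
#' @param features strains x classes matrix (raw or per-Mb).
#' @param habitats named vector strain -> habitat (LA/SA/OA).
#' @param taxa named vector strain -> taxon cluster.
#' @return data.frame with columns scan ("LA_vs_SA_t" or
#'   "habitat_anova"), group, class, statistic, p_value, tier, testable,
#'   p_bh.
#' @export
enrichment_scan <- function(features, habitats, taxa) {
  m <- as.matrix(features)
  hab <- habitats[rownames(m)]
  tax <- taxa[rownames(m)]
  rows <- list()
  add <- function(scan, group, class, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      scan = scan, group = group, class = class,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      tier = if (is.null(res)) NA_character_ else res$tier,
      testable = !is.null(res))
  }
  for (t in sort(unique(tax))) {
    for (cls in colnames(m)) {
      x <- m[tax == t & hab == "LA", cls]
      y <- m[tax == t & hab == "SA", cls]
      res <- if (length(x) >= 2 && length(y) >= 2 && any(c(x, y) != 0)) {
        student_t(x, y)
      } else NULL
      add("LA_vs_SA_t", t, cls, res)
    }
  }
  for (h in sort(unique(hab))) {
    for (cls in colnames(m)) {
      gl <- split(m[hab == h, cls], tax[hab == h])
      gl <- gl[vapply(gl, length, 1L) >= 2]
      res <- if (length(gl) >= 2 && any(unlist(gl) != 0)) one_way_anova(gl) else NULL
      add("habitat_anova", h, cls, res)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (s in unique(out$scan)) {
    sel <- out$scan == s & out$testable
    out$p_bh[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out
}
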