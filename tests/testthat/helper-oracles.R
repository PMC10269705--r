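# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# cophenetic distance by walking both root paths and summing the branches
# below the deepest shared ancestor
naive_cophenetic <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- rep(NA_integer_, n + tree$Nnode)
  plen <- rep(NA_real_, n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(i) {
    nodes <- i
    while (!is.na(parent[i])) {
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    nodes
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- path_to_root(i)
    for (j in (i + 1):n) {
      pj <- path_to_root(j)
      shared <- intersect(pi, pj)
      walk <- function(from, stop_at) {
        s <- 0
        while (from != stop_at) {
          s <- s + plen[from]
          from <- parent[from]
        }
        s
      }
      lca <- shared[1]  # paths are ordered leaf -> root; first common node
      for (nd in pi) if (nd %in% pj) { lca <- nd; break }
      d[i, j] <- d[j, i] <- walk(i, lca) + walk(j, lca)
    }
  }
  d
}

# exhaustive PAM optimum: enumerate every medoid subset of size k
brute_pam_objective <- function(d, k) {
  n <- nrow(d)
  sets <- utils::combn(n, k)
  best <- Inf
  for (s in seq_len(ncol(sets))) {
    obj <- sum(apply(d[, sets[, s], drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# exhaustive global-alignment score by plain recursion (match +1,
# mismatch 0, gap -1); exponential, only for short sequences
brute_align_score <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- as.numeric(av[i] == bv[j] && av[i] != "X")
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) - 1)
    if (j > 0) best <- max(best, rec(i, j - 1) - 1)
    best
  }
  rec(length(av), length(bv))
}

# PERMANOVA sums of squares straight from the pairwise-distance identities
permanova_f_direct <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  g <- factor(groups[rownames(d)])
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- sum(vapply(levels(g), function(lev) {
    idx <- which(g == lev)
    sub <- d[idx, idx, drop = FALSE]
    sum(sub[lower.tri(sub)]^2) / length(idx)
  }, 0))
  a <- nlevels(g)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# random protein string
random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE), collapse = "")
}

# small labelled distance matrix from 1-D points
dist_1d <- function(x, ids = sprintf("s%02d", seq_along(x))) {
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(ids, ids)
  d
}

# compact cohort config for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  sim_config(n_strains_per_habitat = c(LA = 12, SA = 12, OA = 10),
             n_core = 30, n_accessory = 40, n_specific = 20,
             n_redundant_pairs = 3, seed = seed, ...)
}
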