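# choose the index with minimal value, breaking exact ties by
# lexicographic label order (strain ids are unique so this is total)
.argmin_lex <- function(values, labels, tol = 1e-12) {
  best <- min(values)
  cand <- which(values <= best + tol)
  cand[order(labels[cand])][1]
}

#' PAM (partitioning around medoids) k-clustering
#'
#' Classic Kaufman–Rousseeuw BUILD + SWAP on a precomputed distance matrix.
#' BUILD greedily adds the medoid with the largest objective decrease; SWAP
#' evaluates every (medoid, non-medoid) exchange per sweep and applies the
#' single best strictly improving swap until none remains, so the total
#' within-cluster distance to medoids is non-increasing across iterations.
#' Exact ties are broken lexicographically by strain id; the seed is part of
#' the interface for tie-breaking but unique ids make the lexicographic rule
#' decisive.
#'
#' @param dist symmetric distance matrix with unique row/col names.
#' @param k number of clusters, 1 <= k <= n.
#' @param seed integer, reserved for tie-breaking.
#' @return object of class `cluster_assignment`: list with `labels`,
#'   `cluster` (named integer vector in 1..k), `medoids` (strain ids, one
#'   per cluster), `k`, and `objective` (sum of distances to assigned
#'   medoids).
#' @export
pam_cluster <- function(dist, k, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  labels <- rownames(d)
  if (k < 1 || k > n) .fail("k must lie in [1, %d], got %s", n, format(k))
  k <- as.integer(k)

  # BUILD
  med <- .argmin_lex(colSums(d), labels)
  nearest <- d[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gain <- vapply(cand, function(cc) sum(pmax(nearest - d[, cc], 0)), 0)
    pick <- cand[.argmin_lex(-gain, labels[cand])]
    med <- c(med, pick)
    nearest <- pmin(nearest, d[, pick])
  }

  objective_of <- function(meds) {
    sum(do.call(pmin, as.data.frame(d[, meds, drop = FALSE])))
  }
  obj <- objective_of(med)

  # SWAP: best strictly-improving exchange per sweep; candidates are
  # scanned in lexicographic (medoid id, candidate id) order so exact ties
  # resolve to the lexicographically first pair
  repeat {
    best_delta <- 0
    best_pair <- NULL
    nonmed <- setdiff(seq_len(n), med)
    for (m in med[order(labels[med])]) {
      for (h in nonmed[order(labels[nonmed])]) {
        delta <- objective_of(c(setdiff(med, m), h)) - obj
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_pair <- c(m, h)
        }
      }
    }
    if (is.null(best_pair)) break
    med <- c(setdiff(med, best_pair[1]), best_pair[2])
    obj <- objective_of(med)
  }

  med <- med[order(labels[med])]
  assign_idx <- apply(d[, med, drop = FALSE], 1, which.min)
  cluster <- stats::setNames(as.integer(assign_idx), labels)
  structure(list(labels = labels, cluster = cluster,
                 medoids = labels[med], k = k,
                 objective = sum(d[cbind(seq_len(n), med[assign_idx])])),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d strains in %d clusters\n",
              length(x$labels), x$k))
  if (!is.null(x$medoids)) cat("medoids:", paste(x$medoids, collapse = ", "), "\n")
  if (!is.null(x$objective)) cat(sprintf("objective: %.6g\n", x$objective))
  invisible(x)
}

# accept either a cluster_assignment or a named integer vector
.cluster_vector <- function(assignment) {
  if (inherits(assignment, "cluster_assignment")) return(assignment$cluster)
  if (is.null(names(assignment))) .fail("cluster vector must be named by strain id")
  assignment
}

#' Mean silhouette width of a clustering
#'
#' Per point, s(i) = (b(i) - a(i)) / max(a(i), b(i)) where a(i) is the mean
#' distance to the other members of i's cluster and b(i) the smallest mean
#' distance to any other cluster. Points in singleton clusters contribute 0.
#'
#' @param dist symmetric distance matrix.
#' @param assignment `cluster_assignment` or named integer vector.
#' @return unweighted mean silhouette over all points, in \[-1, 1\].
#' @export
mean_silhouette <- function(dist, assignment) {
  d <- as.matrix(dist)
  cl <- .cluster_vector(assignment)
  cl <- cl[rownames(d)]
  ks <- sort(unique(cl))
  if (length(ks) < 2) .fail("silhouette is undefined for fewer than 2 clusters")
  n <- nrow(d)
  s <- numeric(n)
  sizes <- table(cl)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[[as.character(own)]] == 1) { s[i] <- 0; next }
    a <- sum(d[i, cl == own]) / (sizes[[as.character(own)]] - 1)
    b <- min(vapply(ks[ks != own],
                    function(g) mean(d[i, cl == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette-guided choice of the number of clusters
#'
#' Runs [pam_cluster()] and [mean_silhouette()] for each k in
#' `k_min:k_max` and returns the k with the highest mean silhouette
#' (ties broken toward smaller k). k = 1 has no silhouette and is excluded
#' from the scan by construction.
#'
#' @param dist symmetric distance matrix.
#' @param k_min,k_max scan range; `k_max` is clipped to n - 1 with a
#'   warning when necessary.
#' @param seed integer passed to [pam_cluster()].
#' @return list with `k_best`, `curve` (data.frame of k and mean
#'   silhouette), and `assignments` (one `cluster_assignment` per k).
#' @export
select_k <- function(dist, k_min = 2, k_max = 20, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k_min < 2) .fail("k_min must be >= 2 (silhouette undefined at k = 1)")
  if (k_max > n - 1) {
    warning(sprintf("k_max clipped from %d to %d (n = %d)", k_max, n - 1L, n))
    k_max <- n - 1L
  }
  if (k_min > k_max) .fail("empty k range after clipping")
  ks <- seq.int(k_min, k_max)
  fits <- lapply(ks, function(k) pam_cluster(d, k, seed = seed))
  sil <- vapply(fits, function(f) mean_silhouette(d, f), 0)
  best <- ks[which.max(sil)]   # which.max takes the first = smallest k on ties
  list(k_best = best,
       curve = data.frame(k = ks, silhouette = sil),
       assignments = stats::setNames(fits, paste0("k", ks)))
}

#' Complete-linkage hierarchical clustering of feature profiles
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' between per-megabase feature vectors, cut to `n_clusters` groups.
#'
#' @param features strains x classes numeric matrix (per-Mb normalised).
#' @param n_clusters number of groups to cut the dendrogram into.
#' @return `cluster_assignment` (no medoids) with the `hclust` object
#'   attached as `$hclust`.
#' @export
hclust_complete <- function(features, n_clusters) {
  m <- as.matrix(features)
  if (any(!is.finite(m))) .fail("feature table contains non-finite values")
  if (n_clusters < 1 || n_clusters > nrow(m)) .fail("n_clusters out of range")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  structure(list(labels = rownames(m), cluster = cl, medoids = NULL,
                 k = as.integer(n_clusters), objective = NULL, hclust = hc),
            class = "cluster_assignment")
}

#' Percentage shares, printed-table style
#'
#' @param counts numeric vector of counts.
#' @param total denominator (defaults to `sum(counts)`).
#' @return percentages `100 * counts / total` rounded half-up to 2 decimals.
#' @export
share_pct <- function(counts, total = sum(counts)) {
  if (total <= 0) .fail("total must be positive")
  round_half_up(100 * counts / total, 2)
}

#' Habitat composition of clusters
#'
#' @param assignment `cluster_assignment` or named cluster vector.
#' @param habitats named character vector, strain id -> habitat.
#' @return data.frame with one row per (cluster, habitat): `n`,
#'   `cluster_total`, and `pct` of the cluster total (half-up, 2 decimals).
#' @export
cluster_composition <- function(assignment, habitats) {
  cl <- .cluster_vector(assignment)
  miss <- setdiff(names(cl), names(habitats))
  if (length(miss)) .fail("habitats missing for strains: %s", paste(miss, collapse = ", "))
  hab <- habitats[names(cl)]
  tab <- table(cluster = cl, habitat = hab)
  totals <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  out$cluster_total <- totals[out$cluster]
  out$pct <- round_half_up(100 * out$n / out$cluster_total, 2)
  out[order(out$cluster, out$habitat), , drop = FALSE]
}

#' Majority-habitat concordance of a clustering
#'
#' Each cluster is labelled with its majority habitat (ties broken toward
#' the lexicographically smaller habitat); a strain is concordant when its
#' habitat equals its cluster's majority habitat. Percentages use the whole
#' cohort as denominator.
#'
#' @inheritParams cluster_composition
#' @return data.frame with one row per habitat: `concordant` count,
#'   `total_strains`, `pct` of all strains (half-up, 2 decimals).
#' @export
habitat_concordance <- function(assignment, habitats) {
  cl <- .cluster_vector(assignment)
  hab <- habitats[names(cl)]
  n <- length(cl)
  majority <- vapply(split(hab, cl), function(h) {
    t <- sort(table(h), decreasing = TRUE)
    names(t)[t == t[1]][order(names(t)[t == t[1]])][1]
  }, "")
  concord <- hab == majority[as.character(cl)]
  habs <- sort(unique(hab))
  counts <- vapply(habs, function(h) sum(concord & hab == h), 0L)
  data.frame(habitat = habs, concordant = counts, total_strains = n,
             pct = share_pct(counts, n), row.names = NULL)
}
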