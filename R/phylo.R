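#' Parse a Newick tree string
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' an `ape` `phylo` object used throughout the package. Leaf labels must be
#' unique and every edge must carry a branch length.
#'
#' @param text Newick string (terminating `;` required).
#' @return a `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    .fail("malformed Newick string: %s", substr(text, 1, 60))
  }
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) .fail("duplicate leaf labels: %s", paste(unique(dup), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    .fail("tree is missing branch lengths")
  }
  tr
}

#' Serialise a tree to Newick
#'
#' @param tree a `phylo` object.
#' @return single Newick string. `parse_newick(write_newick(t))` preserves
#'   topology, labels and branch lengths to 1e-9.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 12)
}

# depth (root-to-node path length) for every node of a phylo object,
# computed by a preorder sweep over the edge matrix
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- rep(NA_real_, n_node)
  root <- ape::Ntip(tree) + 1L
  depth[root] <- 0
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  depth
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' Total branch length along the unique path between every pair of leaves,
#' computed from root-to-leaf depth vectors and all-pairs most recent common
#' ancestors: d(i, j) = depth(i) + depth(j) - 2 depth(MRCA(i, j)).
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric numeric matrix with zero diagonal; dimnames are the
#'   leaf labels in `tree$tip.label` order.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    .fail("tree is missing branch lengths")
  }
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  anc <- ape::mrca(tree)                 # n x n node indices of the MRCA
  d <- outer(depth[seq_len(n)], depth[seq_len(n)], `+`) - 2 * depth[anc]
  diag(d) <- 0
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei neighbor joining. On an additive matrix the generating
#' (unrooted) topology is reconstructed exactly. Estimated branch lengths
#' that come out negative are clamped to zero with the deficit transferred
#' to the sibling edge of the join, so all reported lengths are
#' non-negative while leaf-to-leaf path lengths at the join are preserved.
#'
#' @param dist symmetric distance matrix with unique dimnames.
#' @return an unrooted `phylo` object (basal trifurcation, as is
#'   conventional for NJ).
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) .fail("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) .fail("distance matrix must be symmetric")
  labels <- rownames(d)
  # each active element carries its newick subtree string
  sub <- labels
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    c(bi, bj)
  }
  while (n > 3) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    bi <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    b <- clamp_pair(bi, bj)
    newsub <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], b[1], sub[j], b[2])
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    sub <- c(sub[keep], newsub)
    n <- n - 1
  }
  ba <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  bb <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  bc <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  b <- pmax(c(ba, bb, bc), 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", sub[1], b[1], sub[2], b[2], sub[3], b[3])
  parse_newick(nwk)
}

#' Single-copy core gene families
#'
#' Families present in exactly one copy in every strain; these are the
#' families whose concatenated alignments underpin strain phylogenies.
#'
#' @param ortho strains x families integer count matrix (an orthogroup
#'   matrix as produced by [simulate_orthogroups()] or read from TSV).
#' @return character vector of family ids in stable column order.
#' @export
single_copy_core_families <- function(ortho) {
  stopifnot(is.matrix(ortho), nrow(ortho) > 0, ncol(ortho) > 0)
  colnames(ortho)[colSums(ortho == 1L) == nrow(ortho)]
}
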