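HABITATS <- c("LA", "SA", "OA")

CAZY_CLASSES <- c("AA", "CBM", "CE", "GH", "GT", "PL")
BGC_CLASSES <- c("NRPS", "NRPS.like", "PKS.like", "T3PKS", "transAT.PKS",
                 "bacteriocin", "terpene", "siderophore", "hserlactone",
                 "NAGGN", "arylpolyene", "betalactone")

# default per-Mb feature rates; SA-enriched CAZymes and mostly SA-enriched
# BGC classes (terpene and beta-lactone lean LA), giving per-genome CAZyme
# totals in the low-hundreds range observed for soil and leaf bacteria
default_feature_rates <- function() {
  rates <- rbind(
    LA = c(AA = 1.5, CBM = 2.0, CE = 2.5, GH = 14, GT = 12, PL = 0.6,
           NRPS = 0.25, NRPS.like = 0.10, PKS.like = 0.05, T3PKS = 0.10,
           transAT.PKS = 0.05, bacteriocin = 0.20, terpene = 0.35,
           siderophore = 0.10, hserlactone = 0.10, NAGGN = 0.05,
           arylpolyene = 0.10, betalactone = 0.20),
    SA = c(AA = 3.0, CBM = 4.0, CE = 5.0, GH = 25, GT = 18, PL = 1.5,
           NRPS = 0.60, NRPS.like = 0.25, PKS.like = 0.15, T3PKS = 0.20,
           transAT.PKS = 0.15, bacteriocin = 0.50, terpene = 0.30,
           siderophore = 0.25, hserlactone = 0.30, NAGGN = 0.15,
           arylpolyene = 0.30, betalactone = 0.10),
    OA = c(AA = 2.5, CBM = 3.0, CE = 4.0, GH = 20, GT = 16, PL = 1.2,
           NRPS = 0.40, NRPS.like = 0.15, PKS.like = 0.10, T3PKS = 0.15,
           transAT.PKS = 0.10, bacteriocin = 0.35, terpene = 0.30,
           siderophore = 0.15, hserlactone = 0.20, NAGGN = 0.10,
           arylpolyene = 0.20, betalactone = 0.15))
  rates
}

#' Configuration for a synthetic cohort
#'
#' Defaults encode the habitat conditions the analysis targets: cohort
#' sizes 195/283/95 (LA/SA/OA), mean genome sizes 4.67/6.08/5.97 Mb, mean
#' GC 63.27/57.12/56.95 percent, habitat-monophyletic clades, and per-Mb
#' feature-class rates with soil-enriched CAZymes. Spread parameters (SDs)
#' and orthogroup counts are free choices documented in the package
#' vignette; orthogroup counts default to the flower-plot structure scaled
#' down 100-fold.
#'
#' @param n_strains_per_habitat named integer vector (LA, SA, OA).
#' @param genome_size_mean_mb,genome_size_sd_mb named numeric per habitat.
#' @param gc_mean_pct,gc_sd_pct GC distribution per habitat (sd scalar ok).
#' @param feature_rate_per_mb habitat x class rate matrix, all >= 0.
#' @param n_core,n_accessory,n_specific,n_single_copy orthogroup structure.
#' @param n_taxa number of taxon groups strains are spread over.
#' @param n_redundant_pairs planted near-duplicate genome pairs.
#' @param habitat_assortativity in \[0, 1\]; 1 = habitats are monophyletic.
#' @param clade_separation stem branch length separating habitat clades,
#'   relative to unit within-clade tree height.
#' @param seed integer root seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains_per_habitat = c(LA = 195, SA = 283, OA = 95),
                       genome_size_mean_mb = c(LA = 4.67, SA = 6.08, OA = 5.97),
                       genome_size_sd_mb = c(LA = 0.8, SA = 1.2, OA = 1.2),
                       gc_mean_pct = c(LA = 63.27, SA = 57.12, OA = 56.95),
                       gc_sd_pct = 3,
                       feature_rate_per_mb = default_feature_rates(),
                       n_core = 163, n_accessory = 378, n_specific = 212,
                       n_single_copy = 14,
                       n_taxa = 4,
                       n_redundant_pairs = 5,
                       habitat_assortativity = 1,
                       clade_separation = 4,
                       seed = 1) {
  cfg <- list(n_strains_per_habitat = n_strains_per_habitat,
              genome_size_mean_mb = genome_size_mean_mb,
              genome_size_sd_mb = genome_size_sd_mb,
              gc_mean_pct = gc_mean_pct,
              gc_sd_pct = if (length(gc_sd_pct) == 1)
                stats::setNames(rep(gc_sd_pct, 3), HABITATS) else gc_sd_pct,
              feature_rate_per_mb = feature_rate_per_mb,
              n_core = n_core, n_accessory = n_accessory,
              n_specific = n_specific, n_single_copy = n_single_copy,
              n_taxa = n_taxa, n_redundant_pairs = n_redundant_pairs,
              habitat_assortativity = habitat_assortativity,
              clade_separation = clade_separation, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param cfg a configuration list.
#' @export
validate_sim_config <- function(cfg) {
  for (f in c("n_strains_per_habitat", "genome_size_mean_mb",
              "genome_size_sd_mb", "gc_mean_pct", "gc_sd_pct")) {
    if (!setequal(names(cfg[[f]]), HABITATS)) {
      .fail("%s must be named with exactly LA, SA, OA", f)
    }
  }
  if (any(cfg$genome_size_mean_mb <= 0) || any(cfg$gc_mean_pct <= 0)) {
    .fail("means must be positive")
  }
  if (any(cfg$genome_size_sd_mb < 0) || any(cfg$gc_sd_pct < 0)) .fail("sds must be >= 0")
  if (any(cfg$feature_rate_per_mb < 0)) .fail("feature rates must be >= 0")
  if (!setequal(rownames(cfg$feature_rate_per_mb), HABITATS)) {
    .fail("feature_rate_per_mb rows must be LA, SA, OA")
  }
  counts <- unlist(cfg[c("n_core", "n_accessory", "n_specific",
                         "n_single_copy", "n_redundant_pairs", "n_taxa")])
  if (any(counts < 0)) .fail("counts must be >= 0")
  if (cfg$n_single_copy > cfg$n_core) .fail("n_single_copy cannot exceed n_core")
  if (cfg$habitat_assortativity < 0 || cfg$habitat_assortativity > 1) {
    .fail("habitat_assortativity must lie in [0, 1]")
  }
  if (cfg$n_redundant_pairs > sum(cfg$n_strains_per_habitat) / 2) {
    .fail("n_redundant_pairs exceeds n_strains / 2")
  }
  invisible(cfg)
}

#' Simulate a tree with planted clades
#'
#' One Yule subtree (unit birth rate) per clade, rescaled to unit height,
#' joined by a backbone whose stem branches set the between-clade
#' separation; the planted clade of each tip is returned as the `clade`
#' attribute. Building block of [simulate_tree()], also useful directly
#' for planting an arbitrary number of clusters.
#'
#' @param clade_sizes (optionally named) integer vector of tips per clade.
#' @param seed integer seed.
#' @param separation stem branch length relative to the unit clade height.
#' @param tip_ids optional tip labels, assigned clade by clade.
#' @return `phylo` object with a `clade` attribute.
#' @export
simulate_clade_tree <- function(clade_sizes, seed = 1, separation = 4,
                                tip_ids = NULL) {
  stopifnot(all(clade_sizes >= 1), length(clade_sizes) >= 1)
  n <- sum(clade_sizes)
  if (is.null(tip_ids)) tip_ids <- sprintf("S%03d", seq_len(n))
  if (n < 3) .fail("need at least 3 taxa")
  with_seed(seed, {
    offset <- 0L
    subs <- character(length(clade_sizes))
    clade_of <- character(0)
    for (ci in seq_along(clade_sizes)) {
      sz <- clade_sizes[ci]
      ids <- tip_ids[offset + seq_len(sz)]
      if (sz == 1) {
        subs[ci] <- ids
      } else {
        tr <- ape::rphylo(sz, birth = 1, death = 0)
        ht <- max(node_depths(tr)[seq_len(sz)])
        tr$edge.length <- tr$edge.length / ht          # unit height
        tr$edge.length <- pmax(tr$edge.length, 1e-8)
        tr$tip.label <- ids
        subs[ci] <- sub(";$", "", ape::write.tree(tr, digits = 12))
      }
      clade_of <- c(clade_of, stats::setNames(rep(names(clade_sizes)[ci] %||%
                                                    as.character(ci), sz), ids))
      offset <- offset + sz
    }
    nwk <- subs[1]
    first <- TRUE
    for (ci in seq_along(subs)[-1]) {
      b1 <- if (first) separation else 1e-8 + stats::rexp(1, 10)
      first <- FALSE
      nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk, b1, subs[ci], separation)
    }
    tree <- parse_newick(paste0(nwk, ";"))
    attr(tree, "clade") <- clade_of[tree$tip.label]
    tree
  })
}

#' Simulate a strain phylogeny with habitat structure
#'
#' Yule subtrees (unit birth rate) per habitat, rescaled to unit height and
#' joined by long stem branches, so at `habitat_assortativity = 1` each
#' habitat's leaves are monophyletic. Below 1, each leaf's habitat label is
#' independently redrawn with probability `1 - habitat_assortativity` from
#' the habitat frequencies, so at 0 habitats are assigned uniformly at
#' random over leaves.
#'
#' @param n_taxa total number of leaves (>= 3).
#' @param seed integer seed.
#' @param habitat_assortativity real in \[0, 1\].
#' @param habitat_counts named integer vector (LA/SA/OA); defaults to an
#'   even split of `n_taxa`.
#' @param clade_separation stem branch length between habitat clades.
#' @return `phylo` object with a `habitat` attribute (named character
#'   vector over the tips).
#' @export
simulate_tree <- function(n_taxa, seed = 1, habitat_assortativity = 1,
                          habitat_counts = NULL, clade_separation = 4) {
  if (n_taxa < 3) .fail("n_taxa must be >= 3")
  if (is.null(habitat_counts)) {
    base <- n_taxa %/% 3
    habitat_counts <- stats::setNames(c(base, base, n_taxa - 2 * base), HABITATS)
  }
  habitat_counts <- habitat_counts[habitat_counts > 0]
  stopifnot(sum(habitat_counts) == n_taxa)
  tree <- simulate_clade_tree(habitat_counts, seed = seed,
                              separation = clade_separation)
  hab <- attr(tree, "clade")
  if (habitat_assortativity < 1) {
    freqs <- habitat_counts / sum(habitat_counts)
    hab <- with_seed(stage_seed(seed, "relabel"), {
      redraw <- stats::runif(length(hab)) > habitat_assortativity
      hab[redraw] <- sample(names(freqs), sum(redraw), replace = TRUE,
                            prob = freqs)
      hab
    })
  }
  attr(tree, "habitat") <- hab
  attr(tree, "clade") <- NULL
  tree
}

# truncated-normal draw by rejection
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower | out >= upper)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws genome sizes and GC per habitat from truncated normals (sizes
#' truncated at 0.5 Mb, GC to (20, 80)), builds the habitat-structured
#' phylogeny, plants orthogroup structure and redundant genome pairs, and
#' draws feature-class counts Poisson with per-Mb rates. The same config
#' and seed reproduce the cohort exactly.
#'
#' @param config a [sim_config()] object.
#' @return list of class `cohort`: `records` (data.frame), `tree`
#'   (`phylo`), `ortho` (count matrix), `ani_pairs` (data.frame),
#'   `features` (count matrix), `truth` (planted parameters), `seed`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  counts <- config$n_strains_per_habitat[HABITATS]
  n <- sum(counts)
  tree <- simulate_tree(n, seed = stage_seed(config$seed, "tree"),
                        habitat_assortativity = config$habitat_assortativity,
                        habitat_counts = counts,
                        clade_separation = config$clade_separation)
  hab <- attr(tree, "habitat")
  ids <- tree$tip.label
  records <- with_seed(stage_seed(config$seed, "records"), {
    size_mb <- gc <- numeric(n)
    for (h in HABITATS) {
      sel <- hab == h
      size_mb[sel] <- rtrunc_norm(sum(sel), config$genome_size_mean_mb[[h]],
                                  config$genome_size_sd_mb[[h]], lower = 0.5)
      gc[sel] <- rtrunc_norm(sum(sel), config$gc_mean_pct[[h]],
                             config$gc_sd_pct[[h]], lower = 20, upper = 80)
    }
    taxon <- paste0("T", sample.int(config$n_taxa, n, replace = TRUE))
    data.frame(id = ids, habitat = unname(hab[ids]), taxon = taxon,
               size_bp = as.integer(round(size_mb * 1e6)),
               gc_pct = gc,
               completeness_pct = stats::runif(n, 97, 100),
               contamination_pct = stats::runif(n, 0, 3))
  })
  unit_of <- stats::setNames(paste(records$taxon, records$habitat, sep = "_"),
                             records$id)
  ortho <- simulate_orthogroups(records$id, unit_of,
                                n_core = config$n_core,
                                n_accessory = config$n_accessory,
                                n_specific = config$n_specific,
                                n_single_copy = config$n_single_copy,
                                seed = stage_seed(config$seed, "ortho"))
  ani <- simulate_ani_pairs(records$id, config$n_redundant_pairs,
                            seed = stage_seed(config$seed, "ani"))
  features <- simulate_features(records, config$feature_rate_per_mb,
                                seed = stage_seed(config$seed, "features"))
  structure(list(records = records, tree = tree, ortho = ortho,
                 ani_pairs = ani$pairs, features = features,
                 truth = list(habitat = stats::setNames(records$habitat, records$id),
                              taxon = stats::setNames(records$taxon, records$id),
                              unit = unit_of,
                              family_class = attr(ortho, "truth"),
                              single_copy = attr(ortho, "single_copy"),
                              redundant_pairs = ani$truth,
                              config = config),
                 seed = config$seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d strains (%s), %d gene families, %d feature classes\n",
              nrow(x$records),
              paste(sprintf("%s %d", names(table(x$records$habitat)),
                            table(x$records$habitat)), collapse = ", "),
              ncol(x$ortho), ncol(x$features)))
  invisible(x)
}

#' Plant an orthogroup count matrix with known class structure
#'
#' Core families are present in every strain (the first `n_single_copy` in
#' exactly one copy everywhere), unit-specific families are confined to a
#' single taxon-by-habitat unit, and accessory families span at least two
#' units without covering all strains, so [partition_pangenome()] recovers
#' the planted counts exactly. Columns are shuffled.
#'
#' @param strains character strain ids.
#' @param unit_of named vector strain -> unit; must cover all strains.
#' @param n_core,n_accessory,n_specific class sizes (sum > 0).
#' @param n_single_copy number of core families planted single-copy.
#' @param seed integer seed.
#' @return strains x families integer matrix with attributes `truth`
#'   (family -> planted class) and `single_copy` (family ids).
#' @export
simulate_orthogroups <- function(strains, unit_of, n_core, n_accessory,
                                 n_specific, n_single_copy = 0, seed = 1) {
  n <- length(strains)
  if (n_core + n_accessory + n_specific == 0) .fail("no families requested")
  miss <- setdiff(strains, names(unit_of))
  if (length(miss)) .fail("unit_of missing strains: %s", paste(miss, collapse = ", "))
  units <- unit_of[strains]
  n_units <- length(unique(units))
  if (n_accessory > 0 && (n_units < 2 || n < 3)) {
    .fail("planting accessory families requires >= 2 units and >= 3 strains")
  }
  if (n_specific > 0 && n < 2) .fail("planting specific families requires >= 2 strains")
  total <- n_core + n_accessory + n_specific
  with_seed(seed, {
    m <- matrix(0L, n, total, dimnames = list(strains, NULL))
    cls <- character(total)
    col <- 0L
    for (i in seq_len(n_core)) {
      col <- col + 1L
      m[, col] <- if (i <= n_single_copy) 1L else 1L + stats::rpois(n, 0.3)
      cls[col] <- "core"
    }
    unit_list <- split(strains, units)
    unit_names <- names(unit_list)
    for (i in seq_len(n_specific)) {
      col <- col + 1L
      u <- unit_list[[unit_names[1 + (i - 1) %% n_units]]]
      sz <- sample.int(min(length(u), n - 1), 1)
      carriers <- sample(u, sz)
      m[carriers, col] <- 1L + stats::rpois(sz, 0.2)
      cls[col] <- "specific"
    }
    for (i in seq_len(n_accessory)) {
      col <- col + 1L
      # anchor in two distinct units, then fill to a random size < n
      anchors <- vapply(sample(unit_names, 2), function(u)
        sample(unit_list[[u]], 1), "")
      extra_n <- sample.int(n - 2, 1) - 1L          # 0 .. n-3
      carriers <- unique(c(anchors,
                           sample(setdiff(strains, anchors),
                                  min(extra_n, n - 2 - 1))))
      m[carriers, col] <- 1L + stats::rpois(length(carriers), 0.2)
      cls[col] <- "accessory"
    }
    fam_ids <- sprintf("OG%05d", seq_len(total))
    shuffle <- sample.int(total)
    m <- m[, shuffle, drop = FALSE]
    cls <- cls[shuffle]
    colnames(m) <- fam_ids
    truth <- stats::setNames(cls, fam_ids)
    attr(m, "truth") <- truth
    attr(m, "single_copy") <- fam_ids[colSums(m == 1L) == n & truth == "core"]
    m
  })
}

#' Plant redundant genome pairs with ANI/coverage signatures
#'
#' Exactly `n_redundant` disjoint pairs get ANI >= 99.9 percent and both
#' directional coverages > 95 percent; background pairs fail at least one
#' threshold.
#'
#' @param strains character strain ids.
#' @param n_redundant number of planted redundant pairs (<= n/2).
#' @param seed integer seed.
#' @param n_background additional non-redundant pairs to emit.
#' @return list with `pairs` (data.frame id_a, id_b, ani_pct,
#'   coverage_ab_pct, coverage_ba_pct) and `truth` (data.frame of planted
#'   redundant pairs).
#' @export
simulate_ani_pairs <- function(strains, n_redundant, seed = 1,
                               n_background = 2 * n_redundant + 5) {
  n <- length(strains)
  if (n_redundant > n / 2) .fail("n_redundant exceeds n_strains / 2")
  with_seed(seed, {
    chosen <- if (n_redundant > 0) sample(strains, 2 * n_redundant) else character(0)
    red <- if (n_redundant > 0) {
      data.frame(id_a = chosen[seq_len(n_redundant) * 2 - 1],
                 id_b = chosen[seq_len(n_redundant) * 2],
                 ani_pct = stats::runif(n_redundant, 99.9, 100),
                 coverage_ab_pct = stats::runif(n_redundant, 95.5, 100),
                 coverage_ba_pct = stats::runif(n_redundant, 95.5, 100))
    } else data.frame(id_a = character(0), id_b = character(0),
                      ani_pct = numeric(0), coverage_ab_pct = numeric(0),
                      coverage_ba_pct = numeric(0))
    bg <- NULL
    if (n_background > 0 && n >= 2) {
      seen <- paste(pmin(red$id_a, red$id_b), pmax(red$id_a, red$id_b))
      rows <- list()
      tries <- 0
      while (length(rows) < n_background && tries < 50 * n_background) {
        tries <- tries + 1
        p <- sample(strains, 2)
        key <- paste(min(p), max(p))
        if (key %in% seen) next
        seen <- c(seen, key)
        fail_cov <- stats::runif(1) < 0.5
        rows[[length(rows) + 1]] <- data.frame(
          id_a = p[1], id_b = p[2],
          ani_pct = if (fail_cov) stats::runif(1, 99.9, 100) else stats::runif(1, 85, 99.8),
          coverage_ab_pct = if (fail_cov) stats::runif(1, 60, 94.9) else stats::runif(1, 80, 100),
          coverage_ba_pct = stats::runif(1, 80, 100))
      }
      bg <- do.call(rbind, rows)
    }
    list(pairs = rbind(red, bg), truth = red)
  })
}

#' Draw feature-class counts for a cohort
#'
#' Counts are Poisson with mean `rate_per_mb x genome size in Mb`, per
#' habitat and feature class.
#'
#' @param records cohort records data.frame (`id`, `habitat`, `size_bp`).
#' @param rates habitat x class per-Mb rate matrix.
#' @param seed integer seed.
#' @return strains x classes integer count matrix (`normalized` FALSE).
#' @export
simulate_features <- function(records, rates = default_feature_rates(), seed = 1) {
  with_seed(seed, {
    classes <- colnames(rates)
    m <- matrix(0L, nrow(records), length(classes),
                dimnames = list(records$id, classes))
    size_mb <- records$size_bp / 1e6
    for (cls in classes) {
      lambda <- rates[records$habitat, cls] * size_mb
      m[, cls] <- stats::rpois(nrow(records), lambda)
    }
    attr(m, "normalized") <- FALSE
    m
  })
}

#' Mutate reference proteins to target identities
#'
#' Each query starts from a reference family sequence and receives point
#' substitutions (no indels) until its global-alignment identity against
#' the source lands within +/- 2 percentage points of its target, so the
#' family-assignment truth is exact.
#'
#' @param family_refs named character vector of reference sequences, names
#'   `id|FAMILY`.
#' @param n_queries number of query proteins.
#' @param identity_targets percent identities in \[0, 100\], recycled.
#' @param seed integer seed.
#' @return list with `queries` (named character vector) and `truth`
#'   (data.frame: query, ref, family, target_identity, realized_identity).
#' @export
simulate_proteins <- function(family_refs, n_queries, identity_targets, seed = 1) {
  family_refs <- .as_seq_vector(family_refs, "family_refs")
  if (length(family_refs) == 0) .fail("reference set is empty")
  if (any(identity_targets < 0 | identity_targets > 100)) {
    .fail("identity targets must lie in [0, 100]")
  }
  targets <- rep_len(identity_targets, n_queries)
  fam <- .parse_family(names(family_refs))
  with_seed(seed, {
    src <- sample.int(length(family_refs), n_queries, replace = TRUE)
    queries <- character(n_queries)
    realized <- numeric(n_queries)
    for (qi in seq_len(n_queries)) {
      ref <- family_refs[[src[qi]]]
      chars <- strsplit(ref, "")[[1]]
      L <- length(chars)
      t <- targets[qi]
      n_mut <- min(L, round(L * (1 - t / 100)))
      pos <- sample.int(L, n_mut)
      mutated <- chars
      for (p in pos) {
        mutated[p] <- sample(setdiff(AA_ALPHABET[1:20], chars[p]), 1)
      }
      q <- paste(mutated, collapse = "")
      id <- global_identity(q, ref)[["identity_pct"]]
      free <- setdiff(seq_len(L), pos)
      iter <- 0
      while (id > t + 2 && length(free) && iter < 3 * L) {
        iter <- iter + 1
        p <- free[1]; free <- free[-1]
        mutated[p] <- sample(setdiff(AA_ALPHABET[1:20], chars[p]), 1)
        q <- paste(mutated, collapse = "")
        id <- global_identity(q, ref)[["identity_pct"]]
      }
      while (id < t - 2 && length(pos) && iter < 6 * L) {
        iter <- iter + 1
        p <- pos[1]; pos <- pos[-1]
        mutated[p] <- chars[p]
        q <- paste(mutated, collapse = "")
        id <- global_identity(q, ref)[["identity_pct"]]
      }
      queries[qi] <- q
      realized[qi] <- id
    }
    names(queries) <- sprintf("Q%04d", seq_len(n_queries))
    list(queries = queries,
         truth = data.frame(query = names(queries),
                            ref = names(family_refs)[src],
                            family = fam[src],
                            target_identity = targets,
                            realized_identity = realized))
  })
}

#' Random reference protein families
#'
#' @param families character vector of family names (e.g. "GH13").
#' @param length sequence length in residues.
#' @param seed integer seed.
#' @return named character vector with headers `REF_<family>|<family>`.
#' @export
simulate_reference_families <- function(families, length = 80, seed = 1) {
  with_seed(seed, {
    seqs <- vapply(families, function(f)
      paste(sample(AA_ALPHABET[1:20], length, replace = TRUE), collapse = ""), "")
    stats::setNames(seqs, sprintf("REF_%s|%s", families, families))
  })
}
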