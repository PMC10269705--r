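#' Partition gene families into core, accessory and unit-specific
#'
#' Units are taxon-by-habitat combinations (the petals of a pan-genome
#' flower plot). A family is core when it is present (count >= 1) in every
#' strain; unit-specific when it is not core and all strains carrying it
#' belong to a single unit; accessory otherwise. Classes are mutually
#' exclusive and exhaustive over the families of the matrix.
#'
#' @param ortho strains x families non-negative integer matrix with
#'   dimnames.
#' @param unit_of named character vector, strain id -> unit label, covering
#'   all strains of the matrix.
#' @return list with `summary` (data.frame: n_total, n_core, n_accessory,
#'   n_specific and their percentage shares, half-up to 2 decimals) and
#'   `class_of` (named character vector family -> "core" / "accessory" /
#'   "specific").
#' @export
partition_pangenome <- function(ortho, unit_of) {
  stopifnot(is.matrix(ortho))
  if (nrow(ortho) == 0 || ncol(ortho) == 0) .fail("empty orthogroup matrix")
  strains <- rownames(ortho)
  miss <- setdiff(strains, names(unit_of))
  if (length(miss)) .fail("unit_of missing strains: %s", paste(miss, collapse = ", "))
  units <- unit_of[strains]
  present <- ortho >= 1L
  n_strains <- nrow(ortho)
  core <- colSums(present) == n_strains
  # number of distinct units each family's carriers span
  unit_mat <- rowsum((present) * 1L, group = units)   # units x families
  units_hit <- colSums(unit_mat > 0)
  specific <- !core & units_hit == 1L & colSums(present) >= 1L
  accessory <- !core & !specific
  class_of <- rep("accessory", ncol(ortho))
  class_of[core] <- "core"
  class_of[specific] <- "specific"
  names(class_of) <- colnames(ortho)
  counts <- c(n_total = ncol(ortho), n_core = sum(core),
              n_accessory = sum(accessory), n_specific = sum(specific))
  list(summary = cbind(as.data.frame(as.list(counts)),
                       partition_shares(sum(core), sum(accessory), sum(specific))),
       class_of = class_of)
}

#' Percentage shares of a pan-genome partition
#'
#' @param n_core,n_accessory,n_specific class counts.
#' @return data.frame with `core_pct`, `accessory_pct`, `specific_pct`:
#'   100 x count / total, rounded half-up to 2 decimals.
#' @export
partition_shares <- function(n_core, n_accessory, n_specific) {
  total <- n_core + n_accessory + n_specific
  if (total <= 0) .fail("partition is empty")
  data.frame(core_pct = share_pct(n_core, total),
             accessory_pct = share_pct(n_accessory, total),
             specific_pct = share_pct(n_specific, total))
}

#' Phylogenetically matched subsampling across habitats
#'
#' Balances habitat panels for core-genome comparison: the reference
#' habitat contributes all its strains (or a seeded random `n_per_group` if
#' it has more); every other habitat contributes the `n_per_group`
#' candidates whose mean cophenetic distance to the reference panel deviates
#' least from the grand mean of those candidate means, so each panel is
#' phylogenetically centred on the reference rather than dominated by
#' outlier clades.
#'
#' @param dist cophenetic distance matrix over all strains.
#' @param habitats named character vector, strain id -> habitat.
#' @param reference_habitat habitat whose strains anchor the matching.
#' @param n_per_group panel size per habitat.
#' @param seed integer; used for the reference draw and documented
#'   tie-breaking (ties first break lexicographically by strain id).
#' @return named list habitat -> character vector of selected strain ids.
#' @export
matched_subsample <- function(dist, habitats, reference_habitat, n_per_group, seed = 1) {
  d <- as.matrix(dist)
  ids <- rownames(d)
  hab <- habitats[ids]
  if (!reference_habitat %in% hab) .fail("reference habitat %s has no strains", reference_habitat)
  pools <- split(ids, hab)
  short <- names(pools)[vapply(pools, length, 1L) < n_per_group]
  if (length(short)) {
    .fail("n_per_group = %d exceeds pool size for habitat(s): %s",
          n_per_group, paste(short, collapse = ", "))
  }
  ref_pool <- sort(pools[[reference_habitat]])
  ref_sel <- if (length(ref_pool) > n_per_group) {
    with_seed(seed, sort(sample(ref_pool, n_per_group)))
  } else ref_pool
  out <- list()
  out[[reference_habitat]] <- ref_sel
  for (h in setdiff(names(pools), reference_habitat)) {
    cand <- sort(pools[[h]])
    mean_to_ref <- rowMeans(d[cand, ref_sel, drop = FALSE])
    dev <- abs(mean_to_ref - mean(mean_to_ref))
    out[[h]] <- cand[order(dev, cand)][seq_len(n_per_group)]
  }
  out
}

#' Per-group abundance of selected gene families
#'
#' Mean count, standard deviation and group size for each (group, family)
#' pair, the input to downstream ANOVA / bar-chart comparisons of core-gene
#' abundance across habitats.
#'
#' @param ortho strains x families count matrix.
#' @param families character vector of family ids to summarise.
#' @param group_of named character vector, strain id -> group.
#' @return data.frame with columns group, family, mean, sd (NA when the
#'   group has a single strain), n.
#' @export
family_abundance_by_group <- function(ortho, families, group_of) {
  unknown <- setdiff(families, colnames(ortho))
  if (length(unknown)) .fail("unknown families: %s", paste(unknown, collapse = ", "))
  groups <- group_of[rownames(ortho)]
  res <- expand.grid(group = sort(unique(groups)), family = families,
                     stringsAsFactors = FALSE)
  res$mean <- NA_real_; res$sd <- NA_real_; res$n <- NA_integer_
  for (r in seq_len(nrow(res))) {
    x <- ortho[groups == res$group[r], res$family[r]]
    res$mean[r] <- mean(x)
    res$sd[r] <- if (length(x) > 1) stats::sd(x) else NA_real_
    res$n[r] <- length(x)
  }
  res
}
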