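#' Genome quality filtering by completeness and contamination
#'
#' Keeps genomes that are at least `min_completeness` percent complete and
#' carry no more than `max_contamination` percent contamination (both bounds
#' inclusive). Estimates are consumed as metadata (e.g. CheckM output); this
#' function applies the rule only.
#'
#' @param records data.frame of genome records with at least columns
#'   `id`, `completeness_pct`, `contamination_pct`.
#' @param min_completeness minimum completeness percentage, in \[0, 100\].
#' @param max_contamination maximum contamination percentage, in \[0, 100\].
#' @return list with `kept` (data.frame, input order preserved) and
#'   `removed` (data.frame with a `reason` column: "completeness",
#'   "contamination", or "completeness;contamination").
#' @examples
#' g <- data.frame(id = c("a", "b"), completeness_pct = c(99, 90),
#'                 contamination_pct = c(1, 1))
#' quality_filter(g)$removed$id
#' @export
quality_filter <- function(records, min_completeness = 95, max_contamination = 5) {
  stopifnot(is.data.frame(records))
  if (min_completeness < 0 || min_completeness > 100 ||
      max_contamination < 0 || max_contamination > 100) {
    .fail("thresholds must lie in [0, 100]")
  }
  req <- c("id", "completeness_pct", "contamination_pct")
  miss <- setdiff(req, names(records))
  if (length(miss)) .fail("records is missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(records) == 0) {
    return(list(kept = records, removed = cbind(records, reason = character(0))))
  }
  bad_comp <- records$completeness_pct < min_completeness
  bad_cont <- records$contamination_pct > max_contamination
  ok <- !bad_comp & !bad_cont
  reason <- rep(NA_character_, nrow(records))
  reason[bad_comp & !bad_cont] <- "completeness"
  reason[!bad_comp & bad_cont] <- "contamination"
  reason[bad_comp & bad_cont] <- "completeness;contamination"
  removed <- records[!ok, , drop = FALSE]
  removed$reason <- reason[!ok]
  list(kept = records[ok, , drop = FALSE], removed = removed)
}

#' Dereplicate near-identical genomes by ANI and coverage
#'
#' Two genomes are treated as functionally redundant when their average
#' nucleotide identity is at least `ani_min` percent and both directional
#' alignment coverages exceed `cov_min` percent. Redundancy edges are closed
#' into connected components and one representative per component is kept,
#' chosen uniformly at random with the seeded RNG, so the result is
#' deterministic for a fixed seed.
#'
#' @param records data.frame with an `id` column (one row per genome).
#' @param pairs data.frame of pairwise comparisons with columns `id_a`,
#'   `id_b`, `ani_pct`, `coverage_ab_pct`, `coverage_ba_pct`.
#' @param ani_min ANI threshold (inclusive), default 99.9.
#' @param cov_min coverage threshold (strict, applied to the smaller of the
#'   two directional coverages), default 95.
#' @param seed integer seed for the representative draw.
#' @return list with `kept` (character ids), `removed` (character ids) and
#'   `components` (list of character vectors, the redundancy groups of
#'   size >= 2).
#' @export
dereplicate <- function(records, pairs, ani_min = 99.9, cov_min = 95, seed = 1) {
  stopifnot(is.data.frame(records), "id" %in% names(records))
  ids <- as.character(records$id)
  if (anyDuplicated(ids)) .fail("duplicate genome ids in records")
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(kept = ids, removed = character(0), components = list()))
  }
  unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), ids)
  if (length(unknown)) {
    .fail("ANI pairs reference unknown genome ids: %s", paste(unknown, collapse = ", "))
  }
  redundant <- pairs$ani_pct >= ani_min &
    pmin(pairs$coverage_ab_pct, pairs$coverage_ba_pct) > cov_min
  edges <- pairs[redundant, c("id_a", "id_b"), drop = FALSE]
  if (nrow(edges) == 0) {
    return(list(kept = ids, removed = character(0), components = list()))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- lapply(groups, sort)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  removed <- with_seed(seed, {
    unlist(lapply(groups, function(members) {
      keep <- members[sample.int(length(members), 1L)]
      setdiff(members, keep)
    }), use.names = FALSE)
  })
  list(kept = setdiff(ids, removed),
       removed = removed %||% character(0),
       components = unname(groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
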