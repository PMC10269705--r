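AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

.check_protein <- function(seq, what) {
  if (!nzchar(seq)) .fail("%s sequence is empty", what)
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(ch), AA_ALPHABET)
  if (length(bad)) .fail("%s sequence contains invalid letters: %s", what,
                         paste(bad, collapse = ""))
  ch
}

#' Global alignment percent identity between two proteins
#'
#' Needleman–Wunsch with match +1, mismatch 0 and linear gap penalty -1;
#' `X` never matches. Identity is 100 x matched columns / total alignment
#' columns, gap columns included in the denominator. The traceback prefers
#' diagonal over up over left, so tied optima resolve deterministically.
#'
#' @param seq_a,seq_b protein strings over the 20-letter alphabet (plus X).
#' @return named numeric vector: `identity_pct`, `alignment_length`.
#' @export
global_identity <- function(seq_a, seq_b) {
  a <- .check_protein(seq_a, "first")
  b <- .check_protein(seq_b, "second")
  la <- length(a); lb <- length(b)
  S <- matrix(0, la + 1, lb + 1)
  S[, 1] <- -(0:la)
  S[1, ] <- -(0:lb)
  jj <- seq_len(lb)
  for (i in seq_len(la)) {
    sub <- as.numeric(a[i] == b & a[i] != "X" & b != "X")
    tmp <- pmax(S[i, jj] + sub, S[i, jj + 1] - 1)      # diag, up
    g <- cummax(c(S[i + 1, 1], tmp + jj))              # left chain via cummax
    S[i + 1, jj + 1] <- g[jj + 1] - jj
  }
  # traceback, diagonal > up > left
  i <- la; j <- lb; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (i > 0 && j > 0) {
      sub <- as.numeric(a[i] == b[j] && a[i] != "X" && b[j] != "X")
      if (S[i + 1, j + 1] == S[i, j] + sub) {
        matches <- matches + as.integer(sub == 1)
        i <- i - 1; j <- j - 1
        next
      }
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  c(identity_pct = 100 * matches / cols, alignment_length = cols)
}

# reference headers carry the family after a pipe: ">id|FAMILY"
.parse_family <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- headers[vapply(parts, length, 1L) < 2]
  if (length(bad)) {
    .fail("reference header(s) without '|FAMILY' suffix: %s",
          paste(bad, collapse = ", "))
  }
  vapply(parts, function(p) p[[2]], "")
}

#' Assign query proteins to reference families by best-hit identity
#'
#' Every query is globally aligned against every reference; the best hit is
#' the reference with the highest percent identity (ties broken by longer
#' alignment, then lexicographic reference id). A query is kept only when
#' its best identity is strictly greater than `min_identity` percent.
#'
#' @param queries named character vector of protein sequences (or
#'   `Biostrings::AAStringSet`).
#' @param refdb named character vector of reference sequences with headers
#'   `id|FAMILY` (or `AAStringSet`).
#' @param min_identity keep threshold in percent (strict), default 40.
#' @return data.frame: query, ref, family, identity_pct, alignment_length,
#'   kept.
#' @export
assign_families <- function(queries, refdb, min_identity = 40) {
  queries <- .as_seq_vector(queries, "queries")
  refdb <- .as_seq_vector(refdb, "refdb")
  if (length(refdb) == 0) .fail("reference database is empty")
  fam <- .parse_family(names(refdb))
  ref_ids <- sub("\\|.*$", "", names(refdb))
  ord <- order(ref_ids)
  out <- lapply(seq_along(queries), function(qi) {
    hits <- vapply(refdb, function(r) global_identity(queries[[qi]], r),
                   c(identity_pct = 0, alignment_length = 0))
    best <- ord[order(-hits["identity_pct", ord],
                      -hits["alignment_length", ord])][1]
    data.frame(query = names(queries)[qi],
               ref = ref_ids[best],
               family = fam[best],
               identity_pct = hits["identity_pct", best],
               alignment_length = hits["alignment_length", best],
               kept = hits["identity_pct", best] > min_identity,
               row.names = NULL)
  })
  do.call(rbind, out)
}

.as_seq_vector <- function(x, what) {
  if (inherits(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x)) .fail("%s must be a named character vector or AAStringSet", what)
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    .fail("%s must be named", what)
  }
  x
}

#' Per-strain feature-class counts from kept assignments
#'
#' @param assignments data.frame from [assign_families()].
#' @param class_of named character vector, family -> feature class (e.g.
#'   "GH13" -> "GH"); must cover every kept family.
#' @param strain_of optional named vector, query id -> strain id; when
#'   omitted all queries count toward a single strain `"all"`.
#' @param classes optional class universe; classes with no hits get 0.
#' @return strains x classes integer matrix (raw counts, `normalized`
#'   attribute FALSE).
#' @export
class_counts <- function(assignments, class_of, strain_of = NULL, classes = NULL) {
  kept <- assignments[assignments$kept, , drop = FALSE]
  unmapped <- setdiff(unique(kept$family), names(class_of))
  if (length(unmapped)) .fail("families without a class: %s", paste(unmapped, collapse = ", "))
  strains <- if (is.null(strain_of)) {
    stats::setNames(rep("all", nrow(assignments)), assignments$query)
  } else strain_of
  if (is.null(classes)) classes <- sort(unique(class_of))
  all_strains <- sort(unique(strains[assignments$query]))
  m <- matrix(0L, length(all_strains), length(classes),
              dimnames = list(all_strains, classes))
  if (nrow(kept)) {
    cl <- class_of[kept$family]
    st <- strains[kept$query]
    t <- table(st, cl)
    m[rownames(t), colnames(t)] <- m[rownames(t), colnames(t)] + t
  }
  attr(m, "normalized") <- FALSE
  m
}

#' Normalise a feature table to counts per megabase
#'
#' @param features strains x classes raw count matrix.
#' @param sizes_bp named numeric vector, strain id -> genome size in bp.
#' @return matrix of per-Mb rates with `normalized` attribute TRUE.
#' @export
per_mb <- function(features, sizes_bp) {
  m <- as.matrix(features)
  miss <- setdiff(rownames(m), names(sizes_bp))
  if (length(miss)) .fail("missing genome sizes for: %s", paste(miss, collapse = ", "))
  sz <- sizes_bp[rownames(m)]
  if (any(sz <= 0)) .fail("genome sizes must be positive")
  out <- m / (sz / 1e6)
  attr(out, "normalized") <- TRUE
  out
}
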