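#' Read and write the package's tabular formats
#'
#' Plain TSV with a header row. Matrices (orthogroups, features, distance
#' matrices) carry their row labels in a leading `id` column.
#'
#' @param path file path.
#' @name pgpan-io
NULL

#' @rdname pgpan-io
#' @export
read_genomes_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pgpan-io
#' @param df data.frame to write.
#' @export
write_genomes_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname pgpan-io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pgpan-io
#' @param m matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname pgpan-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname pgpan-io
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `genomes.tsv`, `tree.nwk`, `orthogroups.tsv`, `ani_pairs.tsv`,
#' `features.tsv` and `truth.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genomes_tsv(cohort$records, file.path(dir, "genomes.tsv"))
  writeLines(write_newick(cohort$tree), file.path(dir, "tree.nwk"))
  write_matrix_tsv(cohort$ortho, file.path(dir, "orthogroups.tsv"))
  write_genomes_tsv(cohort$ani_pairs, file.path(dir, "ani_pairs.tsv"))
  write_matrix_tsv(cohort$features, file.path(dir, "features.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
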