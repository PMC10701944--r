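## External formats: MatrixMarket for matrices, JSON-lines for sequences.

#' Write a feature matrix as MatrixMarket plus sidecars
#'
#' Writes `matrix.mtx` (sparse MatrixMarket), `feature_map.tsv` and
#' `row_ids.txt` under `dir`.
#'
#' @param fm a `feature_matrix`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(fm$matrix, file.path(dir, "matrix.mtx"))
  data.table::fwrite(fm$feature_map, file.path(dir, "feature_map.tsv"), sep = "\t")
  writeLines(fm$row_ids, file.path(dir, "row_ids.txt"))
  invisible(dir)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param dir directory holding `matrix.mtx`, `feature_map.tsv`, `row_ids.txt`.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  fmap <- data.table::fread(file.path(dir, "feature_map.tsv"),
                            colClasses = list(character = "concept_id"))
  row_ids <- readLines(file.path(dir, "row_ids.txt"))
  dimnames(m) <- list(row_ids, paste0(fmap$concept_id, "_", fmap$window))
  new_feature_matrix(m, fmap, numeric_cols = which(fmap$concept_id == "age"))
}

#' Write visit sequences as JSON-lines
#'
#' One JSON object per observation: `observation_id`, `outcome`, `static`
#' (age, sex), `days_before_index`, `concepts` (list of per-visit 0-based
#' concept index vectors). A `concept_map.tsv` sidecar is written alongside.
#'
#' @param seqs a `visit_sequences`.
#' @param path output `.jsonl` path; the sidecar goes next to it.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (oid in names(seqs$sequences)) {
    s <- seqs$sequences[[oid]]
    rec <- list(observation_id = oid,
                outcome = unname(seqs$outcome[[oid]]),
                static = as.list(seqs$static[oid, ]),
                days_before_index = s$days_before_index,
                concepts = lapply(s$concept_indices, function(v) v - 1L))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  data.table::fwrite(seqs$concept_map,
                     file.path(dirname(path), "concept_map.tsv"), sep = "\t")
  invisible(path)
}
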