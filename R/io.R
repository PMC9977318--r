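#' Write a count matrix as MatrixMarket plus index files
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if needed).
#' @param prefix file prefix.
#' @return invisibly, the paths written.
#' @export
write_counts_mtx <- function(counts, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.txt", "_cells.txt")))
  Matrix::writeMM(m, paths[1L])
  writeLines(rownames(counts), paths[2L])
  writeLines(colnames(counts), paths[3L])
  invisible(paths)
}

#' Read a count matrix written by [write_counts_mtx()]
#' @param dir directory; @param prefix file prefix.
#' @return genes x cells dense integer matrix.
#' @export
read_counts_mtx <- function(dir, prefix = "counts") {
  m <- as.matrix(Matrix::readMM(file.path(dir, paste0(prefix, ".mtx"))))
  rownames(m) <- readLines(file.path(dir, paste0(prefix, "_genes.txt")))
  colnames(m) <- readLines(file.path(dir, paste0(prefix, "_cells.txt")))
  storage.mode(m) <- "integer"
  m
}

write_stage_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = !is.null(rownames(x)))
  path
}
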