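#' Write a pixel-by-sgRNA matrix as Matrix Market plus axis tables
#'
#' Writes `matrix.mtx` (sparse counts), `pixels.tsv`
#' (`position_id  a  b`), `sgrnas.tsv` (`name`), and `long_counts.tsv`
#' (`a  b  sgRNA  umi_count`, non-zero entries only) into `dir`.
#'
#' @param x An `sgrna_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sgrna_matrix <- function(x, dir) {
  stopifnot(inherits(x, "sgrna_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  ab <- pixel_ab(rownames(x$counts))
  write.table(data.frame(position_id = rownames(x$counts), a = ab$a, b = ab$b),
              file.path(dir, "pixels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(name = colnames(x$counts)),
              file.path(dir, "sgrnas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sm <- methods::as(x$counts, "TsparseMatrix")
  long <- data.frame(a = ab$a[sm@i + 1L], b = ab$b[sm@i + 1L],
                     sgRNA = colnames(x$counts)[sm@j + 1L],
                     umi_count = sm@x)
  write.table(long[order(long$a, long$b), ],
              file.path(dir, "long_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a pixel-by-sgRNA matrix written by [write_sgrna_matrix()]
#' @param dir Directory holding `matrix.mtx`, `pixels.tsv`, `sgrnas.tsv`.
#' @return An `sgrna_matrix`.
#' @export
read_sgrna_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  pixels <- read.delim(file.path(dir, "pixels.tsv"))
  sgrnas <- read.delim(file.path(dir, "sgrnas.tsv"))
  dimnames(m) <- list(pixels$position_id, sgrnas$name)
  structure(list(counts = m, grid = c(max(pixels$a), max(pixels$b)),
                 provenance = list(source = dir)),
            class = "sgrna_matrix")
}

#' Read a tissue mask TSV
#'
#' Accepts either columns `a`, `b` or a single `position_id` column of
#' `"AxB"` ids.
#' @param path TSV file path.
#' @return Data frame with integer columns `a`, `b`.
#' @export
read_mask <- function(path) {
  tab <- read.delim(path)
  if (all(c("a", "b") %in% names(tab)))
    return(data.frame(a = as.integer(tab$a), b = as.integer(tab$b)))
  if ("position_id" %in% names(tab)) return(pixel_ab(tab$position_id))
  stop("mask must have columns a/b or position_id")
}

#' Write a rejection-reason summary TSV
#' @param result A `demux_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reject_summary <- function(result, path) {
  tab <- as.data.frame(table(factor(result$rejects$reason, REJECT_REASONS)))
  names(tab) <- c("reason", "n_reads")
  tab <- rbind(tab, data.frame(reason = "assigned",
                               n_reads = nrow(result$assignments)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pixel-by-gene count matrix as Matrix Market plus axis tables
#' @param counts Pixel x gene matrix (rows named by position id).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_gex_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(position_id = rownames(counts)),
              file.path(dir, "pixels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = colnames(counts)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a pixel-by-gene matrix written by [write_gex_matrix()]
#' @param dir Directory holding `matrix.mtx`, `pixels.tsv`, `genes.tsv`.
#' @return Dense pixel x gene matrix.
#' @export
read_gex_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  dimnames(m) <- list(read.delim(file.path(dir, "pixels.tsv"))$position_id,
                      read.delim(file.path(dir, "genes.tsv"))$gene)
  m
}
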