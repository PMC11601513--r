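#' Load a spatial barcode whitelist
#'
#' Reads a tab-separated whitelist with columns `index` and `sequence`
#' (1-based, stable index order). An optional leading comment of the form
#' `# linker=ACGT...` records the ligation linker associated with the set.
#'
#' @param path TSV file path.
#' @param set_name Barcode set, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return An object of class `barcode_whitelist` with fields `set_name`,
#'   `entries` (character vector ordered by index) and `linker`.
#' @export
load_whitelist <- function(path, set_name = c("A", "B", "C", "D")) {
  set_name <- match.arg(set_name)
  lines <- readLines(path)
  linker <- NA_character_
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("linker\\s*=\\s*[ACGT]+", hdr))
  if (length(m)) linker <- sub("linker\\s*=\\s*", "", m[1])
  tab <- read.delim(text = lines[!grepl("^#", lines)], header = TRUE,
                    colClasses = c("integer", "character"))
  if (!all(c("index", "sequence") %in% names(tab)))
    stop("whitelist must have columns 'index' and 'sequence'")
  tab <- tab[order(tab$index), , drop = FALSE]
  barcode_whitelist(tab$sequence, set_name, linker = linker)
}

#' Construct a barcode whitelist from sequences
#'
#' @param entries Character vector of distinct 8-mers, in index order.
#' @param set_name Barcode set (`A`/`B`/`C`/`D`).
#' @param linker Optional 10-mer ligation linker associated with the set.
#' @return A `barcode_whitelist`.
#' @export
barcode_whitelist <- function(entries, set_name = "A", linker = NA_character_) {
  len <- nchar(entries)
  if (any(len != 8L))
    stop("whitelist entries must all be 8-mers; offending entries: ",
         paste(entries[len != 8L], collapse = ", "))
  if (anyDuplicated(entries))
    stop("duplicate whitelist sequences: ",
         paste(unique(entries[duplicated(entries)]), collapse = ", "))
  if (any(grepl("[^ACGT]", entries)))
    stop("whitelist entries must be ACGT strings")
  structure(list(set_name = set_name, entries = entries, linker = linker),
            class = "barcode_whitelist")
}

#' Write a barcode whitelist to TSV
#' @param wl A `barcode_whitelist`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(wl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(wl$linker)) writeLines(paste0("# linker=", wl$linker), con)
  writeLines("index\tsequence", con)
  writeLines(paste(seq_along(wl$entries), wl$entries, sep = "\t"), con)
  invisible(path)
}

# Random distinct k-mers with minimum pairwise Hamming distance, grown
# greedily under a fixed seed.
.random_kmers_min_dist <- function(n, k, min_dist, max_tries = 50000L) {
  out <- character(0)
  mat <- matrix(integer(0), nrow = 0, ncol = k)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not generate ", n, " ", k, "-mers at min distance ", min_dist)
    cand <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    ci <- match(cand, c("A", "C", "G", "T"))
    if (nrow(mat) > 0) {
      d <- rowSums(mat != matrix(ci, nrow(mat), k, byrow = TRUE))
      if (min(d) < min_dist) next
    }
    mat <- rbind(mat, ci)
    out <- c(out, paste(cand, collapse = ""))
  }
  out
}

#' Generate a synthetic barcode whitelist
#'
#' Random distinct 8-mers with a minimum pairwise Hamming distance, so that
#' single-substitution correction is always unambiguous. These stand in for
#' production channel barcodes, which are instrument-specific.
#'
#' @param n Number of barcodes.
#' @param set_name Barcode set label.
#' @param seed RNG seed.
#' @param width Barcode length (8).
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @return A `barcode_whitelist`.
#' @export
synthetic_whitelist <- function(n, set_name = "A", seed = 0, width = 8,
                                min_dist = 3) {
  set.seed(seed + match(set_name, c("A", "B", "C", "D")) * 1000L)
  barcode_whitelist(.random_kmers_min_dist(n, width, min_dist), set_name,
                    linker = paste(sample(c("A", "C", "G", "T"), 10,
                                          replace = TRUE), collapse = ""))
}

#' Load an sgRNA spacer library
#'
#' Reads a TSV with columns `name`, `spacer` and optionally `gene`. Spacer
#' sequences must be 15-30 nt; duplicate names are an error, duplicate
#' spacer sequences only a warning (they are flagged, not dropped).
#'
#' @param path TSV file path.
#' @param ntc_pattern Regular expression identifying non-targeting control
#'   names (case-insensitive).
#' @return An object of class `spacer_library`: a data frame with columns
#'   `name`, `spacer`, `gene`, plus attributes `ntc_names` and
#'   `duplicated_spacers`.
#' @export
load_spacer_library <- function(path, ntc_pattern = "NTC|non.?target") {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("name", "spacer") %in% names(tab)))
    stop("spacer library must have columns 'name' and 'spacer'")
  if (!"gene" %in% names(tab)) tab$gene <- NA_character_
  spacer_library(tab$name, tab$spacer, tab$gene, ntc_pattern)
}

#' Construct an sgRNA spacer library
#' @param name sgRNA names (unique).
#' @param spacer Spacer sequences, 15-30 nt each.
#' @param gene Optional target gene symbols.
#' @param ntc_pattern Regex marking non-targeting controls.
#' @return A `spacer_library` data frame.
#' @export
spacer_library <- function(name, spacer, gene = NA_character_,
                           ntc_pattern = "NTC|non.?target") {
  len <- nchar(spacer)
  if (any(len < 15L | len > 30L))
    stop("spacer lengths must be within [15, 30]; offending: ",
         paste(name[len < 15L | len > 30L], collapse = ", "))
  if (anyDuplicated(name))
    stop("duplicate sgRNA names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (any(grepl("[^ACGT]", spacer)))
    stop("spacer sequences must be ACGT strings")
  dup <- unique(spacer[duplicated(spacer)])
  if (length(dup))
    warning("duplicate spacer sequences shared by multiple sgRNAs: ",
            paste(dup, collapse = ", "))
  out <- data.frame(name = name, spacer = spacer,
                    gene = rep_len(gene, length(name)),
                    stringsAsFactors = FALSE)
  attr(out, "ntc_names") <- name[grepl(ntc_pattern, name, ignore.case = TRUE)]
  attr(out, "duplicated_spacers") <- dup
  class(out) <- c("spacer_library", "data.frame")
  out
}

#' Write a spacer library to TSV
#' @param lib A `spacer_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spacer_library <- function(lib, path) {
  write.table(as.data.frame(lib)[, c("name", "spacer", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic sgRNA spacer library
#'
#' Random 20-mer spacers at a minimum pairwise Hamming distance (default 5,
#' so two-substitution matching cannot collide), named `<gene>_sg1` with one
#' gene per guide plus optional `NTC_sg<i>` non-targeting controls.
#'
#' @param n_genes Number of targeting guides (one per synthetic gene).
#' @param n_ntc Number of non-targeting controls.
#' @param seed RNG seed.
#' @param spacer_len Spacer length (20).
#' @param min_dist Minimum pairwise Hamming distance.
#' @return A `spacer_library`.
#' @export
synthetic_spacer_library <- function(n_genes, n_ntc = 0, seed = 0,
                                     spacer_len = 20, min_dist = 5) {
  set.seed(seed + 77L)
  n <- n_genes + n_ntc
  seqs <- .random_kmers_min_dist(n, spacer_len, min_dist)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  nm <- c(paste0(genes, "_sg1"),
          if (n_ntc > 0) sprintf("NTC_sg%d", seq_len(n_ntc)))
  gn <- c(genes, rep(NA_character_, n_ntc))
  spacer_library(nm, seqs, gn)
}
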