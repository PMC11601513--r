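#' @importFrom stats median prcomp rbinom rnbinom rpois runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

ELEMENT_NAMES <- c("barcode_A", "barcode_B", "barcode_C", "barcode_D",
                   "umi", "spacer")
DIALECTS <- c("polyA_enrichment", "capture_v1", "capture_v2", "pixel100")

#' Extraction rule for one read element
#'
#' An element rule describes how one component of a read pair (a spatial
#' barcode, the UMI, or the sgRNA spacer) is located and clipped out of the
#' raw sequence: which mate carries it, the constant flank(s) that anchor it,
#' the admissible length range, and the error tolerance applied when locating
#' the flank.
#'
#' @param element_name One of `barcode_A`, `barcode_B`, `barcode_C`,
#'   `barcode_D`, `umi`, `spacer`.
#' @param read_of_pair Mate carrying the element (1 or 2).
#' @param flank5,flank3 Constant sequences immediately 5' / 3' of the element
#'   (uppercase ACGTN; `N` matches any base). Either may be empty, but not
#'   both.
#' @param min_len,max_len Admissible element length in nt.
#' @param fixed_len Optional fixed element length; when set the element is
#'   clipped to exactly this many bases next to the anchoring flank.
#' @param error_rate Fraction of the flank length allowed as substitutions
#'   when locating the flank (in `[0, 0.25]`).
#' @param min_overlap Minimum number of flank bases required when the flank
#'   runs off a read end.
#' @param discard_untrimmed Reject reads in which the flank is not found.
#' @param max_n Maximum number of ambiguous (`N`) bases tolerated in the
#'   extracted element; use `Inf` for unlimited.
#' @return An object of class `element_rule`.
#' @export
element_rule <- function(element_name, read_of_pair, flank5 = "", flank3 = "",
                         min_len, max_len, fixed_len = NULL,
                         error_rate = 0.1, min_overlap = 3,
                         discard_untrimmed = TRUE, max_n = 0) {
  if (!element_name %in% ELEMENT_NAMES)
    stop("element_name must be one of: ", paste(ELEMENT_NAMES, collapse = ", "))
  if (!read_of_pair %in% c(1L, 2L))
    stop("read_of_pair must be 1 or 2 (element ", element_name, ")")
  for (fl in c(flank5 = flank5, flank3 = flank3)) {
    if (nchar(fl) > 0 && grepl("[^ACGTN]", fl))
      stop("flanks must be uppercase ACGTN strings (element ", element_name, ")")
  }
  if (nchar(flank5) == 0 && nchar(flank3) == 0)
    stop("at least one flank required (element ", element_name, ")")
  if (min_len > max_len)
    stop("min_len must be <= max_len (element ", element_name, ")")
  if (!is.null(fixed_len) && (fixed_len < min_len || fixed_len > max_len))
    stop("fixed_len must lie in [min_len, max_len] (element ", element_name, ")")
  if (error_rate < 0 || error_rate > 0.25)
    stop("error_rate must be in [0, 0.25] (element ", element_name, ")")
  structure(list(
    element_name = element_name,
    read_of_pair = as.integer(read_of_pair),
    flank5 = flank5, flank3 = flank3,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    fixed_len = if (is.null(fixed_len)) NULL else as.integer(fixed_len),
    error_rate = error_rate, min_overlap = as.integer(min_overlap),
    discard_untrimmed = isTRUE(discard_untrimmed),
    max_n = max_n
  ), class = "element_rule")
}

#' Read chemistry schema
#'
#' Bundles the per-element extraction rules of one chemistry dialect with the
#' pixel grid dimensions, the modality policy used to separate sgRNA from
#' mRNA reads, and the read templates used by the simulator (the inverse of
#' the extraction rules).
#'
#' @param name Dialect name; one of `polyA_enrichment`, `capture_v1`,
#'   `capture_v2`, `pixel100`.
#' @param rules List of [element_rule()] objects, exactly one per element.
#' @param pixel_grid Integer vector `(n_A, n_B)` of channel counts; each must
#'   be 50 or 100.
#' @param modality_policy `"spacer-match"` (reads whose insert matches a
#'   spacer are sgRNA reads) or `"barcode-set"` (sgRNA reads carry the C/D
#'   barcode sets).
#' @param read_template Named list with `read1` and `read2` character
#'   vectors; entries are literal sequences or `"<element_name>"` slots.
#' @return An object of class `chemistry_schema`.
#' @export
chemistry_schema <- function(name, rules, pixel_grid,
                             modality_policy = c("spacer-match", "barcode-set"),
                             read_template = NULL) {
  if (!name %in% DIALECTS)
    stop("unknown dialect '", name, "'; known dialects: ",
         paste(DIALECTS, collapse = ", "))
  modality_policy <- match.arg(modality_policy)
  stopifnot(length(pixel_grid) == 2)
  if (!all(pixel_grid %in% c(50L, 100L)))
    stop("pixel_grid dimensions must be 50 or 100")
  if (!all(vapply(rules, inherits, logical(1), "element_rule")))
    stop("rules must be a list of element_rule objects")
  nm <- vapply(rules, `[[`, character(1), "element_name")
  if (anyDuplicated(nm))
    stop("duplicate rule for element: ", nm[duplicated(nm)][1])
  names(rules) <- nm
  required <- if (modality_policy == "barcode-set")
    c("barcode_C", "barcode_D", "umi", "spacer")
  else c("barcode_A", "barcode_B", "umi", "spacer")
  missing <- setdiff(required, nm)
  if (length(missing))
    stop("schema lacks required element rule(s): ",
         paste(missing, collapse = ", "))
  structure(list(name = name, rules = rules,
                 pixel_grid = as.integer(pixel_grid),
                 modality_policy = modality_policy,
                 read_template = read_template),
            class = "chemistry_schema")
}

# Constant flank strings of the four printed dialects. The PolyA spacer 5'
# flank carries four terminal G, the capture/pixel100 variants three.
.preset_def <- function(name) {
  sp3 <- "GTTTTAGAGCTAGAAATAGC"
  switch(name,
    polyA_enrichment = list(
      grid = c(50L, 50L),
      bcA5 = "ATCCACGTGCTTGAGAGGCCAGAGCATTCG",
      bcB5 = "CAAGCGTTGGCTTCTCGCATCT", bcB3 = "",
      umi5 = "GGCCGATGTTTCGCATCGGCGTACGACT",
      sp5  = "GGTATCAACGCAGAGTGAATGGGG", sp3 = sp3),
    capture_v1 = list(
      grid = c(50L, 50L),
      bcA5 = "CCCATGATCGTCCGACGCGCTGCATACTTG",
      bcB5 = "", bcB3 = "CCCATGATCGTCCGACGCGCTGCATACTTG",
      umi5 = "GTGGCCGATGTTTCGCCCATGATCGTCCGA",
      sp5  = "GGTATCAACGCAGAGTGAATGGG", sp3 = sp3),
    capture_v2 = list(
      grid = c(50L, 50L),
      bcA5 = "CCCATGATCGTCCGACGCGCTGCATACTTG",
      bcB5 = "GTCAGATGTGTATAAGAGACAG", bcB3 = "",
      umi5 = "GATATCGGTCTCGTGGGCTCGG",
      sp5  = "GGTATCAACGCAGAGTGAATGGG", sp3 = sp3),
    pixel100 = list(
      grid = c(100L, 100L),
      bcA5 = "ATCCACGTGCTTGAGAGGCCAGAGCATTCG",
      # barcode B sits 10 nt (the UMI) downstream of the ligation linker;
      # encoded as linker + 10 wildcard positions, anchored with -O 13.
      bcB5 = paste0("CAAGCGTTGGCTTCTCGCATCT", strrep("N", 10)), bcB3 = "",
      umi5 = "CAAGCGTTGGCTTCTCGCATCT",
      sp5  = "GGTATCAACGCAGAGTGAATGGG", sp3 = sp3),
    stop("unknown dialect '", name, "'; known dialects: ",
         paste(DIALECTS, collapse = ", "))
  )
}

#' Built-in chemistry presets
#'
#' Returns the fully specified schema for one of the four supported read
#' chemistries (`polyA_enrichment`, `capture_v1`, `capture_v2`, `pixel100`),
#' including the flank sequences, length windows and error tolerances of
#' every element, and the read templates used by [emit_reads()].
#'
#' @param name Dialect name.
#' @return A `chemistry_schema`.
#' @examples
#' sc <- chemistry_preset("polyA_enrichment")
#' sc$rules$barcode_A$flank5
#' @export
chemistry_preset <- function(name) {
  d <- .preset_def(name)
  mo_bcB <- if (name == "pixel100") 13L else 3L
  rules <- list(
    element_rule("barcode_A", 2L, flank5 = d$bcA5,
                 min_len = 8, max_len = 10, fixed_len = 8),
    element_rule("barcode_B", 2L, flank5 = d$bcB5, flank3 = d$bcB3,
                 min_len = 8, max_len = 10, fixed_len = 8,
                 min_overlap = mo_bcB),
    element_rule("umi", 2L, flank5 = d$umi5,
                 min_len = 10, max_len = 12, fixed_len = 10, max_n = 0),
    element_rule("spacer", 1L, flank5 = d$sp5, flank3 = d$sp3,
                 min_len = 15, max_len = 30, min_overlap = 6)
  )
  # Simulator templates: read 1 carries the spacer between its two flanks,
  # read 2 carries UMI then barcode B then barcode A, each behind its anchor.
  r2 <- switch(name,
    polyA_enrichment = c(d$umi5, "<umi>", d$bcB5, "<barcode_B>",
                         d$bcA5, "<barcode_A>"),
    capture_v1 = c(d$umi5, "<umi>", "<barcode_B>", d$bcA5, "<barcode_A>"),
    capture_v2 = c(d$umi5, "<umi>", d$bcB5, "<barcode_B>",
                   d$bcA5, "<barcode_A>"),
    pixel100 = c("CAAGCGTTGGCTTCTCGCATCT", "<umi>", "<barcode_B>",
                 d$bcA5, "<barcode_A>"))
  tmpl <- list(
    read1 = c(d$sp5, "<spacer>", d$sp3, strrep("T", 20)),
    read2 = c(r2, strrep("T", 20))
  )
  chemistry_schema(name, rules, d$grid, "spacer-match", read_template = tmpl)
}

#' Load a chemistry schema from a preset name or config file
#'
#' @param x A preset dialect name, or the path of a YAML schema file as
#'   written by [write_schema()].
#' @return A `chemistry_schema`.
#' @export
load_schema <- function(x) {
  if (x %in% DIALECTS) return(chemistry_preset(x))
  if (!file.exists(x))
    stop("'", x, "' is neither a known dialect (",
         paste(DIALECTS, collapse = ", "), ") nor a readable file")
  cfg <- yaml::read_yaml(x)
  if (is.null(cfg$name) || !cfg$name %in% DIALECTS)
    stop("unknown dialect '", cfg$name, "'; known dialects: ",
         paste(DIALECTS, collapse = ", "))
  rules <- lapply(cfg$rules, function(r) {
    element_rule(r$element_name, r$read_of_pair,
                 flank5 = r$flank5 %||% "", flank3 = r$flank3 %||% "",
                 min_len = r$min_len, max_len = r$max_len,
                 fixed_len = r$fixed_len,
                 error_rate = r$error_rate %||% 0.1,
                 min_overlap = r$min_overlap %||% 3,
                 discard_untrimmed = r$discard_untrimmed %||% TRUE,
                 max_n = if (identical(r$max_n, "unlimited")) Inf else
                   (r$max_n %||% 0))
  })
  tmpl <- cfg$read_template
  if (!is.null(tmpl))
    tmpl <- list(read1 = unlist(tmpl$read1), read2 = unlist(tmpl$read2))
  chemistry_schema(cfg$name, rules, unlist(cfg$pixel_grid),
                   cfg$modality_policy %||% "spacer-match", tmpl)
}

#' Serialize a chemistry schema to a YAML config file
#'
#' The written file reloads field-identically through [load_schema()].
#'
#' @param schema A `chemistry_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  rules <- lapply(unname(schema$rules), function(r) {
    r <- unclass(r)
    r$max_n <- if (is.infinite(r$max_n)) "unlimited" else r$max_n
    r[!vapply(r, is.null, logical(1))]
  })
  yaml::write_yaml(list(
    name = schema$name, pixel_grid = schema$pixel_grid,
    modality_policy = schema$modality_policy, rules = rules,
    read_template = schema$read_template
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chemistry_schema <- function(x, ...) {
  cat("chemistry_schema '", x$name, "': grid ", x$pixel_grid[1], "x",
      x$pixel_grid[2], ", modality ", x$modality_policy, "\n", sep = "")
  for (r in x$rules)
    cat(sprintf("  %-10s read %d  len %d-%d%s  flank5 %s  flank3 %s\n",
                r$element_name, r$read_of_pair, r$min_len, r$max_len,
                if (is.null(r$fixed_len)) "" else paste0(" (fixed ", r$fixed_len, ")"),
                if (nzchar(r$flank5)) r$flank5 else "-",
                if (nzchar(r$flank3)) r$flank3 else "-"))
  invisible(x)
}
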