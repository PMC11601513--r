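REJECT_REASONS <- c("no_flank", "length_out_of_range", "too_many_N",
                    "no_barcode_match", "ambiguous_barcode",
                    "umi_not_in_whitelist", "no_spacer_match",
                    "ambiguous_spacer")

.as_char_reads <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readDNAStringSet(x, format = "fastq")
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  as.character(x)
}

# First full occurrence of `flank` in each read, allowing
# ceiling(error_rate * flank_len) substitutions (N in the flank matches any
# base). If no full occurrence exists, a flank running off the near read end
# is accepted down to `min_overlap` bases.
.locate_flank <- function(reads, flank, error_rate, min_overlap,
                          side = c("5prime", "3prime"), from = NULL) {
  side <- match.arg(side)
  n <- length(reads)
  len <- nchar(flank)
  mm <- ceiling(error_rate * len)
  subj <- Biostrings::DNAStringSet(reads)
  hits <- Biostrings::vmatchPattern(flank, subj, max.mismatch = mm,
                                    fixed = FALSE)
  start <- rep(NA_integer_, n); end <- rep(NA_integer_, n)
  si <- Biostrings::startIndex(hits)
  for (i in seq_len(n)) {
    s <- si[[i]]
    if (is.null(s) || length(s) == 0) next
    if (!is.null(from)) {
      if (is.na(from[i])) next
      s <- s[s > from[i]]
    }
    if (length(s) == 0) next
    start[i] <- min(s); end[i] <- min(s) + len - 1L
  }
  # partial flank at the read end nearest the element
  unresolved <- which(is.na(start))
  if (length(unresolved) && min_overlap < len) {
    for (L in seq(len - 1L, min_overlap)) {
      if (!length(unresolved)) break
      tol <- ceiling(error_rate * L)
      if (side == "5prime") {
        frag <- substr(flank, len - L + 1L, len)
        seg <- substr(reads[unresolved], 1L, L)
        ok <- .hamming_vec(seg, frag) <= tol & nchar(seg) == L
        if (!is.null(from)) ok <- ok & (0L > from[unresolved])
        ok[is.na(ok)] <- FALSE
        start[unresolved[ok]] <- 1L - (len - L)  # virtual start before read
        end[unresolved[ok]] <- L
      } else {
        frag <- substr(flank, 1L, L)
        rl <- nchar(reads[unresolved])
        seg <- substr(reads[unresolved], rl - L + 1L, rl)
        ok <- .hamming_vec(seg, frag) <= tol & nchar(seg) == L
        if (!is.null(from)) ok <- ok & (rl - L + 1L > from[unresolved])
        ok[is.na(ok)] <- FALSE
        start[unresolved[ok]] <- rl[ok] - L + 1L
        end[unresolved[ok]] <- rl[ok] + (len - L)
      }
      unresolved <- which(is.na(start))
    }
  }
  data.frame(start = start, end = end)
}

# Hamming distance between equal-length strings (N in `ref` matches any).
.hamming_vec <- function(x, ref) {
  rs <- strsplit(ref, "", fixed = TRUE)[[1]]
  xs <- strsplit(x, "", fixed = TRUE)
  vapply(xs, function(ch) {
    if (length(ch) != length(rs)) return(NA_integer_)
    sum(ch != rs & rs != "N")
  }, integer(1))
}

#' Extract a read element by its anchoring flank(s)
#'
#' Locates the rule's flank(s) allowing `ceiling(error_rate * flank_len)`
#' substitutions (with partial flank overlap of at least `min_overlap` bases
#' at read ends) and clips out the adjacent segment: after `flank5`, before
#' `flank3`, or between the two when both are set. Fixed-length elements are
#' clipped to `fixed_len`; variable-length elements must fall in
#' `[min_len, max_len]`.
#'
#' Rejections are returned as values, not raised: the result carries one row
#' per read with the extracted `segment` (`NA` when rejected) and a
#' `reject` reason (`no_flank`, `length_out_of_range`, `too_many_N`, or
#' `NA` on success).
#'
#' @param reads Character vector of read sequences (ACGTN), a
#'   `DNAStringSet`, or a FASTQ path.
#' @param rule An [element_rule()].
#' @return Data frame with columns `segment` and `reject`.
#' @export
extract_element <- function(reads, rule) {
  reads <- .as_char_reads(reads)
  n <- length(reads)
  seg <- rep(NA_character_, n)
  rej <- rep(NA_character_, n)
  rl <- nchar(reads)
  has5 <- nzchar(rule$flank5); has3 <- nzchar(rule$flank3)

  if (has5) {
    h5 <- .locate_flank(reads, rule$flank5, rule$error_rate,
                        rule$min_overlap, "5prime")
    miss <- is.na(h5$start)
    rej[miss] <- if (rule$discard_untrimmed) "no_flank" else NA_character_
    if (has3) {
      # linked 5'...3' extraction (spacer-style, variable length)
      h3 <- .locate_flank(reads, rule$flank3, rule$error_rate,
                          rule$min_overlap, "3prime", from = h5$end)
      miss3 <- !miss & is.na(h3$start)
      rej[miss3] <- "no_flank"
      ok <- !miss & !miss3
      st <- h5$end + 1L; en <- h3$start - 1L
      width <- en - st + 1L
      bad_len <- ok & (width < rule$min_len | width > rule$max_len)
      rej[bad_len] <- "length_out_of_range"
      take <- ok & !bad_len
      seg[take] <- substr(reads[take], st[take], en[take])
    } else {
      ok <- !miss
      st <- h5$end + 1L
      avail <- rl - h5$end
      bad_len <- ok & avail < rule$min_len
      rej[bad_len] <- "length_out_of_range"
      take <- ok & !bad_len
      want <- if (is.null(rule$fixed_len)) rule$max_len else rule$fixed_len
      en <- pmin(st + want - 1L, rl)
      seg[take] <- substr(reads[take], st[take], en[take])
    }
  } else if (has3) {
    h3 <- .locate_flank(reads, rule$flank3, rule$error_rate,
                        rule$min_overlap, "3prime")
    miss <- is.na(h3$start)
    rej[miss] <- if (rule$discard_untrimmed) "no_flank" else NA_character_
    ok <- !miss
    want <- if (is.null(rule$fixed_len)) rule$max_len else rule$fixed_len
    st <- h3$start - want; en <- h3$start - 1L
    bad_len <- ok & (h3$start - 1L) < rule$min_len
    rej[bad_len] <- "length_out_of_range"
    take <- ok & !bad_len
    seg[take] <- substr(reads[take], pmax(st[take], 1L), en[take])
  }
  if (is.finite(rule$max_n)) {
    nN <- vapply(gregexpr("N", seg, fixed = TRUE),
                 function(g) sum(g > 0), integer(1))
    too_n <- !is.na(seg) & nN > rule$max_n
    seg[too_n] <- NA_character_
    rej[too_n] <- "too_many_N"
  }
  data.frame(segment = seg, reject = rej, stringsAsFactors = FALSE)
}

#' Build a UMI whitelist from the data
#'
#' Extracts the UMI region of every read with the UMI rule and collects the
#' distinct passing 10-mers. Downstream UMI matching is exact membership in
#' this data-derived set.
#'
#' @param reads Reads of the UMI-bearing mate (character vector,
#'   `DNAStringSet`, or FASTQ path).
#' @param umi_rule The UMI [element_rule()].
#' @return Character vector of distinct UMIs. An empty whitelist triggers a
#'   warning; downstream matching then degenerates to pass-through.
#' @export
build_umi_whitelist <- function(reads, umi_rule) {
  ex <- extract_element(reads, umi_rule)
  wl <- unique(ex$segment[!is.na(ex$segment)])
  if (length(wl) == 0)
    warning("empty UMI whitelist; UMI matching degenerates to pass-through")
  wl
}

.seq_char_mat <- function(x) {
  do.call(rbind, strsplit(x, "", fixed = TRUE))
}

#' Mismatch-tolerant matching against an ordered reference set
#'
#' For each query, let `H` be the set of references within Hamming distance
#' `max_mismatches` (queries are compared only against references of equal
#' length; no gaps). If `|H| > max_hits` the query is ambiguous. Otherwise
#' the unique reference at minimal distance is returned; two or more
#' references tied at the minimal distance are ambiguous; an empty `H` is a
#' no-hit. Ambiguity is resolved by rejection, never arbitration, so the
#' result is deterministic.
#'
#' @param queries Character vector of query sequences.
#' @param references Ordered character vector of reference sequences; the
#'   returned index is 1-based into this vector.
#' @param max_mismatches Maximum Hamming distance.
#' @param max_hits Maximum size of the candidate set before rejection.
#' @return Data frame with columns `index` (integer, `NA` when unmatched)
#'   and `status` (`"hit"`, `"no_hit"`, `"ambiguous"`).
#' @export
match_with_tolerance <- function(queries, references, max_mismatches = 1,
                                 max_hits = 2) {
  n <- length(queries)
  index <- rep(NA_integer_, n)
  status <- rep("no_hit", n)
  qlen <- nchar(queries)
  rlen <- nchar(references)
  if (max_mismatches == 0) {
    idx <- match(queries, references)
    hit <- !is.na(idx)
    index[hit] <- idx[hit]
    status[hit] <- "hit"
    return(data.frame(index = index, status = status,
                      stringsAsFactors = FALSE))
  }
  if (length(unique(rlen)) == 1 && any(qlen != rlen[1]) &&
      all(qlen == qlen[1]))
    stop("query length ", qlen[1], " does not match reference length ",
         rlen[1])
  for (L in intersect(unique(qlen), unique(rlen))) {
    qi <- which(qlen == L); ri <- which(rlen == L)
    Q <- .seq_char_mat(queries[qi]); R <- .seq_char_mat(references[ri])
    D <- matrix(0L, length(qi), length(ri))
    for (l in seq_len(L))
      D <- D + outer(Q[, l], R[, l], "!=")
    nh <- rowSums(D <= max_mismatches)
    first <- max.col(-D, ties.method = "first")
    last <- max.col(-D, ties.method = "last")
    dmin <- D[cbind(seq_along(qi), first)]
    amb <- nh > max_hits | (nh >= 1 & first != last)
    ok <- nh >= 1 & nh <= max_hits & first == last & dmin <= max_mismatches
    status[qi[amb]] <- "ambiguous"
    status[qi[ok]] <- "hit"
    index[qi[ok]] <- ri[first[ok]]
  }
  data.frame(index = index, status = status, stringsAsFactors = FALSE)
}

#' Assign read pairs to pixel, sgRNA and UMI
#'
#' Runs flank-anchored extraction for every schema element on its designated
#' mate, then matches spatial barcodes against their whitelists (1 mismatch,
#' up to 2 candidate hits), the UMI exactly against the data-derived UMI
#' whitelist, and the spacer against the library (2 mismatches, up to 2
#' candidate hits). A read pair is assigned only when every element
#' resolves; otherwise it is rejected with the first failing element's
#' reason, processing elements in barcode A, barcode B, UMI, spacer order.
#'
#' @param r1,r2 Mate 1 / mate 2 reads (character vectors, `DNAStringSet`s,
#'   or FASTQ paths). Mates are paired by read id.
#' @param schema A `chemistry_schema`.
#' @param whitelists Named list of [barcode_whitelist()]s (`A`, `B`, and
#'   `C`, `D` for direct-capture schemas).
#' @param spacers A [spacer_library()].
#' @param umi_whitelist Optional precomputed UMI whitelist; built from the
#'   data with [build_umi_whitelist()] when `NULL`.
#' @param bc_max_mm,bc_max_hits Barcode matching tolerance (defaults 1, 2).
#' @param umi_max_mm,umi_max_hits UMI matching tolerance (defaults 0, 4).
#' @param sp_max_mm,sp_max_hits Spacer matching tolerance (defaults 2, 2).
#' @return An object of class `demux_result`: list with `assignments`
#'   (data frame `read_id`, `a`, `b`, `sgRNA`, `umi`), `rejects` (data frame
#'   `read_id`, `reason`), `n_total`, and `params`.
#' @export
assign_reads <- function(r1, r2, schema, whitelists, spacers,
                         umi_whitelist = NULL,
                         bc_max_mm = 1, bc_max_hits = 2,
                         umi_max_mm = 0, umi_max_hits = 4,
                         sp_max_mm = 2, sp_max_hits = 2) {
  r1 <- .as_char_reads(r1); r2 <- .as_char_reads(r2)
  if (!is.null(names(r1)) && !is.null(names(r2))) {
    if (!setequal(names(r1), names(r2)))
      stop("mates do not share read ids")
    r2 <- r2[names(r1)]
  } else if (length(r1) != length(r2)) {
    stop("mates do not share read ids")
  }
  ids <- names(r1) %||% sprintf("read_%07d", seq_along(r1))
  n <- length(r1)
  mates <- list(`1` = r1, `2` = r2)

  dc <- schema$modality_policy == "barcode-set"
  bc_a <- if (dc) "barcode_C" else "barcode_A"
  bc_b <- if (dc) "barcode_D" else "barcode_B"
  wl_a <- whitelists[[sub("barcode_", "", bc_a)]]
  wl_b <- whitelists[[sub("barcode_", "", bc_b)]]
  if (is.null(wl_a) || is.null(wl_b))
    stop("whitelists must name the ", sub("barcode_", "", bc_a), " and ",
         sub("barcode_", "", bc_b), " sets")

  if (is.null(umi_whitelist)) {
    ur <- schema$rules$umi
    umi_whitelist <- build_umi_whitelist(mates[[as.character(ur$read_of_pair)]],
                                         ur)
  }

  reason <- rep(NA_character_, n)
  note <- function(r) ifelse(is.na(reason), r, reason)

  resolve <- function(element, refs, max_mm, max_hits, no_hit, ambiguous) {
    rule <- schema$rules[[element]]
    ex <- extract_element(mates[[as.character(rule$read_of_pair)]], rule)
    reason <<- note(ex$reject)
    res <- data.frame(index = rep(NA_integer_, n), status = "no_hit",
                      stringsAsFactors = FALSE)
    okq <- which(!is.na(ex$segment))
    if (length(okq) && length(refs))
      res[okq, ] <- match_with_tolerance(ex$segment[okq], refs, max_mm,
                                         max_hits)
    fail <- !is.na(ex$segment) &
      res$status != "hit"
    reason <<- note(ifelse(fail,
                           ifelse(res$status == "ambiguous", ambiguous,
                                  no_hit),
                           NA_character_))
    list(index = res$index, segment = ex$segment)
  }

  a_res <- resolve(bc_a, wl_a$entries, bc_max_mm, bc_max_hits,
                   "no_barcode_match", "ambiguous_barcode")
  b_res <- resolve(bc_b, wl_b$entries, bc_max_mm, bc_max_hits,
                   "no_barcode_match", "ambiguous_barcode")
  if (length(umi_whitelist)) {
    u_res <- resolve("umi", umi_whitelist, umi_max_mm, umi_max_hits,
                     "umi_not_in_whitelist", "umi_not_in_whitelist")
    umi <- umi_whitelist[u_res$index]
  } else {
    # degenerate whitelist: pass extracted UMIs through
    rule <- schema$rules$umi
    ex <- extract_element(mates[[as.character(rule$read_of_pair)]], rule)
    reason <- note(ex$reject)
    umi <- ex$segment
  }
  s_res <- resolve("spacer", spacers$spacer, sp_max_mm, sp_max_hits,
                   "no_spacer_match", "ambiguous_spacer")

  ok <- is.na(reason) & !is.na(a_res$index) & !is.na(b_res$index) &
    !is.na(umi) & !is.na(s_res$index)
  assignments <- data.frame(
    read_id = ids[ok], a = a_res$index[ok], b = b_res$index[ok],
    sgRNA = spacers$name[s_res$index[ok]], umi = umi[ok],
    stringsAsFactors = FALSE)
  rejects <- data.frame(read_id = ids[!ok], reason = reason[!ok],
                        stringsAsFactors = FALSE)
  structure(list(assignments = assignments, rejects = rejects, n_total = n,
                 params = list(schema = schema$name, bc_max_mm = bc_max_mm,
                               bc_max_hits = bc_max_hits,
                               umi_max_mm = umi_max_mm,
                               umi_max_hits = umi_max_hits,
                               sp_max_mm = sp_max_mm,
                               sp_max_hits = sp_max_hits)),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demux_result: ", x$n_total, " read pairs, ",
      nrow(x$assignments), " assigned, ", nrow(x$rejects), " rejected\n",
      sep = "")
  if (nrow(x$rejects)) print(table(x$rejects$reason))
  invisible(x)
}

#' Deduplicated pixel-by-sgRNA UMI count matrix
#'
#' Each entry is the number of distinct UMI sequences among the assignments
#' to that (pixel, sgRNA) pair. Axes always span the full grid (or the
#' tissue mask when given) and the full sgRNA library, so absent
#' combinations are explicit zeros.
#'
#' @param assignments Assignment data frame (from [assign_reads()], or any
#'   data frame with columns `a`, `b`, `sgRNA`, `umi`).
#' @param grid Integer `(n_A, n_B)` channel counts.
#' @param sgRNAs Character vector of library sgRNA names (column axis).
#' @param mask Optional data frame with columns `a`, `b`: pixels outside it
#'   are dropped.
#' @return An object of class `sgrna_matrix`: list with `counts` (sparse
#'   `dgCMatrix`, pixels x sgRNAs, rows named `"AxB"`), `grid`, and
#'   `provenance`.
#' @export
count_matrix <- function(assignments, grid, sgRNAs, mask = NULL) {
  if (inherits(assignments, "demux_result"))
    assignments <- assignments$assignments
  grid <- as.integer(grid)
  if (is.null(mask)) {
    pix <- pixel_id(rep(seq_len(grid[1]), each = grid[2]),
                    rep(seq_len(grid[2]), grid[1]))
  } else {
    pix <- pixel_id(mask$a, mask$b)
  }
  stopifnot(!anyDuplicated(pix), !anyDuplicated(sgRNAs))
  counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0),
                                 dims = c(length(pix), length(sgRNAs)),
                                 dimnames = list(pix, sgRNAs))
  if (nrow(assignments)) {
    if (any(assignments$a > grid[1] | assignments$b > grid[2]))
      stop("assignment pixel indices outside the grid")
    key <- unique(assignments[, c("a", "b", "sgRNA", "umi")])
    kp <- pixel_id(key$a, key$b)
    keep <- kp %in% pix
    key <- key[keep, , drop = FALSE]; kp <- kp[keep]
    if (nrow(key)) {
      tab <- stats::aggregate(list(n = rep(1L, nrow(key))),
                              by = list(pixel = kp, sgRNA = key$sgRNA), sum)
      counts <- counts + Matrix::sparseMatrix(
        i = match(tab$pixel, pix), j = match(tab$sgRNA, sgRNAs), x = tab$n,
        dims = dim(counts), dimnames = dimnames(counts))
    }
  }
  structure(list(counts = methods::as(counts, "CsparseMatrix"), grid = grid,
                 provenance = list(package = "dbitscreen",
                                   version = as.character(
                                     utils::packageVersion("dbitscreen")))),
            class = "sgrna_matrix")
}

#' @export
print.sgrna_matrix <- function(x, ...) {
  cat("sgrna_matrix: ", nrow(x$counts), " pixels x ", ncol(x$counts),
      " sgRNAs, ", sum(x$counts), " deduplicated UMIs\n", sep = "")
  invisible(x)
}

#' Detection area of sgRNAs
#'
#' The area of an sgRNA is the number of pixels in which it is detected with
#' at least one deduplicated UMI. It is the unit used by the perturbation
#' signature gate (area >= 4) and the pooled-vs-spatial benchmark response
#' (area > 2).
#'
#' @param x An `sgrna_matrix`.
#' @param sgRNA Optional single sgRNA name; when omitted, areas for all
#'   sgRNAs are returned.
#' @return Named integer vector of pixel counts (or a single integer).
#' @export
sgrna_area <- function(x, sgRNA = NULL) {
  m <- if (inherits(x, "sgrna_matrix")) x$counts else x
  areas <- Matrix::colSums(m >= 1)
  if (is.null(sgRNA)) return(areas)
  if (!sgRNA %in% colnames(m)) stop("unknown sgRNA: ", sgRNA)
  areas[[sgRNA]]
}
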