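#' Simulate a clonally structured barcoded tissue
#'
#' Places `n_clones` disc-shaped clonal patches on the pixel grid, assigns
#' each clone a single sgRNA, and draws sgRNA molecules: every clone pixel
#' receives `Poisson(umi_rate)` molecules of the clone's guide, and every
#' on-tissue pixel additionally receives `Poisson(ambient_rate)` molecules of
#' uniformly random guides (ambient, off-clone noise). Each molecule gets a
#' random 10-mer UMI. Clones are placed to fit entirely inside the grid and,
#' by default, without overlapping each other.
#'
#' @param grid Integer vector `(n_A, n_B)` of channel counts.
#' @param n_clones Number of clonal patches.
#' @param clone_radius Disc radius in pixels (pixels with squared center
#'   distance `<= clone_radius^2` belong to the clone).
#' @param library A [spacer_library()]; each clone draws one guide from it
#'   (without replacement while possible).
#' @param umi_rate Mean molecules per clone pixel (> 0).
#' @param ambient_rate Mean ambient molecules per on-tissue pixel (>= 0).
#' @param mask Optional data frame with columns `a`, `b` of on-tissue
#'   pixels; default is the full grid.
#' @param allow_overlap Allow clone pixel sets to overlap (default FALSE).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return An object of class `tissue_truth`: list with `grid`, `clones`
#'   (data frame `clone_id`, `sgRNA`, `center_a`, `center_b`, `radius`,
#'   `n_pixels`), `clone_pixels` (list of pixel-id vectors), `molecules`
#'   (data frame `read_id`, `a`, `b`, `sgRNA`, `umi`), `mask`, `seed`.
#' @export
simulate_tissue <- function(grid = c(50, 50), n_clones = 4, clone_radius = 2.9,
                            library, umi_rate = 5, ambient_rate = 0,
                            mask = NULL, allow_overlap = FALSE, seed = 0) {
  stopifnot(umi_rate > 0, ambient_rate >= 0, nrow(library) > 0)
  grid <- as.integer(grid)
  set.seed(seed)
  if (is.null(mask))
    mask <- expand.grid(a = seq_len(grid[1]), b = seq_len(grid[2]))
  mask_id <- pixel_id(mask$a, mask$b)

  r <- clone_radius
  lo <- ceiling(1 + r); hi_a <- floor(grid[1] - r); hi_b <- floor(grid[2] - r)
  if (lo > hi_a || lo > hi_b)
    stop("clone_radius too large for the grid: clones exceed grid capacity")
  disc <- expand.grid(da = -floor(r):floor(r), db = -floor(r):floor(r))
  disc <- disc[disc$da^2 + disc$db^2 <= r^2, ]

  centers <- matrix(NA_integer_, n_clones, 2)
  pix_sets <- vector("list", n_clones)
  taken <- character(0)
  tries <- 0L
  i <- 1L
  while (i <= n_clones) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("could not place ", n_clones,
           " non-overlapping clones: clones exceed grid capacity")
    if (tries %% 500L == 0L) {
      # restart the whole configuration: an unlucky early placement can
      # make the remaining clones impossible to fit
      i <- 1L; taken <- character(0)
    }
    ca <- sample(lo:hi_a, 1); cb <- sample(lo:hi_b, 1)
    px <- pixel_id(ca + disc$da, cb + disc$db)
    px <- px[px %in% mask_id]
    if (length(px) == 0) next
    if (!allow_overlap && any(px %in% taken)) next
    centers[i, ] <- c(ca, cb)
    pix_sets[[i]] <- px
    taken <- c(taken, px)
    i <- i + 1L
  }

  guides <- if (n_clones <= nrow(library)) sample(library$name, n_clones)
            else sample(library$name, n_clones, replace = TRUE)
  clones <- data.frame(clone_id = seq_len(n_clones), sgRNA = guides,
                       center_a = centers[, 1], center_b = centers[, 2],
                       radius = r,
                       n_pixels = lengths(pix_sets))

  # clone molecules
  mol_a <- integer(0); mol_b <- integer(0); mol_g <- character(0)
  for (i in seq_len(n_clones)) {
    ab <- pixel_ab(pix_sets[[i]])
    k <- rpois(nrow(ab), umi_rate)
    mol_a <- c(mol_a, rep(ab$a, k)); mol_b <- c(mol_b, rep(ab$b, k))
    mol_g <- c(mol_g, rep(guides[i], sum(k)))
  }
  # ambient molecules on every masked pixel
  if (ambient_rate > 0) {
    k <- rpois(nrow(mask), ambient_rate)
    mol_a <- c(mol_a, rep(mask$a, k)); mol_b <- c(mol_b, rep(mask$b, k))
    mol_g <- c(mol_g, sample(library$name, sum(k), replace = TRUE))
  }
  n <- length(mol_a)
  umis <- random_seq(n, 10)
  molecules <- data.frame(
    read_id = sprintf("read_%07d", seq_len(n)),
    a = mol_a, b = mol_b, sgRNA = mol_g, umi = umis,
    stringsAsFactors = FALSE)

  structure(list(grid = grid, clones = clones, clone_pixels = pix_sets,
                 molecules = molecules, mask = mask, seed = seed),
            class = "tissue_truth")
}

#' @export
print.tissue_truth <- function(x, ...) {
  cat("tissue_truth: grid ", x$grid[1], "x", x$grid[2], ", ",
      nrow(x$clones), " clones, ", nrow(x$molecules), " molecules\n", sep = "")
  invisible(x)
}

#' Pixel position identifiers
#'
#' Pixels are identified as `"AxB"` with 1-based channel indices, e.g.
#' `"12x34"` for A-channel 12 and B-channel 34.
#' @param a,b 1-based channel indices.
#' @return Character vector of position ids.
#' @export
pixel_id <- function(a, b) paste0(a, "x", b)

#' Split position ids into channel indices
#' @param id Character vector of `"AxB"` position ids.
#' @return Data frame with integer columns `a` and `b`.
#' @export
pixel_ab <- function(id) {
  parts <- strsplit(id, "x", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[`, character(1), 1)),
             b = as.integer(vapply(parts, `[`, character(1), 2)))
}

random_seq <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Emit paired sgRNA reads for a simulated tissue
#'
#' Writes one read pair per truth molecule. Reads are exact concatenations of
#' the schema's read templates (flanks, barcodes, UMI, spacer in dialect
#' order), then corrupted by i.i.d. base substitutions at
#' `substitution_rate`. Constant quality `I` (Q40) is emitted.
#'
#' @param truth A [simulate_tissue()] result.
#' @param schema A `chemistry_schema` with a read template.
#' @param whitelists Named list of [barcode_whitelist()]s, at least `A` and
#'   `B`; barcode indices map channel index -> barcode sequence.
#' @param library The [spacer_library()] the truth was simulated from.
#' @param substitution_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param r1_path,r2_path Output FASTQ paths (`.gz` supported). When `NULL`,
#'   reads are returned but not written.
#' @param truth_path Optional path for the per-read truth TSV
#'   (`read_id a b sgRNA umi`).
#' @return Invisibly, a list with `truth` (the per-read truth table), `r1`,
#'   `r2` (`Biostrings::DNAStringSet`), and the output paths.
#' @export
emit_reads <- function(truth, schema, whitelists, library,
                       substitution_rate = 0, seed = 0,
                       r1_path = NULL, r2_path = NULL, truth_path = NULL) {
  stopifnot(inherits(truth, "tissue_truth"),
            inherits(schema, "chemistry_schema"))
  if (is.null(schema$read_template))
    stop("schema has no read template; use a preset or supply read_template")
  mol <- truth$molecules
  need <- c("A", "B")
  if (!all(need %in% names(whitelists)))
    stop("whitelists must name the A and B sets")
  for (s in need)
    if (truth$grid[match(s, c("A", "B"))] > length(whitelists[[s]]$entries))
      stop("whitelist ", s, " smaller than the grid dimension")
  sp <- setNames(library$spacer, library$name)
  if (!all(mol$sgRNA %in% names(sp)))
    stop("truth sgRNAs missing from library")

  fill <- list(barcode_A = whitelists$A$entries[mol$a],
               barcode_B = whitelists$B$entries[mol$b],
               umi = mol$umi, spacer = unname(sp[mol$sgRNA]))
  build <- function(tokens) {
    parts <- lapply(tokens, function(tk) {
      if (grepl("^<.*>$", tk)) fill[[gsub("[<>]", "", tk)]]
      else rep(tk, nrow(mol))
    })
    do.call(paste0, parts)
  }
  set.seed(seed)
  r1 <- corrupt_reads(build(schema$read_template$read1), substitution_rate)
  r2 <- corrupt_reads(build(schema$read_template$read2), substitution_rate)
  r1 <- Biostrings::DNAStringSet(setNames(r1, mol$read_id))
  r2 <- Biostrings::DNAStringSet(setNames(r2, mol$read_id))
  if (!is.null(r1_path))
    Biostrings::writeXStringSet(r1, r1_path, format = "fastq",
                                compress = grepl("\\.gz$", r1_path))
  if (!is.null(r2_path))
    Biostrings::writeXStringSet(r2, r2_path, format = "fastq",
                                compress = grepl("\\.gz$", r2_path))
  if (!is.null(truth_path))
    write.table(mol, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(truth = mol, r1 = r1, r2 = r2,
                 r1_path = r1_path, r2_path = r2_path))
}

# i.i.d. substitutions; a hit base is replaced by one of the other three.
corrupt_reads <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  total <- sum(lens)
  hit <- runif(total) < rate
  if (!any(hit)) return(seqs)
  flat <- unlist(chars, use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  idx <- which(hit)
  # draw a uniformly random *different* base
  cur <- match(flat[idx], bases)
  shift <- sample.int(3, length(idx), replace = TRUE)
  flat[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  starts <- cumsum(c(1L, lens[-length(lens)]))
  vapply(seq_along(seqs),
         function(i) paste(flat[starts[i]:(starts[i] + lens[i] - 1L)],
                           collapse = ""),
         character(1))
}

#' Simulate a pixel-by-gene expression matrix with perturbation effects
#'
#' Draws negative-binomial counts for every on-tissue pixel: gene `g` in a
#' pixel belonging to a clone carrying sgRNA `s` has mean
#' `mu_g * 2^effect` if `g` is in `target_sets[[s]]`, otherwise `mu_g`.
#'
#' @param truth A [simulate_tissue()] result.
#' @param n_genes Number of genes.
#' @param baseline_mu Per-gene baseline means; a scalar is recycled, or a
#'   vector of length `n_genes`.
#' @param dispersion Negative-binomial size parameter (> 0); larger is less
#'   overdispersed.
#' @param target_sets Named list sgRNA -> character vector of perturbed gene
#'   names (genes are `gene0001`, ...).
#' @param effect Additive log2-scale shift applied to target genes in clone
#'   pixels.
#' @param seed RNG seed.
#' @return An object of class `gex_truth`: list with `counts` (pixel x gene
#'   integer matrix, rows named by position id), `target_sets`, `effect`,
#'   `dispersion`, `baseline_mu`, `pixel_sgRNA` (named vector, `NA` for
#'   pixels outside any clone).
#' @export
emit_gex <- function(truth, n_genes = 200, baseline_mu = 10, dispersion = 10,
                     target_sets = list(), effect = 0, seed = 0) {
  stopifnot(is.finite(effect), dispersion > 0)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  mu <- rep_len(baseline_mu, n_genes)
  if (length(target_sets)) {
    bad <- setdiff(names(target_sets), truth$clones$sgRNA)
    if (length(bad))
      stop("unknown sgRNA in target_sets: ", paste(bad, collapse = ", "))
    for (ts in target_sets)
      if (!all(ts %in% genes)) stop("target_sets genes must exist")
  }
  pix <- pixel_id(truth$mask$a, truth$mask$b)
  pixel_sgRNA <- setNames(rep(NA_character_, length(pix)), pix)
  for (i in seq_len(nrow(truth$clones))) {
    hit <- truth$clone_pixels[[i]]
    pixel_sgRNA[hit[hit %in% pix]] <- truth$clones$sgRNA[i]
  }
  set.seed(seed)
  counts <- matrix(0L, length(pix), n_genes, dimnames = list(pix, genes))
  mu_mat <- matrix(mu, length(pix), n_genes, byrow = TRUE)
  if (effect != 0 && length(target_sets)) {
    for (s in names(target_sets)) {
      rows <- which(!is.na(pixel_sgRNA) & pixel_sgRNA == s)
      cols <- match(target_sets[[s]], genes)
      mu_mat[rows, cols] <- mu_mat[rows, cols] * 2^effect
    }
  }
  counts[] <- rnbinom(length(mu_mat), mu = mu_mat, size = dispersion)
  structure(list(counts = counts, target_sets = target_sets, effect = effect,
                 dispersion = dispersion, baseline_mu = mu,
                 pixel_sgRNA = pixel_sgRNA, seed = seed),
            class = "gex_truth")
}
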