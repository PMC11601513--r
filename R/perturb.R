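#' Label pixels by their detected sgRNAs
#'
#' A pixel with no detected guide is `non_perturbed`; with exactly one,
#' `unique`; with several, `resolved` in favor of the top guide if and only
#' if the top guide has at least `min_top` UMIs and every other detected
#' guide has at most `max_other`, otherwise `ambiguous`.
#'
#' @param x An `sgrna_matrix` (or a pixel x sgRNA count matrix).
#' @param min_top Minimum top-guide UMI count for resolution (default 10).
#' @param max_other Maximum UMI count tolerated for every other guide
#'   (default 1).
#' @return A data frame with one row per pixel: `pixel`, `state`
#'   (`non_perturbed` / `unique` / `resolved` / `ambiguous`), `sgRNA`
#'   (`NA` unless unique or resolved), `n_detected`, `top_count`.
#' @export
label_pixels <- function(x, min_top = 10, max_other = 1) {
  m <- if (inherits(x, "sgrna_matrix")) x$counts else x
  m <- as.matrix(m)
  n_det <- rowSums(m >= 1)
  top_count <- apply(m, 1, max)
  top_idx <- max.col(m, ties.method = "first")
  state <- rep("ambiguous", nrow(m))
  state[n_det == 0] <- "non_perturbed"
  state[n_det == 1] <- "unique"
  multi <- which(n_det >= 2)
  if (length(multi)) {
    mm <- m[multi, , drop = FALSE]
    second <- vapply(seq_along(multi), function(i) {
      v <- mm[i, ]; v[top_idx[multi[i]]] <- -Inf; max(v)
    }, numeric(1))
    res <- top_count[multi] >= min_top & second <= max_other
    # a tie at the top means the "other" guide exceeds max_other
    state[multi[res]] <- "resolved"
  }
  sg <- rep(NA_character_, nrow(m))
  hit <- state %in% c("unique", "resolved")
  sg[hit] <- colnames(m)[top_idx[hit]]
  data.frame(pixel = rownames(m), state = state, sgRNA = sg,
             n_detected = as.integer(n_det), top_count = as.numeric(top_count),
             stringsAsFactors = FALSE)
}

#' Normalize a pixel-by-gene count matrix
#'
#' Counts are scaled to the median pixel depth, log1p-transformed, and
#' (optionally) centered and unit-scaled per gene. Zero-variance genes are
#' dropped with a warning. This is a documented simple normalization; it is
#' the scheme used throughout the package's perturbation analyses.
#'
#' @param counts Pixel x gene non-negative count matrix (rows named by
#'   position id).
#' @return An object of class `gex_norm`: list with `depth_scaled`
#'   (counts / depth * median depth), `lognorm` (`log1p` of the former),
#'   `scaled` (per-gene centered, unit variance), `depth`, and `dropped`
#'   (names of removed zero-variance genes).
#' @export
normalize_gex <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  depth <- rowSums(counts)
  scale_to <- median(depth)
  f <- ifelse(depth > 0, scale_to / depth, 0)
  depth_scaled <- counts * f
  lognorm <- log1p(depth_scaled)
  sds <- apply(lognorm, 2, sd)
  dropped <- colnames(lognorm)[sds == 0 | is.na(sds)]
  if (length(dropped))
    warning("dropping ", length(dropped), " constant gene(s): ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  keep <- setdiff(colnames(lognorm), dropped)
  lognorm <- lognorm[, keep, drop = FALSE]
  depth_scaled <- depth_scaled[, keep, drop = FALSE]
  scaled <- scale(lognorm)
  structure(list(depth_scaled = depth_scaled, lognorm = lognorm,
                 scaled = scaled, depth = depth, dropped = dropped),
            class = "gex_norm")
}

#' @export
print.gex_norm <- function(x, ...) {
  cat("gex_norm: ", nrow(x$lognorm), " pixels x ", ncol(x$lognorm),
      " genes (", length(x$dropped), " dropped)\n", sep = "")
  invisible(x)
}

#' Choose the number of principal components at the variance elbow
#'
#' The elbow is the component maximizing the perpendicular distance to the
#' straight line joining the first and last variance points (ties broken to
#' the smallest index). The returned count is floored at 10 and capped at
#' 50; with fewer than 3 components, all are returned.
#'
#' @param variances Non-increasing per-component variances.
#' @return Integer number of components to retain.
#' @export
select_pcs <- function(variances) {
  k <- length(variances)
  if (k < 3) return(k)
  x <- seq_len(k); y <- variances
  x1 <- c(1, y[1]); x2 <- c(k, y[k])
  v <- x2 - x1
  # perpendicular distance from (x, y) to the chord
  d <- abs(v[2] * (x - x1[1]) - v[1] * (y - x1[2])) / sqrt(sum(v^2))
  # ties (within numerical noise) break to the smallest index
  elbow <- which(d >= max(d) - 1e-8 * max(1, max(d)))[1]
  min(max(elbow, 10L), 50L, k)
}

.knn_index <- function(query, ref, k) {
  # row indices into ref of the k nearest neighbors of each query row
  d2 <- outer(rowSums(query^2), rowSums(ref^2), "+") -
    2 * tcrossprod(query, ref)
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

#' Perturbation signatures against nearest non-perturbed pixels
#'
#' For every eligible pixel, the signature is its normalized expression
#' minus the mean normalized expression of its `k` nearest non-perturbed
#' (NP) pixels in principal-component space; NP pixels are referenced
#' against their `k` nearest NP neighbors excluding themselves. This
#' isolates the local transcriptional effect of the knockout from the
#' ambient expression field.
#'
#' Signatures are computed for sgRNAs detected with an area of at least
#' `area_gate` pixels; when the library holds fewer than 100 distinct
#' guides, all guides are included.
#'
#' @param norm A [normalize_gex()] result (or a pixel x gene matrix used
#'   as-is).
#' @param labels A [label_pixels()] data frame.
#' @param counts Optional `sgrna_matrix` used to compute guide areas for
#'   the gate.
#' @param k Number of nearest NP neighbors (default 20).
#' @param area_gate Minimum detection area (default 4).
#' @param library_size Number of distinct guides in the screen library;
#'   when `< 100` (or `NULL`) the area gate is bypassed.
#' @param n_pcs Number of PCs for the neighbor space; chosen by
#'   [select_pcs()] when `NULL`.
#' @return An object of class `signature_assay`: list with `signatures`
#'   (pixel x gene matrix), `labels` (rows for included pixels),
#'   `included_sgRNAs`, `k`, `n_pcs`.
#' @export
perturbation_signature <- function(norm, labels, counts = NULL, k = 20,
                                   area_gate = 4, library_size = NULL,
                                   n_pcs = NULL) {
  x <- if (inherits(norm, "gex_norm")) norm$scaled else as.matrix(norm)
  stopifnot(!is.null(rownames(x)))
  labels <- labels[match(rownames(x), labels$pixel), ]
  if (anyNA(labels$state)) stop("labels must cover every expression pixel")

  np <- labels$pixel[labels$state == "non_perturbed"]
  if (length(np) < k)
    stop("fewer than k = ", k, " non-perturbed pixels; use a smaller k")

  detected <- unique(labels$sgRNA[!is.na(labels$sgRNA)])
  included <- detected
  if (!is.null(counts) && !is.null(library_size) && library_size >= 100) {
    areas <- sgrna_area(counts)
    included <- intersect(detected, names(areas)[areas >= area_gate])
  }
  eligible <- labels$state == "non_perturbed" |
    (labels$state %in% c("unique", "resolved") & labels$sgRNA %in% included)

  pv <- prcomp(x, center = FALSE, scale. = FALSE)
  if (is.null(n_pcs)) n_pcs <- select_pcs(pv$sdev^2)
  pc <- pv$x[, seq_len(min(n_pcs, ncol(pv$x))), drop = FALSE]

  np_idx <- which(labels$state == "non_perturbed")
  sig <- matrix(NA_real_, sum(eligible), ncol(x),
                dimnames = list(rownames(x)[eligible], colnames(x)))
  el_idx <- which(eligible)
  is_np <- labels$state[el_idx] == "non_perturbed"
  # perturbed (and other eligible non-NP) pixels: k nearest NP pixels
  if (any(!is_np)) {
    nn <- .knn_index(pc[el_idx[!is_np], , drop = FALSE],
                     pc[np_idx, , drop = FALSE], k)
    for (i in seq_len(sum(!is_np))) {
      ref <- colMeans(x[np_idx[nn[i, ]], , drop = FALSE])
      sig[which(!is_np)[i], ] <- x[el_idx[!is_np][i], ] - ref
    }
  }
  # NP pixels: k nearest NP neighbors excluding self (one fewer when the
  # NP pool is exactly k)
  if (any(is_np)) {
    kk <- min(k, length(np_idx) - 1L)
    nn <- .knn_index(pc[el_idx[is_np], , drop = FALSE],
                     pc[np_idx, , drop = FALSE], min(kk + 1L, length(np_idx)))
    for (i in seq_len(sum(is_np))) {
      self <- match(el_idx[is_np][i], np_idx)
      nbr <- setdiff(nn[i, ], self)[seq_len(kk)]
      ref <- colMeans(x[np_idx[nbr], , drop = FALSE])
      sig[which(is_np)[i], ] <- x[el_idx[is_np][i], ] - ref
    }
  }
  structure(list(signatures = sig, labels = labels[eligible, ],
                 included_sgRNAs = included, k = k, n_pcs = n_pcs),
            class = "signature_assay")
}

#' @export
print.signature_assay <- function(x, ...) {
  cat("signature_assay: ", nrow(x$signatures), " pixels x ",
      ncol(x$signatures), " genes, ", length(x$included_sgRNAs),
      " included sgRNAs, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Per-pixel perturbation scores
#'
#' The class vector of a guide is the mean signature over pixels labeled
#' with it. A labeled pixel's score is the Pearson correlation between its
#' signature and its class vector; a non-perturbed pixel is scored against
#' the mean of all class vectors. Scores live on a fixed `[-1, 1]` scale,
#' which the `+/- 0.2` filtering thresholds refer to.
#'
#' @param assay A [perturbation_signature()] result.
#' @return Named numeric vector of scores (one per assay pixel), with the
#'   guide class vectors attached as attribute `class_vectors`.
#' @export
perturbation_score <- function(assay) {
  sig <- assay$signatures
  lab <- assay$labels
  guides <- intersect(assay$included_sgRNAs, lab$sgRNA)
  if (!length(guides)) stop("no labeled pixels to build class vectors from")
  cv <- vapply(guides, function(g)
    colMeans(sig[which(lab$sgRNA %in% g), , drop = FALSE]), numeric(ncol(sig)))
  cv <- t(cv)  # guide x gene
  mean_cv <- colMeans(cv)
  scores <- setNames(rep(NA_real_, nrow(sig)), rownames(sig))
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      warning("zero-variance signature; score set to 0")
      return(0)
    }
    stats::cor(a, b)
  }
  for (i in seq_len(nrow(sig))) {
    v <- if (!is.na(lab$sgRNA[i]) && lab$sgRNA[i] %in% guides)
      cv[lab$sgRNA[i], ] else mean_cv
    scores[i] <- safe_cor(sig[i, ], v)
  }
  attr(scores, "class_vectors") <- cv
  scores
}

#' Filter pixels by perturbation score
#'
#' Perturbed pixels are labeled (unique/resolved) pixels scoring above
#' `thr`; control pixels are non-perturbed pixels scoring below `-thr`.
#'
#' @param scores Scores from [perturbation_score()].
#' @param labels The matching label rows (e.g. `assay$labels`).
#' @param thr Score threshold (default 0.2).
#' @return List with character vectors `perturbed` and `control` of pixel
#'   ids.
#' @export
filter_by_score <- function(scores, labels, thr = 0.2) {
  labels <- labels[match(names(scores), labels$pixel), ]
  labeled <- labels$state %in% c("unique", "resolved")
  np <- labels$state == "non_perturbed"
  perturbed <- names(scores)[labeled & scores > thr]
  control <- names(scores)[np & scores < -thr]
  if (!length(perturbed)) warning("empty perturbed pixel set")
  list(perturbed = perturbed, control = control)
}

.snn_graph <- function(pc, k) {
  n <- nrow(pc)
  k <- min(k, n - 1L)
  nn <- .knn_index(pc, pc, k + 1L)  # includes self at distance 0
  B <- matrix(0L, n, n)
  B[cbind(rep(seq_len(n), k + 1L), as.vector(nn))] <- 1L
  shared <- tcrossprod(B)
  union <- (k + 1L) * 2L - shared
  J <- shared / union
  neighbor <- (B + t(B)) > 0
  J[!neighbor] <- 0
  J[J < 1 / 15] <- 0  # prune weak shared-neighbor edges
  diag(J) <- 0
  igraph::graph_from_adjacency_matrix(J, mode = "undirected", weighted = TRUE)
}

#' Cluster pixels on an SNN graph with silhouette-guided resolution
#'
#' PCA reduces the feature matrix, [select_pcs()] picks the retained
#' components, a shared-nearest-neighbor graph (k neighbors, Jaccard
#' weights) is built in PC space, and modularity communities are detected
#' at each candidate resolution. Among solutions with more than
#' `min_clusters` clusters the resolution maximizing the average silhouette
#' width (in PC space) wins; ties break to the smaller total within-cluster
#' sum of squares, then the smaller resolution. If no solution exceeds
#' `min_clusters` clusters, the best silhouette overall is used with a
#' warning. A 2-D UMAP (min_dist 0.01) is attached for visualization only.
#'
#' Pixels are ordered canonically by row name before graph construction, so
#' the assignment is invariant to input row order at a fixed seed.
#'
#' @param x Pixel x feature matrix with row names.
#' @param resolutions Candidate modularity resolutions.
#' @param k Neighbors for the SNN graph (default 20).
#' @param n_pcs Retained components; chosen by [select_pcs()] when `NULL`.
#' @param min_clusters Solutions must exceed this many clusters (default 3).
#' @param umap Compute the UMAP embedding (default TRUE).
#' @param seed RNG seed for community detection and UMAP.
#' @return An object of class `cluster_result`: list with `cluster` (named
#'   integer vector), `embedding` (pixel x 2 or `NULL`), `resolution`,
#'   `n_pcs`, `silhouette`.
#' @export
cluster_pixels <- function(x, resolutions = seq(0.2, 2, by = 0.2), k = 20,
                           n_pcs = NULL, min_clusters = 3, umap = TRUE,
                           seed = 0) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 pixels")
  if (is.null(rownames(x))) rownames(x) <- sprintf("px%06d", seq_len(nrow(x)))
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]

  keep <- apply(x, 2, sd) > 0
  if (!any(keep)) {
    warning("no variable features; assigning a single cluster")
    cl <- setNames(rep(1L, nrow(x)), rownames(x))
    return(structure(list(cluster = cl[order(ord)], embedding = NULL,
                          resolution = NA_real_, n_pcs = 0L,
                          silhouette = NA_real_),
                     class = "cluster_result"))
  }
  pv <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  if (is.null(n_pcs)) n_pcs <- select_pcs(pv$sdev^2)
  pc <- pv$x[, seq_len(min(n_pcs, ncol(pv$x))), drop = FALSE]

  g <- .snn_graph(pc, k)
  d <- stats::dist(pc)
  eval_res <- function(r) {
    set.seed(seed)
    cl <- igraph::membership(igraph::cluster_louvain(g, resolution = r))
    ncl <- length(unique(cl))
    sil <- if (ncl >= 2 && ncl < nrow(pc))
      mean(cluster::silhouette(as.integer(cl), d)[, "sil_width"])
    else NA_real_
    wss <- sum(vapply(unique(cl), function(ci) {
      rowsq <- pc[cl == ci, , drop = FALSE]
      sum(scale(rowsq, scale = FALSE)^2)
    }, numeric(1)))
    list(cl = as.integer(cl), ncl = ncl, sil = sil, wss = wss, r = r)
  }
  sols <- lapply(resolutions, eval_res)
  pick_best <- function(cand) {
    sil <- vapply(cand, `[[`, numeric(1), "sil")
    wss <- vapply(cand, `[[`, numeric(1), "wss")
    res <- vapply(cand, `[[`, numeric(1), "r")
    ord2 <- order(-sil, wss, res)
    cand[[ord2[1]]]
  }
  ok <- Filter(function(s) s$ncl > min_clusters && !is.na(s$sil), sols)
  if (length(ok)) {
    best <- pick_best(ok)
  } else {
    warning("no solution with > ", min_clusters,
            " clusters; falling back to best silhouette overall")
    with_sil <- Filter(function(s) !is.na(s$sil), sols)
    best <- if (length(with_sil)) pick_best(with_sil) else sols[[1]]
  }
  emb <- NULL
  if (umap) {
    set.seed(seed)
    emb <- uwot::umap(pc, min_dist = 0.01,
                      n_neighbors = min(15, nrow(pc) - 1))
    rownames(emb) <- rownames(pc)
    emb <- emb[order(ord), , drop = FALSE]
  }
  cl <- setNames(best$cl, rownames(pc))
  structure(list(cluster = cl[order(ord)], embedding = emb,
                 resolution = best$r, n_pcs = n_pcs,
                 silhouette = best$sil),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(unique(x$cluster)), " clusters over ",
      length(x$cluster), " pixels (resolution ", x$resolution,
      ", mean silhouette ", round(x$silhouette, 3), ")\n", sep = "")
  invisible(x)
}

#' Name clusters by their major perturbations
#'
#' A perturbation is major in a cluster when it covers more than
#' `major_frac` of the cluster's pixels. The cluster name joins its major
#' perturbations with `_` in decreasing frequency; a cluster with no major
#' perturbation is named `"NP+n"` where `n` is the number of distinct
#' perturbations detected in it.
#'
#' @param cluster Named integer vector pixel -> cluster id.
#' @param perturbation Named character vector pixel -> perturbation label
#'   (gene or guide), with `"NP"` (or `NA`) for non-perturbed pixels.
#' @param major_frac Major-perturbation threshold (default 0.20).
#' @return Named character vector cluster id -> name.
#' @export
name_clusters <- function(cluster, perturbation, major_frac = 0.20) {
  perturbation <- perturbation[names(cluster)]
  perturbation[is.na(perturbation)] <- "NP"
  ids <- sort(unique(cluster))
  nm <- vapply(as.character(ids), function(ci) {
    p <- perturbation[cluster == as.integer(ci)]
    size <- length(p)
    tab <- sort(table(p[p != "NP"]), decreasing = TRUE)
    majors <- names(tab)[tab / size > major_frac]
    if (length(majors)) paste(majors, collapse = "_")
    else paste0("NP+", length(tab))
  }, character(1))
  setNames(nm, ids)
}

#' Wilcoxon rank-sum differential expression between pixel groups
#'
#' Genes detected in more than `min_pct` of group A pixels are tested by a
#' two-sided Wilcoxon rank-sum test (exact when both groups have at most 10
#' pixels and the data are tie-free, normal approximation with tie
#' correction otherwise), with Benjamini-Hochberg adjustment across tested
#' genes. Fold-changes are log2 ratios of group means on the depth-scaled
#' scale with a pseudocount of 1.
#'
#' @param norm A [normalize_gex()] result.
#' @param group_a,group_b Disjoint pixel-id vectors, each of at least 3
#'   pixels.
#' @param min_pct Minimum detected fraction in group A for a gene to be
#'   tested (default 0.20).
#' @return A data frame: `gene`, `log2fc`, `p`, `padj`, `pct_a`, `pct_b`,
#'   sorted by `p`.
#' @export
de_wilcoxon <- function(norm, group_a, group_b, min_pct = 0.20) {
  stopifnot(inherits(norm, "gex_norm"))
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 pixels")
  xs <- norm$depth_scaled
  missing <- setdiff(c(group_a, group_b), rownames(xs))
  if (length(missing)) stop("unknown pixels: ", paste(head(missing), collapse = ", "))
  A <- xs[group_a, , drop = FALSE]
  B <- xs[group_b, , drop = FALSE]
  pct_a <- colMeans(A > 0); pct_b <- colMeans(B > 0)
  tested <- which(pct_a > min_pct)
  exact <- length(group_a) <= 10 && length(group_b) <= 10
  p <- vapply(tested, function(j)
    suppressWarnings(stats::wilcox.test(A[, j], B[, j], exact = exact,
                                        correct = TRUE)$p.value),
    numeric(1))
  out <- data.frame(
    gene = colnames(xs)[tested],
    log2fc = log2((colMeans(A[, tested, drop = FALSE]) + 1) /
                  (colMeans(B[, tested, drop = FALSE]) + 1)),
    p = p,
    padj = stats::p.adjust(p, method = "BH"),
    pct_a = pct_a[tested], pct_b = pct_b[tested],
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p), ]
}
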