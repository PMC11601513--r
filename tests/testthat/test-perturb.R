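test_that("pixel labeling applies the top/other count rule", {
  m <- rbind(`1x1` = c(0, 0, 0), `1x2` = c(5, 0, 0), `1x3` = c(12, 1, 1),
             `1x4` = c(12, 2, 0), `1x5` = c(9, 1, 0))
  colnames(m) <- c("g1", "g2", "g3")
  lab <- label_pixels(m)
  expect_identical(lab$state, c("non_perturbed", "unique", "resolved",
                                "ambiguous", "ambiguous"))
  expect_identical(lab$sgRNA, c(NA, "g1", "g1", NA, NA))
})

test_that("pixel labeling matches the brute-force predicate exhaustively", {
  # all count vectors with <= 3 guides and counts 0..15
  grid <- expand.grid(c1 = 0:15, c2 = 0:15, c3 = 0:15)
  m <- as.matrix(grid)
  rownames(m) <- pixel_id(seq_len(nrow(m)), 1L)
  colnames(m) <- c("g1", "g2", "g3")
  lab <- label_pixels(m)
  want <- apply(m, 1, brute_force_label)
  expect_identical(lab$state, unname(want))
})

test_that("normalization scales to median depth, logs, and drops constants", {
  counts <- rbind(`1x1` = c(10, 0, 5), `1x2` = c(20, 0, 10),
                  `1x3` = c(40, 0, 21))
  colnames(counts) <- c("gA", "gB", "gC")
  expect_warning(nrm <- normalize_gex(counts), "constant")
  expect_identical(nrm$dropped, "gB")
  # median depth is 30; pixel 1 has depth 15 -> factor 2
  expect_equal(unname(nrm$depth_scaled["1x1", "gA"]), 20)
  expect_equal(unname(nrm$lognorm["1x1", "gA"]), log1p(20))
  # depth scaling is per-pixel: scaling one non-median pixel's counts
  # leaves its depth-scaled row unchanged
  counts2 <- counts; counts2["1x3", ] <- counts2["1x3", ] * 3
  nrm2 <- suppressWarnings(normalize_gex(counts2))
  expect_equal(nrm2$depth_scaled["1x3", ], nrm$depth_scaled["1x3", ])
  expect_error(normalize_gex(matrix(0, 2, 2)), "all-zero")
})

test_that("the PC elbow maximizes chord distance with floor and cap", {
  expect_equal(select_pcs(c(100, 10, 9.5, 9.4, 9.3)), 5)  # elbow 2 -> floor
  v <- c(100, 10, 9.5, 9.4, 9.3, rep(9.2, 20))
  expect_equal(select_pcs(v), 10)  # floor applies with enough components
  expect_equal(select_pcs(seq(100, 1, length.out = 200)), 10)  # ties -> first
  expect_equal(select_pcs(c(5, 1)), 2)  # < 3 components: all
  # planted spectrum: elbow lands within [5, 10]
  v <- c(50, 40, 30, 20, 10, 1 / (1:45))
  expect_true(select_pcs(v) >= 5 && select_pcs(v) <= 10)
})

test_that("signatures subtract the nearest non-perturbed reference", {
  # identical NP pixels -> all signatures exactly zero
  x <- matrix(1, 30, 5, dimnames = list(pixel_id(1:30, 1),
                                        paste0("g", 1:5)))
  labs <- data.frame(pixel = rownames(x), state = "non_perturbed",
                     sgRNA = NA_character_)
  sa <- perturbation_signature(x, labs, k = 5)
  expect_true(all(sa$signatures == 0))

  # one perturbed pixel: signature is x minus the mean of its k NP
  # neighbors, computed directly
  set.seed(3)
  x <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(pixel_id(1:40, 1), paste0("g", 1:6)))
  labs <- data.frame(pixel = rownames(x),
                     state = c("unique", rep("non_perturbed", 39)),
                     sgRNA = c("s1", rep(NA, 39)))
  sa <- perturbation_signature(x, labs, k = 39, n_pcs = 6)
  ref <- colMeans(x[2:40, ])
  expect_equal(sa$signatures["1x1", ], x["1x1", ] - ref)
})

test_that("fewer non-perturbed pixels than k is an instructive error", {
  x <- matrix(rnorm(20), 4, 5, dimnames = list(pixel_id(1:4, 1), NULL))
  labs <- data.frame(pixel = rownames(x), state = "non_perturbed",
                     sgRNA = NA_character_)
  expect_error(perturbation_signature(x, labs, k = 20), "smaller k")
})

test_that("simulated target-gene signatures dwarf off-target signatures", {
  # 50 target genes out of 1000: depth scaling couples off-target genes to
  # the perturbation (compositional effect), so the off-target magnitude is
  # small but non-zero; at a 5% target fraction the on-target mean clears it
  fx <- make_two_clone_gex(seed = 19, n_genes = 1000)
  labs <- label_pixels(fx$counts)
  nrm <- normalize_gex(fx$gex$counts)
  sa <- perturbation_signature(nrm, labs, counts = fx$counts, k = 20,
                               library_size = nrow(fx$lib))
  pert <- sa$labels$pixel[!is.na(sa$labels$sgRNA) &
                          sa$labels$sgRNA == fx$g1]
  on_target <- mean(sa$signatures[pert, fx$targets[[fx$g1]]])
  off <- setdiff(colnames(sa$signatures), unlist(fx$targets))
  off_target <- mean(sa$signatures[pert, off])
  expect_gt(on_target, 0)
  expect_gt(on_target, 5 * abs(off_target))
})

test_that("perturbation scores are correlations with the class vector", {
  # class s1 has vector v1 (two pixels at v1); class s2 averages to -v1/3
  # (pixels at -v1, -v1, +v1); the NP pixel sits at v2, orthogonal to v1,
  # so it is uncorrelated with the mean class vector v1/3
  v1 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  v2 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  sig <- rbind(a1 = v1, a2 = v1, c1 = -v1, c2 = -v1, d1 = v1, n1 = v2)
  colnames(sig) <- paste0("g", 1:8)
  labs <- data.frame(pixel = rownames(sig),
                     state = c(rep("unique", 5), "non_perturbed"),
                     sgRNA = c("s1", "s1", "s2", "s2", "s2", NA))
  assay <- structure(list(signatures = sig, labels = labs,
                          included_sgRNAs = c("s1", "s2"), k = 1,
                          n_pcs = 2), class = "signature_assay")
  sc <- perturbation_score(assay)
  expect_equal(unname(sc["a1"]), 1)    # signature equals its class vector
  expect_equal(unname(sc["c1"]), 1)    # correlation is scale-free
  expect_equal(unname(sc["d1"]), -1)   # signature opposes its class vector
  expect_equal(unname(sc["n1"]), 0)    # orthogonal to the mean class vector
})

test_that("score filtering splits perturbed and control pixels at 0.2", {
  labs <- data.frame(pixel = c("1x1", "1x2", "2x1", "2x2"),
                     state = c("unique", "unique", "non_perturbed",
                               "non_perturbed"),
                     sgRNA = c("s1", "s1", NA, NA))
  sc <- setNames(c(0.3, 0.1, -0.25, -0.1), labs$pixel)
  fl <- filter_by_score(sc, labs)
  expect_identical(fl$perturbed, "1x1")
  expect_identical(fl$control, "2x1")
  expect_warning(filter_by_score(setNames(c(0.1, 0.1, 0, 0), labs$pixel),
                                 labs), "empty perturbed")
})

test_that("well-separated blobs are clustered and named correctly", {
  set.seed(8)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  n_per <- 40
  x <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(n_per, centers[i, 1], 0.3),
          rnorm(n_per, centers[i, 2], 0.3))))
  x <- cbind(x, matrix(rnorm(nrow(x) * 3, sd = 0.3), ncol = 3))
  rownames(x) <- pixel_id(seq_len(nrow(x)), 1)
  truth <- rep(1:4, each = n_per)
  cr <- cluster_pixels(x, seed = 0)
  expect_gte(mclust::adjustedRandIndex(cr$cluster, truth), 0.99)

  # naming: blob 1 pixels carry guide gA, blob 2 is half gB, others NP
  pert <- setNames(rep("NP", nrow(x)), rownames(x))
  pert[truth == 1] <- "gA"
  pert[truth == 2][1:12] <- "gB"  # 30% of the blob
  nms <- name_clusters(cr$cluster, pert)
  named <- nms[as.character(cr$cluster)]
  expect_true(any(named == "gA"))
  expect_true(any(named == "gB"))
  expect_true(any(grepl("^NP\\+", named)))
})

test_that("cluster assignment is invariant to pixel order at a fixed seed", {
  set.seed(12)
  x <- rbind(matrix(rnorm(200, 0), 50, 4), matrix(rnorm(200, 6), 50, 4),
             matrix(rnorm(200, 12), 50, 4), matrix(rnorm(200, 18), 50, 4))
  rownames(x) <- pixel_id(seq_len(nrow(x)), 2)
  cr1 <- cluster_pixels(x, seed = 0, umap = FALSE)
  perm <- sample(nrow(x))
  cr2 <- cluster_pixels(x[perm, ], seed = 0, umap = FALSE)
  expect_identical(cr1$cluster[names(cr2$cluster)], cr2$cluster)
})

test_that("degenerate identical pixels fall back to a single cluster", {
  x <- matrix(1, 30, 4, dimnames = list(pixel_id(1:30, 3), NULL))
  expect_warning(cr <- cluster_pixels(x, seed = 0, umap = FALSE),
                 "single cluster")
  expect_equal(length(unique(cr$cluster)), 1)
})

test_that("cluster naming joins majors and falls back to NP+n", {
  cl <- setNames(rep(1L, 10), pixel_id(1:10, 1))
  pert <- setNames(c(rep("g1", 6), rep("NP", 4)), names(cl))
  expect_identical(unname(name_clusters(cl, pert)), "g1")

  pert <- setNames(c(rep("g1", 3), rep("g2", 3), rep("NP", 4)), names(cl))
  # 30% and 30%: both major, higher count first (tie broken by table order)
  expect_identical(unname(name_clusters(cl, pert,
                                        major_frac = 0.25)), "g1_g2")

  # NP plus 16 minor perturbations, each below 20% -> "NP+16"
  cl <- setNames(rep(1L, 100), pixel_id(1:100, 1))
  pert <- setNames(c(rep("NP", 52), rep(paste0("g", 1:16), 3)), names(cl))
  expect_identical(unname(name_clusters(cl, pert)), "NP+16")
})

test_that("rank-sum DE matches exact enumeration and flags no nulls", {
  # identical groups: log2FC 0, nothing significant
  set.seed(4)
  base <- matrix(rpois(12 * 20, 10), 12, 20,
                 dimnames = list(pixel_id(1:12, 1), paste0("g", 1:20)))
  base[7:12, ] <- base[1:6, ]
  nrm <- normalize_gex(base)
  de <- de_wilcoxon(nrm, pixel_id(1:6, 1), pixel_id(7:12, 1))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$padj >= 0.999))

  # 4-vs-4: p equals exhaustive rank-sum enumeration (tie-free data)
  set.seed(9)
  cnt <- matrix(rgamma(8 * 15, 20, 1), 8, 15,
                dimnames = list(pixel_id(1:8, 2), paste0("g", 1:15)))
  nrm2 <- normalize_gex(cnt)
  de2 <- de_wilcoxon(nrm2, pixel_id(1:4, 2), pixel_id(5:8, 2))
  for (g in de2$gene) {
    want <- enumerate_ranksum_p(nrm2$depth_scaled[pixel_id(1:4, 2), g],
                                nrm2$depth_scaled[pixel_id(5:8, 2), g])
    expect_equal(de2$p[de2$gene == g], want, tolerance = 1e-12)
  }

  expect_error(de_wilcoxon(nrm, character(0), pixel_id(7:12, 1)), "empty")
  expect_error(de_wilcoxon(nrm, pixel_id(1:6, 1), pixel_id(6:12, 1)),
               "disjoint")
})

test_that("BH adjustment follows the closed form", {
  # implementation routes through stats::p.adjust; the closed form for
  # (0.01, 0.02, 0.03) with m = 3 is (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(2)
  cnt <- matrix(rpois(20 * 10, 8), 20, 10,
                dimnames = list(pixel_id(1:20, 5), paste0("g", 1:10)))
  nrm <- normalize_gex(cnt)
  de <- de_wilcoxon(nrm, pixel_id(1:10, 5), pixel_id(11:20, 5))
  expect_equal(de$padj, p.adjust(de$p, "BH")[order(de$p)])
  expect_true(all(de$padj >= de$p))
})

test_that("min_pct gates which genes are tested", {
  cnt <- matrix(5, 10, 3, dimnames = list(pixel_id(1:10, 6),
                                          c("on", "rare", "off")))
  cnt[, "rare"] <- c(5, rep(0, 9))   # 20% detection in group A, not > 0.2
  cnt[, "off"] <- c(rep(0, 5), rep(3, 5))  # absent from group A
  cnt[1, "on"] <- 6  # break the all-constant degenerate case
  nrm <- suppressWarnings(normalize_gex(cnt))
  de <- de_wilcoxon(nrm, pixel_id(1:5, 6), pixel_id(6:10, 6))
  expect_true("on" %in% de$gene)
  expect_false("rare" %in% de$gene)
  expect_false("off" %in% de$gene)
})
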