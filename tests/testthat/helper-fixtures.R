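# Shared small fixtures and independent oracles, built in code.

fixture_library <- function(n_genes = 8, n_ntc = 2, seed = 1) {
  synthetic_spacer_library(n_genes, n_ntc = n_ntc, seed = seed)
}

fixture_whitelists <- function(grid = c(50, 50), seed = 1) {
  list(A = synthetic_whitelist(grid[1], "A", seed = seed),
       B = synthetic_whitelist(grid[2], "B", seed = seed))
}

# --- independent oracles ---------------------------------------------------

# Exhaustive Hamming scan implementing the matcher post-condition directly.
brute_force_match <- function(query, references, max_mm, max_hits) {
  qs <- strsplit(query, "")[[1]]
  d <- vapply(strsplit(references, ""), function(r) {
    if (length(r) != length(qs)) return(NA_integer_)
    sum(r != qs)
  }, integer(1))
  H <- which(!is.na(d) & d <= max_mm)
  if (length(H) == 0) return(list(index = NA_integer_, status = "no_hit"))
  if (length(H) > max_hits) return(list(index = NA_integer_,
                                        status = "ambiguous"))
  dmin <- min(d[H])
  best <- H[d[H] == dmin]
  if (length(best) > 1) return(list(index = NA_integer_,
                                    status = "ambiguous"))
  list(index = best, status = "hit")
}

# AUC by brute-force pairwise concordance (ties count one half).
concordance_auc <- function(predictor, response) {
  pos <- predictor[as.logical(response)]
  neg <- predictor[!as.logical(response)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Two-sided rank-sum p by exhaustive enumeration of group-A assignments.
enumerate_ranksum_p <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(x), na)
  sums <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Direct restatement of the pixel-labeling rule for one count vector.
brute_force_label <- function(counts, min_top = 10, max_other = 1) {
  det <- counts[counts >= 1]
  if (length(det) == 0) return("non_perturbed")
  if (length(det) == 1) return("unique")
  top <- max(det)
  others <- sort(det, decreasing = TRUE)[-1]
  if (top >= min_top && all(others <= max_other)) "resolved" else "ambiguous"
}

# Simulate, emit reads and demultiplex in one call; returns truth + result.
run_roundtrip <- function(seed, substitution_rate = 0, grid = c(50, 50),
                          n_clones = 4, clone_radius = 2.9, umi_rate = 5,
                          ambient_rate = 0.05, lib = fixture_library(),
                          wl = NULL, schema = chemistry_preset("polyA_enrichment")) {
  if (is.null(wl)) wl <- fixture_whitelists(grid)
  tt <- simulate_tissue(grid = grid, n_clones = n_clones,
                        clone_radius = clone_radius, library = lib,
                        umi_rate = umi_rate, ambient_rate = ambient_rate,
                        seed = seed)
  em <- emit_reads(tt, schema, wl, lib, substitution_rate = substitution_rate,
                   seed = seed)
  res <- assign_reads(em$r1, em$r2, schema, wl, lib)
  list(truth = tt, emitted = em, result = res)
}

# Two-clone perturbed tissue with NB expression, shared by clustering and DE
# tests; sizes chosen so each class has ~200 pixels.
make_two_clone_gex <- function(seed = 11, n_genes = 400, effect = 2) {
  lib <- fixture_library()
  tt <- simulate_tissue(grid = c(34, 34), n_clones = 2, clone_radius = 8,
                        library = lib, umi_rate = 5, ambient_rate = 0.02,
                        seed = seed)
  g1 <- tt$clones$sgRNA[1]; g2 <- tt$clones$sgRNA[2]
  targets <- setNames(list(sprintf("gene%04d", 1:50),
                           sprintf("gene%04d", 51:100)), c(g1, g2))
  set.seed(seed + 500)
  mu <- exp(rnorm(n_genes, log(8), 0.5))
  gx <- emit_gex(tt, n_genes = n_genes, baseline_mu = mu, dispersion = 10,
                 target_sets = targets, effect = effect, seed = seed)
  cm <- count_matrix(tt$molecules, tt$grid, lib$name)
  list(lib = lib, truth = tt, gex = gx, counts = cm,
       g1 = g1, g2 = g2, targets = targets)
}
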