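#' Receiver-operator curve and rank-based AUC
#'
#' The AUC is the Mann-Whitney statistic `U / (n1 * n0)` computed with
#' midranks, so ties contribute one half; it equals the trapezoidal area
#' under the returned curve. The curve enumerates the distinct predictor
#' values as thresholds (predictions `>= threshold` are called positive).
#'
#' @param predictor Numeric scores.
#' @param response Binary response (logical, or 0/1).
#' @return An object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(predictor, response) {
  response <- as.logical(response)
  stopifnot(length(predictor) == length(response), !anyNA(predictor),
            !anyNA(response))
  n_pos <- sum(response); n_neg <- sum(!response)
  if (n_pos == 0 || n_neg == 0)
    stop("response must contain both classes")
  r <- rank(predictor)  # midranks
  auc <- (sum(r[response]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(predictor), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(response & predictor >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!response & predictor >= t), numeric(1))
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tp / n_pos),
                 fpr = c(0, fp / n_neg), auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC ", round(x$auc, 4), " (", x$n_pos, " positive, ",
      x$n_neg, " negative)\n", sep = "")
  invisible(x)
}

#' Benchmark pooled guide detection against spatial detection area
#'
#' Builds the ROC of the pooled screen's per-guide detection fraction (the
#' continuous predictor) against spatial detection (`area > area_thr`, the
#' binary response). Guides absent from either side are treated as zero on
#' that side. The conventional pooled cut (`pooled_thr`, default 25%) is
#' reported as a marked operating point on the curve together with its 2x2
#' contingency table, rather than binarizing the predictor, which would
#' degenerate the AUC.
#'
#' @param pooled Named numeric vector of pooled detection fractions per
#'   sgRNA (or a data frame with columns `sgRNA`, `fraction`).
#' @param spatial An `sgrna_matrix` (or named vector of areas).
#' @param area_thr Spatial detection gate on area (default 2, exclusive).
#' @param pooled_thr Pooled operating point (default 0.25).
#' @return List with `roc` (a `roc_result`), `contingency` (2x2 table at
#'   `pooled_thr`), `operating_point` (tpr/fpr at `pooled_thr`), and
#'   `table` (the per-guide merged data).
#' @export
pooled_vs_spatial <- function(pooled, spatial, area_thr = 2,
                              pooled_thr = 0.25) {
  if (is.data.frame(pooled))
    pooled <- setNames(pooled$fraction, pooled$sgRNA)
  areas <- if (inherits(spatial, "sgrna_matrix")) sgrna_area(spatial)
           else spatial
  if (!length(intersect(names(pooled), names(areas))))
    stop("no overlapping sgRNAs between pooled and spatial data")
  all_sg <- union(names(pooled), names(areas))
  pf <- setNames(rep(0, length(all_sg)), all_sg)
  pf[names(pooled)] <- pooled
  ar <- setNames(rep(0L, length(all_sg)), all_sg)
  ar[names(areas)] <- areas
  response <- ar > area_thr
  roc <- roc_auc(pf, response)
  called <- pf > pooled_thr
  contingency <- table(pooled = factor(called, c(FALSE, TRUE)),
                       spatial = factor(response, c(FALSE, TRUE)))
  op <- c(tpr = sum(called & response) / sum(response),
          fpr = sum(called & !response) / sum(!response))
  list(roc = roc, contingency = contingency, operating_point = op,
       table = data.frame(sgRNA = all_sg, pooled_fraction = pf, area = ar,
                          detected = response, row.names = NULL))
}

#' Demultiplexer recovery report against simulator truth
#'
#' Compares read assignments with the per-read truth table: an assignment
#' is correct when its pixel and sgRNA match the truth row of the same read
#' id. Precision is correct / assigned, recall is correct / truth reads;
#' the exact-triple fraction additionally requires the UMI sequence to
#' match. Per-sgRNA detection areas are compared with truth areas.
#'
#' @param result A [assign_reads()] `demux_result` (or an assignment data
#'   frame).
#' @param truth Per-read truth table (`read_id`, `a`, `b`, `sgRNA`, `umi`).
#' @return An object of class `recovery_report`: list with `n_total`,
#'   `n_assigned`, `n_rejected`, `reasons` (named counts), `precision`,
#'   `recall`, `umi_triple_exact`, `area_error` (named assigned - truth
#'   area per sgRNA).
#' @export
demux_recovery <- function(result, truth) {
  if (inherits(result, "demux_result")) {
    asg <- result$assignments
    reasons <- table(result$rejects$reason)
    n_total <- result$n_total
  } else {
    asg <- result
    reasons <- table(character(0))
    n_total <- nrow(truth)
  }
  unknown <- setdiff(asg$read_id, truth$read_id)
  if (length(unknown))
    stop("assignments contain read ids absent from truth: ",
         paste(head(unknown), collapse = ", "))
  tr <- truth[match(asg$read_id, truth$read_id), ]
  correct <- asg$a == tr$a & asg$b == tr$b & asg$sgRNA == tr$sgRNA
  triple <- correct & asg$umi == tr$umi
  area_of <- function(df) {
    key <- unique(df[, c("a", "b", "sgRNA")])
    tapply(rep(1L, nrow(key)), key$sgRNA, sum)
  }
  ta <- area_of(truth)
  aa <- area_of(asg)
  sg <- union(names(ta), names(aa))
  area_err <- setNames(rep(0L, length(sg)), sg)
  area_err[names(aa)] <- aa
  area_err <- area_err - ifelse(is.na(ta[sg]), 0L, ta[sg])
  structure(list(
    n_total = n_total, n_assigned = nrow(asg),
    n_rejected = n_total - nrow(asg),
    reasons = reasons,
    precision = if (nrow(asg)) mean(correct) else NA_real_,
    recall = sum(correct) / nrow(truth),
    umi_triple_exact = if (nrow(asg)) mean(triple) else NA_real_,
    area_error = area_err), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report: ", x$n_assigned, "/", x$n_total, " assigned; ",
      "precision ", signif(x$precision, 6), ", recall ",
      signif(x$recall, 6), ", exact-triple ",
      signif(x$umi_triple_exact, 6), "\n", sep = "")
  invisible(x)
}
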