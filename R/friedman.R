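# Friedman rank test and Nemenyi post-hoc comparison for detector
# benchmarking: k models ranked over n metric blocks.

#' Rank models per metric
#'
#' Builds a [RankTable-class] from a metric table: within each metric
#' column, rank 1 is best (highest value when \code{higherIsBetter}), and
#' ties receive average ranks.
#'
#' @param metrics data.frame with a \code{model} column and one numeric
#'   column per metric, or a numeric matrix with rownames.
#' @param higherIsBetter Logical, default TRUE.
#' @return A [RankTable-class].
#' @export
rankModels <- function(metrics, higherIsBetter = TRUE) {
  if (is.data.frame(metrics)) {
    models <- metrics$model
    m <- as.matrix(metrics[, setdiff(names(metrics), "model"), drop = FALSE])
    rownames(m) <- models
  } else m <- as.matrix(metrics)
  r <- apply(m, 2, function(col)
    rank(if (higherIsBetter) -col else col, ties.method = "average"))
  RankTable(r)
}

#' Friedman test on a rank table
#'
#' Classical statistic
#' \eqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)} over k
#' treatments (models) and n blocks (metrics), with \eqn{R_j} the rank sum
#' of model j. With \code{tieCorrection} (default on) the statistic is
#' divided by \eqn{1 - \sum (t^3 - t) / (n k (k^2 - 1))} summed over tie
#' groups, which leaves tie-free tables unchanged. The p-value uses the
#' \eqn{\chi^2_{k-1}} reference distribution.
#'
#' @param rt A [RankTable-class] (or k x n rank matrix).
#' @param tieCorrection Apply the tie correction (default TRUE).
#' @return List: \code{statistic}, \code{df}, \code{p.value}, \code{k},
#'   \code{n}, \code{rankSums}.
#' @export
friedmanRankTest <- function(rt, tieCorrection = TRUE) {
  r <- if (is(rt, "RankTable")) modelRanks(rt) else as.matrix(rt)
  k <- nrow(r); n <- ncol(r)
  Rj <- rowSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  if (tieCorrection) {
    tieTerm <- sum(apply(r, 2, function(col) {
      t <- table(col)
      sum(t^3 - t)
    }))
    denom <- 1 - tieTerm / (n * k * (k^2 - 1))
    if (denom > 0) stat <- stat / denom
  }
  list(statistic = stat, df = k - 1,
       p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       k = k, n = n, rankSums = Rj)
}

# Nemenyi critical values q_alpha(k) (studentized range / sqrt(2)),
# k = 2..10, the standard table used for critical-difference diagrams.
.NEMENYI_Q <- list(
  "0.05" = c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728,
             `6` = 2.850, `7` = 2.949, `8` = 3.031, `9` = 3.102,
             `10` = 3.164),
  "0.1"  = c(`2` = 1.645, `3` = 2.052, `4` = 2.291, `5` = 2.459,
             `6` = 2.589, `7` = 2.693, `8` = 2.780, `9` = 2.855,
             `10` = 2.920))

#' Nemenyi critical distance
#'
#' \eqn{CD = q_\alpha(k) \sqrt{k (k+1) / (6 n)}}: the minimum average-rank
#' difference deemed significant in the post-hoc pairwise comparison after
#' a Friedman test. For six models over four metrics at
#' \eqn{\alpha = 0.05}, CD = 3.770; for four over four, CD = 2.345.
#'
#' @param k Number of treatments (2..10).
#' @param n Number of blocks.
#' @param alpha 0.05 or 0.1.
#' @return The critical distance (scalar).
#' @export
nemenyiCD <- function(k, n, alpha = 0.05) {
  qtab <- .NEMENYI_Q[[as.character(alpha)]]
  if (is.null(qtab)) stop("alpha must be 0.05 or 0.1")
  q <- qtab[as.character(k)]
  if (is.na(q)) stop("k must be between 2 and 10")
  unname(q * sqrt(k * (k + 1) / (6 * n)))
}

#' Pairwise Nemenyi comparison report
#'
#' Average rank per model plus all pairwise average-rank differences,
#' flagged significant when the absolute difference exceeds the critical
#' distance.
#'
#' @param rt A [RankTable-class].
#' @param alpha Significance level (0.05 or 0.1).
#' @return List: \code{friedman} (see [friedmanRankTest()]), \code{cd},
#'   \code{averageRanks}, and \code{pairs} — data.frame with columns
#'   \code{model1, model2, diff, significant}.
#' @export
compareReport <- function(rt, alpha = 0.05) {
  fr <- friedmanRankTest(rt)
  cd <- nemenyiCD(fr$k, fr$n, alpha)
  avg <- averageRanks(rt)
  models <- names(avg)
  if (is.null(models)) models <- paste0("model", seq_along(avg))
  cmb <- utils::combn(seq_along(avg), 2)
  pairs <- data.frame(model1 = models[cmb[1, ]], model2 = models[cmb[2, ]],
                      diff = abs(avg[cmb[1, ]] - avg[cmb[2, ]]))
  pairs$significant <- pairs$diff > cd
  rownames(pairs) <- NULL
  list(friedman = fr, cd = cd, averageRanks = avg, pairs = pairs)
}

#' Load a packaged benchmark table
#'
#' The published benchmark and ablation tables for the goat-face study are
#' shipped as CSV fixtures: per-model P/R/F1/AP (\code{"small_metrics"},
#' \code{"normal_metrics"}, \code{"ablation_metrics"}) and the
#' corresponding printed rank tables (\code{"small_ranks"},
#' \code{"normal_ranks"}, \code{"ablation_ranks"}).
#'
#' @param which Table name (see above).
#' @return data.frame; rank tables can be passed to [RankTable()].
#' @export
benchmarkTable <- function(which = c("small_metrics", "normal_metrics",
                                     "ablation_metrics", "small_ranks",
                                     "normal_ranks", "ablation_ranks")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"),
                      package = "capriDetect", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
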