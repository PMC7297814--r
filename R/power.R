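#' Closed-form power for a two-group RNA-seq comparison
#'
#' Hart-style analytic power for detecting a fold change `fc` between two
#' groups of `n` samples each, for a gene sequenced at mean depth `depth`
#' with biological coefficient of variation `cv`, at two-sided level `alpha`:
#'
#'   power = Phi( sqrt( n (ln fc)^2 / (2 (1/depth + cv^2)) ) - z_{1-alpha/2} )
#'
#' The variance term `1/depth + cv^2` is the per-sample variance of the log
#' counts under the negative-binomial model (shot noise plus biological
#' overdispersion). Defaults correspond to the blood sRNA study this package
#' reproduces: n = 20 per group, depth 676, cv 0.47, alpha 0.1 — the pairing
#' that reproduces all four of its printed power values.
#'
#' @param fc Fold change(s), each > 1.
#' @param n Per-group sample size (>= 2).
#' @param depth Mean counts per gene (> 0).
#' @param cv Biological coefficient of variation (>= 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power value(s) in \code{[0, 1]}, same length as `fc`.
#' @examples
#' hart_power(c(1.2, 1.5, 1.7, 2))  # 0.336, 0.859, 0.972, 0.9987
#' @export
hart_power <- function(fc, n = 20, depth = 676, cv = 0.47, alpha = 0.1) {
  if (any(fc <= 1)) stop("fc must exceed 1 (direction is handled by the caller)")
  if (n < 2) stop("n must be at least 2")
  if (depth <= 0) stop("depth must be positive")
  if (cv < 0) stop("cv must be nonnegative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::pnorm(sqrt(n * log(fc)^2 / (2 * (1 / depth + cv^2))) -
                 stats::qnorm(1 - alpha / 2))
}

#' Per-group sample size for a target power
#'
#' Inverts [hart_power] for `n` (rounded up). A convenience, not a validated
#' study-design tool.
#'
#' @inheritParams hart_power
#' @param power Target power in (alpha/2, 1).
#' @return Smallest integer per-group `n` reaching the target.
#' @export
hart_sample_size <- function(power, fc, depth = 676, cv = 0.47, alpha = 0.1) {
  if (any(fc <= 1)) stop("fc must exceed 1")
  if (power <= alpha / 2 || power >= 1) stop("power must lie in (alpha/2, 1)")
  z <- stats::qnorm(power) + stats::qnorm(1 - alpha / 2)
  ceiling(z^2 * 2 * (1 / depth + cv^2) / log(fc)^2)
}

#' Shuffle-and-spike empirical power
#'
#' The permutation-based power estimate used alongside the closed form:
#' (1) each sRNA's counts are permuted across samples (destroying the group
#' structure while preserving each sRNA's count multiset), (2) a random
#' subset of sRNAs is spiked by multiplying their counts in one group by
#' `fc` (rounded to integers), (3) the NB quasi-likelihood omnibus test and
#' BH adjustment are rerun, and (4) the fraction of spiked sRNAs detected at
#' `q < fdr_threshold` is reported together with the empirical FDR among the
#' detections. Library sizes are re-totalled from the spiked matrix, as they
#' would be for a real dataset.
#'
#' @param x A detectability-filtered [srna_counts].
#' @param groups Named factor from [sample_groups].
#' @param fc Simulated fold change (> 0; 1 gives the null spike).
#' @param spike_fraction Fraction of sRNAs to spike, in (0, 1).
#' @param fdr_threshold Detection cutoff on the BH q-value.
#' @param seed Integer seed.
#' @param spike_group Group receiving the fold change (default `"RAA"`).
#' @param shuffle `"within"` permutes each sRNA's samples independently;
#'   `"global"` permutes all matrix entries.
#' @param keep_matrix Also return the shuffled-and-spiked count matrix.
#' @return List: `n_spiked`, `n_detected`, `detection_fraction`,
#'   `empirical_fdr` (NA when nothing is detected), `seed`, `spiked_ids`,
#'   and `matrix` when requested.
#' @export
shuffle_spike_power <- function(x, groups, fc, spike_fraction = 0.1,
                                fdr_threshold = 0.1, seed = 1,
                                spike_group = "RAA",
                                shuffle = c("within", "global"),
                                keep_matrix = FALSE) {
  stopifnot(inherits(x, "srna_counts"))
  shuffle <- match.arg(shuffle)
  if (fc <= 0) stop("fc must be positive")
  if (spike_fraction <= 0 || spike_fraction >= 1)
    stop("spike_fraction must lie in (0, 1)")
  groups <- groups[colnames(x$counts)]
  if (!spike_group %in% levels(groups)) stop("no such group: ", spike_group)
  set.seed(child_seed(seed, "spike"))

  cnt <- x$counts
  if (shuffle == "within") {
    cnt <- t(apply(cnt, 1, sample))
    colnames(cnt) <- colnames(x$counts)
  } else {
    cnt[] <- sample(cnt)
  }
  n_spiked <- floor(spike_fraction * nrow(cnt))
  spiked <- sample(rownames(cnt), n_spiked)
  sel <- groups == spike_group
  cnt[spiked, sel] <- pmax(0, round(cnt[spiked, sel] * fc))

  de <- srna_de(srna_counts(cnt), groups)
  hit <- de$table$q < fdr_threshold
  detected <- de$table$srna_id[hit]
  fp <- sum(!detected %in% spiked)
  out <- list(n_spiked = n_spiked,
              n_detected = sum(detected %in% spiked),
              detection_fraction = if (n_spiked > 0) mean(spiked %in% detected) else NA_real_,
              empirical_fdr = if (length(detected) > 0) fp / length(detected) else NA_real_,
              seed = seed, spiked_ids = spiked)
  if (keep_matrix) out$matrix <- cnt
  out
}
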