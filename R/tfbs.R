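#' Expression-matched nonregulated background
#'
#' Samples a background set whose mean-expression distribution matches the
#' query's, removing expression level as a confounder of ChIP-seq signal:
#' query mean log-CPM values are binned into deciles, the background quota
#' per decile is the query's occupancy scaled to `size` (largest-remainder
#' rounding), and each quota is drawn without replacement from the
#' nonregulated ids falling in that decile. A decile whose nonregulated
#' stratum is too small triggers a warning and proportional reallocation of
#' the shortfall to the remaining strata.
#'
#' @param regulated Character vector of query (regulated) sRNA ids.
#' @param nonregulated Character vector of candidate background ids.
#' @param expression Named numeric vector of per-sRNA mean log-CPM covering
#'   both sets.
#' @param size Background size (default 455).
#' @param seed Integer seed.
#' @return Character vector of background ids of length `size` (or the whole
#'   pool when smaller).
#' @export
matched_background <- function(regulated, nonregulated, expression,
                               size = 455, seed = 1) {
  if (length(intersect(regulated, nonregulated)) > 0)
    stop("regulated and nonregulated sets overlap")
  miss <- setdiff(c(regulated, nonregulated), names(expression))
  if (length(miss) > 0)
    stop("expression missing for ", length(miss), " sRNA(s)")
  if (size > length(nonregulated))
    stop("requested background of ", size, " from only ",
         length(nonregulated), " nonregulated sRNAs")
  set.seed(child_seed(seed, "background"))

  eq <- expression[regulated]
  breaks <- unique(stats::quantile(eq, probs = seq(0, 1, 0.1), names = FALSE))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  q_bin <- cut(eq, breaks = breaks, include.lowest = TRUE)
  pool_bin <- cut(expression[nonregulated], breaks = breaks,
                  include.lowest = TRUE)
  pool <- split(nonregulated, pool_bin)

  quota <- largest_remainder(tabulate(q_bin, nbins = nlevels(q_bin)), size)
  avail <- vapply(levels(q_bin), function(b) length(pool[[b]]), integer(1))
  short <- pmax(0, quota - avail)
  if (any(short > 0)) {
    warning("empty or undersized nonregulated stratum in ", sum(short > 0),
            " decile(s); reallocating ", sum(short),
            " draw(s) proportionally")
    quota <- pmin(quota, avail)
    room <- avail - quota
    while (sum(short) > 0 && sum(room) > 0) {
      add <- largest_remainder(room, min(sum(short), sum(room)))
      quota <- quota + add
      short <- c(sum(short) - sum(add), rep(0, length(short) - 1))
      room <- avail - quota
    }
  }
  out <- unlist(lapply(seq_along(quota), function(i) {
    ids <- pool[[levels(q_bin)[i]]]
    if (quota[i] == 0) character(0) else sample(ids, quota[i])
  }))
  unname(out)
}

#' Mean ChIP-seq coverage in a window around locus starts
#'
#' Per-locus mean per-base coverage over the window `[start - w, start + w]`
#' centered on the strand-aware 5' start (the `start` coordinate on `+`, the
#' last base on `-`), with uncovered bases counting 0. Windows running off
#' the chromosome origin are clipped and flagged; the divisor stays the full
#' window length so off-end bases also count 0.
#'
#' @param track Coverage track ([read_bedgraph] layout).
#' @param annotation Annotation rows for the loci of interest.
#' @param window Half-width in bp (>= 0), default 1000.
#' @param mode `"window"` (default) averages around the 5' start; `"body"`
#'   averages over the annotated locus body instead.
#' @return Data frame: `srna_id`, `signal`, `clipped`.
#' @export
locus_signal <- function(track, annotation, window = 1000,
                         mode = c("window", "body")) {
  mode <- match.arg(mode)
  track <- validate_track(track)
  if (window < 0) stop("window must be nonnegative")
  if (mode == "body") {
    from <- annotation$start
    to <- annotation$end
  } else {
    center <- ifelse(annotation$strand == "+", annotation$start,
                     annotation$end - 1L)
    from <- center - window
    to <- center + window + 1L
  }
  len <- to - from
  clipped <- from < 0
  from <- pmax(0L, from)
  sums <- track_interval_sums(track, annotation$chrom, from, to)
  data.frame(srna_id = annotation$srna_id, signal = sums / len,
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Welch-test overrepresentation of ChIP-seq signal
#'
#' Two-sided Welch (unequal-variance) t-test of per-locus query signals
#' against background signals, Bonferroni-corrected over the number of
#' tracks tested in the experiment. Degenerate input with zero variance on
#' both sides and equal means yields t = 0, p = 1.
#'
#' @param query,background Numeric vectors of per-locus signals (>= 2 each).
#' @param n_tracks Number of tracks in the family (Bonferroni factor).
#' @param tf Optional track label carried into the result.
#' @return One-row data frame: `tf`, `mean_query`, `mean_background`,
#'   `t`, `df`, `p`, `p_adjusted`, `n_query`, `n_background`.
#' @export
test_overrepresentation <- function(query, background, n_tracks = 1,
                                    tf = NA_character_) {
  if (length(query) < 2 || length(background) < 2)
    stop("need at least 2 signal values per side")
  if (stats::sd(query) == 0 && stats::sd(background) == 0) {
    tt <- list(statistic = if (mean(query) == mean(background)) 0 else
                 sign(mean(query) - mean(background)) * Inf,
               parameter = NA_real_,
               p.value = if (mean(query) == mean(background)) 1 else 0)
  } else {
    tt <- stats::t.test(query, background, var.equal = FALSE)
  }
  data.frame(tf = tf, mean_query = mean(query),
             mean_background = mean(background),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, p_adjusted = min(1, tt$p.value * n_tracks),
             n_query = length(query), n_background = length(background),
             stringsAsFactors = FALSE)
}

#' Strand-oriented signal profile around locus starts
#'
#' Per-locus binned coverage over relative positions `-window .. +window`
#' around the strand-aware 5' start, with the across-locus mean profile —
#' the data behind an averaged ChIP-signal histogram. Rows of minus-strand
#' loci are reversed so columns always read 5' upstream to downstream.
#'
#' @param track Coverage track.
#' @param annotation Annotation rows of the loci.
#' @param window Half-width in bp; must be a multiple of `bin`.
#' @param bin Bin width in bp.
#' @return List: `matrix` (loci x bins, dimnames = ids x relative bin start),
#'   `position` (bin start offsets), `mean` (averaged profile).
#' @export
signal_profile <- function(track, annotation, window = 1000, bin = 50) {
  if (window %% bin != 0) stop("window must be a multiple of bin")
  track <- validate_track(track)
  offs <- seq(-window, window - bin, by = bin)
  center <- ifelse(annotation$strand == "+", annotation$start,
                   annotation$end - 1L)
  n_bin <- length(offs)
  prof <- matrix(0, nrow = nrow(annotation), ncol = n_bin,
                 dimnames = list(annotation$srna_id, offs))
  slices <- split(track, track$chrom)
  for (i in seq_len(nrow(annotation))) {
    sl <- slices[[annotation$chrom[i]]]
    if (is.null(sl)) next
    from <- center[i] - window
    to <- from + n_bin * bin
    lo <- findInterval(from + 0.5, sl$end) + 1L
    hi <- findInterval(to - 0.5, sl$start)
    if (lo > hi) next
    for (r in lo:hi) {
      s <- max(sl$start[r], from, 0)
      e <- min(sl$end[r], to)
      if (e <= s) next
      b1 <- (s - from) %/% bin + 1L
      b2 <- (e - 1 - from) %/% bin + 1L
      for (b in b1:b2) {
        bs <- from + (b - 1L) * bin
        prof[i, b] <- prof[i, b] +
          sl$score[r] * (min(e, bs + bin) - max(s, bs))
      }
    }
  }
  prof <- prof / bin
  minus <- annotation$strand == "-"
  prof[minus, ] <- prof[minus, n_bin:1, drop = FALSE]
  list(matrix = prof, position = offs, mean = colMeans(prof))
}

#' Partition query loci into bound / unbound by ChIP signal
#'
#' A locus is called bound when its signal exceeds the background mean by
#' more than `k` background standard deviations (default k = 2). With a
#' degenerate background (zero SD) any signal above the background mean is
#' bound. The two id sets feed [chisq_composition] for a bound-vs-unbound
#' class-composition test.
#'
#' @param signals Data frame from [locus_signal] for the query loci.
#' @param background_signals Numeric vector of background per-locus signals.
#' @param k Threshold in background SD units.
#' @return List: `bound`, `unbound` (id vectors), `threshold`.
#' @export
classify_bound <- function(signals, background_signals, k = 2) {
  mu <- mean(background_signals)
  sdev <- stats::sd(background_signals)
  thr <- if (is.na(sdev) || sdev == 0) mu else mu + k * sdev
  bound <- signals$signal > thr
  list(bound = signals$srna_id[bound], unbound = signals$srna_id[!bound],
       threshold = thr)
}

#' TFBS overrepresentation analysis over a set of ChIP tracks
#'
#' Full query-vs-matched-background analysis: per track, per-locus window
#' signals for the query loci and the expression-matched background, a Welch
#' test Bonferroni-corrected across tracks, the averaged signal profile, and
#' the bound/unbound partition with its composition test.
#'
#' @param tracks Named list of coverage tracks (one per TF).
#' @param query_ids Regulated sRNA ids forming the query set.
#' @param annotation Annotation data frame covering query and background.
#' @param background_ids Background ids (e.g. from [matched_background]).
#' @param window,bin Profile/window parameters (bp).
#' @param mode Signal mode passed to [locus_signal].
#' @param k Bound-call threshold in background SD units.
#' @param profiles Also compute per-track averaged profiles (the slowest
#'   part; can be skipped in large replicate studies).
#' @return List: `enrichment` (one row per track), `profiles`, `bound`
#'   (per-track bound/unbound partition), `signals` (per-track query and
#'   background signal frames).
#' @export
tfbs_analysis <- function(tracks, query_ids, annotation, background_ids,
                          window = 1000, bin = 50,
                          mode = c("window", "body"), k = 2,
                          profiles = TRUE) {
  mode <- match.arg(mode)
  q_ann <- annotation[match(query_ids, annotation$srna_id), ]
  b_ann <- annotation[match(background_ids, annotation$srna_id), ]
  if (anyNA(q_ann$srna_id) || anyNA(b_ann$srna_id))
    stop("query or background ids missing from the annotation")
  res <- list(); prof <- list(); bound <- list(); signals <- list()
  for (tf in names(tracks)) {
    qs <- locus_signal(tracks[[tf]], q_ann, window = window, mode = mode)
    bs <- locus_signal(tracks[[tf]], b_ann, window = window, mode = mode)
    res[[tf]] <- test_overrepresentation(qs$signal, bs$signal,
                                         n_tracks = length(tracks), tf = tf)
    if (profiles)
      prof[[tf]] <- signal_profile(tracks[[tf]], q_ann, window = window,
                                   bin = bin)
    bound[[tf]] <- classify_bound(qs, bs$signal, k = k)
    signals[[tf]] <- list(query = qs, background = bs)
  }
  list(enrichment = do.call(rbind, res), profiles = prof, bound = bound,
       signals = signals)
}
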