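#' Read / write a bedGraph track
#'
#' Four tab-separated columns (chrom, start, end, score), 0-based half-open.
#' Intervals are returned sorted by chromosome and start; overlapping
#' intervals on one chromosome are rejected because per-base scores would be
#' ambiguous.
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  validate_track(df)
}

#' @rdname read_bedgraph
#' @param track Track data frame.
#' @export
write_bedgraph <- function(track, path) {
  track <- validate_track(track)
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_track <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(track)))
  if (any(track$end <= track$start)) stop("track intervals need start < end")
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  ov <- unlist(tapply(seq_len(nrow(track)), track$chrom, function(i) {
    if (length(i) < 2) return(FALSE)
    track$start[i][-1] < track$end[i][-length(i)]
  }))
  if (any(ov)) stop("track has overlapping intervals")
  rownames(track) <- NULL
  track
}

# Sum of score * covered-base-count over [from, to) for each query, on a
# single-chromosome slice of a sorted non-overlapping track. Binary-search
# narrowing keeps this near O(hits) per query.
track_weighted_sum <- function(starts, ends, scores, from, to) {
  n <- length(starts)
  if (n == 0) return(numeric(length(from)))
  vapply(seq_along(from), function(k) {
    lo <- findInterval(from[k] + 0.5, ends) + 1L       # first row with end > from
    hi <- findInterval(to[k] - 0.5, starts)            # last row with start < to
    if (lo > hi) return(0)
    i <- lo:hi
    sum(scores[i] * pmax(0, pmin(ends[i], to[k]) - pmax(starts[i], from[k])))
  }, numeric(1))
}

# Dispatch weighted sums over chromosomes for arbitrary query intervals.
track_interval_sums <- function(track, chrom, from, to) {
  out <- numeric(length(from))
  for (ch in unique(chrom)) {
    sl <- track[track$chrom == ch, , drop = FALSE]
    q <- which(chrom == ch)
    out[q] <- track_weighted_sum(sl$start, sl$end, sl$score, from[q], to[q])
  }
  out
}

#' Mean conservation score over genomic intervals
#'
#' Per-base track scores averaged across each interval, with bases not
#' covered by the track contributing a score of 0 — i.e. the sum of
#' score-weighted covered bases divided by the full interval length.
#'
#' @param track Conservation track ([read_bedgraph] layout), scores in
#'   \code{[0, 1]}.
#' @param intervals Data frame with `chrom`, `start`, `end` (an annotation
#'   table works as is).
#' @return Numeric vector of per-interval means, named by `srna_id` when
#'   present.
#' @export
mean_conservation <- function(track, intervals) {
  track <- validate_track(track)
  if (any(track$score < 0 | track$score > 1))
    stop("conservation scores must lie in [0, 1]")
  len <- intervals$end - intervals$start
  if (any(len <= 0)) stop("zero-length interval")
  out <- track_interval_sums(track, intervals$chrom, intervals$start,
                             intervals$end) / len
  if (!is.null(intervals$srna_id)) names(out) <- intervals$srna_id
  out
}

#' Conservation summary by class and regulation status
#'
#' Descriptive statistics (count, mean, median, quartiles) of per-sRNA mean
#' conservation, grouped by sRNA class crossed with regulation status
#' (`down`, `up`, `mixed`, `nonregulated`) derived from the pattern calls.
#' Purely descriptive: no test is attached, matching how class-specific
#' conservation is reported for this design.
#'
#' @param scores Named per-sRNA mean scores from [mean_conservation].
#' @param annotation Annotation data frame.
#' @param calls Optional data frame from [classify_patterns]; all sRNAs are
#'   summarized as `nonregulated` when omitted.
#' @return Data frame: `class`, `regulation`, `n`, `mean`, `q25`, `median`,
#'   `q75`.
#' @export
summarize_conservation <- function(scores, annotation, calls = NULL) {
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by sRNA id")
  cls <- annotation$class[match(ids, annotation$srna_id)]
  if (anyNA(cls)) stop("scores contain unannotated sRNA ids")
  reg <- rep("nonregulated", length(ids))
  if (!is.null(calls)) {
    i <- match(ids, calls$srna_id)
    dir <- calls$direction[i]
    mem <- calls$membership[i]
    reg[!is.na(mem) & mem != "none"] <-
      ifelse(grepl("^mixed", dir[!is.na(mem) & mem != "none"]), "mixed",
             dir[!is.na(mem) & mem != "none"])
  }
  key <- interaction(cls, reg, drop = TRUE, sep = "\r")
  stat <- t(vapply(split(scores, key), function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(length(v), mean(v), qs)
  }, numeric(5)))
  parts <- strsplit(rownames(stat), "\r", fixed = TRUE)
  out <- data.frame(class = vapply(parts, `[`, "", 1),
                    regulation = vapply(parts, `[`, "", 2),
                    n = as.integer(stat[, 1]), mean = stat[, 2],
                    q25 = stat[, 3], median = stat[, 4], q75 = stat[, 5],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$class, out$regulation), ]
  rownames(out) <- NULL
  out
}
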