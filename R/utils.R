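#' Largest-remainder apportionment
#'
#' Distributes `total` integer units over categories proportionally to
#' `weights`, rounding so the result sums to `total` exactly. Used to realize
#' class proportions and expression-matched background quotas without
#' systematic rounding drift.
#'
#' @param weights Nonnegative numeric weights (need not sum to 1).
#' @param total Integer total to apportion.
#' @return Integer vector, same length as `weights`, summing to `total`.
#' @keywords internal
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    if (total > 0) stop("cannot apportion a positive total over all-zero weights")
    return(out)
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Stable per-stage child seeds derived from one run seed; kept below 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(annotation = 101L, counts = 211L, chip = 307L,
               conservation = 401L, background = 503L, spike = 601L,
               pipeline = 701L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# Format a numeric for TSV output at 6 significant digits; integers untouched.
format_num <- function(x) {
  if (is.double(x)) signif(x, 6) else x
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
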