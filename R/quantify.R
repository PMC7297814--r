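#' Small-RNA count matrix
#'
#' Container for a raw sRNA-by-sample count table together with its library
#' sizes ("total clone counts"). Library sizes default to the column sums but
#' are stored explicitly so that CPM values keep using the pre-filter totals
#' after rows are removed by the detectability filter.
#'
#' @param counts Nonnegative integer matrix, rows = sRNA ids, columns =
#'   sample ids; dimnames required and unique.
#' @param lib_sizes Optional named numeric vector of per-sample library sizes;
#'   defaults to `colSums(counts)`.
#' @return An object of class `srna_counts`: a list with elements `counts`
#'   and `lib_sizes`.
#' @export
srna_counts <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sRNA row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sRNA ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  } else {
    if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(counts)
    if (!identical(sort(names(lib_sizes)), sort(colnames(counts))))
      stop("lib_sizes names must match sample ids")
    lib_sizes <- lib_sizes[colnames(counts)]
  }
  structure(list(counts = counts, lib_sizes = lib_sizes), class = "srna_counts")
}

#' @export
print.srna_counts <- function(x, ...) {
  cat("srna_counts: ", nrow(x$counts), " sRNAs x ", ncol(x$counts),
      " samples; median library size ",
      format(stats::median(x$lib_sizes), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
dim.srna_counts <- function(x) dim(x$counts)

#' Counts per million
#'
#' CPM against the stored library sizes: `cpm[g, j] = counts[g, j] /
#' lib_sizes[j] * 1e6`. When the library sizes are the column sums, each
#' column of the result sums to exactly one million.
#'
#' @param x An [srna_counts] object.
#' @return Numeric matrix of CPM values with the same dimnames as the counts.
#' @export
compute_cpm <- function(x) {
  stopifnot(inherits(x, "srna_counts"))
  zero <- x$lib_sizes <= 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(names(x$lib_sizes)[zero], collapse = ", "))
  t(t(x$counts) / x$lib_sizes) * 1e6
}

#' Detectability filter
#'
#' Retains the sRNAs with CPM strictly above `cpm_threshold` in at least
#' `min_samples` samples (counted over all samples, not per group). Library
#' sizes are by default carried over unchanged from the unfiltered matrix, so
#' downstream CPM values stay on the original total-count scale; set
#' `recompute_lib_sizes = TRUE` to re-total after filtering.
#'
#' @param x An [srna_counts] object.
#' @param cpm_threshold CPM cutoff (strict inequality). Default 2.
#' @param min_samples Minimum number of samples above the cutoff. Default 10.
#' @param recompute_lib_sizes Recompute library sizes from the filtered
#'   matrix. Default `FALSE`.
#' @return A filtered [srna_counts] object (possibly with zero rows).
#' @export
filter_detectable <- function(x, cpm_threshold = 2, min_samples = 10,
                              recompute_lib_sizes = FALSE) {
  stopifnot(inherits(x, "srna_counts"))
  if (cpm_threshold <= 0 || min_samples <= 0)
    stop("cpm_threshold and min_samples must be positive")
  cpm <- compute_cpm(x)
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  if (recompute_lib_sizes) out$lib_sizes <- colSums(out$counts)
  out
}

#' Sample-to-group mapping
#'
#' Validates and normalizes a sample grouping for the three-arm design
#' (acute-phase RAA, chronic-phase RAC, controls C). The control group is
#' placed first so it acts as the reference level in model fits.
#'
#' @param groups Character or factor vector of group labels, named by sample
#'   id (or accompanied by `sample_ids`).
#' @param sample_ids Optional sample ids if `groups` is unnamed.
#' @param reference Reference group label, default `"C"` when present.
#' @return Named factor with the reference level first.
#' @export
sample_groups <- function(groups, sample_ids = NULL, reference = NULL) {
  if (!is.null(sample_ids)) names(groups) <- sample_ids
  if (is.null(names(groups))) stop("groups must be named by sample id")
  g <- factor(as.character(groups))
  names(g) <- names(groups)
  if (is.null(reference)) reference <- if ("C" %in% levels(g)) "C" else levels(g)[1]
  if (!reference %in% levels(g)) stop("reference group not present: ", reference)
  g <- stats::relevel(g, ref = reference)
  tab <- table(g)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2))
    stop("every group needs >= 2 samples; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  g
}

# ---- file I/O -------------------------------------------------------------

#' Read / write a counts table
#'
#' Tab-separated, header row of sample ids, first column the sRNA id.
#' @param path File path.
#' @param lib_sizes Optional library sizes passed to [srna_counts].
#' @return An [srna_counts] object.
#' @export
read_counts_tsv <- function(path, lib_sizes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1)
  srna_counts(as.matrix(df), lib_sizes = lib_sizes)
}

#' @rdname read_counts_tsv
#' @param x An [srna_counts] object.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "srna_counts"))
  df <- data.frame(srna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample grouping table
#'
#' Two tab-separated columns with header: `sample_id`, `group`.
#' @param path File path.
#' @return A named factor as produced by [sample_groups].
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_groups(df$group, sample_ids = df$sample_id)
}

#' @rdname read_groups_tsv
#' @param groups Named factor of group labels.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(
    data.frame(sample_id = names(groups), group = as.character(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sRNA annotation
#'
#' BED6+1: chrom, start, end, name, score, strand, class — 0-based half-open
#' coordinates. `read_annotation_gtf` accepts a GTF with a `class`
#' attribute instead (1-based closed coordinates, converted on read).
#'
#' @param path File path.
#' @return Data frame with columns `srna_id`, `class`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_annotation_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "class"))
  ann <- data.frame(srna_id = df$name, class = df$class, chrom = df$chrom,
                    start = df$start, end = df$end, strand = df$strand,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation_bed
#' @param ann Annotation data frame.
#' @export
write_annotation_bed <- function(ann, path) {
  ann <- validate_annotation(ann)
  utils::write.table(
    data.frame(ann$chrom, ann$start, ann$end, ann$srna_id, 0L, ann$strand,
               ann$class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_annotation_bed
#' @export
read_annotation_gtf <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    sub(paste0(key, ' "([^"]*)"'), "\\1", m)
  }
  ann <- data.frame(srna_id = attr_get(df$V9, "gene_id"),
                    class = attr_get(df$V9, "class"),
                    chrom = df$V1, start = df$V4 - 1L, end = df$V5,
                    strand = df$V7, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  need <- c("srna_id", "class", "chrom", "start", "end", "strand")
  if (!all(need %in% names(ann)))
    stop("annotation missing columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  if (anyDuplicated(ann$srna_id)) stop("duplicate srna_id in annotation")
  if (any(ann$start >= ann$end)) stop("annotation intervals need start < end")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be + or -")
  ann[need]
}
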