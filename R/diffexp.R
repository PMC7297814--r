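#' Negative-binomial quasi-likelihood differential expression
#'
#' Fits, for each sRNA, a negative-binomial log-linear model on the group
#' factor with log library sizes as offsets, and tests the omnibus null of no
#' group effect with the quasi-likelihood F-test: genewise dispersions are
#' shrunk toward the trended/common dispersion by empirical Bayes, the
#' genewise quasi-dispersions are squeezed toward their trend (prior df by
#' moment matching of the scaled-F distribution), and the omnibus F statistic
#' is referred to an F distribution whose denominator df is the residual df
#' plus the estimated prior df. The engine is edgeR's QL pipeline
#' (`estimateDisp`, `glmQLFit`, `glmQLFTest`) — the same machinery used for
#' the blood sRNA analysis this package reproduces. Total-count normalization
#' only: the stored library sizes are the offsets and no TMM-style scaling
#' factors are applied.
#'
#' Fold changes are reported per non-reference group on the linear scale
#' against the reference (control) group, computed from the fitted group
#' means. All-zero rows are flagged and assigned `F = 0`, `p = 1`,
#' fold change 1.
#'
#' @param x An [srna_counts] object, already detectability-filtered.
#' @param groups Named factor from [sample_groups] (reference level first).
#' @return An object of class `srna_de`: list with `table` (data frame with
#'   `srna_id`, one `fc_<group>` column per non-reference group, `F`,
#'   `df_residual`, `df_prior`, `p`, `q`, `degenerate`), plus `groups`,
#'   `reference` and the edgeR fit in `fit`.
#' @export
srna_de <- function(x, groups) {
  stopifnot(inherits(x, "srna_counts"))
  groups <- groups[colnames(x$counts)]
  if (anyNA(groups)) stop("every sample in the count matrix needs a group")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  groups <- droplevels(groups)
  if (nrow(x$counts) < 2) stop("need at least 2 sRNAs to estimate dispersion")

  zero <- rowSums(x$counts) == 0
  y <- edgeR::DGEList(counts = x$counts, lib.size = unname(x$lib_sizes),
                      group = groups)
  design <- stats::model.matrix(~groups)
  colnames(design) <- sub("^groups", "", colnames(design))
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  test <- edgeR::glmQLFTest(fit, coef = 2:ncol(design))

  contrasts <- levels(groups)[-1]
  fc <- exp(fit$coefficients[, contrasts, drop = FALSE])
  colnames(fc) <- paste0("fc_", contrasts)
  tab <- data.frame(srna_id = rownames(x$counts), fc,
                    F = test$table$F,
                    df_residual = ncol(x$counts) - ncol(design),
                    df_prior = rep_len(unname(fit$df.prior), nrow(x$counts)),
                    p = test$table$PValue,
                    degenerate = zero,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(zero)) {
    tab[zero, grep("^fc_", names(tab))] <- 1
    tab$F[zero] <- 0
    tab$p[zero] <- 1
  }
  tab$q <- bh_adjust(tab$p)
  structure(list(table = tab, groups = groups, reference = levels(groups)[1],
                 fit = fit),
            class = "srna_de")
}

#' @export
print.srna_de <- function(x, ...) {
  cat("srna_de: NB quasi-likelihood omnibus F-test\n")
  cat("  ", nrow(x$table), " sRNAs; groups: ",
      paste(levels(x$groups), collapse = ", "),
      " (reference ", x$reference, ")\n", sep = "")
  cat("  q < 0.1: ", sum(x$table$q < 0.1), " sRNAs\n", sep = "")
  invisible(x)
}

#' @export
summary.srna_de <- function(object, fdr_threshold = 0.1, fc_threshold = 1.2,
                            ...) {
  calls <- classify_patterns(object, fdr_threshold = fdr_threshold,
                             fc_threshold = fc_threshold)
  out <- list(n = nrow(object$table),
              significant = sum(object$table$q < fdr_threshold),
              partition = table(calls$membership),
              direction = table(calls$membership, calls$direction))
  class(out) <- "summary.srna_de"
  out
}

#' @export
print.summary.srna_de <- function(x, ...) {
  cat("sRNAs tested:", x$n, "\n")
  cat("significant (q below threshold):", x$significant, "\n")
  cat("timepoint membership:\n")
  print(x$partition)
  invisible(x)
}

#' @export
coef.srna_de <- function(object, ...) {
  fc <- object$table[, grep("^fc_", names(object$table)), drop = FALSE]
  m <- log(as.matrix(fc))
  rownames(m) <- object$table$srna_id
  colnames(m) <- sub("^fc_", "log_fc_", colnames(m))
  m
}

#' Mean-difference plot of one contrast
#'
#' @param x An `srna_de` object.
#' @param contrast Which non-reference group to plot (default the first).
#' @param fdr_threshold Highlight sRNAs with `q` below this value.
#' @param ... Passed to [plot()].
#' @export
plot.srna_de <- function(x, contrast = NULL,
                         fdr_threshold = 0.1, ...) {
  fc_cols <- grep("^fc_", names(x$table), value = TRUE)
  if (is.null(contrast)) contrast <- sub("^fc_", "", fc_cols[1])
  col <- paste0("fc_", contrast)
  if (!col %in% fc_cols) stop("no such contrast: ", contrast)
  avg <- edgeR::aveLogCPM(x$fit)
  sig <- x$table$q < fdr_threshold
  plot(avg, log2(x$table[[col]]),
       xlab = "average log2 CPM", ylab = paste0("log2 FC (", contrast, " vs ",
                                                x$reference, ")"),
       col = ifelse(sig, "red3", "grey50"), pch = 20, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (q-values): `q_(i) = min_{j >= i}
#' m p_(j) / j`, returned in the original order.
#'
#' @param p Vector of p-values in \code{[0, 1]}.
#' @return Vector of q-values, pointwise at least `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Timepoint-membership and direction classification
#'
#' Implements the regulated-set logic of the three-arm design: an sRNA is
#' significant when its omnibus q-value falls below `fdr_threshold`; a
#' contrast "passes" when its fold change exceeds `fc_threshold` (up) or
#' falls below `1 / fc_threshold` (down). Membership records which contrasts
#' pass (`acute_only`, `chronic_only`, `both`, `none`); direction is `up` or
#' `down` when all passing contrasts agree and `mixed_down_up` /
#' `mixed_up_down` when both pass in opposite directions.
#'
#' @param de An `srna_de` object (or its `table`).
#' @param fdr_threshold Omnibus FDR cutoff, default 0.1.
#' @param fc_threshold Linear fold-change cutoff, default 1.2.
#' @param acute,chronic Group labels of the two contrasts against control.
#' @return Data frame: `srna_id`, `significant`, `membership`, `direction`.
#' @export
classify_patterns <- function(de, fdr_threshold = 0.1, fc_threshold = 1.2,
                              acute = "RAA", chronic = "RAC") {
  tab <- if (inherits(de, "srna_de")) de$table else de
  fa <- tab[[paste0("fc_", acute)]]
  fchr <- tab[[paste0("fc_", chronic)]]
  if (is.null(fa) || is.null(fchr))
    stop("DE table lacks fold-change columns for contrasts ", acute, "/", chronic)
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  sig <- tab$q < fdr_threshold
  dir_a <- ifelse(fa > fc_threshold, 1L, ifelse(fa < 1 / fc_threshold, -1L, 0L))
  dir_c <- ifelse(fchr > fc_threshold, 1L, ifelse(fchr < 1 / fc_threshold, -1L, 0L))
  pass_a <- sig & dir_a != 0L
  pass_c <- sig & dir_c != 0L
  membership <- ifelse(pass_a & pass_c, "both",
                ifelse(pass_a, "acute_only",
                ifelse(pass_c, "chronic_only", "none")))
  direction <- rep(NA_character_, nrow(tab))
  direction[pass_a & !pass_c] <- ifelse(dir_a[pass_a & !pass_c] > 0, "up", "down")
  direction[pass_c & !pass_a] <- ifelse(dir_c[pass_c & !pass_a] > 0, "up", "down")
  bb <- pass_a & pass_c
  direction[bb] <- ifelse(dir_a[bb] > 0 & dir_c[bb] > 0, "up",
                   ifelse(dir_a[bb] < 0 & dir_c[bb] < 0, "down",
                   ifelse(dir_a[bb] < 0, "mixed_down_up", "mixed_up_down")))
  data.frame(srna_id = tab$srna_id, significant = sig,
             membership = membership, direction = direction,
             stringsAsFactors = FALSE)
}

#' Map (membership, direction) calls onto planted pattern labels
#'
#' Convenience for scoring recovery against a simulation truth table: turns
#' the classification of [classify_patterns] into the [DE_PATTERNS]
#' vocabulary used by the generator.
#'
#' @param membership,direction Columns of a [classify_patterns] result.
#' @return Character vector of pattern labels (`"null"` for unregulated).
#' @export
call_to_pattern <- function(membership, direction) {
  out <- rep("null", length(membership))
  out[membership == "acute_only" & direction == "up"] <- "acute_up"
  out[membership == "acute_only" & direction == "down"] <- "acute_down"
  out[membership == "chronic_only" & direction == "up"] <- "chronic_up"
  out[membership == "chronic_only" & direction == "down"] <- "chronic_down"
  out[membership == "both" & direction == "up"] <- "both_up"
  out[membership == "both" & direction == "down"] <- "both_down"
  out[membership == "both" & direction == "mixed_down_up"] <- "mixed_du"
  out[membership == "both" & direction == "mixed_up_down"] <- "mixed_ud"
  out
}
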