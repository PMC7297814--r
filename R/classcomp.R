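#' Sample a nonregulated background set
#'
#' Uniform, seeded sample without replacement from the nonregulated pool —
#' the "randomly selected, nonregulated sRNAs" reference sets used both for
#' the class-composition comparison (size 233) and, expression-matched, for
#' the TFBS analysis (size 455; see [matched_background]).
#'
#' @param nonregulated Character vector of candidate sRNA ids.
#' @param size Number of ids to draw.
#' @param seed Integer seed.
#' @return Character vector of sampled ids.
#' @export
sample_background <- function(nonregulated, size, seed = 1) {
  if (size > length(nonregulated))
    stop("requested background of ", size, " from only ",
         length(nonregulated), " nonregulated sRNAs")
  set.seed(child_seed(seed, "background"))
  sample(nonregulated, size)
}

#' Class composition of an sRNA id set
#'
#' Exact per-class counts over the annotation's class vocabulary; classes
#' with zero members are kept so compositions are always comparable.
#'
#' @param ids Character vector of sRNA ids (possibly empty).
#' @param annotation Annotation data frame ([read_annotation_bed] layout).
#' @param classes Class vocabulary; defaults to the classes present in the
#'   annotation.
#' @return Named integer vector of class counts.
#' @export
compose <- function(ids, annotation, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(annotation$class))
  idx <- match(ids, annotation$srna_id)
  if (anyNA(idx))
    stop("unannotated sRNA id(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  tab <- table(factor(annotation$class[idx], levels = classes))
  out <- as.integer(tab)
  names(out) <- classes
  out
}

#' Chi-square test of two class compositions
#'
#' Pearson chi-square on the 2 x k contingency table of two composition rows
#' (expected counts from the pooled margins, df = k - 1 after dropping
#' classes empty in both rows, no continuity correction). Cells with expected
#' counts below 5 trigger a warning rather than an error, since several sRNA
#' classes are genuinely small.
#'
#' @param a,b Named integer vectors over the same class vocabulary.
#' @return List: `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
chisq_composition <- function(a, b) {
  if (!identical(names(a), names(b)))
    stop("compositions must share one class vocabulary")
  keep <- a + b > 0
  if (sum(keep) < 2) stop("need at least 2 non-empty classes")
  m <- rbind(query = a[keep], reference = b[keep])
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5))
    warning("expected counts below 5 in ", sum(res$expected < 5),
            " cell(s); chi-square approximation may be coarse")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, observed = m, expected = res$expected)
}

#' Composition table of regulated pattern groups versus a background
#'
#' Builds the stacked-bar style summary: one composition row per
#' (membership, direction) group of regulated sRNAs plus one for a seeded
#' random nonregulated background of `background_size` ids, with chi-square
#' tests of each group against the background.
#'
#' @param calls Data frame from [classify_patterns].
#' @param annotation Annotation data frame.
#' @param background_size Size of the nonregulated reference set (default
#'   233, the size of the largest regulated group in the motivating study).
#' @param seed Seed for the background draw.
#' @return List: `composition` (data frame, one row per set), `background_ids`,
#'   `tests` (per-group chi-square against the background).
#' @export
composition_analysis <- function(calls, annotation, background_size = 233,
                                 seed = 1) {
  classes <- sort(unique(annotation$class))
  regulated <- calls$srna_id[calls$membership != "none"]
  nonreg <- setdiff(calls$srna_id, regulated)
  background_size <- min(background_size, length(nonreg))
  bg <- sample_background(nonreg, background_size, seed = seed)

  grp_label <- ifelse(calls$membership == "none", NA,
                      paste(calls$membership, calls$direction, sep = "_"))
  sets <- split(calls$srna_id, grp_label)
  sets <- c(list(nonregulated = bg), sets)
  comp <- t(vapply(sets, compose, integer(length(classes)),
                   annotation = annotation, classes = classes))
  tests <- lapply(setdiff(names(sets), "nonregulated"), function(s) {
    ct <- tryCatch(chisq_composition(comp[s, ], comp["nonregulated", ]),
                   error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    data.frame(set = s, chisq = ct$statistic, df = ct$df,
               p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  list(composition = data.frame(set = rownames(comp), comp,
                                total = rowSums(comp), row.names = NULL,
                                check.names = FALSE),
       background_ids = bg,
       tests = do.call(rbind, tests))
}
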