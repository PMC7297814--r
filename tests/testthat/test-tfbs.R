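test_that("expression-matched background matches the query's deciles", {
  set.seed(1)
  expr <- setNames(rnorm(3000, 8, 2), sprintf("id%04d", 1:3000))
  reg <- names(expr)[1:500]
  pool <- names(expr)[501:3000]
  bg <- matched_background(reg, pool, expr, size = 455, seed = 2)
  expect_length(bg, 455)
  expect_length(intersect(bg, reg), 0)
  expect_identical(bg, matched_background(reg, pool, expr, size = 455, seed = 2))
  # decile histogram of the background tracks the query occupancy (45.5/bin)
  breaks <- quantile(expr[reg], seq(0, 1, 0.1))
  breaks[c(1, 11)] <- c(-Inf, Inf)
  h <- table(cut(expr[bg], breaks))
  expect_true(all(abs(h - 45.5) <= 1))
})

test_that("matched sampling beats uniform sampling under an expression shift", {
  set.seed(7)
  expr <- c(setNames(rnorm(300, 6, 1), sprintf("q%03d", 1:300)),
            setNames(rnorm(2000, 8, 1), sprintf("n%04d", 1:2000)))
  reg <- grep("^q", names(expr), value = TRUE)
  pool <- grep("^n", names(expr), value = TRUE)
  dm <- du <- numeric(50)
  for (s in 1:50) {
    # strata in the far tail of the shifted pool may be sparse; the warning
    # path is itself under test further below
    m <- suppressWarnings(matched_background(reg, pool, expr, size = 200,
                                             seed = s))
    u <- sample_background(pool, 200, seed = s)
    dm[s] <- abs(mean(expr[m]) - mean(expr[reg]))
    du[s] <- abs(mean(expr[u]) - mean(expr[reg]))
  }
  expect_lt(mean(dm), mean(du))
  expect_lt(mean(dm), 0.5 * mean(du))
})

test_that("an undersized stratum triggers reallocation, not failure", {
  expr <- c(setNames(1:100, paste0("q", 1:100)),
            setNames(rep(50, 120), paste0("n", 1:120)))  # pool all in one bin
  expect_warning(
    bg <- matched_background(paste0("q", 1:100), paste0("n", 1:120), expr,
                             size = 100, seed = 1),
    "stratum")
  expect_length(bg, 100)
})

test_that("windowed locus signal matches the per-base brute force", {
  glen <- 2000
  for (seed in 1:100) {
    track <- random_track(seed, glen = glen, n = 30, max_score = 5)
    base <- track_per_base(track, glen)
    set.seed(seed + 9000)
    n <- 4
    start <- sample(300:(glen - 400), n)
    ann <- data.frame(srna_id = paste0("L", 1:n), chrom = "chrT",
                      start = start, end = start + 40,
                      strand = sample(c("+", "-"), n, replace = TRUE))
    w <- 150
    got <- locus_signal(track, ann, window = w)
    want <- vapply(seq_len(n), function(i) {
      center <- if (ann$strand[i] == "+") ann$start[i] else ann$end[i] - 1
      mean(base[(center - w + 1):(center + w + 1)])
    }, numeric(1))
    expect_equal(got$signal, want, tolerance = 1e-12)
    expect_false(any(got$clipped))
  }
})

test_that("locus signal handles constants, emptiness and clipping", {
  flat <- data.frame(chrom = "chrT", start = 0, end = 5000, score = 2.5)
  ann <- data.frame(srna_id = "A", chrom = "chrT", start = 2000, end = 2040,
                    strand = "+")
  expect_equal(locus_signal(flat, ann, window = 100)$signal, 2.5)
  empty <- data.frame(chrom = "chrT", start = 4500, end = 4600, score = 3)
  expect_equal(locus_signal(empty, ann, window = 100)$signal, 0)
  # window off the chromosome start: clipped, off-end bases count as zero
  annL <- data.frame(srna_id = "B", chrom = "chrT", start = 10, end = 50,
                     strand = "+")
  got <- locus_signal(flat, annL, window = 100)
  expect_true(got$clipped)
  expect_equal(got$signal, 2.5 * 111 / 201)
  # body mode averages over the annotated interval
  expect_equal(locus_signal(flat, ann, mode = "body")$signal, 2.5)
})

test_that("Welch overrepresentation test handles degenerate input", {
  same <- rep(c(1, 2, 3), 4)
  r <- test_overrepresentation(same, same)
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_equal(r$t, 0, tolerance = 1e-12)
  rc <- test_overrepresentation(c(2, 2, 2), c(2, 2, 2, 2))
  expect_equal(rc$t, 0)
  expect_equal(rc$p, 1)
  # Bonferroni caps at 1 and is monotone in the raw p
  r5 <- test_overrepresentation(c(1, 2, 3), c(1.1, 2.2, 2.9), n_tracks = 50)
  expect_equal(r5$p_adjusted, min(1, r5$p * 50))
  expect_gte(r5$p_adjusted, r5$p)
  # agrees with stats::t.test
  set.seed(3)
  a <- rnorm(30); b <- rnorm(40, 0.5)
  expect_equal(test_overrepresentation(a, b)$p, t.test(a, b)$p.value)
})

test_that("profiles peak at the start, flatten on flat tracks, mirror strand", {
  ann <- data.frame(srna_id = c("P", "M"), chrom = "chrT",
                    start = c(5000, 12000), end = c(5040, 12040),
                    strand = c("+", "-"))
  # synthetic symmetric peak at each 5' start
  mk_peak <- function(center) {
    st <- seq(center - 300, center + 300, by = 5)
    data.frame(chrom = "chrT", start = st, end = st + 5,
               score = exp(-((st + 2.5) - center)^2 / (2 * 60^2)))
  }
  track <- rbind(mk_peak(5000), mk_peak(12039))
  pr <- signal_profile(track, ann, window = 500, bin = 25)
  peak_pos <- pr$position[which.max(pr$mean)]
  expect_lte(abs(peak_pos + 25 / 2), 25)     # maximum at relative position ~0
  # flat track gives a flat profile
  flat <- data.frame(chrom = "chrT", start = 0, end = 20000, score = 1)
  prf <- signal_profile(flat, ann, window = 500, bin = 25)
  expect_true(all(abs(prf$matrix - 1) < 1e-12))
  # reversing a locus's strand reverses its profile row (1 bp locus, so the
  # 5' anchor base is identical on both strands)
  one <- data.frame(srna_id = "O", chrom = "chrT", start = 5000, end = 5001,
                    strand = "+")
  one_flip <- one
  one_flip$strand <- "-"
  a <- signal_profile(track, one, window = 500, bin = 25)$matrix
  b <- signal_profile(track, one_flip, window = 500, bin = 25)$matrix
  expect_equal(unname(a["O", ]), unname(rev(b["O", ])), tolerance = 1e-12)
  expect_error(signal_profile(track, ann, window = 500, bin = 33), "multiple")
})

test_that("bound classification thresholds on background mean + k SD", {
  sig <- data.frame(srna_id = c("a", "b", "c"), signal = c(0.1, 5, 1.1),
                    clipped = FALSE)
  bg <- c(1, 1.2, 0.8, 1.0, 1.0)
  r <- classify_bound(sig, bg, k = 2)
  expect_equal(r$bound, "b")
  expect_setequal(r$unbound, c("a", "c"))
  # all below background mean: nothing bound
  low <- data.frame(srna_id = c("a", "b"), signal = c(0.1, 0.2), clipped = FALSE)
  expect_length(classify_bound(low, bg)$bound, 0)
  # degenerate background: any excess over the mean is bound
  r2 <- classify_bound(sig, rep(1, 5))
  expect_setequal(r2$bound, c("b", "c"))
})

test_that("planted enrichment is recovered through the full TFBS path", {
  study <- study_fixture(42)
  truth <- study$truth
  query <- truth$srna_id[truth$pattern == "both_down"]
  r <- de_fixture(42)
  nonreg <- intersect(truth$srna_id[truth$pattern == "null"],
                      rownames(r$x$counts))
  expr <- setNames(rowMeans(log2(compute_cpm(r$x) + 0.5)),
                   rownames(r$x$counts))
  bg <- matched_background(query, nonreg, expr, size = 455, seed = 4)
  res <- tfbs_analysis(study$chip_tracks, query, study$annotation, bg)
  e <- res$enrichment
  expect_lt(e$p_adjusted[e$tf == "GR"], 0.05)
  expect_gt(e$mean_query, e$mean_background)
  # bound partition recovers the planted enrichment flags
  b <- res$bound$GR
  planted <- study$chip_enriched$GR
  expect_gt(mean(planted %in% b$bound), 0.9)                      # sensitivity
  expect_gt(mean(!setdiff(query, planted) %in% b$bound), 0.9)     # specificity
  # the averaged profile is maximal near the locus start
  pk <- res$profiles$GR$position[which.max(res$profiles$GR$mean)]
  expect_lte(abs(pk + 25), 50)
  # bound-vs-unbound composition shift is strongly class-biased
  ct <- suppressWarnings(chisq_composition(compose(b$bound, study$annotation),
                                           compose(b$unbound, study$annotation)))
  expect_lt(ct$p_value, 0.01)
})
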