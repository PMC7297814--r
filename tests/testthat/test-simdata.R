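test_that("identical config and seed give byte-identical simulations", {
  cfg <- sim_config(n_srna = 300, detectable_fraction = 0.8, seed = 7)
  a <- simulate_srna_study(cfg)
  b <- simulate_srna_study(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$chip_tracks, b$chip_tracks)
  expect_identical(a$truth, b$truth)
  # a different seed changes the data
  c <- simulate_srna_study(sim_config(n_srna = 300, detectable_fraction = 0.8,
                                      seed = 8))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("null simulation matches the stated NB moments", {
  cfg <- sim_config(n_srna = 2000, depth_mean = 676, cv = 0.47,
                    detectable_fraction = 1, de_spec = NULL, seed = 11)
  sim <- simulate_counts(cfg)
  cnt <- sim$counts$counts
  expect_gt(mean(cnt), 600)
  expect_lt(mean(cnt), 750)
  # per-sRNA CV of depth-normalized expression is dominated by the
  # biological CV at this depth
  cpm <- compute_cpm(sim$counts)
  cvs <- apply(cpm, 1, function(v) sd(v) / mean(v))
  expect_gt(median(cvs), 0.35)
  expect_lt(median(cvs), 0.60)
})

test_that("cv = 0 with no planted effects reduces to Poisson counts", {
  cfg <- sim_config(n_srna = 2000, cv = 0, libsize_sdlog = 0,
                    detectable_fraction = 1, de_spec = NULL, seed = 12)
  cnt <- simulate_counts(cfg)$counts$counts
  vmr <- apply(cnt, 1, var) / rowMeans(cnt)
  expect_gt(median(vmr), 0.8)
  expect_lt(median(vmr), 1.25)
})

test_that("spiked group means track the planted fold changes", {
  cfg <- sim_config(n_srna = 2000, detectable_fraction = 1,
                    libsize_sdlog = 0, seed = 13,
                    de_spec = data.frame(pattern = "acute_up", fraction = 0.2,
                                         fc = 2))
  sim <- simulate_counts(cfg)
  cnt <- sim$counts$counts
  spiked <- sim$truth$pattern == "acute_up"
  raa <- sim$groups == "RAA"
  ctl <- sim$groups == "C"
  ratio <- rowMeans(cnt[spiked, raa]) / rowMeans(cnt[spiked, ctl])
  # median ratio of ~400 spiked loci is within a few SE of the planted 2
  expect_gt(median(ratio), 1.8)
  expect_lt(median(ratio), 2.2)
  ratio0 <- rowMeans(cnt[!spiked, raa]) / rowMeans(cnt[!spiked, ctl])
  expect_lt(abs(median(ratio0) - 1), 0.1)
})

test_that("every simulated sRNA carries exactly one pattern label", {
  sim <- simulate_counts(sim_config(n_srna = 500, seed = 2))
  expect_equal(nrow(sim$truth), 500)
  expect_true(all(sim$truth$pattern %in% DE_PATTERNS))
  expect_false(anyNA(sim$truth$pattern))
  # planted pattern counts realize the configured fractions of detectable loci
  n_det <- sum(sim$truth$detectable)
  spec <- sim_config(n_srna = 500, seed = 2)$de_spec
  realized <- table(factor(sim$truth$pattern, levels = spec$pattern))
  expect_true(all(abs(realized - spec$fraction * n_det) <= 1))
})

test_that("annotation realizes class proportions and yields clean intervals", {
  cfg <- sim_config(n_srna = 10, seed = 3,
                    class_proportions = c(piRNA = 0.5, rRNA_5S = 0.5))
  ann <- simulate_annotation(cfg)
  expect_equal(sum(ann$class == "piRNA"), 5)
  expect_equal(sum(ann$class == "rRNA_5S"), 5)

  ann2 <- simulate_annotation(sim_config(n_srna = 1200, seed = 4))
  expect_true(all(ann2$start < ann2$end))
  expect_true(!is.unsorted(ann2$start))
  expect_true(all(ann2$start[-1] >= ann2$end[-nrow(ann2)]))  # no overlap
  expect_true(all(ann2$strand %in% c("+", "-")))

  # realized composition is chi-square compatible with the request
  props <- sim_config(n_srna = 1200)$class_proportions
  obs <- table(factor(ann2$class, levels = names(props)))
  chisq <- sum((obs - props * 1200)^2 / (props * 1200))
  expect_gt(pchisq(chisq, df = length(props) - 1, lower.tail = FALSE), 0.99)
})

test_that("annotation rejects a genome too short for the loci", {
  expect_error(simulate_annotation(sim_config(n_srna = 1000,
                                              genome_length = 3e4)),
               "genome too short")
})

test_that("chip track degenerates correctly at zero peak height and zero noise", {
  cfg <- sim_config(n_srna = 400, seed = 5, detectable_fraction = 1)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)

  # peak_height = 0: pure noise, enriched and unenriched loci indistinguishable
  cfg0 <- cfg
  cfg0$chip_spec$GR$peak_height <- 0
  tr0 <- simulate_chip_track(cfg0, ann, sim$truth, "GR")
  sig <- locus_signal(tr0$track, ann, window = 500)
  enr <- sig$srna_id %in% tr0$enriched_ids
  se <- sqrt(var(sig$signal[enr]) / sum(enr) +
               var(sig$signal[!enr]) / sum(!enr))
  expect_lt(abs(mean(sig$signal[enr]) - mean(sig$signal[!enr])), 2 * se)

  # noise_level = 0 with one enriched locus: zero coverage outside the peak
  cfg1 <- cfg
  cfg1$chip_spec$GR$noise_level <- 0
  cfg1$chip_spec$GR$n_enriched <- 1
  tr1 <- simulate_chip_track(cfg1, ann, sim$truth, "GR")
  row <- ann[ann$srna_id == tr1$enriched_ids, ]
  center <- if (row$strand == "+") row$start else row$end - 1
  half <- 3 * cfg1$chip_spec$GR$window_bp / 4 + 10
  expect_true(all(tr1$track$start >= center - half &
                    tr1$track$end <= center + half))
  expect_true(all(tr1$track$score >= 0))
})

test_that("study writer round-trips through the package readers", {
  study <- simulate_srna_study(sim_config(n_srna = 150, seed = 6,
                                          detectable_fraction = 1))
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  x <- read_counts_tsv(paths[["counts"]])
  expect_equal(x$counts, study$counts$counts)
  g <- read_groups_tsv(paths[["groups"]])
  expect_equal(as.character(g), as.character(study$groups))
  ann <- read_annotation_bed(paths[["annotation"]])
  expect_equal(ann$start, study$annotation$start)
  expect_equal(ann$class, study$annotation$class)
  tr <- read_bedgraph(paths[["track_GR"]])
  expect_equal(nrow(tr), nrow(study$chip_tracks$GR))
  expect_equal(sum(tr$score), sum(study$chip_tracks$GR$score), tolerance = 1e-6)
})
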