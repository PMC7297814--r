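test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.08 / 3, 0.04))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("groups with identical count columns give a null test result", {
  col <- c(5, 9, 0, 14, 3, 7, 21, 2)
  m <- matrix(rep(col, 8), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:8)))
  g <- sample_groups(setNames(rep(c("C", "RAA"), each = 4), colnames(m)))
  # edgeR warns that all residual variances are zero, which is the point here
  de <- suppressWarnings(srna_de(srna_counts(m), g))
  expect_true(all(abs(de$table$F) < 1e-8))
  expect_true(all(de$table$p > 1 - 1e-8))
  expect_true(all(abs(de$table$fc_RAA - 1) < 1e-8))
})

test_that("all-zero rows are flagged and assigned the null result", {
  x <- tiny_counts(n_srna = 30, n_sample = 12, seed = 5)
  x$counts[3, ] <- 0
  g <- sample_groups(setNames(rep(c("C", "RAA", "RAC"), each = 4),
                              colnames(x$counts)))
  de <- srna_de(srna_counts(x$counts), g)
  row <- de$table[de$table$srna_id == "g03", ]
  expect_true(row$degenerate)
  expect_equal(row$p, 1)
  expect_equal(row$fc_RAA, 1)
  expect_equal(row$F, 0)
})

test_that("single-group designs are rejected", {
  x <- tiny_counts(n_srna = 5, n_sample = 4, seed = 1)
  g <- factor(rep("C", 4))
  names(g) <- colnames(x$counts)
  expect_error(srna_de(x, g), "2 groups")
})

test_that("fold-change estimates for spiked sRNAs are close to unbiased", {
  cfg <- sim_config(n_srna = 2000, detectable_fraction = 1, seed = 21,
                    de_spec = data.frame(pattern = "acute_up",
                                         fraction = 0.02, fc = 2))
  sim <- simulate_counts(cfg)
  de <- srna_de(sim$counts, sim$groups)
  spiked <- sim$truth$srna_id[sim$truth$pattern == "acute_up"]
  est <- de$table$fc_RAA[match(spiked, de$table$srna_id)]
  expect_lt(abs(median(est) - 2) / 2, 0.05)
})

test_that("pattern classification implements the membership/direction contract", {
  tab <- data.frame(
    srna_id = c("a", "b", "c", "d", "e", "f"),
    fc_RAA = c(1.5, 0.8, 3.0, 1.0, 0.7, 1.5),
    fc_RAC = c(1.3, 1.3, 1.0, 1.5, 0.6, 0.5),
    q = c(0.01, 0.01, 0.5, 0.02, 0.05, 0.01))
  calls <- classify_patterns(tab, fdr_threshold = 0.1, fc_threshold = 1.2)
  expect_equal(calls$membership,
               c("both", "both", "none", "chronic_only", "both", "both"))
  expect_equal(calls$direction,
               c("up", "mixed_down_up", NA, "up", "down", "mixed_up_down"))
  # mixed directions arise only for 'both' membership
  expect_true(all(calls$membership[grepl("mixed", calls$direction)] == "both"))
  # membership implies significance
  expect_true(all(tab$q[calls$membership != "none"] < 0.1))
})

test_that("regulated calls partition into acute-only / chronic-only / both", {
  r <- de_fixture(42)
  calls <- classify_patterns(r$de)
  part <- table(calls$membership)
  n_reg <- sum(calls$membership != "none")
  expect_equal(sum(part[c("acute_only", "chronic_only", "both")]), n_reg)
  expect_true(all(!is.na(calls$direction[calls$membership != "none"])))
  expect_true(all(is.na(calls$direction[calls$membership == "none"])))
})

test_that("power is monotone in the planted fold change", {
  det <- vapply(c(1.3, 1.7, 2.5), function(fc) {
    cfg <- sim_config(n_srna = 800, detectable_fraction = 1, seed = 31,
                      de_spec = data.frame(pattern = "acute_up",
                                           fraction = 0.1, fc = fc))
    sim <- simulate_counts(cfg)
    de <- srna_de(sim$counts, sim$groups)
    spiked <- sim$truth$pattern == "acute_up"
    mean(de$table$q[match(sim$truth$srna_id[spiked], de$table$srna_id)] < 0.1)
  }, numeric(1))
  expect_true(!is.unsorted(det))
  expect_gt(det[3], 0.9)
})
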