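#' sRNA classes used throughout the package
#'
#' DASHR-style small-RNA class labels: PIWI-interacting RNAs, ribosomal RNA
#' fragments (5S and small/large subunit), primary microRNAs and their 5p/3p
#' arms, small cytoplasmic RNA, transfer RNA and its 3'/5' fragments,
#' small nucleolar and small nuclear RNA.
#' @export
SRNA_CLASSES <- c("piRNA", "rRNA_5S", "rRNA_SSU", "rRNA_LSU", "miRNA_primary",
                  "mir_5p", "mir_3p", "scRNA", "tRNA", "tRF3", "tRF5",
                  "snoRNA", "snRNA", "other")

#' Regulation patterns over the two timepoint contrasts
#'
#' Each differentially expressed locus follows one pattern: changed only in
#' the acute phase, only in the chronic phase, in both phases with a common
#' direction, or in both phases with opposite directions (`mixed_du` = down
#' in acute / up in chronic, `mixed_ud` the reverse). `null` marks
#' non-regulated loci.
#' @export
DE_PATTERNS <- c("acute_up", "acute_down", "chronic_up", "chronic_down",
                 "both_up", "both_down", "mixed_du", "mixed_ud", "null")

default_class_proportions <- function() {
  c(piRNA = 0.22, rRNA_5S = 0.05, rRNA_SSU = 0.05, rRNA_LSU = 0.05,
    miRNA_primary = 0.14, mir_5p = 0.05, mir_3p = 0.04, scRNA = 0.08,
    tRNA = 0.09, tRF3 = 0.04, tRF5 = 0.04, snoRNA = 0.10, snRNA = 0.05)
}

#' Default planted regulation spec
#'
#' Regulated-set sizes mirroring the three-arm blood study the generator
#' emulates: of 1766 detectable loci, 105 acute-only (45 up / 60 down), 77
#' chronic-only (42 up / 35 down) and 334 changed at both timepoints (76 up,
#' 210 down, 41 down-then-up, 7 up-then-down) — 516 regulated in total.
#'
#' @param fc Planted fold change applied to every pattern (default 2).
#' @return Data frame with columns `pattern`, `fraction`, `fc`.
#' @export
default_de_spec <- function(fc = 2) {
  n_det <- 1766
  counts <- c(acute_up = 45, acute_down = 60, chronic_up = 42,
              chronic_down = 35, both_up = 76, both_down = 210,
              mixed_du = 41, mixed_ud = 7)
  data.frame(pattern = names(counts), fraction = as.numeric(counts) / n_det,
             fc = fc, stringsAsFactors = FALSE)
}

# The planted bound set is biased toward the classes reported as
# GR-bound in this design (tRNA and the rRNA subtypes), so the bound-vs-
# unbound composition contrast has a magnitude comparable to the real one.
default_chip_spec <- function() {
  list(GR = list(peak_height = 30, window_bp = 200, noise_level = 1,
                 n_enriched = 61, target_pattern = "both_down",
                 bias_class = c("tRNA", "rRNA_5S", "rRNA_SSU", "rRNA_LSU"),
                 bias_weight = 8))
}

# Class-specific conservation levels: tRNA-derived fragments and scRNA least
# conserved; tRNA, piRNA and mature 5p miRNA arms most conserved.
default_conservation_spec <- function() {
  c(piRNA = 0.70, rRNA_5S = 0.50, rRNA_SSU = 0.50, rRNA_LSU = 0.50,
    miRNA_primary = 0.60, mir_5p = 0.75, mir_3p = 0.65, scRNA = 0.20,
    tRNA = 0.85, tRF3 = 0.10, tRF5 = 0.10, snoRNA = 0.55, snRNA = 0.50,
    other = 0.30)
}

#' Configuration for the synthetic sRNA study generator
#'
#' Defaults emulate the blood small-RNA study the pipeline was built around:
#' three groups of 19/20/20 subjects (acute, chronic, control), 4000
#' annotated loci of which 1766 are expressed at detectable levels, mean
#' per-locus depth 676 counts, biological coefficient of variation 0.47, and
#' a planted regulated set with all eight timepoint/direction patterns.
#'
#' @param n_per_group Named integer vector of group sizes (RAA, RAC, C).
#' @param n_srna Total number of annotated loci.
#' @param depth_mean Mean raw count per detectable locus.
#' @param cv Biological coefficient of variation of the negative-binomial
#'   counts (variance `m + cv^2 m^2`).
#' @param detectable_fraction Fraction of loci drawn from the expressed
#'   (detectable) abundance distribution; the rest are near-silent.
#' @param low_mu Mean count of the near-silent loci.
#' @param baseline_sdlog Log-sd of the log-normal per-locus baseline means.
#' @param libsize_sdlog Log-sd of per-sample sequencing-depth factors.
#' @param class_proportions Named vector of class fractions (sums to 1).
#' @param de_spec Data frame (`pattern`, `fraction`, `fc`): fraction of
#'   detectable loci planted with each regulation pattern and its fold
#'   change. Fractions must sum to at most 1; the remainder is null. `NULL`
#'   plants no regulation at all (a pure null study).
#' @param chip_spec Named list (one entry per TF) of
#'   `peak_height`, `window_bp`, `noise_level`, `n_enriched`,
#'   `target_pattern`, `bias_class`, `bias_weight`.
#' @param conservation_spec Named vector of per-class mean conservation in
#'   \code{[0, 1]}.
#' @param genome_length Length (bp) of the single synthetic chromosome;
#'   defaults to 5000 bp per locus (minimum 2 Mb) so that windowed ChIP
#'   signals of neighboring loci do not share coverage.
#' @param locus_length Range of locus lengths in bp.
#' @param seed Integer seed; fixes all generated output byte-for-byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(RAA = 19, RAC = 20, C = 20),
                       n_srna = 4000,
                       depth_mean = 676,
                       cv = 0.47,
                       detectable_fraction = 1766 / 4000,
                       low_mu = 0.5,
                       baseline_sdlog = 1,
                       libsize_sdlog = 0.15,
                       class_proportions = default_class_proportions(),
                       de_spec = default_de_spec(),
                       chip_spec = default_chip_spec(),
                       conservation_spec = default_conservation_spec(),
                       genome_length = NULL,
                       locus_length = c(20, 60),
                       seed = 1) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (cv < 0) stop("cv must be nonnegative")
  if (any(n_per_group < 2)) stop("every group needs at least 2 samples")
  if (is.null(names(n_per_group))) stop("n_per_group must be named")
  if (is.null(de_spec))
    de_spec <- data.frame(pattern = character(0), fraction = numeric(0),
                          fc = numeric(0))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class proportions must be >= 0")
  if (!all(c("pattern", "fraction", "fc") %in% names(de_spec)))
    stop("de_spec needs columns pattern, fraction, fc")
  if (!all(de_spec$pattern %in% setdiff(DE_PATTERNS, "null")))
    stop("unknown DE pattern in de_spec")
  if (sum(de_spec$fraction) > 1 + 1e-9) stop("de_spec fractions must sum to <= 1")
  if (any(de_spec$fc <= 1)) stop("de_spec fold changes must exceed 1")
  if (detectable_fraction <= 0 || detectable_fraction > 1)
    stop("detectable_fraction must be in (0, 1]")
  for (tf in names(chip_spec)) {
    sp <- chip_spec[[tf]]
    if (sp$peak_height < 0) stop("negative peak height for ", tf)
    if (sp$noise_level < 0) stop("negative noise level for ", tf)
  }
  if (any(conservation_spec < 0 | conservation_spec > 1))
    stop("conservation means must lie in [0, 1]")
  if (is.null(genome_length)) genome_length <- max(2e6, n_srna * 5000)
  structure(list(n_per_group = n_per_group, n_srna = as.integer(n_srna),
                 depth_mean = depth_mean, cv = cv,
                 detectable_fraction = detectable_fraction, low_mu = low_mu,
                 baseline_sdlog = baseline_sdlog,
                 libsize_sdlog = libsize_sdlog,
                 class_proportions = class_proportions, de_spec = de_spec,
                 chip_spec = chip_spec,
                 conservation_spec = conservation_spec,
                 genome_length = genome_length, locus_length = locus_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the locus annotation
#'
#' Places non-overlapping stranded intervals on one synthetic chromosome and
#' assigns class labels realizing `class_proportions` by largest-remainder
#' rounding (realized counts within one of the exact quotas).
#'
#' @param config A [sim_config].
#' @return Annotation data frame (`srna_id`, `class`, `chrom`, `start`,
#'   `end`, `strand`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "annotation"))
  n <- config$n_srna
  slot <- floor(config$genome_length / n)
  max_len <- max(config$locus_length)
  if (slot <= max_len)
    stop("genome too short to place ", n, " non-overlapping loci of up to ",
         max_len, " bp")
  n_class <- largest_remainder(config$class_proportions, n)
  cls <- sample(rep(names(config$class_proportions), n_class))
  len <- sample(seq(config$locus_length[1], config$locus_length[2]), n,
                replace = TRUE)
  offset <- vapply(slot - len, function(m) sample.int(m, 1L) - 1L, integer(1))
  start <- (seq_len(n) - 1L) * slot + offset
  data.frame(srna_id = sprintf("sRNA%05d", seq_len(n)), class = cls,
             chrom = "chrS", start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Group-mean multipliers implied by a regulation pattern at fold change fc.
pattern_multipliers <- function(pattern, fc) {
  m <- c(RAA = 1, RAC = 1)
  switch(pattern,
         acute_up     = m["RAA"] <- fc,
         acute_down   = m["RAA"] <- 1 / fc,
         chronic_up   = m["RAC"] <- fc,
         chronic_down = m["RAC"] <- 1 / fc,
         both_up      = m[c("RAA", "RAC")] <- fc,
         both_down    = m[c("RAA", "RAC")] <- 1 / fc,
         mixed_du     = m[c("RAA", "RAC")] <- c(1 / fc, fc),
         mixed_ud     = m[c("RAA", "RAC")] <- c(fc, 1 / fc),
         null         = NULL,
         stop("unknown pattern: ", pattern))
  m
}

#' Simulate the count matrix and its ground truth
#'
#' Per-locus baselines are log-normal (so the CPM filter has a low tail to
#' remove), per-sample depth factors are log-normal, and counts are
#' negative-binomial with variance `m + cv^2 m^2` (Poisson when `cv = 0`).
#' Fold changes act multiplicatively on the affected group means according to
#' the locus's planted pattern.
#'
#' @param config A [sim_config].
#' @param annotation Optional annotation from [simulate_annotation]; generated
#'   from `config` when missing.
#' @return List with `counts` (an [srna_counts]), `groups` (named factor,
#'   control first) and `truth` (per-locus pattern, true per-contrast fold
#'   changes, class, interval, detectability flag).
#' @export
simulate_counts <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  set.seed(child_seed(config$seed, "counts"))
  n <- config$n_srna
  npg <- config$n_per_group
  sample_id <- unlist(lapply(names(npg),
                             function(g) sprintf("%s_%02d", g, seq_len(npg[[g]]))))
  group <- sample_groups(rep(names(npg), npg), sample_ids = sample_id)

  n_det <- round(config$detectable_fraction * n)
  det <- rep(FALSE, n)
  det[sample.int(n, n_det)] <- TRUE
  mu <- numeric(n)
  mu[det] <- stats::rlnorm(n_det,
                           meanlog = log(config$depth_mean) -
                             config$baseline_sdlog^2 / 2,
                           sdlog = config$baseline_sdlog)
  mu[!det] <- stats::rlnorm(n - n_det, meanlog = log(config$low_mu), sdlog = 0.5)

  # plant patterns among detectable loci (largest-remainder realized counts)
  pat <- rep("null", n)
  spec <- config$de_spec
  n_pat <- largest_remainder(c(spec$fraction, 1 - sum(spec$fraction)), n_det)
  det_idx <- sample(which(det))
  labels <- rep(c(spec$pattern, "null"), n_pat)
  pat[det_idx] <- labels

  fc_acute <- fc_chronic <- rep(1, n)
  for (k in seq_len(nrow(spec))) {
    sel <- pat == spec$pattern[k]
    mm <- pattern_multipliers(spec$pattern[k], spec$fc[k])
    fc_acute[sel] <- mm["RAA"]
    fc_chronic[sel] <- mm["RAC"]
  }

  s_j <- stats::rlnorm(length(group), meanlog = -config$libsize_sdlog^2 / 2,
                       sdlog = config$libsize_sdlog)
  mult <- cbind(C = rep(1, n), RAA = fc_acute, RAC = fc_chronic)
  m <- (mu * mult[, as.character(group)]) * rep(s_j, each = n)
  cnt <- if (config$cv == 0) {
    stats::rpois(length(m), lambda = m)
  } else {
    stats::rnbinom(length(m), mu = m, size = 1 / config$cv^2)
  }
  cnt <- matrix(cnt, nrow = n, dimnames = list(annotation$srna_id, sample_id))

  truth <- data.frame(annotation,
                      detectable = det, pattern = pat,
                      fc_acute = fc_acute, fc_chronic = fc_chronic,
                      chip_enriched = FALSE, cons_mean = NA_real_,
                      stringsAsFactors = FALSE)
  list(counts = srna_counts(cnt), groups = group, truth = truth)
}

#' Simulate a ChIP-seq coverage track with planted peaks
#'
#' Background coverage is exponential noise on fixed-width bins; each
#' enriched locus receives a Gaussian-shaped peak of height `peak_height`
#' (sd = `window_bp / 4`) centered on its strand-aware 5' start, mirroring
#' binding signal concentrated near the start of the sRNA sequence. Enriched
#' loci are drawn from the loci with the configured true pattern, with
#' sampling weight `bias_weight` for `bias_class` so the bound set has a
#' class-biased composition.
#'
#' @param config A [sim_config].
#' @param annotation Annotation data frame.
#' @param truth Truth table from [simulate_counts].
#' @param tf Name of the `chip_spec` entry to realize.
#' @param noise_bin Width (bp) of background noise bins.
#' @return List with `track` (bedGraph-style data frame `chrom`, `start`,
#'   `end`, `score`) and `enriched_ids`.
#' @export
simulate_chip_track <- function(config, annotation, truth, tf,
                                noise_bin = 200) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$chip_spec[[tf]]
  if (is.null(sp)) stop("no chip_spec entry for TF: ", tf)
  set.seed((child_seed(config$seed, "chip") +
              match(tf, names(config$chip_spec))) %% .Machine$integer.max)

  cand <- truth$srna_id[truth$pattern == sp$target_pattern]
  n_enr <- min(sp$n_enriched, length(cand))
  w <- ifelse(truth$class[match(cand, truth$srna_id)] %in% sp$bias_class,
              sp$bias_weight, 1)
  enriched <- if (n_enr > 0) sample(cand, n_enr, prob = w) else character(0)

  glen <- config$genome_length
  res <- 5L  # bp resolution under peaks
  nb <- ceiling(glen / noise_bin)
  noise <- if (sp$noise_level > 0) stats::rexp(nb, rate = 1 / sp$noise_level)
           else numeric(nb)

  # peak contribution on the fine grid around each enriched locus
  sd_pk <- sp$window_bp / 4
  peak_cells <- NULL
  if (sp$peak_height > 0 && length(enriched) > 0) {
    rows <- match(enriched, annotation$srna_id)
    center <- ifelse(annotation$strand[rows] == "+", annotation$start[rows],
                     annotation$end[rows] - 1L)
    half <- ceiling(3 * sd_pk)
    cells <- lapply(center, function(cc) {
      # snap to the global fine grid so cells merge exactly with noise bins
      st <- seq(max(0L, (cc - half) %/% res * res),
                min(glen - res, (cc + half) %/% res * res), by = res)
      val <- sp$peak_height * exp(-((st + res / 2) - cc)^2 / (2 * sd_pk^2))
      cbind(st, val)
    })
    peak_cells <- do.call(rbind, cells)
    peak_cells <- cbind(as.numeric(rownames(rowsum(peak_cells[, 2, drop = FALSE],
                                                   peak_cells[, 1]))),
                        rowsum(peak_cells[, 2, drop = FALSE], peak_cells[, 1]))
  }

  if (is.null(peak_cells)) {
    if (sp$noise_level == 0)
      return(list(track = data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), score = numeric(0)),
                  enriched_ids = enriched))
    track <- data.frame(chrom = "chrS",
                        start = (seq_len(nb) - 1L) * noise_bin,
                        end = pmin(seq_len(nb) * noise_bin, glen),
                        score = noise, stringsAsFactors = FALSE)
    return(list(track = track, enriched_ids = enriched))
  }

  # split noise bins under peaks into fine cells, add the peak signal
  pk_bin <- unique(peak_cells[, 1] %/% noise_bin + 1)
  plain_df <- NULL
  if (sp$noise_level > 0) {
    plain <- setdiff(seq_len(nb), pk_bin)
    plain_df <- data.frame(chrom = "chrS", start = (plain - 1L) * noise_bin,
                           end = pmin(plain * noise_bin, glen),
                           score = noise[plain], stringsAsFactors = FALSE)
  }
  fine_start <- unlist(lapply(pk_bin, function(b)
    seq((b - 1L) * noise_bin, min(b * noise_bin, glen) - res, by = res)))
  fine_score <- noise[fine_start %/% noise_bin + 1]
  pk_add <- rep(0, length(fine_start))
  idx <- match(peak_cells[, 1], fine_start)
  ok <- !is.na(idx)
  pk_add[idx[ok]] <- pk_add[idx[ok]] + peak_cells[ok, 2]
  fine <- data.frame(chrom = "chrS", start = as.integer(fine_start),
                     end = as.integer(fine_start + res),
                     score = fine_score + pk_add, stringsAsFactors = FALSE)
  fine <- fine[fine$score > 0, ]
  track <- rbind(plain_df, fine)
  track <- track[order(track$start), ]
  rownames(track) <- NULL
  list(track = track, enriched_ids = enriched)
}

#' Simulate a conservation track
#'
#' Each locus is covered at a constant score drawn around its class mean
#' (normal, sd 0.05, clamped to \code{[0, 1]}); intergenic bases are left
#' uncovered, which downstream averaging scores as 0.
#'
#' @param config A [sim_config].
#' @param annotation Annotation data frame.
#' @return List with `track` (bedGraph data frame) and `cons_mean` (named
#'   per-locus true mean score).
#' @export
simulate_conservation_track <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "conservation"))
  spec <- config$conservation_spec
  mu <- spec[annotation$class]
  mu[is.na(mu)] <- 0.3
  val <- pmin(1, pmax(0, stats::rnorm(nrow(annotation), mean = mu, sd = 0.05)))
  names(val) <- annotation$srna_id
  track <- data.frame(chrom = annotation$chrom, start = annotation$start,
                      end = annotation$end, score = val,
                      stringsAsFactors = FALSE)
  rownames(track) <- NULL
  list(track = track, cons_mean = val)
}

#' Simulate a complete synthetic study
#'
#' Runs all generators off one seed and assembles counts, grouping,
#' annotation, per-TF ChIP tracks, a conservation track and the complete
#' ground-truth table.
#'
#' @param config A [sim_config].
#' @return List of class `srna_study`: `config`, `counts`, `groups`,
#'   `annotation`, `truth`, `chip_tracks` (named list), `chip_enriched`
#'   (named list of id vectors), `conservation_track`.
#' @export
simulate_srna_study <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  cg <- simulate_counts(config, ann)
  truth <- cg$truth
  tracks <- list(); enriched <- list()
  for (tf in names(config$chip_spec)) {
    tr <- simulate_chip_track(config, ann, truth, tf)
    tracks[[tf]] <- tr$track
    enriched[[tf]] <- tr$enriched_ids
    if (config$chip_spec[[tf]]$peak_height > 0)
      truth$chip_enriched <- truth$chip_enriched | truth$srna_id %in% tr$enriched_ids
  }
  cons <- simulate_conservation_track(config, ann)
  truth$cons_mean <- unname(cons$cons_mean[truth$srna_id])
  structure(list(config = config, counts = cg$counts, groups = cg$groups,
                 annotation = ann, truth = truth, chip_tracks = tracks,
                 chip_enriched = enriched,
                 conservation_track = cons$track),
            class = "srna_study")
}

#' Write a synthetic study to disk
#'
#' Counts TSV, groups TSV, annotation BED6+1, truth TSV, one bedGraph per
#' ChIP track, conservation bedGraph, and a YAML echo of the configuration.
#'
#' @param study An `srna_study` from [simulate_srna_study].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "srna_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(counts = file.path(dir, "counts.tsv"),
         groups = file.path(dir, "groups.tsv"),
         annotation = file.path(dir, "annotation.bed"),
         truth = file.path(dir, "truth.tsv"),
         conservation = file.path(dir, "conservation.bedGraph"),
         config = file.path(dir, "config.yaml"))
  write_counts_tsv(study$counts, p["counts"])
  write_groups_tsv(study$groups, p["groups"])
  write_annotation_bed(study$annotation, p["annotation"])
  write_tsv(study$truth, p["truth"])
  write_bedgraph(study$conservation_track, p["conservation"])
  for (tf in names(study$chip_tracks)) {
    tp <- file.path(dir, paste0(tf, ".bedGraph"))
    write_bedgraph(study$chip_tracks[[tf]], tp)
    p[paste0("track_", tf)] <- tp
  }
  cfg <- study$config
  cfg$de_spec <- as.list(cfg$de_spec)
  yaml::write_yaml(lapply(unclass(cfg), function(z) if (is.numeric(z) && !is.null(names(z))) as.list(z) else z),
                   p["config"])
  invisible(p)
}
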