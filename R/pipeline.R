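#' Pipeline run configuration
#'
#' Bundles the input locations (or a simulation config) with every analysis
#' threshold, one run seed and the output directory. Defaults are the
#' motivating study's settings: CPM > 2 in at least 10 samples, omnibus FDR
#' 0.1, fold-change cutoff 1.2, power level alpha = 0.1, background sizes 233
#' (composition) and 455 (TFBS), TFBS window 1000 bp with 50 bp bins.
#'
#' @param sim Optional [sim_config]; when given, inputs are generated and
#'   written under `out_dir/simdata` and read back from disk, so a run
#'   exercises the same file formats as a run on real data.
#' @param counts,groups,annotation Paths to the counts TSV, groups TSV and
#'   BED6+1 annotation (ignored when `sim` is given).
#' @param conservation_track Path to a conservation bedGraph, or `NULL`.
#' @param chip_tracks Named character vector of bedGraph paths (names = TF
#'   labels), or a directory containing `<TF>.bedGraph` files, or `NULL`.
#' @param cpm_threshold,min_samples Detectability filter settings.
#' @param fdr,fc Significance and fold-change thresholds for regulation calls.
#' @param alpha Two-sided level of the closed-form power calculation.
#' @param power_fc Fold changes tabulated by the power stage.
#' @param spike_fc Fold change for one shuffle-and-spike run, or `NULL` to
#'   skip the spike simulation.
#' @param spike_fraction Fraction of sRNAs spiked.
#' @param background_size Nonregulated set size for the composition stage.
#' @param tfbs_background_size Expression-matched background size for TFBS.
#' @param window,bin TFBS window half-width and profile bin (bp).
#' @param signal_mode `"window"` or `"body"` ChIP signal aggregation.
#' @param seed Run seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, counts = NULL, groups = NULL,
                       annotation = NULL, conservation_track = NULL,
                       chip_tracks = NULL,
                       cpm_threshold = 2, min_samples = 10,
                       fdr = 0.1, fc = 1.2, alpha = 0.1,
                       power_fc = c(1.2, 1.5, 1.7, 2),
                       spike_fc = 2, spike_fraction = 0.1,
                       background_size = 233, tfbs_background_size = 455,
                       window = 1000, bin = 50,
                       signal_mode = c("window", "body"),
                       seed = 1, out_dir = "srnaflow_out") {
  signal_mode <- match.arg(signal_mode)
  stopifnot(cpm_threshold > 0, min_samples > 0, fdr > 0, fc > 1,
            alpha > 0, alpha < 1, window >= 0, bin > 0)
  if (is.null(sim) && (is.null(counts) || is.null(groups) || is.null(annotation)))
    stop("either a simulation config or counts/groups/annotation paths are required")
  structure(as.list(environment()), class = "run_config")
}

resolve_chip_tracks <- function(chip_tracks) {
  if (is.null(chip_tracks)) return(NULL)
  if (length(chip_tracks) == 1 && dir.exists(chip_tracks)) {
    files <- list.files(chip_tracks, pattern = "\\.bedGraph$",
                        full.names = TRUE)
    names(files) <- sub("\\.bedGraph$", "", basename(files))
    chip_tracks <- files
  }
  lapply(chip_tracks, read_bedgraph)
}

#' Run the complete pipeline
#'
#' Executes, in order: (optional) simulation, quantification and
#' detectability filtering, NB quasi-likelihood differential expression with
#' pattern classification, power estimation (closed form, plus one optional
#' shuffle-and-spike run), class composition against a random nonregulated
#' background, conservation averaging, and TFBS overrepresentation against an
#' expression-matched background. Every table is written as TSV under
#' `config$out_dir` together with a JSON run summary; identical config and
#' seed reproduce identical outputs. Any stage failure aborts with the stage
#' name.
#'
#' @param config A [run_config].
#' @param verbose Print stage progress.
#' @return The run summary, invisibly (also written to `summary.json`).
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[srnaflow] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- inputs ----------------------------------------------------------------
  paths <- stage("simulate", {
    if (!is.null(config$sim)) {
      say("simulating study data")
      study <- simulate_srna_study(config$sim)
      write_study(study, file.path(config$out_dir, "simdata"))
    } else {
      c(counts = config$counts, groups = config$groups,
        annotation = config$annotation)
    }
  })
  x <- stage("inputs", read_counts_tsv(paths[["counts"]]))
  groups <- stage("inputs", read_groups_tsv(paths[["groups"]]))
  ann <- stage("inputs", read_annotation_bed(paths[["annotation"]]))
  cons_path <- if (!is.null(config$sim))
    file.path(config$out_dir, "simdata", "conservation.bedGraph")
  else config$conservation_track
  tracks <- stage("tracks", {
    if (!is.null(config$sim)) {
      tfs <- names(config$sim$chip_spec)
      files <- file.path(config$out_dir, "simdata", paste0(tfs, ".bedGraph"))
      names(files) <- tfs
      resolve_chip_tracks(files)
    } else resolve_chip_tracks(config$chip_tracks)
  })

  # -- quantify --------------------------------------------------------------
  say("quantify: CPM filter")
  det <- stage("quantify",
               filter_detectable(x, cpm_threshold = config$cpm_threshold,
                                 min_samples = config$min_samples))
  cpm <- compute_cpm(det)
  mean_log_cpm <- setNames(rowMeans(log2(cpm + 0.5)), rownames(det$counts))

  # -- differential expression ----------------------------------------------
  say("differential expression: NB quasi-likelihood omnibus test")
  de <- stage("diffexp", srna_de(det, groups))
  calls <- classify_patterns(de, fdr_threshold = config$fdr,
                             fc_threshold = config$fc)
  de_tab <- merge(de$table, calls, by = "srna_id", sort = FALSE)
  de_tab$class <- ann$class[match(de_tab$srna_id, ann$srna_id)]
  write_tsv(de_tab, file.path(config$out_dir, "de_table.tsv"))

  # -- power -----------------------------------------------------------------
  say("power estimation")
  n_min <- min(table(groups))
  hart <- stage("power", data.frame(
    fc = config$power_fc,
    power = hart_power(config$power_fc, n = n_min,
                       depth = mean(det$counts[rowSums(det$counts) > 0, ,
                                               drop = FALSE]),
                       cv = config$sim$cv %||% 0.47, alpha = config$alpha)))
  write_tsv(hart, file.path(config$out_dir, "power_hart.tsv"))
  spike <- NULL
  if (!is.null(config$spike_fc)) {
    sp <- stage("power",
                shuffle_spike_power(det, groups, fc = config$spike_fc,
                                    spike_fraction = config$spike_fraction,
                                    fdr_threshold = config$fdr,
                                    seed = config$seed))
    spike <- data.frame(fc = config$spike_fc, n_spiked = sp$n_spiked,
                        n_detected = sp$n_detected,
                        detection_fraction = sp$detection_fraction,
                        empirical_fdr = sp$empirical_fdr, seed = sp$seed)
    write_tsv(spike, file.path(config$out_dir, "power_spike.tsv"))
  }

  # -- class composition -----------------------------------------------------
  say("class composition")
  compres <- stage("classcomp",
                   composition_analysis(calls, ann,
                                        background_size = config$background_size,
                                        seed = config$seed))
  write_tsv(compres$composition, file.path(config$out_dir, "composition.tsv"))
  if (!is.null(compres$tests))
    write_tsv(compres$tests, file.path(config$out_dir, "composition_tests.tsv"))

  # -- conservation ----------------------------------------------------------
  cons_summary <- NULL
  if (!is.null(cons_path) && file.exists(cons_path)) {
    say("conservation averaging")
    cons <- stage("conservation", {
      tr <- read_bedgraph(cons_path)
      sc <- mean_conservation(tr, ann[match(rownames(det$counts),
                                            ann$srna_id), ])
      list(scores = sc,
           summary = summarize_conservation(sc, ann, calls))
    })
    write_tsv(data.frame(srna_id = names(cons$scores),
                         mean_conservation = unname(cons$scores)),
              file.path(config$out_dir, "conservation_per_srna.tsv"))
    write_tsv(cons$summary, file.path(config$out_dir, "conservation_summary.tsv"))
    cons_summary <- cons$summary
  }

  # -- TFBS ------------------------------------------------------------------
  tfbs <- NULL
  if (!is.null(tracks) && length(tracks) > 0) {
    say("TFBS overrepresentation over ", length(tracks), " track(s)")
    tfbs <- stage("tfbs", {
      regulated <- calls$srna_id[calls$membership != "none"]
      query <- calls$srna_id[calls$membership == "both" &
                               calls$direction == "down"]
      if (length(query) < 2) query <- regulated
      nonreg <- setdiff(calls$srna_id, regulated)
      bg <- matched_background(query, nonreg, mean_log_cpm,
                               size = min(config$tfbs_background_size,
                                          length(nonreg)),
                               seed = config$seed)
      res <- tfbs_analysis(tracks, query, ann, bg, window = config$window,
                           bin = config$bin, mode = config$signal_mode)
      res$query_ids <- query
      res$background_ids <- bg
      res
    })
    write_tsv(tfbs$enrichment, file.path(config$out_dir, "enrichment.tsv"))
    for (tf in names(tfbs$profiles)) {
      pr <- tfbs$profiles[[tf]]
      write_tsv(data.frame(position = pr$position, mean_signal = pr$mean),
                file.path(config$out_dir, paste0("profile_", tf, ".tsv")))
    }
    bc <- lapply(names(tfbs$bound), function(tf) {
      b <- tfbs$bound[[tf]]
      if (length(b$bound) == 0 || length(b$unbound) == 0) return(NULL)
      comp_b <- compose(b$bound, ann)
      comp_u <- compose(b$unbound, ann)
      ct <- tryCatch(suppressWarnings(chisq_composition(comp_b, comp_u)),
                     error = function(e) NULL)
      data.frame(tf = tf, n_bound = length(b$bound),
                 n_unbound = length(b$unbound),
                 chisq = if (is.null(ct)) NA else ct$statistic,
                 p_value = if (is.null(ct)) NA else ct$p_value,
                 stringsAsFactors = FALSE)
    })
    bc <- do.call(rbind, bc)
    if (!is.null(bc))
      write_tsv(bc, file.path(config$out_dir, "bound_composition.tsv"))
  }

  # -- summary ---------------------------------------------------------------
  part <- table(factor(calls$membership,
                       levels = c("acute_only", "chronic_only", "both", "none")))
  summary <- list(
    seed = config$seed,
    thresholds = list(cpm_threshold = config$cpm_threshold,
                      min_samples = config$min_samples, fdr = config$fdr,
                      fc = config$fc, alpha = config$alpha),
    n_input = nrow(x$counts),
    n_detectable = nrow(det$counts),
    n_significant = sum(de$table$q < config$fdr),
    n_regulated = sum(calls$membership != "none"),
    partition = as.list(part[c("acute_only", "chronic_only", "both")]),
    power_hart = stats::setNames(as.list(hart$power), paste0("fc_", hart$fc)),
    spike = spike,
    tfbs_hits = if (!is.null(tfbs))
      as.list(stats::setNames(tfbs$enrichment$p_adjusted,
                              tfbs$enrichment$tf)) else NULL,
    versions = list(srnaflow = as.character(utils::packageVersion("srnaflow")),
                    edgeR = as.character(utils::packageVersion("edgeR"))))
  stopifnot(sum(part[c("acute_only", "chronic_only", "both")]) ==
              summary$n_regulated)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", config$out_dir)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
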