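#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default, as a nested list that can
#' be serialised to / read from YAML or JSON.  In `simulate` mode a
#' synthetic cohort is generated from the `simulate` block; in `ingest` mode
#' `sample_sheet` must point at methratio files.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    sample_sheet = NULL,
    gene_model = NULL,            # GTF/BED12 path in ingest mode
    simulate = list(
      n_chromosomes = 2L, cpgs_per_chromosome = 600L,
      spacing = list(type = "clustered", cluster_size = 10L,
                     within = 50, between = 5000),
      n_case = 10L, n_control = 10L,
      coverage = list(mean = 30, size = 8),
      chemistry = list(eps_fail = 0.005, eps_over = 0.005, eta_ox = 0.95),
      baseline = list(m_weights = c(0.5, 0.5), m_shape1 = c(1, 8),
                      m_shape2 = c(10, 2), h_shape1 = 1.2, h_shape2 = 15),
      sample_sd = list(m = 0.10, h = 0.05),
      effects = list(list(mark = "5mC", delta = 0.3, coupling = -0.15, n = 4L),
                     list(mark = "5hmC", delta = 0.15, coupling = 0, n = 4L))
    ),
    estimate = list(min_cov = 5L, mode = "raw"),
    segmentation = list(max_gap = 300L, min_cpg = 5L,
                        min_group_presence = 0.8, split_gain = 0.05),
    thresholds = list(diff_5mc = 0.2, diff_5hmc = 0.1, diff_bs = 0.2,
                      q_max = 0.05),
    annotation = list(promoter = c(1000L, 100L), tts = c(100L, 1000L)),
    screen = list(auc_cutoff = 0.8, min_frac_samples = 0.8),
    median_split_ties = "low",
    contrasts = list(list(name = "case_vs_control", column = "group",
                          case = "case", control = "control")),
    marks = c("5mC", "5hmC", "BS")
  )
}

#' Read a pipeline configuration
#'
#' YAML (or JSON) file merged over [default_config()]: any key absent from
#' the file keeps its default.
#'
#' @param path Config file path, or a list to merge directly.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      if (is.list(over[[k]]) && is.list(base[[k]]) &&
          !is.null(names(over[[k]])) && !is.null(names(base[[k]]))) {
        base[[k]] <- merge_cfg(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_cfg(default_config(), user)
}

.log_line <- function(state, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  cat(line, "\n", sep = "")
  if (!is.null(state$log)) cat(line, "\n", sep = "", file = state$log,
                               append = TRUE)
  invisible(line)
}

.cfg_truth_spec <- function(cfg) {
  sm <- cfg$simulate
  ref <- simulate_reference(sm$n_chromosomes, sm$cpgs_per_chromosome,
                            spacing_spec(sm$spacing$type,
                                         sm$spacing$cluster_size,
                                         sm$spacing$within,
                                         sm$spacing$between),
                            seed = cfg$seed)
  groups <- stats::setNames(c(rep("case", sm$n_case),
                              rep("control", sm$n_control)),
                            c(sprintf("case%02d", seq_len(sm$n_case)),
                              sprintf("ctrl%02d", seq_len(sm$n_control))))
  eff <- NULL
  if (length(sm$effects) > 0) {
    spec <- do.call(rbind, lapply(sm$effects, function(e)
      data.frame(mark = e$mark, delta = e$delta,
                 coupling = if (is.null(e$coupling)) 0 else e$coupling,
                 n = e$n)))
    eff <- plant_effects(ref$map, spec)
  }
  list(spec = truth_spec(ref$map, groups, regions = eff,
                         baseline = do.call(baseline_spec, sm$baseline),
                         coverage = coverage_spec(sm$coverage$mean,
                                                  sm$coverage$size),
                         chemistry = chemistry_params(sm$chemistry$eps_fail,
                                                      sm$chemistry$eps_over,
                                                      sm$chemistry$eta_ox),
                         sample_sd = c(m = sm$sample_sd$m, h = sm$sample_sd$h),
                         seed = cfg$seed),
       genes = ref$genes)
}

.resolve_contrasts <- function(cfg, sample_data) {
  lapply(cfg$contrasts, function(cc) {
    col <- sample_data[[cc$column]]
    if (is.null(col)) stop("contrast '", cc$name, "': sample sheet has no column '",
                           cc$column, "'")
    names(col) <- sample_data$sample_id
    if (!is.null(cc$split) && identical(cc$split, "median")) {
      v <- stats::setNames(as.numeric(col), names(col))
      median_split(v, name = cc$name, ties = cfg$median_split_ties)
    } else {
      cs <- names(col)[col == cc$case]
      ks <- names(col)[col == cc$control]
      if (length(cs) == 0L || length(ks) == 0L)
        stop("contrast '", cc$name, "': a group has no samples")
      contrast_design(cc$name, cs, ks)
    }
  })
}

#' Run the full paired BS/oxBS analysis pipeline
#'
#' simulate (or ingest) -> estimate -> DMR calling per contrast and mark ->
#' annotation -> biomarker screening -> three-signal comparison, writing all
#' reports, a structured log and a manifest (with a hash of the resolved
#' configuration and checksums of every output) to `outdir`.  Deterministic
#' for a fixed seed.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param outdir Output directory (created; existing files overwritten).
#' @param seed Optional seed override.
#' @return Invisibly, a list with the manifest and the in-memory results.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list(log = file.path(outdir, "run_log.txt"))
  if (file.exists(state$log)) unlink(state$log)
  .log_line(state, "pipeline start (mode = %s, seed = %d)", cfg$mode, cfg$seed)

  # -- stage 1: cohort ------------------------------------------------------
  if (cfg$mode == "simulate") {
    ts <- .cfg_truth_spec(cfg)
    cohort <- simulate_counts(ts$spec)
    genes <- ts$genes
    write_cohort(cohort, file.path(outdir, "cohort"))
    sample_data <- utils::read.csv(file.path(outdir, "cohort",
                                             "sample_sheet.csv"),
                                   stringsAsFactors = FALSE)
  } else if (cfg$mode == "ingest") {
    if (is.null(cfg$sample_sheet)) stop("ingest mode needs a sample_sheet path")
    cohort <- read_cohort(cfg$sample_sheet)
    sample_data <- cohort$sample_data
    genes <- if (!is.null(cfg$gene_model)) read_gene_model(cfg$gene_model)
      else gene_model(data.frame(tx_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character()),
                      data.frame(tx_id = character(), chrom = character(),
                                 start = integer(), end = integer()))
  } else stop("unknown mode: ", cfg$mode)
  .log_line(state, "cohort: %d CpGs x %d samples", nrow(cohort$map),
            ncol(cohort$counts$bs_c))

  # -- stage 2: estimation --------------------------------------------------
  pm <- estimate_cohort(cohort, min_cov = cfg$estimate$min_cov,
                        mode = cfg$estimate$mode)
  write_paired_tables(pm, file.path(outdir, "paired"))
  .log_line(state, "estimation: mode %s, %.1f%% callable entries",
            pm$mode, 100 * mean(!is.na(pm$beta_bs)))

  contrasts <- .resolve_contrasts(cfg, sample_data)
  thr <- dmr_thresholds(cfg$thresholds$diff_5mc, cfg$thresholds$diff_5hmc,
                        cfg$thresholds$diff_bs, cfg$thresholds$q_max)
  sp <- seg_params(cfg$segmentation$max_gap, cfg$segmentation$min_cpg,
                   cfg$segmentation$min_group_presence,
                   cfg$segmentation$split_gain)

  results <- list()
  for (ct in contrasts) {
    for (mark in cfg$marks) {
      # -- stage 3: DMR calling -------------------------------------------
      dmrs <- call_dmrs(pm, ct, mark, thr, sp)
      cnt <- attr(dmrs, "counts")
      .log_line(state,
                "dmr [%s/%s]: %d candidates, %d tested, %d significant (%d hyper/%d hypo)",
                ct$name, mark, cnt["n_candidates"], cnt["n_tested"],
                cnt["n_significant"], cnt["n_hyper"], cnt["n_hypo"])
      tag <- sprintf("%s_%s", ct$name, gsub("5", "x5", mark))
      write_dmr_bed(dmrs, file.path(outdir, sprintf("dmrs_%s.bed", tag)))

      # -- stage 4: annotation --------------------------------------------
      ann <- annotate_dmrs(dmrs, genes,
                           promoter = cfg$annotation$promoter,
                           tts = cfg$annotation$tts)
      cc <- category_counts(ann)
      utils::write.table(as.data.frame(cc),
                         file.path(outdir, sprintf("annotation_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      # -- stage 5: biomarker screen --------------------------------------
      scr <- screen_biomarkers(dmrs, pm, ct,
                               auc_cutoff = cfg$screen$auc_cutoff,
                               min_frac_samples = cfg$screen$min_frac_samples)
      .log_line(state, "screen [%s/%s]: %d/%d pass AUC > %.2g", ct$name, mark,
                sum(scr$passes_screen), nrow(scr), cfg$screen$auc_cutoff)
      utils::write.table(as.data.frame(scr),
                         file.path(outdir, sprintf("biomarkers_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results[[ct$name]][[mark]] <- list(dmrs = ann, screen = scr)
    }

    # -- stage 6: signal comparison + anti-correlation ---------------------
    dm <- results[[ct$name]][["5mC"]]$dmrs
    if (!is.null(dm) && any(dm$significant)) {
      top <- dm[dm$significant, , drop = FALSE]
      top <- top[order(top$q), , drop = FALSE][seq_len(min(10, nrow(top))), ]
      cmp <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
        cbind(region = sprintf("%s:%d-%d", top$chrom[i], top$start[i],
                               top$end[i]),
              compare_signals(top[i, ], pm, ct))
      }))
      utils::write.table(cmp,
                         file.path(outdir,
                                   sprintf("signal_comparison_%s.tsv", ct$name)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    dh <- results[[ct$name]][["5hmC"]]$dmrs
    if (!is.null(dm) && !is.null(dh) && nrow(dm) >= 3 && nrow(dh) >= 3) {
      pa <- differential_profile(dm)
      # 5hmC differences over the same intervals for the anti-correlation scan
      ph <- tryCatch({
        rm5 <- region_sample_means(as.data.frame(dm), pm, "5hmC")
        cs <- intersect(ct$case, colnames(rm5))
        ks <- intersect(ct$control, colnames(rm5))
        rowMeans(rm5[, cs, drop = FALSE], na.rm = TRUE) -
          rowMeans(rm5[, ks, drop = FALSE], na.rm = TRUE)
      }, warning = function(w) NULL, error = function(e) NULL)
      if (!is.null(ph) && sum(names(pa) %in% names(ph)) >= 3) {
        pc <- profile_correlation(pa, ph)
        .log_line(state, "anti-correlation [%s]: r = %.3f (p = %.3g, n = %d)",
                  ct$name, pc$r, pc$p, pc$n)
        writeLines(jsonlite::toJSON(pc, auto_unbox = TRUE, digits = NA),
                   file.path(outdir,
                             sprintf("delta_correlation_%s.json", ct$name)))
      }
    }
  }

  # -- manifest -------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  files <- setdiff(list.files(outdir, recursive = TRUE),
                   c("manifest.json", "run_log.txt"))
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed, mode = cfg$mode,
                   files = as.list(tools::md5sum(file.path(outdir,
                                                           sort(files)))))
  names(manifest$files) <- sort(files)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(outdir, "manifest.json"))
  .log_line(state, "pipeline done: %d output files", length(files))
  invisible(list(manifest = manifest, results = results, pm = pm,
                 cohort = cohort, genes = genes, config = cfg))
}
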