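.pipeline_defaults <- function() {
  list(matching = "tss", ratio = 10L, window_bp = 10000L,
       representation = "read", peak_quantile = 0.90, base_kind = "tree",
       threshold = NULL, grid = seq(0.01, 0.20, by = 0.01), C = NULL,
       k = 5L, alpha = 0.05, thin = FALSE, min_gap_bp = 10000L, sim = list())
}

#' Run the full prioritization pipeline
#'
#' Orchestrates an end-to-end run: simulate (or load) data, construct matched
#' benign controls, annotate variants against the tracks, select features and
#' train the ensemble, score the variants, evaluate by stratified
#' cross-validation and run the factor over-representation analysis. Every
#' stage draws its seed deterministically from the run seed and the stage
#' name, the configuration is echoed verbatim into the output directory, and
#' re-running with the same configuration and seed reproduces identical
#' artifacts. Any stage error aborts with the stage name.
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: `matching` (`"tss"` or `"region"`), `ratio`, `window_bp`,
#'   `representation` (`"read"` or `"peak"`), `peak_quantile`, `base_kind`,
#'   `threshold` (fixed cutoff, or `NULL` to tune on `grid`), `grid`, `C`,
#'   `k`, `alpha`, `thin`/`min_gap_bp` (proximity thinning before CV), and
#'   `sim` (arguments passed to [simulation_config()]). To run on data on
#'   disk instead of simulating, supply `manifest`, `genome_file`, `risk`,
#'   `pool` and `tss` paths.
#' @param out_dir output directory for artifacts.
#' @param seed run seed.
#' @param verbose print stage banners (always logged to `run.log`).
#' @return invisibly, a list with the fitted model (`fit`), the
#'   cross-validation result (`cv`), the enrichment result (`enrichment`),
#'   the annotated matrix (`matrix`), the variant tables, and `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    writeLines(line, log_con)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    say("== stage: %s ==", name)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s (artifacts in %s)", name,
            conditionMessage(e), out_dir))
  }
  echo <- cfg
  echo$seed <- seed
  echo$grid <- as.numeric(echo$grid)
  if (!is.null(echo$sim$chrom_lengths))   # keep names through YAML
    echo$sim$chrom_lengths <- as.list(echo$sim$chrom_lengths)
  yaml::write_yaml(echo, file.path(out_dir, "config.yaml"))
  say("config echoed to config.yaml (seed %d)", seed)

  dat <- stage("simulate", {
    if (!is.null(cfg$manifest)) {
      gl <- utils::read.table(cfg$genome_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      genome <- binned_genome(stats::setNames(gl$length, gl$chrom),
                              if (is.null(cfg$bin_width)) 200L else cfg$bin_width)
      man <- read_manifest(cfg$manifest)
      list(tracks = load_tracks(man, genome, dirname(cfg$manifest)),
           manifest = man, genome = genome,
           risk = read_variants(cfg$risk), pool = read_variants(cfg$pool),
           tss = read_tss(cfg$tss))
    } else {
      sim <- simulate_dataset(do.call(simulation_config, cfg$sim),
                              seed = derive_seed(seed, "simulate"))
      say("simulated %d tracks, %d risk variants, pool %d",
          length(sim$tracks), nrow(sim$risk), nrow(sim$pool))
      sim
    }
  })

  controls <- stage("controls", {
    risk <- dat$risk
    if (isTRUE(cfg$thin)) risk <- thin_by_proximity(risk, cfg$min_gap_bp)
    benign <- if (cfg$matching == "region")
      match_benign_region(risk, dat$pool, window_bp = cfg$window_bp,
                          ratio = cfg$ratio, seed = derive_seed(seed, "controls"))
    else
      match_benign_tss(risk, dat$pool, dat$tss, ratio = cfg$ratio,
                       seed = derive_seed(seed, "controls"))
    write_variants(risk, file.path(out_dir, "risk.tsv"))
    write_variants(benign, file.path(out_dir, "benign.tsv"))
    say("matched %d benign controls (%s criterion) to %d risk variants",
        nrow(benign), cfg$matching, nrow(risk))
    list(risk = risk, benign = benign)
  })

  am <- stage("annotate", {
    tracks <- dat$tracks
    if (cfg$representation == "peak")
      tracks <- lapply(tracks, track_to_peaks, genome = dat$genome,
                       quantile = cfg$peak_quantile)
    v <- rbind(controls$risk, controls$benign)
    m <- build_annotation_matrix(v, tracks, dat$genome)
    write_annotation_matrix(m, file.path(out_dir, "annotation.tsv"))
    m
  })
  variants <- rbind(controls$risk, controls$benign)
  labels <- variants$label

  fit <- stage("train", {
    f <- suppressWarnings(
      epirisk(am, labels, base_kind = cfg$base_kind, threshold = cfg$threshold,
              grid = cfg$grid, C = cfg$C, k = cfg$k,
              seed = derive_seed(seed, "train"),
              disease = variants$disease[1L]))
    save_model(f, file.path(out_dir, "model"))
    write_selection(f$pvalues, file.path(out_dir, "selection.tsv"))
    say("selected %d/%d features at p < %g; ensemble of %d %s learners",
        length(f$selected_features), nrow(f$pvalues), f$threshold,
        f$ensemble$C, f$base_kind)
    f
  })

  stage("score", {
    write_scores(variants, predict(fit), file.path(out_dir, "scores.tsv"))
  })

  cv <- stage("evaluate", {
    r <- cross_validate(am, labels, k = cfg$k, base_kind = cfg$base_kind,
                        threshold = cfg$threshold, grid = cfg$grid, C = cfg$C,
                        seed = derive_seed(seed, "evaluate"))
    write_evaluation(r, file.path(out_dir, "evaluation.tsv"))
    say("cross-validation mean AUC %.3f (sd %.3f)", r$mean_auc, r$sd_auc)
    r
  })

  enr <- stage("enrich", {
    sel <- fit$pvalues
    sel$factor <- dat$manifest$factor[match(sel$track_id, dat$manifest$track_id)]
    e <- factor_enrichment(stats::setNames(list(sel), variants$disease[1L]),
                           alpha = cfg$alpha)
    write_enrichment(e, file.path(out_dir, "enrichment"))
    e
  })

  say("pipeline complete")
  invisible(list(fit = fit, cv = cv, enrichment = enr, matrix = am,
                 risk = controls$risk, benign = controls$benign,
                 out_dir = out_dir))
}
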