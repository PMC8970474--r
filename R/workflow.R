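#' Pipeline orchestration and reporting
#'
#' `run_pipeline()` executes the analysis stages in dependency order
#' from a single configuration (R list or YAML file), writes per-stage
#' TSV outputs plus a JSON run manifest (config hash, seed, per-stage
#' row counts, warnings), and `report()` regenerates summary plots from
#' those TSVs. Stages consume seeds derived from the master seed, so a
#' run is reproducible end to end.
#'
#' @name workflow_cli
NULL

default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("dstorm", "proteomics"),
    dstorm = list(n_synapses = 25L, max_uncertainty = 20,
                  epsilon = 20, min_points = 5),
    sim3d = list(n_synapses = 4L),
    spines = list(n_images = 3L, cooccurrence_fraction = 0.2),
    proteomics = list(fold_threshold = 7)
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], config[[nm]])
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

stage_dstorm <- function(cfg, outdir) {
  n <- cfg$dstorm$n_synapses
  rows <- vector("list", n)
  prev <- logical(n)
  for (i in seq_len(n)) {
    sim <- simulate_bracelet_synapse(seed = cfg$seed + i)
    res <- lapply(sim$localizations[c("SynCAM1", "MPP2")], function(tab) {
      tab <- filter_by_precision(tab, cfg$dstorm$max_uncertainty)
      detect_clusters_dbscan(tab, cluster_params(cfg$dstorm$epsilon,
                                                 cfg$dstorm$min_points))
    })
    cls <- classify_bracelet(res, centre = sim$truth$centre)
    prev[i] <- cls$bracelet
    ring <- lapply(res, function(cs) estimate_ring_diameter(cs$clusters))
    rows[[i]] <- data.frame(
      synapse = i, bracelet_true = sim$truth$bracelet,
      bracelet_called = cls$bracelet, score = cls$score,
      diameter_syncam1 = ring$SynCAM1$diameter,
      diameter_mpp2 = ring$MPP2$diameter)
  }
  df <- do.call(rbind, rows)
  write_tsv(df, file.path(outdir, "dstorm_synapses.tsv"))
  list(table = "dstorm_synapses.tsv", n_rows = nrow(df),
       prevalence = mean(prev))
}

stage_proteomics <- function(cfg, outdir) {
  sim <- simulate_peptide_table(seed = cfg$seed + 1000L)
  res <- run_proteomics(
    sim$peptides,
    quant_filter_params(fold_threshold = cfg$proteomics$fold_threshold))
  write_tsv(res$proteins, file.path(outdir, "proteins.tsv"))
  list(table = "proteins.tsv", n_rows = nrow(res$proteins),
       n_quantified = res$n_quantified,
       n_mpp2_enriched = length(res$mpp2_enriched))
}

stage_spines <- function(cfg, outdir) {
  n <- cfg$spines$n_images
  fr <- numeric(n)
  for (i in seq_len(n)) {
    scn <- simulate_confocal_scene(
      confocal_scene_config(
        cooccurrence_fraction = cfg$spines$cooccurrence_fraction),
      seed = cfg$seed + 2000L + i)
    fr[i] <- analyze_spine_scene(scn$images)$fraction
  }
  df <- data.frame(image = seq_len(n), fraction = fr)
  write_tsv(df, file.path(outdir, "spine_fractions.tsv"))
  list(table = "spine_fractions.tsv", n_rows = n,
       mean_fraction = mean(fr, na.rm = TRUE))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages ("dstorm", "spines", "proteomics") and
#' writes stage TSVs plus `manifest.json` to `outdir`. Skipped stages
#' are logged in the manifest. Stage failures abort the run after
#' removing partial outputs.
#'
#' @param config R list or path to a YAML file; see
#'   `synbracelet:::default_pipeline_config()` for the shape.
#' @param outdir output directory (created if needed).
#' @return the run manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("run")) {
  cfg <- load_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  known <- c("dstorm", "spines", "proteomics")
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   package_version =
                     as.character(utils::packageVersion("synbracelet")),
                   stages = list(), skipped = setdiff(known, cfg$stages))
  for (st in intersect(known, cfg$stages)) {
    res <- tryCatch(
      switch(st,
             dstorm = stage_dstorm(cfg, outdir),
             spines = stage_spines(cfg, outdir),
             proteomics = stage_proteomics(cfg, outdir)),
      error = function(e) {
        # remove partial outputs of the failing stage, then abort
        unlink(list.files(outdir, full.names = TRUE))
        stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
             call. = FALSE)
      })
    manifest$stages[[st]] <- res
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate summary plots from pipeline outputs
#'
#' Reads the stage TSVs in `outdir` and writes ggplot2 figures (PDF).
#' Missing stage outputs are skipped with a notice.
#'
#' @param outdir directory written by [run_pipeline()].
#' @return character vector of figure paths.
#' @export
report <- function(outdir) {
  figs <- character(0)
  f <- file.path(outdir, "dstorm_synapses.tsv")
  if (file.exists(f)) {
    df <- utils::read.delim(f)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = diameter_syncam1)) +
      ggplot2::geom_histogram(binwidth = 50, boundary = 0) +
      ggplot2::labs(x = "fitted ring diameter (nm)", y = "synapses")
    out <- file.path(outdir, "ring_diameters.pdf")
    ggplot2::ggsave(out, p, width = 4, height = 3)
    figs <- c(figs, out)
  } else {
    message("dstorm output missing; section skipped")
  }
  f <- file.path(outdir, "proteins.tsv")
  if (file.exists(f)) {
    df <- utils::read.delim(f)
    p <- ggplot2::ggplot(df, ggplot2::aes(ratio_A, ratio_B,
                                          colour = quadrant)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::labs(x = "replicate A (normalized ratio)",
                    y = "replicate B (normalized ratio)")
    out <- file.path(outdir, "enrichment_scatter.pdf")
    ggplot2::ggsave(out, p, width = 5, height = 4)
    figs <- c(figs, out)
  } else {
    message("proteomics output missing; section skipped")
  }
  f <- file.path(outdir, "spine_fractions.tsv")
  if (file.exists(f)) {
    df <- utils::read.delim(f)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(image),
                                          y = fraction)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "image", y = "triple-positive fraction")
    out <- file.path(outdir, "spine_fractions.pdf")
    ggplot2::ggsave(out, p, width = 4, height = 3)
    figs <- c(figs, out)
  } else {
    message("spine output missing; section skipped")
  }
  invisible(figs)
}
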