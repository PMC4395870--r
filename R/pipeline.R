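#' Resolved run configuration
#'
#' One object holding everything a pipeline run needs: calibration,
#' synthetic-scene and splice-scenario parameters, the top-level seed and
#' the output directory. The resolved configuration (plus its hash) is
#' written to the output directory before any computation starts, so every
#' run is reproducible from its artifacts.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Top-level integer seed; all randomness flows from it.
#' @param params [forward_model_params()] for the synthetic imager.
#' @param calib [calibration_params()] for the analysis.
#' @param scene_args List of arguments for [tension_scene()].
#' @param scenario [splice_scenario()] for the array half.
#' @param n_frames z-frames per simulated embryo.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("fretsplice-run-"),
                       seed = 1L,
                       params = forward_model_params(),
                       calib = calibration_from_model(params),
                       scene_args = list(),
                       scenario = splice_scenario(seed = seed),
                       n_frames = 3) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), params = params,
                 calib = calib, scene_args = scene_args, scenario = scenario,
                 n_frames = n_frames),
            class = "run_config")
}

# hash of the scientific configuration only: where the artifacts land must
# not change what they contain
config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

write_config_record <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- list(
    package = as.character(utils::packageVersion("fretsplice")),
    seed = config$seed,
    config_hash = config_hash(config),
    calibration = unclass(config$calib),
    forward_model = unclass(config$params),
    scene_args = config$scene_args,
    scenario = unclass(config$scenario),
    n_frames = config$n_frames
  )
  yaml::write_yaml(rec, file.path(config$out_dir, "run-config.yml"))
}

#' Run a pipeline stage
#'
#' Composes the package's modules into the end-to-end workflows. Available
#' subcommands:
#' \describe{
#'   \item{`simulate-fret`}{render the synthetic embryo stack; writes
#'     `stack.tif`, `truth_e.tif`, `embryo_mask.tif` and `roi.tsv`.}
#'   \item{`fret-index`}{run [fret_pipeline()] on `stack.tif`; writes
#'     `fret_f.tif`, `fret_sigma.tif`, `valid.tif` and `pixels.tsv`.}
#'   \item{`roi-stats`}{ROI extraction, per-embryo pooling and the paired
#'     statistics; writes `embryo_measurements.tsv` and `stats.tsv`.}
#'   \item{`simulate-array`}{generate the probe tables; writes
#'     `probes.tsv`, `annotation.tsv`, `truth_regions.tsv`.}
#'   \item{`classify-regions`}{fold changes, category calls, gene-level
#'     aggregation and enrichment; writes `region_calls.tsv`,
#'     `gene_summary.tsv`, `category_counts.tsv`,
#'     `enrichment_proportions.tsv`, `enrichment_pairwise.tsv` and
#'     `enrichment_background.tsv`.}
#'   \item{`report`}{one-file summary of whatever stages have run.}
#' }
#' Identical configuration and seed give identical artifacts.
#'
#' @param config A [run_config()].
#' @param subcommand One of the stages above.
#' @return A named list of the paths written, invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate-fret", "fret-index",
                                        "roi-stats", "simulate-array",
                                        "classify-regions", "report")) {
  stopifnot(inherits(config, "run_config"))
  subcommand <- match.arg(subcommand)
  write_config_record(config)
  out <- function(...) file.path(config$out_dir, ...)

  paths <- switch(subcommand,
    "simulate-fret" = {
      scene <- do.call(tension_scene,
                       utils::modifyList(list(params = config$params,
                                              seed = config$seed),
                                         config$scene_args))
      sim <- simulate_fret_stack(scene, config$params,
                                 n_frames = config$n_frames, seed = config$seed)
      write_stack(sim$stack, out("stack.tif"))
      write_map(sim$truth_e, out("truth_e.tif"))
      write_map(scene$embryo_mask + 0, out("embryo_mask.tif"))
      write_tsv_prov(
        tibble::tibble(embryo_id = "embryo01",
                       row0 = scene$sdr_box[1], row1 = scene$sdr_box[2],
                       col0 = scene$sdr_box[3], col1 = scene$sdr_box[4]),
        out("roi.tsv"), config, config$seed)
      list(stack = out("stack.tif"), truth_e = out("truth_e.tif"),
           embryo_mask = out("embryo_mask.tif"), roi = out("roi.tsv"))
    },
    "fret-index" = {
      stack <- read_stack(out("stack.tif"))
      fm <- fret_pipeline(stack, config$calib)
      write_map(fm$F, out("fret_f.tif"))
      write_map(fm$sigma_f, out("fret_sigma.tif"))
      write_map(fm$valid + 0, out("valid.tif"))
      px <- tidy(fm)
      write_tsv_prov(px, out("pixels.tsv"), config, config$seed)
      list(f = out("fret_f.tif"), sigma = out("fret_sigma.tif"),
           valid = out("valid.tif"), pixels = out("pixels.tsv"))
    },
    "roi-stats" = {
      stack <- read_stack(out("stack.tif"))
      fm <- fret_pipeline(stack, config$calib)
      roi_tab <- read_tsv_prov(out("roi.tsv"))
      emb_mask <- read_map(out("embryo_mask.tif"))[, , 1] > 0.5
      rows <- purrr::map_dfr(seq_len(nrow(roi_tab)), function(i) {
        roi <- roi_spec(unlist(roi_tab[i, c("row0", "row1", "col0", "col1")]),
                        emb_mask)
        pool_embryo(extract_roi_values(fm, roi),
                    embryo_id = roi_tab$embryo_id[i])
      })
      write_tsv_prov(rows, out("embryo_measurements.tsv"), config, config$seed)
      stats_tab <- if (nrow(rows) >= 2) {
        paired_test(rows$sdr_mean, rows$nonsdr_mean)
      } else {
        tibble::tibble(method = "paired t-test", estimate = NA_real_,
                       statistic = NA_real_, df = NA_real_, p.value = NA_real_)
      }
      write_tsv_prov(stats_tab, out("stats.tsv"), config, config$seed)
      list(embryos = out("embryo_measurements.tsv"), stats = out("stats.tsv"))
    },
    "simulate-array" = {
      sim <- simulate_probe_table(config$scenario)
      write_tsv_prov(sim$probes, out("probes.tsv"), config, config$seed)
      write_tsv_prov(sim$annotation, out("annotation.tsv"), config, config$seed)
      write_tsv_prov(sim$truth, out("truth_regions.tsv"), config, config$seed)
      list(probes = out("probes.tsv"), annotation = out("annotation.tsv"),
           truth = out("truth_regions.tsv"))
    },
    "classify-regions" = {
      probes <- read_tsv_prov(out("probes.tsv"))
      annot <- read_tsv_prov(out("annotation.tsv"))
      annot$as_flag <- as.logical(annot$as_flag)
      calls <- classify_regions(region_fold_changes(probes))
      agg <- aggregate_genes(calls)
      enr <- as_enrichment(agg$genes, annot)
      write_tsv_prov(calls, out("region_calls.tsv"), config, config$seed)
      write_tsv_prov(agg$genes, out("gene_summary.tsv"), config, config$seed)
      write_tsv_prov(agg$counts, out("category_counts.tsv"), config, config$seed)
      write_tsv_prov(enr$proportions, out("enrichment_proportions.tsv"),
                     config, config$seed)
      write_tsv_prov(enr$pairwise, out("enrichment_pairwise.tsv"),
                     config, config$seed)
      write_tsv_prov(enr$vs_background, out("enrichment_background.tsv"),
                     config, config$seed)
      list(calls = out("region_calls.tsv"), genes = out("gene_summary.tsv"),
           counts = out("category_counts.tsv"),
           proportions = out("enrichment_proportions.tsv"),
           pairwise = out("enrichment_pairwise.tsv"),
           background = out("enrichment_background.tsv"))
    },
    "report" = {
      files <- list.files(config$out_dir)
      lines <- c(sprintf("fretsplice run report (seed %d, hash %s)",
                         config$seed, config_hash(config)),
                 sprintf("artifacts: %s", paste(files, collapse = ", ")))
      writeLines(lines, out("report.txt"))
      list(report = out("report.txt"))
    }
  )
  invisible(paths)
}
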