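#' Assemble a pipeline configuration
#'
#' One flat, serializable record of every stage parameter, so a run is a
#' pure function of (input, config, seed) and any result can be reproduced
#' from its manifest. Write/read with [write_config()] / [read_config()].
#'
#' @param input path to the input multi-page TIFF series (may be `NULL` when
#'   the pipeline is run on an in-memory [frame_series()]).
#' @param out_dir output directory for all artifacts.
#' @param pixel_scale micrometres per pixel.
#' @param clamp_fraction optional clamp level in (0, 1]; `NULL` disables
#'   clamping.
#' @param denoise logical: run the denoiser.
#' @param sigma denoiser noise level on the `[0, 1]` scale.
#' @param denoise_method denoiser registry name.
#' @param backend segmentation backend name.
#' @param threshold foreground threshold for the baseline backend.
#' @param grid_n prompt-grid side for prompt-based backends.
#' @param min_area,max_area,r1,r2,K,iou_threshold,edge_margin,closing_radius
#'   see [filter_config()].
#' @param stages post-processing stages to run (see [run_postprocess()]).
#' @param model morphometric model, `"rod"` or `"sphere"`.
#' @param annotations optional path to an annotation CSV for evaluation.
#' @param seed integer seed recorded in the manifest (the standard stages
#'   are deterministic; a stochastic backend must draw from it).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = "microseg_out",
                            pixel_scale = DEFAULT_PIXEL_SCALE,
                            clamp_fraction = NULL, denoise = TRUE,
                            sigma = 0.2, denoise_method = "nlm",
                            backend = "baseline", threshold = 0.5,
                            grid_n = 32L, min_area = 10, max_area = NULL,
                            r1 = 1.3, r2 = 1.3, K = 3L, iou_threshold = 0.3,
                            edge_margin = 2L, closing_radius = 1L,
                            stages = c("area", "intensity", "nms", "edge",
                                       "closing"),
                            model = "rod", annotations = NULL, seed = 1L) {
  cfg <- list(input = input, out_dir = out_dir, pixel_scale = pixel_scale,
              clamp_fraction = clamp_fraction, denoise = denoise,
              sigma = sigma, denoise_method = denoise_method,
              backend = backend, threshold = threshold,
              grid_n = as.integer(grid_n), min_area = min_area,
              max_area = max_area, r1 = r1, r2 = r2, K = as.integer(K),
              iou_threshold = iou_threshold,
              edge_margin = as.integer(edge_margin),
              closing_radius = as.integer(closing_radius), stages = stages,
              model = model, annotations = annotations,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / deserialize a pipeline configuration
#'
#' YAML round trip; `read_config()` re-validates through
#' [pipeline_config()] so a hand-edited file gets the same checking as a
#' programmatic one.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1L))]
  do.call(pipeline_config, vals)
}

#' Run the full segmentation pipeline
#'
#' Executes stack -> normalize -> (clamp) -> (denoise) -> propose ->
#' post-process -> features (-> evaluate), writing every intermediate
#' artifact plus a YAML manifest (configuration, package version, seed,
#' per-stage mask counts, MD5 checksums of all outputs) into
#' `config$out_dir`.
#'
#' Artifacts: `stacked.tif`, `normalized.tif`, optionally `clamped.tif` and
#' `denoised.tif`, `proposal_masks.tif` + `proposal_scores.csv`,
#' `labels.tif` (16-bit, background 0), `removals.csv`, `features.csv`,
#' optionally `errors.csv`, and `manifest.yaml`.
#'
#' @param config a [pipeline_config()].
#' @param frames optional in-memory [frame_series()] overriding
#'   `config$input`.
#' @return invisibly, a run summary list: the retained [proposal_set()],
#'   the feature table, the removal report, the evaluation result (or
#'   `NULL`), stage mask counts and the manifest path.
#' @export
run_pipeline <- function(config, frames = NULL) {
  if (!inherits(config, "pipeline_config"))
    abort_microseg("'config' must be a pipeline_config")
  if (is.null(frames)) {
    if (is.null(config$input))
      abort_microseg("no input: set config$input or pass 'frames'")
    frames <- read_frames(config$input, pixel_scale = config$pixel_scale)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  scales <- list()

  stacked <- stack_frames(frames)
  scales$stacked <- write_image(stacked, out("stacked.tif"))
  work <- normalize_image(stacked)
  write_image(work, out("normalized.tif"))
  if (!is.null(config$clamp_fraction)) {
    work <- normalize_image(clamp_image(work, config$clamp_fraction))
    write_image(work, out("clamped.tif"))
  }
  if (isTRUE(config$denoise)) {
    work <- denoise_image(work, sigma = config$sigma,
                          method = config$denoise_method)
    write_image(work, out("denoised.tif"))
  }

  backend_args <- if (config$backend == "baseline")
    list(threshold = config$threshold) else list(grid_n = config$grid_n)
  proposals <- do.call(propose, c(list(work, backend = config$backend),
                                  backend_args))
  counts <- c(proposed = length(proposals))
  if (length(proposals) > 0L)
    write_proposals(proposals, out("proposal_masks.tif"),
                    out("proposal_scores.csv"))

  fc <- filter_config(min_area = config$min_area, max_area = config$max_area,
                      r1 = config$r1, r2 = config$r2, K = config$K,
                      iou_threshold = config$iou_threshold,
                      edge_margin = config$edge_margin,
                      closing_radius = config$closing_radius)
  pp <- run_postprocess(proposals, work, fc, stages = config$stages)
  counts <- c(counts, retained = length(pp$proposals))
  write_labels(proposals_to_labels(pp$proposals), out("labels.tif"))
  utils::write.csv(pp$report, out("removals.csv"), row.names = FALSE)

  features <- extract_features(pp$proposals, stacked, model = config$model,
                               pixel_scale = config$pixel_scale)
  write_features(features, out("features.csv"))

  evaluation <- NULL
  if (!is.null(config$annotations)) {
    ann <- if (inherits(config$annotations, "annotation_set"))
      config$annotations
    else read_annotations(config$annotations, dim(stacked$values))
    evaluation <- match_detections(pp$proposals, ann)
    utils::write.csv(error_table(list(evaluation)), out("errors.csv"),
                     row.names = FALSE)
  }

  artifacts <- list.files(config$out_dir, full.names = TRUE)
  artifacts <- artifacts[!basename(artifacts) %in% "manifest.yaml"]
  manifest <- list(
    package = "microseg",
    version = as.character(utils::packageVersion("microseg")),
    seed = config$seed,
    config = unclass(config),
    intensity_scales = scales,
    stage_counts = as.list(counts),
    error_rate = if (!is.null(evaluation)) evaluation$error_rate else NULL,
    checksums = as.list(tools::md5sum(sort(artifacts)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  yaml::write_yaml(manifest, out("manifest.yaml"))

  invisible(list(proposals = pp$proposals, features = features,
                 report = pp$report, evaluation = evaluation,
                 counts = counts, manifest = out("manifest.yaml")))
}
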