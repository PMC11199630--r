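#' Run the full colour-based reconstruction pipeline
#'
#' Orchestrates: detector linearity correction, linear spectral unmixing,
#' fragment extraction from SWC traces, quality control, dCrawler
#' clustering (at a fixed Th(d) or optimized against labels), and — when
#' ground-truth labels are supplied — per-neuron F1 scoring.  Every output
#' file carries a JSON provenance record of the thresholds and seed used.
#'
#' Chromatic-aberration correction is an explicit no-op hook
#' (`config$aberration_hook`): cleared-tissue imaging may need a
#' system-specific correction between linearity correction and unmixing,
#' and a user function `function(img) img` can be slotted in there.
#'
#' @param config a list (or YAML path, see [read_pipeline_config()]) with
#'   elements:
#'   * `image`: a [channel_image] or TIFF path (+ `n_channels`,
#'     `voxel_size`);
#'   * `traces`: list of `swc_trace` or an SWC path;
#'   * `fragments`: optional pre-fragmented [neurite_fragment] list (used
#'     instead of re-splitting `traces`, preserving fragment ids);
#'   * `linearity`: optional [linearity_coefficients] or list `(a, b, c,
#'     saturation_cutoff)`;
#'   * `reference`: optional [spectral_reference] or YAML path;
#'   * `qc`: optional [qc_config] arguments;
#'   * `th_d`: threshold distance, or `"optimize"` (requires `labels`);
#'   * `labels`: optional data.frame `fragment_id`, `neuron_id` or CSV
#'     path;
#'   * `seed`: RNG seed (default 1);
#'   * `out_dir`: output directory (optional; no files written when
#'     `NULL`).
#' @return A list of class `qdf_run`: `vectors`, `qc`, `clusters`
#'   (a [dcrawler]), `scores` (when labelled), `thd` (when optimized),
#'   `provenance`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- "preflight"
  out <- list()
  tryCatch({
    cfg <- config
    if (!is.null(cfg$seed)) set.seed(cfg$seed)

    stage <- "load-image"
    img <- cfg$image
    if (is.character(img)) {
      if (!file.exists(img)) stop("image file not found: ", img)
      img <- read_channel_image(img, cfg$n_channels %||% 1L,
                                cfg$voxel_size %||% c(1, 1, 1))
    }

    stage <- "linearity"
    if (!is.null(cfg$linearity)) {
      co <- cfg$linearity
      if (!inherits(co, "linearity_coefficients"))
        co <- linearity_coefficients(co$a, co$b, co$c, co$saturation_cutoff)
      img <- apply_linearity_correction(img, co)
    } else attr(img, "linearity_corrected") <- TRUE  # assume pre-corrected

    stage <- "aberration"
    if (!is.null(cfg$aberration_hook)) img <- cfg$aberration_hook(img)

    stage <- "unmix"
    if (!is.null(cfg$reference)) {
      ref <- cfg$reference
      if (is.character(ref)) ref <- read_spectral_reference(ref)
      img <- unmix(img, ref)
    }

    stage <- "extract"
    if (!is.null(cfg$fragments)) {
      # pre-fragmented input (ids preserved, e.g. phantom ground truth)
      fragments <- cfg$fragments
    } else {
      traces <- cfg$traces
      if (is.character(traces)) {
        if (!file.exists(traces)) stop("trace file not found: ", traces)
        traces <- read_swc(traces)
      }
      fragments <- unlist(lapply(seq_along(traces), function(i)
        split_at_branches(traces[[i]], id_prefix = sprintf("t%03d", i))),
        recursive = FALSE)
    }

    stage <- "qc"
    qc_cfg <- if (inherits(cfg$qc, "qc_config")) cfg$qc
              else do.call(qc_config, as.list(cfg$qc))
    qc <- run_qc(fragments, img, qc_cfg)
    out$qc <- qc
    out$vectors <- qc$vectors

    stage <- "cluster"
    labels <- cfg$labels
    if (is.character(labels)) labels <- utils::read.csv(labels)
    th_d <- cfg$th_d %||% 0.2
    if (identical(th_d, "optimize")) {
      if (is.null(labels))
        stop("th_d = \"optimize\" requires ground-truth labels")
      lab_map <- merge_labels(qc$vectors, labels)
      thd <- optimal_threshold(qc$vectors, lab_map)
      out$thd <- thd
      th_d <- thd$best_th_d
    }
    fit <- dcrawler(qc$vectors, th_d = th_d)
    out$clusters <- fit

    stage <- "evaluate"
    if (!is.null(labels)) {
      lab_map <- merge_labels(qc$vectors, labels)
      out$scores <- match_and_score(
        lab_map, stats::setNames(fit$cluster,
                                 as.character(qc$vectors$fragment_id)))
    }

    stage <- "write"
    out$provenance <- list(
      th_d = th_d, seed = cfg$seed %||% NA,
      qc = qc$report[c("min_length_um", "min_magnitude")],
      snr_threshold = qc_cfg$snr_threshold, split_d = qc_cfg$split_d,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_colour_vectors(qc$vectors,
                           file.path(cfg$out_dir, "vectors.csv"))
      write_clusters(fit, qc$vectors,
                     file.path(cfg$out_dir, "clusters.csv"))
      write_qc_report(qc, file.path(cfg$out_dir, "qc_report.json"))
      if (!is.null(out$scores))
        utils::write.csv(out$scores, file.path(cfg$out_dir, "scores.csv"),
                         row.names = FALSE)
      jsonlite::write_json(out$provenance,
                           file.path(cfg$out_dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    structure(out, class = "qdf_run")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Carry ground-truth labels over to QC-surviving colour vectors
#'
#' Quality control drops fragments and renames colour-change split pieces
#' (`"<id>s<k>"`).  This restricts a fragment-to-neuron label table to the
#' vectors that survived, letting split pieces inherit their parent's
#' neuron.
#'
#' @param vectors a [colour_vectors] object (e.g. `run_qc()$vectors`).
#' @param labels data.frame with columns `fragment_id`, `neuron_id`.
#' @return Named vector: neuron id per surviving fragment id.
#' @export
fragment_labels <- function(vectors, labels) {
  lab <- stats::setNames(labels$neuron_id, as.character(labels$fragment_id))
  ids <- as.character(vectors$fragment_id)
  # colour-change splitting renames pieces "<id>s<k>"; inherit the parent id
  base_ids <- sub("s[0-9]+$", "", ids)
  hit <- lab[base_ids]
  if (anyNA(hit))
    stop("no ground-truth label for fragment(s): ",
         paste(utils::head(ids[is.na(hit)], 5), collapse = ", "))
  stats::setNames(hit, ids)
}

merge_labels <- fragment_labels

#' @export
print.qdf_run <- function(x, ...) {
  cat("Pipeline run\n")
  if (!is.null(x$qc)) print(x$qc)
  if (!is.null(x$clusters))
    cat(sprintf("  %d clusters at Th(d) = %g\n",
                nrow(x$clusters$centroids), x$clusters$th_d))
  if (!is.null(x$scores))
    cat(sprintf("  median per-neuron F1 = %.3f\n",
                stats::median(x$scores$f1)))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields documented in [run_all()].
#' @return A config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
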