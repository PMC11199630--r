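#' Score a clustering against ground-truth neuron labels
#'
#' Each ground-truth neuron is matched to its *best cluster* — the cluster
#' containing the most of that neuron's fragments (ties to the lower
#' cluster id).  Fragments are then classified per neuron: true positive
#' (in the best cluster and from the neuron), false positive (in the best
#' cluster, from another neuron), false negative (from the neuron, in
#' another cluster) and true negative (neither), from which precision,
#' recall and the F1 score follow.  Several neurons may share a best
#' cluster (over-merged clustering); both then score poorly on precision.
#'
#' @param labels ground truth: named vector/factor mapping fragment id to
#'   neuron id, or data.frame with columns `fragment_id`, `neuron_id`.
#' @param clusters predicted: named vector mapping fragment id to cluster
#'   id, or data.frame with columns `fragment_id`, `cluster_id`.
#' @return data.frame, one row per neuron: `neuron_id`, `best_cluster_id`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
match_and_score <- function(labels, clusters) {
  lab <- as_fragment_map(labels, "neuron_id")
  clu <- as_fragment_map(clusters, "cluster_id")
  only_l <- setdiff(names(lab), names(clu))
  only_c <- setdiff(names(clu), names(lab))
  if (length(only_l) || length(only_c))
    stop("fragment universes differ; only in labels: [",
         paste(utils::head(only_l, 5), collapse = ", "),
         "], only in clusters: [",
         paste(utils::head(only_c, 5), collapse = ", "), "]")
  clu <- clu[names(lab)]
  total <- length(lab)
  neurons <- unique(lab)
  cluster_ids <- sort(unique(clu))
  res <- lapply(neurons, function(nu) {
    in_neuron <- lab == nu
    shared <- vapply(cluster_ids, function(cid)
      sum(clu == cid & in_neuron), integer(1))
    best <- cluster_ids[which.max(shared)]      # ties -> lower cluster id
    in_best <- clu == best
    tp <- sum(in_best & in_neuron)
    fp <- sum(in_best & !in_neuron)
    fn <- sum(!in_best & in_neuron)
    tn <- total - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(neuron_id = nu, best_cluster_id = best, tp = tp, fp = fp,
               fn = fn, tn = tn, precision = precision, recall = recall,
               f1 = f1)
  })
  do.call(rbind, res)
}

as_fragment_map <- function(x, value_col) {
  if (is.data.frame(x)) {
    stopifnot(all(c("fragment_id", value_col) %in% names(x)))
    stats::setNames(x[[value_col]], as.character(x$fragment_id))
  } else {
    if (is.null(names(x))) names(x) <- seq_along(x)
    x
  }
}

#' Optimal threshold distance by median F1 over a Th(d) grid
#'
#' Runs the dCrawler at every threshold of the grid, scores each solution
#' against the ground-truth labels with [match_and_score()], and returns
#' the threshold with the highest median per-neuron F1 (ties to the
#' smaller threshold), together with the full threshold-vs-F1 curve.
#'
#' @param points a [colour_vectors] object or matrix of colour vectors, in
#'   the same fragment order as `labels`.
#' @param labels neuron label per point (vector aligned with rows of
#'   `points`, or a fragment map as in [match_and_score()]).
#' @param th_grid candidate thresholds (default 0.05 to 1 in steps of
#'   0.025).
#' @param ... passed to [dcrawler()].
#' @return A list of class `thd_curve`: `best_th_d`, `best_median_f1`,
#'   `curve` (data.frame `th_d`, `median_f1`, `n_clusters`), and `scores`
#'   (per-neuron scores at the best threshold).
#' @export
optimal_threshold <- function(points, labels, th_grid = seq(0.05, 1, 0.025),
                              ...) {
  ids <- if (inherits(points, "colour_vectors"))
    as.character(points$fragment_id) else
      as.character(seq_len(nrow(as.matrix(points))))
  lab <- if (is.data.frame(labels)) as_fragment_map(labels, "neuron_id")
         else stats::setNames(labels, ids)
  if (length(unique(lab)) < 2)
    stop("optimal threshold is undefined with fewer than 2 neurons")
  rows <- lapply(th_grid, function(th) {
    fit <- dcrawler(points, th_d = th, ...)
    sc <- match_and_score(lab, stats::setNames(fit$cluster, ids))
    list(th_d = th, median_f1 = stats::median(sc$f1),
         n_clusters = nrow(fit$centroids), scores = sc)
  })
  curve <- data.frame(th_d = vapply(rows, `[[`, numeric(1), "th_d"),
                      median_f1 = vapply(rows, `[[`, numeric(1),
                                         "median_f1"),
                      n_clusters = vapply(rows, `[[`, numeric(1),
                                          "n_clusters"))
  best <- which.max(curve$median_f1)            # ties -> smaller th_d
  structure(list(best_th_d = curve$th_d[best],
                 best_median_f1 = curve$median_f1[best],
                 curve = curve, scores = rows[[best]]$scores),
            class = "thd_curve")
}

#' @export
print.thd_curve <- function(x, ...) {
  cat(sprintf("Optimum Th(d) = %g (median F1 = %.3f over %d neurons)\n",
              x$best_th_d, x$best_median_f1, nrow(x$scores)))
  invisible(x)
}

#' @export
plot.thd_curve <- function(x, ...) {
  graphics::plot(x$curve$th_d, x$curve$median_f1, type = "b", pch = 16,
                 xlab = "Th(d)", ylab = "median F1", ...)
  graphics::abline(v = x$best_th_d, lty = 3)
  invisible(x)
}

#' Percent of the ground truth covered by a predicted reconstruction
#'
#' Both trace sets are rasterized on a common voxel grid: the ground truth
#' at its native width, the prediction dilated by `dilation_px` voxels to
#' forgive small misalignments.  The score is
#' `100 * |ground truth AND dilated prediction| / |ground truth|`.
#'
#' @param ground_truth list of `swc_trace` (or [neurite_fragment]) objects.
#' @param predicted list of `swc_trace` (or [neurite_fragment]) objects.
#' @param voxel_size micrometres per voxel (length 3 or scalar).
#' @param dilation_px isotropic dilation of the prediction, in voxels
#'   (default 10).
#' @param dims optional grid extent in voxels; defaults to the bounding
#'   box of both trace sets.
#' @return Percentage in `[0, 100]`.
#' @export
percent_reconstructed <- function(ground_truth, predicted,
                                  voxel_size = c(1, 1, 1),
                                  dilation_px = 10, dims = NULL) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  gt_pts <- lapply(ground_truth, trace_polylines)
  pr_pts <- lapply(predicted, trace_polylines)
  gt_pts <- unlist(gt_pts, recursive = FALSE)
  pr_pts <- unlist(pr_pts, recursive = FALSE)
  if (!length(gt_pts)) stop("ground truth is empty")
  if (is.null(dims)) {
    all_pts <- do.call(rbind, c(gt_pts, pr_pts))
    pad <- (dilation_px + 2) * max(voxel_size) +
      max(all_pts$radius)
    dims <- um_to_index(c(max(all_pts$x), max(all_pts$y),
                          max(all_pts$z)) + pad, voxel_size)
  }
  rast <- function(pieces, extra_um) {
    idx <- lapply(pieces, function(p) {
      p$radius <- p$radius + extra_um
      polyline_voxels(p, dims, voxel_size, clip_warn = FALSE)
    })
    unique(unlist(idx))
  }
  gt_vox <- rast(gt_pts, 0)
  if (!length(gt_vox)) stop("ground truth rasterizes to no voxels")
  pr_vox <- if (length(pr_pts))
    rast(pr_pts, dilation_px * min(voxel_size)) else integer(0)
  100 * length(intersect(gt_vox, pr_vox)) / length(gt_vox)
}

# unbranched polylines (points data.frames) of a trace or fragment
trace_polylines <- function(x) {
  if (inherits(x, "neurite_fragment")) return(list(x$points))
  stopifnot(inherits(x, "swc_trace"))
  frags <- split_at_branches(x, exclude_soma = FALSE)
  lapply(frags, `[[`, "points")
}
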