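#' Quality-control configuration
#'
#' Thresholds for the staged quality control that turns raw neurite
#' fragments into reliable colour vectors:
#'
#' * `snr_threshold`: a channel is kept only if its signal-to-noise ratio
#'   (bright-fragment mean over background median) is at least this
#'   (default 2.5).
#' * `snr_percentile_range`: percentile window of the fragment-intensity
#'   distribution defining "bright" (default 80-100).
#' * `min_length_um`: minimum fragment length, or `"auto"` to derive it
#'   from the data as the shortest sub-fragment length whose colour vectors
#'   still track their parent fragment (median distance at most
#'   `sub_accuracy_d`, default 0.1).
#' * `min_magnitude`: minimum colour-vector magnitude (brightness), or
#'   `"auto"` to pick the smallest cut-off at which fewer than
#'   `inaccuracy_fraction` (default 5%) of sub-fragments are inaccurate
#'   (further than `inaccuracy_d`, default 0.2, from their parent).
#' * `split_d`: fragments are cut where adjacent sub-fragment colour
#'   vectors differ by more than this (default 0.3), catching mis-joined
#'   hybrid fragments.
#'
#' @param snr_threshold minimum per-channel S/N (default 2.5).
#' @param snr_percentile_range two percentiles (default `c(80, 100)`).
#' @param min_length_um micrometres, or `"auto"`.
#' @param sub_accuracy_d length criterion distance (default 0.1).
#' @param inaccuracy_d brightness criterion distance (default 0.2).
#' @param inaccuracy_fraction tolerated inaccurate fraction (default 0.05).
#' @param min_magnitude magnitude cut-off, or `"auto"`.
#' @param split_d colour-change split distance (default 0.3).
#' @param length_grid candidate lengths for the `"auto"` minimum-length
#'   scan, micrometres.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(snr_threshold = 2.5, snr_percentile_range = c(80, 100),
                      min_length_um = "auto", sub_accuracy_d = 0.1,
                      inaccuracy_d = 0.2, inaccuracy_fraction = 0.05,
                      min_magnitude = "auto", split_d = 0.3,
                      length_grid = c(1, 2, 2.5, 3, 4, 5, 7.5, 10, 15, 20)) {
  stopifnot(snr_threshold > 0, length(snr_percentile_range) == 2,
            all(snr_percentile_range >= 0 & snr_percentile_range <= 100),
            sub_accuracy_d > 0, inaccuracy_d > 0,
            inaccuracy_fraction > 0, split_d > 0)
  if (!identical(min_length_um, "auto")) stopifnot(min_length_um > 0)
  if (!identical(min_magnitude, "auto")) stopifnot(min_magnitude >= 0)
  structure(list(snr_threshold = snr_threshold,
                 snr_percentile_range = snr_percentile_range,
                 min_length_um = min_length_um,
                 sub_accuracy_d = sub_accuracy_d,
                 inaccuracy_d = inaccuracy_d,
                 inaccuracy_fraction = inaccuracy_fraction,
                 min_magnitude = min_magnitude, split_d = split_d,
                 length_grid = length_grid),
            class = "qc_config")
}

#' Per-channel signal-to-noise screening
#'
#' For each channel, S/N is the mean fragment intensity within the
#' configured upper percentile window (default 80-100) of that channel's
#' fragment-intensity distribution, divided by the channel's background
#' median.  Channels below the threshold carry no reliable label and are
#' dropped: all downstream colour vectors lose that dimension.
#'
#' @param fragments list of [neurite_fragment]s with `raw_means` sampled.
#' @param background named per-channel background medians (see
#'   [image_background()]).
#' @param config a [qc_config].
#' @return data.frame with columns `channel`, `snr`, `keep`.
#' @export
channel_snr <- function(fragments, background, config = qc_config()) {
  if (length(fragments) < 10)
    warning("fewer than 10 fragments: S/N estimates will be unstable")
  means <- do.call(rbind, lapply(fragments, `[[`, "raw_means"))
  if (is.null(means)) stop("fragments carry no sampled intensities")
  pr <- config$snr_percentile_range / 100
  snr <- vapply(seq_len(ncol(means)), function(ch) {
    v <- means[, ch]
    qs <- stats::quantile(v, pr)
    top <- mean(v[v >= qs[1] & v <= qs[2]])
    if (background[ch] <= 0) {
      warning("background median is 0 in channel ", ch,
              "; treating S/N as infinite")
      return(Inf)
    }
    top / background[ch]
  }, numeric(1))
  keep <- snr >= config$snr_threshold
  if (!any(keep))
    stop("all channels fall below the S/N threshold (",
         config$snr_threshold, "); nothing to analyse")
  data.frame(channel = colnames(means) %||% seq_along(snr),
             snr = snr, keep = keep)
}

# Colour vectors from raw channel means: subtract background medians, clip
# at zero, scale each channel by its maximum over the fragment set, then
# unit-normalize.  Shared by QC stages and the final computation.
raw_means_to_vectors <- function(means, background, channel_max = NULL) {
  adj <- sweep(means, 2, background, "-")
  adj[adj < 0] <- 0
  if (is.null(channel_max)) {
    channel_max <- apply(adj, 2, max)
    if (any(channel_max <= 0))
      stop("per-channel maximum is 0 for channel(s) ",
           paste(which(channel_max <= 0), collapse = ", "),
           ": a dead channel slipped past the S/N screen")
  }
  scaled <- sweep(adj, 2, pmax(channel_max, 1e-12), "/")
  list(vectors = vector_normalize(scaled), channel_max = channel_max)
}

# distance between each sub-fragment's colour vector and its parent's,
# for pieces of length L; needs the image to sample sub-fragment means
subfragment_distances <- function(fragments, img, L, background,
                                  kept = NULL) {
  pieces <- list(); parent_of <- integer(0)
  for (i in seq_along(fragments)) {
    for (p in subdivide_fragment(fragments[[i]], L)) {
      pieces[[length(pieces) + 1L]] <- sample_fragment_intensities(p, img)
      parent_of <- c(parent_of, i)
    }
  }
  pm <- do.call(rbind, lapply(pieces, `[[`, "raw_means"))
  fm <- do.call(rbind, lapply(fragments, `[[`, "raw_means"))
  if (!is.null(kept)) { pm <- pm[, kept, drop = FALSE]
                        fm <- fm[, kept, drop = FALSE]
                        background <- background[kept] }
  # one shared per-channel scale so piece and parent are comparable
  both <- raw_means_to_vectors(rbind(fm, pm), background)
  nv <- both$vectors$values
  fv <- nv[seq_len(nrow(fm)), , drop = FALSE]
  pv <- nv[-seq_len(nrow(fm)), , drop = FALSE]
  data.frame(parent = parent_of,
             d = sqrt(rowSums((pv - fv[parent_of, , drop = FALSE])^2)),
             magnitude = both$vectors$magnitude[-seq_len(nrow(fm))],
             piece_length = vapply(pieces, `[[`, numeric(1), "length_um"))
}

#' Determine the minimum reliable fragment length
#'
#' Colour vectors of very short fragments fluctuate: sub-dividing fragments
#' into pieces of decreasing length and measuring the colour distance *d*
#' from each piece to its parent fragment shows *d* rising as pieces
#' shrink.  The minimum length is the smallest candidate length whose
#' median piece-to-parent distance stays at or below `sub_accuracy_d`.
#'
#' @param fragments list of sampled [neurite_fragment]s.
#' @param img the [channel_image] the fragments were sampled from.
#' @param background per-channel background medians.
#' @param config a [qc_config] (supplies the candidate grid and criterion).
#' @param kept logical vector of channels retained by [channel_snr()].
#' @return A list: `min_length_um` and `curve` (data.frame of length vs
#'   median distance).
#' @export
determine_min_length <- function(fragments, img, background,
                                 config = qc_config(), kept = NULL) {
  grid <- sort(config$length_grid)
  med <- vapply(grid, function(L) {
    sd <- subfragment_distances(fragments, img, L, background, kept)
    # whole fragments shorter than L pass through subdivision untouched
    # (d = 0 by construction); they must not dilute the median
    stats::median(sd$d[sd$piece_length >= L * 0.99])
  }, numeric(1))
  ok <- which(med <= config$sub_accuracy_d)
  if (!length(ok)) {
    warning("no candidate length meets the accuracy criterion; ",
            "using the largest grid value")
    ok <- length(grid)
  }
  list(min_length_um = grid[min(ok)],
       curve = data.frame(length_um = grid, median_d = med))
}

#' Determine the minimum colour-vector magnitude (brightness)
#'
#' Dim fragments produce proportionally inaccurate colour vectors.  After
#' cutting fragments into minimum-length pieces, a piece is *inaccurate*
#' when its colour vector sits further than `inaccuracy_d` from its
#' parent's.  Scanning magnitude cut-offs from dim to bright, the minimum
#' magnitude is the smallest cut-off at which fewer than
#' `inaccuracy_fraction` of the surviving pieces are inaccurate.
#'
#' @inheritParams determine_min_length
#' @param min_length_um piece length for the scan.
#' @return A list: `min_magnitude` and `scan` (cut-off vs inaccurate
#'   fraction).
#' @export
determine_min_brightness <- function(fragments, img, background,
                                     min_length_um, config = qc_config(),
                                     kept = NULL) {
  sd <- subfragment_distances(fragments, img, min_length_um, background,
                              kept)
  inaccurate <- sd$d > config$inaccuracy_d
  cutoffs <- sort(unique(c(0, sd$magnitude)))
  frac <- vapply(cutoffs, function(m) {
    sel <- sd$magnitude >= m
    if (!any(sel)) return(0)
    mean(inaccurate[sel])
  }, numeric(1))
  ok <- which(frac < config$inaccuracy_fraction)
  if (!length(ok)) {
    warning("brightness criterion unreachable; using the maximum ",
            "observed magnitude")
    return(list(min_magnitude = max(sd$magnitude),
                scan = data.frame(cutoff = cutoffs,
                                  inaccurate_fraction = frac)))
  }
  list(min_magnitude = cutoffs[min(ok)],
       scan = data.frame(cutoff = cutoffs, inaccurate_fraction = frac))
}

#' Split fragments where the colour changes abruptly
#'
#' A fragment whose colour hue jumps in the middle is most likely a wrong
#' hybrid of two crossing neurites mis-joined by the tracing software.  The
#' fragment is scanned in adjacent minimum-length sub-fragments and cut at
#' every boundary where the adjacent colour vectors differ by more than
#' `split_d`.  Fragments shorter than two minimum lengths pass through
#' unchanged.
#'
#' @param frag a sampled [neurite_fragment].
#' @param img the source [channel_image].
#' @param background per-channel background medians.
#' @param min_length_um sub-fragment length.
#' @param config a [qc_config] (supplies `split_d`).
#' @param kept logical vector of retained channels.
#' @param channel_max per-channel scale of the surrounding dataset (from
#'   [compute_colour_vectors()]); defaults to the maxima over this
#'   fragment's own pieces.
#' @return List of [neurite_fragment]s (possibly just the input), each with
#'   freshly sampled `raw_means`.
#' @export
split_colour_changes <- function(frag, img, background, min_length_um,
                                 config = qc_config(), kept = NULL,
                                 channel_max = NULL) {
  if (frag$length_um < 2 * min_length_um) return(list(frag))
  pieces <- lapply(subdivide_fragment(frag, min_length_um),
                   sample_fragment_intensities, img = img)
  pm <- do.call(rbind, lapply(pieces, `[[`, "raw_means"))
  if (!is.null(kept)) pm <- pm[, kept, drop = FALSE]
  pv <- raw_means_to_vectors(pm, if (is.null(kept)) background
                             else background[kept],
                             channel_max = channel_max)$vectors$values
  gap <- sqrt(rowSums((pv[-1, , drop = FALSE] -
                       pv[-nrow(pv), , drop = FALSE])^2))
  cut_after <- which(gap > config$split_d)
  if (!length(cut_after)) return(list(frag))
  groups <- cumsum(c(1L, as.integer(seq_len(length(pieces) - 1L) %in%
                                      cut_after)))
  out <- lapply(split(seq_along(pieces), groups), function(ix) {
    pts <- do.call(rbind, lapply(pieces[ix], function(p)
      p$points))
    pts <- pts[!duplicated(round(pts[, c("x", "y", "z")], 9)), ]
    sample_fragment_intensities(
      neurite_fragment(pts,
                       fragment_id = paste0(frag$fragment_id, "s",
                                            ix[1]),
                       neuron_id = frag$neuron_id), img)
  })
  unname(out)
}

#' Final colour-vector computation
#'
#' Converts the raw per-channel fragment means that survived quality
#' control into colour vectors: subtract the per-channel background median,
#' clip negatives to zero, scale each channel by its maximum over the
#' surviving fragment set (so jointly processed datasets share one scale),
#' and unit-normalize.  The pre-normalization norm is kept as the
#' magnitude.
#'
#' @param fragments list of sampled [neurite_fragment]s.
#' @param background per-channel background medians.
#' @param kept logical vector of channels retained by [channel_snr()]
#'   (default: all).
#' @return A [colour_vectors] object, one row per fragment.
#' @export
compute_colour_vectors <- function(fragments, background, kept = NULL) {
  means <- do.call(rbind, lapply(fragments, `[[`, "raw_means"))
  if (is.null(means)) stop("fragments carry no sampled intensities")
  if (!is.null(kept)) {
    means <- means[, kept, drop = FALSE]
    background <- background[kept]
  }
  res <- raw_means_to_vectors(means, background)
  cv <- res$vectors
  cv$fragment_id <- vapply(fragments, function(f)
    as.character(f$fragment_id), character(1))
  cv$length_um <- vapply(fragments, `[[`, numeric(1), "length_um")
  cv$channels <- colnames(means) %||% cv$channels
  colnames(cv$values) <- cv$channels
  attr(cv, "channel_max") <- res$channel_max
  cv
}

#' Run the full quality-control pipeline
#'
#' Applies, in order: per-channel S/N screening (dropping unreliable
#' channels), the minimum-length filter, the minimum-brightness filter,
#' colour-change splitting, and the final colour-vector computation.
#' Thresholds set to `"auto"` in the configuration are derived from the
#' data; the report records every threshold used and the number of
#' fragments dropped at each stage.
#'
#' @param fragments list of [neurite_fragment]s (sampled or not; unsampled
#'   fragments are sampled from `img` first).
#' @param img the [channel_image] fragments were traced on.
#' @param config a [qc_config].
#' @return A list of class `qc_result`: `vectors` (a [colour_vectors]),
#'   `fragments` (the survivors), and `report`.
#' @export
run_qc <- function(fragments, img, config = qc_config()) {
  report <- list(n_input = length(fragments), config = config)
  if (!length(fragments)) {
    return(structure(list(vectors = NULL, fragments = list(),
                          report = c(report, list(empty = TRUE))),
                     class = "qc_result"))
  }
  needs <- vapply(fragments, function(f) is.null(f$raw_means), logical(1))
  fragments[needs] <- lapply(fragments[needs], sample_fragment_intensities,
                             img = img)
  background <- image_background(img, fragments)
  report$background <- background

  snr <- channel_snr(fragments, background, config)
  kept <- snr$keep
  report$snr <- snr

  if (identical(config$min_length_um, "auto")) {
    ml <- determine_min_length(fragments, img, background, config, kept)
    min_len <- ml$min_length_um
    report$min_length_curve <- ml$curve
  } else min_len <- config$min_length_um
  report$min_length_um <- min_len
  long_enough <- vapply(fragments, function(f) f$length_um >= min_len,
                        logical(1))
  report$n_dropped_short <- sum(!long_enough)
  fragments <- fragments[long_enough]
  if (!length(fragments)) stop("no fragments pass the minimum length")

  if (identical(config$min_magnitude, "auto")) {
    mb <- determine_min_brightness(fragments, img, background, min_len,
                                   config, kept)
    min_mag <- mb$min_magnitude
    report$brightness_scan <- mb$scan
  } else min_mag <- config$min_magnitude
  report$min_magnitude <- min_mag
  cv_pre <- compute_colour_vectors(fragments, background, kept)
  bright <- cv_pre$magnitude >= min_mag
  report$n_dropped_dim <- sum(!bright)
  fragments <- fragments[bright]
  if (!length(fragments)) stop("no fragments pass the minimum brightness")

  split_out <- lapply(fragments, split_colour_changes, img = img,
                      background = background, min_length_um = min_len,
                      config = config, kept = kept,
                      channel_max = attr(cv_pre, "channel_max"))
  report$n_split <- sum(lengths(split_out) > 1L)
  fragments <- unlist(split_out, recursive = FALSE)
  # splitting can create pieces below the thresholds; re-apply both filters
  keep2 <- vapply(fragments, function(f) f$length_um >= min_len, logical(1))
  fragments <- fragments[keep2]
  mags2 <- compute_colour_vectors(fragments, background, kept)$magnitude
  fragments <- fragments[mags2 >= min_mag]
  report$n_output <- length(fragments)

  vectors <- compute_colour_vectors(fragments, background, kept)
  structure(list(vectors = vectors, fragments = fragments,
                 report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("Quality control:", r$n_input, "fragments in")
  if (isTRUE(r$empty)) { cat(" (empty input)\n"); return(invisible(x)) }
  cat(",", r$n_output, "colour vectors out\n")
  cat(sprintf("  channels kept: %d/%d (S/N >= %g)\n", sum(r$snr$keep),
              nrow(r$snr), r$config$snr_threshold))
  cat(sprintf("  min length %g um (dropped %d), min magnitude %g (dropped %d), %d fragment(s) split\n",
              r$min_length_um, r$n_dropped_short, r$min_magnitude,
              r$n_dropped_dim, r$n_split))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param x a `qc_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  r <- x$report
  out <- list(n_input = r$n_input, n_output = r$n_output,
              background = as.list(r$background),
              snr = r$snr, min_length_um = r$min_length_um,
              min_magnitude = r$min_magnitude,
              n_dropped_short = r$n_dropped_short,
              n_dropped_dim = r$n_dropped_dim, n_split = r$n_split,
              thresholds = r$config[c("snr_threshold", "sub_accuracy_d",
                                      "inaccuracy_d",
                                      "inaccuracy_fraction", "split_d")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
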