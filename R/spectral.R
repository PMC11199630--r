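#' Multichannel 3-D fluorescence volume
#'
#' Container for an N-channel image stack: a 4-D numeric array indexed
#' `[x, y, z, channel]`, voxel size in micrometres, and channel labels.
#' `NA` voxels mark saturated (discarded) intensities.
#'
#' @param voxels numeric array, either 3-D (single channel) or 4-D
#'   `[x, y, z, channel]`.
#' @param voxel_size numeric length-3, micrometres per voxel along x, y, z.
#' @param channels channel labels.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(voxels, voxel_size = c(1, 1, 1), channels = NULL) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 4L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (is.null(channels)) channels <- paste0("ch_", seq_len(dim(voxels)[4]))
  stopifnot(length(channels) == dim(voxels)[4])
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 channels = channels),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Channel image: %d x %d x %d voxels, %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %g x %g x %g um; %d saturated voxel(s)\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              sum(is.na(x$voxels))))
  invisible(x)
}

n_channels <- function(img) dim(img$voxels)[4]

#' Read / write multichannel TIFF volumes
#'
#' Volumes are stored as 32-bit float TIFF stacks with slices ordered
#' channel-fastest (`z1c1, z1c2, ..., z2c1, ...`), the interleaved
#' hyperstack convention.  TIFF samples are kept in `[0, 1]`, so
#' intensities are scaled down on write; a JSON sidecar
#' (`<path>.json`) records the scale, the saturated-voxel (`NA`)
#' encoding, the voxel size and the channel labels, and is consulted on
#' read when present.  A set of one single-channel stack per file is also
#' read (`read_channel_image` with a vector of paths).
#'
#' @param img a [channel_image].
#' @param path file path (`.tif`); for reading, one path (hyperstack) or a
#'   vector of per-channel paths.
#' @param n_channels channel count of an interleaved hyperstack (ignored
#'   when a sidecar is present).
#' @param voxel_size,channels metadata to attach when no sidecar exists.
#' @return `read_channel_image` returns a [channel_image];
#'   `write_channel_image` returns `path` invisibly.
#' @export
write_channel_image <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  d <- dim(img$voxels)
  vox <- img$voxels
  scale <- max(vox, 0, na.rm = TRUE)
  if (scale <= 0) scale <- 1
  # data occupies [0, 0.98]; exactly 1.0 encodes a saturated (NA) voxel
  vox <- vox / scale * 0.98
  vox[is.na(vox)] <- 1
  slices <- vector("list", d[3] * d[4])
  k <- 1L
  for (z in seq_len(d[3])) for (ch in seq_len(d[4])) {
    # tiff slices are row-major matrices: rows = y, cols = x
    slices[[k]] <- t(vox[, , z, ch])
    k <- k + 1L
  }
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, data_max = 0.98, na_value = 1,
         n_channels = d[4], voxel_size = img$voxel_size,
         channels = img$channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path, n_channels = 1L, voxel_size = c(1, 1, 1),
                               channels = NULL) {
  if (length(path) > 1L) {          # one single-channel stack per file
    per_ch <- lapply(path, function(p)
      read_channel_image(p, 1L, voxel_size)$voxels)
    vox <- array(unlist(per_ch), c(dim(per_ch[[1]])[1:3], length(path)))
    return(channel_image(vox, voxel_size, channels))
  }
  meta <- NULL
  if (file.exists(paste0(path, ".json"))) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n_channels <- meta$n_channels
    voxel_size <- meta$voxel_size
    channels <- meta$channels
  }
  slices <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(slices)) slices <- list(slices)
  n_ch <- as.integer(n_channels)
  stopifnot(length(slices) %% n_ch == 0L)
  nz <- length(slices) %/% n_ch
  dimxy <- dim(slices[[1]])
  vox <- array(NA_real_, c(dimxy[2], dimxy[1], nz, n_ch))
  k <- 1L
  for (z in seq_len(nz)) for (ch in seq_len(n_ch)) {
    vox[, , z, ch] <- t(slices[[k]])
    k <- k + 1L
  }
  if (!is.null(meta)) {
    sat <- vox > (meta$data_max + meta$na_value) / 2
    vox <- vox / meta$data_max * meta$scale
    vox[sat] <- NA_real_
  }
  channel_image(vox, voxel_size, channels)
}

#' Detector linearity coefficients
#'
#' Parameters of the intensity linearization `y = a*x + b*exp(c*x) - b`
#' mapping measured detector counts `x` to linearized intensities `y`.
#' Photon-counting detectors under-report at high count rates; the
#' exponential term restores the linear relationship, and counts above
#' `saturation_cutoff` are considered unrecoverable and are discarded
#' (set to `NA`) rather than corrected.
#'
#' @param a linear gain.
#' @param b exponential amplitude.
#' @param c exponential rate (per intensity unit), `>= 0`.
#' @param saturation_cutoff measured intensity above which voxels are
#'   discarded.
#' @return An object of class `linearity_coefficients`.
#' @export
linearity_coefficients <- function(a, b, c, saturation_cutoff) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), c >= 0,
            saturation_cutoff > 0)
  # monotone on [0, cutoff]: y' = a + b*c*exp(c*x) > 0 at both ends
  dy0 <- a + b * c
  dy1 <- a + b * c * exp(c * saturation_cutoff)
  if (dy0 <= 0 || dy1 <= 0)
    stop("correction is not monotonically increasing on [0, cutoff]")
  structure(list(a = a, b = b, c = c,
                 saturation_cutoff = saturation_cutoff),
            class = "linearity_coefficients")
}

#' @export
print.linearity_coefficients <- function(x, ...) {
  cat(sprintf("Linearity correction: y = %.4g*x + %.4g*(exp(%.4g*x) - 1); cutoff %g\n",
              x$a, x$b, x$c, x$saturation_cutoff))
  invisible(x)
}

#' Evaluate the linearity correction
#'
#' @param x measured intensities (any numeric array).
#' @param coeffs a [linearity_coefficients] object.
#' @return Corrected intensities; values above the saturation cutoff are
#'   `NA`.
#' @examples
#' co <- linearity_coefficients(0.9838, 1.1044, 0.001, 7000)
#' linearity_transform(0, co)      # exactly 0
#' linearity_transform(7000, co)   # ~8096.6
#' @export
linearity_transform <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "linearity_coefficients"))
  y <- coeffs$a * x + coeffs$b * exp(coeffs$c * x) - coeffs$b
  y[x > coeffs$saturation_cutoff] <- NA_real_
  y
}

#' Fit detector linearity from a laser-power calibration series
#'
#' A bright, photostable specimen is imaged at a series of relative laser
#' powers.  Powers inside `linear_range` are assumed to drive the detector
#' in its linear regime; a per-pixel straight-line fit (through the origin)
#' over that range predicts the *true* intensity each pixel should have
#' shown at every power.  The pooled (measured, predicted) pairs are then
#' fit by least squares to `predicted = a*measured + b*exp(c*measured) - b`.
#' The saturation cutoff is the smallest measured intensity at which the
#' fit's relative residual exceeds `max_rel_error` (defaulting to the
#' largest measured value when the fit holds everywhere).
#'
#' @param measured numeric matrix, pixels x powers, measured intensities.
#' @param powers relative laser powers, one per column.
#' @param linear_range powers (a subset of `powers`, at least 3) treated as
#'   linear for the per-pixel trend.
#' @param max_rel_error relative residual tolerance defining the usable
#'   range (default 0.1).
#' @param start optional starting values `list(a=, b=, c=)` for the
#'   nonlinear fit.
#' @return A [linearity_coefficients] object with attribute `"fit"` holding
#'   pooled residual diagnostics.
#' @export
fit_linearity <- function(measured, powers, linear_range,
                          max_rel_error = 0.1, start = NULL) {
  measured <- as.matrix(measured)
  stopifnot(ncol(measured) == length(powers))
  in_lin <- powers %in% linear_range
  if (sum(in_lin) < 3)
    stop("need at least 3 power levels inside linear_range")
  if (mean(diff(colMeans(measured)[order(powers)]) >= 0) < 0.5)
    stop("calibration series is not monotone non-decreasing in power ",
         "on average: check acquisition order / bleaching")
  # per-pixel linear trend through the origin over the linear range
  p_lin <- powers[in_lin]
  slope <- as.numeric(measured[, in_lin, drop = FALSE] %*% p_lin) /
    sum(p_lin^2)
  cm <- colMeans(measured)[order(powers)]
  if (all(slope <= 0) || cm[length(cm)] - cm[1] <= 0)
    stop("degenerate calibration: no signal growth across powers")
  predicted <- outer(slope, powers)          # true intensity at each power
  df <- data.frame(x = as.numeric(measured), y = as.numeric(predicted))
  df <- df[is.finite(df$x) & is.finite(df$y), ]
  if (is.null(start)) start <- list(a = 1, b = 1, c = 1e-4)
  fit <- minpack.lm::nlsLM(y ~ a * x + b * exp(c * x) - b, data = df,
                           start = start,
                           lower = c(a = 0, b = 0, c = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid_rel <- abs(stats::resid(fit)) / pmax(abs(df$y), 1e-12)
  bad <- df$x[resid_rel > max_rel_error & df$x > 0]
  cutoff <- if (length(bad)) min(bad) else max(df$x)
  out <- linearity_coefficients(cf[["a"]], cf[["b"]], cf[["c"]], cutoff)
  attr(out, "fit") <- list(rse = summary(fit)$sigma,
                           max_rel_error = max_rel_error,
                           n_points = nrow(df))
  out
}

#' Apply linearity correction to a multichannel volume
#'
#' Every voxel at or below the saturation cutoff is mapped through the
#' correction curve; voxels above it are discarded (`NA`), as they are
#' saturated beyond recovery and would otherwise corrupt the channel
#' ratios that unmixing relies on.
#'
#' @param img a [channel_image] of measured intensities.
#' @param coeffs a [linearity_coefficients] object.
#' @return A corrected [channel_image].
#' @export
apply_linearity_correction <- function(img, coeffs) {
  stopifnot(inherits(img, "channel_image"))
  out <- img
  out$voxels <- linearity_transform(img$voxels, coeffs)
  attr(out, "linearity_corrected") <- TRUE
  out
}

#' Spectral reference for linear unmixing
#'
#' Per-excitation-group mixing matrices.  Each group names a laser, the
#' detection channels read out under that laser, the fluorophores excited,
#' and a channels x fluorophores mixing matrix whose columns (one per
#' fluorophore, L1-normalized) give the fraction of that fluorophore's
#' emission landing in each in-group channel.  Channels belong to exactly
#' one group; bleed-through across lasers is taken as zero.
#'
#' @param groups list of groups, each a list with elements `laser`
#'   (label), `channels` (integer indices into the image channels),
#'   `fluorophores` (labels) and `M` (mixing matrix).
#' @return An object of class `spectral_reference`.
#' @export
spectral_reference <- function(groups) {
  seen <- integer(0)
  for (g in groups) {
    stopifnot(!is.null(g$channels), !is.null(g$M))
    M <- as.matrix(g$M)
    if (any(M < 0)) stop("mixing matrix entries must be non-negative")
    if (any(abs(colSums(M) - 1) > 1e-6))
      stop("mixing matrix columns must be L1-normalized")
    if (nrow(M) != length(g$channels))
      stop("mixing matrix rows must match group channels")
    if (any(g$channels %in% seen))
      stop("channels may appear in exactly one excitation group")
    seen <- c(seen, g$channels)
  }
  structure(list(groups = groups), class = "spectral_reference")
}

#' @export
print.spectral_reference <- function(x, ...) {
  cat("Spectral reference:", length(x$groups), "excitation group(s)\n")
  for (g in x$groups)
    cat(sprintf("  %s: channels [%s] -> fluorophores [%s]\n",
                g$laser %||% "?", paste(g$channels, collapse = ","),
                paste(g$fluorophores, collapse = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a spectral reference to / from YAML
#'
#' @param ref a [spectral_reference].
#' @param path YAML file path.
#' @return `read_spectral_reference` returns a [spectral_reference];
#'   `write_spectral_reference` returns `path` invisibly.
#' @export
write_spectral_reference <- function(ref, path) {
  lst <- lapply(ref$groups, function(g)
    list(laser = g$laser, channels = as.integer(g$channels),
         fluorophores = g$fluorophores,
         M = apply(as.matrix(g$M), 1, as.numeric, simplify = FALSE)))
  yaml::write_yaml(list(groups = lst), path)
  invisible(path)
}

#' @rdname write_spectral_reference
#' @export
read_spectral_reference <- function(path) {
  raw <- yaml::read_yaml(path)
  groups <- lapply(raw$groups, function(g) {
    g$M <- do.call(rbind, lapply(g$M, as.numeric))
    g
  })
  spectral_reference(groups)
}

#' Build a mixing matrix from single-fluorophore reference images
#'
#' Reference volumes are acquired from cells expressing one fluorophore
#' each.  For each fluorophore, foreground voxels are selected as the top
#' `foreground_fraction` of total in-group intensity; the per-channel
#' background (median of the remaining voxels) is subtracted and the mean
#' foreground intensity per channel, clipped at zero and L1-normalized,
#' becomes that fluorophore's column of the group's mixing matrix.
#'
#' @param reference_images named list (one per fluorophore, in group order)
#'   of [channel_image]s covering that fluorophore's excitation-group
#'   channels.
#' @param group_layout list of groups, each with `laser`, `channels` and
#'   `fluorophores` (names indexing into `reference_images`).
#' @param foreground_fraction fraction of voxels treated as foreground
#'   (default 0.1).
#' @return A [spectral_reference].
#' @export
build_mixing_matrix <- function(reference_images, group_layout,
                                foreground_fraction = 0.1) {
  groups <- lapply(group_layout, function(g) {
    cols <- lapply(g$fluorophores, function(fl) {
      img <- reference_images[[fl]]
      if (is.null(img)) stop("no reference image for fluorophore ", fl)
      vox <- img$voxels
      stopifnot(dim(vox)[4] == length(g$channels))
      flat <- matrix(vox, ncol = dim(vox)[4])   # voxels x channels
      flat <- flat[stats::complete.cases(flat), , drop = FALSE]
      total <- rowSums(flat)
      thr <- stats::quantile(total, 1 - foreground_fraction)
      fg <- total > thr
      if (!any(fg) || thr <= 0)
        stop("reference for fluorophore ", fl,
             " has no foreground above the background percentile")
      bg <- apply(flat[!fg, , drop = FALSE], 2, stats::median)
      col <- pmax(colMeans(flat[fg, , drop = FALSE]) - bg, 0)
      if (sum(col) <= 0)
        stop("reference for fluorophore ", fl, " has no net signal")
      col / sum(col)
    })
    M <- do.call(cbind, cols)
    colnames(M) <- g$fluorophores
    if (ncol(M) > 1) {
      cd <- as.matrix(stats::dist(t(M)))
      diag(cd) <- Inf
      if (min(cd) < 1e-3)
        warning("near-identical reference columns in group ",
                g$laser %||% "?", ": unmixing will be rank-deficient")
    }
    list(laser = g$laser, channels = g$channels,
         fluorophores = g$fluorophores, M = M)
  })
  spectral_reference(groups)
}

#' Linear unmixing of a multichannel volume
#'
#' For every voxel and every excitation group, solves the linear system
#' `M %*% u ~ s` for fluorophore abundances `u` given the measured
#' in-group channel signals `s` (square groups: direct solve; otherwise
#' least squares), then clips negative abundances to zero.  Optionally a
#' non-negative least-squares solve is used instead of clipping.  Voxels
#' discarded as saturated (`NA`) in any in-group channel propagate `NA` to
#' all of that group's fluorophores.
#'
#' Linearity correction should already have been applied; a warning is
#' emitted otherwise.
#'
#' @param img a [channel_image] whose channels cover all group channels.
#' @param ref a [spectral_reference].
#' @param method `"clip"` (default) or `"nnls"`.
#' @return A [channel_image] with one channel per fluorophore.
#' @export
unmix <- function(img, ref, method = c("clip", "nnls")) {
  method <- match.arg(method)
  stopifnot(inherits(img, "channel_image"),
            inherits(ref, "spectral_reference"))
  if (is.null(attr(img, "linearity_corrected")))
    warning("input image has not been linearity-corrected; ",
            "channel ratios may be distorted")
  d <- dim(img$voxels)
  flu_names <- unlist(lapply(ref$groups, `[[`, "fluorophores"))
  out <- array(NA_real_, c(d[1:3], length(flu_names)))
  off <- 0L
  for (g in ref$groups) {
    M <- as.matrix(g$M)
    if (nrow(M) == ncol(M) &&
        abs(det(M)) < 1e-12)
      stop("singular mixing matrix in group ", g$laser %||% "?",
           ": redesign the reference (fluorophores not separable)")
    s <- matrix(img$voxels[, , , g$channels, drop = FALSE],
                ncol = length(g$channels))        # voxels x channels
    ok <- stats::complete.cases(s)
    u <- matrix(NA_real_, nrow(s), ncol(M))
    if (any(ok)) {
      if (method == "nnls") {
        if (!requireNamespace("pracma", quietly = TRUE))
          stop("method = \"nnls\" requires the pracma package")
        sv <- s[ok, , drop = FALSE]
        u[ok, ] <- t(apply(sv, 1, function(r)
          pracma::lsqnonneg(M, r)$x))
      } else {
        sol <- if (nrow(M) == ncol(M)) solve(M, t(s[ok, , drop = FALSE]))
               else qr.solve(M, t(s[ok, , drop = FALSE]))
        u[ok, ] <- pmax(t(sol), 0)
      }
    }
    out[, , , off + seq_len(ncol(M))] <- array(u, c(d[1:3], ncol(M)))
    off <- off + ncol(M)
  }
  res <- channel_image(out, img$voxel_size, flu_names)
  attr(res, "linearity_corrected") <- attr(img, "linearity_corrected")
  res
}

#' Forward-mix per-fluorophore abundances into channel signals
#'
#' The inverse operation of [unmix()], used for round-trip validation and
#' phantom construction: channel signal `s = M %*% u` within each
#' excitation group.
#'
#' @param abundances a [channel_image] with one channel per fluorophore (in
#'   group order).
#' @param ref a [spectral_reference].
#' @return A [channel_image] with one channel per detection channel.
#' @export
mix <- function(abundances, ref) {
  stopifnot(inherits(abundances, "channel_image"))
  d <- dim(abundances$voxels)
  n_ch <- max(unlist(lapply(ref$groups, `[[`, "channels")))
  out <- array(0, c(d[1:3], n_ch))
  off <- 0L
  for (g in ref$groups) {
    M <- as.matrix(g$M)
    u <- matrix(abundances$voxels[, , , off + seq_len(ncol(M)), drop = FALSE],
                ncol = ncol(M))
    s <- u %*% t(M)
    out[, , , g$channels] <- array(s, c(d[1:3], nrow(M)))
    off <- off + ncol(M)
  }
  channel_image(out, abundances$voxel_size)
}
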