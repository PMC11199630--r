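#' Read neuron morphologies from an SWC file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; '#' comment lines) into one trace per connected tree.  A trace is
#' a `data.frame` with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#' `parent` (coordinates and radii in micrometres; `parent == -1` marks a
#' root) and class `swc_trace`.  Type code 1 marks soma points.
#'
#' @param path SWC file path.
#' @return A list of `swc_trace` data frames, one per tree root.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (!length(lineno)) stop("SWC file contains no sample lines")
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], ": expected 7 columns")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(!is.finite(m)))
    stop("non-numeric value on SWC line ",
         lineno[which(rowSums(!is.finite(m)) > 0)[1]])
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                   parent = as.integer(m[, 7]))
  if (anyDuplicated(df$id))
    stop("duplicate SWC sample id on line ",
         lineno[which(duplicated(df$id))[1]])
  if (any(df$radius <= 0))
    stop("non-positive radius on SWC line ", lineno[which(df$radius <= 0)[1]])
  dangling <- df$parent != -1L & !(df$parent %in% df$id)
  if (any(dangling))
    stop("dangling parent reference on SWC line ", lineno[which(dangling)[1]])
  # forward references break the "parents precede children" convention
  pos <- match(df$parent, df$id)
  fwd <- which(df$parent != -1L & pos > seq_len(nrow(df)))
  if (length(fwd))
    stop("parent defined after child on SWC line ", lineno[fwd[1]])
  # split into connected trees by walking each sample up to its root
  root_of <- integer(nrow(df))
  for (i in seq_len(nrow(df)))
    root_of[i] <- if (df$parent[i] == -1L) i else root_of[pos[i]]
  lapply(unique(root_of), function(r) {
    tr <- df[root_of == r, , drop = FALSE]
    rownames(tr) <- NULL
    class(tr) <- c("swc_trace", "data.frame")
    tr
  })
}

#' Write neuron morphologies to an SWC file
#'
#' Samples are renumbered consecutively across traces; topology,
#' coordinates, radii and type labels are preserved so that a
#' read/write/read round trip is lossless.
#'
#' @param traces a single `swc_trace` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(traces, path) {
  if (inherits(traces, "swc_trace")) traces <- list(traces)
  offset <- 0L
  rows <- lapply(traces, function(tr) {
    new_id <- seq_len(nrow(tr)) + offset
    new_parent <- ifelse(tr$parent == -1L, -1L,
                         new_id[match(tr$parent, tr$id)])
    offset <<- offset + nrow(tr)
    sprintf("%d %d %.6f %.6f %.6f %.6f %d",
            new_id, tr$type, tr$x, tr$y, tr$z, tr$radius, new_parent)
  })
  writeLines(c("# SWC written by qdyefinder", unlist(rows)), path)
  invisible(path)
}

# ids of points with >= 2 children (branch points)
branch_point_ids <- function(trace) {
  kids <- table(trace$parent[trace$parent != -1L])
  as.integer(names(kids)[kids >= 2L])
}

#' Neurite fragment
#'
#' An unbranched piece of a traced neurite: an ordered run of 3-D points
#' with radii, its arc length, and (once sampled from an image) per-channel
#' mean raw intensities.  Fragments are the regions of interest from which
#' colour vectors are computed.
#'
#' @param points data.frame with columns `x`, `y`, `z`, `radius` (um).
#' @param fragment_id identifier.
#' @param neuron_id optional ground-truth neuron label.
#' @param raw_means optional per-channel mean raw intensities.
#' @return An object of class `neurite_fragment`.
#' @export
neurite_fragment <- function(points, fragment_id = NA, neuron_id = NA,
                             raw_means = NULL) {
  stopifnot(all(c("x", "y", "z", "radius") %in% names(points)),
            nrow(points) >= 2L)
  len <- polyline_length(points)
  if (len <= 0) stop("fragment must have positive length")
  structure(list(fragment_id = fragment_id, points = points,
                 length_um = len, neuron_id = neuron_id,
                 raw_means = raw_means),
            class = "neurite_fragment")
}

#' @export
print.neurite_fragment <- function(x, ...) {
  cat(sprintf("Neurite fragment %s: %d points, %.2f um",
              format(x$fragment_id), nrow(x$points), x$length_um))
  if (!is.na(x$neuron_id)) cat(sprintf(" (neuron %s)", format(x$neuron_id)))
  cat("\n")
  invisible(x)
}

polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(diff(points$x)^2 + diff(points$y)^2 + diff(points$z)^2))
}

#' Split a trace into unbranched fragments
#'
#' Automated tracing frequently mis-joins neurites at branch and crossing
#' points, so traces are broken into unbranched fragments there: every edge
#' run between a root, branch point or leaf becomes one fragment, with
#' branch points duplicated as endpoints of each incident fragment.  Soma
#' points (SWC type 1) are excluded by default, as soma signal is beyond
#' the linear intensity range.
#'
#' @param trace an `swc_trace`.
#' @param exclude_soma drop soma-labelled points and their incident edges
#'   (default `TRUE`).
#' @param neuron_id optional neuron label stamped on every fragment.
#' @param id_prefix prefix for generated fragment ids.
#' @return A list of [neurite_fragment]s partitioning the (non-soma) edges.
#' @export
split_at_branches <- function(trace, exclude_soma = TRUE, neuron_id = NA,
                              id_prefix = "frag") {
  stopifnot(inherits(trace, "swc_trace"))
  tr <- trace
  edges <- tr[tr$parent != -1L, c("id", "parent")]
  if (exclude_soma) {
    soma <- tr$id[tr$type == 1L]
    edges <- edges[!(edges$id %in% soma) & !(edges$parent %in% soma), ,
                   drop = FALSE]
  }
  if (!nrow(edges)) return(list())
  # children map restricted to surviving edges
  kids <- split(edges$id, factor(edges$parent, levels = tr$id))
  n_kids <- lengths(kids)[match(tr$id, tr$id)]
  names(n_kids) <- tr$id
  has_parent_edge <- tr$id %in% edges$id
  # fragment start nodes: any node that is not a plain mid-run node
  is_break <- n_kids >= 2L | !has_parent_edge   # branch point or run start
  frags <- list()
  idx <- match(tr$id, tr$id)
  getrow <- function(id) tr[match(id, tr$id), c("x", "y", "z", "radius")]
  starts <- tr$id[is_break & n_kids >= 1L]
  k <- 0L
  for (s in starts) {
    for (child in kids[[as.character(s)]]) {
      run <- c(s, child)
      cur <- child
      while (!is.na(n_kids[as.character(cur)]) &&
             n_kids[as.character(cur)] == 1L) {
        cur <- kids[[as.character(cur)]][1]
        run <- c(run, cur)
      }
      k <- k + 1L
      frags[[k]] <- neurite_fragment(
        do.call(rbind, lapply(run, getrow)),
        fragment_id = paste0(id_prefix, "_", k), neuron_id = neuron_id)
    }
  }
  frags
}

#' Cut a fragment into consecutive sub-fragments of fixed arc length
#'
#' Sub-fragments of `piece_length` are cut along the polyline (interpolating
#' cut points inside segments).  A final remainder shorter than half of
#' `piece_length` is merged into the previous piece rather than emitted as
#' an unreliably short stub.
#'
#' @param frag a [neurite_fragment].
#' @param piece_length target arc length per piece, micrometres.
#' @return A list of [neurite_fragment]s whose concatenation reproduces the
#'   parent polyline.
#' @export
subdivide_fragment <- function(frag, piece_length) {
  stopifnot(inherits(frag, "neurite_fragment"), piece_length > 0)
  total <- frag$length_um
  n_pieces <- max(1L, floor(total / piece_length))
  if (total - n_pieces * piece_length >= piece_length / 2)
    n_pieces <- n_pieces + 1L
  if (n_pieces == 1L) return(list(frag))
  cuts <- piece_length * seq_len(n_pieces - 1L)
  pts <- frag$points
  seg_len <- sqrt(diff(pts$x)^2 + diff(pts$y)^2 + diff(pts$z)^2)
  cum <- c(0, cumsum(seg_len))
  interp_at <- function(s) {        # point at arc length s
    i <- max(which(cum <= s + 1e-12)); i <- min(i, nrow(pts) - 1L)
    t <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
    data.frame(x = pts$x[i] + t * (pts$x[i + 1] - pts$x[i]),
               y = pts$y[i] + t * (pts$y[i + 1] - pts$y[i]),
               z = pts$z[i] + t * (pts$z[i + 1] - pts$z[i]),
               radius = pts$radius[i] + t * (pts$radius[i + 1] - pts$radius[i]))
  }
  bounds <- c(0, cuts, total)
  lapply(seq_len(n_pieces), function(p) {
    lo <- bounds[p]; hi <- bounds[p + 1]
    inner <- which(cum > lo + 1e-9 & cum < hi - 1e-9)
    piece <- rbind(interp_at(lo), pts[inner, c("x", "y", "z", "radius")],
                   interp_at(hi))
    neurite_fragment(piece,
                     fragment_id = paste0(frag$fragment_id, ".", p),
                     neuron_id = frag$neuron_id)
  })
}

# --- voxel geometry -------------------------------------------------------
# World coordinates are micrometres; voxel i spans
# [(i-1)*voxel_size, i*voxel_size), so um -> index is floor(u/vs) + 1.

um_to_index <- function(u, voxel_size) floor(u / voxel_size) + 1L

index_centre_um <- function(i, voxel_size) (i - 0.5) * voxel_size

# linear indices of voxels covered by the union of spheres swept along a
# polyline (radius per point, min 1 voxel); dims = image x/y/z extent
polyline_voxels <- function(points, dims, voxel_size,
                            clip_warn = TRUE) {
  pts <- densify_polyline(points, step = min(voxel_size) / 2)
  vs <- voxel_size
  out <- vector("list", nrow(pts))
  clipped <- FALSE
  for (i in seq_len(nrow(pts))) {
    r <- max(pts$radius[i], max(vs) / 2)     # at least ~1 voxel wide
    lo <- um_to_index(c(pts$x[i] - r, pts$y[i] - r, pts$z[i] - r), vs)
    hi <- um_to_index(c(pts$x[i] + r, pts$y[i] + r, pts$z[i] + r), vs)
    if (any(hi < 1L) || any(lo > dims)) { clipped <- TRUE; next }
    if (any(lo < 1L) || any(hi > dims)) clipped <- TRUE
    lo <- pmax(lo, 1L); hi <- pmin(hi, dims)
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    cx <- index_centre_um(g$x, vs[1]) - pts$x[i]
    cy <- index_centre_um(g$y, vs[2]) - pts$y[i]
    cz <- index_centre_um(g$z, vs[3]) - pts$z[i]
    keep <- cx^2 + cy^2 + cz^2 <= r^2
    idx <- (g$z[keep] - 1L) * dims[1] * dims[2] +
      (g$y[keep] - 1L) * dims[1] + g$x[keep]
    # the voxel containing the sample point always belongs to the footprint
    # (coarse grids can put every voxel centre outside the sphere)
    own <- um_to_index(c(pts$x[i], pts$y[i], pts$z[i]), vs)
    if (all(own >= 1L) && all(own <= dims))
      idx <- c(idx, (own[3] - 1L) * dims[1] * dims[2] +
                 (own[2] - 1L) * dims[1] + own[1])
    out[[i]] <- idx
  }
  if (clipped && clip_warn)
    warning("fragment extends outside the image bounds; clipped")
  unique(unlist(out))
}

# resample a polyline at roughly fixed arc-length steps (keeps vertices)
densify_polyline <- function(points, step) {
  if (nrow(points) < 2L) return(points)
  segs <- lapply(seq_len(nrow(points) - 1L), function(i) {
    p <- points[i, ]; q <- points[i + 1L, ]
    len <- sqrt((q$x - p$x)^2 + (q$y - p$y)^2 + (q$z - p$z)^2)
    n <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    data.frame(x = p$x + t * (q$x - p$x), y = p$y + t * (q$y - p$y),
               z = p$z + t * (q$z - p$z),
               radius = p$radius + t * (q$radius - p$radius))
  })
  rbind(do.call(rbind, segs), points[nrow(points), c("x", "y", "z", "radius")])
}

#' Per-channel background medians of the non-trace volume
#'
#' The background of each channel is the median intensity over all voxels
#' not covered by any fragment, computed once per image and reused by
#' signal-to-noise screening and colour-vector computation.
#'
#' @param img a [channel_image].
#' @param fragments list of [neurite_fragment]s whose voxels are excluded.
#' @return Named numeric vector of per-channel medians.
#' @export
image_background <- function(img, fragments) {
  d <- dim(img$voxels)
  covered <- unique(unlist(lapply(fragments, function(f)
    polyline_voxels(f$points, d[1:3], img$voxel_size, clip_warn = FALSE))))
  flat <- matrix(img$voxels, ncol = d[4])
  bg_rows <- if (length(covered)) flat[-covered, , drop = FALSE] else flat
  stats::setNames(apply(bg_rows, 2, stats::median, na.rm = TRUE),
                  img$channels)
}

#' Sample per-channel mean intensities along a fragment
#'
#' Identifies the voxels covered by the fragment (union of spheres of the
#' per-point radius, at least one voxel wide, swept along the polyline) and
#' returns the mean raw intensity of those voxels per channel.  Saturated
#' (`NA`) voxels are excluded from the means.
#'
#' @param frag a [neurite_fragment].
#' @param img a [channel_image].
#' @return The fragment with `raw_means` filled in and the voxel count in
#'   `n_voxels`.
#' @export
sample_fragment_intensities <- function(frag, img) {
  stopifnot(inherits(frag, "neurite_fragment"),
            inherits(img, "channel_image"))
  d <- dim(img$voxels)
  vox <- polyline_voxels(frag$points, d[1:3], img$voxel_size)
  if (!length(vox))
    stop("fragment ", frag$fragment_id, " covers no voxels inside the image")
  flat <- matrix(img$voxels, ncol = d[4])
  frag$raw_means <- stats::setNames(
    colMeans(flat[vox, , drop = FALSE], na.rm = TRUE), img$channels)
  frag$n_voxels <- length(vox)
  frag
}

#' Recentre trace points onto the neurite axis
#'
#' Automated tracing sometimes places sample points on the edge rather than
#' the centre of a neurite.  Each point is moved to the intensity-weighted
#' centroid of the channel-maximum image within `search_radius`, with the
#' displacement capped at `search_radius`; points in zero-signal
#' neighbourhoods are left unmoved and topology is never altered.
#'
#' @param trace an `swc_trace`.
#' @param img a [channel_image].
#' @param search_radius neighbourhood radius in micrometres.
#' @return The recentred `swc_trace`.
#' @export
recenter_points <- function(trace, img, search_radius) {
  stopifnot(inherits(trace, "swc_trace"), search_radius > 0)
  d <- dim(img$voxels)
  chmax <- apply(img$voxels, 1:3, max, na.rm = TRUE)
  chmax[!is.finite(chmax)] <- 0
  vs <- img$voxel_size
  for (i in seq_len(nrow(trace))) {
    p <- c(trace$x[i], trace$y[i], trace$z[i])
    lo <- pmax(um_to_index(p - search_radius, vs), 1L)
    hi <- pmin(um_to_index(p + search_radius, vs), d[1:3])
    if (any(lo > hi)) next
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    cx <- index_centre_um(g$x, vs[1]); cy <- index_centre_um(g$y, vs[2])
    cz <- index_centre_um(g$z, vs[3])
    within <- (cx - p[1])^2 + (cy - p[2])^2 + (cz - p[3])^2 <=
      search_radius^2
    w <- chmax[cbind(g$x, g$y, g$z)] * within
    if (sum(w) <= 0) next
    target <- c(sum(w * cx), sum(w * cy), sum(w * cz)) / sum(w)
    shift <- target - p
    nrm <- sqrt(sum(shift^2))
    if (nrm > search_radius) shift <- shift * (search_radius / nrm)
    trace$x[i] <- p[1] + shift[1]
    trace$y[i] <- p[2] + shift[2]
    trace$z[i] <- p[3] + shift[3]
  }
  trace
}

#' Tabulate fragments
#'
#' @param fragments list of [neurite_fragment]s.
#' @return data.frame with fragment id, neuron id, length and any sampled
#'   per-channel raw means.
#' @export
fragment_table <- function(fragments) {
  base <- data.frame(
    fragment_id = vapply(fragments, function(f) as.character(f$fragment_id),
                         character(1)),
    neuron_id = vapply(fragments, function(f) as.character(f$neuron_id),
                       character(1)),
    length_um = vapply(fragments, function(f) f$length_um, numeric(1)),
    stringsAsFactors = FALSE)
  means <- lapply(fragments, `[[`, "raw_means")
  if (all(!vapply(means, is.null, logical(1))))
    base <- cbind(base, do.call(rbind, means))
  base
}
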