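#' dCrawler: threshold-distance clustering
#'
#' Unsupervised clustering in which the only parameter is a threshold
#' distance Th(d): at convergence every point lies within `th_d` of its
#' cluster centroid, and no two centroids lie within the final merge
#' threshold of each other.  Unlike k-means no cluster count is assumed,
#' and unlike density-based methods no density kernel is required — suited
#' to colour vectors where the number of labelled neurons and the number
#' of fragments per neuron are both unknown.
#'
#' The algorithm loops over three phases until the assignment stabilizes:
#'
#' 1. **Crawl** — unassigned points are visited in order; a point joins the
#'    first-nearest existing cluster whose centroid is within `th_d`
#'    (updating that centroid immediately), otherwise it seeds a new
#'    cluster.
#' 2. **Adjust** — points are re-allocated to their nearest centroid and
#'    centroids recomputed, iterated to a fixed point, removing the
#'    primacy bias of the crawl order.
#' 3. **Merge** — while any two centroids are within the merge threshold,
#'    the closest pair is merged; afterwards points farther than `th_d`
#'    from their (possibly moved) centroid are unassigned and re-enter the
#'    next crawl.
#'
#' To guarantee termination, the merge threshold decays by a factor 0.99
#' per loop after loop 20.  Centroids are magnitude-weighted means of
#' member points (see [weighted_centroid()]); ties between equidistant
#' centroids go to the lowest cluster id, so runs are deterministic for a
#' fixed input order.
#'
#' @param points a [colour_vectors] object, or a numeric matrix (one point
#'   per row).
#' @param th_d threshold distance Th(d) (`> 0`).
#' @param weights centroid weights; defaults to the magnitudes of a
#'   `colour_vectors` input, else 1.
#' @param order_by `"input"` (default) to crawl points in input order, or
#'   `"magnitude"` to seed with the brightest (most reliable) points first.
#' @param max_loops hard cap on outer loops (default 1000; the decay makes
#'   reaching it indicate a bug).
#' @param adjust_cap iteration cap for the adjust phase (default 100).
#' @return An object of class `dcrawler` with elements `cluster` (integer
#'   assignments), `centroids` (matrix, one row per cluster), `size`,
#'   `th_d`, `n_loops`, `final_merge_threshold` and `weights`.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(40, 0, .03), 20) + rep(c(0, 1), each = 20),
#'              matrix(rnorm(40, 0, .03), 20) + rep(c(1, 0), each = 20))
#' cl <- dcrawler(pts, th_d = 0.2)
#' table(cl$cluster)
#' @export
dcrawler <- function(points, th_d, weights = NULL,
                     order_by = c("input", "magnitude"),
                     max_loops = 1000L, adjust_cap = 100L) {
  order_by <- match.arg(order_by)
  if (inherits(points, "colour_vectors")) {
    if (is.null(weights)) weights <- points$magnitude
    ids <- points$fragment_id
    points <- points$values
  } else ids <- NULL
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1, th_d > 0)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || all(weights == 0)) weights <- rep(1, n)
  perm <- if (order_by == "magnitude") order(weights, decreasing = TRUE)
          else seq_len(n)

  state <- list(cluster = rep(NA_integer_, n), centroids = NULL)
  merge_threshold <- th_d
  prev <- NULL
  loop <- 0L
  repeat {
    loop <- loop + 1L
    if (loop > max_loops)
      stop("dCrawler failed to stabilize within ", max_loops,
           " loops; this should be unreachable")
    state <- dcrawler_crawl(points, state, th_d, weights, perm)
    state <- dcrawler_adjust(points, state, weights, cap = adjust_cap)
    state <- dcrawler_merge(points, state, merge_threshold, th_d, weights)
    if (!is.null(prev) && !anyNA(state$cluster) &&
        identical(prev, state$cluster)) break
    prev <- state$cluster
    if (loop >= 20L) merge_threshold <- merge_threshold * 0.99
  }
  state <- compact_clusters(state, weights, points)
  structure(list(cluster = state$cluster, centroids = state$centroids,
                 size = tabulate(state$cluster, nrow(state$centroids)),
                 th_d = th_d, n_loops = loop,
                 final_merge_threshold = merge_threshold,
                 weights = weights, fragment_id = ids, points = points),
            class = "dcrawler")
}

#' dCrawler phases
#'
#' The three phases of the [dcrawler()] loop, exposed for inspection and
#' testing.  `state` is a list with `cluster` (integer assignments, `NA`
#' for unassigned) and `centroids` (matrix, one row per cluster).
#'
#' @param points numeric matrix of points.
#' @param state phase state (see Details).
#' @param th_d threshold distance.
#' @param weights centroid weights.
#' @param perm crawl visiting order (default input order).
#' @return The updated state.
#' @keywords internal
#' @export
dcrawler_crawl <- function(points, state, th_d, weights = NULL,
                           perm = seq_len(nrow(points))) {
  if (is.null(weights)) weights <- rep(1, nrow(points))
  cl <- state$cluster
  cent <- state$centroids
  for (i in perm[is.na(cl[perm])]) {
    if (!is.null(cent) && nrow(cent) > 0) {
      d <- sqrt(colSums((t(cent) - points[i, ])^2))
      j <- which.min(d)             # ties -> lowest cluster id
      if (d[j] <= th_d) {
        cl[i] <- j
        members <- which(cl == j)
        cent[j, ] <- weighted_centroid(points[members, , drop = FALSE],
                                       weights[members])
        next
      }
    }
    cent <- rbind(cent, points[i, , drop = FALSE])
    cl[i] <- nrow(cent)
  }
  list(cluster = cl, centroids = cent)
}

#' @rdname dcrawler_crawl
#' @param cap maximum reassignment iterations.
#' @export
dcrawler_adjust <- function(points, state, weights = NULL, cap = 100L) {
  if (is.null(weights)) weights <- rep(1, nrow(points))
  cl <- state$cluster
  cent <- state$centroids
  if (is.null(cent) || nrow(cent) <= 1L) return(state)
  for (it in seq_len(cap)) {
    d <- cross_dist(points, cent)
    new_cl <- max.col(-d, ties.method = "first")   # nearest, ties -> low id
    if (identical(new_cl, cl)) break
    st <- compact_clusters(list(cluster = new_cl, centroids = cent),
                           weights, points)
    cl <- st$cluster
    cent <- st$centroids
    if (it == cap)
      warning("adjust phase hit its iteration cap without converging")
  }
  list(cluster = cl, centroids = cent)
}

#' @rdname dcrawler_crawl
#' @param merge_threshold centroid distance at or below which clusters are
#'   fused.
#' @export
dcrawler_merge <- function(points, state, merge_threshold, th_d,
                           weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(points))
  cl <- state$cluster
  cent <- state$centroids
  if (!is.null(cent)) while (nrow(cent) >= 2L) {
    d <- cross_dist(cent, cent)
    d[upper.tri(d, diag = TRUE)] <- Inf
    j <- arrayInd(which.min(d), dim(d))   # closest pair, row > col
    if (d[j] > merge_threshold) break
    keep <- j[2]; gone <- j[1]            # fuse into the lower id
    cl[cl == gone] <- keep
    cl[cl > gone] <- cl[cl > gone] - 1L
    cent <- cent[-gone, , drop = FALSE]
    members <- which(cl == keep)
    cent[keep, ] <- weighted_centroid(points[members, , drop = FALSE],
                                      weights[members])
  }
  # evict points now outside the cluster radius; they re-enter the crawl
  if (!is.null(cent) && nrow(cent) > 0) {
    assigned <- which(!is.na(cl))
    d_own <- sqrt(rowSums((points[assigned, , drop = FALSE] -
                           cent[cl[assigned], , drop = FALSE])^2))
    evict <- assigned[d_own > th_d]
    if (length(evict)) {
      cl[evict] <- NA_integer_
      st <- compact_clusters(list(cluster = cl, centroids = cent),
                             weights, points)
      return(st)
    }
  }
  list(cluster = cl, centroids = cent)
}

# drop empty clusters, renumber contiguously, recompute centroids from
# their member points
compact_clusters <- function(state, weights, points) {
  cl <- state$cluster
  used <- sort(unique(cl[!is.na(cl)]))
  cl <- match(cl, used)
  cent <- matrix(0, length(used), ncol(points))
  for (j in seq_along(used)) {
    members <- which(cl == j)
    cent[j, ] <- weighted_centroid(points[members, , drop = FALSE],
                                   weights[members])
  }
  list(cluster = cl, centroids = cent)
}

#' @export
print.dcrawler <- function(x, ...) {
  cat(sprintf("dCrawler: %d points -> %d clusters at Th(d) = %g (%d loops)\n",
              length(x$cluster), nrow(x$centroids), x$th_d, x$n_loops))
  cat("Cluster sizes:\n")
  print(x$size)
  invisible(x)
}

#' @export
summary.dcrawler <- function(object, ...) {
  d_own <- sqrt(rowSums((pick_points(object) -
                         object$centroids[object$cluster, ,
                                          drop = FALSE])^2))
  structure(list(n_points = length(object$cluster),
                 n_clusters = nrow(object$centroids),
                 th_d = object$th_d, n_loops = object$n_loops,
                 final_merge_threshold = object$final_merge_threshold,
                 size = object$size,
                 d_to_centroid = summary(d_own)),
            class = "summary.dcrawler")
}

#' @export
print.summary.dcrawler <- function(x, ...) {
  cat(sprintf("dCrawler solution: %d clusters over %d points, Th(d) = %g\n",
              x$n_clusters, x$n_points, x$th_d))
  cat(sprintf("  %d loops; final merge threshold %.4g\n", x$n_loops,
              x$final_merge_threshold))
  cat("  distance to centroid:\n")
  print(x$d_to_centroid)
  invisible(x)
}

pick_points <- function(x) x$points

#' Assign new points to an existing dCrawler solution
#'
#' @param object a fitted `dcrawler` object.
#' @param newdata matrix or [colour_vectors] of points to assign.
#' @param ... unused.
#' @return Integer cluster ids; `NA` where no centroid is within `th_d`.
#' @export
predict.dcrawler <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "colour_vectors")) newdata$values
       else as.matrix(newdata)
  d <- cross_dist(v, object$centroids)
  j <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(nrow(d)), j)]
  ifelse(dmin <= object$th_d, j, NA_integer_)
}

#' Plot a dCrawler solution
#'
#' Scatter of the first two dimensions (or a chosen pair), points coloured
#' by cluster, centroids marked, with circles of radius Th(d).
#'
#' @param x a `dcrawler` object.
#' @param points optional replacement for the stored point matrix (e.g. a
#'   2-D embedding of high-dimensional colour vectors).
#' @param dims the two dimensions to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dcrawler <- function(x, points = NULL, dims = c(1, 2), ...) {
  v <- if (is.null(points)) pick_points(x)
       else if (inherits(points, "colour_vectors")) points$values
       else as.matrix(points)
  cols <- grDevices::hcl.colors(max(nrow(x$centroids), 2), "Dark 3")
  graphics::plot(v[, dims[1]], v[, dims[2]],
                 col = cols[x$cluster], pch = 16,
                 xlab = paste("dim", dims[1]),
                 ylab = paste("dim", dims[2]), ...)
  graphics::points(x$centroids[, dims[1]], x$centroids[, dims[2]],
                   pch = 3, cex = 1.5, lwd = 2)
  th <- seq(0, 2 * pi, length.out = 90)
  for (j in seq_len(nrow(x$centroids)))
    graphics::lines(x$centroids[j, dims[1]] + x$th_d * cos(th),
                    x$centroids[j, dims[2]] + x$th_d * sin(th),
                    lty = 3, col = "grey50")
  invisible(x)
}

#' Write cluster assignments and centroids to CSV
#'
#' @param x a `dcrawler` object.
#' @param points optional replacement point matrix for the per-point
#'   distance-to-centroid column.
#' @param path assignments CSV path; centroids go to
#'   `<path>_centroids.csv` unless `centroid_path` is given.
#' @param centroid_path optional explicit centroids path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, points = NULL, path,
                           centroid_path = NULL) {
  v <- if (is.null(points)) pick_points(x)
       else if (inherits(points, "colour_vectors")) points$values
       else as.matrix(points)
  d_own <- sqrt(rowSums((v - x$centroids[x$cluster, , drop = FALSE])^2))
  ids <- x$fragment_id %||% seq_along(x$cluster)
  utils::write.csv(data.frame(fragment_id = ids, cluster_id = x$cluster,
                              d_to_centroid = d_own),
                   path, row.names = FALSE)
  cp <- centroid_path %||% sub("(\\.[^.]*)?$", "_centroids.csv", path)
  utils::write.csv(data.frame(cluster_id = seq_len(nrow(x$centroids)),
                              x$centroids, size = x$size),
                   cp, row.names = FALSE)
  invisible(path)
}
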