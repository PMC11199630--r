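#' Colour vectors: unit-normalized N-channel intensity profiles
#'
#' A `colour_vectors` object holds one row per neurite fragment (or simulated
#' cell): the unit-normalized per-channel intensity profile (`values`), the
#' Euclidean norm the profile had before unit normalization (`magnitude`,
#' the "brightness" used both for quality control and as the weight in
#' centroid computations), and optional fragment metadata.
#'
#' All-zero rows are representable: their `values` stay zero and their
#' `magnitude` is 0, so downstream quality control can drop them explicitly
#' instead of failing on a division by zero.
#'
#' @param values numeric matrix, one row per vector; rows either all-zero or
#'   unit norm (checked to 1e-9 under the L2 convention).
#' @param magnitude numeric vector of pre-normalization norms, one per row.
#' @param channels optional character vector of channel labels.
#' @param fragment_id optional identifiers, one per row.
#' @param length_um optional fragment lengths in micrometres.
#' @param norm normalization convention the rows obey, `"l2"` (default) or
#'   `"l1"`.
#' @return An object of class `colour_vectors`.
#' @seealso [vector_normalize()], [colour_distance()], [weighted_centroid()]
#' @export
colour_vectors <- function(values, magnitude, channels = NULL,
                           fragment_id = NULL, length_um = NULL,
                           norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  magnitude <- as.numeric(magnitude)
  stopifnot(nrow(values) == length(magnitude))
  if (any(!is.finite(values)) || any(values < 0))
    stop("colour vector values must be finite and non-negative")
  if (any(!is.finite(magnitude)) || any(magnitude < 0))
    stop("magnitudes must be finite and non-negative")
  rn <- if (norm == "l2") sqrt(rowSums(values^2)) else rowSums(abs(values))
  bad <- magnitude > 0 & abs(rn - 1) >= 1e-9
  if (any(bad))
    stop(sum(bad), " row(s) with magnitude > 0 are not unit-normalized")
  if (is.null(channels)) channels <- paste0("ch_", seq_len(ncol(values)))
  colnames(values) <- channels
  if (is.null(fragment_id)) fragment_id <- seq_len(nrow(values))
  structure(
    list(values = values, magnitude = magnitude, channels = channels,
         fragment_id = fragment_id, length_um = length_um, norm = norm),
    class = "colour_vectors")
}

#' @export
print.colour_vectors <- function(x, ...) {
  cat(sprintf("Colour vectors: %d x %d channels (%s-normalized)\n",
              nrow(x$values), ncol(x$values), toupper(x$norm)))
  cat("  magnitude: ",
      paste(sprintf("%.3g", stats::quantile(x$magnitude,
                                            c(0, .5, 1))), collapse = " / "),
      " (min / median / max)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.colour_vectors <- function(x, ...) x$values

#' @export
length.colour_vectors <- function(x) nrow(x$values)

#' @export
`[.colour_vectors` <- function(x, i, ...) {
  colour_vectors(x$values[i, , drop = FALSE], x$magnitude[i],
                 channels = x$channels, fragment_id = x$fragment_id[i],
                 length_um = if (!is.null(x$length_um)) x$length_um[i],
                 norm = x$norm)
}

#' Vector-normalize raw channel intensities
#'
#' Converts raw non-negative channel intensities into colour vectors by
#' dividing each row by its norm; the pre-normalization norm is retained as
#' the `magnitude`.  The Euclidean (L2) norm is the default, placing colour
#' vectors on the positive orthant of the unit hypersphere where the maximum
#' possible distance between two colour hues is sqrt(2); an L1 (simplex)
#' convention is available as an option.
#'
#' All-zero rows produce all-zero values with magnitude 0 rather than an
#' error, so that unlabelled/dark fragments survive to quality control where
#' they are dropped with an explicit reason.
#'
#' @param raw numeric vector (a single profile) or matrix (one profile per
#'   row) of finite, non-negative intensities.
#' @param norm `"l2"` (default) or `"l1"`.
#' @inheritParams colour_vectors
#' @return A [colour_vectors] object (one row for vector input).
#' @examples
#' vector_normalize(c(3, 4))$values      # 0.6 0.8
#' vector_normalize(c(3, 4))$magnitude   # 5
#' @export
vector_normalize <- function(raw, norm = c("l2", "l1"), channels = NULL,
                             fragment_id = NULL, length_um = NULL) {
  norm <- match.arg(norm)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (any(!is.finite(raw)))
    stop("raw intensities must be finite")
  if (any(raw < 0))
    stop("raw intensities must be non-negative")
  mag <- if (norm == "l2") sqrt(rowSums(raw^2)) else rowSums(raw)
  vals <- raw / ifelse(mag > 0, mag, 1)
  colour_vectors(vals, mag, channels = channels, fragment_id = fragment_id,
                 length_um = length_um, norm = norm)
}

#' Euclidean distance between colour vectors
#'
#' The colour-hue dissimilarity *d* used throughout the pipeline: the
#' Euclidean distance between (normalized) colour vectors.  Two hues are
#' considered discriminable when *d* exceeds a threshold distance Th(d).
#'
#' @param a,b numeric vectors of equal length, matrices with equal column
#'   counts, or [colour_vectors] objects.  Vector/vector input returns a
#'   scalar; matrix/vector a per-row vector; matrix/matrix the full
#'   `nrow(a)` x `nrow(b)` cross-distance matrix.
#' @return Non-negative distances.
#' @examples
#' colour_distance(c(0.6, 0.8), c(0.8, 0.6))  # 0.28284
#' @export
colour_distance <- function(a, b) {
  a <- if (inherits(a, "colour_vectors")) a$values else a
  b <- if (inherits(b, "colour_vectors")) b$values else b
  avec <- is.null(dim(a)); bvec <- is.null(dim(b))
  if (avec && bvec) {
    if (length(a) != length(b))
      stop("dimension mismatch: ", length(a), " vs ", length(b))
    return(sqrt(sum((a - b)^2)))
  }
  a <- if (avec) matrix(a, nrow = 1) else as.matrix(a)
  b <- if (bvec) matrix(b, nrow = 1) else as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("dimension mismatch: ", ncol(a), " vs ", ncol(b))
  d <- cross_dist(a, b)
  if (bvec) drop(d) else if (nrow(a) == 1L && nrow(b) == 1L) d[1, 1] else d
}

# ||a_i - b_j|| for all i, j, numerically floored at 0
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Magnitude-weighted centroid of colour vectors
#'
#' Centroid position used by the dCrawler: the mean of the member colour
#' vectors weighted by their magnitudes, so that brighter (more reliable)
#' fragments pull the centroid harder.  The result is deliberately *not*
#' re-projected onto the unit sphere; cluster membership tests measure the
#' distance to this raw weighted mean.
#'
#' @param points a [colour_vectors] object, or a numeric matrix of positions
#'   (one per row).
#' @param weights weights, one per row; defaults to the magnitudes when
#'   `points` is a `colour_vectors` object, else to 1.
#' @return Numeric vector: the weighted mean position.
#' @examples
#' weighted_centroid(rbind(c(1, 0), c(0, 1)), weights = c(1, 3))  # 0.25 0.75
#' @export
weighted_centroid <- function(points, weights = NULL) {
  if (inherits(points, "colour_vectors")) {
    if (is.null(weights)) weights <- points$magnitude
    points <- points$values
  }
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("cannot take the centroid of an empty set")
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (length(weights) != nrow(points))
    stop("one weight per point required")
  tw <- sum(weights)
  if (tw <= 0) stop("total weight must be positive")
  drop(crossprod(points, weights)) / tw
}

#' Read / write colour-vector tables
#'
#' Colour vectors are interchanged as plain CSV with columns `fragment_id`,
#' `ch_1..ch_N` (normalized values), `magnitude` and optionally `length_um`.
#'
#' @param x a [colour_vectors] object.
#' @param path file path.
#' @return `read_colour_vectors` returns a [colour_vectors] object;
#'   `write_colour_vectors` returns `path` invisibly.
#' @export
write_colour_vectors <- function(x, path) {
  stopifnot(inherits(x, "colour_vectors"))
  df <- data.frame(fragment_id = x$fragment_id, x$values,
                   magnitude = x$magnitude, check.names = FALSE)
  if (!is.null(x$length_um)) df$length_um <- x$length_um
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_colour_vectors
#' @export
read_colour_vectors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ch <- setdiff(names(df), c("fragment_id", "magnitude", "length_um"))
  colour_vectors(as.matrix(df[ch]), df$magnitude, channels = ch,
                 fragment_id = df$fragment_id,
                 length_um = df[["length_um"]])
}
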