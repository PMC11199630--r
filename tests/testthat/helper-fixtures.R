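# Shared fixtures, built in code.  The phantom is generated once per test
# run and reused by the trace/QC/pipeline tests.

.fixture_env <- new.env(parent = emptyenv())

shared_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    set.seed(4242)
    .fixture_env$phantom <- generate_phantom(phantom_config())
  }
  .fixture_env$phantom
}

# small unbranched trace along +x with given number of points
straight_trace <- function(n = 11, spacing = 2, radius = 0.5, type = 3L) {
  tr <- data.frame(id = seq_len(n), type = type,
                   x = (seq_len(n) - 1) * spacing, y = 10, z = 5,
                   radius = radius,
                   parent = c(-1L, seq_len(n - 1L)))
  class(tr) <- c("swc_trace", "data.frame")
  tr
}

# random tree morphology: each new point attaches to a random earlier one
random_tree_trace <- function(n_points, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parent <- c(-1L, vapply(2:n_points, function(i)
    sample.int(i - 1L, 1L), integer(1)))
  tr <- data.frame(id = seq_len(n_points), type = 3L,
                   x = cumsum(runif(n_points, -2, 2)) + 50,
                   y = cumsum(runif(n_points, -2, 2)) + 50,
                   z = runif(n_points, 0, 10), radius = 0.5,
                   parent = parent)
  class(tr) <- c("swc_trace", "data.frame")
  tr
}

# uniform-value image
flat_image <- function(value = 100, dims = c(20, 20, 6), n_ch = 2,
                       voxel_size = c(1, 1, 1)) {
  channel_image(array(value, c(dims, n_ch)), voxel_size)
}

# random unit-normalized nonnegative vectors
random_unit_rows <- function(n, d) {
  m <- matrix(stats::rexp(n * d), n, d)
  m / sqrt(rowSums(m^2))
}
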