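#' Stochastic-labelling model for combinatorial fluorophore expression
#'
#' Describes the copy-number model for stochastic multicolour labelling:
#' every cell receives, for each of `n_channels` fluorophores, a transgene
#' copy number drawn from a Poisson distribution with mean `mean_copies`
#' (copies/colour/cell), truncated at `max_copies`.  The resulting raw
#' copy-number profile, unit-normalized, is the cell's colour vector.
#'
#' Two generation methods are provided.  `"shuffle"` (default) fixes the
#' per-channel copy-number composition of the cohort to the Poisson
#' probability mass function (cumulative rounding to whole cells) and
#' shuffles which cell gets which copy number, mimicking plasmid uptake
#' being distributed over a fixed pool; `"poisson"` draws every cell's copy
#' numbers independently.  The two agree in distribution for large cohorts
#' but differ slightly in nearest-neighbour statistics for cohorts of a few
#' hundred cells, where the fixed composition matters.
#'
#' @param n_channels number of fluorophore channels (1-7 typical).
#' @param mean_copies Poisson mean, copies/colour/cell.
#' @param max_copies truncation of the copy-number distribution (default 50).
#' @param noise_sd per-channel Gaussian noise SD applied to normalized
#'   vectors by [discriminability_with_noise()] (default 0.1 there).
#' @param method `"shuffle"` or `"poisson"` (see Details).
#' @return An object of class `label_model`.
#' @export
label_model <- function(n_channels, mean_copies, max_copies = 50L,
                        noise_sd = 0, method = c("shuffle", "poisson")) {
  method <- match.arg(method)
  stopifnot(n_channels >= 1, mean_copies >= 0, max_copies >= 1,
            noise_sd >= 0)
  structure(list(n_channels = as.integer(n_channels),
                 mean_copies = mean_copies,
                 max_copies = as.integer(max_copies),
                 noise_sd = noise_sd, method = method),
            class = "label_model")
}

#' @export
print.label_model <- function(x, ...) {
  cat(sprintf("Labelling model: %d channels, Poisson(%g) copies (max %d), %s draw",
              x$n_channels, x$mean_copies, x$max_copies, x$method))
  if (x$noise_sd > 0) cat(sprintf(", noise SD %g", x$noise_sd))
  cat("\n")
  invisible(x)
}

# copy-number matrix (cells x channels) under the model; all-zero cells
# handled per method (redraw for "poisson", drop for "shuffle")
draw_copies <- function(model, n_cells) {
  n_ch <- model$n_channels
  lam <- model$mean_copies
  if (lam <= 0) stop("mean_copies must be > 0 to label any cell")
  if (model$method == "poisson") {
    m <- matrix(pmin(stats::rpois(n_cells * n_ch, lam), model$max_copies),
                n_cells, n_ch)
    zero <- rowSums(m) == 0
    while (any(zero)) {   # unlabelled cells are invisible: redraw them
      m[zero, ] <- pmin(stats::rpois(sum(zero) * n_ch, lam),
                        model$max_copies)
      zero <- rowSums(m) == 0
    }
  } else {
    kmax <- model$max_copies
    quota <- diff(c(0, round(n_cells * stats::ppois(0:kmax, lam))))
    quota[kmax + 1L] <- quota[kmax + 1L] + (n_cells - sum(quota))
    pool <- rep.int(0:kmax, quota)
    m <- vapply(seq_len(n_ch),
                function(j) as.numeric(pool[sample.int(length(pool))]),
                numeric(n_cells))
    m <- matrix(m, n_cells, n_ch)           # vapply drops dims at n = 1
    m <- m[rowSums(m) > 0, , drop = FALSE]  # unlabelled cells are invisible
  }
  m
}

#' Simulate colour vectors of stochastically labelled cells
#'
#' Draws per-cell, per-channel fluorophore copy numbers under the model and
#' unit-normalizes each cell's copy-number profile into a colour vector.
#' Cells expressing zero copies of every fluorophore are unlabelled and do
#' not appear in the output (redrawn under `method = "poisson"`, dropped
#' under `"shuffle"`; negligible for Poisson means of 1 or more).
#'
#' @param model a [label_model].
#' @param n_cells cohort size (before removal of unlabelled cells).
#' @return A [colour_vectors] object; `magnitude` is the Euclidean norm of
#'   the raw copy-number profile.
#' @examples
#' set.seed(1)
#' v <- simulate_cells(label_model(7, 2), 100)
#' @export
simulate_cells <- function(model, n_cells) {
  stopifnot(inherits(model, "label_model"), n_cells >= 1)
  vector_normalize(draw_copies(model, n_cells))
}

#' Percentage of discriminable cell pairs
#'
#' Two cells are discriminable when the Euclidean distance between their
#' colour vectors exceeds the threshold distance `th_d`.  Returns the
#' percentage of discriminable unordered pairs, plus the per-cell fraction
#' of discriminable partners (mean and SD across cells).  Pair distances
#' are computed in row blocks so cohorts of 10,000 cells stay within a few
#' hundred megabytes.
#'
#' @param vectors a [colour_vectors] object or numeric matrix (rows = cells).
#' @param th_d threshold distance Th(d).
#' @param block rows per block for the pairwise sweep.
#' @return A list: `percent` (scalar), `per_cell` (vector of per-cell
#'   discriminable fractions, in percent), `per_cell_mean`, `per_cell_sd`,
#'   `n_pairs`.
#' @export
percent_discriminable <- function(vectors, th_d, block = 1000L) {
  v <- if (inherits(vectors, "colour_vectors")) vectors$values else
    as.matrix(vectors)
  n <- nrow(v)
  if (n < 2) stop("need at least 2 cells")
  # neighbours[i] = number of j != i with d(i, j) <= th_d
  neighbours <- neighbour_counts(v, th_d, block)
  per_cell <- 100 * (1 - neighbours / (n - 1))
  n_indis <- sum(neighbours) / 2     # indiscriminable unordered pairs
  n_pairs <- n * (n - 1) / 2
  list(percent = 100 * (1 - n_indis / n_pairs),
       per_cell = per_cell,
       per_cell_mean = mean(per_cell),
       per_cell_sd = stats::sd(per_cell),
       n_pairs = n_pairs)
}

# for each row, how many other rows lie within th_d (Euclidean)
neighbour_counts <- function(v, th_d, block = 1000L) {
  n <- nrow(v)
  sq <- rowSums(v^2)
  counts <- integer(n)
  thr2 <- th_d^2
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(v[idx, , drop = FALSE], v)
    counts[idx] <- rowSums(d2 <= thr2 + 1e-12) - 1L  # minus self
  }
  counts
}

#' Percentage of uniquely labelled cells (Monte-Carlo)
#'
#' A cell is uniquely labelled when no other cell of the cohort lies within
#' `th_d` of its colour vector.  Even with high pairwise discriminability
#' the fraction of unique cells drops as the cohort grows (the birthday
#' problem).  Repeats the simulation `n_sims` times and reports the mean
#' and SD of the percent-unique across simulations.
#'
#' @param model a [label_model].
#' @param n_cells cells per simulated cohort.
#' @param th_d threshold distance Th(d).
#' @param n_sims number of Monte-Carlo cohorts (default 200).
#' @return A list: `mean`, `sd`, and `per_sim` (percent unique per cohort).
#' @export
percent_unique <- function(model, n_cells, th_d, n_sims = 200L) {
  stopifnot(n_cells >= 2, n_sims >= 1)
  per_sim <- vapply(seq_len(n_sims), function(i) {
    v <- simulate_cells(model, n_cells)$values
    100 * mean(neighbour_counts(v, th_d) == 0L)
  }, numeric(1))
  list(mean = mean(per_sim), sd = stats::sd(per_sim), per_sim = per_sim)
}

#' Discriminability under the neurite-noise model
#'
#' Neurite colour vectors fluctuate around their cell's true colour.  The
#' noise model adds independent Gaussian noise (SD `model$noise_sd`) to each
#' channel of the normalized vector, clips at zero and re-normalizes, giving
#' one noisy "neurite" replicate per cell.  The working threshold distance
#' is then set to the 95th percentile of the noisy-replicate-to-true
#' distances — i.e. Th(d) is chosen to cover 95% of a neuron's own neurite
#' colour scatter — and pairwise discriminability of the true vectors is
#' evaluated at that threshold.
#'
#' @param model a [label_model] with `noise_sd > 0`.
#' @param n_cells number of simulated cells (default 10,000).
#' @param coverage quantile of self-distances used to set the threshold
#'   (default 0.95).
#' @return A list: `th_d` (derived threshold), `percent` (discriminable
#'   pairs of true vectors at that threshold), `self_distances`.
#' @export
discriminability_with_noise <- function(model, n_cells = 10000L,
                                        coverage = 0.95) {
  stopifnot(inherits(model, "label_model"))
  if (model$noise_sd <= 0) stop("model$noise_sd must be > 0")
  v <- simulate_cells(model, n_cells)$values
  noisy <- v + matrix(stats::rnorm(length(v), 0, model$noise_sd),
                      nrow(v), ncol(v))
  noisy[noisy < 0] <- 0
  nn <- sqrt(rowSums(noisy^2))
  noisy <- noisy / ifelse(nn > 0, nn, 1)
  self_d <- sqrt(rowSums((v - noisy)^2))
  th_d <- unname(stats::quantile(self_d, coverage))
  list(th_d = th_d,
       percent = percent_discriminable(v, th_d)$percent,
       self_distances = self_d)
}
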