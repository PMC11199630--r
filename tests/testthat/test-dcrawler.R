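blob_data <- function(k = 4, per = 25, d = 2, spread = 0.03, sep = 1,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centres <- matrix(runif(k * d, 0, sep * 3), k, d)
  while (min(dist(centres)) < 3 * spread + 0.5)
    centres <- matrix(runif(k * d, 0, sep * 3), k, d)
  pts <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(rnorm(per * d, 0, spread), per, d) +
      matrix(centres[j, ], per, d, byrow = TRUE)))
  list(points = pts, label = rep(seq_len(k), each = per))
}

test_that("crawl accretes within Th(d) and seeds beyond it", {
  st0 <- list(cluster = rep(NA_integer_, 1), centroids = NULL)
  one <- dcrawler_crawl(matrix(c(0.3, 0.4), 1), st0, 0.2)
  expect_equal(one$cluster, 1L)
  expect_equal(drop(one$centroids), c(0.3, 0.4))

  near <- rbind(c(0, 0), c(0.1, 0))
  st <- dcrawler_crawl(near, list(cluster = rep(NA_integer_, 2),
                                  centroids = NULL), 0.2)
  expect_equal(st$cluster, c(1L, 1L))

  far <- rbind(c(0, 0), c(0.5, 0))
  st <- dcrawler_crawl(far, list(cluster = rep(NA_integer_, 2),
                                 centroids = NULL), 0.2)
  expect_equal(st$cluster, c(1L, 2L))
})

test_that("crawl updates the centroid after every accretion", {
  pts <- rbind(c(0, 0), c(0.18, 0), c(0.3, 0))
  # third point is 0.3 from the first but 0.21 from the running centroid
  # (0.09, 0) -- with incremental updates it joins the cluster
  st <- dcrawler_crawl(pts, list(cluster = rep(NA_integer_, 3),
                                 centroids = NULL), th_d = 0.22)
  expect_equal(st$cluster, c(1L, 1L, 1L))
})

test_that("adjust reaches the brute-force nearest-centroid fixed point", {
  for (seed in 1:10) {
    b <- blob_data(k = 3, per = 15, seed = seed)
    st <- dcrawler_crawl(b$points,
                         list(cluster = rep(NA_integer_, nrow(b$points)),
                              centroids = NULL), th_d = 0.25)
    adj <- dcrawler_adjust(b$points, st)
    d <- qdyefinder:::cross_dist(b$points, adj$centroids)
    brute <- apply(d, 1, which.min)
    expect_equal(adj$cluster, as.integer(brute))
  }
})

test_that("adjust leaves a converged configuration unchanged", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(1, 1), c(1.1, 1))
  st <- list(cluster = c(1L, 1L, 2L, 2L),
             centroids = rbind(c(0.05, 0), c(1.05, 1)))
  adj <- dcrawler_adjust(pts, st)
  expect_equal(adj$cluster, st$cluster)
  expect_equal(adj$centroids, st$centroids, tolerance = 1e-12)
})

test_that("equidistant points break ties toward the lower cluster id", {
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, 0))
  st <- list(cluster = c(1L, 2L, 1L),
             centroids = rbind(c(0, 0), c(1, 0)))
  adj <- dcrawler_adjust(pts, st)
  expect_equal(adj$cluster[3], 1L)
})

test_that("merge fuses only centroid pairs within the threshold", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(2, 2), c(2.1, 2))
  st <- list(cluster = c(1L, 1L, 2L, 2L),
             centroids = rbind(c(0.05, 0), c(2.05, 2)))
  kept <- dcrawler_merge(pts, st, merge_threshold = 0.2, th_d = 0.2)
  expect_equal(length(unique(kept$cluster)), 2)

  st2 <- list(cluster = c(1L, 2L, 3L, 4L),
              centroids = pts)
  merged <- dcrawler_merge(rbind(c(0, 0), c(0.1, 0), c(2, 2), c(2.1, 2)),
                           st2, merge_threshold = 0.2, th_d = 0.3)
  expect_equal(length(unique(merged$cluster[!is.na(merged$cluster)])), 2)
})

test_that("merge order follows closest-first agglomeration", {
  # collinear centroids at spacing 0.15: closest-first fuses neighbours,
  # after which the combined centroids move and further merges depend on
  # the recomputed positions -- mirror that with a brute-force loop
  pts <- rbind(c(0, 0), c(0.15, 0), c(0.3, 0))
  st <- list(cluster = c(1L, 2L, 3L), centroids = pts)
  got <- dcrawler_merge(pts, st, merge_threshold = 0.2, th_d = 1)
  cent <- pts; cl <- 1:3
  repeat {
    d <- as.matrix(dist(cent)); d[upper.tri(d, diag = TRUE)] <- Inf
    if (min(d) > 0.2) break
    ij <- arrayInd(which.min(d), dim(d))
    keep <- min(ij); gone <- max(ij)
    cl[cl == gone] <- keep; cl[cl > gone] <- cl[cl > gone] - 1
    cent <- cent[-gone, , drop = FALSE]
    cent[keep, ] <- colMeans(pts[cl == keep, , drop = FALSE])
  }
  expect_equal(length(unique(got$cluster)), length(unique(cl)))
})

test_that("dcrawler recovers well-separated blobs exactly", {
  b <- blob_data(k = 5, per = 20, seed = 41)
  fit <- dcrawler(b$points, th_d = 0.2)
  expect_equal(nrow(fit$centroids), 5)
  expect_equal(length(unique(paste(fit$cluster, b$label))), 5)
})

test_that("degenerate inputs cluster sensibly", {
  same <- matrix(0.5, 10, 3)
  fit <- dcrawler(same, th_d = 0.2)
  expect_equal(nrow(fit$centroids), 1)
  one <- dcrawler(matrix(c(0.6, 0.8), 1), th_d = 0.2)
  expect_equal(one$cluster, 1L)
  expect_equal(drop(one$centroids), c(0.6, 0.8))
})

test_that("post-convergence invariants hold on random datasets", {
  set.seed(42)
  for (i in 1:25) {
    d <- sample(2:7, 1)
    n <- sample(20:60, 1)
    pts <- random_unit_rows(n, d)
    w <- rexp(n) + 0.1
    th <- runif(1, 0.15, 0.4)
    fit <- dcrawler(pts, th_d = th, weights = w)
    expect_false(anyNA(fit$cluster))
    d_own <- sqrt(rowSums((pts - fit$centroids[fit$cluster, ,
                                               drop = FALSE])^2))
    expect_lte(max(d_own), th + 1e-9)
    if (nrow(fit$centroids) > 1) {
      cd <- dist(fit$centroids)
      expect_gt(min(cd), fit$final_merge_threshold)
    }
  }
})

test_that("results are insensitive to input order on blob data", {
  b <- blob_data(k = 4, per = 20, seed = 43)
  ref <- dcrawler(b$points, th_d = 0.2)
  set.seed(44)
  ari <- vapply(1:20, function(i) {
    perm <- sample.int(nrow(b$points))
    fit <- dcrawler(b$points[perm, ], th_d = 0.2)
    mclust::adjustedRandIndex(fit$cluster[order(perm)], ref$cluster)
  }, numeric(1))
  expect_true(all(ari >= 0.95))
})

test_that("raising Th(d) does not inflate the cluster count", {
  set.seed(45)
  pts <- rbind(random_unit_rows(60, 4),
               random_unit_rows(60, 4))
  ks <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8), function(th)
    nrow(dcrawler(pts, th_d = th)$centroids), numeric(1))
  expect_true(all(diff(ks) <= 1))   # non-strict trend, tolerance 1
})

test_that("noisy per-neuron colour vectors cluster to their neurons", {
  set.seed(46)
  n_neurons <- 35
  truth <- simulate_cells(label_model(7, 2), n_neurons)$values
  per <- sample(5:15, n_neurons, replace = TRUE)
  pts <- do.call(rbind, lapply(seq_len(n_neurons), function(j) {
    m <- matrix(truth[j, ], per[j], 7, byrow = TRUE) +
      matrix(rnorm(per[j] * 7, 0, 0.05), per[j], 7)
    m[m < 0] <- 0
    m / sqrt(rowSums(m^2))
  }))
  lab <- rep(seq_len(n_neurons), per)
  fit <- dcrawler(pts, th_d = 0.2)
  sc <- match_and_score(setNames(lab, seq_along(lab)),
                        setNames(fit$cluster, seq_along(lab)))
  expect_gte(median(sc$f1), 0.9)
})

test_that("predict assigns new points to the fitted centroids", {
  b <- blob_data(k = 3, per = 15, seed = 47)
  fit <- dcrawler(b$points, th_d = 0.2)
  pr <- predict(fit, b$points)
  expect_equal(pr, fit$cluster)
  expect_true(is.na(predict(fit, matrix(99, 1, 2))))
})

test_that("cluster tables are written with distances to centroids", {
  b <- blob_data(k = 2, per = 10, seed = 48)
  fit <- dcrawler(b$points, th_d = 0.2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_clusters(fit, path = p)
  tab <- read.csv(p)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$d_to_centroid <= 0.2))
  expect_true(file.exists(sub("\\.csv$", "_centroids.csv", p)))
})
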