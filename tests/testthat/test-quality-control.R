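# fragments with prescribed raw means, for stages that need no image
fake_fragments <- function(means_matrix) {
  lapply(seq_len(nrow(means_matrix)), function(i) {
    f <- neurite_fragment(data.frame(x = c(0, 10), y = i, z = 0,
                                     radius = 0.5),
                          fragment_id = paste0("f", i))
    f$raw_means <- means_matrix[i, ]
    f
  })
}

test_that("a silent channel is flagged and dropped by the S/N screen", {
  set.seed(51)
  means <- cbind(runif(20, 400, 900), runif(20, 300, 800),
                 runif(20, 9, 11))          # ch3 sits at background
  colnames(means) <- paste0("ch_", 1:3)
  bg <- c(ch_1 = 10, ch_2 = 10, ch_3 = 10)
  snr <- channel_snr(fake_fragments(means), bg)
  expect_equal(snr$keep, c(TRUE, TRUE, FALSE))
  expect_lt(snr$snr[3], 2.5)
  expect_gt(snr$snr[1], 2.5)
})

test_that("zero background yields infinite S/N with a warning, not a crash", {
  means <- cbind(runif(12, 50, 100), runif(12, 50, 100))
  colnames(means) <- c("a", "b")
  expect_warning(snr <- channel_snr(fake_fragments(means), c(0, 10)),
                 "infinite")
  expect_true(is.infinite(snr$snr[1]))
})

test_that("losing every channel is a hard error", {
  means <- cbind(runif(12, 9, 11), runif(12, 9, 11))
  expect_error(channel_snr(fake_fragments(means), c(10, 10)),
               "all channels")
})

test_that("colour vectors follow the background/max/normalize recipe", {
  means <- rbind(c(10, 0), c(0, 20))
  cv <- compute_colour_vectors(fake_fragments(means), background = c(0, 0))
  expect_equal(unname(cv$values), rbind(c(1, 0), c(0, 1)))
  # raw mean below background contributes zero
  means2 <- rbind(c(5, 30), c(40, 15))
  cv2 <- compute_colour_vectors(fake_fragments(means2),
                                background = c(10, 10))
  expect_equal(unname(cv2$values[1, ]), c(0, 1))
  # dead channel (all below background) points back at the S/N screen
  expect_error(compute_colour_vectors(fake_fragments(rbind(c(5, 30),
                                                           c(7, 20))),
                                      background = c(10, 10)),
               "S/N")
})

test_that("colour vectors are invariant to a global intensity rescale", {
  set.seed(52)
  means <- matrix(rexp(15 * 4, 1 / 200), 15, 4)
  bg <- c(5, 8, 3, 6)
  a <- compute_colour_vectors(fake_fragments(means), bg)
  b <- compute_colour_vectors(fake_fragments(means * 7.3), bg * 7.3)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("minimum length is the first grid value meeting the criterion", {
  ph <- shared_phantom()
  frs <- lapply(ph$fragments[1:8], sample_fragment_intensities,
                img = ph$image)
  bg <- image_background(ph$image, frs)
  res <- determine_min_length(frs, ph$image, bg,
                              qc_config(length_grid = c(2.5, 5, 10)))
  expect_true(res$min_length_um %in% c(2.5, 5, 10))
  expect_equal(res$curve$length_um, c(2.5, 5, 10))
  # the curve is the decision record: its first value <= 0.1 is the answer
  first_ok <- res$curve$length_um[which(res$curve$median_d <= 0.1)[1]]
  expect_equal(res$min_length_um, first_ok)
})

test_that("noiseless fibres make the smallest grid length acceptable", {
  set.seed(53)
  ph0 <- generate_phantom(phantom_config(n_neurons = 4,
                                         colour_jitter_sd = 0))
  frs <- lapply(ph0$fragments, sample_fragment_intensities,
                img = ph0$image)
  bg <- image_background(ph0$image, frs)
  res <- determine_min_length(frs, ph0$image, bg,
                              qc_config(length_grid = c(2.5, 5, 10)))
  expect_equal(res$min_length_um, 2.5)
})

test_that("brightness cut-off isolates the dim, inaccurate pieces", {
  ph <- shared_phantom()
  frs <- lapply(ph$fragments[1:10], sample_fragment_intensities,
                img = ph$image)
  bg <- image_background(ph$image, frs)
  res <- determine_min_brightness(frs, ph$image, bg, min_length_um = 5)
  expect_gte(res$min_magnitude, 0)
  # at the returned cut-off the inaccurate fraction is below 5%
  sel <- res$scan$cutoff >= res$min_magnitude
  expect_lt(res$scan$inaccurate_fraction[which(sel)[1]], 0.05)
})

test_that("hybrid fragments are split at the colour boundary", {
  set.seed(54)
  a <- c(1, 0, 0, 0.2, 0, 0, 0)
  b <- c(0, 0, 1, 0, 0.2, 0, 0)    # d(a, b) well above 0.3
  hy <- make_hybrid_fragment(a, b, lengths = c(15, 15))
  frag <- sample_fragment_intensities(hy$fragment, hy$image)
  bg <- rep(20, 7)
  pieces <- split_colour_changes(frag, hy$image, bg, min_length_um = 5,
                                 channel_max = rep(2000, 7))
  expect_length(pieces, 2)
  # boundary within one sub-fragment of the true colour change
  expect_equal(pieces[[1]]$length_um, hy$boundary_um, tolerance = 5)
  # a uniform fragment passes through untouched
  uni <- make_hybrid_fragment(a, a, lengths = c(15, 15))
  ufrag <- sample_fragment_intensities(uni$fragment, uni$image)
  expect_length(split_colour_changes(ufrag, uni$image, bg, 5,
                                     channel_max = rep(2000, 7)), 1)
  # fragments shorter than two minimum lengths are never scanned
  shorty <- make_hybrid_fragment(a, b, lengths = c(4, 4))
  sfrag <- sample_fragment_intensities(shorty$fragment, shorty$image)
  expect_length(split_colour_changes(sfrag, shorty$image, bg, 5,
                                     channel_max = rep(2000, 7)), 1)
})

test_that("the full QC pipeline keeps clean bright fragments intact", {
  set.seed(55)
  ph0 <- generate_phantom(phantom_config(n_neurons = 6,
                                         colour_jitter_sd = 0))
  qc <- run_qc(ph0$fragments, ph0$image,
               qc_config(min_length_um = 5, min_magnitude = 0.05))
  long_enough <- sum(vapply(ph0$fragments, function(f)
    f$length_um >= 5, logical(1)))
  expect_equal(length(qc$vectors), long_enough)
  expect_equal(qc$report$n_dropped_dim, 0)
})

test_that("short fragments are dropped exactly", {
  ph <- shared_phantom()
  frs <- ph$fragments
  qc <- run_qc(frs, ph$image, qc_config(min_length_um = 10,
                                        min_magnitude = 0))
  expect_equal(qc$report$n_dropped_short,
               sum(vapply(frs, function(f) f$length_um < 10, logical(1))))
})

test_that("every surviving vector satisfies the QC thresholds", {
  ph <- shared_phantom()
  qc <- run_qc(ph$fragments, ph$image,
               qc_config(min_length_um = 5, min_magnitude = 0.1))
  expect_true(all(qc$vectors$magnitude >= 0.1))
  expect_true(all(qc$vectors$length_um >= 5))
  expect_true(all(abs(sqrt(rowSums(qc$vectors$values^2)) - 1) < 1e-9))
})

test_that("QC is idempotent on its own output", {
  set.seed(56)
  ph0 <- generate_phantom(phantom_config(n_neurons = 5,
                                         colour_jitter_sd = 0))
  cfg <- qc_config(min_length_um = 5, min_magnitude = 0.05)
  once <- run_qc(ph0$fragments, ph0$image, cfg)
  twice <- run_qc(once$fragments, ph0$image, cfg)
  expect_equal(length(twice$vectors), length(once$vectors))
  expect_equal(twice$report$n_dropped_short, 0)
  expect_equal(twice$report$n_split, 0)
  expect_equal(twice$vectors$values, once$vectors$values,
               tolerance = 1e-9)
})

test_that("empty input produces an empty result, not an error", {
  ph <- shared_phantom()
  qc <- run_qc(list(), ph$image, qc_config())
  expect_null(qc$vectors)
  expect_length(qc$fragments, 0)
})

test_that("QC reports serialize to JSON", {
  ph <- shared_phantom()
  qc <- run_qc(ph$fragments[1:12], ph$image,
               qc_config(min_length_um = 5, min_magnitude = 0.1))
  p <- withr::local_tempfile(fileext = ".json")
  write_qc_report(qc, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$n_output, qc$report$n_output)
  expect_equal(back$min_length_um, 5)
})
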