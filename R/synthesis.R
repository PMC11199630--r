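#' Phantom configuration
#'
#' Parameters of the synthetic multicolour-labelled volume generator.  The
#' phantom emulates, at toy scale, a cleared-tissue volume of stochastically
#' labelled neurons: each neuron receives a colour from the Poisson
#' copy-number model, its neurites are persistent random-walk fibres, and
#' the volume is rendered as Gaussian-profile tubes over a constant
#' background with Poisson-like shot noise.
#'
#' @param n_neurons number of labelled neurons.
#' @param n_channels fluorophore channels.
#' @param mean_copies Poisson mean copies/colour/cell (default 2).
#' @param dims volume extent in voxels (x, y, z).
#' @param voxel_size micrometres per voxel (x, y, z).
#' @param n_segments fibre steps per neurite branch.
#' @param step_um arc length per fibre step.
#' @param tortuosity SD of the per-step direction jitter (radians-like;
#'   0 = straight fibres).
#' @param branch_prob probability that a neuron's fibre bifurcates at a
#'   given step (at most once per step).
#' @param radius_range neurite radius range, micrometres.
#' @param psf_sigma Gaussian tube profile SD per axis, micrometres.
#' @param brightness peak tube amplitude (detector counts).
#' @param background constant background level (counts).
#' @param shot_noise_scale scale of the Poisson-like noise: voxel values
#'   are drawn as `rpois(value / s) * s` (0 disables noise).
#' @param colour_jitter_sd per-segment SD of Gaussian colour jitter applied
#'   to the normalized colour vector (default 0.05, matching the neurite
#'   fluctuation level seen in real data).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_neurons = 20, n_channels = 7, mean_copies = 2,
                           dims = c(128, 128, 32),
                           voxel_size = c(0.5, 0.5, 1),
                           n_segments = 30, step_um = 1.5, tortuosity = 0.25,
                           branch_prob = 0.1, radius_range = c(0.3, 0.6),
                           psf_sigma = c(0.3, 0.3, 0.6), brightness = 2000,
                           background = 20, shot_noise_scale = 0,
                           colour_jitter_sd = 0.05) {
  stopifnot(n_neurons >= 1, n_channels >= 1, mean_copies > 0,
            length(dims) == 3, all(dims >= 4), all(voxel_size > 0),
            n_segments >= 2, step_um > 0, tortuosity >= 0,
            branch_prob >= 0, branch_prob <= 1,
            length(radius_range) == 2, all(radius_range > 0),
            all(psf_sigma > 0), brightness > 0, background >= 0,
            shot_noise_scale >= 0, colour_jitter_sd >= 0)
  structure(as.list(environment()), class = "phantom_config")
}

# persistent random walk inside the volume; returns an swc_trace
random_fibre <- function(cfg, neuron_type = 3L) {
  ext <- cfg$dims * cfg$voxel_size
  margin <- 0.05 * ext
  p <- stats::runif(3, margin, ext - margin)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  radius <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
  pts <- list(c(p, radius))
  branch_from <- integer(0)
  for (i in seq_len(cfg$n_segments)) {
    dir <- dir + stats::rnorm(3, 0, cfg$tortuosity)
    dir <- dir / sqrt(sum(dir^2))
    q <- p + dir * cfg$step_um
    # reflect off the walls to stay inside
    for (k in 1:3) {
      if (q[k] < margin[k]) { q[k] <- 2 * margin[k] - q[k]; dir[k] <- -dir[k] }
      hi <- ext[k] - margin[k]
      if (q[k] > hi) { q[k] <- 2 * hi - q[k]; dir[k] <- -dir[k] }
    }
    p <- q
    pts[[length(pts) + 1L]] <- c(p, radius)
    if (stats::runif(1) < cfg$branch_prob && i < cfg$n_segments)
      branch_from <- c(branch_from, length(pts))
  }
  m <- do.call(rbind, pts)
  tr <- data.frame(id = seq_len(nrow(m)), type = neuron_type,
                   x = m[, 1], y = m[, 2], z = m[, 3], radius = m[, 4],
                   parent = c(-1L, seq_len(nrow(m) - 1L)))
  # optional side branches off the main shaft
  for (b in branch_from) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    p <- c(tr$x[b], tr$y[b], tr$z[b])
    parent <- tr$id[b]
    for (i in seq_len(max(2L, cfg$n_segments %/% 3L))) {
      dir <- dir + stats::rnorm(3, 0, cfg$tortuosity)
      dir <- dir / sqrt(sum(dir^2))
      p <- pmin(pmax(p + dir * cfg$step_um, margin), ext - margin)
      id <- max(tr$id) + 1L
      tr <- rbind(tr, data.frame(id = id, type = neuron_type, x = p[1],
                                 y = p[2], z = p[3],
                                 radius = tr$radius[b], parent = parent))
      parent <- id
    }
  }
  class(tr) <- c("swc_trace", "data.frame")
  tr
}

# add a Gaussian-profile tube to an accumulator array (single channel
# weights); returns the updated array
render_tube <- function(acc, points, cfg) {
  vs <- cfg$voxel_size
  d <- dim(acc)
  sig <- cfg$psf_sigma
  reach <- 3 * sig
  pts <- densify_polyline(points, step = min(vs) / 2)
  for (i in seq_len(nrow(pts))) {
    centre <- c(pts$x[i], pts$y[i], pts$z[i])
    r <- pts$radius[i]
    lo <- pmax(um_to_index(centre - reach - r, vs), 1L)
    hi <- pmin(um_to_index(centre + reach + r, vs), d)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    gx <- exp(-pmax(abs(index_centre_um(xs, vs[1]) - centre[1]) - r, 0)^2 /
                (2 * sig[1]^2))
    gy <- exp(-pmax(abs(index_centre_um(ys, vs[2]) - centre[2]) - r, 0)^2 /
                (2 * sig[2]^2))
    gz <- exp(-pmax(abs(index_centre_um(zs, vs[3]) - centre[3]) - r, 0)^2 /
                (2 * sig[3]^2))
    block <- outer(outer(gx, gy), gz)
    cur <- acc[xs, ys, zs]
    acc[xs, ys, zs] <- pmax(cur, block)   # max-projection of tube profile
  }
  acc
}

#' Generate a synthetic multicolour-labelled phantom
#'
#' Draws one colour vector per neuron from the Poisson copy-number model,
#' grows a random fibre skeleton per neuron, renders Gaussian-profile
#' tubes with per-channel amplitudes proportional to the neuron's colour
#' (with per-neurite-segment colour jitter), adds a constant background
#' and optional Poisson-like noise, and returns the volume plus complete
#' ground truth: SWC traces, the fragment-to-neuron label table, and each
#' neuron's true colour vector.  Fully reproducible from the RNG state.
#'
#' @param cfg a [phantom_config].
#' @return A list of class `phantom`: `image` ([channel_image]), `traces`
#'   (list of `swc_trace`), `fragments` (ground-truth unbranched
#'   [neurite_fragment]s, neuron-labelled), `labels` (data.frame
#'   `fragment_id`, `neuron_id`), `colours` ([colour_vectors], one row per
#'   neuron).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  model <- label_model(cfg$n_channels, cfg$mean_copies)
  colours <- simulate_cells(model, cfg$n_neurons)
  while (nrow(colours$values) < cfg$n_neurons)   # replace dropped zero cells
    colours <- simulate_cells(model, cfg$n_neurons)
  cols <- colours$values
  d <- c(cfg$dims, cfg$n_channels)
  vol <- array(0, d)
  traces <- vector("list", cfg$n_neurons)
  fragments <- list()
  for (nu in seq_len(cfg$n_neurons)) {
    tr <- random_fibre(cfg)
    traces[[nu]] <- tr
    frs <- split_at_branches(tr, exclude_soma = TRUE,
                             neuron_id = nu,
                             id_prefix = sprintf("n%02d", nu))
    fragments <- c(fragments, frs)
    for (fr in frs) {
      # per-segment colour jitter: render the fragment in jittered chunks
      chunks <- subdivide_fragment(fr, piece_length = 5 * cfg$step_um)
      for (ch_piece in chunks) {
        cvec <- cols[nu, ]
        if (cfg$colour_jitter_sd > 0) {
          cvec <- pmax(cvec + stats::rnorm(length(cvec), 0,
                                           cfg$colour_jitter_sd), 0)
          nn <- sqrt(sum(cvec^2))
          if (nn > 0) cvec <- cvec / nn
        }
        mask <- render_tube(array(0, cfg$dims), ch_piece$points, cfg)
        nz <- which(mask > 1e-4)
        if (!length(nz)) next
        nvox <- prod(cfg$dims)
        for (ch in seq_len(cfg$n_channels)) {
          amp <- cfg$brightness * cvec[ch]
          if (amp <= 0) next
          at <- nz + (ch - 1L) * nvox
          vol[at] <- pmax(vol[at], amp * mask[nz])
        }
      }
    }
  }
  fibre_fraction <- mean(apply(vol, 1:3, max) > 0.1 * cfg$brightness)
  if (fibre_fraction > 0.3)
    warning(sprintf("volume is overcrowded (%.0f%% fibre voxels); ",
                    100 * fibre_fraction),
            "colour vectors of crossing fibres will mix")
  vol <- vol + cfg$background
  if (cfg$shot_noise_scale > 0) {
    s <- cfg$shot_noise_scale
    vol[] <- stats::rpois(length(vol), vol / s) * s
  }
  img <- channel_image(vol, cfg$voxel_size)
  structure(list(image = img, traces = traces, fragments = fragments,
                 labels = data.frame(
                   fragment_id = vapply(fragments, function(f)
                     as.character(f$fragment_id), character(1)),
                   neuron_id = vapply(fragments, function(f)
                     as.integer(f$neuron_id), integer(1))),
                 colours = colours, config = cfg),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom: %d neurons, %d channels, %s voxels\n",
              x$config$n_neurons, x$config$n_channels,
              paste(x$config$dims, collapse = "x")))
  cat(sprintf("  %d ground-truth fragments\n", length(x$fragments)))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the rendered volume (multichannel TIFF), ground-truth traces
#' (SWC), fragment labels (CSV) and true neuron colours (CSV) into a
#' directory.
#'
#' @param x a `phantom`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_channel_image(x$image, file.path(dir, "phantom.tif"))
  write_swc(x$traces, file.path(dir, "truth.swc"))
  utils::write.csv(x$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  write_colour_vectors(x$colours, file.path(dir, "true_colours.csv"))
  jsonlite::write_json(
    list(n_neurons = x$config$n_neurons, n_channels = x$config$n_channels,
         dims = x$config$dims, voxel_size = x$config$voxel_size),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build a hybrid two-colour fragment fixture
#'
#' Constructs a straight fragment whose first part carries colour A and
#' second part colour B, rendered into a small volume — the situation a
#' mis-joined crossing produces, used to exercise colour-change splitting.
#'
#' @param colour_a,colour_b numeric channel vectors (unit-normalized or
#'   not).
#' @param lengths lengths (um) of the A and B parts.
#' @param radius fragment radius (um).
#' @param brightness,background,voxel_size rendering parameters.
#' @return A list: `fragment` (spanning both parts), `image`
#'   ([channel_image]), `boundary_um` (arc length of the colour change).
#' @export
make_hybrid_fragment <- function(colour_a, colour_b, lengths = c(15, 15),
                                 radius = 0.4, brightness = 2000,
                                 background = 20,
                                 voxel_size = c(0.5, 0.5, 1)) {
  stopifnot(length(colour_a) == length(colour_b), length(lengths) == 2,
            all(lengths > 0))
  n_ch <- length(colour_a)
  a <- colour_a / sqrt(sum(colour_a^2))
  b <- colour_b / sqrt(sum(colour_b^2))
  total <- sum(lengths)
  margin <- 3
  dims <- c(ceiling((total + 2 * margin) / voxel_size[1]),
            ceiling((2 * margin) / voxel_size[2]) + 4L,
            max(6L, ceiling((2 * margin) / voxel_size[3])))
  y0 <- dims[2] * voxel_size[2] / 2
  z0 <- dims[3] * voxel_size[3] / 2
  mk_pts <- function(from, to) {
    xs <- seq(from, to, by = 1)
    if (xs[length(xs)] != to) xs <- c(xs, to)
    data.frame(x = margin + xs, y = y0, z = z0, radius = radius)
  }
  pts_a <- mk_pts(0, lengths[1])
  pts_b <- mk_pts(lengths[1], total)
  cfg <- phantom_config(n_neurons = 1, n_channels = n_ch, dims = dims,
                        voxel_size = voxel_size, brightness = brightness,
                        background = background, colour_jitter_sd = 0)
  vol <- array(0, c(dims, n_ch))
  for (part in list(list(p = pts_a, c = a), list(p = pts_b, c = b))) {
    mask <- render_tube(array(0, dims), part$p, cfg)
    for (ch in seq_len(n_ch)) {
      plane <- vol[, , , ch]
      plane <- pmax(plane, brightness * part$c[ch] * mask)
      vol[, , , ch] <- plane
    }
  }
  vol <- vol + background
  frag <- neurite_fragment(rbind(pts_a, pts_b[-1, ]),
                           fragment_id = "hybrid", neuron_id = NA)
  list(fragment = frag, image = channel_image(vol, voxel_size),
       boundary_um = lengths[1])
}
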