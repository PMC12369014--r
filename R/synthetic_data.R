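#' Specification of a synthetic SEM-like micrograph
#'
#' Describes a ground-truthed stand-in for an SEM field of adhered cocci:
#' bright, roughly 0.8 um diameter spherical cells (rendered as
#' anti-aliased discs) on a darker background, some as isolated singles
#' and some as tightly packed multi-cell aggregates, degraded by smooth
#' illumination non-uniformity and Gaussian sensor noise.
#'
#' @param image_size Image side, px (default 1024, matching the
#'   simulation lattice).
#' @param pixel_size um/px (default 0.05, so a 0.8 um coccus spans 16 px).
#' @param n_singles Number of isolated single cells.
#' @param n_clusters Number of aggregates.
#' @param cluster_size_range Integer range of cells per aggregate.
#' @param cell_diameter Cell diameter, um.
#' @param overlap_fraction Proportion of singles placed as touching pairs.
#' @param noise_sd Gaussian noise SD, intensity units on [0, 1].
#' @param gradient_amplitude Peak-to-trough illumination gradient
#'   amplitude, intensity units.
#' @param seed RNG seed.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(image_size = 1024L, pixel_size = 0.05,
                                 n_singles = 50L, n_clusters = 10L,
                                 cluster_size_range = c(3L, 6L),
                                 cell_diameter = 0.8,
                                 overlap_fraction = 0.05,
                                 noise_sd = 0.05,
                                 gradient_amplitude = 0.1,
                                 seed = 1L) {
  stopifnot(n_singles >= 0, n_clusters >= 0, cell_diameter > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            pixel_size > 0, image_size >= 8)
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size,
                 n_singles = as.integer(n_singles),
                 n_clusters = as.integer(n_clusters),
                 cluster_size_range = as.integer(cluster_size_range),
                 cell_diameter = cell_diameter,
                 overlap_fraction = overlap_fraction,
                 noise_sd = noise_sd,
                 gradient_amplitude = gradient_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Anti-aliased disc coverage added into a canvas (in place semantics via
# return): intensity ramps linearly across the half-pixel boundary band.
add_disc <- function(canvas, cx, cy, r) {
  n <- nrow(canvas)
  x0 <- max(1L, floor(cx - r - 2)); x1 <- min(n, ceiling(cx + r + 2))
  y0 <- max(1L, floor(cy - r - 2)); y1 <- min(ncol(canvas), ceiling(cy + r + 2))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
  cov <- pmin(1, pmax(0, r - d + 0.5))
  canvas[xs, ys] <- pmax(canvas[xs, ys], cov)
  canvas
}

#' Generate a synthetic micrograph with exact ground truth
#'
#' Renders the requested singles, touching single pairs and aggregates at
#' rejection-sampled non-overlapping positions, then adds a smooth
#' illumination gradient and Gaussian noise. Aggregate cells are packed at
#' center spacings of 1.0--1.3 cell radii, producing the lobed,
#' low-solidity blobs the classifier must recognize; touching pairs are
#' placed at 1.9 radii (slight overlap) to exercise watershed splitting.
#'
#' @param spec A [synthetic_image_spec()].
#' @return List with `image` (an [image_record()]), `truth` (data frame:
#'   `id`, `class`, `x`, `y`, `n_cells`), `mask` (noiseless foreground),
#'   `total_cells` and `coverage_fraction`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  n <- spec$image_size
  r <- spec$cell_diameter / 2 / spec$pixel_size  # cell radius, px
  canvas <- matrix(0, n, n)
  margin <- 4 * r
  placed <- matrix(numeric(0), 0, 3)  # x, y, clearance radius

  place <- function(clearance) {
    for (it in 1:4000) {
      x <- stats::runif(1, margin, n - margin)
      y <- stats::runif(1, margin, n - margin)
      if (nrow(placed) == 0L ||
          all((placed[, 1] - x)^2 + (placed[, 2] - y)^2 >
                (placed[, 3] + clearance)^2))
        return(c(x, y))
    }
    stop("particle demand exceeds packable area")
  }

  truth <- list()
  id <- 0L
  n_pair_cells <- 2L * (round(spec$n_singles * spec$overlap_fraction) %/% 2L)
  n_iso <- spec$n_singles - n_pair_cells

  for (i in seq_len(n_iso)) {
    p <- place(2.5 * r)
    canvas <- add_disc(canvas, p[1], p[2], r)
    placed <- rbind(placed, c(p, 1.5 * r))
    id <- id + 1L
    truth[[id]] <- data.frame(id = id, class = "single",
                              x = p[1], y = p[2], n_cells = 1L)
  }
  for (i in seq_len(n_pair_cells %/% 2L)) {
    p <- place(4.5 * r)
    ang <- stats::runif(1, 0, 2 * pi)
    d <- 1.9 * r
    for (s in c(-0.5, 0.5)) {
      cx <- p[1] + s * d * cos(ang); cy <- p[2] + s * d * sin(ang)
      canvas <- add_disc(canvas, cx, cy, r)
      id <- id + 1L
      truth[[id]] <- data.frame(id = id, class = "single",
                                x = cx, y = cy, n_cells = 1L)
    }
    placed <- rbind(placed, c(p, 2.5 * r))
  }
  for (i in seq_len(spec$n_clusters)) {
    k <- sample(seq(spec$cluster_size_range[1], spec$cluster_size_range[2]), 1)
    p <- place(2.5 * r + 1.3 * r * k / 2)
    cells <- matrix(p, 1, 2)
    canvas <- add_disc(canvas, p[1], p[2], r)
    for (j in seq_len(k - 1L)) {
      base <- cells[sample.int(nrow(cells), 1L), ]
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 1.0, 1.3) * r
      cx <- base[1] + d * cos(ang); cy <- base[2] + d * sin(ang)
      cells <- rbind(cells, c(cx, cy))
      canvas <- add_disc(canvas, cx, cy, r)
    }
    placed <- rbind(placed, c(p, 1.5 * r + 1.3 * r * k / 2))
    id <- id + 1L
    truth[[id]] <- data.frame(id = id, class = "aggregate",
                              x = mean(cells[, 1]), y = mean(cells[, 2]),
                              n_cells = k)
  }

  mask <- (canvas >= 0.5) * 1
  bg <- 0.2
  xs <- seq(0, 1, length.out = n)
  gradient <- spec$gradient_amplitude *
    outer(xs, seq(0, 1, length.out = n), function(a, b) (a + b) / 2)
  img <- bg + gradient + 0.6 * canvas +
    matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)

  truth <- if (id > 0L) do.call(rbind, truth) else
    data.frame(id = integer(0), class = character(0), x = numeric(0),
               y = numeric(0), n_cells = integer(0))
  list(image = image_record(img, spec$pixel_size,
                            source_id = sprintf("synthetic-%d", spec$seed)),
       truth = truth,
       mask = mask,
       total_cells = sum(truth$n_cells),
       coverage_fraction = sum(mask) / length(mask))
}

#' Generate a synthetic balanced count table
#'
#' Emulates the factorial design of the adhesion-count comparisons:
#' treatment (hydro-softened vs unsoftened) crossed with morphology
#' (single vs aggregate), Gaussian counts rounded to integers and clipped
#' at zero.
#'
#' @param mean_a,mean_b Treatment group means (applied to both
#'   morphologies).
#' @param sd Within-cell standard deviation.
#' @param n_per_group Replicates per treatment x morphology cell (>= 2).
#' @param seed RNG seed.
#' @return Data frame with columns `treatment`, `morphology`, `count`.
#' @export
generate_count_table <- function(mean_a, mean_b, sd, n_per_group = 4L,
                                 seed = 1L) {
  stopifnot(n_per_group >= 2, sd > 0)
  set.seed(seed)
  grid <- expand.grid(treatment = c("hydro-softened", "unsoftened"),
                      morphology = c("single", "aggregate"),
                      rep = seq_len(n_per_group),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(grid$treatment == "hydro-softened", mean_a, mean_b)
  grid$count <- pmax(0, round(stats::rnorm(nrow(grid), mu, sd)))
  grid[c("treatment", "morphology", "count")]
}
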