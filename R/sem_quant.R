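#' Grayscale micrograph container
#'
#' @param pixels Numeric matrix of intensities (any finite range; the
#'   pipeline rescales).
#' @param pixel_size Physical pixel size, um/pixel.
#' @param source_id Free-text identifier.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, pixel_size, source_id = "") {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), all(is.finite(pixels)), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 source_id = as.character(source_id)),
            class = "image_record")
}

#' Read a TIFF/PNG micrograph
#'
#' @param path Image path (TIFF or PNG, grayscale or RGB; RGB is averaged).
#' @param pixel_size um/pixel.
#' @return An [image_record()].
#' @export
read_micrograph <- function(path, pixel_size) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != EBImage::Grayscale)
    img <- EBImage::channel(img, "gray")
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2L) px <- px[, , 1L]
  image_record(px, pixel_size, source_id = basename(path))
}

#' Preprocess a micrograph for segmentation
#'
#' Applies, in order: contrast-limited adaptive histogram equalization
#' (local contrast recovery without over-enhancement), Gaussian smoothing
#' (high-frequency sensor noise), and background subtraction using a
#' morphological opening with a structuring element much larger than a
#' bacterium as the background estimate (corrects smooth illumination
#' non-uniformity). Output intensities are rescaled to [0, 1].
#'
#' @param img An [image_record()].
#' @param clahe_clip CLAHE clip limit (EBImage `limit`); higher means
#'   stronger equalization, 0 disables the equalization step.
#' @param clahe_ntiles Number of CLAHE tiles per axis.
#' @param gaussian_sigma Gaussian smoothing sigma, px.
#' @param bg_radius Radius, px, of the disc structuring element of the
#'   background opening; must be much larger than a particle.
#' @return A preprocessed [image_record()] with intensities in [0, 1].
#' @export
preprocess <- function(img, clahe_clip = 2, clahe_ntiles = 8L,
                       gaussian_sigma = 2, bg_radius = 40L) {
  stopifnot(inherits(img, "image_record"))
  dims <- dim(img$pixels)
  brush_side <- 2L * as.integer(bg_radius) + 1L
  if (brush_side > min(dims))
    stop("background kernel larger than image")
  x <- EBImage::Image(img$pixels)
  rng <- range(img$pixels)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  # a constant (featureless) image carries no local contrast to equalize
  if (clahe_clip > 0 && diff(rng) > 0)
    x <- EBImage::clahe(x, nx = clahe_ntiles, ny = clahe_ntiles,
                        limit = clahe_clip, keep.range = TRUE)
  x <- EBImage::gblur(x, sigma = gaussian_sigma)
  bg <- EBImage::opening(x, EBImage::makeBrush(brush_side, shape = "disc"))
  x <- x - bg
  # clip, do not re-stretch: re-normalizing here would inflate residual
  # noise on sparse or empty fields
  px <- pmin(pmax(EBImage::imageData(x), 0), 1)
  image_record(px, img$pixel_size, img$source_id)
}

#' Binarize a preprocessed micrograph
#'
#' Local-mean adaptive threshold (a pixel is foreground when it exceeds
#' the mean of its `block_size` window by more than `offset`), followed by
#' area-based filtering that removes connected regions smaller than
#' `min_area` pixels (debris and noise speckles).
#'
#' @param img Preprocessed [image_record()] with intensities in [0, 1].
#' @param block_size Odd window size, px (>= 3).
#' @param offset Threshold offset on [0, 1] intensities.
#' @param min_area Minimum connected-region area, px.
#' @return Binary matrix (0/1) of the same dimensions.
#' @export
binarize <- function(img, block_size = 51L, offset = 0.1, min_area = 50L) {
  stopifnot(inherits(img, "image_record"))
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L)
    stop("block_size must be odd and >= 3")
  half <- (block_size - 1L) / 2L
  mask <- EBImage::thresh(EBImage::Image(img$pixels),
                          w = half, h = half, offset = offset)
  mask <- EBImage::imageData(mask)
  if (min_area > 0 && any(mask > 0)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    mask <- matrix(as.numeric(lab %in% keep), nrow(mask), ncol(mask))
  }
  mask
}

# Local maxima of the distance map with a minimum mutual separation:
# candidates are neighborhood maxima; greedy suppression (by decreasing
# peak height) enforces the separation.
find_peaks <- function(dm, min_distance) {
  side <- 2L * as.integer(ceiling(min_distance)) + 1L
  dmx <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(dm), EBImage::makeBrush(side, shape = "disc")))
  cand <- which(dm > 0 & dm >= dmx, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cand)
  ord <- order(dm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  acc <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0L ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_distance^2) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Split touching particles by marker-controlled watershed
#'
#' Computes the Euclidean distance transform of the mask, places markers
#' at its local maxima subject to a minimum mutual separation, and grows
#' the markers over the foreground (marker-controlled watershed), so that
#' blobs containing several distance peaks are partitioned along their
#' necks. Every foreground pixel receives exactly one label.
#'
#' @param mask Binary matrix from [binarize()].
#' @param min_distance Minimum marker separation, px; peaks closer than
#'   this merge into one object.
#' @return Integer label matrix (0 = background).
#' @export
split_touching <- function(mask, min_distance = 12) {
  mask <- (as.matrix(mask) > 0) * 1
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
  peaks <- find_peaks(dm, min_distance)
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  seeds[peaks] <- seq_len(nrow(peaks))
  lab <- EBImage::propagate(EBImage::Image(dm), EBImage::Image(seeds),
                            mask = EBImage::Image(mask) > 0, lambda = 1e-4)
  lab <- EBImage::imageData(lab)
  # pixels of components without any marker (cannot occur for distance
  # maxima, but guard): fall back to connected-component labels
  orphan <- mask > 0 & lab == 0
  if (any(orphan)) {
    cc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
    lab[orphan] <- max(lab) + cc[orphan]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Label connected components of a binary mask
#'
#' @param mask Binary matrix.
#' @return Integer label matrix.
#' @export
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((as.matrix(mask) > 0) * 1)))
  storage.mode(lab) <- "integer"
  lab
}

# Convex-hull area of a pixel set, treating pixels as unit squares:
# lattice-polygon area of the hull of pixel centers plus the boundary
# correction (Pick).
hull_area <- function(coords) {
  if (nrow(coords) < 3L) return(nrow(coords))
  h <- grDevices::chull(coords)
  xy <- coords[h, , drop = FALSE]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  a <- abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
  per <- sum(sqrt(rowSums((xy - xy[j, , drop = FALSE])^2)))
  a + per / 2 + 1
}

#' Measure particle morphometrics
#'
#' For each label: area (px and um^2), perimeter (length of the traced
#' object contour), circularity `4*pi*A/P^2` (1 for a disc, lower for
#' elongated or lobed objects), solidity (area over convex-hull area; low
#' for multi-lobed aggregates) and centroid. Each object's binary mask is
#' smoothed by morphological closing before measurement to suppress
#' thresholding roughness.
#'
#' @param labels Integer label matrix from [split_touching()] or
#'   [label_components()].
#' @param pixel_size um/pixel.
#' @param smooth_size Side of the closing brush, px (odd); 0 disables
#'   smoothing.
#' @return Data frame of class `particle_table`: one row per particle with
#'   columns `label`, `area_px`, `area_um2`, `perimeter`, `circularity`,
#'   `solidity`, `centroid_x`, `centroid_y`. Empty mask gives zero rows.
#' @export
measure <- function(labels, pixel_size, smooth_size = 5L) {
  labels <- as.matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  out <- data.frame(label = integer(0), area_px = numeric(0),
                    area_um2 = numeric(0), perimeter = numeric(0),
                    circularity = numeric(0), solidity = numeric(0),
                    centroid_x = numeric(0), centroid_y = numeric(0))
  class(out) <- c("particle_table", "data.frame")
  if (length(ids) == 0L) return(out)
  pad <- max(2L, smooth_size)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    w <- which(labels == id, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - pad); r1 <- min(nrow(labels), max(w[, 1]) + pad)
    c0 <- max(1L, min(w[, 2]) - pad); c1 <- min(ncol(labels), max(w[, 2]) + pad)
    crop <- (labels[r0:r1, c0:c1] == id) * 1
    if (smooth_size >= 3L) {
      crop <- EBImage::imageData(EBImage::closing(
        EBImage::Image(crop),
        EBImage::makeBrush(as.integer(smooth_size), shape = "disc")))
    }
    area <- sum(crop)
    oc <- EBImage::ocontour(EBImage::Image(crop))[[1]]
    nn <- nrow(oc)
    jj <- c(nn, seq_len(nn - 1L))
    per <- sum(sqrt(rowSums((oc - oc[jj, , drop = FALSE])^2)))
    if (per <= 0) per <- 4  # single-pixel object
    coords <- which(crop == 1, arr.ind = TRUE)
    rows[[k]] <- data.frame(
      label = id, area_px = area, area_um2 = area * pixel_size^2,
      perimeter = per, circularity = 4 * pi * area / per^2,
      solidity = min(1, area / hull_area(coords)),
      centroid_x = mean(w[, 1]), centroid_y = mean(w[, 2]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("particle_table", "data.frame")
  out
}

#' Classify particles as single cells or aggregates
#'
#' A particle is a `single` iff its area does not exceed
#' `area_single_max`, its circularity is at least `circ_min` and its
#' solidity at least `solid_min` (all comparisons inclusive); otherwise it
#' is an `aggregate`. Area threshold is expressed in um^2 so pixel scale
#' cannot silently change the classification.
#'
#' @param particles A `particle_table` from [measure()].
#' @param area_single_max Maximum single-cell area, um^2; default 1.5x the
#'   area of a 0.8 um diameter coccus.
#' @param circ_min Minimum circularity of a single.
#' @param solid_min Minimum solidity of a single.
#' @return The table with a `morphology_class` factor column added.
#' @export
classify <- function(particles, area_single_max = 1.5 * pi * 0.4^2,
                     circ_min = 0.7, solid_min = 0.9) {
  stopifnot(is.data.frame(particles))
  single <- particles$area_um2 <= area_single_max &
    particles$circularity >= circ_min &
    particles$solidity >= solid_min
  particles$morphology_class <- factor(ifelse(single, "single", "aggregate"),
                                       levels = c("single", "aggregate"))
  particles
}

#' Summarize adhesion on one micrograph
#'
#' Counts by morphology class, surface coverage, and the coverage-scaled
#' bacterial count: `scaled_count = coverage_fraction /
#' per_bacterium_fraction`, using the mean surface fraction occupied by
#' one bacterium (default 0.0077% of the field).
#'
#' @param particles Classified `particle_table`.
#' @param mask Binary mask the particles came from.
#' @param per_bacterium_fraction Surface fraction per bacterium
#'   (default 7.7e-5).
#' @return A list of class `adhesion_summary` with `n_total`, `n_single`,
#'   `n_aggregate`, `coverage_fraction`, `scaled_count`.
#' @examples
#' # coverage of 0.0077% of the field corresponds to one bacterium
#' @export
summarize_adhesion <- function(particles, mask,
                               per_bacterium_fraction = 7.7e-5) {
  if (per_bacterium_fraction <= 0)
    stop("per_bacterium_fraction must be positive")
  mask <- as.matrix(mask) > 0
  cov <- sum(mask) / length(mask)
  n_single <- sum(particles$morphology_class == "single")
  n_aggregate <- sum(particles$morphology_class == "aggregate")
  structure(list(n_total = n_single + n_aggregate,
                 n_single = n_single, n_aggregate = n_aggregate,
                 coverage_fraction = cov,
                 scaled_count = cov / per_bacterium_fraction),
            class = "adhesion_summary")
}

#' @export
print.adhesion_summary <- function(x, ...) {
  cat(sprintf(
    "Adhesion summary: %d particles (%d single, %d aggregate)\ncoverage %.4f%%, scaled count %.1f bacteria\n",
    x$n_total, x$n_single, x$n_aggregate,
    100 * x$coverage_fraction, x$scaled_count))
  invisible(x)
}

#' Full micrograph quantification pipeline
#'
#' Runs preprocessing, binarization, particle labeling, morphometrics,
#' classification and summary in one call. A particle is a connected
#' component of the binary mask (an adhered single cell or a
#' multi-cell aggregate); setting `split = TRUE` instead labels via the
#' marker-controlled watershed, which partitions aggregates into their
#' constituent cells (markers farther apart than `min_distance`) — useful
#' for per-cell counting, at the cost of dissolving aggregate morphology.
#'
#' @param img An [image_record()].
#' @param split Label by watershed-split cells instead of connected
#'   components?
#' @param min_distance Marker separation for [split_touching()], px.
#' @param ... Passed to [classify()].
#' @param block_size,offset,min_area Passed to [binarize()].
#' @return List with `particles` (classified table), `mask`, `labels`,
#'   and `summary` (an `adhesion_summary`).
#' @export
quantify_image <- function(img, split = FALSE, min_distance = 12,
                           block_size = 51L, offset = 0.1, min_area = 50L,
                           ...) {
  pre <- preprocess(img)
  mask <- binarize(pre, block_size = block_size, offset = offset,
                   min_area = min_area)
  labels <- if (split) split_touching(mask, min_distance = min_distance)
            else label_components(mask)
  particles <- classify(measure(labels, img$pixel_size), ...)
  list(particles = particles, mask = mask, labels = labels,
       summary = summarize_adhesion(particles, mask))
}

#' Write a per-image particle table to CSV
#'
#' @param particles Classified `particle_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE)
  invisible(path)
}
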