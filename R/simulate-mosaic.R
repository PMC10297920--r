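#' Simulate a boundary-stained muscle cross-section
#'
#' Generates a synthetic transverse muscle section in the style of a WGA
#' (wheat germ agglutinin) stained image: dark fiber interiors separated by a
#' bright extracellular-matrix boundary network. Fiber geometry comes from a
#' seeded Voronoi tessellation of spread points; each cell is then eroded so a
#' boundary stripe of roughly `boundary_width_px` separates neighbouring
#' fibers (the image frame is treated as boundary too, so no fiber interior
#' touches the border). The ground-truth label map and per-fiber pixel areas
#' are returned alongside the image, so segmentation accuracy can be scored
#' exactly.
#'
#' The `area_cv` knob controls the regularity of the seed point process
#' (best-candidate sampling; small values give near-regular packings, values
#' near the Poisson limit of about 0.53 give irregular ones). It shapes, but
#' does not exactly fix, the realized coefficient of variation of fiber areas.
#'
#' @param n_fibers Number of fibers to tessellate.
#' @param mean_area_px Target mean interior area per fiber, in pixels.
#' @param area_cv Area variability knob in `[0, 1)`.
#' @param boundary_width_px Approximate boundary stripe width (pixels).
#' @param boundary_intensity,interior_intensity Intensities of the boundary
#'   network and the fiber interiors; the boundary must be brighter
#'   (boundary-stained contrast).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (0 gives a noiseless two-level image).
#' @param image_shape Optional `c(rows, cols)`. When omitted, a square image
#'   just large enough for `n_fibers` fibers of `mean_area_px` (plus boundary
#'   loss) is used. A shape too small to hold the requested fibers is an
#'   error, never a silently smaller mosaic.
#' @param um_per_px Optional calibration forwarded to the image.
#' @param seed Integer seed; the same spec and seed give bit-identical output.
#'
#' @return A list of class `fiber_mosaic`:
#'   * `image` — [image_grid()] (8-bit),
#'   * `label_map` — integer matrix, 0 for boundary pixels, fiber id otherwise;
#'     the nonzero labels partition the interior pixels,
#'   * `fibers` — tibble with `fiber_id`, `area_px` (exactly the label-map
#'     pixel count), `centroid_row`, `centroid_col`.
#' @export
#' @examples
#' m <- simulate_fiber_mosaic(n_fibers = 20, mean_area_px = 900, seed = 1)
#' sum(m$fibers$area_px) + sum(m$label_map == 0) == prod(dim(m$label_map))
simulate_fiber_mosaic <- function(n_fibers = 100,
                                  mean_area_px = 5000,
                                  area_cv = 0.25,
                                  boundary_width_px = 3,
                                  boundary_intensity = 255,
                                  interior_intensity = 40,
                                  noise_sd = 0,
                                  image_shape = NULL,
                                  um_per_px = NULL,
                                  seed = 1) {
  check_count(n_fibers, "n_fibers")
  check_positive_scalar(mean_area_px, "mean_area_px")
  abort_if(!is_scalar_number(area_cv) || area_cv < 0 || area_cv >= 1,
           "`area_cv` must lie in [0, 1)")
  check_count(boundary_width_px, "boundary_width_px")
  abort_if(boundary_intensity <= interior_intensity,
           "`boundary_intensity` must exceed `interior_intensity` (boundary-stained contrast)")
  abort_if(boundary_intensity <= 0 || boundary_intensity > 255 ||
             interior_intensity < 0 || interior_intensity >= 255,
           "intensities must satisfy 0 <= interior < 255, 0 < boundary <= 255")
  abort_if(!is_scalar_number(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")

  erode_r <- ceiling(boundary_width_px / 2)
  if (is.null(image_shape)) {
    # cell area before erosion: A - c*r*sqrt(A) = mean_area, perimeter ~ 3.8 sqrt(A)
    cr <- 3.8 * erode_r
    sqrtA <- (cr + sqrt(cr^2 + 4 * mean_area_px)) / 2
    side <- ceiling(sqrt(n_fibers * sqrtA^2))
    image_shape <- c(side, side)
  }
  abort_if(length(image_shape) != 2 || any(image_shape < 1),
           "`image_shape` must be two positive integers")
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  abort_if(as.numeric(nr) * nc < n_fibers * mean_area_px,
           "infeasible packing: %d x %d px cannot hold %d fibers of mean area %g px",
           nr, nc, n_fibers, mean_area_px)

  withr::with_seed(seed, {
    pts <- spread_points(n_fibers, nr, nc, area_cv)
    label <- voronoi_labels(pts, nr, nc)
    label_map <- erode_labels(label, erode_r)
    areas <- tabulate(label_map, nbins = n_fibers)
    abort_if(any(areas == 0),
             "infeasible packing: a fiber interior vanished after boundary erosion; enlarge the image or reduce n_fibers")
    px <- matrix(interior_intensity, nr, nc)
    px[label_map == 0] <- boundary_intensity
    if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
    px <- round(pmin(pmax(px, 0), 255))
  })

  idx <- which(label_map > 0, arr.ind = TRUE)
  cent <- tibble::tibble(
    fiber_id = seq_len(n_fibers),
    area_px = areas,
    centroid_row = as.numeric(tapply(idx[, 1], label_map[label_map > 0], mean)),
    centroid_col = as.numeric(tapply(idx[, 2], label_map[label_map > 0], mean))
  )
  structure(list(image = image_grid(px, 8L, um_per_px = um_per_px),
                 label_map = label_map, fibers = cent,
                 params = list(n_fibers = n_fibers, mean_area_px = mean_area_px,
                               area_cv = area_cv,
                               boundary_width_px = boundary_width_px,
                               boundary_intensity = boundary_intensity,
                               interior_intensity = interior_intensity,
                               noise_sd = noise_sd, image_shape = c(nr, nc),
                               seed = seed)),
            class = "fiber_mosaic")
}

# best-candidate (Mitchell) sampling followed by Lloyd (centroidal Voronoi)
# relaxation; the requested area CV sets both the candidate count and the
# number of relaxation sweeps (a Poisson process has cell-area CV ~ 0.53,
# relaxation drives it toward a regular packing)
spread_points <- function(n, nr, nc, area_cv) {
  k <- max(1L, min(48L, round((0.53 / max(area_cv, 0.08))^2)))
  pr <- numeric(n); pc <- numeric(n)
  pr[1] <- runif(1, 1, nr); pc[1] <- runif(1, 1, nc)
  if (n > 1) for (i in 2:n) {
    cr <- runif(k, 1, nr); cc <- runif(k, 1, nc)
    prev_r <- pr[seq_len(i - 1)]; prev_c <- pc[seq_len(i - 1)]
    dmin <- vapply(seq_len(k), function(j)
      min((prev_r - cr[j])^2 + (prev_c - cc[j])^2), numeric(1))
    best <- which.max(dmin)
    pr[i] <- cr[best]; pc[i] <- cc[best]
  }
  pts <- cbind(pr, pc)
  sweeps <- min(6, round(10 * max(0, 0.53 - min(area_cv, 0.53)) / 0.53))
  if (sweeps > 0) {
    # relax on a stride-3 subgrid: ample resolution for centroid updates
    rows <- seq(1, nr, by = 3); cols <- seq(1, nc, by = 3)
    rv <- rep(rows, times = length(cols))
    cv <- rep(cols, each = length(rows))
    for (s in seq_len(sweeps)) {
      lab <- as.vector(voronoi_labels(pts, length(rows), length(cols),
                                      row_coords = rows, col_coords = cols))
      sums <- rowsum(cbind(rv, cv, 1), lab)
      hit <- as.integer(rownames(sums))
      pts[hit, 1] <- sums[, 1] / sums[, 3]
      pts[hit, 2] <- sums[, 2] / sums[, 3]
    }
  }
  pts
}

voronoi_labels <- function(pts, nr, nc, row_coords = seq_len(nr),
                           col_coords = seq_len(nc)) {
  rowm <- matrix(row_coords, nr, nc)
  colm <- matrix(col_coords, nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc)
  label <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(pts))) {
    d <- (rowm - pts[i, 1])^2 + (colm - pts[i, 2])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    label[upd] <- i
  }
  label
}

# pixels whose disk(r) neighbourhood is entirely same-labelled stay interior;
# out-of-frame counts as foreign, so the frame becomes boundary as well
erode_labels <- function(label, r) {
  nr <- nrow(label); nc <- ncol(label)
  pad <- matrix(-1L, nr + 2 * r, nc + 2 * r)
  pad[r + seq_len(nr), r + seq_len(nc)] <- label
  interior <- matrix(TRUE, nr, nc)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    if (di^2 + dj^2 > r^2) next
    shifted <- pad[r + di + seq_len(nr), r + dj + seq_len(nc)]
    interior <- interior & (shifted == label)
  }
  out <- label
  out[!interior] <- 0L
  out
}

#' Simulate an ATPase-stained fiber-typing image
#'
#' Generates a mosaic in the style of an ATPase stain: slow-twitch (type I)
#' fibers render dark, fast-twitch (type II) fibers render lighter grey, and
#' the boundary network stays brightest. The number of slow fibers is
#' `round(proportion_slow * n_fibers)` with ties rounded to even.
#'
#' @param proportion_slow Target slow-twitch proportion in `[0, 1]`.
#' @param n_fibers,mean_area_px,noise_sd,image_shape,seed As in
#'   [simulate_fiber_mosaic()].
#' @param slow_intensity,fast_intensity Interior intensities of the two fiber
#'   classes (slow must be darker).
#'
#' @return A list of class `atpase_mosaic` with `image`, `label_map`,
#'   and `fibers` (tibble adding a `type` column, `"slow"`/`"fast"`).
#' @export
simulate_atpase_image <- function(proportion_slow,
                                  n_fibers = 50,
                                  mean_area_px = 4000,
                                  slow_intensity = 40,
                                  fast_intensity = 110,
                                  noise_sd = 0,
                                  image_shape = NULL,
                                  seed = 1) {
  abort_if(!is_scalar_number(proportion_slow) ||
             proportion_slow < 0 || proportion_slow > 1,
           "`proportion_slow` must lie in [0, 1]")
  abort_if(slow_intensity >= fast_intensity,
           "`slow_intensity` must be darker than `fast_intensity`")
  mos <- simulate_fiber_mosaic(n_fibers = n_fibers, mean_area_px = mean_area_px,
                               interior_intensity = slow_intensity,
                               noise_sd = 0, image_shape = image_shape,
                               seed = seed)
  n_slow <- round(proportion_slow * n_fibers)  # round-half-even
  withr::with_seed(seed + 1L, {
    slow_ids <- sample(n_fibers, n_slow)
    px <- mos$image$pixels
    fast_mask <- mos$label_map > 0 & !(mos$label_map %in% slow_ids)
    px[fast_mask] <- fast_intensity
    if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
    px <- round(pmin(pmax(px, 0), 255))
  })
  fibers <- dplyr::mutate(mos$fibers,
    type = ifelse(.data$fiber_id %in% slow_ids, "slow", "fast"))
  structure(list(image = image_grid(px, 8L), label_map = mos$label_map,
                 fibers = fibers,
                 params = c(mos$params, list(proportion_slow = proportion_slow,
                                             n_slow = n_slow))),
            class = "atpase_mosaic")
}
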