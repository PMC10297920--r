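#' Morphometry configuration
#'
#' Parameters of the histology pipeline. The defaults are the published
#' candidate-fiber selection rules: areas from 1400 to 80,000 pixels and
#' circularity from 0.2 to 1.0, both intervals closed. Binarization defaults
#' to Otsu's threshold on the Gaussian-smoothed grayscale; a fixed threshold
#' can be supplied instead.
#'
#' @param gaussian_sigma_px Gaussian smoothing sigma in pixels (0 disables
#'   smoothing).
#' @param binarization `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity threshold used when
#'   `binarization = "fixed"`.
#' @param foreground `"dark"` when fiber interiors are darker than the
#'   boundary stain (WGA-like images), `"bright"` otherwise.
#' @param area_min_px,area_max_px Closed area acceptance interval, pixels.
#' @param circularity_min,circularity_max Closed circularity acceptance
#'   interval.
#' @param adhesion_opening_radius_px Disk radius of the morphological opening
#'   used to split adhered fibers (0 disables).
#' @param fill_holes Fill holes inside candidate fibers before measuring.
#' @param circularity_epsilon Digitization overshoot allowed above 1 before
#'   clipping; circularity is reported clipped to
#'   `[0, 1 + circularity_epsilon]`.
#' @return A list of class `morphometry_config`.
#' @export
morphometry_config <- function(gaussian_sigma_px = 1,
                               binarization = c("otsu", "fixed"),
                               fixed_threshold = NULL,
                               foreground = c("dark", "bright"),
                               area_min_px = 1400,
                               area_max_px = 80000,
                               circularity_min = 0.2,
                               circularity_max = 1.0,
                               adhesion_opening_radius_px = 3,
                               fill_holes = TRUE,
                               circularity_epsilon = 0.05) {
  binarization <- match.arg(binarization)
  foreground <- match.arg(foreground)
  cfg <- list(gaussian_sigma_px = gaussian_sigma_px,
              binarization = binarization, fixed_threshold = fixed_threshold,
              foreground = foreground,
              area_min_px = area_min_px, area_max_px = area_max_px,
              circularity_min = circularity_min,
              circularity_max = circularity_max,
              adhesion_opening_radius_px = adhesion_opening_radius_px,
              fill_holes = fill_holes,
              circularity_epsilon = circularity_epsilon)
  viol <- validate_morphometry_config(cfg)
  abort_if(length(viol) > 0, paste(viol, collapse = "; "))
  structure(cfg, class = "morphometry_config")
}

validate_morphometry_config <- function(cfg) {
  v <- character()
  if (!is_scalar_number(cfg$gaussian_sigma_px) || cfg$gaussian_sigma_px < 0)
    v <- c(v, "gaussian_sigma_px must be >= 0")
  if (!is_scalar_number(cfg$area_min_px) || !is_scalar_number(cfg$area_max_px) ||
      cfg$area_min_px >= cfg$area_max_px)
    v <- c(v, "area_min_px must be smaller than area_max_px")
  if (!is_scalar_number(cfg$circularity_min) || cfg$circularity_min < 0)
    v <- c(v, "circularity_min must be >= 0")
  if (!is_scalar_number(cfg$circularity_max) ||
      cfg$circularity_min > cfg$circularity_max ||
      cfg$circularity_max > 1 + (cfg$circularity_epsilon %||% 0.05))
    v <- c(v, "circularity bounds must satisfy 0 <= circularity_min <= circularity_max <= 1 + epsilon")
  if (!is_scalar_number(cfg$adhesion_opening_radius_px) ||
      cfg$adhesion_opening_radius_px < 0)
    v <- c(v, "adhesion_opening_radius_px must be >= 0")
  if (identical(cfg$binarization, "fixed") && !is_scalar_number(cfg$fixed_threshold))
    v <- c(v, "fixed binarization requires fixed_threshold")
  v
}

#' Preprocess a stained section image to a binary fiber mask
#'
#' Grayscale conversion (done on construction for RGB input), Gaussian
#' smoothing, and binarization. Foreground in the returned mask is the
#' candidate fiber interior: for boundary-stained images
#' (`foreground = "dark"`) that is everything below the threshold.
#'
#' @param image An [image_grid()] (or plain matrix).
#' @param config A [morphometry_config()].
#' @return A binary [image_grid()] (pixels 0/1) with attributes `threshold`
#'   (the intensity cut actually applied) and `binary = TRUE`.
#' @export
preprocess_image <- function(image, config = morphometry_config()) {
  image <- as_image_grid(image)
  px <- image$pixels
  abort_if(max(px) == min(px), "no contrast: image is constant")
  if (config$gaussian_sigma_px > 0)
    px <- EBImage::gblur(px, sigma = config$gaussian_sigma_px)
  maxval <- 2^image$bit_depth - 1
  thr <- if (config$binarization == "fixed") {
    config$fixed_threshold
  } else {
    sc <- pmin(pmax(px / maxval, 0), 1)
    EBImage::otsu(EBImage::Image(sc), range = c(0, 1),
                  levels = maxval + 1) * maxval
  }
  fg <- if (config$foreground == "dark") px < thr else px > thr
  out <- image_grid(matrix(as.numeric(fg), nrow(px), ncol(px)),
                    bit_depth = image$bit_depth, um_per_px = image$um_per_px)
  attr(out, "threshold") <- thr
  attr(out, "binary") <- TRUE
  out
}

# 4-neighbourhood erosion used by the perimeter estimator
erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  m &
    p[1:nr, 2:(nc + 1)] & p[3:(nr + 2), 2:(nc + 1)] &
    p[2:(nr + 1), 1:nc] & p[2:(nr + 1), 3:(nc + 2)]
}

#' Perimeter of a binary region
#'
#' Weighted border-pixel perimeter estimator (Benkrid-style, the
#' 4-neighbourhood estimator used by common image-analysis toolkits): border
#' pixels are classified by their local configuration and weighted 1 for
#' isothetic steps, `sqrt(2)` for diagonal steps and `(1 + sqrt(2))/2` for
#' corners, which removes most of the staircase bias of naive edge counting
#' (a digitized disk measures within a few percent of `2*pi*r`).
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` is the region.
#' @return Estimated perimeter in pixel units.
#' @export
region_perimeter <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(0)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- matrix(0, nr + 2, nc + 2)
  border[2:(nr + 1), 2:(nc + 1)] <- (mask & !erode4(mask)) * 1
  kern <- matrix(c(10, 2, 10, 2, 1, 2, 10, 2, 10), 3, 3)
  conv <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    conv <- conv + kern[di + 2, dj + 2] *
      border[2 + di + 0:(nr - 1), 2 + dj + 0:(nc - 1)]
  }
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  core <- border[2:(nr + 1), 2:(nc + 1)] > 0
  sum(w[conv[core] + 1])
}

#' Isoperimetric circularity
#'
#' `4 * pi * A / P^2`: 1 for an ideal disk, smaller for elongated or ragged
#' shapes. Values are clipped to `[0, 1 + epsilon]`; perimeter estimators on
#' digitized shapes can overshoot 1 slightly, which is why a small epsilon
#' (default 0.05) is tolerated before clipping.
#'
#' @param area_px Region area (pixels), positive.
#' @param perimeter_px Region perimeter (pixels), positive.
#' @param epsilon Allowed overshoot above 1.
#' @return Circularity value(s) in `[0, 1 + epsilon]`.
#' @export
#' @examples
#' circularity(pi * 50^2, 2 * pi * 50)  # ideal disk: exactly 1
#' circularity(1000, 220)               # 10 x 100 rectangle: ~0.2596
circularity <- function(area_px, perimeter_px, epsilon = 0.05) {
  abort_if(any(area_px <= 0) || any(perimeter_px <= 0),
           "area and perimeter must be positive")
  pmin(pmax(4 * pi * area_px / perimeter_px^2, 0), 1 + epsilon)
}

#' Apply the candidate-fiber acceptance rules to a region table
#'
#' Classifies regions by the closed area interval, the closed circularity
#' interval, and border contact. Rejection reasons are mutually exclusive and
#' assigned in a fixed order — `border_touching`, `too_small`, `too_large`,
#' `non_circular` — so a region failing several checks reports the first.
#'
#' @param regions Data frame with columns `area_px`, `circularity` and
#'   (optionally) logical `border_touching` (assumed `FALSE` when absent).
#' @param config A [morphometry_config()].
#' @return The input as a tibble with `status` (`"accepted"`/`"rejected"`)
#'   and `reason` (`NA` when accepted) columns appended.
#' @export
classify_regions <- function(regions, config = morphometry_config()) {
  regions <- tibble::as_tibble(regions)
  bt <- if ("border_touching" %in% names(regions)) regions$border_touching
        else rep(FALSE, nrow(regions))
  reason <- rep(NA_character_, nrow(regions))
  reason[is.na(reason) & bt] <- "border_touching"
  reason[is.na(reason) & regions$area_px < config$area_min_px] <- "too_small"
  reason[is.na(reason) & regions$area_px > config$area_max_px] <- "too_large"
  reason[is.na(reason) & (regions$circularity < config$circularity_min |
                          regions$circularity > config$circularity_max)] <- "non_circular"
  dplyr::mutate(regions,
                status = ifelse(is.na(reason), "accepted", "rejected"),
                reason = reason)
}

#' Segment candidate muscle fibers from a binary mask
#'
#' Morphological opening with a disk (to split thin adhesions between
#' fibers), optional hole filling, connected-component labelling, and
#' per-region measurement: pixel area, weighted-estimator perimeter,
#' circularity, centroid, and the acceptance status from
#' [classify_regions()].
#'
#' @param binary A binary [image_grid()] from [preprocess_image()] (a raw
#'   grayscale image is preprocessed first).
#' @param config A [morphometry_config()].
#' @return A tibble of class `fiber_regions`, one row per region: `label`,
#'   `area_px`, `area_um2` (NA without calibration), `perimeter_px`,
#'   `circularity`, `centroid_row`, `centroid_col`, `border_touching`,
#'   `status`, `reason`. The label matrix is attached as attribute
#'   `label_map`.
#' @export
segment_fibers <- function(binary, config = morphometry_config()) {
  if (!isTRUE(attr(binary, "binary")))
    binary <- preprocess_image(binary, config)
  mask <- binary$pixels > 0
  if (!any(mask)) {
    out <- tibble::tibble(label = integer(), area_px = integer(),
                          area_um2 = numeric(), perimeter_px = numeric(),
                          circularity = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(), border_touching = logical(),
                          status = character(), reason = character())
    return(structure(out, class = c("fiber_regions", class(out))))
  }
  r <- config$adhesion_opening_radius_px
  if (r > 0)
    mask <- EBImage::opening(mask * 1, EBImage::makeBrush(2 * r + 1, "disc")) > 0
  if (isTRUE(config$fill_holes))
    mask <- EBImage::fillHull(mask * 1) > 0
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab == 0) return(segment_fibers(image_grid(matrix(0, 2, 2)), config))
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  area <- tabulate(l, nbins = nlab)
  cr <- tapply(rows, l, mean); cc <- tapply(cols, l, mean)
  rmin <- tapply(rows, l, min); rmax <- tapply(rows, l, max)
  cmin <- tapply(cols, l, min); cmax <- tapply(cols, l, max)
  border <- rmin == 1 | cmin == 1 | rmax == nr | cmax == nc
  per <- vapply(seq_len(nlab), function(k) {
    sub <- lab[rmin[k]:rmax[k], cmin[k]:cmax[k], drop = FALSE] == k
    region_perimeter(sub)
  }, numeric(1))
  um <- binary$um_per_px
  out <- tibble::tibble(
    label = seq_len(nlab),
    area_px = area,
    area_um2 = if (is.null(um)) NA_real_ else area * um^2,
    perimeter_px = per,
    circularity = circularity(area, per, config$circularity_epsilon),
    centroid_row = as.numeric(cr),
    centroid_col = as.numeric(cc),
    border_touching = as.logical(border)
  )
  out <- classify_regions(out, config)
  structure(out, class = c("fiber_regions", class(out)),
            label_map = lab)
}

#' Fraction of fibers above a hypertrophy threshold
#'
#' The share of fibers whose CSA strictly exceeds a fixed cut — the study
#' field's working indicator of fiber hypertrophy. The threshold's units are
#' whatever units `csa_values` is in; it is a required argument because the
#' published cut (14.2877, "corrected") carries no stated unit or correction
#' procedure, so no default interpretation is hard-coded.
#'
#' @param csa_values Numeric vector of per-fiber CSA values.
#' @param threshold CSA cut; fibers with `csa > threshold` count.
#' @return Fraction in `[0, 1]` (NA for an empty vector).
#' @export
#' @examples
#' hypertrophy_fraction(c(10, 15, 20), 14.2877)  # 2/3
hypertrophy_fraction <- function(csa_values, threshold) {
  abort_if(!is_scalar_number(threshold), "`threshold` must be a single number")
  if (length(csa_values) == 0) return(NA_real_)
  mean(csa_values > threshold)
}

#' Summarize accepted fibers
#'
#' CSA mean and SD over accepted regions only, plus (optionally) the
#' hypertrophy fraction at a caller-chosen threshold. With a calibration, CSA
#' is in square micrometres, otherwise in pixels.
#'
#' @param regions A `fiber_regions` tibble from [segment_fibers()].
#' @param um_per_px Optional calibration overriding the one in the regions.
#' @param hypertrophy_threshold Optional CSA cut passed to
#'   [hypertrophy_fraction()] (same units as the reported CSA).
#' @return A list of class `morphometry_summary`: `n_accepted`, `mean_csa`,
#'   `csa_sd`, `csa_values`, `csa_unit`, `hypertrophy_fraction` (NA when no
#'   threshold given). Zero accepted regions give an explicit empty summary
#'   (`n_accepted = 0`, NA statistics), never an error.
#' @export
summarize_fibers <- function(regions, um_per_px = NULL,
                             hypertrophy_threshold = NULL) {
  acc <- regions[regions$status == "accepted", , drop = FALSE]
  csa <- acc$area_px
  unit <- "px"
  if (!is.null(um_per_px)) {
    csa <- acc$area_px * um_per_px^2
    unit <- "um2"
  } else if (nrow(acc) > 0 && all(!is.na(acc$area_um2))) {
    csa <- acc$area_um2
    unit <- "um2"
  }
  structure(list(
    n_accepted = nrow(acc),
    mean_csa = if (nrow(acc)) mean(csa) else NA_real_,
    csa_sd = if (nrow(acc) > 1) sd(csa) else NA_real_,
    csa_values = as.numeric(csa),
    csa_unit = unit,
    hypertrophy_fraction = if (is.null(hypertrophy_threshold)) NA_real_
                           else hypertrophy_fraction(csa, hypertrophy_threshold)
  ), class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("<morphometry_summary> %d accepted fibers; mean CSA %.4g %s (sd %.4g)\n",
              x$n_accepted, x$mean_csa, x$csa_unit, x$csa_sd))
  if (!is.na(x$hypertrophy_fraction))
    cat(sprintf("  hypertrophy fraction: %.4f\n", x$hypertrophy_fraction))
  invisible(x)
}

#' Slow-twitch proportion from an ATPase-style image
#'
#' Segments fibers exactly as [segment_fibers()] does, then classifies
#' accepted fibers as dark (slow-twitch, type I) versus light (fast-twitch,
#' type II) by a deterministic two-means split of their mean interior
#' intensities. When the intensity distribution shows no usable separation
#' between the two putative classes, a warning is emitted and all fibers are
#' reported as one class.
#'
#' @param image An [image_grid()] of an ATPase-stained section (bright
#'   boundaries, bimodal fiber interiors).
#' @param config A [morphometry_config()].
#' @param min_separation Minimum distance between the two intensity centers,
#'   as a fraction of the intensity range of fiber means, below which the
#'   distribution is declared unimodal.
#' @return A list of class `fiber_typing`: `proportion_slow`, `n_slow`,
#'   `n_fibers`, and `fibers` (tibble with `label`, `mean_intensity`,
#'   `type`).
#' @export
fiber_typing <- function(image, config = morphometry_config(),
                         min_separation = 0.1) {
  image <- as_image_grid(image)
  # ATPase images are trimodal (slow, fast, boundary); binary Otsu can split
  # between the two fiber classes instead of at the boundary. Use a
  # deterministic 3-means of the intensities and cut below the boundary mode.
  ctr <- kmeansk(as.numeric(image$pixels), 3)$centers
  thr <- mean(ctr[2:3])
  bcfg <- config
  bcfg$binarization <- "fixed"; bcfg$fixed_threshold <- thr
  regions <- segment_fibers(preprocess_image(image, bcfg), bcfg)
  lab <- attr(regions, "label_map")
  acc <- regions[regions$status == "accepted", , drop = FALSE]
  abort_if(nrow(acc) == 0, "no accepted fibers to type")
  means <- vapply(acc$label, function(k) mean(image$pixels[lab == k]), numeric(1))
  rng <- diff(range(means))
  # when all fibers form one intensity class, call them slow only if darker
  # than half the fiber/boundary cut (otherwise they are all light, fast)
  one_class <- function() ifelse(means < thr / 2, "slow", "fast")
  if (rng <= .Machine$double.eps^0.5) {
    warning("fiber intensities are unimodal; reporting all fibers as one class")
    type <- one_class()
  } else {
    cts <- kmeansk(means, 2)
    if ((cts$centers[2] - cts$centers[1]) < min_separation * rng) {
      warning("no clear dark/light separation; reporting all fibers as one class")
      type <- one_class()
    } else {
      type <- ifelse(cts$cluster == 1, "slow", "fast")
    }
  }
  fibers <- tibble::tibble(label = acc$label, mean_intensity = means, type = type)
  structure(list(proportion_slow = mean(type == "slow"),
                 n_slow = sum(type == "slow"), n_fibers = length(type),
                 fibers = fibers),
            class = "fiber_typing")
}

# deterministic 1-D k-means (Lloyd from spread quantile init); centers sorted
kmeansk <- function(x, k) {
  ctr <- unname(quantile(x, seq(0.05, 0.95, length.out = k)))
  for (i in 1:200) {
    d <- abs(outer(x, ctr, "-"))
    cl <- max.col(-d, ties.method = "first")
    new_ctr <- vapply(seq_len(k), function(j)
      if (any(cl == j)) mean(x[cl == j]) else ctr[j], numeric(1))
    if (isTRUE(all.equal(new_ctr, ctr))) break
    ctr <- new_ctr
  }
  ord <- order(ctr)
  list(centers = ctr[ord], cluster = match(cl, ord))
}

#' Compare CSA-like measurements between groups
#'
#' Two-sided, equal-variance two-sample t test (exactly two groups) or
#' one-way ANOVA (two or more groups), the standard tests for CSA, slow-twitch
#' proportion and hypertrophy-fraction comparisons between breeds.
#'
#' @param values Either a named list of numeric vectors (one per group) or a
#'   data frame with columns `value` and `group`.
#' @param design `"two_sample_t"` or `"one_way_anova"`.
#' @param var_equal Use the pooled-variance t test (default); set `FALSE` for
#'   Welch.
#' @return A one-row tibble: `design`, `statistic`, `df` (and `df2` for
#'   ANOVA), `p_value`. Degenerate inputs (all groups constant and equal)
#'   return `p_value = 1` with a warning rather than failing.
#' @export
#' @examples
#' compare_groups(list(H = c(5, 6, 7), D = c(8, 9, 10)), "two_sample_t")
compare_groups <- function(values,
                           design = c("two_sample_t", "one_way_anova"),
                           var_equal = TRUE) {
  design <- match.arg(design)
  if (is.data.frame(values)) {
    values <- split(values$value, values$group)
  }
  abort_if(!is.list(values) || length(values) < 2, "need at least 2 groups")
  abort_if(any(vapply(values, length, 1L) < 2), "each group needs n >= 2")
  all_vals <- unlist(values)
  if (var(all_vals) == 0) {
    warning("all groups are identical and constant; p = 1")
    return(tibble::tibble(design = design, statistic = 0,
                          df = NA_real_, p_value = 1))
  }
  if (design == "two_sample_t") {
    abort_if(length(values) != 2, "the t-test path requires exactly 2 groups")
    if (var(values[[1]]) == 0 && var(values[[2]]) == 0 &&
        mean(values[[1]]) == mean(values[[2]])) {
      warning("degenerate zero-variance groups; p = 1")
      return(tibble::tibble(design = design, statistic = 0,
                            df = NA_real_, p_value = 1))
    }
    tt <- t.test(values[[1]], values[[2]], var.equal = var_equal)
    tibble::tibble(design = design, statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    df <- data.frame(value = all_vals,
                     group = rep(names(values) %||% seq_along(values),
                                 vapply(values, length, 1L)))
    ow <- stats::oneway.test(value ~ group, df, var.equal = var_equal)
    tibble::tibble(design = design, statistic = unname(ow$statistic),
                   df = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
                   p_value = ow$p.value)
  }
}
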