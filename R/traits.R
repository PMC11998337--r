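#' Geometry of a multi-well imaging plate
#'
#' Describes the synthetic top-view plate the renderer draws: image size,
#' mm-per-pixel scale, and well centers/radii on a regular grid.  Pixel
#' coordinates are 0-based, row-major (x = column, y = row).
#'
#' @param n_wells number of wells (default 6, laid out 2 x 3).
#' @param ncol,nrow grid shape; `ncol * nrow` must equal `n_wells`.
#' @param width_px,height_px image dimensions in pixels.
#' @param mm_per_px physical scale.
#' @param plate_id identifier stored in image metadata.
#' @return object of class `plate_layout` with a `wells` data frame
#'   (`well`, `cx`, `cy`, `radius_px`).
#' @export
plate_layout <- function(n_wells = 6, ncol = 3, nrow = 2,
                         width_px = 660, height_px = 440,
                         mm_per_px = 0.25, plate_id = "plate_01") {
  stopifnot(ncol * nrow == n_wells, width_px > 0, height_px > 0, mm_per_px > 0)
  cx <- (rep(seq_len(ncol), times = nrow) - 0.5) * width_px / ncol
  cy <- (rep(seq_len(nrow), each = ncol) - 0.5) * height_px / nrow
  r <- 0.44 * min(width_px / ncol, height_px / nrow)
  wells <- data.frame(well = sprintf("W%d", seq_len(n_wells)),
                      cx = cx, cy = cy, radius_px = r,
                      stringsAsFactors = FALSE)
  if (any(cx - r < 0 | cx + r > width_px | cy - r < 0 | cy + r > height_px)) {
    stopf("well geometry exceeds image bounds")
  }
  structure(list(n_wells = n_wells, width_px = width_px,
                 height_px = height_px, mm_per_px = mm_per_px,
                 plate_id = plate_id, wells = wells),
            class = "plate_layout")
}

# Rasterize a rosette (union of elliptical lobes around a center) as TRUE
# pixels on the image grid.  A two-pass radius correction matches the target
# pixel area to within rasterization error.
rasterize_rosette <- function(width_px, height_px, cx, cy, target_px, lobes) {
  draw <- function(R) {
    pad <- ceiling(R) + 2
    xr <- max(0, floor(cx - pad)):min(width_px - 1, ceiling(cx + pad))
    yr <- max(0, floor(cy - pad)):min(height_px - 1, ceiling(cy + pad))
    px <- outer(yr * 0, xr, `+`)          # x coord per cell
    py <- outer(yr, xr * 0, `+`)          # y coord per cell
    u <- px - cx
    v <- py - cy
    inside <- (u^2 + v^2) <= (0.45 * R)^2  # central disk
    if (lobes >= 2) {
      for (i in seq_len(lobes)) {
        th <- 2 * pi * (i - 1) / lobes
        # rotate into the lobe frame; lobe center at 0.5 R outward
        ur <- cos(th) * u + sin(th) * v - 0.5 * R
        vr <- -sin(th) * u + cos(th) * v
        inside <- inside | ((ur / (0.55 * R))^2 + (vr / (0.32 * R))^2 <= 1)
      }
    } else {
      inside <- (u^2 + v^2) <= R^2
    }
    list(x = xr, y = yr, inside = inside)
  }
  R0 <- sqrt(target_px / pi)
  m0 <- draw(R0)
  n0 <- sum(m0$inside)
  if (n0 > 0 && abs(n0 - target_px) / target_px > 0.01) {
    m0 <- draw(R0 * sqrt(target_px / n0))
  }
  m0
}

#' Render a synthetic top-view plate image
#'
#' Draws a deterministic RGB image of a multi-well plate with green rosettes:
#' a light background with seeded sensor noise, darker well circles, and one
#' rosette per specified well whose projected area (mm^2), lobe count and
#' greenness are taken from `plant_specs`.  Plant pixels are spectrally
#' separated from the background in the excess-green channel, which is what
#' the segmenter thresholds.
#'
#' This renderer (and the whole image module) is an invented emulation of an
#' imaging front end, giving the pipeline an end-to-end image-to-table test
#' path; the screening functions accept phenotype tables from CSV without it.
#'
#' @param layout a [plate_layout()].
#' @param plant_specs data frame with columns `well`, `area_mm2`, and
#'   optionally `lobes` (default 1 = plain disk) and `greenness` (G channel
#'   of plant pixels, default 0.55).  May have zero rows (blank plate).
#' @param seed integer seed for the background noise.
#' @return object of class `plate_image`: list with `img` (height x width x 3
#'   array in \[0, 1\]), `layout`, and `mm_per_px`.
#' @export
render_plate <- function(layout, plant_specs = NULL, seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$width_px
  h <- layout$height_px
  if (is.null(plant_specs)) {
    plant_specs <- data.frame(well = character(0), area_mm2 = numeric(0))
  }
  if (!all(c("well", "area_mm2") %in% names(plant_specs))) {
    stopf("plant_specs needs columns 'well' and 'area_mm2'")
  }
  bad <- setdiff(plant_specs$well, layout$wells$well)
  if (length(bad)) stopf("plant_specs references nonexistent well(s): %s",
                         paste(bad, collapse = ", "))
  if (!"lobes" %in% names(plant_specs)) {
    plant_specs$lobes <- rep(1L, nrow(plant_specs))
  }
  if (!"greenness" %in% names(plant_specs)) {
    plant_specs$greenness <- rep(0.55, nrow(plant_specs))
  }

  img <- with_seed(seed, {
    base <- c(0.80, 0.76, 0.70)                       # tray background
    img <- array(rep(base, each = h * w), dim = c(h, w, 3))
    img <- img + array(stats::rnorm(h * w * 3, sd = 0.01), dim = c(h, w, 3))
    # darker well circles
    xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
    yg <- matrix(0:(h - 1), h, w)
    for (i in seq_len(nrow(layout$wells))) {
      d2 <- (xg - layout$wells$cx[i])^2 + (yg - layout$wells$cy[i])^2
      inw <- d2 <= layout$wells$radius_px[i]^2
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[inw] <- pl[inw] * 0.55
        img[, , ch] <- pl
      }
    }
    for (i in seq_len(nrow(plant_specs))) {
      wrow <- layout$wells[layout$wells$well == plant_specs$well[i], ]
      target_px <- plant_specs$area_mm2[i] / layout$mm_per_px^2
      ros <- rasterize_rosette(w, h, wrow$cx, wrow$cy, target_px,
                               plant_specs$lobes[i])
      g <- plant_specs$greenness[i]
      col <- c(0.12, g, 0.10)
      for (ch in 1:3) {
        pl <- img[, , ch]
        # +1: grid coords are 0-based, array indices 1-based
        pl[ros$y + 1, ros$x + 1][ros$inside] <- col[ch]
        img[, , ch] <- pl
      }
    }
    pmin(pmax(img, 0), 1)
  })
  structure(list(img = img, layout = layout, mm_per_px = layout$mm_per_px),
            class = "plate_image")
}

#' Segment plant pixels from a plate image
#'
#' Excess-green thresholding (`2G - R - B > threshold`) followed by
#' connected-component labelling and a minimum-region-size filter; each
#' surviving region is assigned to the well whose center is nearest its
#' centroid.  An empty mask (blank plate) is a valid result, not an error.
#'
#' @param image a [render_plate()] result (or list with `img` and
#'   `mm_per_px`).
#' @param exg_threshold excess-green threshold.
#' @param min_size minimum region size in pixels; smaller specks are noise
#'   and discarded.
#' @return object of class `plant_mask`: list with `labels` (integer matrix,
#'   0 = background, regions relabelled 1..n), `n_regions`, and `regions`
#'   (data frame: `region`, `well`, `size_px`, centroid `cx`/`cy` in 0-based
#'   pixel coordinates).
#' @export
segment_plants <- function(image, exg_threshold = 0.2, min_size = 25) {
  stopifnot(inherits(image, "plate_image") || is.list(image))
  if (is.null(image$mm_per_px)) stopf("image lacks scale metadata (mm_per_px)")
  img <- image$img
  exg <- 2 * img[, , 2] - img[, , 1] - img[, , 3]
  mask <- exg > exg_threshold
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]

  wells <- image$layout$wells
  regions <- do.call(rbind, lapply(seq_along(keep), function(r) {
    idx <- which(lab == r, arr.ind = TRUE)
    cx <- mean(idx[, 2] - 1)
    cy <- mean(idx[, 1] - 1)
    d2 <- (wells$cx - cx)^2 + (wells$cy - cy)^2
    data.frame(region = r, well = wells$well[which.min(d2)],
               size_px = nrow(idx), cx = cx, cy = cy,
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) {
    regions <- data.frame(region = integer(0), well = character(0),
                          size_px = integer(0), cx = numeric(0), cy = numeric(0))
  }
  structure(list(labels = lab, n_regions = length(keep), regions = regions,
                 mm_per_px = image$mm_per_px),
            class = "plant_mask")
}

#' Measure morphometric traits of segmented plants
#'
#' Per region: projected area and convex-hull area (mm^2, via the pixel
#' scale), compactness (area / hull area, in (0, 1] because the hull of the
#' pixel squares contains the region), bounding width and height (mm),
#' eccentricity of the pixel cloud (from the second-moment eigenvalues), and
#' mean greenness (mean G channel over the region).
#'
#' @param mask a [segment_plants()] result.
#' @param image the matching [render_plate()] image.
#' @return data frame, one row per region: `region`, `well`, `area_mm2`,
#'   `hull_area_mm2`, `compactness`, `width_mm`, `height_mm`, `eccentricity`,
#'   `greenness`.
#' @export
measure_traits <- function(mask, image) {
  stopifnot(inherits(mask, "plant_mask"))
  if (is.null(image$mm_per_px)) stopf("image lacks scale metadata (mm_per_px)")
  s <- image$mm_per_px
  g_chan <- image$img[, , 2]
  rows <- lapply(seq_len(mask$n_regions), function(r) {
    idx <- which(mask$labels == r, arr.ind = TRUE)
    x <- idx[, 2] - 1
    y <- idx[, 1] - 1
    npx <- length(x)
    # hull over pixel-square corners so the hull always contains the region
    cx4 <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
    cy4 <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
    hidx <- grDevices::chull(cx4, cy4)
    hull_px <- polygon_area(cx4[hidx], cy4[hidx])
    ecc <- if (npx > 2) {
      ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE,
                  only.values = TRUE)$values
      if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
    } else 0
    data.frame(
      region = r,
      well = mask$regions$well[r],
      area_mm2 = npx * s^2,
      hull_area_mm2 = hull_px * s^2,
      compactness = npx / hull_px,
      width_mm = (diff(range(x)) + 1) * s,
      height_mm = (diff(range(y)) + 1) * s,
      eccentricity = ecc,
      greenness = mean(g_chan[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = integer(0), well = character(0), area_mm2 = numeric(0),
               hull_area_mm2 = numeric(0), compactness = numeric(0),
               width_mm = numeric(0), height_mm = numeric(0),
               eccentricity = numeric(0), greenness = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write / read a plate image as PNG with a JSON metadata sidecar
#'
#' PNG carries the pixels; well geometry and the mm-per-pixel scale go to
#' `<path>.json` so a round trip preserves the measurement scale.
#'
#' @param image a [render_plate()] result.
#' @param path PNG file path.
#' @return `path`, invisibly (write) or a `plate_image` (read).
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  png::writePNG(image$img, path)
  meta <- list(mm_per_px = image$mm_per_px,
               n_wells = image$layout$n_wells,
               width_px = image$layout$width_px,
               height_px = image$layout$height_px,
               plate_id = image$layout$plate_id,
               wells = image$layout$wells)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_plate_image
#' @export
read_plate_image <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layout <- structure(
    list(n_wells = meta$n_wells, width_px = meta$width_px,
         height_px = meta$height_px, mm_per_px = meta$mm_per_px,
         plate_id = meta$plate_id, wells = as.data.frame(meta$wells)),
    class = "plate_layout")
  structure(list(img = img, layout = layout, mm_per_px = meta$mm_per_px),
            class = "plate_image")
}
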