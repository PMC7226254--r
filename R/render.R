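#' Field-image rendering specification
#'
#' Geometry and intensity parameters for synthetic single-channel
#' fluorescence fields: cells are rendered as non-overlapping bright
#' ellipses (axis ratio up to `max_axis_ratio`) over a flat background with
#' optional Gaussian noise, emulating GFP-positive suspension cells imaged
#' at low magnification.
#'
#' @param width,height Field size in pixels.
#' @param radius_range Min/max semi-minor axis of a cell, pixels.
#' @param max_axis_ratio Maximum major/minor axis ratio (1 = disks only).
#' @param bg_level Background intensity level (arbitrary units on the
#'   16-bit scale).
#' @param bg_sd Gaussian background noise SD; 0 renders noise-free fields.
#' @param cell_intensity Mean cell intensity.
#' @param cell_intensity_sd Between-cell intensity SD.
#' @param margin Extra background pixels kept free around each cell and
#'   between a cell and the field border; >= 1 guarantees objects stay
#'   8-disconnected and never touch the border.
#' @param bit_depth Bits per sample used when writing TIFFs.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(width = 256, height = 256, radius_range = c(2, 3.5),
                       max_axis_ratio = 1.3, bg_level = 100, bg_sd = 8,
                       cell_intensity = 600, cell_intensity_sd = 60,
                       margin = 2, bit_depth = 16) {
  stopifnot(width >= 8, height >= 8, length(radius_range) == 2,
            radius_range[1] >= 1, diff(radius_range) >= 0,
            max_axis_ratio >= 1, bg_sd >= 0, margin >= 1,
            cell_intensity > bg_level)
  structure(as.list(environment()), class = "field_spec")
}

#' Render one synthetic fluorescence field with ground truth
#'
#' Places `n_cells` non-overlapping bright ellipses by rejection sampling
#' (centres at least one cell diameter plus `2 * margin` apart and `margin`
#' clear of the border), then adds the background. Returns both the image
#' and the ground-truth centroids so segmentation can be tested against an
#' exact oracle.
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param spec A [field_spec()].
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @param max_tries Rejection-sampling attempts per cell before declaring
#'   the requested density infeasible.
#' @return A list of class `field_image` with elements `image` (numeric
#'   matrix, rows = y), `truth` (tibble `row`, `col`, `radius`), `n_cells`,
#'   and `spec`.
#' @export
render_field <- function(n_cells, spec = field_spec(), seed = NULL,
                         max_tries = 2000) {
  stopifnot(n_cells >= 0, inherits(spec, "field_spec"))
  do_render <- function() {
    rmax <- spec$radius_range[2] * spec$max_axis_ratio
    lo_r <- rmax + spec$margin + 1
    hi_row <- spec$height - lo_r + 1
    hi_col <- spec$width - lo_r + 1
    if (n_cells > 0 && (hi_row <= lo_r || hi_col <= lo_r)) {
      stop("field too small for the requested cell size", call. = FALSE)
    }
    min_sep <- 2 * rmax + 2 * spec$margin
    cr <- numeric(n_cells); cc <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- stats::runif(1, lo_r, hi_row)
        c0 <- stats::runif(1, lo_r, hi_col)
        if (i == 1 ||
            min((cr[seq_len(i - 1)] - r0)^2 + (cc[seq_len(i - 1)] - c0)^2) >=
              min_sep^2) {
          cr[i] <- r0; cc[i] <- c0; placed <- TRUE; break
        }
      }
      if (!placed) {
        stop("could not place ", n_cells, " non-overlapping cells in a ",
             spec$width, "x", spec$height, " field (packing infeasible)",
             call. = FALSE)
      }
    }
    img <- matrix(spec$bg_level, nrow = spec$height, ncol = spec$width)
    if (spec$bg_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$bg_sd),
                          nrow = spec$height)
    }
    radius <- stats::runif(n_cells, spec$radius_range[1], spec$radius_range[2])
    axis_ratio <- stats::runif(n_cells, 1, spec$max_axis_ratio)
    theta <- stats::runif(n_cells, 0, pi)
    inten <- pmax(spec$bg_level + 1,
                  stats::rnorm(n_cells, spec$cell_intensity,
                               spec$cell_intensity_sd))
    for (i in seq_len(n_cells)) {
      a <- radius[i] * axis_ratio[i]; b <- radius[i]
      half <- ceiling(a)
      rows <- max(1, floor(cr[i] - half)):min(spec$height, ceiling(cr[i] + half))
      cols <- max(1, floor(cc[i] - half)):min(spec$width, ceiling(cc[i] + half))
      dy <- rows - cr[i]; dx <- cols - cc[i]
      u <- outer(dy, dx, function(y, x) x * cos(theta[i]) + y * sin(theta[i]))
      v <- outer(dy, dx, function(y, x) -x * sin(theta[i]) + y * cos(theta[i]))
      inside <- (u / a)^2 + (v / b)^2 <= 1
      block <- img[rows, cols, drop = FALSE]
      px_noise <- if (spec$bg_sd > 0) {
        stats::rnorm(sum(inside), 0, spec$bg_sd)
      } else 0
      block[inside] <- inten[i] + px_noise
      img[rows, cols] <- block
    }
    img <- pmin(pmax(img, 0), 2^spec$bit_depth - 1)
    structure(list(image = img,
                   truth = tibble::tibble(row = cr, col = cc, radius = radius),
                   n_cells = as.integer(n_cells), spec = spec),
              class = "field_image")
  }
  if (is.null(seed)) do_render() else withr::with_seed(seed, do_render())
}

#' Render all fields of one well
#'
#' Splits a well's visible cell count across `n_fields` fields, either
#' deterministically (as even as possible, `split = "equal"`) or by
#' multinomial field sampling (`split = "multinomial"`, emulating the random
#' placement of a field of view inside a well).
#'
#' @param n_cells_total Total cells to render across the fields.
#' @param n_fields Number of fields.
#' @param spec A [field_spec()].
#' @param seed Integer seed for placement (and the split when multinomial).
#' @param split `"equal"` or `"multinomial"`.
#' @return List of `field_image` objects of length `n_fields`.
#' @export
render_well_fields <- function(n_cells_total, n_fields = 5,
                               spec = field_spec(), seed = 1L,
                               split = c("equal", "multinomial")) {
  split <- match.arg(split)
  stopifnot(n_cells_total >= 0, n_fields >= 1)
  withr::with_seed(seed, {
    per_field <- if (split == "equal") {
      base <- n_cells_total %/% n_fields
      extra <- n_cells_total %% n_fields
      base + (seq_len(n_fields) <= extra)
    } else {
      as.integer(stats::rmultinom(1, n_cells_total,
                                  rep(1 / n_fields, n_fields)))
    }
    lapply(per_field, render_field, spec = spec, seed = NULL)
  })
}

#' Write a field image as a single-channel 16-bit TIFF
#'
#' Files follow the `plate_well_field.tif` naming convention when `path` is
#' built with [field_tiff_name()].
#'
#' @param field A `field_image` (or bare numeric matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  img <- if (inherits(field, "field_image")) field$image else field
  depth <- if (inherits(field, "field_image")) field$spec$bit_depth else 16
  tiff::writeTIFF(img / (2^depth - 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a field TIFF back as an intensity matrix
#'
#' @param path TIFF path; a missing file raises an error naming it.
#' @param bit_depth Bit depth used when writing.
#' @return Numeric intensity matrix.
#' @export
read_field_tiff <- function(path, bit_depth = 16) {
  if (!file.exists(path)) {
    stop("field image file not found: ", path, call. = FALSE)
  }
  tiff::readTIFF(path) * (2^bit_depth - 1)
}

#' Standard field TIFF file name
#' @param plate_id,well Plate and well identifiers.
#' @param field Field index (1-based).
#' @return `"<plate>_<well>_<field>.tif"`.
#' @export
field_tiff_name <- function(plate_id, well, field) {
  sprintf("%s_%s_%d.tif", plate_id, well, field)
}
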