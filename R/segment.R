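#' Segmentation parameters
#'
#' The detection pipeline is: global intensity threshold, 8-connected
#' component labelling, then per-object filters on area, roundness and mean
#' intensity (the three criteria high-content readers expose). The
#' threshold is either an absolute intensity (foreground = pixels `>=`
#' threshold) or the robust automatic rule `median + k * MAD` of the whole
#' field (foreground = pixels strictly above it, so a noise-free uniform
#' background stays background).
#'
#' @param intensity_threshold `"auto"` or an absolute intensity.
#' @param threshold_k Multiplier on the MAD for the automatic threshold.
#' @param min_area,max_area Accepted object area range, pixels.
#' @param min_roundness Minimum isoperimetric roundness `4*pi*A/P^2` (crack-
#'   length perimeter, clipped to `[0, 1]`). An ideal digital disk scores
#'   `pi^2/16 ~ 0.62` under this estimator, hence the default well below 1.
#' @param min_mean_intensity Minimum mean object intensity (0 disables).
#' @param exclude_border Drop objects touching the field border (standard
#'   high-content practice; edge objects are partially out of field).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(intensity_threshold = "auto", threshold_k = 6,
                       min_area = 10, max_area = 500, min_roundness = 0.4,
                       min_mean_intensity = 0, exclude_border = TRUE) {
  stopifnot(min_area <= max_area, min_area >= 1, threshold_k >= 0,
            min_roundness >= 0, min_mean_intensity >= 0)
  if (!identical(intensity_threshold, "auto")) {
    stopifnot(is.numeric(intensity_threshold),
              length(intensity_threshold) == 1, intensity_threshold >= 0)
  }
  structure(as.list(environment()), class = "seg_params")
}

# Shift a matrix by (dr, dc), padding with `fill`.
.shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

#' 8-connected component labelling of a logical mask
#'
#' Iterative minimum-label propagation: every foreground pixel starts with
#' its own index and repeatedly adopts the smallest label among itself and
#' its 8 neighbours until a fixed point, which assigns one label per
#' 8-connected component. Labels are then renumbered 1..n in raster order.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  repeat {
    m <- lab
    for (k in seq_len(nrow(offs))) {
      m <- pmin(m, .shift_mat(lab, offs[k, 1], offs[k, 2], Inf))
    }
    m[!mask] <- Inf
    if (identical(m, lab)) break
    lab <- m
  }
  lab[!mask] <- 0
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  out[mask] <- match(lab[mask], ids)
  out
}

# Crack-length perimeter per labelled object: number of 4-neighbour edges
# from an object pixel to anything outside that object (background or image
# border).
.crack_perimeter <- function(lab) {
  n_obj <- max(lab)
  per <- integer(n_obj)
  for (k in 1:4) {
    sh <- switch(k, .shift_mat(lab, 1, 0, 0L), .shift_mat(lab, -1, 0, 0L),
                 .shift_mat(lab, 0, 1, 0L), .shift_mat(lab, 0, -1, 0L))
    exposed <- lab > 0 & sh != lab
    per <- per + tabulate(lab[exposed], nbins = n_obj)
  }
  per
}

#' Segment one fluorescence field into cell detections
#'
#' Thresholds the field, labels 8-connected components, and scores every
#' object for area, crack-length perimeter, roundness (`4*pi*A/P^2` clipped
#' to `[0, 1]`), mean intensity, centroid and border contact. Objects are
#' `accepted` when they pass all configured filters; rejected objects are
#' returned too, flagged, so filter behaviour is auditable.
#'
#' @param image A `field_image` from [render_field()] or a numeric intensity
#'   matrix.
#' @param params A [seg_params()].
#' @return Tibble with one row per detected object: `label`, `centroid_row`,
#'   `centroid_col`, `area`, `perimeter`, `roundness`, `mean_intensity`,
#'   `on_border`, `accepted`. Zero rows for a blank field.
#' @export
segment_field <- function(image, params = seg_params()) {
  img <- if (inherits(image, "field_image")) image$image else image
  stopifnot(is.matrix(img), all(is.finite(img)), nrow(img) > 0, ncol(img) > 0)
  if (identical(params$intensity_threshold, "auto")) {
    thr <- stats::median(img) + params$threshold_k * stats::mad(img)
    fg <- img > thr
  } else {
    fg <- img >= params$intensity_threshold
  }
  empty <- tibble::tibble(label = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area = integer(),
                          perimeter = integer(), roundness = numeric(),
                          mean_intensity = numeric(), on_border = logical(),
                          accepted = logical())
  if (!any(fg)) return(empty)
  lab <- label_components(fg)
  n_obj <- max(lab)
  idx <- which(lab > 0)
  obj <- lab[idx]
  rows <- ((idx - 1) %% nrow(img)) + 1
  cols <- ((idx - 1) %/% nrow(img)) + 1
  area <- tabulate(obj, nbins = n_obj)
  cent_r <- tapply(rows, obj, mean)
  cent_c <- tapply(cols, obj, mean)
  mean_int <- tapply(img[idx], obj, mean)
  per <- .crack_perimeter(lab)
  on_border <- as.logical(tapply(rows == 1 | rows == nrow(img) |
                                   cols == 1 | cols == ncol(img), obj, any))
  roundness <- pmin(1, 4 * pi * area / per^2)
  accepted <- area >= params$min_area & area <= params$max_area &
    roundness >= params$min_roundness &
    mean_int >= params$min_mean_intensity &
    !(params$exclude_border & on_border)
  tibble::tibble(label = seq_len(n_obj),
                 centroid_row = as.numeric(cent_r),
                 centroid_col = as.numeric(cent_c),
                 area = as.integer(area), perimeter = as.integer(per),
                 roundness = roundness,
                 mean_intensity = as.numeric(mean_int),
                 on_border = on_border, accepted = accepted)
}

#' Count living cells in a well from its fields
#'
#' Sums accepted detections over all fields of a well (the per-well readout
#' of the screen). Per-field counts are retained for QC.
#'
#' @param fields List of fields: `field_image` objects, intensity matrices,
#'   or TIFF file paths (missing files raise an error naming the field).
#' @param params A [seg_params()].
#' @return List with `count` (total accepted cells), `per_field` (integer
#'   vector), `n_fields`.
#' @export
count_well <- function(fields, params = seg_params()) {
  stopifnot(length(fields) >= 1)
  per_field <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (is.character(f)) f <- read_field_tiff(f)
    sum(segment_field(f, params)$accepted)
  }, integer(1))
  list(count = sum(per_field), per_field = per_field,
       n_fields = length(fields))
}
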