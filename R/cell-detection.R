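#' Split an RGB image into its channel maps
#'
#' The decomposition is lossless: recombining the three maps reproduces the
#' input. The blue channel is reserved for the nuclear (DAPI-like) stain; the
#' red and green channels carry the marker stains.
#'
#' @param image A height x width x 3 numeric array.
#' @return A list of matrices `R`, `G`, `B`.
#' @export
split_channels <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("expected a height x width x 3 RGB image")
  }
  list(R = image[, , 1L], G = image[, , 2L], B = image[, , 3L])
}

#' Extract a denoised marker-positive mask from one channel
#'
#' Pixels at or above the positivity threshold X are kept, then connected
#' components smaller than `min_object_px` pixels are removed (the denoising
#' step: sub-cellular speckles are not credible stained areas).
#'
#' @param channel A numeric matrix (one channel map).
#' @param x_threshold Positivity threshold X for this marker (> 0).
#' @param min_object_px Minimum connected-component size in px retained
#'   (default 10); 0 disables the filter.
#' @return A logical matrix.
#' @export
extract_marker_mask <- function(channel, x_threshold, min_object_px = 10) {
  if (is.null(x_threshold) || is.na(x_threshold) || x_threshold <= 0) {
    stop("a positive threshold X must be configured for the marker")
  }
  mask <- channel >= x_threshold
  if (min_object_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- as.matrix(EBImage::imageData(lab))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_object_px)
    if (length(small) > 0) mask[lab %in% small] <- FALSE
  }
  mask
}

#' Detect nuclei in the nuclear channel
#'
#' Nucleus detection is a pluggable interface: `config$method` selects the
#' detector, and a user-supplied function (`config$method = "custom"`,
#' `config$fn`) can stand in for a learned model. The default classical
#' detector smooths the channel with a Gaussian, thresholds it (Otsu by
#' default), separates touching nuclei by a distance-transform watershed, and
#' reports one centroid per labelled nucleus. The result is deterministic for
#' a fixed input.
#'
#' @param nuclear_channel A numeric matrix.
#' @param config List: `method` (`"classical"` or `"custom"`),
#'   `smooth_sigma` (default 1), `threshold` (`"otsu"` or numeric),
#'   `min_nucleus_px` (default 9), `fn` (for `"custom"`: a function
#'   `f(channel)` returning an integer label matrix).
#' @return A list with `centroids` (data.frame `label`, `x`, `y`; pixel
#'   coordinates, 0-based) and `labels` (integer matrix). A blank image
#'   yields zero nuclei, not an error.
#' @export
detect_nuclei <- function(nuclear_channel, config = list()) {
  stopifnot(is.matrix(nuclear_channel))
  method <- config$method %||% "classical"
  if (method == "custom") {
    labels <- config$fn(nuclear_channel)
  } else {
    sigma <- config$smooth_sigma %||% 1
    img <- EBImage::Image(nuclear_channel)
    if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
    thr <- config$threshold %||% "otsu"
    if (identical(thr, "otsu")) {
      thr <- if (any(nuclear_channel > 0)) EBImage::otsu(img) else Inf
    }
    fg <- EBImage::imageData(img) >= thr
    if (!any(fg)) {
      labels <- matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel))
    } else {
      dm <- EBImage::distmap(EBImage::Image(fg * 1))
      ws <- EBImage::watershed(dm, tolerance = config$tolerance %||% 1)
      labels <- as.matrix(EBImage::imageData(ws))
      min_px <- config$min_nucleus_px %||% 9
      sizes <- tabulate(labels[labels > 0])
      small <- which(sizes < min_px)
      if (length(small) > 0) labels[labels %in% small] <- 0L
      # re-number labels consecutively
      keep <- sort(unique(labels[labels > 0]))
      labels[] <- match(labels, keep, nomatch = 0L)
    }
  }
  storage.mode(labels) <- "integer"
  cents <- nucleus_centroids(labels)
  list(centroids = cents, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centroids (0-based x = col - 1, y = row - 1) of a label mask.
nucleus_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  r <- ((idx - 1L) %% nrow(labels)) + 1L
  c <- ((idx - 1L) %/% nrow(labels)) + 1L
  data.frame(
    label = ids,
    x = as.numeric(tapply(c - 1, lab, mean)[as.character(ids)]),
    y = as.numeric(tapply(r - 1, lab, mean)[as.character(ids)])
  )
}

#' Type detected cells by intersecting centroids with marker masks
#'
#' A cell is positive for a marker exactly when its centroid pixel lies
#' inside that marker's denoised stain mask (the intersection of the nucleus
#' coordinates with the fluorescently stained area). Multi-positive cells are
#' allowed. For each positive marker the staining level is binned from the
#' channel value read at the centroid pixel: `[X, 2X)` is `"+"`, `[2X, 3X)`
#' is `"++"`, and `>= 3X` is `"+++"`.
#'
#' @param centroids A data.frame `label`, `x`, `y` (from [detect_nuclei()]).
#' @param marker_masks Named list of logical matrices, one per marker.
#' @param intensity_maps Named list of channel maps used to read
#'   intensities: either keyed by marker (each marker's own unmixed
#'   component-channel map, as produced by [render_scene()]) or keyed by
#'   optical channel (`R`, `G`), in which case the marker's assigned channel
#'   is read. Marker-keyed maps are required when several markers of the
#'   panel share a channel.
#' @param panel A [panel_spec()].
#' @param thresholds Named numeric vector of per-marker thresholds X.
#' @param intensity_readout `"centroid"` (default) reads the centroid pixel;
#'   `"mean"` averages the channel over the nucleus mask (requires `labels`).
#' @param labels Optional label matrix for `intensity_readout = "mean"`.
#' @return A cell table (data.frame `cell_id`, `x`, `y`, `panel`, `markers`,
#'   `levels`) in the same schema the scene simulator writes.
#' @export
type_cells <- function(centroids, marker_masks, intensity_maps, panel,
                       thresholds,
                       intensity_readout = c("centroid", "mean"),
                       labels = NULL) {
  stopifnot(inherits(panel, "panel_spec"))
  intensity_readout <- match.arg(intensity_readout)
  markers <- names(marker_masks)
  if (!all(markers %in% panel$markers)) stop("mask for marker not in panel")
  map_for <- function(m) {
    intensity_maps[[m]] %||% intensity_maps[[panel$channels[[m]]]] %||%
      stop("no intensity map for marker ", m)
  }
  dim <- if (length(marker_masks)) dim(marker_masks[[1L]]) else
    dim(intensity_maps[[1L]])
  if (nrow(centroids) > 0 &&
      (any(centroids$x < -0.5 | centroids$x > dim[2L] - 0.5) ||
       any(centroids$y < -0.5 | centroids$y > dim[1L] - 0.5))) {
    stop("centroid outside the image frame")
  }
  n <- nrow(centroids)
  px <- position_to_pixel(centroids$x, centroids$y, dim)
  marker_sets <- vector("list", n)
  level_sets <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- character(0); lev <- character(0)
    for (m in markers) {
      if (!marker_masks[[m]][px[i, 1L], px[i, 2L]]) next
      x_thr <- thresholds[[m]]
      map <- map_for(m)
      val <- if (intensity_readout == "centroid") {
        map[px[i, 1L], px[i, 2L]]
      } else {
        mean(map[labels == centroids$label[i]])
      }
      pos <- c(pos, m)
      lev <- c(lev, intensity_bin(val, x_thr))
    }
    marker_sets[[i]] <- pos
    level_sets[[i]] <- lev
  }
  data.frame(
    cell_id = centroids$label,
    x = centroids$x, y = centroids$y,
    panel = rep(panel$panel_id, length.out = n),
    markers = join_markers(marker_sets),
    levels = join_markers(level_sets),
    stringsAsFactors = FALSE
  )
}

#' Bin a fluorescence intensity into low/median/high
#'
#' Bin boundaries are exactly `[X, 2X)` for `"+"`, `[2X, 3X)` for `"++"` and
#' `[3X, Inf)` for `"+++"`. Values below X return `NA` (not positive).
#'
#' @param value Numeric intensity (vectorised).
#' @param x_threshold Threshold X.
#' @return Character vector of bins.
#' @export
intensity_bin <- function(value, x_threshold) {
  # relative tolerance so k*X boundaries are hit despite binary rounding
  r <- value / x_threshold * (1 + 1e-9)
  out <- rep(NA_character_, length(value))
  out[r >= 1] <- "+"
  out[r >= 2] <- "++"
  out[r >= 3] <- "+++"
  out
}

#' Compute the histochemistry score (H-score)
#'
#' `H = low% * 1 + median% * 2 + high% * 3`, where the percentages are the
#' fractions of cells with low (`+`), median (`++`) and high (`+++`) staining
#' strength among all cells considered. The score ranges from 0 (all
#' negative) to 300 (all high).
#'
#' @param low,median,high Percentages in [0, 100], summing to at most 100.
#' @return The H-score.
#' @examples
#' compute_h_score(50, 25, 25)  # 175
#' @export
compute_h_score <- function(low, median, high) {
  vals <- c(low, median, high)
  if (any(vals < 0) || any(vals > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  if (low + median + high > 100 + 1e-9) {
    stop("low + median + high must not exceed 100")
  }
  low * 1 + median * 2 + high * 3
}

#' Assign cells to tumour-nest / tumour-stroma regions
#'
#' Region labels form a partition: a cell is `TN` if its centroid pixel lies
#' in the tumour-nest mask, `TS` if in the tumour-stroma mask, and `none`
#' otherwise. Overlapping masks are rejected.
#'
#' @param cells A cell table with `x`, `y`.
#' @param tn_mask,ts_mask Logical matrices (disjoint).
#' @return The cell table with an added `region` column.
#' @export
assign_region <- function(cells, tn_mask, ts_mask) {
  if (any(tn_mask & ts_mask)) stop("TN and TS masks must be disjoint")
  px <- position_to_pixel(cells$x, cells$y, dim(tn_mask))
  region <- rep("none", nrow(cells))
  region[tn_mask[px]] <- "TN"
  region[ts_mask[px]] <- "TS"
  cells$region <- region
  cells
}

#' Summarise cell quantities per phenotype and region
#'
#' For every marker phenotype within each region the summary reports the
#' density in cells per mm^2 (`count / (area_px * mpp^2 * 1e-6)`), the
#' percentage of all cells in that region, and the H-score computed from the
#' low/median/high staining-level fractions of that phenotype among all
#' cells of the region. Multi-positive cells contribute to every marker they
#' carry, so percentages across phenotypes may exceed 100 in total.
#'
#' @param cells A cell table with `region` (see [assign_region()]).
#' @param region_areas_px Named numeric vector of region areas in pixels,
#'   e.g. `c(TN = ..., TS = ...)`.
#' @param microns_per_pixel Pixel size in microns (default 0.5, a typical
#'   20x whole-slide scan).
#' @return A data.frame with columns `region`, `marker`, `count`, `density`,
#'   `percentage`, `h_score`. Zero-area regions yield `NA` densities.
#' @export
summarize_quantities <- function(cells, region_areas_px,
                                 microns_per_pixel = 0.5) {
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be > 0")
  marker_sets <- split_markers(cells$markers)
  level_sets <- split_markers(cells$levels)
  regions <- intersect(c("TN", "TS"), names(region_areas_px))
  out <- list()
  for (reg in regions) {
    in_reg <- cells$region == reg
    n_all <- sum(in_reg)
    area_mm2 <- region_areas_px[[reg]] * microns_per_pixel^2 * 1e-6
    markers <- sort(unique(unlist(marker_sets[in_reg])))
    if (n_all == 0 || length(markers) == 0) next
    for (m in markers) {
      has <- vapply(marker_sets, function(s) m %in% s, logical(1)) & in_reg
      cnt <- sum(has)
      levs <- mapply(function(s, l) l[match(m, s)],
                     marker_sets[has], level_sets[has])
      pct_bin <- function(b) 100 * sum(levs == b) / n_all
      out[[length(out) + 1L]] <- data.frame(
        region = reg, marker = m, count = cnt,
        density = if (area_mm2 > 0) cnt / area_mm2 else NA_real_,
        percentage = 100 * cnt / n_all,
        h_score = compute_h_score(pct_bin("+"), pct_bin("++"),
                                  pct_bin("+++")),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(region = character(0), marker = character(0),
                      count = integer(0), density = numeric(0),
                      percentage = numeric(0), h_score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Run the full detection-and-typing pipeline on one scene
#'
#' Convenience wrapper: splits the composite into channels, detects nuclei
#' in the blue (nuclear) channel, extracts a denoised positivity mask per
#' marker from its component-channel map, types the detected cells by
#' centroid intersection, and (when region masks are supplied) assigns the
#' tumour-nest / tumour-stroma region.
#'
#' @param scene A `mif_scene` from [render_scene()], or a list with `image`
#'   and `marker_maps`.
#' @param panel A [panel_spec()].
#' @param thresholds Named per-marker thresholds X; defaults to the scene's
#'   rendering threshold for every marker.
#' @param detector_config Passed to [detect_nuclei()].
#' @param min_object_px Passed to [extract_marker_mask()] (default 10).
#' @param tn_mask,ts_mask Optional region masks (default: the scene's).
#' @return A list with the typed cell table (`cells`), `centroids`,
#'   `labels`, and the per-marker `masks`.
#' @export
analyze_scene <- function(scene, panel, thresholds = NULL,
                          detector_config = list(), min_object_px = 10,
                          tn_mask = NULL, ts_mask = NULL) {
  ch <- split_channels(scene$image)
  if (is.null(thresholds)) {
    x0 <- scene$truth$x_threshold %||% 0.2
    thresholds <- setNames(rep(x0, length(panel$markers)), panel$markers)
  }
  det <- detect_nuclei(ch$B, detector_config)
  masks <- setNames(lapply(panel$markers, function(m) {
    extract_marker_mask(scene$marker_maps[[m]], thresholds[[m]],
                        min_object_px = min_object_px)
  }), panel$markers)
  cells <- type_cells(det$centroids, masks, scene$marker_maps, panel,
                      thresholds)
  tn_mask <- tn_mask %||% scene$truth$tn
  ts_mask <- ts_mask %||% scene$truth$ts
  if (!is.null(tn_mask) && !is.null(ts_mask)) {
    cells <- assign_region(cells, tn_mask, ts_mask)
  }
  list(cells = cells, centroids = det$centroids, labels = det$labels,
       masks = masks)
}
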