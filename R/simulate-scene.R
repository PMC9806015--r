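#' Specify a spatial point process for cell placement
#'
#' Three placement regimes cover the spatial structures the downstream graph
#' features are designed to separate: complete spatial randomness
#' (`"poisson"`), clustered placement (a Thomas process: Poisson parents with
#' Gaussian-displaced offspring), which yields closer proximity and more
#' same-type connections, and inhibited placement (simple sequential
#' inhibition), which yields longer distances and fewer connections.
#'
#' @param kind One of `"poisson"`, `"clustered"`, `"inhibited"`.
#' @param intensity Expected points per unit area (per pixel^2); must be > 0.
#' @param cluster_parent_rate Parent intensity for `kind = "clustered"`;
#'   defaults to `intensity / cluster_mean_offspring` so the overall intensity
#'   matches `intensity`.
#' @param cluster_sigma Gaussian offspring displacement SD in px (> 0 for
#'   clustered processes).
#' @param cluster_mean_offspring Mean offspring per parent.
#' @param inhibition_radius Minimum pairwise distance in px for
#'   `kind = "inhibited"` (>= 0).
#' @return An object of class `process_spec`.
#' @examples
#' process_spec("poisson", intensity = 5e-4)
#' process_spec("clustered", intensity = 5e-4, cluster_sigma = 5)
#' @export
process_spec <- function(kind = c("poisson", "clustered", "inhibited"),
                         intensity,
                         cluster_parent_rate = NULL,
                         cluster_sigma = NULL,
                         cluster_mean_offspring = 10,
                         inhibition_radius = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(intensity) || intensity <= 0) {
    stop("intensity must be > 0")
  }
  if (kind == "clustered") {
    if (is.null(cluster_sigma) || cluster_sigma <= 0) {
      stop("cluster_sigma must be > 0 for clustered processes")
    }
    if (is.null(cluster_parent_rate)) {
      cluster_parent_rate <- intensity / cluster_mean_offspring
    }
  }
  if (inhibition_radius < 0) stop("inhibition_radius must be >= 0")
  structure(
    list(kind = kind, intensity = intensity,
         cluster_parent_rate = cluster_parent_rate,
         cluster_sigma = cluster_sigma,
         cluster_mean_offspring = cluster_mean_offspring,
         inhibition_radius = inhibition_radius),
    class = "process_spec"
  )
}

#' Simulate a point pattern inside a region mask
#'
#' Positions are real-valued pixel coordinates (0-based, x = column,
#' y = row) uniformly jittered within their pixel, restricted to the
#' foreground of `region_mask`.
#'
#' @param region_mask Logical or 0/1 matrix; foreground pixels are the
#'   admissible region. Must contain at least one foreground pixel.
#' @param spec A [process_spec()].
#' @param seed Integer seed; all randomness is derived from it.
#' @return A data.frame with columns `x`, `y`.
#' @examples
#' m <- matrix(TRUE, 100, 100)
#' pts <- simulate_point_pattern(m, process_spec("poisson", 5e-3), seed = 1)
#' @export
simulate_point_pattern <- function(region_mask, spec, seed) {
  stopifnot(is.matrix(region_mask), inherits(spec, "process_spec"))
  fg <- which(region_mask != 0)
  if (length(fg) == 0L) stop("region mask has no foreground pixels")
  dim <- dim(region_mask)
  area <- length(fg)
  set.seed(seed)

  sample_fg <- function(n) {
    if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
    idx <- fg[sample.int(area, n, replace = TRUE)]
    r <- ((idx - 1L) %% dim[1L]) + 1L
    c <- ((idx - 1L) %/% dim[1L]) + 1L
    data.frame(x = (c - 1) + runif(n, -0.5, 0.5),
               y = (r - 1) + runif(n, -0.5, 0.5))
  }
  inside <- function(x, y) {
    px <- position_to_pixel(x, y, dim)
    ok <- round(x) >= 0 & round(x) <= dim[2L] - 1 &
      round(y) >= 0 & round(y) <= dim[1L] - 1
    ok & region_mask[px] != 0
  }

  if (spec$kind == "poisson") {
    n <- rpois(1L, spec$intensity * area)
    return(sample_fg(n))
  }

  if (spec$kind == "clustered") {
    n_par <- rpois(1L, spec$cluster_parent_rate * area)
    parents <- sample_fg(n_par)
    if (n_par == 0L) return(parents)
    n_off <- rpois(n_par, spec$cluster_mean_offspring)
    tot <- sum(n_off)
    if (tot == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
    x <- rep(parents$x, n_off) + rnorm(tot, 0, spec$cluster_sigma)
    y <- rep(parents$y, n_off) + rnorm(tot, 0, spec$cluster_sigma)
    keep <- inside(x, y)
    return(data.frame(x = x[keep], y = y[keep]))
  }

  # simple sequential inhibition: dart throwing with a hard-core radius
  target <- rpois(1L, spec$intensity * area)
  if (target == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  r2 <- spec$inhibition_radius^2
  xs <- numeric(target); ys <- numeric(target)
  n_acc <- 0L
  attempts <- 0L; max_attempts <- 50L * target
  while (n_acc < target && attempts < max_attempts) {
    cand <- sample_fg(1L)
    attempts <- attempts + 1L
    if (n_acc > 0L && r2 > 0 &&
        any((xs[seq_len(n_acc)] - cand$x)^2 +
            (ys[seq_len(n_acc)] - cand$y)^2 < r2)) next
    n_acc <- n_acc + 1L
    xs[n_acc] <- cand$x; ys[n_acc] <- cand$y
  }
  data.frame(x = xs[seq_len(n_acc)], y = ys[seq_len(n_acc)])
}

#' Simulate disjoint tumour-nest / tumour-stroma region masks
#'
#' The tumour nest (TN) is drawn as a union of a few random elliptical blobs
#' covering roughly `tn_fraction` of the frame; the tumour stroma (TS) is the
#' complement. The two masks are disjoint by construction, mirroring a
#' pathologist's delineation of nest versus stroma compartments.
#'
#' @param dim Image dimensions `c(height, width)` in px.
#' @param tn_fraction Approximate TN area fraction (default 0.4).
#' @param n_blobs Number of elliptical nest blobs (default 3).
#' @param seed Integer seed.
#' @return A list with logical matrices `tn` and `ts`.
#' @export
simulate_region_masks <- function(dim, tn_fraction = 0.4, n_blobs = 3,
                                  seed = 1) {
  set.seed(seed)
  h <- dim[1L]; w <- dim[2L]
  tn <- matrix(FALSE, h, w)
  # blob semi-axes sized so n_blobs ellipses cover ~ tn_fraction of the frame
  ax <- sqrt(tn_fraction * h * w / (pi * n_blobs))
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  for (i in seq_len(n_blobs)) {
    cy <- runif(1, 0.2 * h, 0.8 * h)
    cx <- runif(1, 0.2 * w, 0.8 * w)
    a <- ax * runif(1, 0.7, 1.3)
    b <- ax^2 / a
    tn <- tn | (((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1)
  }
  list(tn = tn, ts = !tn)
}

#' Assign marker phenotypes and staining levels to simulated cells
#'
#' Each cell first draws at most one primary marker from `marker_probs`
#' (probabilities over the panel's markers; the remainder is left
#' marker-negative). Co-expression rules then add a secondary marker: for a
#' rule `list(markers = c("CD8", "CD133"), p = 0.5)`, each cell positive for
#' the first marker becomes co-positive for the second with probability `p`.
#' Every positive marker receives a staining level drawn from `level_probs`.
#'
#' @param positions A data.frame with `x`, `y` (from
#'   [simulate_point_pattern()]).
#' @param panel A [panel_spec()].
#' @param marker_probs Named numeric vector over (a subset of) the panel's
#'   markers, summing to at most 1.
#' @param coexpression_rules Optional list of rules, each
#'   `list(markers = c(primary, secondary), p = probability)`.
#' @param seed Integer seed.
#' @param level_probs Probabilities of the `"+"`, `"++"`, `"+++"` levels for
#'   each positive marker (default uniform).
#' @return A cell table: data.frame with `cell_id`, `x`, `y`, `panel`,
#'   `markers` (semicolon-joined) and `levels` (semicolon-joined, parallel to
#'   `markers`).
#' @examples
#' pts <- data.frame(x = runif(10, 0, 99), y = runif(10, 0, 99))
#' assign_markers(pts, panel_spec(1), c(CD4 = 0.5, CD20 = 0.3), seed = 1)
#' @export
assign_markers <- function(positions, panel, marker_probs,
                           coexpression_rules = list(), seed,
                           level_probs = c(1, 1, 1) / 3) {
  stopifnot(inherits(panel, "panel_spec"))
  if (!all(names(marker_probs) %in% panel$markers)) {
    stop("marker_probs names must be markers of the panel")
  }
  for (rule in coexpression_rules) {
    if (!all(rule$markers %in% panel$markers)) {
      stop("co-expression rule refers to a marker outside the panel")
    }
  }
  if (sum(marker_probs) > 1 + 1e-12) {
    stop("marker_probs must sum to at most 1")
  }
  n <- nrow(positions)
  set.seed(seed)
  levels_avail <- c("+", "++", "+++")
  draw_levels <- function(k) sample(levels_avail, k, replace = TRUE,
                                    prob = level_probs)
  lab <- if (n > 0) {
    sample(c(names(marker_probs), ".neg"), n, replace = TRUE,
           prob = c(marker_probs, max(0, 1 - sum(marker_probs))))
  } else character(0)
  marker_sets <- lapply(lab, function(l) if (l == ".neg") character(0) else l)
  for (rule in coexpression_rules) {
    primary <- rule$markers[1L]; secondary <- rule$markers[2L]
    has_primary <- vapply(marker_sets, function(m) primary %in% m, logical(1))
    add <- has_primary & rbinom(n, 1L, rule$p) == 1L
    marker_sets[add] <- lapply(marker_sets[add], function(m) {
      unique(c(m, secondary))
    })
  }
  level_sets <- lapply(marker_sets, function(m) draw_levels(length(m)))
  data.frame(
    cell_id = seq_len(n),
    x = positions$x, y = positions$y,
    panel = rep(panel$panel_id, length.out = n),
    markers = join_markers(marker_sets),
    levels = join_markers(level_sets),
    stringsAsFactors = FALSE
  )
}

#' Render a synthetic mIF scene from a cell table
#'
#' Produces an RGB image emulating a multiplex immunofluorescence field:
#' nuclei are rendered as discs in the blue (DAPI-like) channel, and each
#' positive marker as a disc in its assigned red or green channel with an
#' intensity proportional to its staining level. A level `"+"` renders just
#' above the positivity threshold `x_threshold`, `"++"` just above twice it,
#' and `"+++"` just above three times it, so the rendered scene is consistent
#' with X/2X/3X intensity binning by construction. Small speckle objects
#' (1-2 px) are added to the marker channels at rate `noise_level` to
#' exercise the denoising (small-object removal) step; an optional Gaussian
#' point-spread blur can be applied.
#'
#' @param cells A cell table (see [assign_markers()]).
#' @param dim Image dimensions `c(height, width)` in px.
#' @param panel The [panel_spec()] the cells belong to.
#' @param nucleus_radius Nucleus disc radius in px (default 5).
#' @param psf_sigma Gaussian blur SD in px applied to all channels
#'   (default 0 = no blur).
#' @param noise_level Expected speckle objects per pixel (default 0).
#' @param seed Integer seed (used only for noise placement).
#' @param x_threshold Positivity threshold X on the [0, 1] channel scale
#'   (default 0.2).
#' @param tn_mask,ts_mask Optional region masks stored with the ground truth.
#' @return A list of class `mif_scene` with elements `image` (height x width
#'   x 3 composite array, values in [0, 1]), `marker_maps` (named list of
#'   per-marker channel maps — the stain signal each marker's unmixed
#'   component image carries in its assigned R or G channel, speckle noise
#'   included), and `truth`: a list with the integer nucleus `labels` mask,
#'   the input `cells` table, `tn`/`ts` masks and the `x_threshold` used.
#'   Because several markers of a panel share an optical channel, marker
#'   identity lives in the component images, not the composite; the composite
#'   exists for display and channel-arithmetic checks. A warning is raised
#'   when nuclei overlap so much that some ground-truth nucleus loses over
#'   half its pixels.
#' @export
render_scene <- function(cells, dim, panel, nucleus_radius = 5,
                         psf_sigma = 0, noise_level = 0, seed = 1,
                         x_threshold = 0.2, tn_mask = NULL, ts_mask = NULL) {
  stopifnot(inherits(panel, "panel_spec"))
  h <- dim[1L]; w <- dim[2L]
  # pixel centres run 0..w-1; the frame extends half a pixel beyond
  if (nrow(cells) > 0 &&
      (any(cells$x < -0.5 | cells$x > w - 0.5) ||
       any(cells$y < -0.5 | cells$y > h - 0.5))) {
    stop("cells must fit inside the image frame")
  }
  nuc <- matrix(0, h, w)
  maps <- setNames(lapply(panel$markers, function(m) matrix(0, h, w)),
                   panel$markers)
  labels <- matrix(0L, h, w)
  offs <- disc_offsets(nucleus_radius)
  level_mult <- c("+" = 1.1, "++" = 2.1, "+++" = 3.1)
  marker_sets <- split_markers(cells$markers)
  level_sets <- split_markers(cells$levels)
  n_disc_px <- nrow(offs)
  clipped <- 0L
  for (i in seq_len(nrow(cells))) {
    px <- position_to_pixel(cells$x[i], cells$y[i], c(h, w))
    idx <- disc_indices(c(h, w), px[1L], px[2L], offs)
    free <- labels[idx] == 0L
    if (sum(free) < n_disc_px / 2) clipped <- clipped + 1L
    labels[idx[free, , drop = FALSE]] <- cells$cell_id[i]
    nuc[idx] <- pmax(nuc[idx], 0.9)
    ms <- marker_sets[[i]]; ls <- level_sets[[i]]
    for (j in seq_along(ms)) {
      val <- min(1, level_mult[[ls[j]]] * x_threshold)
      maps[[ms[j]]][idx] <- pmax(maps[[ms[j]]][idx], val)
    }
  }
  if (clipped > 0L) {
    warning(sprintf("%d nuclei lost over half their pixels to overlap",
                    clipped))
  }
  if (noise_level > 0) {
    set.seed(seed)
    n_spk <- rpois(1L, noise_level * h * w)
    if (n_spk > 0L) {
      spk_off <- disc_offsets(1)
      for (k in seq_len(n_spk)) {
        r0 <- sample.int(h, 1L); c0 <- sample.int(w, 1L)
        m <- sample(panel$markers, 1L)
        idx <- disc_indices(c(h, w), r0, c0, spk_off)
        keep <- sample.int(nrow(idx), min(nrow(idx), sample(2:3, 1L)))
        idx <- idx[keep, , drop = FALSE]
        maps[[m]][idx] <- pmax(maps[[m]][idx], 1.2 * x_threshold)
      }
    }
  }
  if (psf_sigma > 0) {
    blur <- function(m) as.matrix(EBImage::gblur(EBImage::Image(m),
                                                 sigma = psf_sigma))
    nuc <- blur(nuc)
    maps <- lapply(maps, blur)
  }
  chan <- list(R = matrix(0, h, w), G = matrix(0, h, w), B = nuc)
  for (m in panel$markers) {
    ch <- panel$channels[[m]]
    chan[[ch]] <- pmax(chan[[ch]], maps[[m]])
  }
  img <- array(0, c(h, w, 3L))
  img[, , 1L] <- chan$R; img[, , 2L] <- chan$G; img[, , 3L] <- chan$B
  structure(
    list(image = img, marker_maps = maps,
         truth = list(labels = labels, cells = cells,
                      tn = tn_mask, ts = ts_mask,
                      x_threshold = x_threshold)),
    class = "mif_scene"
  )
}

#' Write and read scene artefacts
#'
#' Scenes are written as PNG (RGB image) or TIFF, the ground-truth label mask
#' as a 16-bit grayscale TIFF, and cell tables as CSV with semicolon-joined
#' marker and level fields.
#'
#' @param scene A `mif_scene` from [render_scene()].
#' @param image_path Output path ending in `.png` or `.tif`/`.tiff`.
#' @param labels_path Optional path for the 16-bit label TIFF.
#' @param cells_path Optional path for the cell-table CSV.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, image_path, labels_path = NULL,
                        cells_path = NULL) {
  stopifnot(inherits(scene, "mif_scene"))
  ext <- tolower(tools::file_ext(image_path))
  if (ext == "png") {
    png::writePNG(scene$image, image_path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scene$image, image_path)
  } else {
    stop("image_path must end in .png or .tif(f)")
  }
  if (!is.null(labels_path)) {
    tiff::writeTIFF(scene$truth$labels / 65535, labels_path,
                    bits.per.sample = 16L)
  }
  if (!is.null(cells_path)) {
    write_cell_table(scene$truth$cells, cells_path)
  }
  invisible(c(image_path, labels_path, cells_path))
}

#' @rdname write_scene
#' @param cells A cell table.
#' @param path CSV path.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_cell_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$markers[is.na(out$markers)] <- ""
  if ("levels" %in% names(out)) out$levels[is.na(out$levels)] <- ""
  out
}
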