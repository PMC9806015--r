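#' Collapse co-located cells into single multi-marker nodes
#'
#' Cells whose positions coincide (within `tol` px) are merged into one node
#' carrying the union of their marker sets, so a double-positive nucleus
#' enters the triangulation once instead of as duplicated points that would
#' degenerate it.
#'
#' @param cells A cell table with `x`, `y`, `markers`.
#' @param tol Distance below which positions count as identical (default
#'   1e-6 px).
#' @return The collapsed cell table.
#' @export
collapse_cells <- function(cells, tol = 1e-6) {
  if (nrow(cells) < 2L) return(cells)
  key <- paste(round(cells$x / tol), round(cells$y / tol))
  if (!anyDuplicated(key)) return(cells)
  groups <- split(seq_len(nrow(cells)), key)
  marker_sets <- split_markers(cells$markers)
  rows <- lapply(groups, function(idx) {
    first <- cells[idx[1L], , drop = FALSE]
    first$markers <- paste(unique(unlist(marker_sets[idx])), collapse = ";")
    first
  })
  out <- do.call(rbind, rows)
  out <- out[order(vapply(groups, min, 1L)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the Delaunay cell-connection graph for one panel of one image
#'
#' Connects the cells of a single slide/panel by Delaunay triangulation and
#' returns the edge table: one row per undirected edge with its Euclidean
#' length in pixels and the endpoints' marker sets. Degenerate inputs return
#' defined results: no or one cell gives an empty table, two cells give the
#' single segment, and fully collinear inputs give the chain of consecutive
#' segments. Exactly coincident points must be collapsed beforehand (see
#' [collapse_cells()]); any residual exact duplicates are collapsed here with
#' a deterministic tolerance.
#'
#' @param cells A cell table with `x`, `y`, `markers` (one panel, one image).
#' @return An object of class `edge_table`: data.frame with `a`, `b` (row
#'   indices into the returned `cells` attribute), `length` (px), `markers_a`,
#'   `markers_b` (semicolon-joined). The node table is attached as attribute
#'   `"cells"`.
#' @examples
#' cells <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1),
#'                     markers = c("CD4", "CD20", "CD4"))
#' build_delaunay(cells)
#' @export
build_delaunay <- function(cells) {
  cells <- collapse_cells(cells)
  n <- nrow(cells)
  empty <- data.frame(a = integer(0), b = integer(0), length = numeric(0),
                      markers_a = character(0), markers_b = character(0),
                      stringsAsFactors = FALSE)
  mk <- function(a, b) {
    len <- sqrt((cells$x[a] - cells$x[b])^2 + (cells$y[a] - cells$y[b])^2)
    out <- data.frame(a = a, b = b, length = len,
                      markers_a = cells$markers[a],
                      markers_b = cells$markers[b],
                      stringsAsFactors = FALSE)
    structure(out, cells = cells, class = c("edge_table", "data.frame"))
  }
  if (n <= 1L) {
    return(structure(empty, cells = cells,
                     class = c("edge_table", "data.frame")))
  }
  if (n == 2L) return(mk(1L, 2L))
  # deldir handles collinear point sets by returning the consecutive chain
  dd <- deldir::deldir(cells$x, cells$y, suppressMsge = TRUE)
  segs <- dd$delsgs
  a <- pmin(segs$ind1, segs$ind2)
  b <- pmax(segs$ind1, segs$ind2)
  keep <- !duplicated(cbind(a, b))
  mk(a[keep], b[keep])
}

#' Tabulate Delaunay edges into the 30-category spatial feature set
#'
#' Traverses every edge of the per-panel edge tables and classifies it by the
#' unordered pair of endpoint marker labels. An edge between a multi-positive
#' cell and another cell contributes one count to every distinct unordered
#' marker pair formed from the two endpoints' label sets. Edges with a
#' marker-negative endpoint are skipped (their count is reported in the
#' `n_skipped` attribute). For each category the connection count `n` and the
#' average connection length `mean_length` (total length / n; `NA` when
#' n = 0) are returned over the fixed 30-slot schema.
#'
#' @param edge_tables A single [build_delaunay()] result or a list of them
#'   (one per panel of the same image pair).
#' @param categories The category schema (default [edge_categories()]).
#' @param panels List of [panel_spec()] used for canonical pair labels.
#' @return An object of class `spatial_features`: the `categories` data.frame
#'   with added columns `n` and `mean_length`.
#' @export
tabulate_edges <- function(edge_tables,
                           panels = list(panel_spec(1), panel_spec(2)),
                           categories = edge_categories(panels)) {
  if (inherits(edge_tables, "edge_table")) edge_tables <- list(edge_tables)
  by_panel <- setNames(panels, vapply(panels, function(p)
    as.character(p$panel_id), character(1)))
  n <- setNames(rep(0, nrow(categories)), categories$category)
  tot <- setNames(rep(0, nrow(categories)), categories$category)
  n_skipped <- 0L
  for (et in edge_tables) {
    if (nrow(et) == 0L) next
    cells <- attr(et, "cells")
    panel_id <- as.character(cells$panel[1L] %||% names(by_panel)[1L])
    panel <- by_panel[[panel_id]] %||% panels[[1L]]
    ma <- split_markers(et$markers_a)
    mb <- split_markers(et$markers_b)
    for (k in seq_len(nrow(et))) {
      A <- ma[[k]]; B <- mb[[k]]
      if (length(A) == 0L || length(B) == 0L) {
        n_skipped <- n_skipped + 1L
        next
      }
      pairs <- unique(category_label(rep(A, each = length(B)),
                                     rep(B, times = length(A)), panel))
      if (!all(pairs %in% names(n))) stop("edge label outside category schema")
      n[pairs] <- n[pairs] + 1
      tot[pairs] <- tot[pairs] + et$length[k]
    }
  }
  out <- categories
  out$n <- as.numeric(n)
  out$mean_length <- ifelse(out$n > 0, tot / out$n, NA_real_)
  structure(out, n_skipped = n_skipped,
            class = c("spatial_features", "data.frame"))
}

#' Normalise spatial features within one image
#'
#' Adds the two relative forms computed over all categories of the same
#' image (both panels' graphs):
#' `pct_len = mean_length / (sum(n_i * mean_length_i) / sum(n_i))` — the
#' category's average connection length relative to the image's overall
#' edge-length mean — and `pct_num = n / sum(n_i)` — the category's share of
#' all classified connections. By construction `sum(pct_num) = 1` and the
#' edge-weighted mean of `pct_len` is 1. With zero classified edges all
#' relative values are `NA`.
#'
#' @param fs A `spatial_features` object from [tabulate_edges()].
#' @return The object with added `pct_len` and `pct_num` columns.
#' @export
normalize_features <- function(fs) {
  stopifnot(inherits(fs, "spatial_features"))
  total_n <- sum(fs$n)
  if (total_n == 0) {
    fs$pct_len <- NA_real_
    fs$pct_num <- NA_real_
    return(fs)
  }
  overall_mean <- sum(fs$n * ifelse(is.na(fs$mean_length), 0,
                                    fs$mean_length)) / total_n
  fs$pct_len <- fs$mean_length / overall_mean
  fs$pct_num <- fs$n / total_n
  fs
}

#' Flatten a spatial feature set into the fixed 120-column vector
#'
#' Column order follows the category schema: raw connection counts
#' (`n_<cat>`), raw average lengths (`len_<cat>`), then the relative forms
#' (`pct_num_<cat>`, `pct_len_<cat>`) when present. The raw part is the
#' 60-feature spatial descriptor (30 counts + 30 average lengths).
#'
#' @param fs A `spatial_features` object.
#' @return A named numeric vector.
#' @export
spatial_feature_vector <- function(fs) {
  stopifnot(inherits(fs, "spatial_features"))
  key <- gsub("[^A-Za-z0-9]+", ".", fs$category)
  out <- c(setNames(fs$n, paste0("n_", key)),
           setNames(fs$mean_length, paste0("len_", key)))
  if (!is.null(fs$pct_num)) {
    out <- c(out, setNames(fs$pct_num, paste0("pct_num_", key)),
             setNames(fs$pct_len, paste0("pct_len_", key)))
  }
  out
}

#' Average slide-level features into a patient-level vector
#'
#' When several pathology slides are available for one patient, each feature
#' is averaged across slides. The mean is missing-aware: slides lacking a
#' category (e.g. an `NA` average length) are ignored for that feature, and
#' the patient value is `NA` only when every slide misses it.
#'
#' @param slide_features A list of feature vectors
#'   ([spatial_feature_vector()]) or `spatial_features` objects.
#' @param patient_id Identifier attached to the result.
#' @return A one-row data.frame: `patient_id` followed by the averaged
#'   features.
#' @export
aggregate_patient <- function(slide_features, patient_id) {
  vecs <- lapply(slide_features, function(f) {
    if (inherits(f, "spatial_features")) spatial_feature_vector(f) else f
  })
  nm <- names(vecs[[1L]])
  if (!all(vapply(vecs, function(v) identical(names(v), nm), logical(1)))) {
    stop("slide feature vectors must share the same schema")
  }
  m <- do.call(rbind, vecs)
  means <- colMeans(m, na.rm = TRUE)
  means[colSums(!is.na(m)) == 0L] <- NA_real_
  out <- data.frame(patient_id = patient_id, t(means),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
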