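#' Marker panel definitions
#'
#' The pipeline analyses two 5-marker panels stained on serial sections of the
#' same tissue block. Panel 1 carries the lymphoid/neutrophil markers
#' (CD38, CD20, CD4, FOXP3, CD66b) and panel 2 the cytotoxic/myeloid/tumour
#' markers (PD-L1, CD163, CD8, CD68, CD133). Each marker is imaged in either
#' the red (R) or green (G) channel; the blue channel is reserved for the
#' DAPI nuclear counterstain.
#'
#' @param panel_id 1 or 2.
#' @param markers Optional character vector of exactly 5 marker names
#'   overriding the defaults.
#' @param channels Optional named character vector mapping each marker to
#'   `"R"` or `"G"`. Defaults follow the channel split used for the default
#'   markers (CD4, CD20, CD38, CD66b, CD133, CD163 in G; CD8, CD68, PD-L1,
#'   FOXP3 in R).
#' @return An object of class `panel_spec`: a list with `panel_id`, `markers`
#'   and `channels`.
#' @examples
#' panel_spec(1)
#' panel_spec(2)$channels
#' @export
panel_spec <- function(panel_id, markers = NULL, channels = NULL) {
  if (!panel_id %in% c(1L, 2L)) {
    stop("panel_id must be 1 or 2")
  }
  defaults <- list(
    `1` = c("CD38", "CD20", "CD4", "FOXP3", "CD66b"),
    `2` = c("PD-L1", "CD163", "CD8", "CD68", "CD133")
  )
  if (is.null(markers)) markers <- defaults[[as.character(panel_id)]]
  if (length(markers) != 5L || anyDuplicated(markers)) {
    stop("a panel must contain exactly 5 distinct markers")
  }
  if (is.null(channels)) {
    green <- c("CD4", "CD20", "CD38", "CD66b", "CD133", "CD163")
    channels <- setNames(ifelse(markers %in% green, "G", "R"), markers)
  }
  if (!all(markers %in% names(channels)) || !all(channels %in% c("R", "G"))) {
    stop("channels must map every panel marker to 'R' or 'G'")
  }
  structure(
    list(panel_id = as.integer(panel_id), markers = markers,
         channels = channels[markers]),
    class = "panel_spec"
  )
}

#' Enumerate the edge-category schema for a set of panels
#'
#' An edge category is an unordered pair of marker labels at the two endpoints
#' of a cell-graph edge, within one panel; self-pairs (A-A) are included.
#' Each 5-marker panel therefore contributes choose(5, 2) + 5 = 15 categories
#' and the default two-panel design yields 30. Because the panels are stained
#' on separate serial sections, cross-panel categories do not exist.
#'
#' @param panels List of [panel_spec()] objects (default: both panels).
#' @return A data.frame with columns `panel`, `marker_a`, `marker_b` and
#'   `category` (the canonical `"A|B"` label with markers in panel order).
#' @examples
#' nrow(edge_categories())  # 30
#' @export
edge_categories <- function(panels = list(panel_spec(1), panel_spec(2))) {
  out <- lapply(panels, function(p) {
    m <- p$markers
    idx <- cbind(rep(seq_along(m), times = seq_along(m)),
                 unlist(lapply(seq_along(m), seq_len)))
    # idx rows are (i >= j); order as (j, i) so marker_a precedes marker_b
    data.frame(
      panel = p$panel_id,
      marker_a = m[idx[, 2L]],
      marker_b = m[idx[, 1L]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$category <- paste(out$marker_a, out$marker_b, sep = "|")
  out
}

#' Canonical category label for a marker pair
#'
#' @param a,b Marker names (vectors recycle).
#' @param panel A [panel_spec()] giving the canonical marker order.
#' @return Character vector of `"A|B"` labels with A before B in panel order.
#' @keywords internal
category_label <- function(a, b, panel) {
  ia <- match(a, panel$markers)
  ib <- match(b, panel$markers)
  if (anyNA(ia) || anyNA(ib)) stop("marker not in panel")
  swap <- ia > ib
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "|")
}
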