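# Fixtures and independent oracles used across the suite. Oracles here are
# deliberately written as brute-force loops, separate from the package's
# implementations.

# Label matrix with discs of `radius` at the given (x, y) centres.
make_disc_labels <- function(centres, radius, dim) {
  lab <- matrix(0L, dim[1L], dim[2L])
  for (i in seq_len(nrow(centres))) {
    for (r in seq_len(dim[1L])) {
      for (c in seq_len(dim[2L])) {
        if ((r - 1 - centres$y[i])^2 + (c - 1 - centres$x[i])^2 <= radius^2) {
          lab[r, c] <- i
        }
      }
    }
  }
  lab
}

# Vectorised variant (fast enough for acceptance-scale fixtures).
make_disc_labels_fast <- function(centres, radius, dim) {
  lab <- matrix(0L, dim[1L], dim[2L])
  rows <- matrix(rep(seq_len(dim[1L]) - 1, dim[2L]), dim[1L], dim[2L])
  cols <- matrix(rep(seq_len(dim[2L]) - 1, each = dim[1L]), dim[1L], dim[2L])
  for (i in seq_len(nrow(centres))) {
    lab[(rows - centres$y[i])^2 + (cols - centres$x[i])^2 <= radius^2] <- i
  }
  lab
}

# Brute-force mean nearest-neighbour distance.
brute_mean_nn <- function(pts) {
  n <- nrow(pts)
  mins <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((pts$x[-i] - pts$x[i])^2 + (pts$y[-i] - pts$y[i])^2)
    mins[i] <- min(d)
  }
  mean(mins)
}

# Brute-force edge tabulation: double loop over edges and category slots,
# classifying every unordered endpoint-label pair independently of the
# package's path.
brute_tabulate <- function(edge_tables, panels) {
  cats <- edge_categories(panels)
  n <- setNames(rep(0, nrow(cats)), cats$category)
  tot <- setNames(rep(0, nrow(cats)), cats$category)
  for (et in edge_tables) {
    cells <- attr(et, "cells")
    pid <- as.character(cells$panel[1L])
    panel <- Filter(function(p) as.character(p$panel_id) == pid, panels)[[1L]]
    for (k in seq_len(nrow(et))) {
      A <- strsplit(et$markers_a[k], ";")[[1L]]
      B <- strsplit(et$markers_b[k], ";")[[1L]]
      A <- A[nzchar(A)]; B <- B[nzchar(B)]
      if (length(A) == 0L || length(B) == 0L) next
      seen <- character(0)
      for (a in A) for (b in B) {
        ia <- match(a, panel$markers); ib <- match(b, panel$markers)
        lab <- if (ia <= ib) paste(a, b, sep = "|") else paste(b, a, sep = "|")
        if (lab %in% seen) next
        seen <- c(seen, lab)
        n[lab] <- n[lab] + 1
        tot[lab] <- tot[lab] + et$length[k]
      }
    }
  }
  list(n = n, mean_length = ifelse(n > 0, tot / n, NA_real_))
}

# Random spatial feature set over the fixed 30-slot schema.
random_feature_set <- function(seed) {
  set.seed(seed)
  fs <- edge_categories()
  fs$n <- rpois(nrow(fs), 4)
  fs$mean_length <- ifelse(fs$n > 0, runif(nrow(fs), 1, 60), NA_real_)
  class(fs) <- c("spatial_features", "data.frame")
  fs
}

# Optimal IoU matching via igraph maximum-weight bipartite matching,
# restricted to pairs above the threshold.
oracle_match <- function(gt_labels, pred_labels, iou_threshold = 0.6) {
  pairs <- spatialmif:::iou_pairs(gt_labels, pred_labels)
  pairs <- pairs[pairs$iou > iou_threshold, , drop = FALSE]
  gt_ids <- sort(unique(gt_labels[gt_labels > 0]))
  pred_ids <- sort(unique(pred_labels[pred_labels > 0]))
  if (nrow(pairs) == 0L) {
    return(list(tp = 0L, total_iou = 0))
  }
  types <- c(rep(TRUE, length(gt_ids)), rep(FALSE, length(pred_ids)))
  edges <- rbind(match(pairs$gt, gt_ids),
                 length(gt_ids) + match(pairs$pred, pred_ids))
  g <- igraph::make_bipartite_graph(types, as.vector(edges))
  m <- igraph::max_bipartite_match(g, weights = pairs$iou)
  list(tp = m$matching_size, total_iou = m$matching_weight)
}

# A well-separated two-panel synthetic image pair with typed cells.
make_image_pair <- function(seed, n_per_panel = 40, dim = c(220, 220)) {
  panels <- list(panel_spec(1), panel_spec(2))
  probs <- list(
    c(CD38 = 0.25, CD20 = 0.2, CD4 = 0.25, FOXP3 = 0.1, CD66b = 0.15),
    c(`PD-L1` = 0.15, CD163 = 0.2, CD8 = 0.25, CD68 = 0.15, CD133 = 0.2)
  )
  mask <- matrix(TRUE, dim[1L], dim[2L])
  lapply(1:2, function(k) {
    spec <- process_spec("poisson", n_per_panel / prod(dim))
    pts <- simulate_point_pattern(mask, spec, seed = seed + k)
    assign_markers(pts, panels[[k]], probs[[k]], seed = seed + 10 + k)
  })
}
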