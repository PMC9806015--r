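test_that("point patterns respect the mask, the rate, and the zero limit", {
  mask <- matrix(FALSE, 60, 80)
  mask[10:50, 20:70] <- TRUE

  # near-zero rate gives an empty pattern
  tiny <- simulate_point_pattern(mask, process_spec("poisson", 1e-12),
                                 seed = 1)
  expect_equal(nrow(tiny), 0)

  # all points land on foreground pixels
  pts <- simulate_point_pattern(mask, process_spec("poisson", 0.05),
                                seed = 2)
  px <- spatialmif:::position_to_pixel(pts$x, pts$y, dim(mask))
  expect_true(all(mask[px]))

  expect_error(simulate_point_pattern(matrix(FALSE, 5, 5),
                                      process_spec("poisson", 1), seed = 1),
               "foreground")
})

test_that("poisson counts match the intensity in mean across replicate seeds", {
  mask <- matrix(TRUE, 1000, 1000)
  spec <- process_spec("poisson", 500 / 1e6)
  counts <- vapply(1:200, function(s) {
    nrow(simulate_point_pattern(mask, spec, seed = s))
  }, numeric(1))
  # Monte-Carlo: mean within 3 standard errors of 500
  se <- sqrt(500 / 200)
  expect_lt(abs(mean(counts) - 500), 3 * se)
  # Poisson dispersion: chi^2 index of dispersion not rejected at alpha=0.01
  disp <- sum((counts - 500)^2 / 500)
  expect_gt(disp, qchisq(0.005, df = 200))
  expect_lt(disp, qchisq(0.995, df = 200))
})

test_that("clustered patterns sit closer and inhibited patterns further apart
           than intensity-matched poisson", {
  mask <- matrix(TRUE, 400, 400)
  int <- 300 / (400 * 400)
  nn <- function(kind, seed, ...) {
    pts <- simulate_point_pattern(mask, process_spec(kind, int, ...), seed)
    brute_mean_nn(pts)
  }
  for (s in c(3, 17, 31)) {
    expect_lt(nn("clustered", s, cluster_sigma = 5), nn("poisson", s))
    expect_gt(nn("inhibited", s, inhibition_radius = 12), nn("poisson", s))
  }
})

test_that("marker assignment honours probabilities and co-expression rules", {
  pts <- data.frame(x = runif(100, 0, 99), y = runif(100, 0, 99))
  p1 <- panel_spec(1)

  none <- assign_markers(pts, p1, c(CD4 = 0), seed = 1)
  expect_true(all(none$markers == ""))

  all_cd4 <- assign_markers(pts, p1, c(CD4 = 1), seed = 1)
  expect_true(all(all_cd4$markers == "CD4"))
  # every positive marker carries a level
  expect_true(all(nchar(all_cd4$levels) > 0))

  expect_error(assign_markers(pts, p1, c(CD8 = 0.5), seed = 1), "panel")
  expect_error(assign_markers(pts, p1, c(CD4 = 0.7, CD20 = 0.7), seed = 1),
               "at most 1")

  # co-expression: of 10^4 CD8+ cells, fraction 0.5 also CD133+
  p2 <- panel_spec(2)
  big <- data.frame(x = runif(1e4, 0, 499), y = runif(1e4, 0, 499))
  tab <- assign_markers(big, p2, c(CD8 = 1),
                        coexpression_rules = list(
                          list(markers = c("CD8", "CD133"), p = 0.5)),
                        seed = 9)
  frac <- mean(grepl("CD133", tab$markers))
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("rendering is deterministic and consistent with its ground truth", {
  p1 <- panel_spec(1)
  cells <- data.frame(cell_id = 1:3, x = c(20, 60, 100), y = c(30, 80, 40),
                      panel = 1,
                      markers = c("CD4", "FOXP3", ""),
                      levels = c("+++", "+", ""))
  a <- render_scene(cells, c(128, 128), p1, nucleus_radius = 5,
                    noise_level = 0.001, seed = 4)
  b <- render_scene(cells, c(128, 128), p1, nucleus_radius = 5,
                    noise_level = 0.001, seed = 4)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$labels, b$truth$labels)

  # one isolated cell -> exactly one connected nuclear component
  solo <- render_scene(cells[1, ], c(64, 64), p1, nucleus_radius = 5)
  ch <- split_channels(solo$image)
  lab <- EBImage::bwlabel(EBImage::Image(ch$B > 0))
  expect_equal(max(lab), 1)

  # "+++" renders at >= 3X at the nucleus; "+" below 2X
  x0 <- a$truth$x_threshold
  expect_gte(a$marker_maps$CD4[31, 21], 3 * x0)
  expect_gte(a$marker_maps$FOXP3[81, 61], x0)
  expect_lt(a$marker_maps$FOXP3[81, 61], 2 * x0)

  # a G-assigned marker appears only in the composite G channel
  g_only <- render_scene(cells[1, ], c(64, 64), p1, nucleus_radius = 5)
  chg <- split_channels(g_only$image)
  expect_true(all(chg$R == 0))
  expect_gt(sum(chg$G), 0)

  # overlapping nuclei warn rather than error
  crowd <- data.frame(cell_id = 1:2, x = c(30, 31), y = c(30, 30), panel = 1,
                      markers = "", levels = "")
  expect_warning(render_scene(crowd, c(64, 64), p1, nucleus_radius = 6),
                 "overlap")
})

test_that("noise-free rendered scenes round-trip through detection", {
  p1 <- panel_spec(1)
  mask <- matrix(TRUE, 256, 256)
  spec <- process_spec("inhibited", 50 / (256^2), inhibition_radius = 18)
  pts <- simulate_point_pattern(mask, spec, seed = 6)
  cells <- assign_markers(pts, p1, c(CD4 = 0.4, CD20 = 0.3, FOXP3 = 0.2),
                          seed = 7)
  scene <- render_scene(cells, c(256, 256), p1, nucleus_radius = 5)
  res <- analyze_scene(scene, p1)
  expect_equal(nrow(res$cells), nrow(cells))
})

test_that("simulated cohorts reproduce their stated hazard and censoring", {
  # parameter recovery: binary variable with true ln HR = ln 2
  gen <- function(n) data.frame(V1 = rbinom(n, 1, 0.5))
  co <- simulate_cohort(cohort_spec(n_patients = 2000,
                                    true_log_hr = c(V1 = log(2)),
                                    censoring_rate = 0, seed = 21), gen)
  fit <- univariate_cox(co$V1, co$time_days, co$event)
  expect_lt(abs(fit$log_hr - log(2)), 0.15)

  # censoring calibration
  co2 <- simulate_cohort(cohort_spec(n_patients = 5000,
                                     true_log_hr = c(V1 = 0.5),
                                     censoring_rate = 0.3, seed = 22))
  cens <- mean(co2$event == 0)
  expect_lt(abs(cens - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))

  # null model: groups split on a feature have indistinguishable survival
  co3 <- simulate_cohort(cohort_spec(n_patients = 1000,
                                     censoring_rate = 0.2, seed = 23))
  grp <- co3$V1 > median(co3$V1)
  km <- km_logrank(co3$time_days, co3$event, grp)
  expect_gt(km$logrank_p, 0.001)

  expect_error(cohort_spec(n_patients = 100, censoring_rate = 1), "censoring")
  expect_error(
    simulate_cohort(cohort_spec(n_patients = 50,
                                true_log_hr = c(absent = 1), seed = 1)),
    "exist")
})

test_that("scene and cell-table IO round-trips through PNG/TIFF/CSV", {
  p1 <- panel_spec(1)
  cells <- data.frame(cell_id = 1:2, x = c(10, 30), y = c(12, 25), panel = 1,
                      markers = c("CD4;CD20", ""), levels = c("+;+++", ""))
  scene <- render_scene(cells, c(48, 48), p1, nucleus_radius = 4)
  tmp <- withr::local_tempdir()
  write_scene(scene, file.path(tmp, "scene.png"),
              labels_path = file.path(tmp, "labels.tif"),
              cells_path = file.path(tmp, "cells.csv"))
  img <- png::readPNG(file.path(tmp, "scene.png"))
  expect_equal(dim(img), dim(scene$image))
  expect_lt(max(abs(img - scene$image)), 1 / 255)
  lab <- tiff::readTIFF(file.path(tmp, "labels.tif"))
  expect_equal(round(lab * 65535), scene$truth$labels,
               ignore_attr = TRUE)
  back <- read_cell_table(file.path(tmp, "cells.csv"))
  expect_equal(back$markers, cells$markers)
  expect_equal(back$x, cells$x)
})
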