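test_that("superpixel maps are contiguous partitions near the target count", {
  img <- matrix(runif(20 * 30), 20, 30)
  for (nt in c(4, 9, 16, 25)) {
    map <- segment_superpixels(img, nt)
    expect_identical(dim(map$labels), dim(img))
    expect_setequal(unique(as.vector(map$labels)), 0:(map$n_segments - 1))
    expect_gte(map$n_segments, ceiling(nt / 2))
    expect_lte(map$n_segments, 2 * nt)
    # contiguity: each segment is one 4-connected rectangle-ish block;
    # check via bounding-box fill (blocks are axis-aligned rectangles)
    for (s in unique(as.vector(map$labels))) {
      w <- which(map$labels == s, arr.ind = TRUE)
      expect_identical(nrow(w),
                       as.integer(diff(range(w[, 1])) + 1) *
                         as.integer(diff(range(w[, 2])) + 1))
    }
  }
  expect_identical(segment_superpixels(img, 9)$labels,
                   segment_superpixels(img, 9)$labels)
  expect_error(segment_superpixels(img, 1), "n_target")
})

test_that("a constant predictor yields zero weights and the constant intercept", {
  img <- matrix(runif(144), 12, 12)
  map <- segment_superpixels(img, 9)
  ex <- explain_instance(img, function(l) rep(0.7, length(l)), map,
                         n_samples = 100, seed = 1)
  expect_lt(max(abs(ex$segment_weights)), 1e-8)
  expect_equal(ex$intercept, 0.7, tolerance = 1e-8)
})

test_that("surrogate recovers a linear predictor and matches the exhaustive fit", {
  set.seed(10)
  img <- matrix(runif(12 * 12), 12, 12)
  map <- segment_superpixels(img, 9)
  ns <- map$n_segments
  beta <- seq(0.005, by = 0.008, length.out = ns)
  state_of <- function(im) vapply(0:(ns - 1), function(s)
    as.numeric(all(im[map$labels == s] == img[map$labels == s])), numeric(1))
  predictor <- function(imgs) vapply(imgs, function(im)
    0.1 + sum(beta * state_of(im)), numeric(1))

  ex <- explain_instance(img, predictor, map, n_samples = 400, seed = 3)
  expect_gt(ex$r2, 0.99)                 # linear-in-segments predictor

  # exhaustive-enumeration oracle: weighted ridge over all 2^ns masks
  Zall <- as.matrix(do.call(expand.grid, rep(list(0:1), ns)))
  yall <- 0.1 + as.vector(Zall %*% beta)
  d <- 1 - sqrt(rowSums(Zall) / ns)
  wall <- exp(-d^2 / 0.25^2)
  oracle <- thermotan:::ridge_fit(Zall, yall, wall, 1.0)$coef
  ord_oracle <- order(-oracle)
  ord_fit <- order(-ex$segment_weights)
  expect_identical(ord_fit[1:3], ord_oracle[1:3])

  # indicator of one segment: its coefficient is the strict maximum
  pred3 <- function(imgs) vapply(imgs, function(im) state_of(im)[4], numeric(1))
  ex3 <- explain_instance(img, pred3, map, n_samples = 300, seed = 5)
  expect_identical(unname(which.max(ex3$segment_weights)), 4L)

  # determinism
  ex_b <- explain_instance(img, predictor, map, n_samples = 400, seed = 3)
  expect_identical(ex_b$segment_weights, ex$segment_weights)

  expect_error(explain_instance(img, function(l) rep(2, length(l)), map,
                                n_samples = 100, seed = 1),
               "probability")
})

test_that("critical ROI maps masks back to grid coordinates", {
  g <- thermogram(matrix(30, 12, 12))
  img <- preprocess_for_cnn(g, cnn_config(input_size = c(12, 12, 1)))
  map <- segment_superpixels(img, 4)
  ex <- explain_instance(img, function(l) vapply(l, mean, numeric(1)) * 0 + 0.6,
                         map, n_samples = 50, seed = 1)
  # force weights: all segments positive -> identity when k covers all
  ex$segment_weights[] <- c(0.3, 0.2, 0.25, 0.15)
  roi <- critical_roi(g, ex, k = 4)
  expect_identical(roi$mask, g$mask)     # all-true mask leaves grid unchanged

  roi1 <- critical_roi(g, ex, k = 1)
  expect_identical(sort(unique(as.vector(map$labels[roi1$mask]))), 0L)

  expect_error(critical_roi(g, ex, k = 0), "k")
  ex$segment_weights[] <- -1
  expect_error(critical_roi(g, ex, k = 2),
               class = "thermotan_empty_segmentation")
})

test_that("explanations localize the constructed hot-spot in sick cases", {
  e <- easy_cohort()
  m <- easy_cnn()
  predictor <- function(l) cnn_predict(m, l)$probability_sick
  sick <- which(e$y == 1)
  hits <- 0; total <- 0
  for (i in sick) {
    comp <- e$composites[[i]]
    map <- segment_superpixels(e$images[[i]], 16)
    ex <- explain_instance(e$images[[i]], predictor, map, n_samples = 150,
                           seed = 1000 + i, fill = 0)
    rec <- e$cohort$records[i, ]
    gaff <- if (rec$affected_side == "left") e$cohort$pairs[[i]]$left else
      e$cohort$pairs[[i]]$right
    hr <- gaff$meta$hotspot_row
    hc <- gaff$meta$hotspot_col + if (rec$affected_side == "right") 24 else 0
    ok <- tryCatch(critical_roi(comp, ex, 3)$mask[hr, hc],
                   error = function(err) FALSE)
    hits <- hits + ok; total <- total + 1
  }
  expect_gte(hits / total, 0.8)
})

test_that("overlay and weight artifacts are written", {
  img <- matrix(runif(100), 10, 10)
  map <- segment_superpixels(img, 4)
  ex <- explain_instance(img, function(l) rep(0.5, length(l)), map,
                         n_samples = 40, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_explanation_overlay(img, ex, p1)
  write_explanation_weights(ex, p2)
  expect_true(file.size(p1) > 0)
  w <- read.csv(p2)
  expect_equal(nrow(w), map$n_segments)
})
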