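test_that("the worked 2x2 example reproduces every factor", {
  aff <- breast_roi(thermogram(matrix(c(30, 32, 31, 35), 2, 2)), "left",
                    "affected")
  hea <- breast_roi(thermogram(matrix(c(30, 31, 30, 32), 2, 2)), "right",
                    "healthy")
  f <- extract_factors(aff, hea)
  expect_equal(f[["Max_Temperature"]], 35)
  expect_equal(f[["Min_temperature"]], 30)
  expect_equal(f[["Temperature_Range"]], 5)
  expect_equal(f[["Mean"]], 32)
  expect_equal(f[["Median"]], 31.5)
  expect_equal(f[["Variance"]], 3.5)
  expect_equal(f[["Standard_Deviation"]], sqrt(3.5), tolerance = 1e-9)
  expect_equal(f[["Deviation_From_Mean"]], 3)
  expect_equal(f[["MaxMax"]], 3)
  expect_equal(f[["MaxMin"]], 5)
  expect_equal(f[["Deviation_Mean_Healthy"]], 4.25)
  expect_equal(f[["Mean_Difference"]], 1.25)
  expect_equal(f[["D"]], sqrt(2), tolerance = 1e-12)
  expect_equal(unname(f[c("A", "B", "C")]), c(1, 4, 1))
  expect_equal(f[["A/B"]], 0.25)
  expect_equal(f[["C/B"]], 0.25)
})

test_that("degenerate and self-comparison cases follow the conventions", {
  const <- breast_roi(thermogram(matrix(30, 3, 3)), "left", "affected")
  other <- breast_roi(thermogram(matrix(c(30, 31, 30, 32), 2, 2)), "right",
                      "healthy")
  f <- extract_factors(const, other)
  expect_equal(unname(f[c("Standard_Deviation", "Variance",
                          "Temperature_Range", "Deviation_From_Mean")]),
               rep(0, 4))
  expect_equal(unname(f[c("A", "C")]), c(0, 0))
  expect_equal(f[["D"]], 0)   # max and min tie-break to the same first cell

  g <- thermogram(matrix(c(30, 31, 33, 29.5, 32, 30.5), 2, 3))
  same <- extract_factors(breast_roi(g, "left", "affected"),
                          breast_roi(g, "right", "healthy"))
  expect_equal(same[["MaxMax"]], 0)
  expect_equal(same[["MaxMin"]], same[["Temperature_Range"]])
  expect_equal(same[["Mean_Difference"]], 0)

  tiny <- thermogram(matrix(c(30, NA, NA, NA), 2, 2),
                     mask = matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_error(extract_factors(breast_roi(tiny, "left"), other),
               "at least 2 valid cells")
})

test_that("every statistic matches the naive reference on random ROIs", {
  set.seed(77)
  for (i in 1:200) {
    ga <- random_grid(sample(3:10, 1), sample(3:10, 1), lo = 27, hi = 37)
    gh <- random_grid(sample(3:10, 1), sample(3:10, 1), lo = 27, hi = 37)
    if (sum(ga$mask) < 2 || sum(gh$mask) < 2) next
    f <- extract_factors(breast_roi(ga, "left", "affected"),
                         breast_roi(gh, "right", "healthy"))
    ref <- reference_factors(ga$values, ga$mask, gh$values, gh$mask)
    expect_equal(f, ref, tolerance = 1e-9)
    expect_lte(f[["A"]], f[["C"]])
    expect_lte(f[["C"]], f[["B"]])
  }
})

test_that("factors are translation-invariant where they should be", {
  set.seed(5)
  shift_keep <- c("Temperature_Range", "Standard_Deviation", "Variance",
                  "Deviation_From_Mean", "MaxMax", "MaxMin",
                  "Deviation_Mean_Healthy", "Mean_Difference",
                  "D", "A", "B", "C", "A/B", "C/B")
  shift_by_c <- c("Max_Temperature", "Min_temperature", "Mean", "Median")
  for (i in 1:20) {
    ga <- random_grid(5, 6, lo = 28, hi = 36)
    gh <- random_grid(5, 6, lo = 28, hi = 36)
    if (sum(ga$mask) < 2 || sum(gh$mask) < 2) next
    cshift <- runif(1, -2, 2)
    f0 <- extract_factors(breast_roi(ga, "left", "affected"),
                          breast_roi(gh, "right", "healthy"))
    ga2 <- thermogram(ga$values + cshift, mask = ga$mask)
    gh2 <- thermogram(gh$values + cshift, mask = gh$mask)
    f1 <- extract_factors(breast_roi(ga2, "left", "affected"),
                          breast_roi(gh2, "right", "healthy"))
    expect_equal(f1[shift_keep], f0[shift_keep], tolerance = 1e-9)
    expect_equal(unname(f1[shift_by_c] - f0[shift_by_c]), rep(cshift, 4),
                 tolerance = 1e-9)
  }
})

test_that("the factor table has the documented shape and flags failures", {
  co <- generate_cohort(cohort_spec(n_healthy = 4, n_sick = 3,
                                    grid_height = 10, grid_width = 10,
                                    seed = 12))
  pairs <- lapply(seq_len(7), function(i) {
    l <- breast_roi(co$pairs[[i]]$left, "left")
    r <- breast_roi(co$pairs[[i]]$right, "right")
    assign_roles(l, r, co$records[i, ])
  })
  tab <- factor_table(co$records, pairs)
  expect_identical(nrow(tab), 7L)
  expect_identical(names(tab),
                   c("patient_id", thermotan:::factor_names,
                     "age", "last_menstrual_period", "diagnosis"))
  expect_setequal(unique(tab$diagnosis), c(0, 1))

  # a broken ROI pair is excluded and reported
  bad <- pairs
  tiny <- thermogram(matrix(c(30, NA, NA, NA), 2, 2),
                     mask = matrix(c(TRUE, rep(FALSE, 3)), 2, 2))
  bad[[2]]$affected$grid <- tiny
  expect_warning(tab2 <- factor_table(co$records, bad), "excluded")
  expect_identical(nrow(tab2), 6L)
  expect_identical(attr(tab2, "failed"), co$records$patient_id[2])
})
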