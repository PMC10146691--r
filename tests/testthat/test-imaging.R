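test_that("Otsu threshold separates a two-level frame", {
  fr <- matrix(c(rep(40, 90), rep(200, 60)), nrow = 150, ncol = 20)
  mask <- otsu_threshold(fr)
  thr <- attr(mask, "threshold")
  expect_true(thr > 40 && thr < 200)
  expect_equal(mean(mask), 0.6)
  expect_error(otsu_threshold(matrix(7, 10, 10)), "segmentation failure")
})

test_that("Otsu threshold is invariant to affine intensity rescaling", {
  fr <- render_coflow_frame(0.55, seed = 4)
  m1 <- otsu_threshold(fr)
  m2 <- otsu_threshold(fr * 3.2 + 17)
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
})

test_that("interface fraction averages per-column blood widths", {
  mask <- matrix(TRUE, 150, 20)
  expect_equal(as.numeric(interface_fraction(mask)), 1.0)
  mask2 <- rbind(matrix(TRUE, 90, 20), matrix(FALSE, 60, 20))
  expect_equal(as.numeric(interface_fraction(mask2)), 0.6)
  # ragged interface: widths 89/90/91 repeating average to 0.6
  widths <- rep(c(89, 90, 91), length.out = 21)
  mask3 <- vapply(widths, function(wd) c(rep(TRUE, wd), rep(FALSE, 150 - wd)),
                  logical(150))
  expect_equal(as.numeric(interface_fraction(mask3)), 0.6)
  # column count does not matter for columnwise-constant masks
  expect_equal(as.numeric(interface_fraction(mask2[, 1:3, drop = FALSE])), 0.6)
  # non-contiguous blood is flagged but still measured
  mask4 <- mask2
  mask4[1:5, ] <- FALSE
  mask4[100:104, ] <- TRUE
  frac <- interface_fraction(mask4)
  expect_true(attr(frac, "contiguity_flag"))
  expect_equal(as.numeric(frac), 0.6)
})

test_that("rendered frames are deterministic and resolvable", {
  f1 <- render_coflow_frame(0.4, seed = 10)
  f2 <- render_coflow_frame(0.4, seed = 10)
  expect_identical(f1, f2)
  f3 <- render_coflow_frame(0.4, seed = 11)
  expect_false(identical(f3, f1))
  expect_error(render_coflow_frame(0.005), "resolution")
  # clean frame roundtrips exactly
  clean <- render_coflow_frame(0.5, blur_sigma = 0, noise_sd = 0)
  expect_equal(as.numeric(interface_fraction(otsu_threshold(clean))), 0.5)
})

test_that("render-extract roundtrip is unbiased within one pixel", {
  for (a in seq(0.2, 0.8, by = 0.1)) {
    fr <- render_coflow_frame(a, seed = round(1000 * a))
    got <- as.numeric(interface_fraction(otsu_threshold(fr)))
    expect_lt(abs(got - a), 0.01)
  }
})

test_that("a stack of rendered frames reproduces a known trajectory", {
  a_true <- seq(0.3, 0.7, length.out = 12)
  stack <- lapply(seq_along(a_true), function(k) {
    render_coflow_frame(a_true[k], seed = 500 + k)
  })
  ts <- (seq_along(stack) - 1) * 0.5
  ser <- series_from_stack(stack, ts)
  expect_equal(nrow(ser), 12)
  expect_lt(max(abs(ser$alpha_b - a_true)), 0.01)
  expect_length(attr(ser, "gaps"), 0)

  # constant frames become gaps, not errors, as long as one frame is usable
  stack2 <- c(stack[1:3], list(matrix(128, 150, 198)))
  ser2 <- series_from_stack(stack2, (0:3) * 0.5)
  expect_equal(attr(ser2, "gaps"), 4L)
  expect_equal(nrow(ser2), 3)

  expect_error(series_from_stack(list(), numeric(0)), "empty")
  expect_error(series_from_stack(stack, ts[-1]), "timestamps")
  # single frame gives a single-sample series
  ser3 <- series_from_stack(stack[1], 0)
  expect_equal(nrow(ser3), 1)
})

test_that("TIFF and PNG stacks read back into matching series", {
  dir <- tempfile(); dir.create(dir)
  a_true <- c(0.35, 0.55, 0.75)
  for (k in seq_along(a_true)) {
    fr <- render_coflow_frame(a_true[k], seed = 30 + k) / 255
    tiff::writeTIFF(fr, file.path(dir, sprintf("f%d.tif", k)))
    png::writePNG(fr, file.path(dir, sprintf("f%d.png", k)))
  }
  tser <- series_from_stack(file.path(dir, sprintf("f%d.tif", 1:3)),
                            (0:2) * 0.5)
  pser <- series_from_stack(file.path(dir, sprintf("f%d.png", 1:3)),
                            (0:2) * 0.5)
  expect_lt(max(abs(tser$alpha_b - a_true)), 0.01)
  expect_equal(tser$alpha_b, pser$alpha_b, tolerance = 0.005)
  unlink(dir, recursive = TRUE)
})
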