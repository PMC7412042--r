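render_fixture <- function(seed = 81, noise = 0, dpi = 144) {
  rec <- generate_dipole_record(dipole_params(),
                                class_perturbation("HC", noise_sd = noise),
                                seed = seed)
  pap <- mask_to_paper_layout(rec$ecg)
  list(rec = rec, pap = pap, img = render_paper_image(pap, dpi = dpi))
}

test_that("calibration frame derives positive factors, rejects degenerate points", {
  cf <- calibration_frame(c(10, 100), c(10, 43.3), c(21.3, 100))
  expect_gt(cf$mv_per_px, 0)
  expect_gt(cf$ms_per_px, 0)
  expect_error(calibration_frame(c(0, 0), c(0, 10), c(0, 20)), "collinear")
  expect_error(color_thresholds(c(1, 1, 1), c(0, 0, 0)), "lower bounds")
})

test_that("rendering: all-zero signals give flat baselines; dpi is honoured", {
  f <- render_fixture()
  zero <- f$pap
  for (l in ECG_LEADS) zero$segments[[l]]$samples[] <- 0
  zero$reference[] <- 0
  img0 <- render_paper_image(zero, dpi = 144)
  mask0 <- remove_grid(img0)
  rows <- which(mask0, arr.ind = TRUE)
  # trace pixels concentrate on the four row baselines
  bl <- sort(unique(vapply(img0$layout, `[[`, numeric(1), "baseline")))
  expect_lte(max(vapply(rows[, 1], function(r) min(abs(r - bl)), numeric(1))), 1)
  # 144 dpi: 10 s at 25 mm/s spans 250 mm -> ~1417 px plus margins
  expect_equal(dim(f$img$pixels)[2], 2 * round(5 * 144 / 25.4) + round(250 * 144 / 25.4))
})

test_that("grid removal keeps the trace and drops the grid", {
  f <- render_fixture()
  # pure-grid page (no trace anywhere) -> empty-trace error
  blank <- f$pap
  grid_only <- render_paper_image(blank, dpi = 100)
  grid_only$pixels[grid_only$pixels == 0] <- 1   # erase the black trace
  expect_error(remove_grid(grid_only), "empty trace")
  # trace-only render: mask equals the non-white pixels exactly
  img_ng <- render_paper_image(f$pap, dpi = 100, grid = "none")
  mask_ng <- remove_grid(img_ng)
  expect_identical(mask_ng, img_ng$pixels[, , 1] < 0.5)
  # with grid: pixel count within 5% of the grid-free render
  mask_g <- remove_grid(render_paper_image(f$pap, dpi = 100))
  expect_lt(abs(sum(mask_g) - sum(mask_ng)) / sum(mask_ng), 0.05)
})

test_that("tracing digitizes amplitudes to calibration accuracy", {
  f <- render_fixture()
  # flat zero lead digitizes to 0 mV everywhere
  zero <- f$pap
  zero$segments$V5$samples[] <- 0
  imgz <- render_paper_image(zero, dpi = 144)
  sig <- digitize_paper_image(imgz)
  quantum <- imgz$calib$mv_per_px
  expect_lte(max(abs(sig$segments$V5$samples)), quantum)
  # a 1 mV calibration pulse digitizes to 1.0 mV within a pixel quantum
  pulse <- f$pap
  pulse$segments$V6$samples[] <- 0
  pulse$segments$V6$samples[300:900] <- 1
  imgp <- render_paper_image(pulse, dpi = 144)
  sigp <- digitize_paper_image(imgp)
  mid <- sigp$segments$V6$samples[500:700]
  expect_lt(abs(mean(mid) - 1), 2 * quantum)
  # known triangle wave round-trips within 2 pixel quanta away from the apex
  tri <- f$pap
  tw <- c(seq(0, 1, length.out = 625), seq(1, 0, length.out = 625))
  tri$segments$V4$samples <- tw
  sigt <- digitize_paper_image(render_paper_image(tri, dpi = 144))
  expect_lt(stats::quantile(abs(sigt$segments$V4$samples - tw), 0.99),
            2 * quantum)
})

test_that("render -> digitize round-trip is faithful (sine and calibration linearity)", {
  f <- render_fixture()
  sine <- f$pap
  t10 <- (0:4999) / 500
  sine$reference <- 0.8 * sin(2 * pi * 1.3 * t10)
  for (l in ECG_LEADS) {
    off <- sine$segments[[l]]$offset
    tt <- ((0:1249) / 500) + off
    sine$segments[[l]]$samples <- 0.8 * sin(2 * pi * 1.3 * tt)
  }
  img <- render_paper_image(sine, dpi = 144)
  dig <- digitize_paper_image(img)
  for (l in c("I", "aVF", "V2", "V6"))
    expect_gte(rsquared(dig$segments[[l]]$samples, sine$segments[[l]]$samples),
               0.99)
  # doubling the rendered amplitude doubles the digitized amplitude
  half <- sine
  for (l in ECG_LEADS) half$segments[[l]]$samples <-
      sine$segments[[l]]$samples / 2
  dig_h <- digitize_paper_image(render_paper_image(half, dpi = 144))
  r <- max(abs(dig$segments$V2$samples)) / max(abs(dig_h$segments$V2$samples))
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("PNG round-trip preserves the image and its geometry", {
  f <- render_fixture(dpi = 144)
  path <- tempfile(fileext = ".png")
  write_paper_png(f$img, path)
  back <- read_paper_png(path)
  expect_equal(back$pixels, f$img$pixels, tolerance = 1 / 255)
  d1 <- digitize_paper_image(back)
  expect_gte(rsquared(d1$segments$II$samples, f$pap$segments$II$samples), 0.95)
  unlink(c(path, paste0(path, ".json")))
})
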