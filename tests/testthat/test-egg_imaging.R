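white_image <- function(h = 10, w = 10) array(255L, dim = c(h, w, 3L))

test_that("blue-channel pixel counting applies the inclusive window", {
  expect_equal(egg_pixel_count(white_image()), 0)
  expect_equal(egg_pixel_count(array(0L, dim = c(10, 10, 3L))), 100)
  # window ends are inclusive on both sides
  img <- white_image()
  img[1, 1, 3] <- 98L
  img[1, 2, 3] <- 99L
  img[1, 3, 3] <- 0L
  expect_equal(egg_pixel_count(img), 2)
  # [0,1]-scaled input (as read from PNG) is handled identically
  expect_equal(egg_pixel_count(img / 255), 2)
  # red/green content is irrelevant
  img2 <- img
  img2[, , 1] <- 0L
  img2[, , 2] <- 130L
  expect_equal(egg_pixel_count(img2), egg_pixel_count(img))
  # monotone in the upper window end
  counts <- vapply(c(50, 98, 255), function(hi) {
    egg_pixel_count(img, egg_calibration(intensity_high = hi))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # grayscale and malformed rasters are rejected
  expect_error(egg_pixel_count(matrix(0, 5, 5)),
               class = "f2screen_input_error")
  expect_error(egg_pixel_count(array(300L, dim = c(2, 2, 3))),
               class = "f2screen_input_error")
})

test_that("pixel counting matches synthetic ground truth exactly", {
  sim <- generate_egg_image(25, width = 300, height = 300, seed = 99)
  expect_equal(egg_pixel_count(sim$image), sim$egg_pixels)
  # zero eggs -> all-white canvas
  sim0 <- generate_egg_image(0, seed = 1)
  expect_equal(sim0$egg_pixels, 0)
  expect_equal(egg_pixel_count(sim0$image), 0)
  expect_true(all(sim0$image == 255L))
  # seeded rendering is byte-identical
  a <- generate_egg_image(10, seed = 42)
  b <- generate_egg_image(10, seed = 42)
  expect_identical(a$image, b$image)
  # impossible placements fail loudly
  expect_error(generate_egg_image(500, width = 20, height = 20, seed = 2),
               class = "f2screen_input_error")
})

test_that("calibration regression recovers exact affine relations", {
  px <- c(100, 200, 300, 400, 500)
  cal <- fit_calibration(px, 0.01 * px)
  expect_equal(cal$slope, 0.01, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  cal2 <- fit_calibration(px, 0.02 * px + 3)
  expect_equal(cal2$slope, 0.02, tolerance = 1e-12)
  expect_equal(cal2$intercept, 3, tolerance = 1e-9)
  expect_error(fit_calibration(c(1, 2), c(1, 2)),
               class = "f2screen_input_error")
  expect_error(fit_calibration(rep(5, 4), 1:4),
               class = "f2screen_input_error")
})

test_that("noisy calibration data recover the slope within 3 standard errors", {
  set.seed(515)
  n <- 50
  px <- runif(n, 500, 5000)
  slope <- 0.011
  eggs <- slope * px + rnorm(n, sd = 4)
  cal <- fit_calibration(px, eggs)
  se <- 4 / sqrt(sum((px - mean(px))^2))  # known-sigma slope s.e.
  expect_lt(abs(cal$slope - slope), 3 * se)
})

test_that("end-to-end egg estimation tracks the generator's truth", {
  set.seed(77)
  n_imgs <- 16
  eggs_true <- sample(5:40, n_imgs, replace = TRUE)
  sims <- lapply(seq_len(n_imgs), function(i) {
    generate_egg_image(eggs_true[i], width = 300, height = 300,
                       seed = 1000 + i)
  })
  px <- vapply(sims, function(s) egg_pixel_count(s$image), numeric(1))
  half <- seq_len(n_imgs / 2)
  cal <- fit_calibration(px[half], eggs_true[half])
  pred <- vapply(sims[-half], function(s) estimate_egg_count(s$image, cal),
                 numeric(1))
  # predicted-vs-true slope ~ 1; residual scatter below the blob-area noise
  fit <- lm(pred ~ eggs_true[-half])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)
  expect_lt(mean(abs(pred - eggs_true[-half])), 3)
  # estimates at calibration points and degenerate inputs
  cal_exact <- fit_calibration(c(100, 200, 300), c(1, 2, 3))
  img <- white_image(20, 20)
  expect_equal(estimate_egg_count(img, cal_exact), 0)  # 0 px, intercept ~ 0
  expect_error(estimate_egg_count(img, egg_calibration()),
               class = "f2screen_state_error")
})

test_that("PNG round trip preserves pixel counts", {
  sim <- generate_egg_image(8, seed = 21)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(sim$image / 255, path)
  back <- read_egg_image(path)
  expect_equal(egg_pixel_count(back), sim$egg_pixels)
  expect_error(read_egg_image("nope.png"), class = "f2screen_input_error")
})
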