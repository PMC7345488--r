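test_that("a color equal to a table entry maps to that entry's thickness", {
  tab <- default_table()
  for (k in c(1, 50, 120, nrow(tab)))
    expect_equal(nearest_llt(as.numeric(tab[k, c("R", "G", "B")]), tab),
                 tab$llt_nm[k])
})

test_that("equidistant colors resolve to the smaller thickness", {
  tab <- structure(
    data.frame(llt_nm = c(40, 80), R = c(100L, 120L), G = c(100L, 100L),
               B = c(100L, 100L)),
    class = c("lookup_table", "data.frame"))
  expect_equal(nearest_llt(c(110, 100, 100), tab), 40)
})

test_that("vectorized lookup equals a brute-force linear scan on 1000 colors", {
  tab <- default_table()
  set.seed(21)
  colors <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  got <- apply(colors, 1, nearest_llt, table = tab)
  want <- apply(colors, 1, nearest_llt_scan, table = tab)
  expect_identical(got, want)
})

test_that("uniform-color frames map to a uniform thickness", {
  tab <- default_table()
  k <- which(tab$llt_nm == 75)
  img <- array(0L, c(20, 20, 3))
  img[, , 1] <- tab$R[k]; img[, , 2] <- tab$G[k]; img[, , 3] <- tab$B[k]
  geom <- ring_geometry(c(10, 10), 2, 8)
  roi <- make_pre_roi(img, geom)
  m <- estimate_llt_map(img, roi, tab)
  expect_true(all(m$values[roi$mask] == 75))
  expect_true(all(is.na(m$values[!roi$mask])))
})

test_that("noiseless phantom bright pixels round-trip exactly", {
  tab <- default_table()
  ph <- uniform_phantom(60)
  pre <- make_pre_roi(ph$image, ph$geometry)
  post <- make_post_roi(ph$image, pre)
  m <- estimate_llt_map(ph$image, post, tab)
  expect_true(all(m$values[post$mask] == 60))
})

test_that("empty or incongruent masks error", {
  tab <- default_table()
  img <- array(100L, c(10, 10, 3))
  empty <- structure(list(mask = matrix(FALSE, 10, 10), stage = "pre",
                          pixel_count = 0), class = "roi_mask")
  expect_error(estimate_llt_map(img, empty, tab), "empty")
  wrong <- structure(list(mask = matrix(TRUE, 5, 5), stage = "pre",
                          pixel_count = 25), class = "roi_mask")
  expect_error(estimate_llt_map(img, wrong, tab), "congruent")
})

test_that("ROI averaging is the arithmetic mean over masked pixels", {
  mk_map <- function(vals) {
    mask <- matrix(TRUE, 2, 2)
    structure(list(values = matrix(vals, 2, 2),
                   mask = structure(list(mask = mask, stage = "post",
                                         pixel_count = 4),
                                    class = "roi_mask"),
                   t_s = 0.5), class = "llt_map")
  }
  expect_equal(average_llt(mk_map(c(40, 50, 60, 70)))$mean_llt_nm, 55)
  expect_equal(average_llt(mk_map(rep(62, 4)))$mean_llt_nm, 62)
  set.seed(3)
  for (i in 1:50) {
    v <- runif(4, 10, 200)
    s <- 0
    for (x in v) s <- s + x       # independent accumulation
    expect_equal(average_llt(mk_map(v))$mean_llt_nm, s / 4,
                 tolerance = 1e-12)
  }
})

test_that("mean LLT is bounded by the table thickness range", {
  tab <- default_table()
  set.seed(4)
  img <- array(sample(0:255, 40 * 40 * 3, TRUE), c(40, 40, 3))
  roi <- make_pre_roi(img, ring_geometry(c(20, 20), 4, 18))
  s <- average_llt(estimate_llt_map(img, roi, tab))
  expect_gte(s$mean_llt_nm, min(tab$llt_nm))
  expect_lte(s$mean_llt_nm, max(tab$llt_nm))
})

test_that("a 41-frame cycle yields 41 summaries, identical when static", {
  tab <- default_table()
  cyc <- static_cycle(60, n = 41)
  ss <- llt_timeseries(cyc, table = tab, stage = "post")
  expect_length(ss, 41)
  means <- vapply(ss, `[[`, numeric(1), "mean_llt_nm")
  expect_true(all(means == means[1]))
  expect_equal(means[1], 60)
  times <- vapply(ss, `[[`, numeric(1), "t_s")
  expect_equal(times, seq(0, 2, by = 0.05))
})

test_that("post-stage pixel counts never exceed pre-stage counts", {
  tab <- default_table()
  cyc <- static_cycle(80, n = 3)
  tp <- c(0, 0.05, 0.1)
  pre <- llt_timeseries(cyc, table = tab, stage = "pre", timepoints_s = tp)
  post <- llt_timeseries(cyc, table = tab, stage = "post",
                         timepoints_s = tp)
  expect_true(all(vapply(post, `[[`, numeric(1), "pixel_count") <=
                  vapply(pre, `[[`, numeric(1), "pixel_count")))
})

test_that("noisy phantoms recover ground truth within 5 nm", {
  tab <- default_table()
  for (d in c(40, 90)) {
    ph <- uniform_phantom(d, noise_sd = 5, seed = 100 + d)
    pre <- make_pre_roi(ph$image, ph$geometry)
    post <- make_post_roi(ph$image, pre)
    s <- average_llt(estimate_llt_map(ph$image, post, tab))
    expect_lt(abs(s$mean_llt_nm - d), 5)
  }
})

test_that("pre- and post-segmentation means correlate across varied phantoms", {
  tab <- default_table()
  llts <- seq(25, 130, length.out = 12)
  pre_m <- post_m <- numeric(length(llts))
  for (i in seq_along(llts)) {
    ph <- uniform_phantom(llts[i], noise_sd = 3, seed = 500 + i)
    pre <- make_pre_roi(ph$image, ph$geometry)
    post <- make_post_roi(ph$image, pre)
    pre_m[i] <- average_llt(estimate_llt_map(ph$image, pre, tab))$mean_llt_nm
    post_m[i] <- average_llt(estimate_llt_map(ph$image, post, tab))$mean_llt_nm
  }
  expect_gt(pearson_r(pre_m, post_m)$r, 0.9)
})
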