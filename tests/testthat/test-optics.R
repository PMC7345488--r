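test_that("zero-thickness film reduces to the bare air/aqueous interface", {
  cfg <- optics_config()
  bare <- ((cfg$n_air - cfg$n_aqueous) / (cfg$n_air + cfg$n_aqueous))^2
  for (lam in c(400, 550, 700))
    expect_equal(thin_film_reflectance(0, lam, cfg), bare,
                 tolerance = 1e-12)
})

test_that("Airy reflectance matches a transfer-matrix oracle on a 20x20 grid", {
  cfg <- optics_config()
  d <- seq(0, 300, length.out = 20)
  lam <- seq(400, 760, length.out = 20)
  g <- expand.grid(d = d, lam = lam)
  got <- thin_film_reflectance(g$d, g$lam, cfg)
  want <- mapply(tm_reflectance, g$d, g$lam)
  expect_lt(max(abs(got - want)), 1e-10)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("oblique incidence still matches the transfer matrix", {
  cfg <- optics_config(incidence_angle_deg = 25)
  d <- seq(10, 250, length.out = 8)
  got <- thin_film_reflectance(d, 550, cfg)
  want <- vapply(d, tm_reflectance, numeric(1), lambda_nm = 550,
                 theta1 = 25 * pi / 180)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("reflectance is periodic in optical thickness", {
  cfg <- optics_config()
  lam <- 550
  period <- lam / (2 * cfg$n_lipid)
  d <- c(20, 75, 130)
  expect_equal(thin_film_reflectance(d + period, lam, cfg),
               thin_film_reflectance(d, lam, cfg), tolerance = 1e-9)
})

test_that("large-thickness reflectance stays within the Airy extrema", {
  cfg <- optics_config()
  a <- abs((1 - 1.48) / (1 + 1.48))
  b <- abs((1.48 - 1.336) / (1.48 + 1.336))
  rmax <- ((a + b) / (1 + a * b))^2
  rmin <- ((a - b) / (1 - a * b))^2
  r <- thin_film_reflectance(seq(1000, 5000, by = 7), 550, cfg)
  expect_true(all(r <= rmax + 1e-12 & r >= rmin - 1e-12))
  # the oscillation actually attains both extrema
  expect_lt(abs(max(r) - rmax), 1e-4)
  expect_lt(abs(min(r) - rmin), 1e-4)
})

test_that("invalid reflectance inputs error", {
  cfg <- optics_config()
  expect_error(thin_film_reflectance(-5, 550, cfg), "non-negative")
  expect_error(thin_film_reflectance(50, 900, cfg), "band")
})

test_that("config invariants are enforced", {
  expect_error(optics_config(n_lipid = 0.9), ">= 1")
  expect_error(optics_config(wavelengths_nm = c(500, 400)), "increasing")
  expect_error(optics_config(wavelengths_nm = c(300, 500)), "380-780")
  expect_error(optics_config(thickness_grid_nm = c(50, 40)), "increasing")
})

test_that("look-up table covers the grid with plausible colors", {
  tab <- build_lookup_table(
    optics_config(thickness_grid_nm = seq(15, 160, by = 1)))
  expect_equal(nrow(tab), 146)
  expect_true(all(diff(tab$llt_nm) > 0))
  ch <- as.matrix(tab[c("R", "G", "B")])
  expect_true(all(ch >= 0 & ch <= 255))
})

test_that("zero-thickness entry is neutral (R = G = B within 1 count)", {
  tab <- build_lookup_table(optics_config(thickness_grid_nm = c(0, 50, 100)))
  e0 <- tab[tab$llt_nm == 0, ]
  expect_lte(max(e0$R, e0$G, e0$B) - min(e0$R, e0$G, e0$B), 1)
})

test_that("adjacent table entries are distinct and the color curve is connected", {
  tab5 <- build_lookup_table(
    optics_config(thickness_grid_nm = seq(15, 160, by = 5)))
  dd <- abs(diff(as.matrix(tab5[c("R", "G", "B")])))
  expect_true(all(rowSums(dd) >= 1))  # every 5-nm step changes a channel
  tab1 <- default_table()
  jump <- sqrt(rowSums(diff(as.matrix(tab1[c("R", "G", "B")]))^2))
  expect_true(all(jump <= 30))
})

test_that("table generation is deterministic (bit-identical CSV)", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  cfg <- optics_config(thickness_grid_nm = seq(20, 120, by = 2))
  write_lookup_table(build_lookup_table(cfg), f1)
  write_lookup_table(build_lookup_table(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate single-thickness grid errors", {
  cfg <- optics_config()
  cfg$thickness_grid_nm <- 60
  expect_error(build_lookup_table(cfg), "at least 2")
})

test_that("look-up CSV round-trips losslessly and rejects bad files", {
  tab <- default_table()
  f <- tempfile(fileext = ".csv")
  write_lookup_table(tab, f)
  back <- read_lookup_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE)

  bad1 <- tempfile(fileext = ".csv")
  writeLines(c("llt_nm,R,G,B", "50,10,10,10", "40,20,20,20"), bad1)
  expect_error(read_lookup_table(bad1), "increasing")

  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("llt_nm,R,G,B", "40,10,10,10", "50,300,20,20"), bad2)
  expect_error(read_lookup_table(bad2), "\\[0, 255\\]")

  expect_error(read_lookup_table(tempfile()), "not found")
})
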