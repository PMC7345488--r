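# Thin-film optics and colorimetry for the LLT <-> interference-color
# look-up table. The tear lipid layer is modeled as a single homogeneous
# film (index n_lipid) between air and the aqueous tear layer; its
# reflectance spectrum is integrated against an illuminant and the CIE 1931
# 2-degree observer to obtain one 8-bit sRGB reference color per thickness.

#' Optics and colorimetry configuration for look-up table generation
#'
#' Bundles the physical constants and sampling grids used by
#' [thin_film_reflectance()] and [build_lookup_table()]. Defaults model the
#' precorneal tear film: a lipid film (n = 1.48) over the aqueous layer
#' (n = 1.336) in air, viewed at normal incidence under a daylight-like
#' illuminant, encoded as gamma-corrected 8-bit sRGB with the illuminant
#' white-balanced to neutral gray.
#'
#' @param n_air,n_lipid,n_aqueous Refractive indices (dimensionless, >= 1).
#'   Dispersion is ignored: indices are wavelength-independent.
#' @param wavelengths_nm Strictly increasing wavelength grid in nm within
#'   the visible band 380--780 nm, used for spectral integration.
#' @param incidence_angle_deg Angle of incidence in air, degrees from the
#'   surface normal. Reflectance at oblique incidence is the unpolarized
#'   mean of the s- and p-polarized Airy reflectances.
#' @param illuminant Spectral power distribution: `"planck6504"` (Planckian
#'   radiator at 6504 K, the daylight correlated color temperature),
#'   `"equal_energy"`, or a function of wavelength (nm) returning relative
#'   power. White balancing makes the table nearly insensitive to this
#'   choice.
#' @param thickness_grid_nm Strictly increasing, non-negative thickness grid
#'   in nm for the look-up table. The default 10--200 nm at 1-nm steps
#'   brackets the physiological lipid layer range of roughly 15--160 nm.
#' @param exposure_gain Linear-RGB scale factor applied before gamma
#'   encoding. `NULL` (default) picks the gain that maps the analytic
#'   maximum of the Airy reflectance to linear value 0.95, so the table
#'   spans the 8-bit range without clipping; deterministic given the
#'   indices.
#'
#' @return An object of class `optics_config` (a validated list).
#' @export
#' @examples
#' cfg <- optics_config()
#' thin_film_reflectance(60, 550, cfg)
optics_config <- function(n_air = 1.0,
                          n_lipid = 1.48,
                          n_aqueous = 1.336,
                          wavelengths_nm = seq(380, 780, by = 5),
                          incidence_angle_deg = 0,
                          illuminant = "planck6504",
                          thickness_grid_nm = seq(10, 200, by = 1),
                          exposure_gain = NULL) {
  stopifnot(is.numeric(n_air), is.numeric(n_lipid), is.numeric(n_aqueous))
  if (n_air < 1 || n_lipid < 1 || n_aqueous < 1)
    stop("refractive indices must be >= 1", call. = FALSE)
  if (!(n_lipid > n_aqueous && n_aqueous > n_air))
    warning("defaults assume n_lipid > n_aqueous > n_air; ",
            "interference contrast may be degraded")
  if (length(wavelengths_nm) < 2 || any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (min(wavelengths_nm) < 380 || max(wavelengths_nm) > 780)
    stop("wavelength grid must lie within 380-780 nm", call. = FALSE)
  if (any(thickness_grid_nm < 0) || any(diff(thickness_grid_nm) <= 0))
    stop("thickness grid must be strictly increasing and non-negative",
         call. = FALSE)
  if (incidence_angle_deg < 0 || incidence_angle_deg >= 90)
    stop("incidence angle must be in [0, 90) degrees", call. = FALSE)
  spd <- resolve_illuminant(illuminant)
  structure(list(
    n_air = n_air, n_lipid = n_lipid, n_aqueous = n_aqueous,
    wavelengths_nm = as.numeric(wavelengths_nm),
    incidence_angle_deg = incidence_angle_deg,
    illuminant = illuminant, spd = spd,
    thickness_grid_nm = as.numeric(thickness_grid_nm),
    exposure_gain = exposure_gain
  ), class = "optics_config")
}

resolve_illuminant <- function(illuminant) {
  if (is.function(illuminant)) return(illuminant)
  switch(illuminant,
    planck6504 = function(lambda_nm) planck_spd(lambda_nm, 6504),
    equal_energy = function(lambda_nm) rep(1, length(lambda_nm)),
    stop("unknown illuminant: ", illuminant, call. = FALSE)
  )
}

# Planck's law, relative spectral radiance (arbitrary scale).
planck_spd <- function(lambda_nm, temp_k) {
  lam <- lambda_nm * 1e-9
  h <- 6.62607015e-34; c <- 299792458; kb <- 1.380649e-23
  spd <- 1 / (lam^5 * (exp(h * c / (lam * kb * temp_k)) - 1))
  spd / max(spd)
}

#' Reflectance of a thin lipid film on the aqueous layer
#'
#' Intensity reflectance of the two-interface (air/lipid/aqueous) system
#' from the Airy summation of multiple reflections:
#' \deqn{r = \frac{r_{12} + r_{23} e^{-2i\beta}}{1 + r_{12} r_{23} e^{-2i\beta}},
#'       \qquad \beta = \frac{2\pi n_{lipid} d \cos\theta_{film}}{\lambda},}
#' with Fresnel amplitude coefficients \eqn{r_{12}} (air/lipid) and
#' \eqn{r_{23}} (lipid/aqueous). At oblique incidence the unpolarized
#' reflectance is the mean of \eqn{|r_s|^2} and \eqn{|r_p|^2}.
#'
#' @param thickness_nm Film thickness in nm (scalar or vector, >= 0).
#' @param wavelength_nm Vacuum wavelength in nm within the config's band.
#' @param config An [optics_config()].
#' @return Reflectance fraction(s) in \[0, 1\], vectorized over the longer
#'   of the two inputs (recycled like arithmetic).
#' @export
thin_film_reflectance <- function(thickness_nm, wavelength_nm,
                                  config = optics_config()) {
  stopifnot(inherits(config, "optics_config"))
  if (any(thickness_nm < 0))
    stop("thickness must be non-negative", call. = FALSE)
  band <- range(config$wavelengths_nm)
  if (any(wavelength_nm < band[1] | wavelength_nm > band[2]))
    stop("wavelength outside the configured band [", band[1], ", ",
         band[2], "] nm", call. = FALSE)
  n1 <- config$n_air; n2 <- config$n_lipid; n3 <- config$n_aqueous
  th1 <- config$incidence_angle_deg * pi / 180
  # Snell's law into the film and substrate
  s1 <- sin(th1)
  th2 <- asin(n1 * s1 / n2)
  th3 <- asin(n1 * s1 / n3)
  beta <- 2 * pi * n2 * thickness_nm * cos(th2) / wavelength_nm
  ph <- exp(-2i * beta)
  refl_pol <- function(r12, r23) {
    r <- (r12 + r23 * ph) / (1 + r12 * r23 * ph)
    Mod(r)^2
  }
  # s polarization: r = (n_i cos(th_i) - n_t cos(th_t)) / (sum)
  rs12 <- fresnel_rs(n1, th1, n2, th2)
  rs23 <- fresnel_rs(n2, th2, n3, th3)
  # p polarization
  rp12 <- fresnel_rp(n1, th1, n2, th2)
  rp23 <- fresnel_rp(n2, th2, n3, th3)
  (refl_pol(rs12, rs23) + refl_pol(rp12, rp23)) / 2
}

fresnel_rs <- function(ni, thi, nt, tht) {
  (ni * cos(thi) - nt * cos(tht)) / (ni * cos(thi) + nt * cos(tht))
}

fresnel_rp <- function(ni, thi, nt, tht) {
  (nt * cos(thi) - ni * cos(tht)) / (nt * cos(thi) + ni * cos(tht))
}

# CIE 1931 2-degree color-matching functions via the multi-lobe
# piecewise-Gaussian analytic fit (accurate to within ~1% of the tabulated
# observer, ample for 8-bit quantization).
piecewise_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

cie_xyz_cmf <- function(lambda_nm) {
  x <- 1.056 * piecewise_gauss(lambda_nm, 599.8, 37.9, 31.0) +
       0.362 * piecewise_gauss(lambda_nm, 442.0, 16.0, 26.7) -
       0.065 * piecewise_gauss(lambda_nm, 501.1, 20.4, 26.2)
  y <- 0.821 * piecewise_gauss(lambda_nm, 568.8, 46.9, 40.5) +
       0.286 * piecewise_gauss(lambda_nm, 530.9, 16.3, 31.1)
  z <- 1.217 * piecewise_gauss(lambda_nm, 437.0, 11.8, 36.0) +
       0.681 * piecewise_gauss(lambda_nm, 459.0, 26.0, 13.8)
  cbind(x = x, y = y, z = z)
}

# XYZ (D65-referenced) -> linear sRGB
xyz_to_linear_srgb <- matrix(c(
   3.2406, -1.5372, -0.4986,
  -0.9689,  1.8758,  0.0415,
   0.0557, -0.2040,  1.0570
), nrow = 3, byrow = TRUE)

srgb_encode <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

# Analytic maximum of the Airy reflectance at normal incidence; used to set
# the default exposure gain deterministically from the indices alone.
airy_max_reflectance <- function(config) {
  a <- abs((config$n_air - config$n_lipid) / (config$n_air + config$n_lipid))
  b <- abs((config$n_lipid - config$n_aqueous) /
           (config$n_lipid + config$n_aqueous))
  ((a + b) / (1 + a * b))^2
}

# Spectra (rows = thickness, cols = wavelength) -> n x 3 matrix of 8-bit RGB.
# White balance: a spectrally flat reflector maps to equal channels.
spectra_to_rgb8 <- function(refl, config) {
  lam <- config$wavelengths_nm
  cmf <- cie_xyz_cmf(lam)
  spd <- config$spd(lam)
  w <- spd * diff(range(lam)) / (length(lam) - 1)  # uniform quadrature
  xyz <- refl %*% (cmf * w)
  lin <- xyz %*% t(xyz_to_linear_srgb)
  # von Kries-style channel balance against the illuminant's own color
  white <- drop(rbind(colSums(cmf * w)) %*% t(xyz_to_linear_srgb))
  lin <- sweep(lin, 2, white, "/")
  gain <- config$exposure_gain
  if (is.null(gain)) gain <- 0.95 / airy_max_reflectance(config)
  rgb8 <- round(srgb_encode(lin * gain) * 255)
  storage.mode(rgb8) <- "integer"
  colnames(rgb8) <- c("R", "G", "B")
  rgb8
}

#' Build the LLT-to-RGB interference color look-up table
#'
#' For every thickness on the config grid, computes the film's reflectance
#' spectrum, integrates it against the illuminant and the CIE 1931
#' 2-degree color-matching functions, and encodes the result as
#' white-balanced 8-bit sRGB. The table is the reference curve used by
#' [nearest_llt()] to invert a pixel color to a thickness.
#'
#' @param config An [optics_config()]; its `thickness_grid_nm` must contain
#'   at least two values.
#' @return A `lookup_table`: data frame with columns `llt_nm`, `R`, `G`,
#'   `B` (thickness ascending) and a `provenance` attribute.
#' @export
#' @examples
#' tab <- build_lookup_table(optics_config(thickness_grid_nm = seq(20, 160, 10)))
#' head(tab)
build_lookup_table <- function(config = optics_config()) {
  stopifnot(inherits(config, "optics_config"))
  d <- config$thickness_grid_nm
  if (length(d) < 2)
    stop("thickness grid must contain at least 2 values", call. = FALSE)
  lam <- config$wavelengths_nm
  refl <- outer(d, lam, function(dd, ll)
    thin_film_reflectance(dd, ll, config))
  rgb8 <- spectra_to_rgb8(refl, config)
  new_lookup_table(data.frame(llt_nm = d, rgb8),
                   provenance = "generated-from-optics")
}

new_lookup_table <- function(df, provenance) {
  rownames(df) <- NULL
  validate_lookup_table(df)
  structure(df, provenance = provenance,
            class = c("lookup_table", "data.frame"))
}

validate_lookup_table <- function(df) {
  need <- c("llt_nm", "R", "G", "B")
  if (!all(need %in% names(df)))
    stop("look-up table needs columns llt_nm,R,G,B", call. = FALSE)
  if (nrow(df) < 2)
    stop("look-up table needs at least 2 entries", call. = FALSE)
  if (any(df$llt_nm < 0))
    stop("look-up table thickness must be non-negative", call. = FALSE)
  if (any(diff(df$llt_nm) <= 0))
    stop("look-up table thickness must be strictly increasing",
         call. = FALSE)
  ch <- as.matrix(df[c("R", "G", "B")])
  if (any(ch < 0 | ch > 255) || any(ch != round(ch)))
    stop("look-up table channels must be integers in [0, 255]",
         call. = FALSE)
  invisible(df)
}

#' Read or write a look-up table CSV
#'
#' The serialized form is a plain CSV with header `llt_nm,R,G,B`, one row
#' per reference point, thickness ascending. `read_lookup_table()`
#' validates monotone thickness and 8-bit channel ranges, so a calibrated
#' table measured on a particular instrument can be substituted for the
#' generated one.
#'
#' @param table A `lookup_table` from [build_lookup_table()] or
#'   `read_lookup_table()`.
#' @param path CSV file path.
#' @return `read_lookup_table()` returns a `lookup_table`;
#'   `write_lookup_table()` returns `path` invisibly.
#' @export
write_lookup_table <- function(table, path) {
  validate_lookup_table(table)
  df <- as.data.frame(table)[c("llt_nm", "R", "G", "B")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  if (!file.exists(path))
    stop("look-up table file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("malformed look-up table CSV: ",
                             conditionMessage(e), call. = FALSE))
  new_lookup_table(df, provenance = paste0("loaded-from-file:", path))
}
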