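#' Substrate concentration field
#'
#' A two-dimensional gold-concentration field c(x, y), the model of a
#' nanoporous gold (NPG) surface (or of the flat-gold control). Values are
#' dimensionless gold fractions in \[0, 1\]; `pixel_size` carries the
#' physical scale in nm per pixel.
#'
#' @param concentration numeric matrix of gold fractions.
#' @param pixel_size nm per pixel (> 0).
#' @param nominal_pore_nm declared pore-size label in nm, or `NA` (flat gold).
#' @param kind `"npg"` or `"flat"`.
#' @return An object of class `substrate_field`.
#' @export
substrate_field <- function(concentration, pixel_size = 1,
                            nominal_pore_nm = NA_real_,
                            kind = c("npg", "flat")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(concentration), pixel_size > 0)
  structure(
    list(concentration = concentration, pixel_size = pixel_size,
         nominal_pore_nm = nominal_pore_nm, kind = kind),
    class = "substrate_field"
  )
}

#' @export
print.substrate_field <- function(x, ...) {
  d <- dim(x$concentration)
  cat(sprintf("<substrate_field> %s, %d x %d px, %.4g nm/px", x$kind,
              d[1], d[2], x$pixel_size))
  if (!is.na(x$nominal_pore_nm)) {
    cat(sprintf(", nominal pore %.4g nm", x$nominal_pore_nm))
  }
  cat(sprintf("\n  gold fraction: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$concentration), min(x$concentration),
              max(x$concentration)))
  invisible(x)
}

#' Parameters of the Cahn-Hilliard substrate generator
#'
#' Dimensionless coefficients of the conserved phase-separation dynamics
#' used to grow bicontinuous NPG-like morphologies. The free energy is the
#' symmetric double well f(c) = c^2 (1 - c)^2 plus a square-gradient penalty
#' kappa/2 |grad c|^2; the physical scale is attached afterwards by
#' calibrating the measured characteristic length to the requested pore size,
#' so these coefficients only control morphology, resolution and run length.
#'
#' @param mean_composition mean gold fraction in (0, 1). The default 0.5
#'   yields a bicontinuous two-phase structure in which ligament and pore
#'   widths are comparable, matching the observed near-1:1 pore-ligament
#'   relation of dealloyed gold.
#' @param mobility positive mobility coefficient.
#' @param kappa positive interface (square-gradient) coefficient.
#' @param dt_ch time step of the semi-implicit spectral update.
#' @param noise_amplitude amplitude of the uniform initial fluctuation about
#'   `mean_composition`.
#' @return An object of class `ch_params`.
#' @export
ch_params <- function(mean_composition = 0.5, mobility = 1, kappa = 1,
                      dt_ch = 0.5, noise_amplitude = 0.05) {
  stopifnot(mean_composition > 0, mean_composition < 1,
            mobility > 0, kappa > 0, dt_ch > 0, noise_amplitude >= 0)
  structure(
    list(mean_composition = mean_composition, mobility = mobility,
         kappa = kappa, dt_ch = dt_ch, noise_amplitude = noise_amplitude),
    class = "ch_params"
  )
}

# squared wavenumber array (radians/pixel) for an n x n periodic grid
ch_k2 <- function(n) {
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  k <- 2 * pi * freq
  outer(k^2, k^2, `+`)
}

# derivative of the double-well bulk free energy f(c) = c^2 (1-c)^2
dwell_prime <- function(c) 2 * c * (1 - c) * (1 - 2 * c)

#' Discrete Ginzburg-Landau free energy of a field
#'
#' Sum over pixels of the double-well density c^2(1-c)^2 plus the
#' square-gradient penalty (periodic forward differences). Used to audit
#' that the evolution dissipates free energy.
#'
#' @param field a [substrate_field()].
#' @param params a [ch_params()] object (supplies kappa).
#' @return Total free energy (dimensionless).
#' @export
ch_free_energy <- function(field, params = ch_params()) {
  c <- field$concentration
  dx <- c[, c(seq_len(ncol(c))[-1], 1)] - c
  dy <- c[c(seq_len(nrow(c))[-1], 1), ] - c
  sum(c^2 * (1 - c)^2) + params$kappa / 2 * sum(dx^2 + dy^2)
}

#' Evolve a concentration field by Cahn-Hilliard dynamics
#'
#' Semi-implicit Fourier-spectral integration of
#' dc/dt = M grad^2 (f'(c) - kappa grad^2 c) on a periodic square grid:
#' the stiff biharmonic term is treated implicitly, the nonlinearity
#' explicitly. The dynamics conserve the spatial mean of c and coarsen the
#' two-phase pattern.
#'
#' @param field a square [substrate_field()], side at least 64 px.
#' @param params a [ch_params()] object.
#' @param n_steps number of update steps (>= 0).
#' @return The evolved `substrate_field` (concentration not clipped; clip at
#'   output with [clip_field()] if a strict \[0, 1\] view is needed).
#' @export
evolve_cahn_hilliard <- function(field, params = ch_params(), n_steps) {
  c <- field$concentration
  if (nrow(c) != ncol(c)) {
    stop("substrate field must be square", call. = FALSE)
  }
  if (nrow(c) < 64) {
    stop("substrate field side must be at least 64 px", call. = FALSE)
  }
  n <- nrow(c)
  k2 <- ch_k2(n)
  denom <- 1 + params$dt_ch * params$mobility * params$kappa * k2^2
  c_hat <- stats::fft(c)
  for (step in seq_len(n_steps)) {
    mu_hat <- stats::fft(dwell_prime(Re(stats::fft(c_hat, inverse = TRUE)) / n^2))
    c_hat <- (c_hat - params$dt_ch * params$mobility * k2 * mu_hat) / denom
  }
  out <- Re(stats::fft(c_hat, inverse = TRUE)) / n^2
  if (any(abs(out - 0.5) > 10)) {
    stop(sprintf(paste0("Cahn-Hilliard integration diverged; reduce dt_ch",
                        " (currently %g)"), params$dt_ch), call. = FALSE)
  }
  substrate_field(out, pixel_size = field$pixel_size,
                  nominal_pore_nm = field$nominal_pore_nm, kind = field$kind)
}

#' Clip a field's concentration into \[0, 1\]
#'
#' @param field a [substrate_field()].
#' @return The field with values clamped to \[0, 1\].
#' @export
clip_field <- function(field) {
  field$concentration <- pmin(pmax(field$concentration, 0), 1)
  field
}

#' Characteristic morphological length of a two-phase field, nm
#'
#' The dominant length scale of the pattern, estimated from the radially
#' averaged structure factor S(k) of the mean-subtracted field: with
#' k1 = sum(|k| S) / sum(S) the first moment over all non-zero modes, the
#' full wavelength is 2 pi / k1 pixels and the reported pore-scale length is
#' half of it, converted to nm via `pixel_size`. A pure stripe pattern of
#' period 20 px therefore reports 10 px — the width of one phase band.
#'
#' @param field a [substrate_field()] with non-zero variance.
#' @return Length in nm.
#' @export
characteristic_length <- function(field) {
  c <- field$concentration
  if (stats::var(as.vector(c)) == 0) {
    stop("characteristic length is undefined for a structureless (uniform) field",
         call. = FALSE)
  }
  n <- nrow(c)
  s <- Mod(stats::fft(c - mean(c)))^2
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  kmag <- 2 * pi * sqrt(outer(freq^2, freq^2, `+`))
  nz <- kmag > 0
  k1 <- sum(kmag[nz] * s[nz]) / sum(s[nz])
  (2 * pi / k1) / 2 * field$pixel_size
}

#' Generate a nanoporous-gold substrate field with a calibrated pore size
#'
#' Grows a bicontinuous two-phase morphology from seeded random fluctuations
#' by Cahn-Hilliard coarsening, binarises it at 0.5, lightly smooths the
#' interface, and then fixes the physical pixel size so that the measured
#' [characteristic_length()] equals `target_length_nm` exactly. Larger pore
#' sizes are obtained from this parent by [rescale_field()].
#'
#' @param seed integer RNG seed; the field is bit-identical for a fixed seed.
#' @param target_length_nm desired pore-scale length in nm (default 20).
#' @param params a [ch_params()] object.
#' @param size_px side of the square grid in pixels (default 256).
#' @param min_feature_px coarsen until the pixel-measured characteristic
#'   length reaches this resolution floor (default 8 px), so each pore spans
#'   several lattice pixels before the physical scale is attached.
#' @param max_steps abort with a convergence error if the target resolution
#'   is not reached within this many steps.
#' @param check_every measure the length every this many steps.
#' @return A `substrate_field` with `nominal_pore_nm = target_length_nm`.
#' @export
generate_npg_field <- function(seed, target_length_nm = 20,
                               params = ch_params(), size_px = 256,
                               min_feature_px = 8, max_steps = 20000,
                               check_every = 250) {
  stopifnot(target_length_nm > 0, size_px >= 64)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  init <- params$mean_composition +
    params$noise_amplitude * (stats::runif(size_px^2) - 0.5)
  f <- substrate_field(matrix(init, size_px, size_px), pixel_size = 1)
  steps_done <- 0
  len_px <- 0
  while (steps_done < max_steps) {
    f <- evolve_cahn_hilliard(f, params, check_every)
    steps_done <- steps_done + check_every
    len_px <- characteristic_length(f)
    if (len_px >= min_feature_px) break
  }
  if (len_px < min_feature_px) {
    stop(sprintf(paste0("substrate did not coarsen to %g px within %d steps ",
                        "(achieved %.2f px)"),
                 min_feature_px, max_steps, len_px), call. = FALSE)
  }
  # binary solid/pore view, then a light linear smoothing of the interface
  bin <- matrix(as.numeric(f$concentration >= 0.5), size_px, size_px)
  sm <- smooth_periodic(bin, passes = 2)
  f$concentration <- pmin(pmax(sm, 0), 1)
  len_px <- characteristic_length(f)
  f$pixel_size <- target_length_nm / len_px
  f$nominal_pore_nm <- target_length_nm
  f
}

# 3x3 periodic mean filter, `passes` times
smooth_periodic <- function(m, passes = 1) {
  n <- nrow(m)
  up <- function(x) x[c(2:n, 1), ]
  dn <- function(x) x[c(n, 1:(n - 1)), ]
  lf <- function(x) x[, c(2:n, 1)]
  rt <- function(x) x[, c(n, 1:(n - 1))]
  for (i in seq_len(passes)) {
    m <- (m + up(m) + dn(m) + lf(m) + rt(m) +
            up(lf(m)) + up(rt(m)) + dn(lf(m)) + dn(rt(m))) / 9
  }
  m
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rescale a substrate field to a larger (or smaller) pore size
#'
#' Enlarging the calibrated parent morphology: pixel values are untouched,
#' only the physical pixel size (and with it the nominal pore size) is
#' multiplied, exactly as a magnified print of the same pattern.
#'
#' @param field a [substrate_field()].
#' @param factor positive scale factor (e.g. 7.5 turns a 20 nm field into a
#'   150 nm one).
#' @return The rescaled `substrate_field`.
#' @export
rescale_field <- function(field, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("`factor` must be a positive scalar", call. = FALSE)
  }
  field$pixel_size <- field$pixel_size * factor
  if (!is.na(field$nominal_pore_nm)) {
    field$nominal_pore_nm <- field$nominal_pore_nm * factor
  }
  field
}

#' Flat gold control substrate
#'
#' @param size_px side of the square field in pixels.
#' @param pixel_size nm per pixel.
#' @return A `substrate_field` of kind `"flat"` whose values are all exactly 1.
#' @export
make_flat_gold <- function(size_px, pixel_size = 1) {
  stopifnot(size_px >= 1)
  substrate_field(matrix(1, size_px, size_px), pixel_size = pixel_size,
                  nominal_pore_nm = NA_real_, kind = "flat")
}

#' Solid (gold) area fraction of a field
#'
#' @param field a [substrate_field()].
#' @param threshold binarisation threshold (default 0.5, the symmetric
#'   double-well midpoint).
#' @return Fraction of pixels at or above the threshold.
#' @export
solid_fraction <- function(field, threshold = 0.5) {
  mean(field$concentration >= threshold)
}

#' Write / read a substrate field as plain text
#'
#' The concentration matrix is stored as a headerless CSV of floats and the
#' metadata (pixel size, nominal pore size, kind) in a JSON sidecar
#' `<path>.json`.
#'
#' @param field a [substrate_field()].
#' @param path CSV file path.
#' @return `write_field`: the path, invisibly. `read_field`: the field.
#' @export
write_field <- function(field, path) {
  utils::write.table(field$concentration, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(pixel_size = field$pixel_size,
               nominal_pore_nm = field$nominal_pore_nm, kind = field$kind)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a field as an 8-bit grayscale PNG
#'
#' Concentration values are clipped to \[0, 1\] and scaled to 0-255. A
#' convenience view for eyeballing morphologies; the CSV + JSON form
#' ([write_field()]) is the lossless serialisation.
#'
#' @param field a [substrate_field()].
#' @param path PNG file path.
#' @return The path, invisibly.
#' @export
write_field_png <- function(field, path) {
  png::writePNG(pmin(pmax(field$concentration, 0), 1), path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  substrate_field(m, pixel_size = meta$pixel_size,
                  nominal_pore_nm = if (is.null(meta$nominal_pore_nm))
                    NA_real_ else meta$nominal_pore_nm,
                  kind = meta$kind)
}
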