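#' Binary image with a physical scale
#'
#' @param pixels logical matrix; `TRUE` is the foreground phase.
#' @param pixel_size nm per pixel (> 0).
#' @param phase_label what the foreground represents: `"pore"`, `"ligament"`
#'   or `"cell"`.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels, pixel_size = 1,
                         phase_label = c("pore", "ligament", "cell")) {
  phase_label <- match.arg(phase_label)
  stopifnot(is.matrix(pixels), is.logical(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 phase_label = phase_label),
            class = "binary_image")
}

#' Swap foreground and background
#'
#' Pore and ligament are dual phases of the same micrograph; inverting the
#' mask turns a pore measurement into a ligament measurement.
#'
#' @param img a [binary_image()].
#' @param phase_label new label for the (now inverted) foreground.
#' @return The inverted `binary_image`.
#' @export
invert_phase <- function(img, phase_label = NULL) {
  if (is.null(phase_label)) {
    phase_label <- switch(img$phase_label, pore = "ligament",
                          ligament = "pore", cell = "cell")
  }
  binary_image(!img$pixels, img$pixel_size, phase_label)
}

#' Granulometric feature sizing of a binary phase
#'
#' Local width of the foreground phase, measured as the largest
#' inscribed-disk diameter at each ridge of the Euclidean distance
#' transform: regional maxima of the distance map are located, adjacent
#' maxima (plateaus) are merged into one feature, and each feature's size is
#' twice its distance value, converted to nm. For an array of discs this
#' recovers the disc diameter; for stripes, the band width. Features whose
#' inscribed disk would cross the image border are excluded (the border is
#' not background, so their local width is untrustworthy — the usual
#' exclude-edge-particles convention). The procedure is deterministic.
#'
#' @param img a [binary_image()] containing both phases.
#' @return An object of class `morphometry_result` with fields `sizes`
#'   (per-feature nm), `mean_size`, `sem` (sd/sqrt(n)) and `n`.
#' @export
granulometry_size <- function(img) {
  px <- img$pixels
  if (all(px) || !any(px)) {
    stop("sizing requires both phases present in the image", call. = FALSE)
  }
  d <- EBImage::distmap(EBImage::Image(px * 1.0))
  d <- EBImage::imageData(d)
  # regional maxima of the distance map (8-neighbour plateau test)
  mx <- shift_max3x3(d)
  peaks <- (d >= mx) & (d > 0)
  # drop maxima whose inscribed disk would cross the image border
  bdist <- pmin(row(d), col(d), nrow(d) + 1 - row(d), ncol(d) + 1 - col(d))
  peaks <- peaks & (bdist > d)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(peaks * 1.0)))
  n_feat <- max(lab)
  if (n_feat == 0) stop("no measurable features found", call. = FALSE)
  radii <- vapply(seq_len(n_feat), function(k) max(d[lab == k]), numeric(1))
  sizes <- 2 * radii * img$pixel_size
  morphometry_result(sizes)
}

# 3x3 neighbourhood maximum with edge replication
shift_max3x3 <- function(d) {
  n <- nrow(d); m <- ncol(d)
  up <- function(x) x[c(1, 1:(n - 1)), , drop = FALSE]
  dn <- function(x) x[c(2:n, n), , drop = FALSE]
  lf <- function(x) x[, c(1, 1:(m - 1)), drop = FALSE]
  rt <- function(x) x[, c(2:m, m), drop = FALSE]
  pmax(up(d), dn(d), lf(d), rt(d),
       up(lf(d)), up(rt(d)), dn(lf(d)), dn(rt(d)))
}

#' Construct a morphometry result from per-feature sizes
#'
#' @param sizes numeric vector of per-feature sizes in nm.
#' @return An object of class `morphometry_result`.
#' @export
morphometry_result <- function(sizes) {
  n <- length(sizes)
  structure(
    list(sizes = sizes, mean_size = mean(sizes),
         sem = if (n > 1) stats::sd(sizes) / sqrt(n) else 0, n = n),
    class = "morphometry_result"
  )
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> %d features: %.2f +/- %.2f nm (mean +/- s.e.m.)\n",
              x$n, x$mean_size, x$sem))
  invisible(x)
}

#' Per-feature sizes of a morphometry result
#' @param x a `morphometry_result`.
#' @param ... unused.
#' @return Tibble with one row per feature.
#' @export
tidy.morphometry_result <- function(x, ...) {
  tibble::tibble(feature = seq_len(x$n), size_nm = x$sizes)
}

#' One-row summary of a morphometry result
#' @param x a `morphometry_result`.
#' @param ... unused.
#' @return Tibble of mean size, s.e.m. and feature count.
#' @export
glance.morphometry_result <- function(x, ...) {
  tibble::tibble(mean_size_nm = x$mean_size, sem_nm = x$sem, n = x$n)
}

#' Circularity of a cell outline
#'
#' The shape descriptor 4 pi A / L^2: exactly 1 for a circle, smaller for
#' any other shape, invariant under scaling. Operates on exact area and
#' perimeter supplied by the caller; for a pixel mask use
#' [mask_circularity()], which is approximate.
#'
#' @param area cell area, squared length units (> 0). Vectorised.
#' @param perimeter cell perimeter, length units (> 0).
#' @return Dimensionless circularity.
#' @examples
#' circularity(pi * 5^2, 2 * pi * 5) # 1
#' circularity(4, 8)                 # square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    stop("`area` and `perimeter` must be positive", call. = FALSE)
  }
  4 * pi * area / perimeter^2
}

#' Approximate circularity of a pixel mask
#'
#' Area is the foreground pixel count times the squared pixel size; the
#' perimeter is the count of foreground pixel edges facing background (or
#' the image border) times the pixel size. Edge counting overestimates the
#' perimeter of smooth shapes (up to ~4/pi for a disc), so this estimate is
#' biased low; it is provided for mask-level work, while [circularity()]
#' keeps the exact formula exact.
#'
#' @param img a [binary_image()] whose foreground is the cell.
#' @return A one-row tibble: area (nm^2), perimeter (nm), circularity.
#' @export
mask_circularity <- function(img) {
  px <- img$pixels
  if (!any(px)) stop("mask has no foreground pixels", call. = FALSE)
  n <- nrow(px); m <- ncol(px)
  padded <- matrix(FALSE, n + 2, m + 2)
  padded[2:(n + 1), 2:(m + 1)] <- px
  core <- padded[2:(n + 1), 2:(m + 1)]
  edges <- sum(core & !padded[1:n, 2:(m + 1)]) +
    sum(core & !padded[3:(n + 2), 2:(m + 1)]) +
    sum(core & !padded[2:(n + 1), 1:m]) +
    sum(core & !padded[2:(n + 1), 3:(m + 2)])
  area <- sum(px) * img$pixel_size^2
  perimeter <- edges * img$pixel_size
  tibble::tibble(area_nm2 = area, perimeter_nm = perimeter,
                 circularity = circularity(area, perimeter))
}

#' Ordinary least-squares fit of ligament size on pore size
#'
#' Dealloyed gold shows a tight linear relation between pore width and the
#' width of the gold ligaments separating pores; this fits ligament = a +
#' b * pore by OLS and reports the fit quality.
#'
#' @param pore_sizes_nm,ligament_sizes_nm equal-length numeric vectors,
#'   n >= 3, pore sizes not all equal.
#' @return An object of class `pore_ligament_fit` wrapping the `lm` fit.
#' @export
fit_pore_ligament <- function(pore_sizes_nm, ligament_sizes_nm) {
  if (length(pore_sizes_nm) != length(ligament_sizes_nm)) {
    stop("pore and ligament size vectors must have equal length", call. = FALSE)
  }
  if (length(pore_sizes_nm) < 3) {
    stop("at least 3 paired sizes are required for a fit", call. = FALSE)
  }
  if (stats::var(pore_sizes_nm) == 0) {
    stop("pore sizes have zero variance; slope is undefined", call. = FALSE)
  }
  df <- data.frame(pore = pore_sizes_nm, ligament = ligament_sizes_nm)
  fit <- stats::lm(ligament ~ pore, data = df)
  structure(list(fit = fit, data = tibble::as_tibble(df)),
            class = "pore_ligament_fit")
}

#' @export
print.pore_ligament_fit <- function(x, ...) {
  g <- glance.pore_ligament_fit(x)
  cat(sprintf("<pore_ligament_fit> ligament = %.4f + %.4f * pore, R^2 = %.4f, p = %.3g (n = %d)\n",
              g$intercept, g$slope, g$r_squared, g$p_value, g$n))
  invisible(x)
}

#' Coefficient table of a pore-ligament fit
#' @param x a `pore_ligament_fit`.
#' @param ... unused.
#' @return Tibble of term, estimate, std.error, statistic, p.value.
#' @export
tidy.pore_ligament_fit <- function(x, ...) {
  s <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a pore-ligament fit
#' @param x a `pore_ligament_fit`.
#' @param ... unused.
#' @return Tibble of slope, intercept, r_squared, p_value (of the slope), n.
#' @export
glance.pore_ligament_fit <- function(x, ...) {
  s <- summary(x$fit)
  cf <- stats::coef(s)
  tibble::tibble(slope = cf["pore", 1], intercept = cf["(Intercept)", 1],
                 r_squared = s$r.squared, p_value = cf["pore", 4],
                 n = length(x$fit$residuals))
}

#' Measured pore and ligament sizes of the five reference substrates
#'
#' Mean +/- s.e.m. (nm, N > 50 features each) of the pore and ligament
#' widths of five dealloyed-gold substrates with nominal pore sizes of 10,
#' 20, 30, 50 and 180 nm, as characterised by SEM image analysis. Used as
#' the reference input for [fit_pore_ligament()].
#'
#' @return A tibble with columns nominal_nm, pore_nm, pore_sem_nm,
#'   ligament_nm, ligament_sem_nm.
#' @export
npg_size_table <- function() {
  tibble::tibble(
    nominal_nm = c(10, 20, 30, 50, 180),
    pore_nm = c(7.649, 23.060, 29.175, 54.411, 186.641),
    pore_sem_nm = c(0.244, 0.343, 1.029, 1.195, 3.583),
    ligament_nm = c(19.472, 25.905, 45.667, 71.251, 210.937),
    ligament_sem_nm = c(0.436, 0.395, 1.533, 1.527, 5.170)
  )
}

#' Read / write binary masks as PNG
#'
#' Masks are stored as black-and-white PNGs (foreground white). Reading
#' thresholds at 0.5, so antialiased inputs degrade gracefully.
#'
#' @param img a [binary_image()].
#' @param path PNG file path.
#' @param pixel_size,phase_label metadata attached on reading (PNG carries
#'   no physical scale).
#' @return `write_mask_png`: the path, invisibly. `read_mask_png`: a
#'   `binary_image`.
#' @export
write_mask_png <- function(img, path) {
  png::writePNG(img$pixels * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, pixel_size = 1, phase_label = "pore") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  binary_image(m >= 0.5, pixel_size = pixel_size, phase_label = phase_label)
}

#' Synthetic binary pore patterns with known feature size
#'
#' Deterministic fixture generator for sizing tests: `discs` (a square array
#' of discs of diameter `feature_nm`), `stripes` (bands of width
#' `feature_nm`, period twice that), or `voronoi` (a random tessellation
#' ridge network of band width about `feature_nm`). Disc and stripe patterns
#' have analytically known feature sizes.
#'
#' @param pattern `"discs"`, `"stripes"` or `"voronoi"`.
#' @param feature_nm feature size in nm (>= 2 pixels).
#' @param pixel_size nm per pixel.
#' @param seed RNG seed (used by `voronoi`; others are deterministic anyway).
#' @param size_px image side in pixels.
#' @return A [binary_image()] whose foreground (`pore`) has the requested
#'   feature size.
#' @export
make_synthetic_pores <- function(pattern = c("discs", "stripes", "voronoi"),
                                 feature_nm, pixel_size = 1, seed = 1,
                                 size_px = 256) {
  pattern <- match.arg(pattern)
  if (feature_nm < 2 * pixel_size) {
    stop("`feature_nm` below 2 pixels cannot be resolved; reduce `pixel_size`",
         call. = FALSE)
  }
  f_px <- feature_nm / pixel_size
  px <- switch(pattern,
    discs = {
      r <- f_px / 2
      pitch <- max(ceiling(2.5 * f_px), 4)
      centers <- seq(ceiling(pitch / 2), size_px, by = pitch)
      xi <- matrix(seq_len(size_px), size_px, size_px)
      yi <- t(xi)
      m <- matrix(FALSE, size_px, size_px)
      for (cx in centers) for (cy in centers) {
        m <- m | ((xi - cx)^2 + (yi - cy)^2 <= r^2)
      }
      m
    },
    stripes = {
      w <- round(f_px)
      colpos <- (seq_len(size_px) - 1) %% (2 * w)
      matrix(rep(colpos < w, each = size_px), size_px, size_px)
    },
    voronoi = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      n_cent <- max(4, round((size_px / (3 * f_px))^2))
      cx <- stats::runif(n_cent, 1, size_px)
      cy <- stats::runif(n_cent, 1, size_px)
      xi <- matrix(seq_len(size_px), size_px, size_px)
      yi <- t(xi)
      d1 <- matrix(Inf, size_px, size_px)
      d2 <- matrix(Inf, size_px, size_px)
      for (k in seq_len(n_cent)) {
        dk <- sqrt((xi - cx[k])^2 + (yi - cy[k])^2)
        closer <- dk < d1
        d2 <- pmin(d2, ifelse(closer, d1, dk))
        d1 <- pmin(d1, dk)
      }
      (d2 - d1) < f_px # ridge band of roughly the requested width
    }
  )
  binary_image(px, pixel_size = pixel_size, phase_label = "pore")
}
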