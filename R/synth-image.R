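#' Parameters for the synthetic well-image generator
#'
#' Bundles the tunable parameters of the fluorescence-image simulator. The
#' simulator emulates the two cell-state phenotypes seen under F-actin
#' staining: activated stellate cells are large and flat with bright linear
#' stress fibers, while deactivated/quiescent-like cells are small and
#' dendritic with dim, diffuse signal. `deactivation_level` morphs
#' continuously between the two (0 = fully activated, 1 = fully
#' quiescent-like); the expected Actin score of a rendered well decreases
#' monotonically as it rises, which is the generator's design guarantee.
#'
#' @param cells_per_well Cells rendered in the imaged field. The default of
#'   60 is the package's scaling of a 5000 cells / 20 uL 384-well seeding to
#'   the small rendered field.
#' @param deactivation_level Fraction in \[0, 1\].
#' @param fiber_intensity Added fluorescence (arbitrary units) of a stress
#'   fiber at full activation.
#' @param fiber_count_per_cell Stress fibers per fully activated cell.
#' @param cell_radius_px Major semi-axis (pixels) of an activated cell body.
#' @param cell_intensity Above-background fluorescence of the cell body.
#' @param background_mean,background_sd Additive Gaussian background, in the
#'   same arbitrary units.
#' @param psf_sigma_px Gaussian point-spread blur applied before noise;
#'   0 disables blurring.
#' @param image_size Integer edge length (pixels) of the square field;
#'   at least 64.
#' @param bit_depth Quantization depth of the stored image (default 16-bit
#'   unsigned; values are clipped at the maximum and flagged as saturated).
#' @param seed Integer seed; rendering is a pure function of the parameters.
#'
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(deactivation_level = 1, seed = 7)
#' img <- render_well_image(p)
#' @export
sim_params <- function(cells_per_well = 60,
                       deactivation_level = 0,
                       fiber_intensity = 400,
                       fiber_count_per_cell = 12,
                       cell_radius_px = 14,
                       cell_intensity = 250,
                       background_mean = 100,
                       background_sd = 8,
                       psf_sigma_px = 1,
                       image_size = 192,
                       bit_depth = 16,
                       seed = 1) {
  p <- list(
    cells_per_well = cells_per_well,
    deactivation_level = deactivation_level,
    fiber_intensity = fiber_intensity,
    fiber_count_per_cell = fiber_count_per_cell,
    cell_radius_px = cell_radius_px,
    cell_intensity = cell_intensity,
    background_mean = background_mean,
    background_sd = background_sd,
    psf_sigma_px = psf_sigma_px,
    image_size = as.integer(image_size),
    bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$deactivation_level < 0 || p$deactivation_level > 1) {
    abort("deactivation_level must lie in [0, 1]")
  }
  if (p$cells_per_well < 0 || p$fiber_count_per_cell < 0) {
    abort("counts must be non-negative")
  }
  if (p$background_sd < 0) abort("background_sd must be non-negative")
  if (p$image_size < 64) abort("image_size must be at least 64 pixels")
  if (2 * p$cell_radius_px >= p$image_size) {
    abort("degenerate geometry: cell diameter exceeds the image")
  }
  invisible(p)
}

#' Render a synthetic fluorescence well image
#'
#' Draws `cells_per_well` cells on a dark canvas, blurs with a Gaussian
#' point-spread function, adds Gaussian background, and quantizes to the
#' requested bit depth. Each cell is an elliptical footprint at
#' `cell_intensity` whose size shrinks with deactivation; stress fibers are
#' anti-aliased chords across the footprint whose number and brightness
#' scale with `(1 - deactivation_level)`, and thin dendritic branches at
#' body intensity grow in as deactivation rises. Fibers are therefore the
#' only driver of the intensity-per-area contrast between the phenotypes.
#'
#' @param params A [sim_params()] object (its `seed` fixes the render).
#' @param plate_id,well Optional metadata carried on the image.
#'
#' @return A `well_image` object: list with `pixels` (integer matrix),
#'   `truth_mask` (logical matrix of painted-cell pixels, before blur and
#'   noise — ground truth for segmentation tests), `saturated` flag, and
#'   the metadata fields.
#' @export
render_well_image <- function(params, plate_id = NA_character_, well = NA_character_) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  n <- params$image_size
  d <- params$deactivation_level

  canvas <- matrix(0, n, n)
  withr::with_seed(params$seed, {
    if (params$cells_per_well > 0) {
      for (i in seq_len(params$cells_per_well)) {
        canvas <- draw_cell(canvas, params)
      }
    }
    truth <- canvas > 0
    if (params$psf_sigma_px > 0) {
      canvas <- EBImage::gblur(canvas, sigma = params$psf_sigma_px)
    }
    canvas <- canvas + params$background_mean +
      rnorm(n * n, sd = params$background_sd)
  })

  maxval <- 2^params$bit_depth - 1
  quantized <- round(pmin(pmax(canvas, 0), maxval))
  structure(
    list(
      pixels = quantized,
      truth_mask = truth,
      saturated = any(canvas > maxval),
      plate_id = plate_id,
      well = well,
      pixel_size = 1
    ),
    class = "well_image"
  )
}

# Draw one cell (body + fibers or dendrites) onto the canvas; assumes the
# caller controls the RNG state.
draw_cell <- function(canvas, params) {
  n <- nrow(canvas)
  d <- params$deactivation_level
  r <- params$cell_radius_px
  cx <- runif(1, r + 1, n - r)
  cy <- runif(1, r + 1, n - r)
  theta <- runif(1, 0, pi)

  # body: ellipse shrinking with deactivation (flat activated cell -> small soma)
  a <- r * (1 - 0.55 * d)
  b <- 0.7 * a
  canvas <- fill_ellipse(canvas, cx, cy, a, b, theta, params$cell_intensity)

  # stress fibers: chords across the body, fading with deactivation
  n_fib <- round(params$fiber_count_per_cell * (1 - d))
  fib_int <- params$fiber_intensity * (1 - d)
  if (n_fib > 0 && fib_int > 0) {
    for (k in seq_len(n_fib)) {
      off <- runif(1, -0.8, 0.8) * b
      ang <- theta + runif(1, -0.25, 0.25)
      half <- a * sqrt(max(0, 1 - (off / b)^2))
      x0 <- cx - half * cos(ang) - off * sin(ang)
      y0 <- cy - half * sin(ang) + off * cos(ang)
      x1 <- cx + half * cos(ang) - off * sin(ang)
      y1 <- cy + half * sin(ang) + off * cos(ang)
      canvas <- draw_segment(canvas, x0, y0, x1, y1, fib_int)
    }
  }

  # dendritic branches: thin processes at body intensity, growing with d
  n_br <- round(5 * d)
  if (n_br > 0) {
    for (k in seq_len(n_br)) {
      ang <- runif(1, 0, 2 * pi)
      len <- r * runif(1, 0.8, 1.6)
      canvas <- draw_segment(
        canvas, cx, cy,
        min(max(cx + len * cos(ang), 1), n), min(max(cy + len * sin(ang), 1), n),
        params$cell_intensity
      )
    }
  }
  canvas
}

fill_ellipse <- function(canvas, cx, cy, a, b, theta, value) {
  n <- nrow(canvas)
  ext <- ceiling(max(a, b))
  xs <- max(1, floor(cx - ext)):min(n, ceiling(cx + ext))
  ys <- max(1, floor(cy - ext)):min(n, ceiling(cy + ext))
  ct <- cos(theta); st <- sin(theta)
  for (x in xs) {
    dx <- x - cx
    u <- dx * ct
    v <- -dx * st
    dy <- ys - cy
    uu <- u + dy * st
    vv <- v + dy * ct
    inside <- (uu / a)^2 + (vv / b)^2 <= 1
    sel <- ys[inside]
    canvas[x, sel] <- pmax(canvas[x, sel], value)
  }
  canvas
}

# Rasterize a one-pixel-wide segment by dense sampling; intensities add so
# fiber crossings are brighter, as in real stress-fiber images.
draw_segment <- function(canvas, x0, y0, x1, y1, value) {
  n <- nrow(canvas)
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  steps <- max(2L, ceiling(2 * len))
  t <- seq(0, 1, length.out = steps)
  xs <- round(x0 + t * (x1 - x0))
  ys <- round(y0 + t * (y1 - y0))
  keep <- xs >= 1 & xs <= n & ys >= 1 & ys <= n
  idx <- unique(cbind(xs[keep], ys[keep]))
  canvas[idx] <- canvas[idx] + value
  canvas
}

#' @method print well_image
#' @export
print.well_image <- function(x, ...) {
  cat(sprintf(
    "<well_image> %d x %d px, range [%d, %d]%s\n",
    nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
    if (isTRUE(x$saturated)) ", saturated" else ""
  ))
  invisible(x)
}
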