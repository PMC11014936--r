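#' Segment the actin-positive area of a well image
#'
#' Produces the binary mask of stain-positive pixels that defines the
#' denominator of the Actin score. The default policy subtracts the image
#' median (a robust background estimate for sparsely seeded wells) and
#' then applies Otsu's threshold to the log-compressed residual — the log
#' keeps the long right tail of bright fiber pixels from pulling the split
#' inside the cells; passing a number instead
#' selects a fixed absolute threshold on the raw intensities. An image
#' with no intensity contrast cannot be thresholded: the mask is empty and
#' carries an `EMPTY_WELL` flag instead of an arbitrary cut.
#'
#' @param image A `well_image` (from [render_well_image()] or
#'   [read_well_image()]) or a bare numeric matrix of intensities.
#' @param method `"otsu"` (default) or a single number giving a fixed
#'   absolute threshold (pixels strictly above it are positive).
#'
#' @return A logical matrix the shape of the image, with attributes
#'   `threshold` (on the raw intensity scale) and `flags` (character,
#'   possibly containing `"EMPTY_WELL"`).
#' @export
segment_actin_area <- function(image, method = "otsu") {
  px <- image_pixels(image)
  if (any(!is.finite(px)) || any(px < 0)) {
    abort("image intensities must be finite and non-negative")
  }
  if (is.numeric(method) && length(method) == 1) {
    mask <- px > method
    return(structure(mask, threshold = as.numeric(method), flags = character()))
  }
  if (!identical(method, "otsu")) abort("method must be \"otsu\" or a number")

  bg <- median(px)
  resid <- px - bg
  rng <- range(resid)
  if (diff(rng) <= 0) {
    return(structure(
      matrix(FALSE, nrow(px), ncol(px)),
      threshold = NA_real_, flags = "EMPTY_WELL"
    ))
  }
  # log-compress the residual before Otsu: bright stress-fiber pixels form a
  # long right tail that would otherwise dominate the between-class variance
  # and pull the split inside the cells instead of between cells and
  # background
  lg <- log1p(resid - rng[1])
  lmax <- max(lg)
  th <- EBImage::otsu(lg / lmax, range = c(0, 1), levels = 1024L)
  th_raw <- expm1(th * lmax) + rng[1]
  mask <- lg / lmax > th
  # contrast guard: on a cell-free well Otsu still bisects the background
  # noise; require the threshold to clear the sub-threshold pixels by 3
  # robust SDs of their own spread
  bgres <- resid[!mask]
  if (length(bgres) == 0 ||
      th_raw - median(bgres) < 3 * stats::mad(bgres)) {
    return(structure(
      matrix(FALSE, nrow(px), ncol(px)),
      threshold = NA_real_, flags = "EMPTY_WELL"
    ))
  }
  structure(mask,
            threshold = th_raw + bg,
            flags = character())
}

#' Measure a well through a segmentation mask
#'
#' Computes the well-level quantities behind the Actin score: total stain
#' intensity over the positive pixels, the positive area in pixels, and
#' their ratio — intensity per unit stained area — which is the *Actin
#' score*. The score is intensive: duplicating the same cell pattern
#' within a well changes neither it nor its interpretation. A well with no
#' positive area has an undefined score and is flagged `EMPTY_WELL` so it
#' can be excluded from plate statistics rather than silently contributing
#' a division by zero.
#'
#' @param image A `well_image` or numeric matrix.
#' @param mask Logical matrix from [segment_actin_area()] (same shape).
#' @param low_area_frac Flag `LOW_AREA` when the positive area is below
#'   this fraction of the image (ratio instability guard); default 0.5%.
#'
#' @return One-row tibble: `total_intensity`, `total_intensity_bgsub`
#'   (background taken as the median of the non-positive pixels),
#'   `positive_area`, `actin_score` (`NA` when the area is zero),
#'   `qc_flags` (semicolon-separated, `""` when clean).
#' @examples
#' img <- matrix(c(rep(0, 50), rep(1000, 50)), 10, 10)
#' m <- segment_actin_area(img)
#' measure_well(img, m)
#' @export
measure_well <- function(image, mask, low_area_frac = 0.005) {
  px <- image_pixels(image)
  if (!identical(dim(px), dim(mask))) {
    abort("mask shape does not match the image")
  }
  flags <- attr(mask, "flags") %||% character()
  area <- sum(mask)
  total <- sum(px[mask])
  bg <- if (area < length(px)) median(px[!mask]) else 0
  if (area == 0) {
    flags <- union(flags, "EMPTY_WELL")
    score <- NA_real_
  } else {
    score <- total / area
    if (area < low_area_frac * length(px)) flags <- union(flags, "LOW_AREA")
  }
  if (isTRUE(image_saturated(image))) flags <- union(flags, "SATURATED")
  tibble(
    total_intensity = total,
    total_intensity_bgsub = max(total - bg * area, 0),
    positive_area = area,
    actin_score = score,
    qc_flags = paste(sort(flags), collapse = ";")
  )
}

#' Quantify every well of a plate
#'
#' Maps images onto a plate layout, segments and measures each well, and
#' returns the per-plate measurement table used by QC and hit calling. The
#' result is deterministic and independent of the order images are given
#' in; a layout well with no image, or with several, is an error naming
#' the offending addresses.
#'
#' @param images A list of `well_image` objects (well taken from each
#'   image's metadata) or a named list of matrices (names are well
#'   addresses).
#' @param layout A `plate_layout` tibble ([generate_plate_layout()]).
#' @param method Threshold policy passed to [segment_actin_area()].
#'
#' @return A tibble with one row per layout well: the layout columns plus
#'   the [measure_well()] quantities.
#' @export
quantify_plate <- function(images, layout, method = "otsu") {
  wells <- names(images)
  if (is.null(wells)) {
    wells <- purrr::map_chr(images, function(im) {
      if (inherits(im, "well_image") && !is.na(im$well)) im$well else NA_character_
    })
  }
  if (anyNA(wells)) abort("every image needs a well address (name or metadata)")
  dup <- unique(wells[duplicated(wells)])
  if (length(dup) > 0) {
    abort(paste0("duplicate image(s) for well(s): ", paste(dup, collapse = ", ")))
  }
  missing <- setdiff(layout$well, wells)
  if (length(missing) > 0) {
    abort(paste0("no image for layout well(s): ", paste(missing, collapse = ", ")))
  }
  names(images) <- wells

  meas <- purrr::map(layout$well, function(w) {
    img <- images[[w]]
    measure_well(img, segment_actin_area(img, method = method))
  }) %>% bind_rows()
  dplyr::bind_cols(
    layout %>% select("plate_id", "well", "kind", "compound_id", "dose_nM"),
    meas
  )
}

image_pixels <- function(image) {
  if (inherits(image, "well_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else abort("expected a well_image or numeric matrix")
}

image_saturated <- function(image) {
  inherits(image, "well_image") && isTRUE(image$saturated)
}

has_flag <- function(qc_flags, flag) {
  vapply(strsplit(qc_flags %+na% "", ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}
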