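#' Read and write the pipeline's tabular interchange formats
#'
#' Thin wrappers fixing the column contracts of the files the pipeline
#' exchanges: plate layouts (CSV: plate_id, well, kind, compound_id,
#' dose_nM), per-plate measurements (TSV, layout columns plus
#' total_intensity, positive_area, actin_score, qc_flags), Ct tables
#' (CSV: condition, gene, replicate, ct) and count matrices (TSV: gene,
#' length_bp, one column per sample).
#'
#' @param path File path.
#' @param x Object to write.
#' @name actinscreen-io
NULL

#' @rdname actinscreen-io
#' @export
read_plate_layout <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         plate_id = "c", well = "c", kind = "c",
                         compound_id = "c", dose_nM = "d"
                       ))
  x %>% mutate(row = substr(.data$well, 1, 1),
               col = as.integer(substr(.data$well, 2, 3))) %>%
    select("plate_id", "well", "row", "col", "kind", "compound_id", "dose_nM")
}

#' @rdname actinscreen-io
#' @export
write_plate_layout <- function(x, path) {
  readr::write_csv(
    x %>% select("plate_id", "well", "kind", "compound_id", "dose_nM"), path
  )
  invisible(path)
}

#' @rdname actinscreen-io
#' @export
read_measurements <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname actinscreen-io
#' @export
write_measurements <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname actinscreen-io
#' @export
read_ct_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         condition = "c", gene = "c",
                         replicate = "i", ct = "d"
                       ))
  class(x) <- c("ct_table", class(x))
  x
}

#' @rdname actinscreen-io
#' @export
write_ct_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @rdname actinscreen-io
#' @export
read_counts_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  as_expr_matrix(as.data.frame(x))
}

#' @rdname actinscreen-io
#' @export
write_counts_matrix <- function(x, path) {
  m <- as_expr_matrix(x)
  df <- dplyr::bind_cols(
    tibble(gene = rownames(m$counts), length_bp = unname(m$gene_lengths)),
    as_tibble(m$counts)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write and read single-well grayscale TIFFs
#'
#' Wells are stored one file each as 16-bit grayscale TIFF named
#' `<plate_id>_<well>.tif`. Requires the `tiff` package.
#'
#' @param image A `well_image`.
#' @param dir Directory for the file.
#' @return The written path / a `well_image`.
#' @export
write_well_image <- function(image, dir = ".") {
  rlang::check_installed("tiff")
  stopifnot(inherits(image, "well_image"))
  path <- file.path(dir, sprintf("%s_%s.tif", image$plate_id %+na% "NA",
                                 image$well %+na% "NA"))
  maxval <- max(2^16 - 1, max(image$pixels))
  tiff::writeTIFF(image$pixels / maxval, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_well_image
#' @param path TIFF path, expected `<plate_id>_<well>.tif`.
#' @export
read_well_image <- function(path) {
  rlang::check_installed("tiff")
  px <- round(tiff::readTIFF(path) * (2^16 - 1))
  base <- sub("\\.tiff?$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  structure(
    list(pixels = px, truth_mask = NULL, saturated = FALSE,
         plate_id = paste(parts[-length(parts)], collapse = "_"),
         well = parts[length(parts)], pixel_size = 1),
    class = "well_image"
  )
}
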