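#' Generate a randomized 384-well plate layout
#'
#' Lays out a screening plate in the standard 16 x 24 (rows A-P, columns
#' 1-24) format: DMSO negative-control wells, positive-control wells
#' (modelling the SDYLRP deactivation cocktail), and library compound wells.
#' Control positions are placed at random, reproducibly for a given seed,
#' so that plate statistics are not confounded with plate geometry.
#'
#' @param n_compound_wells Number of library compound wells.
#' @param n_neg Number of DMSO negative-control wells (at least 2 so that a
#'   control SD is defined).
#' @param n_pos Number of positive-control wells (at least 2).
#' @param seed Integer seed; the layout is a pure function of the arguments.
#' @param plate_id Plate identifier written into every row.
#' @param dose_nM Dose (nM) assigned to every compound well.
#' @param compound_ids Optional character vector of compound identifiers,
#'   length `n_compound_wells`; defaults to `"CPD0001"...`.
#'
#' @return A tibble of class `plate_layout` with one row per assigned well:
#'   `plate_id`, `well` (e.g. `"A01"`), `row`, `col`, `kind` (one of
#'   `"negative_control"`, `"positive_control"`, `"compound"`),
#'   `compound_id` (`NA` for controls), `dose_nM` (`NA` for controls).
#' @examples
#' layout <- generate_plate_layout(360, n_neg = 16, n_pos = 8, seed = 1)
#' dplyr::count(layout, kind)
#' @export
generate_plate_layout <- function(n_compound_wells, n_neg = 16, n_pos = 8,
                                  seed = 1, plate_id = "P01", dose_nM = 2000,
                                  compound_ids = NULL) {
  total <- n_compound_wells + n_neg + n_pos
  if (total > 384) {
    abort(sprintf(
      "plate capacity exceeded: %d compound + %d negative + %d positive = %d wells > 384",
      n_compound_wells, n_neg, n_pos, total
    ))
  }
  if (n_neg < 2 || n_pos < 2) {
    abort("at least 2 negative-control and 2 positive-control wells are required for QC")
  }
  if (is.null(compound_ids)) {
    compound_ids <- sprintf("CPD%04d", seq_len(n_compound_wells))
  }
  stopifnot(length(compound_ids) == n_compound_wells)

  all_wells <- well_addresses()
  layout <- withr::with_seed(seed, {
    use <- sample(all_wells, total)
    ctrl <- use[seq_len(n_neg + n_pos)]
    tibble(
      well = use,
      kind = c(
        rep("negative_control", n_neg),
        rep("positive_control", n_pos),
        rep("compound", n_compound_wells)
      ),
      compound_id = c(rep(NA_character_, n_neg + n_pos), compound_ids),
      dose_nM = c(rep(NA_real_, n_neg + n_pos), rep(dose_nM, n_compound_wells))
    )
  })
  layout <- layout %>%
    mutate(
      plate_id = plate_id,
      row = substr(.data$well, 1, 1),
      col = as.integer(substr(.data$well, 2, 3))
    ) %>%
    select("plate_id", "well", "row", "col", "kind", "compound_id", "dose_nM") %>%
    arrange(.data$row, .data$col)
  class(layout) <- c("plate_layout", class(layout))
  layout
}

#' All 384 well addresses of a 16 x 24 plate
#'
#' @return Character vector `"A01"` ... `"P24"` in row-major order.
#' @export
well_addresses <- function() {
  rows <- LETTERS[1:16]
  as.vector(t(outer(rows, sprintf("%02d", 1:24), paste0)))
}
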