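#' Generate a multi-tier synthetic screen with known ground truth
#'
#' Builds the dataset of a staged deactivation screen: every library
#' compound is assayed once per dose tier (mirroring a primary screen at
#' 2 uM and a secondary at 400 nM of the full library), laid out across
#' 384-well plates with DMSO negative controls and positive-control wells.
#' True hits respond with a saturating one-site dose-response,
#' `deactivation(dose) = max_effect * dose / (dose + potency)`; non-hits
#' stay at deactivation 0 apart from well-to-well noise. The number of true
#' hits is deterministic, `round(n_compounds * hit_fraction)`, so recovery
#' can be tested exactly.
#'
#' In the default `"fast"` mode well Actin scores are drawn directly from
#' the score model `Normal(mean(d), cv_well * mean(d))` with
#' `mean(d) = negative_mean * (1 - separation * d)`: DMSO wells sit at the
#' negative mean, fully deactivated wells (positive controls, `d = 1`) at
#' `(1 - separation)` of it. This keeps library-scale funnels at desk
#' scale; `mode = "image"` instead renders one well image per well via
#' [render_well_image()] and is intended for small screens.
#'
#' @param n_compounds Library size.
#' @param hit_fraction Fraction of true hits in \[0, 1\].
#' @param dose_tiers Numeric doses (nM), one screening tier each, ordered
#'   from primary downwards. Default `c(2000, 400)`.
#' @param n_neg,n_pos Control wells per plate.
#' @param hit_max_effect,hit_potency_nM Ground-truth dose-response of every
#'   true hit (saturating effect in \[0, 1\]; EC50-like potency in nM).
#' @param negative_mean Mean Actin score of activated (DMSO) wells,
#'   arbitrary units.
#' @param separation Fractional drop of the score at full deactivation
#'   (0.8 means positive controls average 20% of the negative mean).
#' @param cv_well Well-to-well coefficient of variation of the score, as a
#'   fraction of each well's own mean.
#' @param mode `"fast"` (score model) or `"image"` (render every well).
#' @param image_params A [sim_params()] template used in image mode.
#' @param seed Integer seed; the whole dataset is a pure function of it.
#'
#' @return A list of class `screen_dataset`:
#'   * `scores` — tibble with one row per well per tier: `tier`, `dose_nM`,
#'     `plate_id`, `well`, `kind`, `compound_id`, `actin_score` (fast mode)
#'     and, in image mode, an `image` list-column;
#'   * `ground_truth` — tibble `compound_id`, `is_true_hit`, `potency_nM`,
#'     `max_effect`;
#'   * `params` — the generator settings, including the seed.
#' @examples
#' scr <- generate_screen(200, hit_fraction = 0.05, seed = 3)
#' sum(scr$ground_truth$is_true_hit)
#' @export
generate_screen <- function(n_compounds, hit_fraction,
                            dose_tiers = c(2000, 400),
                            n_neg = 16, n_pos = 8,
                            hit_max_effect = 0.9, hit_potency_nM = 100,
                            negative_mean = 100, separation = 0.8,
                            cv_well = 0.05,
                            mode = c("fast", "image"),
                            image_params = sim_params(),
                            seed = 1) {
  mode <- match.arg(mode)
  if (length(dose_tiers) == 0) abort("dose_tiers must be non-empty")
  if (hit_fraction < 0 || hit_fraction > 1) abort("hit_fraction must lie in [0, 1]")
  if (hit_max_effect < 0 || hit_max_effect > 1) abort("hit_max_effect must lie in [0, 1]")
  if (hit_potency_nM <= 0) abort("hit_potency_nM must be positive")

  compound_ids <- sprintf("CPD%05d", seq_len(n_compounds))
  n_hits <- round(n_compounds * hit_fraction)
  hit_ids <- withr::with_seed(child_seed(seed, 1), sample(compound_ids, n_hits))
  ground_truth <- tibble(
    compound_id = compound_ids,
    is_true_hit = compound_ids %in% hit_ids,
    potency_nM = ifelse(compound_ids %in% hit_ids, hit_potency_nM, NA_real_),
    max_effect = ifelse(compound_ids %in% hit_ids, hit_max_effect, 0)
  )

  per_plate <- 384 - n_neg - n_pos
  n_plates <- ceiling(n_compounds / per_plate)
  plate_of <- rep(seq_len(n_plates), each = per_plate)[seq_len(n_compounds)]

  tiers <- purrr::imap(dose_tiers, function(dose, t_idx) {
    purrr::map(seq_len(n_plates), function(p) {
      ids <- compound_ids[plate_of == p]
      layout <- generate_plate_layout(
        length(ids), n_neg = n_neg, n_pos = n_pos,
        seed = child_seed(seed, 100 * t_idx + p),
        plate_id = sprintf("T%d_P%02d", t_idx, p),
        dose_nM = dose, compound_ids = ids
      )
      layout$tier <- t_idx
      layout
    }) %>% bind_rows()
  }) %>% bind_rows()

  # ground-truth deactivation level of every well
  tiers <- tiers %>%
    left_join(ground_truth, by = "compound_id") %>%
    mutate(
      deactivation = dplyr::case_when(
        kind == "negative_control" ~ 0,
        kind == "positive_control" ~ 1,
        is_true_hit ~ hit_max_effect * dose_nM / (dose_nM + hit_potency_nM),
        TRUE ~ 0
      )
    )

  if (mode == "fast") {
    mu <- negative_mean * (1 - separation * tiers$deactivation)
    tiers$actin_score <- withr::with_seed(
      child_seed(seed, 2),
      rnorm(nrow(tiers), mean = mu, sd = cv_well * mu)
    )
  } else {
    tiers$image <- purrr::pmap(
      list(tiers$deactivation, seq_len(nrow(tiers)), tiers$plate_id, tiers$well),
      function(d, i, pid, w) {
        p <- image_params
        p$deactivation_level <- d
        p$seed <- child_seed(seed, 10000 + i)
        render_well_image(p, plate_id = pid, well = w)
      }
    )
  }

  scores <- tiers %>%
    select("tier", "dose_nM", "plate_id", "well", "kind", "compound_id",
           dplyr::any_of(c("actin_score", "image")))
  structure(
    list(
      scores = scores,
      ground_truth = ground_truth,
      params = list(
        n_compounds = n_compounds, hit_fraction = hit_fraction,
        dose_tiers = dose_tiers, n_neg = n_neg, n_pos = n_pos,
        hit_max_effect = hit_max_effect, hit_potency_nM = hit_potency_nM,
        negative_mean = negative_mean, separation = separation,
        cv_well = cv_well, mode = mode, seed = seed
      )
    ),
    class = "screen_dataset"
  )
}

#' Simulate one control/validation plate in fast mode
#'
#' Convenience wrapper producing the measurement table of a single plate
#' carrying only controls and inactive library wells, as used for assay
#' validation: DMSO wells at the negative mean, positive-control wells at
#' `(1 - separation)` of it, both with well CV `cv_well`.
#'
#' @inheritParams generate_screen
#' @param n_compound_wells Inactive library wells on the plate.
#' @param dose_nM Dose recorded for the compound wells.
#' @return A tibble shaped like [quantify_plate()] output (`plate_id`,
#'   `well`, `kind`, `compound_id`, `dose_nM`, `actin_score`, `qc_flags`).
#' @export
simulate_control_plate <- function(n_compound_wells = 360, n_neg = 16, n_pos = 8,
                                   negative_mean = 100, separation = 0.8,
                                   cv_well = 0.05, dose_nM = 2000, seed = 1) {
  layout <- generate_plate_layout(
    n_compound_wells, n_neg = n_neg, n_pos = n_pos,
    seed = child_seed(seed, 1), dose_nM = dose_nM
  )
  d <- ifelse(layout$kind == "positive_control", 1, 0)
  mu <- negative_mean * (1 - separation * d)
  layout$actin_score <- withr::with_seed(
    child_seed(seed, 2),
    rnorm(nrow(layout), mean = mu, sd = cv_well * mu)
  )
  layout$qc_flags <- ""
  layout %>% select("plate_id", "well", "kind", "compound_id", "dose_nM",
                    "actin_score", "qc_flags")
}

#' @method print screen_dataset
#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(
    "<screen_dataset> %d compounds (%d true hits), %d dose tier(s), %s mode, seed %d\n",
    x$params$n_compounds, sum(x$ground_truth$is_true_hit),
    length(x$params$dose_tiers), x$params$mode, x$params$seed
  ))
  invisible(x)
}
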