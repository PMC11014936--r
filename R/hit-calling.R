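#' Plate-wise hit threshold (mean minus k standard deviations)
#'
#' The selection rule of the screen: a plate's eligible Actin scores give a
#' mean and sample SD, and wells falling strictly below `mean - k * sd`
#' (default k = 2) are candidate deactivators. Statistics are always
#' per-plate, never pooled across plates.
#'
#' @param scores Numeric vector of at least 3 eligible scores.
#' @param k Positive SD multiplier, default 2.
#' @return The threshold, in Actin-score units.
#' @examples
#' plate_hit_threshold(c(rep(5, 9), 0)) # 4.5 - 2 * 1.5811
#' @export
plate_hit_threshold <- function(scores, k = 2) {
  scores <- as.numeric(scores)
  if (length(scores) < 3 || any(!is.finite(scores))) {
    abort("plate_hit_threshold needs at least 3 finite scores")
  }
  if (k < 0) abort("k must be non-negative")
  mean(scores) - k * sd(scores)
}

#' Call hits on measured plates
#'
#' Applies the plate-wise mean minus `k` SD rule to every plate in a
#' measurement table. By default only compound wells enter the plate mean
#' and SD (controls would bias the spread when a strong positive control
#' is present); set `population = "all"` to include every scored well.
#' Wells flagged `EMPTY_WELL` never enter the statistics nor the hit list.
#' Selection is strict: a hit's score is strictly below the threshold.
#'
#' @param measurements Measurement tibble, possibly spanning plates.
#' @param k SD multiplier, default 2.
#' @param population `"compound"` (default) or `"all"`: which wells supply
#'   the plate mean and SD.
#'
#' @return A tibble of class `hit_list` with one row per hit (`plate_id`,
#'   `well`, `compound_id`, `dose_nM`, `actin_score`, `threshold`), and a
#'   `plate_stats` attribute tibble (`plate_id`, `n_tested`, `mean`, `sd`,
#'   `threshold`, `k`). [glance()] returns the per-plate statistics.
#' @examples
#' plate <- simulate_control_plate(seed = 4)
#' hits <- call_hits(plate)
#' glance(hits)
#' @export
call_hits <- function(measurements, k = 2, population = c("compound", "all")) {
  population <- match.arg(population)
  stopifnot(is.data.frame(measurements))
  usable <- measurements %>%
    filter(!has_flag(.data$qc_flags %+na% "", "EMPTY_WELL"),
           is.finite(.data$actin_score))
  eligible <- if (population == "compound") {
    usable %>% filter(.data$kind == "compound")
  } else {
    usable
  }
  if (nrow(usable %>% filter(.data$kind == "compound")) == 0) {
    abort("no eligible compound wells to test")
  }

  stats <- eligible %>%
    group_by(.data$plate_id) %>%
    summarise(
      n_tested = dplyr::n(),
      mean = mean(.data$actin_score),
      sd = sd(.data$actin_score),
      .groups = "drop"
    ) %>%
    mutate(threshold = .data$mean - k * .data$sd, k = k)
  if (any(stats$n_tested < 3)) {
    abort("each plate needs at least 3 eligible scores for mean/SD statistics")
  }

  hits <- usable %>%
    filter(.data$kind == "compound") %>%
    left_join(stats %>% select("plate_id", "threshold"), by = "plate_id") %>%
    filter(.data$actin_score < .data$threshold) %>%
    select("plate_id", "well", "compound_id", "dose_nM", "actin_score", "threshold") %>%
    arrange(.data$plate_id, .data$actin_score)
  structure(hits,
            plate_stats = stats,
            class = c("hit_list", class(hits)))
}

#' @method tidy hit_list
#' @export
tidy.hit_list <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "hit_list")
  out
}

#' @method glance hit_list
#' @export
glance.hit_list <- function(x, ...) attr(x, "plate_stats")

#' Run the three-tier screening funnel
#'
#' Orchestrates the staged selection of the screen on a
#' [generate_screen()] dataset in which the full library is assayed at
#' every dose tier:
#'
#' 1. **Primary** — hits called with the mean minus `k` SD rule on the
#'    highest-dose plates (2 uM by default).
#' 2. **Secondary** — hits called independently, per plate, on the
#'    next-dose plates (400 nM); the selection is the intersection with
#'    the primary picks, so candidate sets are nested by construction.
#' 3. **Tertiary** — each surviving compound is profiled by qPCR across a
#'    dose grid (`qpcr_doses`) against the five-gene marker panel and kept
#'    only if [classify_deactivation()] calls it `deactivating`. The Ct
#'    data are synthesised from the screen's ground-truth dose-response,
#'    playing the role of the bench confirmation experiment.
#'
#' Plates failing [validate_plate()] are excluded from calling (with a
#' warning) unless `force = TRUE`, in which case the violation is recorded
#' in the report.
#'
#' @param screen A `screen_dataset` (fast mode).
#' @param k SD multiplier for both score tiers.
#' @param population Passed to [call_hits()].
#' @param qpcr_doses Dose grid (nM) of the tertiary qPCR confirmation.
#' @param ct_noise_sd Replicate noise of the synthesised Ct data.
#' @param marker_effects Named numeric: log2 fold change of each marker
#'   gene per unit of deactivation (negative for activation markers).
#' @param force Call hits on QC-failed plates anyway.
#'
#' @return A list of class `funnel_report`: `tiers` (tibble `tier`,
#'   `label`, `dose_nM`, `n_in`, `n_selected`), `selected` (list of
#'   compound-id vectors per tier), `final_candidates`, `hit_lists`,
#'   `classification` (tertiary calls), `qc` (per-tier QC reports),
#'   `qc_violations`.
#' @export
run_funnel <- function(screen, k = 2, population = "compound",
                       qpcr_doses = c(125, 500, 2000),
                       ct_noise_sd = 0.2,
                       marker_effects = c(ACTA2 = -3.5, COL1A1 = -4,
                                          TCF21 = 3, LRAT = 2.5, LHX2 = 2),
                       force = FALSE) {
  stopifnot(inherits(screen, "screen_dataset"))
  if (screen$params$mode != "fast") {
    abort("run_funnel expects a fast-mode screen; quantify images first")
  }
  tiers_dose <- sort(screen$params$dose_tiers, decreasing = TRUE)
  scores <- screen$scores %>% mutate(qc_flags = "")

  qc_all <- list()
  violations <- character()
  hit_lists <- list()
  selected <- list()
  tier_rows <- list()
  carried <- unique(scores$compound_id[!is.na(scores$compound_id)])

  for (t_idx in seq_along(tiers_dose)) {
    dose <- tiers_dose[t_idx]
    tier_id <- unique(scores$tier[scores$kind == "compound" & scores$dose_nM == dose])
    stopifnot(length(tier_id) == 1)
    tier_meas <- scores %>% filter(.data$tier == tier_id)
    qc <- validate_plate(tier_meas)
    qc_all[[t_idx]] <- qc
    bad <- qc$plate_id[!qc$overall_pass]
    if (length(bad) > 0) {
      msg <- sprintf("tier %d: plate(s) failed QC: %s", t_idx, paste(bad, collapse = ", "))
      if (force) {
        violations <- c(violations, msg)
      } else {
        warn(paste(msg, "- excluded from hit calling"))
        tier_meas <- tier_meas %>% filter(!.data$plate_id %in% bad)
      }
    }
    hl <- call_hits(tier_meas, k = k, population = population)
    hit_lists[[t_idx]] <- hl
    picked <- intersect(carried, hl$compound_id)
    tier_rows[[t_idx]] <- tibble(
      tier = t_idx, label = sprintf("score_%gnM", dose), dose_nM = dose,
      n_in = length(carried), n_selected = length(picked)
    )
    selected[[t_idx]] <- picked
    carried <- picked
  }

  # tertiary: qPCR confirmation of the carried compounds
  classification <- NULL
  if (length(carried) > 0) {
    truth <- screen$ground_truth %>% filter(.data$compound_id %in% carried)
    eff <- tidyr::expand_grid(
      compound_id = truth$compound_id, dose = qpcr_doses,
      gene = names(marker_effects)
    ) %>%
      left_join(truth, by = "compound_id") %>%
      mutate(
        deact = .data$max_effect * .data$dose / (.data$dose + .data$potency_nM %+na% 1),
        condition = paste0(.data$compound_id, "@", .data$dose),
        log2fc = marker_effects[.data$gene] * .data$deact
      )
    ct <- generate_ct_table(
      conditions = c("DMSO", unique(eff$condition)),
      genes = c("GAPDH", names(marker_effects)),
      effect_model = eff %>% select("condition", "gene", "log2fc"),
      ct_noise_sd = ct_noise_sd, n_replicates = 3,
      seed = child_seed(screen$params$seed, 999)
    )
    rel <- delta_delta_ct(ct, reference = "GAPDH", calibrator = "DMSO") %>%
      filter(.data$condition != "DMSO") %>%
      tidyr::separate_wider_delim("condition", "@", names = c("compound_id", "dose_chr")) %>%
      mutate(dose_nM = as.numeric(.data$dose_chr)) %>%
      select("compound_id", "dose_nM", "gene", "fold_change")
    classification <- classify_deactivation(rel)
    carried <- classification$compound_id[classification$classification == "deactivating"]
  }
  tier_rows[[length(tier_rows) + 1]] <- tibble(
    tier = length(tiers_dose) + 1, label = "qpcr_panel",
    dose_nM = max(qpcr_doses),
    n_in = tier_rows[[length(tiers_dose)]]$n_selected,
    n_selected = length(carried)
  )
  selected[[length(selected) + 1]] <- carried

  structure(
    list(
      tiers = bind_rows(tier_rows),
      selected = selected,
      final_candidates = carried,
      hit_lists = hit_lists,
      classification = classification,
      qc = qc_all,
      qc_violations = violations
    ),
    class = "funnel_report"
  )
}

#' @method print funnel_report
#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(as.data.frame(x$tiers), row.names = FALSE)
  cat(sprintf("final candidates: %d\n", length(x$final_candidates)))
  invisible(x)
}

#' @method tidy funnel_report
#' @export
tidy.funnel_report <- function(x, ...) x$tiers

#' @method glance funnel_report
#' @export
glance.funnel_report <- function(x, ...) {
  tibble(
    n_tiers = nrow(x$tiers),
    n_screened = x$tiers$n_in[1],
    n_final = length(x$final_candidates),
    qc_violations = length(x$qc_violations)
  )
}

#' Score recovery of known hits
#'
#' Compares a funnel's final candidate list against a screen's ground
#' truth.
#'
#' @param funnel A `funnel_report`.
#' @param ground_truth The `ground_truth` tibble of the screen.
#' @return One-row tibble: `n_true_hits`, `n_called`, `recall`,
#'   `precision`.
#' @export
funnel_recovery <- function(funnel, ground_truth) {
  truth <- ground_truth$compound_id[ground_truth$is_true_hit]
  called <- funnel$final_candidates
  tibble(
    n_true_hits = length(truth),
    n_called = length(called),
    recall = if (length(truth) == 0) NA_real_ else
      length(intersect(called, truth)) / length(truth),
    precision = if (length(called) == 0) NA_real_ else
      length(intersect(called, truth)) / length(called)
  )
}
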