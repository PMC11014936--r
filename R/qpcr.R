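#' Delta-delta-Ct relative quantification
#'
#' Classic comparative-Ct analysis with perfect-doubling amplification:
#' per replicate, `dCt = Ct_target - Ct_reference`; per condition,
#' `ddCt = dCt - mean(dCt of the calibrator)`; the relative expression is
#' `2^(-ddCt)`, so the calibrator condition reads 1 by construction. The
#' per-condition point estimate is `2^(-mean ddCt)` — the geometric mean
#' of the replicate folds — which keeps the calibrator identity exact
#' under replicate noise; the arithmetic mean and SD of the replicate
#' folds are reported alongside. A replicate missing its reference Ct is
#' dropped with a warning; an absent calibrator is an error.
#'
#' @param ct A `ct_table` tibble (`condition`, `gene`, `replicate`, `ct`).
#' @param reference Reference (normalization) gene, default `"GAPDH"`.
#' @param calibrator Condition whose expression defines 1 (a vehicle
#'   control or an untreated baseline — a per-experiment choice, not a
#'   constant).
#' @param target Genes to quantify; default all non-reference genes.
#'
#' @return A tibble of class `relative_expression`: `condition`, `gene`,
#'   `n_replicates`, `fold_change` (geometric-mean estimate),
#'   `fold_mean`, `fold_sd` (arithmetic summaries of replicate folds),
#'   `ddct_mean`, and a `replicates` list-column of per-replicate folds.
#' @examples
#' ct <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2"),
#'   tibble::tibble(condition = "drug", gene = "ACTA2", log2fc = -2),
#'   ct_noise_sd = 0, seed = 1)
#' delta_delta_ct(ct, calibrator = "DMSO")
#' @export
delta_delta_ct <- function(ct, reference = "GAPDH", calibrator, target = NULL) {
  stopifnot(is.data.frame(ct))
  if (!calibrator %in% ct$condition) {
    abort(sprintf("calibrator condition \"%s\" absent from the Ct table", calibrator))
  }
  if (!reference %in% ct$gene) {
    abort(sprintf("reference gene \"%s\" absent from the Ct table", reference))
  }
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) abort("Ct values must be finite and positive")
  genes <- target %||% setdiff(unique(ct$gene), reference)
  if (reference %in% genes) abort("target and reference genes must differ")

  ref <- ct %>%
    filter(.data$gene == reference) %>%
    select("condition", "replicate", ref_ct = "ct")
  dct <- ct %>%
    filter(.data$gene %in% genes) %>%
    left_join(ref, by = c("condition", "replicate"))
  dropped <- dct %>% filter(is.na(.data$ref_ct))
  if (nrow(dropped) > 0) {
    warn(sprintf(
      "%d replicate(s) dropped for missing reference Ct (%s)",
      nrow(dropped),
      paste(unique(paste0(dropped$condition, "/", dropped$gene)), collapse = ", ")
    ))
    dct <- dct %>% filter(!is.na(.data$ref_ct))
  }
  dct <- dct %>% mutate(dct = .data$ct - .data$ref_ct)

  cal <- dct %>%
    filter(.data$condition == calibrator) %>%
    group_by(.data$gene) %>%
    summarise(cal_dct = mean(.data$dct), .groups = "drop")
  if (!all(genes %in% cal$gene)) {
    abort(paste0("calibrator lacks Ct data for gene(s): ",
                 paste(setdiff(genes, cal$gene), collapse = ", ")))
  }

  out <- dct %>%
    left_join(cal, by = "gene") %>%
    mutate(ddct = .data$dct - .data$cal_dct, fold = 2^(-.data$ddct)) %>%
    group_by(.data$condition, .data$gene) %>%
    summarise(
      n_replicates = dplyr::n(),
      # difference of means rather than mean of differences: bitwise-exact
      # cancellation for the calibrator, identical value otherwise
      ddct_mean = mean(.data$dct) - .data$cal_dct[1],
      fold_change = 2^(-.data$ddct_mean),
      fold_mean = mean(.data$fold),
      fold_sd = sd(.data$fold),
      replicates = list(.data$fold),
      .groups = "drop"
    ) %>%
    select("condition", "gene", "n_replicates", "fold_change",
           "fold_mean", "fold_sd", "ddct_mean", "replicates")
  structure(out, calibrator = calibrator, reference = reference,
            class = c("relative_expression", class(out)))
}

#' @method tidy relative_expression
#' @export
tidy.relative_expression <- function(x, ...) {
  out <- as_tibble(x) %>% select(-"replicates")
  class(out) <- setdiff(class(out), "relative_expression")
  out
}

#' @method glance relative_expression
#' @export
glance.relative_expression <- function(x, ...) {
  tibble(
    n_conditions = dplyr::n_distinct(x$condition),
    n_genes = dplyr::n_distinct(x$gene),
    calibrator = attr(x, "calibrator"),
    reference = attr(x, "reference")
  )
}

#' One-way ANOVA of each condition against a control
#'
#' For each non-control condition, fits a one-way ANOVA of the response
#' (typically delta-Ct values, which are approximately normal, or
#' replicate fold changes) for that condition versus the control group and
#' reports the F statistic and two-sided p-value. With two groups this is
#' the classical equal-variance F test. Conditions are tested without
#' multiple-testing correction by default, matching common practice for a
#' small confirmation panel; `p_adjust` switches on Bonferroni.
#'
#' @param data Data frame of replicate-level values.
#' @param value,condition Column names (strings) of the response and the
#'   grouping label.
#' @param control The control condition label (e.g. `"DMSO"`).
#' @param alpha Significance level, default 0.05.
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#'
#' @return Tibble: `condition`, `n`, `df1`, `df2`, `f_statistic`,
#'   `p_value`, `significant`.
#' @examples
#' d <- data.frame(cond = rep(c("DMSO", "drug"), each = 3),
#'                 y = c(1, 2, 3, 4, 5, 6))
#' anova_vs_control(d, "y", "cond", control = "DMSO")
#' @export
anova_vs_control <- function(data, value, condition, control,
                             alpha = 0.05, p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(data))
  y_all <- data[[value]]
  g_all <- as.character(data[[condition]])
  if (!control %in% g_all) abort(sprintf("control condition \"%s\" absent", control))
  others <- setdiff(unique(g_all), control)
  if (length(others) == 0) abort("need at least one non-control condition")

  res <- purrr::map(others, function(cond) {
    keep <- g_all %in% c(control, cond)
    y <- y_all[keep]
    g <- factor(g_all[keep])
    if (any(table(g) < 2)) abort(sprintf("condition \"%s\": each group needs >= 2 replicates", cond))
    within_var <- tapply(y, g, var)
    if (all(within_var == 0)) {
      abort(sprintf("condition \"%s\": zero within-group variance, F undefined", cond))
    }
    fit <- anova(aov(y ~ g))
    tibble(
      condition = cond, n = length(y),
      df1 = fit$Df[1], df2 = fit$Df[2],
      f_statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1]
    )
  }) %>% bind_rows()
  if (p_adjust == "bonferroni") {
    res$p_value <- pmin(1, res$p_value * nrow(res))
  }
  res %>% mutate(significant = .data$p_value < alpha)
}

#' Classify compounds as deactivating from a marker fold-change panel
#'
#' Rule-based call over the five-gene tertiary panel, relative to a
#' vehicle control fixed at 1: at a given dose a compound is
#' *deactivating* when both activation markers are suppressed
#' (`ACTA2 < down_max` and `COL1A1 < down_max`) and at least `min_up` of
#' the quiescence markers (`TCF21`, `LRAT`, `LHX2`) are induced
#' (`> up_min`). The compound-level class is taken at the highest dose:
#' `"deactivating"` if the full rule holds there, `"partial"` if only the
#' suppression rule holds, `"inactive"` otherwise. Lowering an activation
#' marker's fold change can never demote a compound's class.
#'
#' @param expr Tibble with columns `compound_id`, `dose_nM`, `gene`,
#'   `fold_change`; must contain every panel gene at each dose.
#' @param down_max,up_min Fold-change thresholds (defaults 1 and 1, i.e.
#'   any suppression / any induction relative to the control).
#' @param min_up Minimum number of induced quiescence markers (default 3,
#'   i.e. all).
#' @param down_genes,up_genes Panel definition.
#'
#' @return A tibble of class `deactivation_call`: `compound_id`,
#'   `classification`, `top_dose_nM`, plus per-dose logical columns
#'   nested in `by_dose`.
#' @export
classify_deactivation <- function(expr, down_max = 1, up_min = 1, min_up = 3,
                                  down_genes = c("ACTA2", "COL1A1"),
                                  up_genes = c("TCF21", "LRAT", "LHX2")) {
  stopifnot(is.data.frame(expr))
  panel <- c(down_genes, up_genes)
  missing <- setdiff(panel, unique(expr$gene))
  if (length(missing) > 0) {
    abort(paste0("panel gene(s) missing from the fold-change table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"compound_id" %in% names(expr)) expr$compound_id <- "compound"
  if (!"dose_nM" %in% names(expr)) expr$dose_nM <- NA_real_

  by_dose <- expr %>%
    filter(.data$gene %in% panel) %>%
    group_by(.data$compound_id, .data$dose_nM) %>%
    summarise(
      down_rule = all(.data$fold_change[.data$gene %in% down_genes] < down_max) &&
        sum(.data$gene %in% down_genes) == length(down_genes),
      n_up = sum(.data$fold_change[.data$gene %in% up_genes] > up_min),
      deactivating = .data$down_rule && .data$n_up >= min_up,
      .groups = "drop"
    )
  out <- by_dose %>%
    group_by(.data$compound_id) %>%
    dplyr::group_modify(function(d, key) {
      top <- d[which.max(d$dose_nM %+na% -Inf), ]
      tibble(
        classification = if (top$deactivating) "deactivating"
          else if (top$down_rule) "partial" else "inactive",
        top_dose_nM = top$dose_nM,
        by_dose = list(d)
      )
    }) %>%
    ungroup()
  class(out) <- c("deactivation_call", class(out))
  out
}

#' Fold-change matrix for a marker heatmap
#'
#' Reshapes tertiary-panel fold changes into the compound-by-(gene, dose)
#' matrix used for the confirmation heatmap, with the vehicle control
#' fixed at 1 in every cell of its row if present.
#'
#' @param expr Tibble with `compound_id`, `dose_nM`, `gene`,
#'   `fold_change`.
#' @return A wide tibble: `compound_id` plus one `gene@dose` column per
#'   panel cell.
#' @export
expression_heatmap_table <- function(expr) {
  stopifnot(is.data.frame(expr), nrow(expr) > 0)
  expr %>%
    mutate(cell = paste0(.data$gene, "@", .data$dose_nM)) %>%
    select("compound_id", "cell", "fold_change") %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "fold_change")
}
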