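#' Generate a synthetic qPCR Ct table
#'
#' Simulates raw quantification-cycle (Ct) values under the standard
#' exponential-amplification model with perfect doubling: a condition that
#' raises a gene's expression by `log2fc` doublings lowers its Ct by the
#' same number of cycles,
#' `Ct = baseline_ct(gene) - log2fc(condition, gene) + Normal(0, ct_noise_sd)`.
#' The reference gene's programmed fold change is identically zero, so the
#' downstream delta-delta-Ct pipeline recovers the programmed fold changes
#' exactly at zero noise.
#'
#' @param conditions Character vector of condition labels (compound + dose
#'   or control labels). Conditions absent from `effect_model` get
#'   `log2fc = 0` for every gene.
#' @param genes Character vector of gene symbols; must include `reference`.
#' @param effect_model Tibble/data frame with columns `condition`, `gene`,
#'   `log2fc` giving the programmed log2 fold change of each gene under
#'   each condition (relative to the calibrator state). Naming a gene not
#'   in `genes` is an error; programming the reference gene is an error.
#' @param ct_noise_sd Replicate noise SD, in Ct units.
#' @param n_replicates Technical replicates per (condition, gene);
#'   at least 1 (three is the bench convention).
#' @param baseline_ct Named numeric of per-gene baseline Ct values; genes
#'   not named default to 24 cycles (18 for the reference gene).
#' @param reference Reference (normalization) gene symbol, default GAPDH.
#' @param seed Integer seed.
#'
#' @return A tibble of class `ct_table` with columns `condition`, `gene`,
#'   `replicate`, `ct`.
#' @examples
#' eff <- tibble::tibble(condition = "drug", gene = "ACTA2", log2fc = -2)
#' ct <- generate_ct_table(c("DMSO", "drug"), c("GAPDH", "ACTA2"), eff,
#'                         ct_noise_sd = 0, seed = 1)
#' @export
generate_ct_table <- function(conditions, genes, effect_model = NULL,
                              ct_noise_sd = 0.2, n_replicates = 3,
                              baseline_ct = NULL, reference = "GAPDH",
                              seed = 1) {
  if (!reference %in% genes) abort("`genes` must include the reference gene")
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  if (ct_noise_sd < 0) abort("ct_noise_sd must be non-negative")

  if (is.null(effect_model)) {
    effect_model <- tibble(condition = character(), gene = character(),
                           log2fc = numeric())
  }
  effect_model <- as_tibble(effect_model)
  unknown <- setdiff(effect_model$gene, genes)
  if (length(unknown) > 0) {
    abort(paste0("effect model names unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(effect_model$gene == reference & effect_model$log2fc != 0)) {
    abort("the reference gene cannot carry a programmed fold change")
  }

  base <- setNames(rep(24, length(genes)), genes)
  base[reference] <- 18
  if (!is.null(baseline_ct)) base[names(baseline_ct)] <- baseline_ct

  grid <- tidyr::expand_grid(
    condition = conditions, gene = genes, replicate = seq_len(n_replicates)
  ) %>%
    left_join(effect_model, by = c("condition", "gene")) %>%
    mutate(log2fc = .data$log2fc %+na% 0)

  grid$ct <- withr::with_seed(
    seed,
    base[grid$gene] - grid$log2fc + rnorm(nrow(grid), sd = ct_noise_sd)
  )
  out <- grid %>% select("condition", "gene", "replicate", "ct")
  class(out) <- c("ct_table", class(out))
  out
}
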