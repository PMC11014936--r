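#' Default marker program of the four-state stellate-cell design
#'
#' Group-wise mean log2 expression of the canonical marker genes across the
#' four states profiled by bulk RNA-seq: quiescent cells at day 0
#' (`qHSC_d0`), activated cells at days 7 and 10 (`aHSC_d7`, `aHSC_d10`)
#' and deactivated cells at day 10 (`daHSC_d10`). Activation markers
#' (ACTA2, COL1A1, TGFB1) are high in aHSC; quiescence/deactivation
#' markers (LHX2, LRAT, TCF21, MDK, PTN) are high in qHSC and restored in
#' daHSC; NGFR is high only in qHSC — it is deliberately *not* restored on
#' deactivation, reflecting a partial reversion rather than a full return
#' to quiescence.
#'
#' @return Tibble with columns `gene`, `qHSC_d0`, `aHSC_d7`, `aHSC_d10`,
#'   `daHSC_d10` (log2 mean expression).
#' @export
default_marker_program <- function() {
  tibble::tribble(
    ~gene,     ~qHSC_d0, ~aHSC_d7, ~aHSC_d10, ~daHSC_d10,
    "ACTA2",        4.0,      9.0,       9.5,        5.0,
    "COL1A1",       5.0,     10.0,      10.5,        6.0,
    "TGFB1",        5.0,      8.0,       8.3,        5.5,
    "LHX2",         8.0,      4.0,       4.0,        7.5,
    "LRAT",         9.0,      4.5,       4.2,        8.0,
    "TCF21",        7.0,      3.5,       3.5,        7.0,
    "MDK",          8.0,      5.0,       5.0,        7.5,
    "PTN",          8.0,      5.5,       5.2,        7.5,
    "NGFR",         8.0,      4.0,       4.0,        4.0
  )
}

#' Generate an RNA-seq-like count matrix with known group structure
#'
#' Simulates a gene-by-sample negative-binomial count matrix emulating the
#' four-group stellate-cell design. Two layers carry the biology: the
#' explicit `marker_program` (see [default_marker_program()]) and a global
#' *activation program* — a random fraction of the filler transcriptome
#' whose log2 expression shifts along an activation axis scored 0 (qHSC),
#' 1 (aHSC day 7), 1.1 (aHSC day 10) and 0.25 (daHSC, a partial
#' reversion). The second layer reproduces the genome-wide behaviour that
#' makes deactivated samples correlate with quiescent rather than
#' activated samples in clustering and PCA; with only a handful of marker
#' genes that structure would drown in counting noise.
#'
#' @param group_design Named character vector `sample -> group`; groups
#'   must be the four state labels. Default: 3 replicates per group,
#'   samples named `<group>_r1..r3`.
#' @param marker_program Tibble as returned by [default_marker_program()]
#'   (column `gene` plus one log2-mean column per group).
#' @param n_filler Filler genes beyond the markers.
#' @param activation_fraction Fraction of filler genes on the activation
#'   program.
#' @param activation_sd SD of the per-gene activation loading (log2 units
#'   per unit of activation score).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); `0` gives deterministic counts `round(mu)`.
#' @param gene_lengths Named numeric of gene lengths in bp; defaults to
#'   seeded draws from 500-5000 bp.
#' @param seed Integer seed.
#'
#' @return A list of class `expression_set`: `counts` (integer matrix,
#'   genes x samples), `gene_lengths` (named, bp), `sample_groups` (named
#'   character), and `mean_log2` (genes x groups matrix of programmed log2
#'   means — the noise-free ground truth).
#' @examples
#' es <- generate_expression_matrix(seed = 1)
#' dim(es$counts)
#' @export
generate_expression_matrix <- function(group_design = NULL,
                                       marker_program = default_marker_program(),
                                       n_filler = 500,
                                       activation_fraction = 0.4,
                                       activation_sd = 1.2,
                                       dispersion = 0.05,
                                       gene_lengths = NULL,
                                       seed = 1) {
  groups <- c("qHSC_d0", "aHSC_d7", "aHSC_d10", "daHSC_d10")
  if (is.null(group_design)) {
    group_design <- setNames(
      rep(groups, each = 3),
      paste(rep(groups, each = 3), paste0("r", 1:3), sep = "_")
    )
  }
  if (is.null(names(group_design)) || any(!nzchar(names(group_design)))) {
    abort("group_design must be a named vector (sample -> group)")
  }
  if (any(!group_design %in% groups)) {
    abort(paste0("unknown group label(s): ",
                 paste(setdiff(group_design, groups), collapse = ", ")))
  }
  if (any(table(factor(group_design, groups)) < 2)) {
    abort("each group needs at least 2 samples for downstream statistics")
  }
  if (dispersion < 0) abort("dispersion must be non-negative")

  marker_program <- as_tibble(marker_program)
  stopifnot(all(c("gene", groups) %in% names(marker_program)))
  marker_means <- as.matrix(marker_program[, groups])
  rownames(marker_means) <- marker_program$gene

  activation_score <- c(qHSC_d0 = 0, aHSC_d7 = 1, aHSC_d10 = 1.1, daHSC_d10 = 0.25)

  mean_log2 <- withr::with_seed(child_seed(seed, 1), {
    filler_genes <- sprintf("GENE%04d", seq_len(n_filler))
    base <- runif(n_filler, 3, 10)
    on_program <- runif(n_filler) < activation_fraction
    loading <- ifelse(on_program, rnorm(n_filler, sd = activation_sd), 0)
    filler <- outer(base, rep(1, length(groups))) +
      outer(loading, activation_score[groups])
    dimnames(filler) <- list(filler_genes, groups)
    rbind(marker_means, filler)
  })

  genes <- rownames(mean_log2)
  if (is.null(gene_lengths)) {
    gene_lengths <- withr::with_seed(
      child_seed(seed, 2),
      setNames(round(runif(length(genes), 500, 5000)), genes)
    )
  }
  if (any(gene_lengths[genes] <= 0) || any(is.na(gene_lengths[genes]))) {
    abort("every gene needs a positive length")
  }

  mu <- 2^mean_log2[, group_design[names(group_design)], drop = FALSE]
  colnames(mu) <- names(group_design)
  counts <- withr::with_seed(child_seed(seed, 3), {
    if (dispersion == 0) {
      round(mu)
    } else {
      matrix(
        rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
        nrow = nrow(mu), dimnames = dimnames(mu)
      )
    }
  })

  structure(
    list(
      counts = counts,
      gene_lengths = gene_lengths[genes],
      sample_groups = group_design,
      mean_log2 = mean_log2
    ),
    class = "expression_set"
  )
}

#' @method print expression_set
#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "<expression_set> %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(names(table(x$sample_groups)), table(x$sample_groups),
          sep = ":", collapse = ", ")
  ))
  invisible(x)
}
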