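# Independent brute-force implementations used as oracles. These stay
# deliberately naive (explicit loops, textbook formulas) and never call the
# package's own code paths.

brute_actin_score <- function(pixels, mask) {
  total <- 0
  area <- 0L
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      if (mask[i, j]) {
        total <- total + pixels[i, j]
        area <- area + 1L
      }
    }
  }
  list(total = total, area = area, score = total / area)
}

brute_cv <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  100 * s / m
}

brute_z_prime <- function(neg, pos) {
  sdn <- function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / (length(v) - 1))
  }
  1 - 3 * (sdn(pos) + sdn(neg)) / abs(mean(pos) - mean(neg))
}

brute_anova_f <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  groups <- unique(g)
  ssb <- sum(vapply(groups, function(k) {
    length(y[g == k]) * (mean(y[g == k]) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(groups, function(k) {
    sum((y[g == k] - mean(y[g == k]))^2)
  }, numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  (ssb / df1) / (ssw / df2)
}

brute_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# exhaustive per-well hit check against an independently computed threshold
brute_hits <- function(scores, wells, k = 2) {
  m <- mean(scores)
  s <- sqrt(sum((scores - m)^2) / (length(scores) - 1))
  wells[scores < m - k * s]
}

# trapezoidal AUC of score separation (higher score = activated class)
brute_auc <- function(activated, deactivated) {
  mean(outer(activated, deactivated, ">")) +
    0.5 * mean(outer(activated, deactivated, "=="))
}

small_sim_params <- function(...) {
  args <- list(image_size = 96, cells_per_well = 12)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_params, args)
}
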