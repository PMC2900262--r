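# Shared fixtures and independent oracles used across test files.

default_config <- function(seed = 1) assay_config(seed = seed)

# full expression pipeline: plate -> per-sample summary table
run_expression_pipeline <- function(plate, reference = "POOL") {
  mfis <- compute_mfi(plate$events)
  bc <- background_correct(mfis, plate$layout)
  norm <- spike_normalize(bc$corrected)
  summarize_expression(norm, plate$layout, reference, plate$probe_map)
}

# independent two-segment fit oracle: exhaustive knot search with lm() on
# per-amount means (the implementation uses closed-form OLS instead)
oracle_two_segment <- function(amount, mfi) {
  means <- tapply(mfi, amount, mean)
  x <- log10(as.numeric(names(means)))
  y <- log10(as.numeric(means))
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  best <- NULL
  for (k in 3:(n - 2)) {
    fl <- stats::lm(y[1:k] ~ x[1:k])
    fh <- stats::lm(y[k:n] ~ x[k:n])
    sse <- sum(stats::resid(fl)^2) + sum(stats::resid(fh)^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && k > best$k)) {
      best <- list(k = k, sse = sse,
                   slope_low = unname(stats::coef(fl)[2]),
                   slope_high = unname(stats::coef(fh)[2]))
    }
  }
  best$knot <- 10^x[best$k]
  best
}

# textbook Welch two-sample t statistic / df / one-sided p (x < y)
oracle_welch_less <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = stats::pt(t, df))
}

# Spearman rho via explicit average ranks + Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# direct-formula oracle for the ratio summary of two replicate sets
oracle_ratio_summary <- function(sample_wells, ref_wells) {
  ms <- mean(sample_wells); mr <- mean(ref_wells)
  rs <- stats::sd(sample_wells) / ms
  rr <- stats::sd(ref_wells) / mr
  list(ratio = ms / mr, log2_ratio = log2(ms / mr),
       rel_sd = sqrt(rs^2 + rr^2),
       log2_sd = sqrt(rs^2 + rr^2) / log(2))
}
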