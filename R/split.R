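#' Stratified train/validation/test split
#'
#' Randomly assigns each (drug, cell) record to train / val / test while
#' preserving the response distribution: records are binned into response
#' deciles and each bin is allocated proportionally, with fractional
#' carry-over across bins so the global split sizes are exact (any
#' residual off-by-one is corrected by moving single records).  With
#' fewer records than bins the split falls back to unstratified sampling
#' with a warning.
#'
#' @param pairs A `pair_dataset` or data frame with an `ln_ic50` column.
#' @param fractions Train/val/test fractions summing to 1.
#' @param n_bins Number of stratification bins (deciles by default).
#' @param seed Random seed; the assignment is reproducible.
#' @return `pairs` with its `split` column set to
#'   `"train"`/`"val"`/`"test"`.
#' @export
stratified_split <- function(pairs, fractions = c(0.8, 0.1, 0.1),
                             n_bins = 10L, seed = 42L) {
  if (nrow(pairs) == 0L)
    drp_abort("cannot split an empty dataset", "drp_data_error")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    drp_abort("fractions must be three numbers summing to 1",
              "drp_config_error")
  n <- nrow(pairs)
  y <- pairs$ln_ic50
  labels <- c("train", "val", "test")

  # exact global targets by largest remainder
  raw <- n * fractions
  target <- floor(raw)
  rem <- n - sum(target)
  if (rem > 0) {
    ord <- order(raw - target, decreasing = TRUE)
    target[ord[seq_len(rem)]] <- target[ord[seq_len(rem)]] + 1L
  }

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
      globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }

  split <- character(n)
  withr_seed({
    if (n < n_bins) {
      rlang::warn("fewer records than bins; falling back to unstratified split")
      bins <- rep(1L, n)
    } else {
      breaks <- unique(stats::quantile(y, probs = seq(0, 1,
                                                      length.out = n_bins + 1)))
      bins <- if (length(breaks) < 3L) rep(1L, n) else
        cut(y, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    }
    carry <- numeric(3)
    for (b in sort(unique(bins))) {
      idx <- sample(which(bins == b))
      nb <- length(idx)
      ideal <- nb * fractions + carry
      take <- floor(ideal)
      extra <- nb - sum(take)
      if (extra > 0) {
        ordb <- order(ideal - take, decreasing = TRUE)
        take[ordb[seq_len(extra)]] <- take[ordb[seq_len(extra)]] + 1L
      }
      carry <- ideal - take
      split[idx] <- rep(labels, times = take)
    }
    # correct residual drift so global sizes match targets exactly
    counts <- vapply(labels, function(s) sum(split == s), integer(1))
    while (any(counts != target)) {
      from <- labels[which(counts > target)[1]]
      to <- labels[which(counts < target)[1]]
      mv <- sample(which(split == from), 1L)
      split[mv] <- to
      counts[from] <- counts[from] - 1L
      counts[to] <- counts[to] + 1L
    }
  })
  pairs$split <- split
  pairs
}
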