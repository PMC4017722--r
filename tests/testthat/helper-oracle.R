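# Independent brute-force recomputations used as oracles. Written with
# explicit loops and bitmask subset enumeration, sharing no code with the
# package implementation.

# every non-empty subset of labels, as a list of character vectors
brute_subsets <- function(labels) {
  m <- length(labels)
  out <- list()
  for (mask in 1:(2^m - 1)) {
    members <- character(0)
    for (k in 1:m) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0) {
        members <- c(members, labels[k])
      }
    }
    out[[length(out) + 1]] <- members
  }
  out
}

# correlation of every subset's mean-log combination, keyed by sorted label
brute_leaderboard <- function(data, systems, truth = "ic50_nM") {
  y <- log10(data[[truth]])
  res <- numeric(0)
  for (members in brute_subsets(systems)) {
    combined <- numeric(nrow(data))
    for (i in seq_len(nrow(data))) {
      acc <- 0
      for (s in members) acc <- acc + log10(data[[s]][i])
      combined[i] <- acc / length(members)
    }
    key <- paste(sort(members), collapse = "+")
    res[key] <- stats::cor(combined, y)
  }
  res
}

# a small wide activity table with m noisy prediction systems
toy_study <- function(n = 12, m = 3, seed = 99, noise = 0.4) {
  set.seed(seed)
  truth <- runif(n, 0.5, 4.5)
  out <- tibble::tibble(id = sprintf("CPD%03d", seq_len(n)),
                        ic50_nM = 10^truth)
  for (k in seq_len(m)) {
    out[[paste0("S", k)]] <- 10^(truth + rnorm(n, sd = noise))
  }
  out
}
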