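# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Brute-force nearest-neighbour linker: same contract as
# link_localizations (radius, gap-free, greedy ascending distance,
# ties by lower track id then row index) but written as a naive
# repeat-min over the full distance matrix.
oracle_link <- function(locs, radius = 0.32) {
  n <- nrow(locs)
  id <- integer(n)
  nxt <- 1L
  frames <- sort(unique(locs$frame))
  prev <- integer(0)
  for (f in frames) {
    cur <- which(locs$frame == f)
    taken_prev <- rep(FALSE, length(prev))
    taken_cur <- rep(FALSE, length(cur))
    if (length(prev) && any(locs$frame[prev] == f - 1)) {
      repeat {
        best <- NULL
        for (i in seq_along(prev)) {
          if (taken_prev[i]) next
          for (j in seq_along(cur)) {
            if (taken_cur[j]) next
            d <- sqrt((locs$x_um[prev[i]] - locs$x_um[cur[j]])^2 +
                      (locs$y_um[prev[i]] - locs$y_um[cur[j]])^2)
            if (d <= radius) {
              key <- c(d, id[prev[i]], j)
              if (is.null(best) ||
                  key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2]) ||
                  (key[1] == best$key[1] && key[2] == best$key[2] &&
                   key[3] < best$key[3])) {
                best <- list(i = i, j = j, key = key)
              }
            }
          }
        }
        if (is.null(best)) break
        id[cur[best$j]] <- id[prev[best$i]]
        taken_prev[best$i] <- TRUE
        taken_cur[best$j] <- TRUE
      }
    }
    for (j in seq_along(cur)) {
      if (!taken_cur[j]) {
        id[cur[j]] <- nxt
        nxt <- nxt + 1L
      }
    }
    prev <- cur
  }
  id
}

# Analytic survival of a two-population exponential mixture.
mixture_survival <- function(t, k1, k2, f1) {
  f1 * exp(-k1 * t) + (1 - f1) * exp(-k2 * t)
}

# Kolmogorov-Smirnov distance of a sample against a survival function.
ks_distance <- function(x, survival_fun) {
  x <- sort(x)
  n <- length(x)
  s_emp_hi <- 1 - (seq_len(n) - 1) / n
  s_emp_lo <- 1 - seq_len(n) / n
  s_true <- survival_fun(x)
  max(abs(s_true - s_emp_hi), abs(s_true - s_emp_lo))
}

# A partition-equality check that ignores label values.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
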