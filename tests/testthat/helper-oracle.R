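# Independent brute-force oracles for the segmentation module, plus small
# fixture builders shared across test files.

# exhaustive arc search with direct per-arc mean/variance computation
oracle_max_arc <- function(x) {
  n <- length(x)
  q_tot <- sum(x^2)
  var_eps <- 1e-12 * max(1, q_tot)
  best <- list(i = 0L, j = 1L, statistic = 0)
  best_abs <- -1
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      if (i == 0 && j == n) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      m1 <- mean(arc); m2 <- mean(comp)
      ss <- sum((arc - m1)^2) + sum((comp - m2)^2)
      if (n <= 2 || ss <= var_eps) {
        sc <- max(1, abs(m1), abs(m2))
        t <- if (abs(m1 - m2) <= 1e-9 * sc) 0 else sign(m1 - m2) * Inf
      } else {
        t <- (m1 - m2) /
          sqrt(ss / (n - 2) * (1 / length(arc) + 1 / length(comp)))
      }
      if (abs(t) > best_abs) {
        best_abs <- abs(t)
        best <- list(i = i, j = j, statistic = t)
      }
    }
  }
  best
}

# Fisher-Yates shuffle consuming the same uniforms as the package kernel
oracle_shuffle <- function(x) {
  n <- length(x)
  for (k in n:2) {
    idx <- floor(runif(1) * k) + 1
    if (idx > k) idx <- k
    tmp <- x[k]; x[k] <- x[idx]; x[idx] <- tmp
  }
  x
}

oracle_perm_pvalue <- function(x, observed_abs, nperm, seed) {
  count <- withr::with_seed(seed, {
    cnt <- 0
    for (p in seq_len(nperm)) {
      m <- abs(oracle_max_arc(oracle_shuffle(x))$statistic)
      if (m >= observed_abs) cnt <- cnt + 1
    }
    cnt
  })
  (1 + count) / (1 + nperm)
}

oracle_derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  s <- 0
  for (p in parts)
    s <- (s * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(s %% 2147483646) + 1L
}

# recursive CBS oracle mirroring the published node-seeding convention;
# returns segment end indices (1-based inclusive, local coordinates)
oracle_segment <- function(values, alpha, nperm, min_width, seed,
                           offset = 0L) {
  n <- length(values)
  if (n < 2 || n < 2 * min_width) return(n)
  arc <- oracle_max_arc(values)
  node_seed <- oracle_derive_seed(seed, offset + arc$i, offset + arc$j, n)
  p <- oracle_perm_pvalue(values, abs(arc$statistic), nperm, node_seed)
  if (p >= alpha) return(n)
  cuts <- sort(unique(c(arc$i, arc$j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(n)
  bounds <- c(0L, cuts, n)
  if (any(diff(bounds) < min_width)) return(n)
  ends <- integer(0)
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1]
    child <- oracle_segment(values[lo:hi], alpha, nperm, min_width, seed,
                            offset = offset + bounds[k])
    ends <- c(ends, bounds[k] + child)
  }
  ends
}

# wrap a plain numeric vector as a single-contig ratio track
make_track <- function(values, contig = "chr1", bin_size = 1000,
                       mask = rep(TRUE, length(values))) {
  n <- length(values)
  bins <- data.frame(contig = contig, start = (0:(n - 1)) * bin_size,
                     end = (1:n) * bin_size, stringsAsFactors = FALSE)
  structure(list(bins = bins, control_median_rpkm = rep(1, n),
                 log2_ratio = values, mask = mask, sample_id = "test"),
            class = "ratio_track")
}

# the 100-bin engineered-deletion scenario: baseline 0 with SD-0.1 noise,
# bins 41..60 shifted to -1
deletion_scenario <- function(seed) {
  withr::with_seed(seed, {
    v <- rnorm(100, 0, 0.1)
    v[41:60] <- v[41:60] - 1
    v
  })
}
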