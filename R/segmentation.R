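#' Circular binary segmentation parameters
#'
#' @param alpha Significance level for a split (default 0.01).
#' @param nperm Number of permutations for the reference distribution
#'   (default 10000; tests and drivers may lower it).
#' @param min_width Minimum number of bins in any emitted child segment
#'   (default 2).
#' @param seed Integer seed. Each candidate split derives its own
#'   permutation seed from this seed and the split's boundaries, so
#'   p-values are intrinsic to the node, reproducible, and independent of
#'   recursion order.
#' @param undo_sd Optional merge threshold: adjacent segments whose mean
#'   difference is below `undo_sd` residual standard deviations are
#'   merged after segmentation. `NULL` (default) disables merging.
#' @return An object of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, nperm = 10000, min_width = 2,
                       seed = 1L, undo_sd = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nperm < 100) stop("nperm must be >= 100")
  if (min_width < 1) stop("min_width must be >= 1")
  structure(list(alpha = alpha, nperm = as.integer(nperm),
                 min_width = as.integer(min_width), seed = as.integer(seed),
                 undo_sd = undo_sd),
            class = "cbs_params")
}

#' Maximal arc t statistic
#'
#' Treats the sequence as a circle and finds the arc `(i, j)`
#' (0-based half-open: elements `(i+1):j` in 1-based R indexing) that
#' maximises the absolute pooled-variance two-sample t statistic of the
#' arc against its complement. The full-circle arc is excluded. Ties are
#' broken by smallest `i`, then smallest `j`. With zero pooled variance
#' the statistic is 0 for equal means and +/-Inf otherwise.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `i`, `j` and `statistic`.
#' @export
max_arc_statistic <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  max_arc_stat_cpp(as.numeric(values))
}

#' Permutation p-value for an observed max-arc statistic
#'
#' `p = (1 + #\{permutations with max |t| >= |observed|\}) / (1 + nperm)`,
#' permuting the values of the sequence under test.
#'
#' @param values Numeric vector the statistic was computed on.
#' @param observed_t Observed (signed) statistic.
#' @param params A [cbs_params()]; `params$seed` pins the permutations.
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(values, observed_t, params = cbs_params()) {
  obs <- abs(observed_t)
  count <- withr::with_seed(params$seed,
    perm_count_geq_cpp(as.numeric(values), obs, params$nperm))
  (1 + count) / (1 + params$nperm)
}

# recursive splitter on a numeric vector; returns integer vector of
# segment end indices (1-based, inclusive) in local coordinates
cbs_split <- function(values, params, offset = 0L) {
  n <- length(values)
  if (n < 2 || n < 2 * params$min_width) return(n)
  arc <- max_arc_statistic(values)
  node_params <- params
  node_params$seed <- derive_seed(params$seed, offset + arc$i, offset + arc$j, n)
  p <- permutation_pvalue(values, arc$statistic, node_params)
  if (p >= params$alpha) return(n)
  cuts <- sort(unique(c(arc$i, arc$j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(n)
  bounds <- c(0L, cuts, n)
  widths <- diff(bounds)
  if (any(widths < params$min_width)) return(n)
  ends <- integer(0)
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1]
    child <- cbs_split(values[lo:hi], params, offset = offset + bounds[k])
    ends <- c(ends, bounds[k] + child)
  }
  ends
}

# iterative undo-merge of adjacent segments closer than undo_sd residual SDs
cbs_undo <- function(values, ends, undo_sd) {
  repeat {
    if (length(ends) < 2) return(ends)
    starts <- c(1L, head(ends, -1) + 1L)
    means <- mapply(function(a, b) mean(values[a:b]), starts, ends)
    resid <- values - rep(means, ends - starts + 1L)
    rsd <- stats::sd(resid)
    if (!is.finite(rsd) || rsd == 0) rsd <- .Machine$double.eps
    gaps <- abs(diff(means))
    if (all(gaps >= undo_sd * rsd)) return(ends)
    drop <- which.min(gaps)        # merge the closest adjacent pair
    ends <- ends[-drop]
  }
}

#' Segment a log2-ratio track by circular binary segmentation
#'
#' Operates per contig on masked-in bins only. Recursively finds the
#' maximal arc, tests it by permutation, and splits into two (boundary
#' arc) or three (interior arc) children while the split is significant
#' and every child has at least `min_width` bins. Genomic coordinates of
#' a segment span from its first to its last member bin; gaps over
#' masked-out bins are absorbed.
#'
#' @param track A [build_ratio_track()] result.
#' @param params A [cbs_params()].
#' @return Data frame of segments: `contig`, `start`, `end` (0-based
#'   half-open), `first_bin`, `last_bin` (1-based indices into the
#'   contig's masked-in bin sequence), `n_bins`, `mean_log2_ratio`.
#' @export
segment_track <- function(track, params = cbs_params()) {
  out <- list()
  for (ctg in unique(track$bins$contig)) {
    sel <- which(track$bins$contig == ctg & track$mask)
    if (!length(sel)) next
    vals <- track$log2_ratio[sel]
    ends <- if (length(vals) == 1) 1L else cbs_split(vals, params)
    if (!is.null(params$undo_sd)) ends <- cbs_undo(vals, ends, params$undo_sd)
    starts <- c(1L, head(ends, -1) + 1L)
    out[[length(out) + 1]] <- data.frame(
      contig = ctg,
      start = track$bins$start[sel[starts]],
      end = track$bins$end[sel[ends]],
      first_bin = starts, last_bin = ends,
      n_bins = ends - starts + 1L,
      mean_log2_ratio = mapply(function(a, b) mean(vals[a:b]), starts, ends),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), first_bin = integer(),
                      last_bin = integer(), n_bins = integer(),
                      mean_log2_ratio = numeric()))
  }
  do.call(rbind, out)
}

#' Write segments as TSV (or SEG-like with a sample column)
#' @param segments Segment data frame from [segment_track()].
#' @param path Output path.
#' @param sample_id Optional sample id prepended as a first column.
#' @export
write_segments <- function(segments, path, sample_id = NULL) {
  df <- segments[, c("contig", "start", "end", "n_bins", "mean_log2_ratio")]
  if (!is.null(sample_id)) df <- cbind(sample = sample_id, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
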