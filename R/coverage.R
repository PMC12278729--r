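#' Partition contigs into fixed-width genomic bins
#'
#' Tiles each contig with non-overlapping bins of `bin_size` base pairs
#' (0-based, half-open coordinates). The last bin of a contig may be
#' shorter. Bins are ordered by the contig order given, then by start.
#'
#' @param contig_lengths Named numeric vector of contig lengths in bp.
#' @param bin_size Bin width in bp (default 1000).
#' @return A data frame with columns `contig`, `start`, `end`.
#' @examples
#' bin_genome(c(chr1 = 2500), bin_size = 1000)
#' @export
bin_genome <- function(contig_lengths, bin_size = 1000) {
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be a named vector")
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (any(contig_lengths < 1))
    stop("contig lengths must be >= 1 (offending: ",
         paste(names(contig_lengths)[contig_lengths < 1], collapse = ", "), ")")
  pieces <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(contig = ctg, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[i] = counts[i] * 1e9 / (width[i] * total_mapped_reads)`.
#'
#' @param counts Non-negative integer read counts per bin.
#' @param bins Bin data frame from [bin_genome()].
#' @param total_mapped_reads Total mapped reads of the sample (> 0).
#' @return Numeric vector of per-bin RPKM values.
#' @export
compute_rpkm <- function(counts, bins, total_mapped_reads) {
  if (length(counts) != nrow(bins))
    stop("counts length (", length(counts), ") does not match bins (",
         nrow(bins), ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  width <- bins$end - bins$start
  counts * 1e9 / (width * total_mapped_reads)
}

#' Per-sample binned coverage profile
#'
#' Bundles a sample's per-bin read counts with the bin definitions and
#' the RPKM normalisation.
#'
#' @param sample_id Sample identifier.
#' @param bins Bin data frame from [bin_genome()].
#' @param counts Per-bin read counts.
#' @param total_mapped_reads Total mapped reads; defaults to `sum(counts)`.
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(sample_id, bins, counts,
                             total_mapped_reads = sum(counts)) {
  rpkm <- compute_rpkm(counts, bins, total_mapped_reads)
  structure(list(sample_id = sample_id, bins = bins,
                 counts = as.numeric(counts),
                 total_mapped_reads = total_mapped_reads, rpkm = rpkm),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$sample_id, "-", nrow(x$bins), "bins,",
      format(x$total_mapped_reads, big.mark = ","), "mapped reads\n")
  invisible(x)
}

#' Test-versus-median-of-controls log2 ratio track
#'
#' For each bin, takes the median control RPKM and the log2 ratio of the
#' test sample against it. Bins whose control median is at or below
#' `epsilon` are masked out (no ratio defined); masked-in bins where the
#' test RPKM is zero get the floor value `zero_log2` instead of -Inf.
#'
#' @param test A [coverage_profile()] for the test sample.
#' @param controls List of [coverage_profile()] objects (>= 2; the study
#'   design uses a panel of four genomes of similar depth).
#' @param epsilon Control-median RPKM at or below which a bin is masked
#'   (default 0.1).
#' @param zero_log2 Floor log2 ratio for masked-in bins with zero test
#'   RPKM (default -5).
#' @return An object of class `ratio_track` with elements `bins`,
#'   `control_median_rpkm`, `log2_ratio` (NA where masked) and `mask`.
#' @export
build_ratio_track <- function(test, controls, epsilon = 0.1, zero_log2 = -5) {
  if (length(controls) < 2) stop("need at least 2 control profiles")
  for (ctl in controls) {
    same <- identical(dim(ctl$bins), dim(test$bins)) &&
      all(ctl$bins$contig == test$bins$contig) &&
      all(ctl$bins$start == test$bins$start) &&
      all(ctl$bins$end == test$bins$end)
    if (!same) {
      bad <- which(ctl$bins$contig != test$bins$contig |
                     ctl$bins$start != test$bins$start |
                     ctl$bins$end != test$bins$end)[1]
      stop("control '", ctl$sample_id, "' bin list differs from test",
           if (!is.na(bad)) paste0(" (first discrepancy at bin ", bad, ")"))
    }
  }
  ctl_mat <- vapply(controls, function(p) p$rpkm, numeric(nrow(test$bins)))
  med <- apply(ctl_mat, 1, median)
  mask <- med > epsilon
  ratio <- rep(NA_real_, length(med))
  ok <- mask & test$rpkm > 0
  ratio[ok] <- log2(test$rpkm[ok] / med[ok])
  ratio[mask & test$rpkm == 0] <- zero_log2
  structure(list(bins = test$bins, control_median_rpkm = med,
                 log2_ratio = ratio, mask = mask,
                 sample_id = test$sample_id),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat("ratio_track:", x$sample_id %||% "?", "-", nrow(x$bins), "bins,",
      sum(x$mask), "masked-in\n")
  invisible(x)
}

#' Read per-sample bin counts from TSV
#'
#' Expects columns contig, start, end, count (0-based half-open), with or
#' without a header line.
#'
#' @param path File path.
#' @return Data frame with columns `contig`, `start`, `end`, `count`.
#' @export
read_bin_counts <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("contig|chrom", first, ignore.case = TRUE)
  df <- read.table(path, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df)[1:4] <- c("contig", "start", "end", "count")
  df
}

#' Write per-sample bin counts as TSV
#' @param profile A [coverage_profile()].
#' @param path Output path.
#' @export
write_bin_counts <- function(profile, path) {
  df <- data.frame(contig = profile$bins$contig, start = profile$bins$start,
                   end = profile$bins$end, count = profile$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read contig lengths from a FASTA index (.fai)
#' @param path Path to a `.fai` file (name, length in first two columns).
#' @return Named numeric vector of contig lengths.
#' @export
read_fai <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

#' Write a ratio track as bedGraph plus a mask BED
#'
#' @param track A [build_ratio_track()] result.
#' @param bedgraph_path Output bedGraph (masked-in bins only).
#' @param mask_bed_path Optional BED of masked-out bins.
#' @export
write_ratio_bedgraph <- function(track, bedgraph_path, mask_bed_path = NULL) {
  keep <- track$mask
  df <- data.frame(track$bins[keep, c("contig", "start", "end")],
                   log2_ratio = track$log2_ratio[keep])
  write.table(df, bedgraph_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(mask_bed_path)) {
    out <- track$bins[!keep, c("contig", "start", "end")]
    write.table(out, mask_bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(bedgraph_path)
}
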