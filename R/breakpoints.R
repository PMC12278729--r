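#' Synthetic reference locus carrying an engineered deletion
#'
#' Generates a random-sequence locus around a deletion given in absolute
#' genomic coordinates; the sequence is stored with an offset so only the
#' locus needs to exist. Flanking bases are fixed up so the engineered
#' placement is the left-aligned representative and the junction carries
#' exactly `microhomology` identical bases on both flanks.
#'
#' @param contig Contig name.
#' @param first,last First and last deleted base (1-based inclusive).
#' @param flank Flank length in bp on each side (default 3000).
#' @param microhomology Engineered microhomology length in bp (default 0).
#' @param seed Integer seed.
#' @return An object of class `synthetic_locus`: `contig`, `offset`
#'   (genomic position of the first stored base), `seq` (character
#'   string), `deletion = c(first, last)`.
#' @export
make_deletion_locus <- function(contig = "chr2", first = 55556194,
                                last = 55565990, flank = 3000,
                                microhomology = 0, seed = 1L) {
  if (first > last) stop("first must be <= last")
  if (flank <= microhomology + 10) stop("flank too small")
  offset <- first - flank
  n <- (last + flank) - offset + 1
  withr::with_seed(seed, {
    s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    at <- function(pos) pos - offset + 1          # genomic -> local
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    m <- microhomology
    if (m > 0)                                     # plant the homology
      s[at(last + 1):(at(last + m))] <- s[at(first):(at(first + m - 1))]
    # block further right shifts and any left shift
    if (s[at(first + m)] == s[at(last + 1 + m)])
      s[at(last + 1 + m)] <- other(s[at(first + m)])
    if (s[at(first - 1)] == s[at(last)])
      s[at(last)] <- other(s[at(first - 1)])
    structure(list(contig = contig, offset = offset,
                   seq = paste(s, collapse = ""),
                   deletion = c(first = first, last = last)),
              class = "synthetic_locus")
  })
}

# genomic-coordinate substring of a locus sequence
locus_seq <- function(locus, from, to) {
  substr(locus$seq, from - locus$offset + 1, to - locus$offset + 1)
}

#' Simulate breakpoint-spanning reads over an engineered deletion
#'
#' Draws reads from both haplotypes of a heterozygous deletion locus
#' (jittered stratified start positions, so coverage is near-uniform).
#' Reads from the deleted haplotype that span the junction are emitted
#' the way an aligner reports them: the longer portion is anchored
#' (ties go to the prefix) and the shorter portion is soft-clipped, with
#' clip length equal to the read's overhang past the junction.
#'
#' @param locus A [make_deletion_locus()].
#' @param depth Total fold coverage of the diploid locus (> 0); each
#'   haplotype contributes half.
#' @param read_length Read length in bp (must be shorter than the flank).
#' @param seed Integer seed.
#' @return Data frame of aligned-read records: `qname`, `flag`,
#'   `contig`, `pos` (1-based leftmost aligned base), `mapq`, `cigar`,
#'   `seq`.
#' @export
simulate_breakpoint_reads <- function(locus, depth = 30, read_length = 150,
                                      seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  first <- locus$deletion[["first"]]; last <- locus$deletion[["last"]]
  if (read_length >= first - locus$offset)
    stop("read_length must be shorter than the flank")
  ref_len <- nchar(locus$seq)
  del_hap <- paste0(locus_seq(locus, locus$offset, first - 1),
                    locus_seq(locus, last + 1, locus$offset + ref_len - 1))
  junction_local <- first - locus$offset      # bases before the junction
  rl <- read_length
  withr::with_seed(seed, {
    strat_starts <- function(hap_len, n) {
      spacing <- (hap_len - rl) / n
      pmax(1, pmin(hap_len - rl + 1,
                   floor(seq(0, by = spacing, length.out = n) +
                           runif(n, 0, spacing)) + 1))
    }
    # reference haplotype: plain full-length matches
    n_ref <- max(1, round(depth / 2 * ref_len / rl))
    st_r <- strat_starts(ref_len, n_ref)
    ref_df <- data.frame(
      qname = sprintf("ref_%06d", seq_along(st_r)), flag = 0L,
      contig = locus$contig, pos = locus$offset + st_r - 1, mapq = 60L,
      cigar = paste0(rl, "M"),
      seq = substring(locus$seq, st_r, st_r + rl - 1),
      stringsAsFactors = FALSE)
    # deleted haplotype: junction-spanning reads get the longer portion
    # anchored and the shorter soft-clipped
    del_len <- nchar(del_hap)
    n_del <- max(1, round(depth / 2 * del_len / rl))
    st_d <- strat_starts(del_len, n_del)
    pre <- junction_local - st_d + 1   # read bases before the junction
    full_right <- pre <= 0
    full_left <- pre >= rl
    anchor_pre <- !full_right & !full_left & pre >= rl - pre
    anchor_suf <- !full_right & !full_left & !anchor_pre
    pos <- ifelse(full_right, last + (st_d - junction_local),
           ifelse(anchor_suf, last + 1, locus$offset + st_d - 1))
    cigar <- rep(paste0(rl, "M"), n_del)
    cigar[anchor_pre] <- paste0(pre[anchor_pre], "M",
                                rl - pre[anchor_pre], "S")
    cigar[anchor_suf] <- paste0(pre[anchor_suf], "S",
                                rl - pre[anchor_suf], "M")
    del_df <- data.frame(
      qname = sprintf("del_%06d", seq_along(st_d)), flag = 0L,
      contig = locus$contig, pos = pos, mapq = 60L, cigar = cigar,
      seq = substring(del_hap, st_d, st_d + rl - 1),
      stringsAsFactors = FALSE)
    rbind(ref_df, del_df)
  })
}

#' Write aligned-read records as a minimal SAM file
#' @param reads Read data frame from [simulate_breakpoint_reads()].
#' @param path Output path.
#' @param contig_lengths Named vector for the `@SQ` header lines.
#' @export
write_sam <- function(reads, path, contig_lengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                          as.integer(contig_lengths)))
  rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$contig,
                  as.integer(reads$pos), reads$mapq, reads$cigar, reads$seq)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

cigar_lengths <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  setNames(as.integer(sub("[A-Z=]$", "", ops)), sub("^\\d+", "", ops))
}

#' Collect soft-clip clusters from aligned reads
#'
#' Scans read CIGARs for leading/trailing soft clips of at least
#' `min_clip` bases, assigns each clip the 1-based reference base
#' adjacent to the clipped side (for a right clip, one past the last
#' aligned base; for a left clip, one before the first aligned base) and
#' groups clips by (contig, position, side). The clipped consensus is a
#' per-position majority vote anchored at the clip boundary. Reads
#' without a usable CIGAR are skipped with a counted warning.
#'
#' @param reads Read data frame (`contig`, `pos`, `cigar`, `seq`).
#' @param region Optional `c(start, end)` filter (1-based inclusive).
#' @param min_clip Minimum clip length in bp (>= 5).
#' @param pad Padding around `region` in bp (default 2000, bin-resolution
#'   slack around a segment boundary).
#' @return Data frame of clusters sorted by support (descending) then
#'   position: `contig`, `clip_position`, `side`
#'   (`"left"`/`"right"`), `support`, `clipped_consensus`.
#' @export
collect_split_reads <- function(reads, region = NULL, min_clip = 5,
                                pad = 2000) {
  if (min_clip < 5) stop("min_clip must be >= 5")
  skipped <- 0
  clips <- list()
  for (k in seq_len(nrow(reads))) {
    cig <- reads$cigar[k]
    if (is.na(cig) || cig == "" || cig == "*") { skipped <- skipped + 1; next }
    lens <- cigar_lengths(cig)
    ref_span <- sum(lens[names(lens) %in% c("M", "D", "N", "=", "X")])
    nops <- length(lens)
    if (names(lens)[1] == "S" && lens[1] >= min_clip) {
      clips[[length(clips) + 1]] <- data.frame(
        contig = reads$contig[k], clip_position = reads$pos[k] - 1,
        side = "left", clipped_seq = substr(reads$seq[k], 1, lens[1]),
        stringsAsFactors = FALSE)
    }
    if (names(lens)[nops] == "S" && lens[nops] >= min_clip) {
      nc <- nchar(reads$seq[k])
      clips[[length(clips) + 1]] <- data.frame(
        contig = reads$contig[k],
        clip_position = reads$pos[k] + ref_span,
        side = "right",
        clipped_seq = substr(reads$seq[k], nc - lens[nops] + 1, nc),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " read(s) without a usable CIGAR were skipped")
  if (!length(clips))
    return(data.frame(contig = character(), clip_position = numeric(),
                      side = character(), support = integer(),
                      clipped_consensus = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, clips)
  if (!is.null(region))
    df <- df[df$clip_position >= region[1] - pad &
               df$clip_position <= region[2] + pad, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(contig = character(), clip_position = numeric(),
                      side = character(), support = integer(),
                      clipped_consensus = character(),
                      stringsAsFactors = FALSE))
  key <- paste(df$contig, df$clip_position, df$side)
  groups <- split(df, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(contig = g$contig[1], clip_position = g$clip_position[1],
               side = g$side[1], support = nrow(g),
               clipped_consensus = clip_consensus(g$clipped_seq, g$side[1]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$support, out$clip_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# majority-vote consensus; right clips share their left edge (the clip
# boundary), left clips share their right edge
clip_consensus <- function(seqs, side) {
  if (length(seqs) == 1) return(seqs)
  if (side == "left") {
    rev_str <- function(x) vapply(x, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")
    return(rev_str(clip_consensus(rev_str(seqs), "right")))
  }
  maxlen <- max(nchar(seqs))
  cons <- vapply(seq_len(maxlen), function(i) {
    b <- substr(seqs, i, i)
    b <- b[nzchar(b)]
    names(sort(table(b), decreasing = TRUE))[1]
  }, "")
  paste(cons, collapse = "")
}

match_with_tolerance <- function(a, b) {
  # <= 1 mismatch allowed per full 20 bp of compared length
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(FALSE)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  sum(av != bv) <= n %/% 20
}

insufficient_evidence <- function(reason) {
  structure(list(status = "insufficient_split_read_evidence",
                 reason = reason), class = "breakpoint_pair")
}

#' Refine deletion breakpoints from split-read clusters
#'
#' Pairs the best-supported right-clip cluster (candidate left
#' breakpoint) with the best-supported left-clip cluster (candidate
#' right breakpoint), requires each clipped consensus to map across the
#' junction to the mate locus (exact match with one mismatch tolerated
#' per 20 bp), left-aligns the deletion through any breakpoint-flank
#' microhomology, and reports the refined pair. `size_reported` follows
#' the last-minus-first convention; the inclusive span is one larger and
#' is also emitted.
#'
#' @param clusters Cluster data frame from [collect_split_reads()].
#' @param reference A [make_deletion_locus()]-style locus (`seq` +
#'   `offset`) giving reference sequence access.
#' @param min_support Minimum cluster support (default 3).
#' @return An object of class `breakpoint_pair`; on missing evidence an
#'   object with `status = "insufficient_split_read_evidence"` (distinct
#'   from a malformed-input error).
#' @export
refine_breakpoints <- function(clusters, reference, min_support = 3) {
  if (!is.data.frame(clusters)) stop("clusters must be a data frame")
  rc <- clusters[clusters$side == "right" & clusters$support >= min_support, ,
                 drop = FALSE]
  lc <- clusters[clusters$side == "left" & clusters$support >= min_support, ,
                 drop = FALSE]
  if (!nrow(rc) || !nrow(lc))
    return(insufficient_evidence("need both a right- and a left-clipped cluster"))
  best_r <- rc[1, ]; best_l <- lc[1, ]
  first <- best_r$clip_position       # first deleted base
  last <- best_l$clip_position        # last deleted base
  if (first > last)
    return(insufficient_evidence("clip clusters are not in deletion orientation"))
  # cross-map: right-clip consensus continues at last+1; left-clip
  # consensus ends at first-1
  r_cons <- best_r$clipped_consensus
  l_cons <- best_l$clipped_consensus
  mate_r <- locus_seq(reference, last + 1, last + nchar(r_cons))
  mate_l <- locus_seq(reference, first - nchar(l_cons), first - 1)
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  if (!match_with_tolerance(r_cons, mate_r) ||
      !match_with_tolerance(rev1(l_cons), rev1(mate_l)))
    return(insufficient_evidence("clipped consensus does not map across the junction"))
  base <- function(pos) locus_seq(reference, pos, pos)
  lo_bound <- reference$offset + 1
  while (first > lo_bound && base(first - 1) == base(last)) {
    first <- first - 1; last <- last - 1
  }
  hi_bound <- reference$offset + nchar(reference$seq) - 1
  mh <- 0
  while (last + 1 + mh <= hi_bound && first + mh <= hi_bound &&
         base(first + mh) == base(last + 1 + mh)) mh <- mh + 1
  structure(list(status = "ok", contig = best_r$contig,
                 first_deleted = first, last_deleted = last,
                 size_reported = last - first,
                 span_inclusive = last - first + 1,
                 hgvs_g = sprintf("g.%d_%ddel", first, last),
                 microhomology_len = mh,
                 support_right_clip = best_r$support,
                 support_left_clip = best_l$support),
            class = "breakpoint_pair")
}

#' @export
print.breakpoint_pair <- function(x, ...) {
  if (x$status != "ok") {
    cat("breakpoint_pair: insufficient split-read evidence (",
        x$reason, ")\n", sep = "")
  } else {
    cat("breakpoint_pair:", x$contig, x$hgvs_g, "- size", x$size_reported,
        "bp (inclusive span", x$span_inclusive, "bp), microhomology",
        x$microhomology_len, "bp\n")
  }
  invisible(x)
}

#' Write a refined deletion as a precise VCF 4.2 record and TSV line
#'
#' @param bp A `breakpoint_pair` with status `"ok"`.
#' @param reference The locus used for refinement (for the anchor base).
#' @param vcf_path,tsv_path Output paths (either may be NULL).
#' @export
write_breakpoint_pair <- function(bp, reference, vcf_path = NULL,
                                  tsv_path = NULL) {
  stopifnot(bp$status == "ok")
  if (!is.null(vcf_path)) {
    anchor_pos <- bp$first_deleted - 1
    anchor <- locus_seq(reference, anchor_pos, anchor_pos)
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
             "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    row <- sprintf("%s\t%d\t.\t%s\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;HOMLEN=%d",
                   bp$contig, anchor_pos, anchor, bp$last_deleted,
                   bp$microhomology_len)
    writeLines(c(hdr, row), vcf_path)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(contig = bp$contig, hgvs_g = bp$hgvs_g,
                     size_reported = bp$size_reported,
                     span_inclusive = bp$span_inclusive,
                     microhomology_len = bp$microhomology_len,
                     support_right_clip = bp$support_right_clip,
                     support_left_clip = bp$support_left_clip)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bp)
}
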