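#' Filter-cascade configuration
#'
#' Houses the thresholds of the call cascade: calls shared between both
#' affected siblings are kept (>= `reciprocal_overlap_for_shared`
#' reciprocal overlap, same type), calls covered more than
#' `segdup_max_fraction` by segmental duplications are removed, deletions
#' showing internal heterozygous-SNV evidence without read-pair support
#' are rejected, and calls matching a population structural variant above
#' `pop_sv_maf_max` are removed.
#'
#' @param segdup_max_fraction Maximum tolerated segmental-duplication
#'   overlap fraction (default 0.5, i.e. the "> 50%" rule).
#' @param reciprocal_overlap_for_shared Reciprocal overlap required to
#'   call two siblings' calls the same event (default 0.5).
#' @param min_internal_het_snvs_to_reject Balanced heterozygous SNVs
#'   inside a deletion that, with no read-pair/clipped support, mark it a
#'   false positive (default 3).
#' @param het_balance Allele-balance window defining a "balanced" het
#'   SNV (default c(0.35, 0.65)).
#' @param pop_sv_maf_max Maximum population SV frequency (default 0.01).
#' @param het_del_max_log2 Segment mean at or below which a deletion is
#'   called (default -0.6).
#' @param hom_del_max_log2 Mean at or below which a deletion is called
#'   homozygous (default -2.5).
#' @param dup_min_log2 Mean at or above which a duplication is called
#'   (default 0.45).
#' @param min_call_bins Minimum bins per call (default 3).
#' @param autosomes_only Restrict calls to autosomes (default TRUE).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(segdup_max_fraction = 0.5,
                          reciprocal_overlap_for_shared = 0.5,
                          min_internal_het_snvs_to_reject = 3,
                          het_balance = c(0.35, 0.65),
                          pop_sv_maf_max = 0.01,
                          het_del_max_log2 = -0.6,
                          hom_del_max_log2 = -2.5,
                          dup_min_log2 = 0.45,
                          min_call_bins = 3,
                          autosomes_only = TRUE) {
  if (!(het_del_max_log2 < 0 && 0 < dup_min_log2))
    stop("het_del_max_log2 must be < 0 < dup_min_log2")
  structure(as.list(environment()), class = "filter_config")
}

calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$contig,
                         IRanges::IRanges(calls$start, calls$end))
}

bed_granges <- function(bed) {
  GenomicRanges::GRanges(bed$contig,
                         IRanges::IRanges(bed$start + 1, bed$end))
}

# put two GRanges on a shared seqlevel universe before overlap queries
harmonize_levels <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Read a BED(+) annotation track
#'
#' Columns: contig, start, end (0-based half-open), optional name,
#' optional score/MAF. Malformed records raise an error naming the line.
#'
#' @param path File path.
#' @param maf If `TRUE`, the 5th column is parsed as a population SV MAF.
#' @return Data frame with columns `contig`, `start`, `end`, and `name`
#'   / `maf` when present.
#' @export
read_bed <- function(path, maf = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t")
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 3 || is.na(suppressWarnings(as.numeric(p[2]))) ||
        is.na(suppressWarnings(as.numeric(p[3]))))
      stop("malformed BED record at line ", k, " of ", path)
  }
  df <- data.frame(contig = vapply(parts, `[`, "", 1),
                   start = as.numeric(vapply(parts, `[`, "", 2)),
                   end = as.numeric(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (any(lengths(parts) >= 4)) df$name <- vapply(parts, function(p)
    if (length(p) >= 4) p[4] else NA_character_, "")
  if (maf) {
    if (any(lengths(parts) < 5)) stop("population SV BED needs a 5th MAF column")
    df$maf <- as.numeric(vapply(parts, `[`, "", 5))
  }
  df
}

#' Convert CBS segments into typed CNV calls
#'
#' Segments with mean log2 ratio at or below `het_del_max_log2` become
#' deletions (homozygous at or below `hom_del_max_log2`), segments at or
#' above `dup_min_log2` become duplications; everything else emits no
#' call. Calls spanning fewer than `min_call_bins` bins are suppressed,
#' and non-autosomal contigs are dropped by default. Call coordinates
#' are 1-based inclusive.
#'
#' @param segments Segment data frame from [segment_track()].
#' @param config A [filter_config()].
#' @param sample_id Sample the segments belong to.
#' @return CNV call data frame.
#' @export
call_segments <- function(segments, config = filter_config(),
                          sample_id = NA_character_) {
  m <- segments$mean_log2_ratio
  is_del <- m <= config$het_del_max_log2
  is_dup <- m >= config$dup_min_log2
  keep <- (is_del | is_dup) & segments$n_bins >= config$min_call_bins
  if (config$autosomes_only) keep <- keep & is_autosome(segments$contig)
  seg <- segments[keep, , drop = FALSE]
  if (!nrow(seg)) return(empty_calls())
  data.frame(sample_id = sample_id,
             contig = seg$contig,
             start = seg$start + 1,   # 1-based inclusive
             end = seg$end,
             svtype = ifelse(seg$mean_log2_ratio <= config$het_del_max_log2,
                             "DEL", "DUP"),
             genotype_state = ifelse(
               seg$mean_log2_ratio <= config$hom_del_max_log2, "homozygous",
               "heterozygous"),
             mean_log2_ratio = seg$mean_log2_ratio,
             n_bins = seg$n_bins,
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(sample_id = character(), contig = character(),
             start = numeric(), end = numeric(), svtype = character(),
             genotype_state = character(), mean_log2_ratio = numeric(),
             n_bins = integer(), stringsAsFactors = FALSE)
}

#' Annotate CNV calls against BED tracks
#'
#' Adds the segmental-duplication overlap fraction (bases of the call
#' covered by the segdup union over call length), the highest population
#' SV frequency among population SVs with >= 50% reciprocal overlap, and
#' the panel genes / exons overlapped (comma-separated identifiers).
#' Re-annotating is idempotent.
#'
#' @param calls CNV call data frame (1-based inclusive coordinates).
#' @param segdups,panel,exons Data frames from [read_bed()] (may be NULL).
#' @param pop_sv Data frame from [read_bed()] with `maf` (may be NULL).
#' @param reciprocal Reciprocal-overlap fraction for population SV
#'   matching (default 0.5).
#' @return The calls with columns `segdup_overlap_fraction`,
#'   `pop_sv_maf`, `panel_genes`, `exons_overlapped` added.
#' @export
annotate_calls <- function(calls, segdups = NULL, panel = NULL,
                           exons = NULL, pop_sv = NULL, reciprocal = 0.5) {
  if (!nrow(calls)) {
    calls$segdup_overlap_fraction <- numeric(0)
    calls$pop_sv_maf <- numeric(0)
    calls$panel_genes <- character(0)
    calls$exons_overlapped <- character(0)
    return(calls)
  }
  gr <- calls_granges(calls)
  len <- calls$end - calls$start + 1

  calls$segdup_overlap_fraction <- 0
  if (!is.null(segdups) && nrow(segdups)) {
    h <- harmonize_levels(gr, GenomicRanges::reduce(bed_granges(segdups)))
    sd_gr <- h$b
    cov <- numeric(nrow(calls))
    hits <- GenomicRanges::findOverlaps(h$a, sd_gr)
    if (length(hits)) {
      inter <- IRanges::pintersect(h$a[S4Vectors::queryHits(hits)],
                                   sd_gr[S4Vectors::subjectHits(hits)])
      w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
      cov[as.integer(names(w))] <- w
    }
    calls$segdup_overlap_fraction <- cov / len
  }

  calls$pop_sv_maf <- NA_real_
  if (!is.null(pop_sv) && nrow(pop_sv)) {
    h <- harmonize_levels(gr, bed_granges(pop_sv))
    sv_gr <- h$b
    hits <- GenomicRanges::findOverlaps(h$a, sv_gr)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ow <- GenomicRanges::width(IRanges::pintersect(h$a[q], sv_gr[s]))
      rec <- pmin(ow / GenomicRanges::width(h$a[q]),
                  ow / GenomicRanges::width(sv_gr[s]))
      ok <- rec >= reciprocal
      if (any(ok)) {
        mx <- tapply(pop_sv$maf[s[ok]], q[ok], max)
        calls$pop_sv_maf[as.integer(names(mx))] <- mx
      }
    }
  }

  overlap_names <- function(track) {
    out <- rep(NA_character_, nrow(calls))
    if (is.null(track) || !nrow(track)) return(out)
    h <- harmonize_levels(gr, bed_granges(track))
    hits <- GenomicRanges::findOverlaps(h$a, h$b)
    if (length(hits)) {
      nm <- tapply(track$name[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits),
                   function(x) paste(sort(unique(x)), collapse = ","))
      out[as.integer(names(nm))] <- nm
    }
    out
  }
  calls$panel_genes <- overlap_names(panel)
  calls$exons_overlapped <- overlap_names(exons)
  calls
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

#' Keep calls shared between all affected siblings
#'
#' A call is shared iff every affected sibling carries a call of the same
#' type with at least `reciprocal_overlap_for_shared` reciprocal overlap.
#' Shared calls take the union region over the matched siblings' calls;
#' numeric evidence columns are combined conservatively (maximum SNV
#' count, any read support).
#'
#' @param calls Per-sample CNV call data frame (`sample_id` column).
#' @param pedigree Pedigree data frame with >= 2 affected members.
#' @param config A [filter_config()].
#' @return Data frame of shared calls with `shared_in_affected = TRUE`.
#' @export
shared_in_affected <- function(calls, pedigree, config = filter_config()) {
  affected <- pedigree$id[pedigree$affected]
  if (length(affected) < 2)
    stop("need at least 2 affected samples in the pedigree")
  first <- calls[calls$sample_id == affected[1], , drop = FALSE]
  others <- affected[-1]
  out <- list()
  for (k in seq_len(nrow(first))) {
    cl <- first[k, , drop = FALSE]
    matched <- list(cl)
    ok <- TRUE
    for (sib in others) {
      cand <- calls[calls$sample_id == sib & calls$svtype == cl$svtype &
                      calls$contig == cl$contig, , drop = FALSE]
      if (!nrow(cand)) { ok <- FALSE; break }
      rec <- reciprocal_overlap(cl$start, cl$end, cand$start, cand$end)
      if (max(rec) < config$reciprocal_overlap_for_shared) { ok <- FALSE; break }
      matched[[length(matched) + 1]] <- cand[which.max(rec), , drop = FALSE]
    }
    if (!ok) next
    all_m <- do.call(rbind, matched)
    cl$start <- min(all_m$start); cl$end <- max(all_m$end)
    cl$sample_id <- paste(affected, collapse = ",")
    cl$mean_log2_ratio <- mean(all_m$mean_log2_ratio)
    for (col in c("n_internal_het_snvs"))
      if (col %in% names(all_m)) cl[[col]] <- max(all_m[[col]])
    for (col in c("discordant_pair_support", "clipped_read_support"))
      if (col %in% names(all_m)) cl[[col]] <- any(all_m[[col]])
    out[[length(out) + 1]] <- cl
  }
  if (!length(out)) {
    res <- first[0, , drop = FALSE]
  } else {
    res <- do.call(rbind, out)
  }
  res$shared_in_affected <- rep(TRUE, nrow(res))
  res
}

#' Count balanced heterozygous SNVs inside each call
#'
#' @param calls CNV call data frame.
#' @param het_snvs Data frame with `contig`, `pos`, `allele_balance`.
#' @param config A [filter_config()] (supplies the balance window).
#' @return Integer vector, one count per call.
#' @export
count_internal_het_snvs <- function(calls, het_snvs,
                                    config = filter_config()) {
  lo <- config$het_balance[1]; hi <- config$het_balance[2]
  vapply(seq_len(nrow(calls)), function(k) {
    sum(het_snvs$contig == calls$contig[k] &
          het_snvs$pos >= calls$start[k] & het_snvs$pos <= calls$end[k] &
          het_snvs$allele_balance >= lo & het_snvs$allele_balance <= hi)
  }, integer(1))
}

#' Evidence review of deletion calls
#'
#' Automates the read-level review of candidate deletions: a deletion is
#' rejected as a false positive iff it contains at least
#' `min_internal_het_snvs_to_reject` balanced heterozygous SNVs AND shows
#' neither discordant-read-pair nor clipped-read support. Duplications
#' pass through with the stage recorded as not applicable.
#'
#' @param calls CNV call data frame carrying logical columns
#'   `discordant_pair_support` and `clipped_read_support`, and either a
#'   `n_internal_het_snvs` column or a `het_snvs` table to compute it.
#' @param config A [filter_config()].
#' @param het_snvs Optional data frame (`contig`, `pos`,
#'   `allele_balance`) used to (re)compute the internal SNV counts.
#' @return The calls with columns `n_internal_het_snvs` and
#'   `evidence_pass` added.
#' @export
evidence_filter <- function(calls, config = filter_config(),
                            het_snvs = NULL) {
  if (!is.null(het_snvs))
    calls$n_internal_het_snvs <- count_internal_het_snvs(calls, het_snvs,
                                                         config)
  if (is.null(calls$n_internal_het_snvs))
    stop("calls need n_internal_het_snvs (or pass het_snvs)")
  no_support <- !(calls$discordant_pair_support | calls$clipped_read_support)
  fail <- calls$svtype == "DEL" &
    calls$n_internal_het_snvs >= config$min_internal_het_snvs_to_reject &
    no_support
  calls$evidence_pass <- ifelse(calls$svtype == "DEL", !fail, NA)
  calls
}

record_stage <- function(status, stage, outcome) {
  if (!length(outcome)) return(character(0))
  paste0(status, ifelse(nzchar(status), ";", ""), stage, ":", outcome)
}

#' Run the full CNV filter cascade
#'
#' Stage order: (1) shared between all affected siblings, (2) segmental
#' duplication overlap > `segdup_max_fraction` removed, (3) evidence
#' review ([evidence_filter()]), (4) population SV frequency >
#' `pop_sv_maf_max` removed. Every input call receives a `filter_status`
#' string recording each stage outcome once, in cascade order; the
#' ledger counts calls entering and surviving each stage.
#'
#' @param calls Per-sample CNV call data frame (annotated or not; when
#'   `annotations` is given the shared calls are (re)annotated after
#'   stage 1).
#' @param pedigree Pedigree data frame.
#' @param config A [filter_config()].
#' @param annotations Optional list with elements `segdups`, `panel`,
#'   `exons`, `pop_sv` (data frames from [read_bed()]).
#' @param het_snvs Optional balanced-het SNV table for
#'   [evidence_filter()].
#' @return List with `final` (surviving calls), `calls` (all shared
#'   calls with per-stage provenance) and `ledger` (named stage counts).
#' @export
run_cascade <- function(calls, pedigree, config = filter_config(),
                        annotations = NULL, het_snvs = NULL) {
  ledger <- list(input_calls = nrow(calls))

  shared <- shared_in_affected(calls, pedigree, config)
  ledger$shared_in_affected <- nrow(shared)
  if (!is.null(annotations)) {
    shared <- annotate_calls(shared, segdups = annotations$segdups,
                             panel = annotations$panel,
                             exons = annotations$exons,
                             pop_sv = annotations$pop_sv)
  }
  if (is.null(shared$segdup_overlap_fraction))
    stop("shared calls must be annotated (pass `annotations`)")
  status <- rep("shared:pass", nrow(shared))

  segdup_ok <- shared$segdup_overlap_fraction <= config$segdup_max_fraction
  status <- record_stage(status, "segdup", ifelse(segdup_ok, "pass", "fail"))
  ledger$after_segdup_filter <- sum(segdup_ok)

  shared <- evidence_filter(shared, config, het_snvs = het_snvs)
  ev_ok <- is.na(shared$evidence_pass) | shared$evidence_pass
  ev_out <- ifelse(is.na(shared$evidence_pass), "na",
                   ifelse(shared$evidence_pass, "pass", "fail"))
  ev_out[!segdup_ok] <- "not_evaluated"
  status <- record_stage(status, "evidence", ev_out)
  ledger$entering_evidence_review <- sum(segdup_ok)
  ledger$evidence_rejected <- sum(segdup_ok & !ev_ok)
  ledger$to_split_read_analysis <- sum(segdup_ok & ev_ok)

  pop_ok <- is.na(shared$pop_sv_maf) | shared$pop_sv_maf <= config$pop_sv_maf_max
  pop_out <- ifelse(pop_ok, "pass", "fail")
  pop_out[!(segdup_ok & ev_ok)] <- "not_evaluated"
  status <- record_stage(status, "pop_sv", pop_out)
  ledger$pop_sv_removed <- sum(segdup_ok & ev_ok & !pop_ok)
  ledger$final <- sum(segdup_ok & ev_ok & pop_ok)

  shared$filter_status <- status
  list(final = shared[segdup_ok & ev_ok & pop_ok, , drop = FALSE],
       calls = shared, ledger = ledger)
}

#' Packaged CNV-ledger fixture
#'
#' Loads the packaged synthetic call set (with evidence attributes
#' encoded as data) together with its pedigree and annotation tracks.
#' Running the full cascade on it reproduces the reference filter
#' ledger: five heterozygous deletions entering evidence review, three
#' rejected as false positives, two continuing to split-read analysis,
#' one removed as a common population SV (MAF 0.2357), and one final
#' call overlapping panel-gene exons 14-16.
#'
#' @return List with elements `calls`, `pedigree`, `annotations`.
#' @export
make_ledger_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "triocnv",
                                 mustWork = TRUE)
  calls <- read.table(ext("cnv_ledger_synthetic.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  calls$discordant_pair_support <- as.logical(calls$discordant_pair_support)
  calls$clipped_read_support <- as.logical(calls$clipped_read_support)
  list(calls = calls,
       pedigree = read_ped(ext("trio_synthetic.ped")),
       annotations = list(
         segdups = read_bed(ext("segdup_synthetic.bed")),
         panel = read_bed(ext("panel_genes_synthetic.bed")),
         exons = read_bed(ext("exons_synthetic.bed")),
         pop_sv = read_bed(ext("popsv_synthetic.bed"), maf = TRUE)))
}

#' Write CNV calls as TSV
#' @param calls CNV call data frame.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV calls as symbolic VCF 4.2 records
#'
#' Emits `<DEL>` / `<DUP>` ALT alleles with SVTYPE and END INFO keys; the
#' FILTER column mirrors the cascade outcome (`PASS` or the first failed
#' stage).
#'
#' @param calls CNV call data frame (optionally with `filter_status`).
#' @param path Output path.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=NBINS,Number=1,Type=Integer,Description=\"Bins in call\">",
           "##INFO=<ID=LOG2R,Number=1,Type=Float,Description=\"Mean log2 ratio\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- if (!is.null(calls$filter_status)) {
    vapply(calls$filter_status, function(s) {
      fails <- grep(":fail", strsplit(s, ";")[[1]], value = TRUE)
      if (length(fails)) sub(":fail", "", fails[1]) else "PASS"
    }, "")
  } else rep("PASS", nrow(calls))
  rows <- sprintf("%s\t%d\t.\tN\t<%s>\t.\t%s\tSVTYPE=%s;END=%d;NBINS=%d;LOG2R=%.4f",
                  calls$contig, as.integer(calls$start - 1), calls$svtype,
                  filt, calls$svtype, as.integer(calls$end),
                  as.integer(calls$n_bins), calls$mean_log2_ratio)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
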