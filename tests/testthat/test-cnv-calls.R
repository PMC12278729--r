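seg_row <- function(mean, n_bins = 10, contig = "chr2", start = 0,
                    end = n_bins * 1000) {
  data.frame(contig = contig, start = start, end = end, first_bin = 1,
              last_bin = n_bins, n_bins = n_bins, mean_log2_ratio = mean,
              stringsAsFactors = FALSE)
}

test_that("segments become typed calls by log2-ratio thresholds", {
  segs <- rbind(seg_row(-1.0), seg_row(0.02), seg_row(-3.2), seg_row(0.6),
                seg_row(-0.9, n_bins = 2), seg_row(-1.1, contig = "chrX"))
  calls <- call_segments(segs, sample_id = "S1")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$svtype, c("DEL", "DEL", "DUP"))
  expect_equal(calls$genotype_state[1:2], c("heterozygous", "homozygous"))
  # 1-based inclusive coordinates derived from the 0-based segment
  expect_equal(calls$start[1], 1)
  expect_equal(calls$end[1], 10000)
  # near-zero mean emits no call; short and non-autosomal calls suppressed
  expect_false(any(calls$mean_log2_ratio == 0.02))
  expect_false(any(calls$n_bins == 2))
  expect_false(any(calls$contig == "chrX"))
})

test_that("annotation computes overlap fractions, popSV MAF and names", {
  call <- data.frame(sample_id = "S1", contig = "chr1", start = 1001,
                     end = 2000, svtype = "DEL",
                     genotype_state = "heterozygous",
                     mean_log2_ratio = -1, n_bins = 10,
                     stringsAsFactors = FALSE)
  segdups <- data.frame(contig = "chr1", start = 1500, end = 2500,
                        name = "sd1")
  ann <- annotate_calls(call, segdups = segdups)
  expect_equal(ann$segdup_overlap_fraction, 0.5)

  # overlapping segdup records are unioned before the fraction
  sd2 <- rbind(segdups, data.frame(contig = "chr1", start = 1400,
                                   end = 1600, name = "sd2"))
  expect_equal(annotate_calls(call, segdups = sd2)$segdup_overlap_fraction,
               0.6)

  pop <- data.frame(contig = "chr1", start = 1000, end = 2000,
                    name = "sv1", maf = 0.2357)
  expect_equal(annotate_calls(call, pop_sv = pop)$pop_sv_maf, 0.2357)
  # < 50% reciprocal overlap does not match
  pop_small <- data.frame(contig = "chr1", start = 1800, end = 2000,
                          name = "sv2", maf = 0.4)
  expect_true(is.na(annotate_calls(call, pop_sv = pop_small)$pop_sv_maf))

  # idempotence
  fx <- make_ledger_fixture()
  a1 <- annotate_calls(fx$calls, segdups = fx$annotations$segdups,
                       panel = fx$annotations$panel,
                       exons = fx$annotations$exons,
                       pop_sv = fx$annotations$pop_sv)
  a2 <- annotate_calls(a1, segdups = fx$annotations$segdups,
                       panel = fx$annotations$panel,
                       exons = fx$annotations$exons,
                       pop_sv = fx$annotations$pop_sv)
  expect_identical(a1, a2)
})

test_that("malformed BED records are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tok", "chr1\tx\t200\tbad"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("sharing requires same type and sufficient reciprocal overlap", {
  ped <- make_trio_pedigree()
  base <- function(sample, start, end, svtype = "DEL")
    data.frame(sample_id = sample, contig = "chr4", start = start,
               end = end, svtype = svtype, genotype_state = "heterozygous",
               mean_log2_ratio = -1, n_bins = 10, stringsAsFactors = FALSE)

  # identical deletion in both siblings -> shared
  sh <- shared_in_affected(rbind(base("S1", 1e4, 2e4), base("S2", 1e4, 2e4)),
                           ped)
  expect_equal(nrow(sh), 1)
  expect_true(sh$shared_in_affected)

  # DEL vs DUP at the same locus -> not shared
  expect_equal(nrow(shared_in_affected(
    rbind(base("S1", 1e4, 2e4), base("S2", 1e4, 2e4, svtype = "DUP")),
    ped)), 0)

  # ~30% reciprocal overlap under the 50% rule -> not shared
  expect_equal(nrow(shared_in_affected(
    rbind(base("S1", 1e4, 2e4), base("S2", 1.7e4, 2.7e4)), ped)), 0)

  # shared calls take the union region
  sh2 <- shared_in_affected(rbind(base("S1", 1e4, 2e4),
                                  base("S2", 1.2e4, 2.2e4)), ped)
  expect_equal(c(sh2$start, sh2$end), c(1e4, 2.2e4))

  ped1 <- ped[ped$id != "S2", ]
  expect_error(shared_in_affected(base("S1", 1e4, 2e4), ped1),
               "at least 2 affected")
})

test_that("evidence review rejects SNV-heterozygous unsupported deletions", {
  mk <- function(n_snv, disc, clip, svtype = "DEL")
    data.frame(sample_id = "S1", contig = "chr4", start = 1e4, end = 2e4,
               svtype = svtype, genotype_state = "heterozygous",
               mean_log2_ratio = -1, n_bins = 10,
               n_internal_het_snvs = n_snv, discordant_pair_support = disc,
               clipped_read_support = clip, stringsAsFactors = FALSE)
  expect_false(evidence_filter(mk(5, FALSE, FALSE))$evidence_pass)
  expect_true(evidence_filter(mk(0, FALSE, TRUE))$evidence_pass)
  expect_true(evidence_filter(mk(5, TRUE, FALSE))$evidence_pass)  # supported
  expect_true(evidence_filter(mk(2, FALSE, FALSE))$evidence_pass) # < 3 SNVs
  expect_true(is.na(evidence_filter(mk(5, FALSE, FALSE,
                                       svtype = "DUP"))$evidence_pass))

  # counting balanced het SNVs from a site table
  call <- mk(0, FALSE, FALSE)
  snvs <- data.frame(contig = "chr4", pos = c(1.1e4, 1.2e4, 1.3e4, 1.4e4),
                     allele_balance = c(0.5, 0.45, 0.9, 0.36))
  out <- evidence_filter(call, het_snvs = snvs)
  expect_equal(out$n_internal_het_snvs, 3L)   # the 0.9 site is unbalanced
  expect_false(out$evidence_pass)
})

test_that("the cascade ledger is monotone and records provenance", {
  fx <- make_ledger_fixture()
  res <- run_cascade(fx$calls, fx$pedigree, filter_config(),
                     annotations = fx$annotations)
  l <- res$ledger
  expect_true(l$shared_in_affected >= l$after_segdup_filter)
  expect_true(l$entering_evidence_review >= l$to_split_read_analysis)
  expect_true(l$to_split_read_analysis >= l$final)
  expect_true(all(res$final$start %in% res$calls$start))   # subset
  # every retained call records all four stages exactly once, in order
  expect_true(all(grepl("^shared:[a-z_]+;segdup:[a-z_]+;evidence:[a-z_]+;pop_sv:[a-z_]+$",
                        res$calls$filter_status)))

  empty <- run_cascade(fx$calls[0, ], fx$pedigree, filter_config(),
                       annotations = fx$annotations)
  expect_equal(nrow(empty$final), 0)
  expect_equal(empty$ledger$final, 0)
})

test_that("calls serialize as TSV and symbolic VCF", {
  fx <- make_ledger_fixture()
  res <- run_cascade(fx$calls, fx$pedigree, filter_config(),
                     annotations = fx$annotations)
  v <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(res$calls, v)
  lines <- readLines(v)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(res$calls))
  expect_true(all(grepl("SVTYPE=(DEL|DUP);END=\\d+", body)))
  # the popSV-failed record carries the stage name in FILTER
  expect_true(any(grepl("\tpop_sv\t", body)))
})

test_that("simulated trio yields exactly the engineered shared deletion", {
  cfg <- sim_config(seed = 31, contig_lengths = c(chr1 = 1.5e5, chr2 = 1.5e5),
                    engineered_events = data.frame(
                      contig = "chr2", start = 50000, end = 70000,
                      copy_number = 1, carriers = "S1,S2,FA"))
  prof <- simulate_trio_coverage(cfg)
  params <- cbs_params(nperm = 500, seed = 31)
  controls <- prof[paste0("CTRL", 1:4)]
  calls <- do.call(rbind, lapply(c("S1", "S2"), function(sid) {
    tr <- build_ratio_track(prof[[sid]], controls)
    call_segments(segment_track(tr, params), sample_id = sid)
  }))
  calls$n_internal_het_snvs <- 0L
  calls$discordant_pair_support <- FALSE
  calls$clipped_read_support <- TRUE
  res <- run_cascade(calls, make_trio_pedigree(), filter_config(),
                     annotations = list(segdups = NULL, panel = NULL,
                                        exons = NULL, pop_sv = NULL))
  expect_equal(nrow(res$final), 1)
  expect_equal(res$final$contig, "chr2")
  expect_equal(res$final$svtype, "DEL")
  expect_equal(c(res$final$start, res$final$end), c(50001, 70000))
})
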