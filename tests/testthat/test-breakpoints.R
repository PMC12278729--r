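test_that("split-read collection clusters clips and applies thresholds", {
  mk_read <- function(qname, pos, cigar, seq = strrep("A", 50))
    data.frame(qname = qname, flag = 0L, contig = "chrT", pos = pos,
               mapq = 60L, cigar = cigar, seq = seq,
               stringsAsFactors = FALSE)

  # no clipped reads -> empty cluster list
  expect_equal(nrow(collect_split_reads(mk_read("r", 100, "50M"))), 0)

  # 20 reads clipping at one position -> one cluster, support 20
  reads <- do.call(rbind, lapply(1:20, function(k)
    mk_read(paste0("r", k), 100, "30M20S")))
  cl <- collect_split_reads(reads)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 20)
  expect_equal(cl$clip_position, 130)      # one past the last aligned base
  expect_equal(cl$side, "right")

  # clips shorter than min_clip are excluded
  expect_equal(nrow(collect_split_reads(mk_read("r", 100, "46M4S"))), 0)
  expect_error(collect_split_reads(reads, min_clip = 2), "min_clip")

  # left clips anchor at the base before the alignment start
  lcl <- collect_split_reads(mk_read("r", 200, "10S40M"))
  expect_equal(lcl$clip_position, 199)
  expect_equal(lcl$side, "left")

  # unusable CIGARs are skipped with a counted warning
  expect_warning(out <- collect_split_reads(
    rbind(reads, mk_read("bad", 1, "*"))), "1 read")
  expect_equal(out$support, 20)
})

test_that("refinement recovers engineered breakpoints exactly", {
  loc <- make_deletion_locus(contig = "chrT", first = 20000, last = 28000,
                             flank = 2500, seed = 14)
  rd <- simulate_breakpoint_reads(loc, depth = 30, read_length = 150,
                                  seed = 4)
  cl <- collect_split_reads(rd, region = c(19000, 29000))
  bp <- refine_breakpoints(cl, loc)
  expect_equal(bp$status, "ok")
  expect_equal(bp$first_deleted, 20000)
  expect_equal(bp$last_deleted, 28000)
  expect_equal(bp$hgvs_g, "g.20000_28000del")
  expect_equal(bp$size_reported, 8000)
  expect_equal(bp$span_inclusive, bp$size_reported + 1)
  expect_equal(bp$microhomology_len, 0)
})

test_that("recovery is exact across 50 read-sampling seeds at 20x", {
  loc <- make_deletion_locus(contig = "chrT", first = 15000, last = 21000,
                             flank = 2000, seed = 99)
  exact <- 0
  for (s in 1:50) {
    rd <- simulate_breakpoint_reads(loc, depth = 20, read_length = 150,
                                    seed = s)
    bp <- refine_breakpoints(collect_split_reads(rd, region = c(14500, 21500)),
                             loc)
    if (bp$status == "ok" && bp$first_deleted == 15000 &&
        bp$last_deleted == 21000) exact <- exact + 1
  }
  expect_equal(exact, 50)
})

test_that("microhomology placements left-align to one representative", {
  m <- 3
  loc <- make_deletion_locus(contig = "chrT", first = 20000, last = 26000,
                             flank = 2000, microhomology = m, seed = 77)
  # all m+1 equivalent breakpoint placements normalize identically
  results <- lapply(0:m, function(shift) {
    shifted <- loc
    shifted$deletion <- c(first = 20000 + shift, last = 26000 + shift)
    rd <- simulate_breakpoint_reads(shifted, depth = 30, read_length = 150,
                                    seed = 5)
    refine_breakpoints(collect_split_reads(rd, region = c(19000, 27000)), loc)
  })
  for (bp in results) {
    expect_equal(bp$status, "ok")
    expect_equal(bp$first_deleted, 20000)
    expect_equal(bp$last_deleted, 26000)
    expect_equal(bp$microhomology_len, m)
  }
  # and across read-sampling seeds
  for (s in 6:8) {
    rd <- simulate_breakpoint_reads(loc, depth = 30, read_length = 150,
                                    seed = s)
    bp <- refine_breakpoints(collect_split_reads(rd, region = c(19000, 27000)),
                             loc)
    expect_equal(c(bp$first_deleted, bp$last_deleted), c(20000, 26000))
  }
})

test_that("missing evidence yields an outcome, not an error", {
  loc <- make_deletion_locus(contig = "chrT", first = 20000, last = 26000,
                             flank = 2000, seed = 1)
  rd <- simulate_breakpoint_reads(loc, depth = 30, read_length = 150,
                                  seed = 1)
  cl <- collect_split_reads(rd, region = c(19000, 27000))
  only_right <- cl[cl$side == "right", ]
  bp <- refine_breakpoints(only_right, loc)
  expect_equal(bp$status, "insufficient_split_read_evidence")

  # sub-haploid depth over a tiny locus: valid output either way, and
  # refinement reports what it can
  tiny <- make_deletion_locus(contig = "chrT", first = 3000, last = 3600,
                              flank = 1000, seed = 2)
  rd2 <- simulate_breakpoint_reads(tiny, depth = 0.5, read_length = 150,
                                   seed = 3)
  expect_true(is.data.frame(rd2))
  bp2 <- refine_breakpoints(collect_split_reads(rd2, region = c(2500, 4100)),
                            tiny)
  expect_true(bp2$status %in% c("ok", "insufficient_split_read_evidence"))

  # consensus that fails to cross-map is insufficient evidence
  cl_bad <- cl
  cl_bad$clipped_consensus <- strrep("A", 60)
  expect_equal(refine_breakpoints(cl_bad, loc)$status,
               "insufficient_split_read_evidence")
})

test_that("refined deletions serialize as precise VCF and TSV", {
  loc <- make_deletion_locus(contig = "chrT", first = 20000, last = 26000,
                             flank = 2000, seed = 21)
  rd <- simulate_breakpoint_reads(loc, depth = 30, read_length = 150,
                                  seed = 2)
  bp <- refine_breakpoints(collect_split_reads(rd, region = c(19000, 27000)),
                           loc)
  v <- withr::local_tempfile(fileext = ".vcf")
  t <- withr::local_tempfile(fileext = ".tsv")
  write_breakpoint_pair(bp, loc, vcf_path = v, tsv_path = t)
  body <- grep("^#", readLines(v), invert = TRUE, value = TRUE)
  expect_equal(length(body), 1)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(f[2]), 19999)            # anchor base before del
  expect_true(grepl("SVTYPE=DEL;END=26000", f[8]))
  tsv <- read.table(t, header = TRUE, sep = "\t")
  expect_equal(tsv$size_reported, 6000)
  expect_equal(tsv$span_inclusive, 6001)
})
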