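ped <- make_trio_pedigree()

test_that("variant filters implement the consequence/MAF/REVEL rules", {
  tbl <- simulate_trio_snvs()
  out <- filter_variants(tbl)
  removed <- attr(out, "removed")

  # the rare damaging missense (MAF 0.0000924, REVEL 0.594) is retained
  expect_true(any(out$consequence == "missense" & out$gene == "CCDC88A"))
  # each decoy class is removed by its designated rule
  rule_of <- setNames(removed$removed_by, removed$gene)
  expect_equal(unname(rule_of["GENE_SYN"]), "synonymous")
  expect_equal(unname(rule_of["GENE_COMMON"]), "gnomad_maf")
  expect_equal(unname(rule_of["GENE_LOWREVEL"]), "revel")
  expect_equal(unname(rule_of["GENE_INHOUSE"]), "inhouse_freq")
  expect_equal(unname(rule_of["GENE_INTRON"]), "non_exonic")

  # frameshift / stop_gained bypass REVEL; missing REVEL is retained
  expect_true(any(out$consequence == "frameshift"))
  expect_true(any(out$gene == "GENE_ONESIB"))

  # subset + idempotence
  expect_true(all(paste(out$contig, out$pos) %in% paste(tbl$contig, tbl$pos)))
  again <- filter_variants(out)
  expect_equal(nrow(again), nrow(out))

  expect_error(filter_variants(transform(tbl, consequence = "weird")),
               "unknown consequence term")
})

test_that("inheritance models classify trio genotypes correctly", {
  tbl <- filter_variants(simulate_trio_snvs())
  cls <- classify_inheritance(tbl, ped)

  # exactly one compound-het pair: the planted maternal missense +
  # paternal deletion allele
  expect_equal(length(unique(cls$compound_het$pair_id)), 1)
  expect_setequal(cls$compound_het$gene, "CCDC88A")
  expect_setequal(cls$compound_het$transmitted_from, c("father", "mother"))
  # the same-parent (cis) pair is not compound het
  expect_false(any(cls$compound_het$gene == "GENE_CIS"))
  expect_true(all(c("GENE_CIS") %in% cls$shared_het$gene))
  # single-sibling variants are in no candidate set
  expect_false("GENE_ONESIB" %in% unlist(lapply(cls, `[[`, "gene")))

  # homozygous model
  hom <- data.frame(contig = "chr2", pos = 1000, ref = "A", alt = "G",
                    gene = "GENE_HOM", consequence = "missense",
                    gnomad_maf = 1e-4, inhouse_freq = NA, revel = 0.9,
                    FA = "0/1", MO = "0/1", S1 = "1/1", S2 = "1/1",
                    stringsAsFactors = FALSE)
  expect_equal(classify_inheritance(hom, ped)$homozygous$gene, "GENE_HOM")
})

test_that("missing parental genotypes route to shared-het, flagged", {
  v <- data.frame(contig = "chr2", pos = 5000, ref = "A", alt = "T",
                  gene = "G1", consequence = "missense", gnomad_maf = 1e-4,
                  inhouse_freq = NA, revel = 0.8,
                  FA = NA_character_, MO = "0/0", S1 = "0/1", S2 = "0/1",
                  stringsAsFactors = FALSE)
  cls <- classify_inheritance(v, ped)
  expect_equal(nrow(cls$compound_het), 0)
  expect_equal(cls$shared_het$gene, "G1")
  expect_true(cls$shared_het$phase_unknown)
})

test_that("compound-het detection is symmetric in parent labels", {
  tbl <- filter_variants(simulate_trio_snvs())
  swapped <- tbl
  swapped$FA <- tbl$MO
  swapped$MO <- tbl$FA
  a <- classify_inheritance(tbl, ped)$compound_het
  b <- classify_inheritance(swapped, ped)$compound_het
  expect_setequal(paste(a$contig, a$pos), paste(b$contig, b$pos))
  # transmission labels swap with the genotypes
  key <- function(df) setNames(df$transmitted_from, df$pos)
  ka <- key(a); kb <- key(b)
  expect_true(all(ka[names(kb)] != kb))
})

test_that("panel restriction keeps panel genes and logs counts", {
  tbl <- filter_variants(simulate_trio_snvs())
  cls <- classify_inheritance(tbl, ped)
  panel <- c("CCDC88A", sprintf("PANEL_G%03d", 1:229))
  expect_message(res <- apply_panel(cls, panel), "panel restriction")
  expect_setequal(res$compound_het$gene, "CCDC88A")
  expect_equal(nrow(res$shared_het), 0)   # GENE_CIS is off-panel
  counts <- attr(res, "counts")
  expect_equal(unname(counts$compound_het), c(2, 2))
  expect_error(apply_panel(cls, character(0)), "non-empty")

  empty <- lapply(cls, function(df) df[0, , drop = FALSE])
  res0 <- suppressMessages(apply_panel(empty, panel))
  expect_equal(nrow(res0$compound_het), 0)
})

test_that("a CNV pseudo-allele pairs with an SNV across the trio", {
  call <- data.frame(contig = "chr2", start = 55556194, end = 55565990)
  snv <- data.frame(contig = "chr2", pos = 55560000, ref = "T", alt = "G",
                    gene = "CCDC88A", consequence = "missense",
                    gnomad_maf = 0.0000924, inhouse_freq = NA, revel = 0.594,
                    FA = "0/0", MO = "0/1", S1 = "0/1", S2 = "0/1",
                    stringsAsFactors = FALSE)
  tbl <- rbind(snv, cnv_pseudo_variant(call, "CCDC88A", "father"))
  res <- triage_trio(tbl, ped)
  expect_equal(unname(res$summary["compound_het_pairs"]), 1)
})

test_that("variant tables round-trip through TSV and VCF", {
  tbl <- simulate_trio_snvs()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snv_table(tbl, f)
  back <- read_snv_table(f)
  expect_equal(back$pos, tbl$pos)
  expect_equal(back$revel, tbl$revel)
  expect_equal(back$S1, tbl$S1)

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr2>",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"gnomAD AF\">",
           "##INFO=<ID=INHOUSE_AF,Number=1,Type=Float,Description=\"In-house AF\">",
           "##INFO=<ID=REVEL,Number=1,Type=Float,Description=\"REVEL\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tFA\tMO\tS1\tS2",
           paste0("chr2\t55560000\t.\tT\tG\t.\tPASS\t",
                  "GENE=CCDC88A;CSQ=missense;GNOMAD_AF=0.0000924;REVEL=0.594",
                  "\tGT\t0/0\t0/1\t0/1\t0/1"))
  writeLines(hdr, vcf)
  parsed <- read_snv_vcf(vcf)
  expect_equal(parsed$gene, "CCDC88A")
  expect_equal(parsed$revel, 0.594)
  expect_equal(parsed$S2, "0/1")
  got <- triage_trio(parsed, ped)
  expect_equal(unname(got$summary["filtered"]), 1)
})
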