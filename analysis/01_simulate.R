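#!/usr/bin/env Rscript
# Generate the synthetic study inputs: binned trio + control coverage with
# the engineered shared heterozygous deletion, breakpoint-spanning reads
# over the validated deletion locus, and the annotated trio variant table.

suppressPackageStartupMessages(library(triocnv))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20250901,
                  contig_lengths = c(chr1 = 3e5, chr2 = 3e5),
                  mean_depth = 200)   # ~30x with 150-bp reads, 1-kb bins
ped <- make_trio_pedigree()
write_ped(ped, file.path(out, "trio.ped"))

profiles <- simulate_trio_coverage(cfg, ped, n_controls = 4)
for (p in profiles)
  write_bin_counts(p, file.path(out, paste0(p$sample_id, ".counts.tsv")))
cat("wrote per-sample bin counts for", length(profiles), "samples (",
    nrow(profiles[[1]]$bins), "bins each);",
    "carriers S1/S2/FA drop to ~half depth over chr2:50000-70000\n")

locus <- make_deletion_locus(contig = "chr2", first = 55556194,
                             last = 55565990, flank = 3000, seed = 20250902)
reads <- simulate_breakpoint_reads(locus, depth = 30, read_length = 150,
                                   seed = 20250903)
write_sam(reads, file.path(out, "breakpoint_reads.sam"),
          contig_lengths = c(chr2 = locus$offset + nchar(locus$seq)))
write.table(data.frame(contig = locus$contig, offset = locus$offset,
                       first = locus$deletion[["first"]],
                       last = locus$deletion[["last"]]),
            file.path(out, "locus_spec.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", nrow(reads), "aligned reads over the deletion locus;",
    sum(grepl("S", reads$cigar)), "carry soft clips at the junction\n")

snvs <- simulate_trio_snvs(cfg)
write_snv_table(snvs, file.path(out, "trio_snvs.tsv"))
cat("wrote", nrow(snvs), "trio variants:",
    "planted compound-het pair in CCDC88A plus one decoy per filter class\n")
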