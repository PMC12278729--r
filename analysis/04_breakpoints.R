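#!/usr/bin/env Rscript
# Split-read breakpoint refinement of the candidate deletion: cluster the
# soft-clipped reads, pair the junction sides, left-align, and report the
# base-pair-exact deletion.

suppressPackageStartupMessages(library(triocnv))
out <- "results/breakpoints"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- read.table("results/sim/locus_spec.tsv", header = TRUE, sep = "\t")
# regenerate the locus sequence (stored compactly as its generator seed)
locus <- make_deletion_locus(contig = spec$contig, first = spec$first,
                             last = spec$last, flank = 3000,
                             seed = 20250902)

sam <- readLines("results/sim/breakpoint_reads.sam")
body <- strsplit(sam[!startsWith(sam, "@")], "\t")
reads <- data.frame(qname = vapply(body, `[`, "", 1),
                    flag = as.integer(vapply(body, `[`, "", 2)),
                    contig = vapply(body, `[`, "", 3),
                    pos = as.numeric(vapply(body, `[`, "", 4)),
                    mapq = as.integer(vapply(body, `[`, "", 5)),
                    cigar = vapply(body, `[`, "", 6),
                    seq = vapply(body, `[`, "", 10))

clusters <- collect_split_reads(reads,
                                region = c(spec$first - 2000, spec$last + 2000))
cat("split-read clusters:\n")
print(head(clusters[, c("contig", "clip_position", "side", "support")]))

bp <- refine_breakpoints(clusters, locus)
print(bp)
write_breakpoint_pair(bp, locus,
                      vcf_path = file.path(out, "deletion.vcf"),
                      tsv_path = file.path(out, "deletion.tsv"))
cat("wrote refined deletion:", bp$hgvs_g, "(", bp$size_reported, "bp )\n")
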