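#!/usr/bin/env Rscript
# Convert the trio segments into CNV calls and run the filter cascade on
# (a) the simulated trio and (b) the packaged ledger fixture, writing the
# stage ledgers and the surviving calls.

suppressPackageStartupMessages(library(triocnv))
cnv <- "results/cnv"
out <- "results/cascade"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# simulated trio: the engineered deletion is supported by clipped reads
# and contains no heterozygous SNVs
ped <- read_ped("results/sim/trio.ped")
calls <- do.call(rbind, lapply(ped$id[ped$affected], function(sid) {
  segs <- read.table(file.path(cnv, paste0(sid, ".segments.tsv")),
                     header = TRUE, sep = "\t")
  names(segs)[names(segs) == "sample"] <- "sample_id"
  segs$first_bin <- segs$last_bin <- NA
  call_segments(segs, sample_id = sid)
}))
calls$n_internal_het_snvs <- 0L
calls$discordant_pair_support <- FALSE
calls$clipped_read_support <- TRUE
sim_res <- run_cascade(calls, ped, filter_config(),
                       annotations = list(segdups = NULL, panel = NULL,
                                          exons = NULL, pop_sv = NULL))
write_calls_tsv(sim_res$final, file.path(out, "simulated_final_calls.tsv"))
cat("simulated trio:", nrow(calls), "per-sibling calls ->",
    nrow(sim_res$final), "shared surviving call(s):",
    sprintf("%s:%d-%d %s", sim_res$final$contig, sim_res$final$start,
            sim_res$final$end, sim_res$final$svtype), "\n")

# packaged ledger fixture: reference stage counts
fx <- make_ledger_fixture()
res <- run_cascade(fx$calls, fx$pedigree, filter_config(),
                   annotations = fx$annotations)
jsonlite::write_json(res$ledger, file.path(out, "ledger.json"),
                     auto_unbox = TRUE)
write_calls_tsv(res$calls, file.path(out, "fixture_calls.tsv"))
write_calls_vcf(res$calls, file.path(out, "fixture_calls.vcf"))
cat("ledger fixture:", res$ledger$entering_evidence_review,
    "entering evidence review,", res$ledger$evidence_rejected,
    "rejected as false positives,", res$ledger$to_split_read_analysis,
    "to split-read analysis,", res$ledger$final, "final call over",
    res$final$panel_genes, "exons", res$final$exons_overlapped, "\n")
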