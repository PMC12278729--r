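#!/usr/bin/env Rscript
# Build the test-vs-control-median log2 ratio tracks from the simulated
# bin counts and segment them with circular binary segmentation.

suppressPackageStartupMessages(library(triocnv))
sim <- "results/sim"
out <- "results/cnv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ped <- read_ped(file.path(sim, "trio.ped"))
load_profile <- function(sid) {
  df <- read_bin_counts(file.path(sim, paste0(sid, ".counts.tsv")))
  coverage_profile(sid, df[, c("contig", "start", "end")], df$count)
}
controls <- lapply(paste0("CTRL", 1:4), load_profile)

params <- cbs_params(alpha = 0.01, nperm = 1000, seed = 20250904)
for (sid in ped$id) {
  track <- build_ratio_track(load_profile(sid), controls)
  write_ratio_bedgraph(track, file.path(out, paste0(sid, ".log2ratio.bedGraph")),
                       file.path(out, paste0(sid, ".mask.bed")))
  segs <- segment_track(track, params)
  write_segments(segs, file.path(out, paste0(sid, ".segments.tsv")),
                 sample_id = sid)
  hit <- segs[segs$mean_log2_ratio <= -0.6, ]
  cat(sid, ": ", nrow(segs), " segments",
      if (nrow(hit)) sprintf("; deletion-like segment %s:%d-%d (mean %.2f)",
                             hit$contig[1], hit$start[1], hit$end[1],
                             hit$mean_log2_ratio[1]) else "",
      "\n", sep = "")
}
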