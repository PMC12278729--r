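#' Simulation configuration for a trio + control-panel genome study
#'
#' The defaults emulate the study design the pipeline targets: a family
#' quartet (two affected siblings and their parents) sequenced by WGS
#' alongside a panel of four control genomes of similar depth, read depth
#' summarised in 1000-bp bins. `mean_depth` is the expected reads per bin
#' at copy number 2; 200 reads per 1000-bp bin corresponds to roughly
#' 30x coverage with 150-bp reads. Bin counts are negative binomial with
#' dispersion (size) `nb_dispersion`; Poisson is the `nb_dispersion = Inf`
#' limit.
#'
#' @param seed Integer seed; a fixed seed makes every simulated output
#'   byte-identical across runs.
#' @param contig_lengths Named vector of contig lengths in bp.
#' @param bin_size Bin width in bp (default 1000).
#' @param mean_depth Expected reads per bin at copy number 2 (default 200).
#' @param nb_dispersion Negative-binomial size parameter (> 0, `Inf` for
#'   Poisson; default 100).
#' @param read_length Read length in bp (default 150).
#' @param insert_mean,insert_sd Fragment-size model in bp.
#' @param engineered_events Data frame with columns `contig`, `start`,
#'   `end` (0-based half-open), `copy_number` (0-4) and `carriers`
#'   (comma-separated sample ids).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(chr1 = 4e5, chr2 = 4e5),
                       bin_size = 1000,
                       mean_depth = 200,
                       nb_dispersion = 100,
                       read_length = 150,
                       insert_mean = 400,
                       insert_sd = 60,
                       engineered_events = default_engineered_events()) {
  if (bin_size < 100) stop("bin_size must be >= 100")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  ev <- engineered_events
  if (!is.null(ev) && nrow(ev)) {
    if (!all(ev$copy_number %in% 0:4))
      stop("engineered copy_number must be in 0..4")
    for (k in seq_len(nrow(ev))) {
      len <- unname(contig_lengths[ev$contig[k]])
      if (is.na(len) || ev$start[k] < 0 || ev$end[k] > len ||
          ev$start[k] >= ev$end[k])
        stop("engineered event ", k, " (", ev$contig[k], ":", ev$start[k],
             "-", ev$end[k], ") lies outside its contig")
    }
  }
  structure(list(seed = as.integer(seed), contig_lengths = contig_lengths,
                 bin_size = bin_size, mean_depth = mean_depth,
                 nb_dispersion = nb_dispersion, read_length = read_length,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 engineered_events = ev),
            class = "sim_config")
}

#' Default engineered event set: one paternally inherited heterozygous
#' deletion shared by both affected siblings.
#' @return Data frame of engineered events.
#' @export
default_engineered_events <- function() {
  data.frame(contig = "chr2", start = 50000, end = 70000,
             copy_number = 1,
             carriers = "S1,S2,FA", stringsAsFactors = FALSE)
}

#' Pedigree of two affected siblings and their unaffected parents
#'
#' @param family Family identifier.
#' @return Data frame with columns `family`, `id`, `father`, `mother`,
#'   `sex` (1 male / 2 female), `affected` (logical).
#' @export
make_trio_pedigree <- function(family = "FAM1") {
  data.frame(family = family,
             id = c("FA", "MO", "S1", "S2"),
             father = c("0", "0", "FA", "FA"),
             mother = c("0", "0", "MO", "MO"),
             sex = c(1L, 2L, 1L, 2L),
             affected = c(FALSE, FALSE, TRUE, TRUE),
             stringsAsFactors = FALSE)
}

#' Read / write a 6-column PED file
#' @param path File path.
#' @return `read_ped`: a pedigree data frame as in [make_trio_pedigree()].
#' @export
read_ped <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("family", "id", "father", "mother", "sex", "phenotype")
  df$affected <- df$phenotype == 2
  df$phenotype <- NULL
  df
}

#' @rdname read_ped
#' @param pedigree Pedigree data frame.
#' @export
write_ped <- function(pedigree, path) {
  out <- data.frame(pedigree$family, pedigree$id, pedigree$father,
                    pedigree$mother, pedigree$sex,
                    ifelse(pedigree$affected, 2L, 1L))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

nb_draw <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Simulate binned trio + control coverage profiles
#'
#' Draws per-bin read counts for every family member and control from a
#' negative binomial whose mean is `mean_depth * copy_number / 2` inside
#' engineered events (for carrier samples) and `mean_depth` elsewhere.
#' Copy number 0 regions draw from a small background mean (1% of
#' `mean_depth`) emulating stray mismapped reads.
#'
#' @param config A [sim_config()].
#' @param pedigree A pedigree data frame ([make_trio_pedigree()]).
#' @param n_controls Number of control genomes (default 4, the panel size
#'   of the emulated study design).
#' @return Named list of [coverage_profile()] objects (family members
#'   first, then `CTRL1..CTRLn`).
#' @export
simulate_trio_coverage <- function(config, pedigree = make_trio_pedigree(),
                                   n_controls = 4) {
  bins <- bin_genome(config$contig_lengths, config$bin_size)
  width_frac <- (bins$end - bins$start) / config$bin_size
  samples <- c(pedigree$id, if (n_controls > 0) paste0("CTRL", seq_len(n_controls)))
  ev <- config$engineered_events
  withr::with_seed(config$seed, {
    profiles <- lapply(samples, function(sid) {
      cn <- rep(2, nrow(bins))
      if (!is.null(ev) && nrow(ev)) {
        for (k in seq_len(nrow(ev))) {
          carriers <- strsplit(ev$carriers[k], ",")[[1]]
          if (sid %in% carriers) {
            hit <- bins$contig == ev$contig[k] & bins$start < ev$end[k] &
              bins$end > ev$start[k]
            cn[hit] <- ev$copy_number[k]
          }
        }
      }
      mu <- config$mean_depth * pmax(cn / 2, 0.01) * width_frac
      counts <- nb_draw(nrow(bins), mu, config$nb_dispersion)
      coverage_profile(sid, bins, counts)
    })
    names(profiles) <- samples
    profiles
  })
}

#' Specification of the planted compound-heterozygous pair
#'
#' The defaults mirror the kind of hit the pipeline is designed to find:
#' a rare maternally transmitted missense variant (REVEL 0.594, gnomAD
#' MAF 0.0000924) paired with a paternally transmitted intragenic-deletion
#' pseudo-allele in the same gene.
#'
#' @param gene Gene symbol carrying both alleles.
#' @param maternal,paternal Named lists describing each variant
#'   (`contig`, `pos`, `ref`, `alt`, `consequence`, `gnomad_maf`, `revel`).
#' @return A list of class `planted_pair`.
#' @export
planted_pair_spec <- function(gene = "CCDC88A",
                              maternal = list(contig = "chr2", pos = 55560000,
                                              ref = "T", alt = "G",
                                              consequence = "missense",
                                              gnomad_maf = 0.0000924,
                                              revel = 0.594),
                              paternal = list(contig = "chr2", pos = 55558000,
                                              ref = "N", alt = "<DEL>",
                                              consequence = "frameshift",
                                              gnomad_maf = NA_real_,
                                              revel = NA_real_)) {
  structure(list(gene = gene, maternal = maternal, paternal = paternal),
            class = "planted_pair")
}

snv_row <- function(contig, pos, ref, alt, gene, consequence, gnomad_maf,
                    inhouse_freq, revel, FA, MO, S1, S2) {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, gnomad_maf = gnomad_maf,
             inhouse_freq = inhouse_freq, revel = revel,
             FA = FA, MO = MO, S1 = S1, S2 = S2, stringsAsFactors = FALSE)
}

#' Simulate an annotated trio small-variant table
#'
#' Produces the planted compound-heterozygous pair plus (by default) one
#' decoy variant of each class the triage filters are designed to remove:
#' a synonymous variant, a common variant (gnomAD MAF > 0.01), a missense
#' with REVEL <= 0.5, an in-house-frequent variant, an intronic variant,
#' a single-parent (two maternal alleles) pair, and a variant present in
#' only one sibling.
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param planted A [planted_pair_spec()].
#' @param decoys If `FALSE`, only the planted pair is emitted.
#' @return Data frame of small variants with per-member genotype columns
#'   `FA`, `MO`, `S1`, `S2` (strings `0/0`, `0/1`, `1/1`).
#' @export
simulate_trio_snvs <- function(config = sim_config(),
                               planted = planted_pair_spec(),
                               decoys = TRUE) {
  m <- planted$maternal; p <- planted$paternal
  if (is.null(planted$gene) || !nzchar(planted$gene))
    stop("planted pair must name one gene")
  rows <- list(
    snv_row(m$contig, m$pos, m$ref, m$alt, planted$gene, m$consequence,
            m$gnomad_maf, NA, m$revel,
            FA = "0/0", MO = "0/1", S1 = "0/1", S2 = "0/1"),
    snv_row(p$contig, p$pos, p$ref, p$alt, planted$gene, p$consequence,
            p$gnomad_maf, NA, p$revel,
            FA = "0/1", MO = "0/0", S1 = "0/1", S2 = "0/1"))
  if (decoys) {
    rows <- c(rows, list(
      # removed as synonymous
      snv_row("chr3", 1200500, "C", "T", "GENE_SYN", "synonymous",
              0.0004, NA, NA, "0/1", "0/0", "0/1", "0/1"),
      # removed by gnomAD MAF > 0.01
      snv_row("chr4", 8820100, "G", "A", "GENE_COMMON", "missense",
              0.02, NA, 0.9, "0/0", "0/1", "0/1", "0/1"),
      # removed by REVEL <= 0.5
      snv_row("chr5", 3304410, "A", "C", "GENE_LOWREVEL", "missense",
              0.0001, NA, 0.3, "0/1", "0/0", "0/1", "0/1"),
      # removed by in-house frequency
      snv_row("chr6", 9905020, "T", "A", "GENE_INHOUSE", "missense",
              0.002, 0.2, 0.8, "0/0", "0/1", "0/1", "0/1"),
      # removed as non-exonic
      snv_row("chr7", 1550300, "G", "C", "GENE_INTRON", "intronic",
              0.0002, NA, NA, "0/1", "0/0", "0/1", "0/1"),
      # same-parent pair: two maternal alleles, survives filters but is
      # not a compound heterozygote
      snv_row("chr8", 2201000, "C", "G", "GENE_CIS", "missense",
              0.0001, NA, 0.8, "0/0", "0/1", "0/1", "0/1"),
      snv_row("chr8", 2207500, "A", "T", "GENE_CIS", "stop_gained",
              0.0002, NA, NA, "0/0", "0/1", "0/1", "0/1"),
      # present in only one affected sibling
      snv_row("chr9", 7701200, "T", "C", "GENE_ONESIB", "missense",
              0.0003, NA, 0.85, "0/1", "0/0", "0/1", "0/0")))
  }
  withr::with_seed(config$seed, {
    tbl <- do.call(rbind, rows)
    tbl[order(tbl$contig, tbl$pos), , drop = FALSE]
  })
}

#' Inject a CNV call as a pseudo-variant for compound-het detection
#'
#' A deletion call overlapping a gene is represented as a
#' frameshift-equivalent allele with genotypes taken from its carriers,
#' so compound-heterozygote classification can pair an SNV with an
#' intragenic deletion.
#'
#' @param call One-row CNV call data frame (columns `contig`, `start`,
#'   `end`).
#' @param gene Gene symbol the call disrupts.
#' @param carrier_parent `"father"` or `"mother"`.
#' @param pedigree Pedigree data frame.
#' @return One-row small-variant data frame.
#' @export
cnv_pseudo_variant <- function(call, gene, carrier_parent = "father",
                               pedigree = make_trio_pedigree()) {
  affected <- pedigree$id[pedigree$affected]
  gts <- setNames(rep("0/0", nrow(pedigree)), pedigree$id)
  gts[affected] <- "0/1"
  parent_col <- if (carrier_parent == "father") {
    unique(pedigree$father[pedigree$affected])
  } else {
    unique(pedigree$mother[pedigree$affected])
  }
  gts[parent_col] <- "0/1"
  out <- data.frame(contig = call$contig, pos = call$start, ref = "N",
                    alt = "<DEL>", gene = gene, consequence = "frameshift",
                    gnomad_maf = NA_real_, inhouse_freq = NA_real_,
                    revel = NA_real_, stringsAsFactors = FALSE)
  for (id in names(gts)) out[[id]] <- gts[[id]]
  out
}
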