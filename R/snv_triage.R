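#' Trio small-variant triage configuration
#'
#' @param maf_max Maximum gnomAD minor allele frequency (default 0.01).
#' @param inhouse_freq_max Maximum in-house cohort frequency (default
#'   0.05; the in-house rule is frequency-based and the column optional).
#' @param revel_min Missense variants with an available REVEL score must
#'   exceed this to be retained (default 0.5); variants without a score
#'   are kept.
#' @param restrict_exonic_splicing Keep only exonic and splicing
#'   consequences (default TRUE).
#' @param panel Optional character vector of panel gene symbols.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(maf_max = 0.01, inhouse_freq_max = 0.05,
                          revel_min = 0.5, restrict_exonic_splicing = TRUE,
                          panel = NULL) {
  stopifnot(maf_max >= 0, maf_max <= 1, revel_min >= 0, revel_min <= 1,
            inhouse_freq_max >= 0, inhouse_freq_max <= 1)
  structure(list(maf_max = maf_max, inhouse_freq_max = inhouse_freq_max,
                 revel_min = revel_min,
                 restrict_exonic_splicing = restrict_exonic_splicing,
                 panel = panel),
            class = "triage_config")
}

snv_consequences <- c("missense", "synonymous", "frameshift", "stop_gained",
                      "splice", "other_exonic", "intronic")
exonic_splicing <- c("missense", "synonymous", "frameshift", "stop_gained",
                     "splice", "other_exonic")

#' Filter an annotated trio variant table
#'
#' Removes, in order: non-exonic/non-splicing consequences (when
#' configured), synonymous variants, variants above the gnomAD MAF
#' threshold, variants above the in-house frequency threshold, and
#' missense variants whose available REVEL score does not exceed
#' `revel_min`. Variants with missing frequency or REVEL annotations are
#' retained at the corresponding step. The result carries a `removed`
#' attribute recording each dropped row and the rule that removed it.
#'
#' @param table Small-variant data frame (see [simulate_trio_snvs()]).
#' @param config A [triage_config()].
#' @return The filtered table (a subset of the input; the filter is
#'   idempotent).
#' @export
filter_variants <- function(table, config = triage_config()) {
  unknown <- setdiff(unique(table$consequence), snv_consequences)
  if (length(unknown))
    stop("unknown consequence term(s): ", paste(unknown, collapse = ", "))
  reason <- rep(NA_character_, nrow(table))
  mark <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  if (config$restrict_exonic_splicing)
    reason <- mark(!(table$consequence %in% exonic_splicing), "non_exonic")
  reason <- mark(table$consequence == "synonymous", "synonymous")
  reason <- mark(!is.na(table$gnomad_maf) &
                   table$gnomad_maf > config$maf_max, "gnomad_maf")
  if (!is.null(table$inhouse_freq))
    reason <- mark(!is.na(table$inhouse_freq) &
                     table$inhouse_freq > config$inhouse_freq_max,
                   "inhouse_freq")
  reason <- mark(table$consequence == "missense" & !is.na(table$revel) &
                   table$revel <= config$revel_min, "revel")
  keep <- is.na(reason)
  out <- table[keep, , drop = FALSE]
  removed <- table[!keep, , drop = FALSE]
  removed$removed_by <- reason[!keep]
  attr(out, "removed") <- removed
  out
}

gt_has_alt <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/0", "1/1")
gt_het <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/0")
gt_hom_alt <- function(gt) !is.na(gt) & gt == "1/1"
gt_missing <- function(gt) is.na(gt) | gt %in% c("", ".", "./.", "missing")

trio_roles <- function(table, pedigree) {
  affected <- pedigree$id[pedigree$affected]
  if (length(affected) < 2)
    stop("need at least 2 affected siblings with genotypes")
  father <- unique(pedigree$father[pedigree$id %in% affected])
  mother <- unique(pedigree$mother[pedigree$id %in% affected])
  if (length(father) != 1 || length(mother) != 1)
    stop("affected siblings must share exactly one father and one mother")
  missing_cols <- setdiff(c(affected, father, mother), names(table))
  if (length(missing_cols))
    stop("variant table lacks genotype column(s): ",
         paste(missing_cols, collapse = ", "))
  list(affected = affected, father = father, mother = mother)
}

#' Classify filtered trio variants under recessive inheritance models
#'
#' Splits variants heterozygous or homozygous in all affected siblings
#' into three candidate sets: `homozygous` (1/1 in every affected, 0/1
#' in both parents), `compound_het` (gene-grouped pairs heterozygous in
#' every affected with one allele transmitted from each parent — phase
#' by transmission — and neither parent carrying both), and `shared_het`
#' (heterozygous in all affected, not part of the other sets). Variants
#' with a missing parental genotype are routed to `shared_het` with
#' `phase_unknown = TRUE`, never silently dropped.
#'
#' @param filtered Filtered small-variant data frame.
#' @param pedigree Pedigree data frame.
#' @return List with data frames `homozygous`, `compound_het` (columns
#'   `pair_id` and `transmitted_from` added) and `shared_het` (column
#'   `phase_unknown` added).
#' @export
classify_inheritance <- function(filtered, pedigree) {
  roles <- trio_roles(filtered, pedigree)
  aff_gt <- filtered[, roles$affected, drop = FALSE]
  fa <- filtered[[roles$father]]; mo <- filtered[[roles$mother]]

  all_hom <- Reduce(`&`, lapply(aff_gt, gt_hom_alt))
  homozygous <- filtered[all_hom & gt_het(fa) & gt_het(mo), , drop = FALSE]

  all_het <- Reduce(`&`, lapply(aff_gt, gt_het))
  cand <- filtered[all_het, , drop = FALSE]
  cfa <- fa[all_het]; cmo <- mo[all_het]
  phase_unknown <- gt_missing(cfa) | gt_missing(cmo)
  paternal <- !phase_unknown & gt_has_alt(cfa) & !gt_has_alt(cmo)
  maternal <- !phase_unknown & gt_has_alt(cmo) & !gt_has_alt(cfa)

  pairs <- list(); pair_id <- 0L
  in_pair <- rep(FALSE, nrow(cand))
  for (g in unique(cand$gene)) {
    idx_p <- which(cand$gene == g & paternal)
    idx_m <- which(cand$gene == g & maternal)
    for (ip in idx_p) for (im in idx_m) {
      # transmission already implies neither parent carries both
      pair_id <- pair_id + 1L
      two <- cand[c(ip, im), , drop = FALSE]
      two$pair_id <- pair_id
      two$transmitted_from <- c("father", "mother")
      pairs[[length(pairs) + 1]] <- two
      in_pair[c(ip, im)] <- TRUE
    }
  }
  compound_het <- if (length(pairs)) do.call(rbind, pairs) else {
    ch <- cand[0, , drop = FALSE]
    ch$pair_id <- integer(0); ch$transmitted_from <- character(0)
    ch
  }

  shared <- cand[!in_pair, , drop = FALSE]
  shared$phase_unknown <- phase_unknown[!in_pair]
  rownames(homozygous) <- rownames(compound_het) <- rownames(shared) <- NULL
  list(homozygous = homozygous, compound_het = compound_het,
       shared_het = shared)
}

#' Restrict candidate sets to a gene panel
#'
#' @param candidates List from [classify_inheritance()].
#' @param panel Character vector of panel gene symbols (non-empty).
#' @return The candidate sets restricted to panel genes, with an attribute
#'   `counts` holding before/after counts per set.
#' @export
apply_panel <- function(candidates, panel) {
  if (!length(panel)) stop("panel must be non-empty")
  counts <- lapply(candidates, function(df)
    c(before = nrow(df), after = sum(df$gene %in% panel)))
  out <- lapply(candidates, function(df)
    df[df$gene %in% panel, , drop = FALSE])
  attr(out, "counts") <- counts
  message("panel restriction: ",
          paste(sprintf("%s %d -> %d", names(counts),
                        vapply(counts, `[`, 0, "before"),
                        vapply(counts, `[`, 0, "after")), collapse = "; "))
  out
}

#' Read an annotated small-variant table from TSV
#' @param path File path (columns as written by [write_snv_table()]).
#' @return Small-variant data frame.
#' @export
read_snv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", "."))
}

#' @rdname read_snv_table
#' @param table Small-variant data frame.
#' @export
write_snv_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read an annotated trio VCF into a small-variant table
#'
#' Maps the INFO keys `GENE`, `CSQ`, `GNOMAD_AF`, `INHOUSE_AF`, `REVEL`
#' and per-sample GT fields onto the columns [filter_variants()] expects.
#'
#' @param path Path to a VCF 4.x file.
#' @return Small-variant data frame with one genotype column per sample.
#' @export
read_snv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  info_key <- function(key) {
    val <- unname(vcfR::extract.info(v, element = key))
    if (!length(val)) rep(NA_character_, n) else val
  }
  tbl <- data.frame(contig = fix$CHROM, pos = as.numeric(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    gene = info_key("GENE"),
                    consequence = info_key("CSQ"),
                    gnomad_maf = suppressWarnings(as.numeric(info_key("GNOMAD_AF"))),
                    inhouse_freq = suppressWarnings(as.numeric(info_key("INHOUSE_AF"))),
                    revel = suppressWarnings(as.numeric(info_key("REVEL"))),
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)
  gt <- gsub("\\|", "/", gt)
  for (s in colnames(gt)) tbl[[s]] <- unname(gt[, s])
  tbl
}

#' End-to-end trio triage
#'
#' Convenience wrapper: filter, classify, optionally panel-restrict, and
#' summarise stage counts.
#'
#' @param table Annotated small-variant table.
#' @param pedigree Pedigree data frame.
#' @param config A [triage_config()].
#' @return List with `candidates` (per-model sets), `filtered` table and
#'   `summary` (named stage counts).
#' @export
triage_trio <- function(table, pedigree, config = triage_config()) {
  filtered <- filter_variants(table, config)
  candidates <- classify_inheritance(filtered, pedigree)
  if (!is.null(config$panel))
    candidates <- suppressMessages(apply_panel(candidates, config$panel))
  summary <- c(input = nrow(table), filtered = nrow(filtered),
               homozygous = nrow(candidates$homozygous),
               compound_het_pairs =
                 length(unique(candidates$compound_het$pair_id)),
               shared_het = nrow(candidates$shared_het))
  list(candidates = candidates, filtered = filtered, summary = summary)
}
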