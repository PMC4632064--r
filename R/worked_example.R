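# Deterministic worked-example fixture. Encodes per-subject damaging
# missense counts whose group means reproduce the headline gene-set
# effect-size ratios (1.80, 4.00, 2.50, 1.27, and an "nc" row) of the
# emulated study; genome-wide totals vary mildly across subjects so the
# percent-normalized tests are non-degenerate.

#' Generate the deterministic worked-example cohort
#'
#' Six cases (SCZ1-SCZ6) and three controls (NP1-NP3). Damaging missense
#' counts per gene set and subject are fixed so that the ratio-of-means
#' column of the burden table is exactly: neuron projection 1.80,
#' DGCR8-restricted neuron projection 4.00, synaptic pathways 2.50,
#' abnormal sensory system 1.27, and "nc" for the GABAergic synapse set
#' (no control variants). Every subject also carries filler non-damaging
#' missense (bringing genome-wide missense totals to 90-100 per subject),
#' one LoF and one splicing-regulatory filler variant.
#'
#' @return A `synthetic_cohort` bundle (no PRS panel or ncRNA catalog).
#' @export
generate_worked_example <- function() {
  set.seed(20260920)
  subjects <- data.frame(
    id = c(sprintf("SCZ%d", 1:6), sprintf("NP%d", 1:3)),
    group = rep(c("CASE", "CONTROL"), c(6, 3)),
    sex = rep(c("MALE", "FEMALE", "MALE"), 3),
    stringsAsFactors = FALSE)

  gene_sets <- list(
    neuron_projection = sprintf("NPG%02d", 1:53),
    synaptic_pathways = sprintf("SYN%02d", 1:15),
    abnormal_sensory = sprintf("ABS%02d", 1:58),
    gabaergic_synapse = sprintf("GAB%02d", 1:7))
  attr(gene_sets, "sources") <- c(neuron_projection = "GO",
                                  synaptic_pathways = "KEGG",
                                  abnormal_sensory = "MGI",
                                  gabaergic_synapse = "KEGG")
  dgcr8_genes <- sprintf("NPG%02d", 1:16)

  # per-subject damaging missense counts (cases then controls)
  counts <- list(
    # neuron projection: 54 over cases (mean 9.00), 15 over controls (5.00)
    # of which the 16 DGCR8-restricted genes carry 16 (2.67) vs 2 (0.67)
    np_restricted = c(3, 3, 3, 3, 2, 2, 1, 1, 0),
    np_other = c(6, 6, 6, 6, 7, 7, 4, 4, 5),
    synaptic = c(3, 3, 3, 2, 2, 2, 1, 1, 1),        # 2.50 vs 1.00
    sensory = c(11, 10, 10, 10, 10, 10, 8, 8, 8),   # 10.17 vs 8.00
    gaba = c(2, 1, 1, 1, 1, 1, 0, 0, 0))            # 1.17 vs 0 -> nc

  pools <- list(np_restricted = sprintf("NPG%02d", 1:16),
                np_other = sprintf("NPG%02d", 17:53),
                synaptic = gene_sets$synaptic_pathways,
                sensory = gene_sets$abnormal_sensory,
                gaba = gene_sets$gabaergic_synapse)

  alloc <- make_allocator()
  parts <- list()
  for (si in seq_len(nrow(subjects))) {
    id <- subjects$id[si]
    n_set <- 0L
    for (block in names(counts)) {
      n <- counts[[block]][si]
      n_set <- n_set + n
      if (n == 0L) next
      pool <- pools[[block]]
      genes <- pool[((seq_len(n) + si) %% length(pool)) + 1L]
      chrom <- paste0("chr", (seq_len(n) %% 4) + 1)
      pos <- vapply(chrom, alloc, 0L)
      parts[[length(parts) + 1L]] <-
        make_variant_rows(n, id, chrom, pos, genes, class = "MISSENSE",
                          n_deleterious = rep(6L, n))
    }
    # filler: bring each subject's genome-wide missense total to a value
    # near the cohort mean, varying by subject so percent burdens are not
    # within-group constant
    totals <- c(90L, 92L, 94L, 96L, 98L, 100L, 91L, 95L, 99L)
    n_fill <- totals[si] - n_set
    chrom <- paste0("chr", (seq_len(n_fill) %% 4) + 1)
    pos <- vapply(chrom, alloc, 0L)
    parts[[length(parts) + 1L]] <-
      make_variant_rows(n_fill, id, chrom, pos,
                        genes = sprintf("FIL%03d", seq_len(n_fill)),
                        class = "MISSENSE",
                        n_deleterious = rep(2L, n_fill))
    # one LoF and one splicing-regulatory filler so all three broad-class
    # totals are nonzero
    parts[[length(parts) + 1L]] <-
      make_variant_rows(1L, id, "chr1", alloc("chr1"), genes = "FILLOF",
                        class = "STOP_GAIN")
    parts[[length(parts) + 1L]] <-
      make_variant_rows(1L, id, "chr2", alloc("chr2"), genes = "FILSPL",
                        class = "INTRONIC", splice_score = -12)
  }

  calls <- do.call(rbind, lapply(parts, `[[`, "calls"))
  annotations <- do.call(rbind, lapply(parts, `[[`, "annotations"))
  rownames(calls) <- rownames(annotations) <- NULL
  annotations <- annotations[!duplicated(annotations$key), , drop = FALSE]

  structure(list(subjects = subjects, calls = calls,
                 annotations = annotations, gene_sets = gene_sets,
                 dgcr8_genes = dgcr8_genes, regions_22q11 = REGION_22Q11,
                 prs_records = NULL, ref_intervals = NULL,
                 ncrna_catalog = NULL,
                 config = list(seed = 20260920, worked_example = TRUE)),
            class = "synthetic_cohort")
}

#' Write a cohort bundle to disk
#'
#' Emits exactly the files [read_cohort()] (and the pipeline) reads:
#' `subjects.tsv`, `calls.vcf`, `annotations.tsv`, `gene_sets.gmt`,
#' `dgcr8_genes.txt`, `exclude_22q11.bed`, and, when present,
#' `prs_snps.tsv`, `ref_intervals/<id>.bed`, `ncrna_catalog.tsv`.
#'
#' @param bundle A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_subjects(bundle$subjects, file.path(dir, "subjects.tsv"))
  write_vcf(bundle$calls, bundle$subjects, file.path(dir, "calls.vcf"))
  write_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_gene_sets(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  writeLines(bundle$dgcr8_genes, file.path(dir, "dgcr8_genes.txt"))
  write_regions(bundle$regions_22q11, file.path(dir, "exclude_22q11.bed"))
  if (!is.null(bundle$prs_records)) {
    write_prs_table(bundle$prs_records, file.path(dir, "prs_snps.tsv"))
    write_reference_intervals(bundle$ref_intervals, bundle$subjects,
                              file.path(dir, "ref_intervals"))
  }
  if (!is.null(bundle$ncrna_catalog)) {
    write_ncrna_catalog(bundle$ncrna_catalog,
                        file.path(dir, "ncrna_catalog.tsv"))
  }
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Inverse of [write_cohort()]; optional inputs (PRS panel, reference
#' intervals, ncRNA catalog) are NULL when their files are absent.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `synthetic_cohort`-shaped list.
#' @export
read_cohort <- function(dir) {
  subjects <- read_subjects(file.path(dir, "subjects.tsv"))
  prs_path <- file.path(dir, "prs_snps.tsv")
  nc_path <- file.path(dir, "ncrna_catalog.tsv")
  ri_dir <- file.path(dir, "ref_intervals")
  structure(list(
    subjects = subjects,
    calls = read_variant_calls(file.path(dir, "calls.vcf"), subjects),
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    gene_sets = read_gene_sets(file.path(dir, "gene_sets.gmt")),
    dgcr8_genes = read_gene_list(file.path(dir, "dgcr8_genes.txt")),
    regions_22q11 = read_regions(file.path(dir, "exclude_22q11.bed")),
    prs_records = if (file.exists(prs_path)) read_prs_table(prs_path),
    ref_intervals = if (dir.exists(ri_dir)) {
      read_reference_intervals(ri_dir, subjects)
    },
    ncrna_catalog = if (file.exists(nc_path)) read_ncrna_catalog(nc_path),
    config = NULL), class = "synthetic_cohort")
}
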