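# Writers that emit exactly the formats cohort_io reads. The synthetic
# generator uses these to materialize a cohort on disk; round-trip identity
# (write then read) is part of the test contract.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a subject table
#' @param subjects Subject data.frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_subjects <- function(subjects, path) write_tsv(subjects, path)

#' Write variant calls as a multi-sample VCF
#'
#' Emits a minimal VCFv4.2 with GT-only genotypes, one sample column per
#' subject. Calls flagged `high_quality = FALSE` get `FILTER=LowQual`.
#' Calls at the same site for different subjects share one record.
#'
#' @param calls Call table (see [read_variant_calls()]).
#' @param subjects Subject table (defines the sample columns).
#' @param path Output VCF path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, subjects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", subjects$id), collapse = "\t")), con)
  if (nrow(calls) == 0L) return(invisible(path))
  site <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  for (k in unique(site)) {
    rows <- calls[site == k, , drop = FALSE]
    gts <- setNames(rep("0/0", nrow(subjects)), subjects$id)
    for (j in seq_len(nrow(rows))) {
      gts[rows$subject_id[j]] <- switch(rows$genotype[j],
                                        HET = "0/1", HOM_ALT = "1/1", HEMI = "1")
    }
    filt <- if (all(rows$high_quality)) "PASS" else "LowQual"
    writeLines(paste(c(rows$chrom[1], rows$pos[1], ".", rows$ref[1],
                       rows$alt[1], ".", filt, ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write an annotation table
#' @param annotations Annotation data.frame from [read_annotations()] or the
#'   synthetic generator.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations
  df$key <- NULL
  tool_cols <- grep("^tool[0-9]+$", names(df), value = TRUE)
  for (tc in tool_cols) df[[tc]] <- as.integer(df[[tc]])
  df$class <- tolower(df$class)
  write_tsv(df, path)
}

#' Write gene sets as GMT
#' @param gene_sets Named list of gene vectors (optionally with a `sources`
#'   attribute).
#' @param path Output GMT path.
#' @return The path, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  sources <- attr(gene_sets, "sources") %||%
    setNames(rep("custom", length(gene_sets)), names(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, sources[[nm]], gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write regions as BED
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_regions <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PRS SNP table
#' @param records PRS records from [read_prs_table()] or the generator.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_prs_table <- function(records, path) {
  df <- data.frame(chrom = records$chrom, pos = records$pos,
                   effect_allele = records$effect_allele,
                   other_allele = records$other_allele,
                   ref_allele = records$ref_allele,
                   or = exp(records$log_or), assoc_p = records$assoc_p,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write the ncRNA catalog
#' @param catalog Catalog data.frame from [read_ncrna_catalog()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_ncrna_catalog <- function(catalog, path) {
  df <- catalog
  df$kind <- ifelse(df$kind == "LINCRNA", "lincRNA", "miRNA")
  write_tsv(df, path)
}

#' Write per-subject reference intervals
#' @param intervals data.frame with `subject_id`, `chrom`, `start`, `end`.
#' @param subjects Subject table (one BED written per subject).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_reference_intervals <- function(intervals, subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in subjects$id) {
    reg <- intervals[intervals$subject_id == id, c("chrom", "start", "end"),
                     drop = FALSE]
    write_regions(reg, file.path(dir, paste0(id, ".bed")))
  }
  invisible(dir)
}
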