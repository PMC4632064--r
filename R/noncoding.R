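# Noncoding RNA burden: conservation-ranked lincRNA gene-hit counts and the
# miRNA variant tally under a broadened rarity threshold.

#' Top conserved genes of a catalog
#'
#' Ranks lincRNA genes by their regional conservation score (descending)
#' and returns the top `ceiling(fraction * N)`; ties at the cut are all
#' included.
#'
#' @param catalog ncRNA catalog data.frame (see [read_ncrna_catalog()]).
#' @param fraction Fraction in (0, 1]; default 0.10 (top decile).
#' @param kind Which genes to rank; default `"LINCRNA"`.
#' @return Character vector of gene ids.
#' @export
rank_conserved <- function(catalog, fraction = 0.10, kind = "LINCRNA") {
  stopifnot(fraction > 0, fraction <= 1)
  genes <- unique(catalog[catalog$kind == kind, c("id", "conservation")])
  if (!nrow(genes)) return(character())
  genes <- genes[order(-genes$conservation, genes$id), , drop = FALSE]
  m <- ceiling(fraction * nrow(genes))
  cut_score <- genes$conservation[m]
  genes$id[genes$conservation >= cut_score]
}

# Qualifying noncoding variants: high-quality, rare at the given threshold,
# inside a catalog region of the given kind. Returns calls annotated with
# the hit gene id (one row per call x overlapping gene).
qualifying_nc_variants <- function(calls, annotations, catalog, kind,
                                   rarity_threshold) {
  regions <- catalog[catalog$kind == kind, , drop = FALSE]
  if (!nrow(calls) || !nrow(regions)) {
    return(cbind(calls[0, , drop = FALSE],
                 nc_gene = character(0), stringsAsFactors = FALSE))
  }
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  idx <- match(key, annotations$key)
  rare <- rep(TRUE, nrow(calls))
  rare[!is.na(idx)] <- is_rare(annotations[idx[!is.na(idx)], , drop = FALSE],
                               rarity_threshold)
  cand <- calls[calls$high_quality & rare, , drop = FALSE]
  if (!nrow(cand)) {
    return(cbind(calls[0, , drop = FALSE],
                 nc_gene = character(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (r in seq_len(nrow(regions))) {
    hit <- cand$chrom == regions$chrom[r] &
      regions$start[r] < cand$pos & cand$pos <= regions$end[r]
    if (any(hit)) {
      out[[length(out) + 1L]] <- cbind(cand[hit, , drop = FALSE],
                                       nc_gene = regions$id[r],
                                       stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(cbind(calls[0, , drop = FALSE],
                 nc_gene = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # one row per (call, gene): collapse duplicates from split exon regions
  res[!duplicated(paste(res$subject_id, res$chrom, res$pos, res$ref,
                        res$alt, res$nc_gene)), , drop = FALSE]
}

#' lincRNA burden (distinct genes hit per subject)
#'
#' A variant qualifies when high-quality, rare (strictly below
#' `rarity_threshold` in every observed database) and inside a lincRNA
#' region. The burden unit is distinct lincRNA genes hit per subject,
#' computed for the whole catalog and for the conserved subset; the
#' one-sided t test (case > control) runs on the conserved-subset counts.
#'
#' @param calls Variant call table.
#' @param annotations Annotation table (for allele frequencies).
#' @param catalog ncRNA catalog.
#' @param conserved_set Gene ids from [rank_conserved()].
#' @param rarity_threshold Default 0.01.
#' @param unit `"genes"` (default, distinct genes hit) or `"variants"`.
#' @param subjects Subject table.
#' @return List with `per_subject` (rows `subject_id`, `group`,
#'   `n_lincRNA_genes_hit`, `n_conserved_lincRNA_genes_hit`), `test`
#'   (one-sided t on the conserved counts, or NULL with `reason` when the
#'   conserved set is empty), `effect_ratio`, `hits` (qualifying
#'   variant-gene pairs).
#' @export
lincRNA_burden <- function(calls, annotations, catalog, conserved_set,
                           rarity_threshold = 0.01,
                           unit = c("genes", "variants"), subjects) {
  unit <- match.arg(unit)
  hits <- qualifying_nc_variants(calls, annotations, catalog, "LINCRNA",
                                 rarity_threshold)
  per_subject <- data.frame(
    subject_id = subjects$id, group = subjects$group,
    n_lincRNA_genes_hit = vapply(subjects$id, function(id) {
      h <- hits[hits$subject_id == id, , drop = FALSE]
      if (unit == "genes") length(unique(h$nc_gene)) else nrow(h)
    }, integer(1)),
    n_conserved_lincRNA_genes_hit = vapply(subjects$id, function(id) {
      h <- hits[hits$subject_id == id & hits$nc_gene %in% conserved_set, ,
                drop = FALSE]
      if (unit == "genes") length(unique(h$nc_gene)) else nrow(h)
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!length(conserved_set)) {
    message("lincRNA burden: conserved set empty; test skipped")
    return(list(per_subject = per_subject, test = NULL,
                reason = "empty conserved set", effect_ratio = NA_real_,
                hits = hits))
  }
  cv <- per_subject$n_conserved_lincRNA_genes_hit
  grp <- per_subject$group
  er <- ratio_of_means(cv[grp == "CASE"], cv[grp == "CONTROL"])
  if (sum(grp == "CASE") < 2L || sum(grp == "CONTROL") < 2L) {
    message("lincRNA burden: fewer than 2 subjects in a group; test skipped")
    return(list(per_subject = per_subject, test = NULL,
                reason = "group too small", effect_ratio = er, hits = hits))
  }
  tt <- one_sided_t_test(cv[grp == "CASE"], cv[grp == "CONTROL"])
  list(per_subject = per_subject, test = tt, reason = NULL,
       effect_ratio = er, hits = hits)
}

#' miRNA variant tally
#'
#' Counts qualifying variants (high-quality, rare at the broadened
#' `rarity_threshold`, default < 5%) inside miRNA regions per subject. The
#' burden test is attempted only when both groups have at least one
#' subject with a nonzero count and the cohort-wide total reaches
#' `min_total`; otherwise a tally-only decision is returned (small miRNA
#' genes rarely carry enough rare variants to test).
#'
#' @param calls Variant call table.
#' @param annotations Annotation table.
#' @param catalog ncRNA catalog.
#' @param rarity_threshold Default 0.05.
#' @param min_total Minimum cohort-wide count to test; default 5.
#' @param subjects Subject table.
#' @return List with `per_subject` (`subject_id`, `group`,
#'   `n_mirna_variants`), `decision` (`"tested"`/`"tally_only"`), `test`
#'   (NULL when tally-only).
#' @export
mirna_tally <- function(calls, annotations, catalog, rarity_threshold = 0.05,
                        min_total = 5, subjects) {
  hits <- qualifying_nc_variants(calls, annotations, catalog, "MIRNA",
                                 rarity_threshold)
  per_subject <- data.frame(
    subject_id = subjects$id, group = subjects$group,
    n_mirna_variants = vapply(subjects$id, function(id) {
      h <- hits[hits$subject_id == id, , drop = FALSE]
      length(unique(paste(h$chrom, h$pos, h$ref, h$alt)))
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  cnt <- per_subject$n_mirna_variants
  grp <- per_subject$group
  testable <- any(cnt[grp == "CASE"] > 0) && any(cnt[grp == "CONTROL"] > 0) &&
    sum(cnt) >= min_total &&
    sum(grp == "CASE") >= 2L && sum(grp == "CONTROL") >= 2L
  if (!testable) {
    return(list(per_subject = per_subject, decision = "tally_only",
                test = NULL))
  }
  list(per_subject = per_subject, decision = "tested",
       test = one_sided_t_test(cnt[grp == "CASE"], cnt[grp == "CONTROL"]))
}
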