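# Variant prioritization: quality and rarity screens, damage-category
# assignment, and the a priori exclusion of the intact 22q11.2 region and
# chromosome X (tallied separately, never tested).

CATEGORIES <- c("LOF", "DAMAGING_MISSENSE", "SPLICE_REG")

#' Rarity test across population databases
#'
#' A variant is rare when every *observed* database allele frequency is
#' strictly below the threshold; a database where the variant is unobserved
#' (missing cell) imposes no constraint, so a variant absent everywhere is
#' rare.
#'
#' @param annotation One annotation row (or a data.frame of rows).
#' @param threshold Strict upper bound on each observed AF; default 0.01.
#' @return Logical vector, one value per annotation row.
#' @export
is_rare <- function(annotation, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  af_cols <- grep("^af_", names(annotation), value = TRUE)
  if (!length(af_cols)) return(rep(TRUE, nrow(annotation)))
  af <- as.matrix(annotation[, af_cols, drop = FALSE])
  apply(af, 1L, function(x) all(is.na(x) | x < threshold))
}

#' Assign a damage category to an annotated variant
#'
#' Categories, most severe first: `LOF` (stop-gain, frameshift, core splice
#' site), `DAMAGING_MISSENSE` (missense called deleterious by at least
#' `consensus_k` of `consensus_n` prediction tools), `SPLICE_REG` (splicing
#' regulatory: predicted exon-inclusion change at or below
#' `splice_threshold`, for variants outside the LoF classes). A variant
#' qualifying under several rules gets the most severe category; variants
#' qualifying under none get `NA`.
#'
#' @param annotation Annotation row(s).
#' @param splice_threshold Negative score cutoff; default -5 (percent-units
#'   of predicted exon-inclusion change).
#' @param consensus_k,consensus_n Tool-consensus rule; default 5 of 7.
#' @return Character vector of categories (`NA` = no category).
#' @export
assign_category <- function(annotation, splice_threshold = -5,
                            consensus_k = 5, consensus_n = 7) {
  stopifnot(splice_threshold < 0, consensus_k >= 1, consensus_k <= consensus_n)
  tool_cols <- grep("^tool[0-9]+$", names(annotation), value = TRUE)
  if (length(tool_cols) != consensus_n) {
    stop_rv(sprintf("expected %d tool columns, found %d",
                    consensus_n, length(tool_cols)))
  }
  cls <- annotation$class
  out <- rep(NA_character_, nrow(annotation))
  out[cls %in% LOF_CLASSES] <- "LOF"

  mis <- which(cls == "MISSENSE")
  if (length(mis)) {
    tools <- as.matrix(annotation[mis, tool_cols, drop = FALSE])
    if (any(rowSums(!is.na(tools)) != consensus_n)) {
      stop_rv("missense variant without a call from all ", consensus_n,
              " prediction tools")
    }
    out[mis][rowSums(tools) >= consensus_k] <- "DAMAGING_MISSENSE"
  }

  splice <- which(is.na(out) & !cls %in% LOF_CLASSES &
                    !is.na(annotation$splice_score) &
                    annotation$splice_score <= splice_threshold)
  out[splice] <- "SPLICE_REG"
  out
}

broad_class_of <- function(category) {
  switch(category,
         LOF = "LOF_CLASS",
         DAMAGING_MISSENSE = "MISSENSE_CLASS",
         SPLICE_REG = "SPLICE_CLASS",
         stop_rv("unknown category: ", category))
}

#' Prioritize a cohort's variant calls
#'
#' Applies, in order: the quality screen (only `high_quality` calls), the
#' rarity screen (strict, in every observed database), category assignment,
#' and region partitioning. Qualifying variants overlapping the configured
#' 22q11.2 exclusion regions or chromosome X are tallied separately and
#' excluded from burden testing; remaining autosomal variants form the
#' retained set. Zygosity is ignored: a homozygous variant counts once
#' (haploinsufficiency counting).
#'
#' Per-subject genome-wide totals are stored both per category and per
#' broad class — all missense for `DAMAGING_MISSENSE`, all LoF-class for
#' `LOF`, the splice-qualifying variants themselves for `SPLICE_REG` — over
#' the same quality+rarity+region-filtered stream; these broad-class totals
#' are the denominators of percent normalization.
#'
#' @param calls Call table from [read_variant_calls()].
#' @param annotations Annotation table from [read_annotations()].
#' @param regions_22q11 Exclusion regions (0-based half-open), or NULL.
#' @param subjects Subject table; needed so zero-count subjects appear in
#'   the totals.
#' @param rarity_threshold Strict AF bound; default 0.01.
#' @param splice_threshold,consensus_k,consensus_n Passed to
#'   [assign_category()].
#' @return An object of class `prioritized_variants`: list with `retained`,
#'   `tally_22q11`, `tally_chrX` (data.frames of categorized variants),
#'   `totals` (subject x category counts), `class_totals` (subject x broad
#'   class counts), `subjects`, and the parameters used.
#' @export
prioritize <- function(calls, annotations, regions_22q11 = NULL,
                       subjects = NULL, rarity_threshold = 0.01,
                       splice_threshold = -5, consensus_k = 5,
                       consensus_n = 7) {
  if (is.null(subjects)) {
    subjects <- data.frame(id = unique(calls$subject_id),
                           group = NA_character_, sex = "UNKNOWN",
                           stringsAsFactors = FALSE)
  }
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  idx <- match(key, annotations$key)
  if (anyNA(idx)) {
    stop_rv("no annotation for variant key(s): ",
            paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  ann <- annotations[idx, , drop = FALSE]
  av <- cbind(calls, ann[, setdiff(names(ann), c("chrom", "pos", "ref", "alt")),
                         drop = FALSE])
  rownames(av) <- NULL

  keep <- av$high_quality & is_rare(av, rarity_threshold)
  av <- av[keep, , drop = FALSE]
  av$category <- assign_category(av, splice_threshold = splice_threshold,
                                 consensus_k = consensus_k,
                                 consensus_n = consensus_n)

  in22 <- pos_in_regions(av$chrom, av$pos, regions_22q11)
  onx <- is_chrx(av$chrom)
  cat_ok <- !is.na(av$category)
  retained <- av[cat_ok & !in22 & !onx, , drop = FALSE]
  tally22 <- av[cat_ok & in22, , drop = FALSE]
  tallyx <- av[cat_ok & onx & !in22, , drop = FALSE]

  totals <- count_by_subject(retained, retained$category, CATEGORIES, subjects)
  # Broad-class denominators come from the same quality+rarity+region-
  # filtered stream *before* the tool-consensus screen, so "all missense"
  # includes non-damaging missense.
  filtered_all <- av[!in22 & !onx, , drop = FALSE]
  bc <- ifelse(filtered_all$class %in% LOF_CLASSES, "LOF_CLASS",
        ifelse(!is.na(filtered_all$category) &
                 filtered_all$category == "SPLICE_REG", "SPLICE_CLASS",
        ifelse(filtered_all$class == "MISSENSE", "MISSENSE_CLASS",
               NA_character_)))
  class_totals <- count_by_subject(filtered_all[!is.na(bc), , drop = FALSE],
                                   bc[!is.na(bc)],
                                   c("LOF_CLASS", "MISSENSE_CLASS",
                                     "SPLICE_CLASS"), subjects)

  structure(list(retained = retained, tally_22q11 = tally22,
                 tally_chrX = tallyx, totals = totals,
                 class_totals = class_totals, subjects = subjects,
                 params = list(rarity_threshold = rarity_threshold,
                               splice_threshold = splice_threshold,
                               consensus_k = consensus_k,
                               consensus_n = consensus_n)),
            class = "prioritized_variants")
}

count_by_subject <- function(df, groups, levels, subjects) {
  tab <- table(factor(df$subject_id, levels = subjects$id),
               factor(groups, levels = levels))
  mat <- matrix(as.integer(tab), nrow = nrow(subjects),
                dimnames = list(subjects$id, levels))
  as.data.frame(mat)
}

#' @export
print.prioritized_variants <- function(x, ...) {
  cat("Prioritized variant set:\n")
  cat("  retained (autosomal, outside 22q11.2):", nrow(x$retained), "\n")
  cat("  tallied in 22q11.2 region:", nrow(x$tally_22q11), "\n")
  cat("  tallied on chromosome X:", nrow(x$tally_chrX), "\n")
  cat("  subjects:", nrow(x$subjects), "\n")
  invisible(x)
}

#' Restrict a gene set to a gene list
#'
#' Intersection restriction, used for the DGCR8-dysregulation analysis: the
#' restricted twin of set `name` is named `<name>|restricted` and may be
#' empty.
#'
#' @param genes Character vector: the gene set.
#' @param restriction Character vector: the restriction list (non-empty).
#' @param name Optional set name; the result carries `<name>|restricted` as
#'   its `name` attribute.
#' @return Character vector of the intersection, with a `name` attribute.
#' @export
restrict_to <- function(genes, restriction, name = NULL) {
  if (!length(restriction)) stop_rv("restriction list is empty")
  out <- intersect(toupper(genes), toupper(restriction))
  if (!is.null(name)) attr(out, "name") <- paste0(name, "|restricted")
  out
}
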