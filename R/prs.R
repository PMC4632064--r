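# Polygenic risk scoring: match panel SNPs against cohort calls and
# reference intervals, count effect alleles, score at association p-value
# thresholds (with negative-control bins), and compare groups.

#' Match a risk-score SNP panel against a cohort
#'
#' Per subject, each panel SNP is resolved either by a variant call at the
#' same coordinates with agreeing alleles (effect-allele count from the
#' genotype), or by falling inside one of the subject's reference intervals
#' (homozygous reference: count 2 when the effect allele is the reference
#' base, 0 otherwise). A call at the right position with non-matching
#' alleles leaves the SNP unresolved for that subject. Only SNPs resolved
#' in every subject are callable and enter scoring.
#'
#' @param calls Variant call table.
#' @param reference_intervals data.frame `subject_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param records PRS records from [read_prs_table()].
#' @param subjects Subject table.
#' @return List of class `prs_panel`: `records` (all), `callable`
#'   (callable subset, key order sorted), `allele_counts` (subjects x
#'   callable-SNP matrix of 0/1/2), `subjects`.
#' @export
match_panel <- function(calls, reference_intervals, records, subjects) {
  nsub <- nrow(subjects); nsnp <- nrow(records)
  counts <- matrix(NA_integer_, nrow = nsub, ncol = nsnp,
                   dimnames = list(subjects$id, prs_key(records)))
  for (si in seq_len(nsub)) {
    id <- subjects$id[si]
    sc <- calls[calls$subject_id == id, , drop = FALSE]
    sri <- reference_intervals[reference_intervals$subject_id == id, ,
                               drop = FALSE]
    call_idx <- match(paste(records$chrom, records$pos),
                      paste(sc$chrom, sc$pos))
    in_ref <- pos_in_regions(records$chrom, records$pos, sri)
    for (j in seq_len(nsnp)) {
      ci <- call_idx[j]
      if (!is.na(ci)) {
        if (!isTRUE(sc$high_quality[ci])) next  # unresolved: failed filters
        a <- effect_allele_count(sc[ci, ], records[j, ])
        if (!is.na(a)) counts[si, j] <- a
      } else if (in_ref[j]) {
        counts[si, j] <-
          if (records$effect_allele[j] == records$ref_allele[j]) 2L else 0L
      }
    }
  }
  callable <- which(colSums(is.na(counts)) == 0L)
  callable <- callable[order(colnames(counts)[callable])]
  structure(list(records = records,
                 callable = records[callable, , drop = FALSE],
                 allele_counts = counts[, callable, drop = FALSE],
                 subjects = subjects),
            class = "prs_panel")
}

prs_key <- function(records) {
  paste(records$chrom, records$pos, records$effect_allele, sep = ":")
}

# Effect-allele count from one biallelic call; NA when panel and call
# alleles disagree.
effect_allele_count <- function(call, rec) {
  alt_copies <- switch(call$genotype, HET = 1L, HOM_ALT = 2L, HEMI = 1L)
  ploidy <- if (call$genotype == "HEMI") 1L else 2L
  alleles_match <- setequal(c(call$ref, call$alt),
                            c(rec$effect_allele, rec$other_allele)) &&
    call$ref == rec$ref_allele
  if (!alleles_match) return(NA_integer_)
  if (rec$effect_allele == call$alt) alt_copies else ploidy - alt_copies
}

#' Subset PRS records by association p-value
#'
#' Threshold bins follow the printed rules exactly: inclusive for the risk
#' bins (`assoc_p <= tau`) and strict for the negative-control bins
#' (`assoc_p > tau`).
#'
#' @param records PRS record data.frame.
#' @param tau Threshold in (0, 1).
#' @param rule `"le"` (`<= tau`) or `"gt"` (`> tau`).
#' @return The matching rows of `records`.
#' @export
subset_by_threshold <- function(records, tau, rule = c("le", "gt")) {
  rule <- match.arg(rule)
  stopifnot(tau > 0, tau < 1)
  keep <- if (rule == "le") records$assoc_p <= tau else records$assoc_p > tau
  records[keep, , drop = FALSE]
}

#' Per-subject polygenic risk scores
#'
#' `S_i = sum_j a_ij * beta_j` over the callable SNPs of a threshold
#' subset; the sum is accumulated in sorted key order so scores do not
#' depend on record order.
#'
#' @param panel `prs_panel` from [match_panel()].
#' @param subset Rows of `panel$callable` (e.g. from
#'   [subset_by_threshold()]); SNPs outside the callable set are ignored.
#' @param label Optional threshold label attached to the result.
#' @return data.frame with `subject_id`, `group`, `score`, `n_snps`,
#'   `threshold`.
#' @export
score_subjects <- function(panel, subset, label = NA_character_) {
  keys <- sort(intersect(prs_key(subset), colnames(panel$allele_counts)))
  if (length(keys)) {
    beta <- panel$callable$log_or[match(keys, prs_key(panel$callable))]
    a <- panel$allele_counts[, keys, drop = FALSE]
    scores <- as.vector(a %*% beta)
  } else {
    scores <- rep(0, nrow(panel$subjects))
  }
  data.frame(subject_id = panel$subjects$id, group = panel$subjects$group,
             score = scores, n_snps = length(keys), threshold = label,
             stringsAsFactors = FALSE)
}

#' Compare PRS distributions between groups
#'
#' One-sided pooled t test (case > control), one-sided Wilcoxon rank-sum
#' (exact for combined n <= 20 without ties, tie-corrected normal
#' approximation otherwise), and the maximum correctly-predicted
#' percentage: balanced accuracy (mean of per-group percent correct) of
#' the rule "case if score >= threshold", maximized over midpoints of
#' adjacent distinct scores. Overall (unbalanced) accuracy by flag.
#'
#' @param scores Score data.frame from [score_subjects()] (needs `score`
#'   and `group`).
#' @param balanced Use balanced accuracy (default) or overall accuracy.
#' @return List with `t_p`, `wilcoxon_p`, `max_correct_pct`,
#'   `best_threshold`, `mean_case`, `mean_control`.
#' @export
compare_groups <- function(scores, balanced = TRUE) {
  cs <- scores$score[scores$group == "CASE"]
  ct <- scores$score[scores$group == "CONTROL"]
  stopifnot(length(cs) >= 1L, length(ct) >= 1L)
  all_equal <- length(unique(scores$score)) == 1L
  if (all_equal) {
    return(list(t_p = 0.5, wilcoxon_p = 0.5, max_correct_pct = 50,
                best_threshold = NA_real_, mean_case = mean(cs),
                mean_control = mean(ct)))
  }
  t_p <- if (length(cs) >= 2L && length(ct) >= 2L) {
    one_sided_t_test(cs, ct)$p
  } else NA_real_
  n <- length(cs) + length(ct)
  has_ties <- anyDuplicated(c(cs, ct)) > 0L
  w <- suppressWarnings(
    wilcox.test(cs, ct, alternative = "greater",
                exact = (n <= 20L && !has_ties), correct = TRUE))
  sweep_pts <- sort(unique(scores$score))
  thresholds <- (head(sweep_pts, -1L) + sweep_pts[-1L]) / 2
  acc <- vapply(thresholds, function(th) {
    pc_case <- mean(cs >= th); pc_ctrl <- mean(ct < th)
    if (balanced) {
      50 * (pc_case + pc_ctrl)
    } else {
      100 * (sum(cs >= th) + sum(ct < th)) / n
    }
  }, numeric(1))
  best <- which.max(acc)
  list(t_p = t_p, wilcoxon_p = w$p.value, max_correct_pct = acc[best],
       best_threshold = thresholds[best], mean_case = mean(cs),
       mean_control = mean(ct))
}

#' Run the PRS threshold sweep
#'
#' Scores every subject in each risk bin (`<= 0.001`, `<= 0.0001`,
#' `<= 0.00001`) and negative-control bin (`> 0.5`, `> 0.9`), and compares
#' groups per bin.
#'
#' @param panel `prs_panel` from [match_panel()].
#' @param risk_thresholds Inclusive upper bounds for risk bins.
#' @param control_thresholds Strict lower bounds for control bins.
#' @param balanced Passed to [compare_groups()].
#' @return List with `scores` (long data.frame over bins) and `comparison`
#'   (one row per bin).
#' @export
prs_threshold_sweep <- function(panel,
                                risk_thresholds = c(0.001, 0.0001, 0.00001),
                                control_thresholds = c(0.5, 0.9),
                                balanced = TRUE) {
  bins <- c(setNames(lapply(risk_thresholds, function(x) list(tau = x, rule = "le")),
                     paste0("le_", risk_thresholds)),
            setNames(lapply(control_thresholds, function(x) list(tau = x, rule = "gt")),
                     paste0("gt_", control_thresholds)))
  scores <- list(); comps <- list()
  for (nm in names(bins)) {
    sub <- subset_by_threshold(panel$callable, bins[[nm]]$tau, bins[[nm]]$rule)
    sc <- score_subjects(panel, sub, label = nm)
    cmp <- compare_groups(sc, balanced = balanced)
    scores[[nm]] <- sc
    comps[[nm]] <- data.frame(threshold = nm, n_snps = sc$n_snps[1],
                              mean_case = cmp$mean_case,
                              mean_control = cmp$mean_control,
                              t_p = cmp$t_p, wilcoxon_p = cmp$wilcoxon_p,
                              max_correct_pct = cmp$max_correct_pct,
                              stringsAsFactors = FALSE)
  }
  list(scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
       comparison = do.call(rbind, c(comps, list(make.row.names = FALSE))))
}
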