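# Gene-set burden testing: per-subject counts, percent normalization,
# one-sided pooled t tests, the screening rule, the joint Hotelling
# T-squared stage, and ratio-of-means effect sizes.

#' Per-subject gene-set burden matrix
#'
#' Counts, for every subject, the retained variants of one category whose
#' annotated genes intersect the gene set (a variant is counted once even
#' when it hits several set genes), and normalizes by the subject's
#' genome-wide broad-class total: the percent burden is
#' `b = 100 * k / K` (0 when `K = 0`).
#'
#' @param pvs A `prioritized_variants` object from [prioritize()].
#' @param gene_set Character vector of gene symbols.
#' @param category One of `"LOF"`, `"DAMAGING_MISSENSE"`, `"SPLICE_REG"`.
#' @return data.frame with `subject_id`, `group`, `k`, `K`, `percent`.
#' @export
burden_matrix <- function(pvs, gene_set, category) {
  stopifnot(inherits(pvs, "prioritized_variants"),
            category %in% CATEGORIES, length(gene_set) >= 1L)
  gene_set <- toupper(gene_set)
  ret <- pvs$retained[pvs$retained$category == category, , drop = FALSE]
  in_set <- vapply(strsplit(ret$genes, "[,;]"), function(g) {
    any(trimws(g) %in% gene_set)
  }, logical(1))
  hits <- ret[in_set, , drop = FALSE]
  k <- vapply(pvs$subjects$id,
              function(id) sum(hits$subject_id == id), integer(1))
  K <- pvs$class_totals[pvs$subjects$id, broad_class_of(category)]
  data.frame(subject_id = pvs$subjects$id, group = pvs$subjects$group,
             k = as.integer(k), K = as.integer(K),
             percent = ifelse(K > 0, 100 * k / K, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sided two-sample t test (case > control)
#'
#' Pooled-variance Student t by default; Welch by flag. The one-sided p is
#' the upper-tail probability of the observed statistic. Degenerate inputs
#' (zero pooled variance) return p = 0.5 for equal means, or 0/1 by the
#' sign of the mean difference, with a `degenerate` flag.
#'
#' @param case_values,control_values Numeric vectors (>= 2 each).
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return List with `t`, `p`, `df`, `mean_case`, `mean_control`,
#'   `degenerate`.
#' @export
one_sided_t_test <- function(case_values, control_values, welch = FALSE) {
  n1 <- length(case_values); n2 <- length(control_values)
  stopifnot(n1 >= 2L, n2 >= 2L)
  m1 <- mean(case_values); m2 <- mean(control_values)
  if (welch) {
    tt <- t.test(case_values, control_values, alternative = "greater",
                 var.equal = FALSE)
    return(list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter), mean_case = m1, mean_control = m2,
                degenerate = FALSE))
  }
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var(case_values) + (n2 - 1) * var(control_values)) / df
  if (sp2 <= 0) {
    p <- if (isTRUE(all.equal(m1, m2))) 0.5 else if (m1 > m2) 0 else 1
    return(list(t = if (m1 == m2) 0 else sign(m1 - m2) * Inf, p = p, df = df,
                mean_case = m1, mean_control = m2, degenerate = TRUE))
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, p = pt(tstat, df, lower.tail = FALSE), df = df,
       mean_case = m1, mean_control = m2, degenerate = FALSE)
}

#' Ratio-of-means effect size
#'
#' `mean(case) / mean(control)`; `NA` ("nc", not calculable) when the
#' control mean is zero, matching the convention that no effect size is
#' reported when the comparison group carries no variants.
#'
#' @param case_counts,control_counts Non-negative numeric vectors.
#' @return A single number, or `NA` when not calculable.
#' @export
ratio_of_means <- function(case_counts, control_counts) {
  stopifnot(all(case_counts >= 0), all(control_counts >= 0))
  m2 <- mean(control_counts)
  if (m2 == 0) return(NA_real_)
  mean(case_counts) / m2
}

#' Screening rule for the joint test
#'
#' A gene set enters the joint multivariate stage when any variant category
#' shows nominally significant one-sided burden: strictly below
#' `p_missense` for damaging missense, strictly below `p_lof_splice` for
#' LoF and splicing-regulatory.
#'
#' @param results data.frame with columns `gene_set`, `category`, `p`.
#' @param p_missense Threshold for `DAMAGING_MISSENSE`; default 0.05.
#' @param p_lof_splice Threshold for `LOF`/`SPLICE_REG`; default 0.10.
#' @return Character vector of gene-set names passing the screen.
#' @export
screen_gene_sets <- function(results, p_missense = 0.05, p_lof_splice = 0.10) {
  stopifnot(p_missense > 0, p_missense < 1, p_lof_splice > 0, p_lof_splice < 1)
  thr <- ifelse(results$category == "DAMAGING_MISSENSE",
                p_missense, p_lof_splice)
  pass <- !is.na(results$p) & results$p < thr
  unique(results$gene_set[pass])
}

#' Two-sample Hotelling T-squared test
#'
#' Joint multivariate comparison of the per-subject category burden
#' vectors: `T2 = (n1*n2/(n1+n2)) * d' S^-1 d` with `d` the mean-difference
#' vector and `S` the pooled covariance, transformed to
#' `F = ((n1+n2-p-1) / (p*(n1+n2-2))) * T2` on `(p, n1+n2-p-1)` degrees of
#' freedom.
#'
#' @param case_matrix,control_matrix Numeric matrices, subjects x variables
#'   (same columns).
#' @param drop_degenerate Drop zero-variance variables (and lower `p`)
#'   instead of erroring on a singular pooled covariance.
#' @return List with `t2`, `f_statistic`, `df1`, `df2`, `p_value`,
#'   `variables` (columns actually tested), `dropped`.
#' @export
hotelling_t2 <- function(case_matrix, control_matrix, drop_degenerate = FALSE) {
  x <- as.matrix(case_matrix); y <- as.matrix(control_matrix)
  stopifnot(ncol(x) == ncol(y))
  vars <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- colnames(y) <- vars
  dropped <- character()
  if (drop_degenerate) {
    # a variable is degenerate when it has no within-group variance in
    # either group (its pooled variance is zero)
    keep <- apply(x, 2L, var) + apply(y, 2L, var) > 0
    dropped <- vars[!keep]
    if (!any(keep)) stop_rv("all variables have zero variance")
    x <- x[, keep, drop = FALSE]; y <- y[, keep, drop = FALSE]
    vars <- vars[keep]
  }
  n1 <- nrow(x); n2 <- nrow(y); p <- ncol(x)
  if (n1 + n2 - 2L < p) {
    stop_rv("too few subjects for ", p, " variables (need n1+n2-2 >= p)")
  }
  d <- colMeans(x) - colMeans(y)
  S <- ((n1 - 1) * cov_or_zero(x) + (n2 - 1) * cov_or_zero(y)) / (n1 + n2 - 2)
  qrS <- qr(S)
  if (qrS$rank < p) {
    zv <- vars[diag(S) == 0]
    stop_rv("singular pooled covariance",
            if (length(zv)) paste0(" (zero-variance variable(s): ",
                                   paste(zv, collapse = ", "),
                                   "); rerun with drop_degenerate = TRUE")
            else "")
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S, d))
  df1 <- p
  df2 <- n1 + n2 - p - 1L
  f <- (df2 / (p * (n1 + n2 - 2))) * t2
  list(t2 = t2, f_statistic = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       variables = vars, dropped = dropped)
}

cov_or_zero <- function(m) {
  if (nrow(m) < 2L) matrix(0, ncol(m), ncol(m)) else stats::cov(m)
}

#' Run the full gene-set burden analysis
#'
#' For every gene set (and, when a restriction list is given, its
#' restricted twin) and every variant category: builds the burden matrix,
#' tests percent burdens one-sided (case > control), and estimates the
#' ratio of raw count means. Sets passing the screening rule then get the
#' joint Hotelling test on the per-subject percent vectors of the three
#' categories (raw-count scale by option). Displayed means are raw
#' per-subject count means; tests run on percents.
#'
#' @param pvs `prioritized_variants` object.
#' @param gene_sets Named list of gene vectors.
#' @param restriction Optional gene list for restricted twins (e.g., genes
#'   dysregulated under DGCR8 haploinsufficiency).
#' @param p_missense,p_lof_splice Screening thresholds (defaults 0.05, 0.10).
#' @param hotelling_scale `"percent"` (default) or `"count"`.
#' @param drop_degenerate Passed to [hotelling_t2()]; default TRUE (small
#'   cohorts routinely have an all-zero category).
#' @param welch Use Welch t instead of pooled.
#' @param display_max_genes Sets at or above this size are flagged out of
#'   the display filter (default 2000).
#' @return List of class `burden_analysis`: `results` (one row per set x
#'   category), `joint` (one row per screened set), `screened` (names),
#'   and the parameters.
#' @export
run_burden_analysis <- function(pvs, gene_sets, restriction = NULL,
                                p_missense = 0.05, p_lof_splice = 0.10,
                                hotelling_scale = c("percent", "count"),
                                drop_degenerate = TRUE, welch = FALSE,
                                display_max_genes = 2000) {
  hotelling_scale <- match.arg(hotelling_scale)
  all_sets <- list()
  for (nm in names(gene_sets)) {
    all_sets[[nm]] <- list(genes = gene_sets[[nm]], restricted = FALSE)
    if (!is.null(restriction)) {
      rg <- restrict_to(gene_sets[[nm]], restriction, name = nm)
      if (length(rg)) {
        all_sets[[paste0(nm, "|restricted")]] <-
          list(genes = as.character(rg), restricted = TRUE)
      }
    }
  }
  if (!length(all_sets)) {
    return(structure(list(results = empty_burden_results(),
                          joint = empty_joint_results(),
                          screened = character(),
                          params = list()), class = "burden_analysis"))
  }

  grp <- pvs$subjects$group
  rows <- list(); mats <- list()
  for (nm in names(all_sets)) {
    entry <- all_sets[[nm]]
    percents <- list()
    for (category in CATEGORIES) {
      bm <- burden_matrix(pvs, entry$genes, category)
      percents[[category]] <- bm$percent
      tt <- one_sided_t_test(bm$percent[grp == "CASE"],
                             bm$percent[grp == "CONTROL"], welch = welch)
      er <- ratio_of_means(bm$k[grp == "CASE"], bm$k[grp == "CONTROL"])
      n_case_genes <- n_genes_hit(pvs, entry$genes, category, "CASE")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = nm, restricted = entry$restricted, category = category,
        n_genes = length(entry$genes), n_case_genes = n_case_genes,
        mean_case = mean(bm$k[grp == "CASE"]),
        mean_control = mean(bm$k[grp == "CONTROL"]),
        t = tt$t, p = tt$p, effect_ratio = er,
        display = length(entry$genes) < display_max_genes,
        stringsAsFactors = FALSE)
    }
    mats[[nm]] <- do.call(cbind, percents)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  screened <- screen_gene_sets(results, p_missense, p_lof_splice)
  joint <- list()
  for (nm in screened) {
    m <- mats[[nm]]
    if (hotelling_scale == "count") {
      m <- sapply(CATEGORIES, function(category) {
        burden_matrix(pvs, all_sets[[nm]]$genes, category)$k
      })
    }
    ht <- tryCatch(
      hotelling_t2(m[grp == "CASE", , drop = FALSE],
                   m[grp == "CONTROL", , drop = FALSE],
                   drop_degenerate = drop_degenerate),
      error = function(e) e)
    joint[[length(joint) + 1L]] <- if (inherits(ht, "error")) {
      data.frame(gene_set = nm, t2 = NA_real_, f_statistic = NA_real_,
                 df1 = NA_integer_, df2 = NA_integer_, p_value = NA_real_,
                 dropped = NA_character_, note = conditionMessage(ht),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_set = nm, t2 = ht$t2, f_statistic = ht$f_statistic,
                 df1 = ht$df1, df2 = ht$df2, p_value = ht$p_value,
                 dropped = paste(ht$dropped, collapse = ","), note = "",
                 stringsAsFactors = FALSE)
    }
  }
  joint <- if (length(joint)) do.call(rbind, joint) else empty_joint_results()
  rownames(joint) <- NULL

  structure(list(results = results, joint = joint, screened = screened,
                 params = list(p_missense = p_missense,
                               p_lof_splice = p_lof_splice,
                               hotelling_scale = hotelling_scale,
                               drop_degenerate = drop_degenerate,
                               welch = welch,
                               display_max_genes = display_max_genes)),
            class = "burden_analysis")
}

n_genes_hit <- function(pvs, gene_set, category, group) {
  ids <- pvs$subjects$id[pvs$subjects$group == group]
  ret <- pvs$retained[pvs$retained$category == category &
                        pvs$retained$subject_id %in% ids, , drop = FALSE]
  genes <- unlist(strsplit(ret$genes, "[,;]"))
  length(intersect(trimws(genes), toupper(gene_set)))
}

empty_burden_results <- function() {
  data.frame(gene_set = character(), restricted = logical(),
             category = character(), n_genes = integer(),
             n_case_genes = integer(), mean_case = numeric(),
             mean_control = numeric(), t = numeric(), p = numeric(),
             effect_ratio = numeric(), display = logical(),
             stringsAsFactors = FALSE)
}

empty_joint_results <- function() {
  data.frame(gene_set = character(), t2 = numeric(), f_statistic = numeric(),
             df1 = integer(), df2 = integer(), p_value = numeric(),
             dropped = character(), note = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.burden_analysis <- function(x, ...) {
  cat("Gene-set burden analysis:", length(unique(x$results$gene_set)),
      "set(s),", nrow(x$results), "tests\n")
  cat("  screened into joint stage:",
      if (length(x$screened)) paste(x$screened, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
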