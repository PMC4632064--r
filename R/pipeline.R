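# Configuration-driven end-to-end runs: prioritization -> coding burden
# (with optional DGCR8 restriction) -> screening -> joint test -> power
# projection -> PRS -> noncoding burden, with TSV/JSON reports and a run
# manifest. Optional stages (PRS, noncoding) are skipped with a log line
# when their inputs are absent.

#' Default pipeline parameters
#'
#' @return Named list of every tunable pipeline parameter with its default.
#' @export
default_params <- function() {
  list(rarity_threshold = 0.01, mirna_rarity_threshold = 0.05,
       consensus_k = 5, consensus_n = 7, splice_score_cutoff = -5,
       screen_p_missense = 0.05, screen_p_lof_splice = 0.10,
       hotelling_scale = "percent", drop_degenerate = TRUE, welch = FALSE,
       display_max_genes = 2000, conserved_fraction = 0.10,
       mirna_min_total = 5, power_n_grid = c(25, 50, 100),
       power_alpha = 0.05, power_sided = "one",
       prs_risk_thresholds = c(0.001, 0.0001, 0.00001),
       prs_control_thresholds = c(0.5, 0.9), prs_balanced = TRUE)
}

#' Run the full analysis pipeline
#'
#' @param config Either a path to a YAML file or a list, with elements
#'   `inputs` (paths: `dir` for a [write_cohort()] bundle, or individual
#'   `subjects`, `vcf`, `annotations`, `gene_sets`, `exclusion_bed`,
#'   `dgcr8_genes`, `prs_table`, `ref_intervals_dir`, `ncrna_catalog`),
#'   `params` (overrides of [default_params()]) and `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return List of class `pipeline_result` with `prioritized`, `burden`,
#'   `power`, `prs`, `noncoding`, `params`, `manifest`; reports are written
#'   to `out_dir` when given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_params(), config$params %||% list())
  inputs <- config$inputs %||% list()
  out_dir <- out_dir %||% config$out_dir

  bundle <- if (!is.null(inputs$dir)) {
    read_cohort(inputs$dir)
  } else {
    load_inputs(inputs)
  }
  stage_log("inputs", sprintf("%d subjects, %d calls, %d annotated variants, %d gene sets",
                              nrow(bundle$subjects), nrow(bundle$calls),
                              nrow(bundle$annotations),
                              length(bundle$gene_sets)))

  pvs <- prioritize(bundle$calls, bundle$annotations,
                    regions_22q11 = bundle$regions_22q11,
                    subjects = bundle$subjects,
                    rarity_threshold = params$rarity_threshold,
                    splice_threshold = params$splice_score_cutoff,
                    consensus_k = params$consensus_k,
                    consensus_n = params$consensus_n)
  stage_log("prioritize",
            sprintf("%d calls in -> %d retained, %d in 22q11.2 tally, %d on X",
                    nrow(bundle$calls), nrow(pvs$retained),
                    nrow(pvs$tally_22q11), nrow(pvs$tally_chrX)))

  burden <- run_burden_analysis(
    pvs, bundle$gene_sets, restriction = bundle$dgcr8_genes,
    p_missense = params$screen_p_missense,
    p_lof_splice = params$screen_p_lof_splice,
    hotelling_scale = params$hotelling_scale,
    drop_degenerate = params$drop_degenerate, welch = params$welch,
    display_max_genes = params$display_max_genes)
  stage_log("burden", sprintf("%d tests, %d set(s) screened into joint stage",
                              nrow(burden$results), length(burden$screened)))

  power <- pipeline_power(pvs, bundle$gene_sets, burden, params)
  stage_log("power", sprintf("%d projection cells", nrow(power)))

  prs <- NULL
  if (!is.null(bundle$prs_records) && !is.null(bundle$ref_intervals)) {
    panel <- match_panel(bundle$calls, bundle$ref_intervals,
                         bundle$prs_records, bundle$subjects)
    prs <- prs_threshold_sweep(panel,
                               risk_thresholds = params$prs_risk_thresholds,
                               control_thresholds = params$prs_control_thresholds,
                               balanced = params$prs_balanced)
    prs$n_callable <- nrow(panel$callable)
    stage_log("prs", sprintf("%d/%d panel SNPs callable in all subjects",
                             nrow(panel$callable), nrow(bundle$prs_records)))
  } else {
    stage_log("prs", "skipped (no PRS table or reference intervals)")
  }

  noncoding <- NULL
  if (!is.null(bundle$ncrna_catalog)) {
    conserved <- rank_conserved(bundle$ncrna_catalog,
                                fraction = params$conserved_fraction)
    linc <- lincRNA_burden(bundle$calls, bundle$annotations,
                           bundle$ncrna_catalog, conserved,
                           rarity_threshold = params$rarity_threshold,
                           subjects = bundle$subjects)
    mir <- mirna_tally(bundle$calls, bundle$annotations,
                       bundle$ncrna_catalog,
                       rarity_threshold = params$mirna_rarity_threshold,
                       min_total = params$mirna_min_total,
                       subjects = bundle$subjects)
    noncoding <- list(conserved = conserved, lincRNA = linc, mirna = mir)
    stage_log("noncoding", sprintf("%d conserved lincRNA genes; miRNA decision: %s",
                                   length(conserved), mir$decision))
  } else {
    stage_log("noncoding", "skipped (no ncRNA catalog)")
  }

  manifest <- list(params = params,
                   seed = bundle$config$seed %||% NA,
                   inputs = input_checksums(inputs),
                   n_subjects = nrow(bundle$subjects),
                   n_calls = nrow(bundle$calls))
  result <- structure(list(prioritized = pvs, burden = burden, power = power,
                           prs = prs, noncoding = noncoding, params = params,
                           manifest = manifest), class = "pipeline_result")
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

load_inputs <- function(inputs) {
  required <- c("subjects", "vcf", "annotations", "gene_sets")
  miss <- required[!vapply(required, function(k) !is.null(inputs[[k]]),
                           logical(1))]
  if (length(miss)) {
    stop_rv("pipeline config missing input path(s): ",
            paste(miss, collapse = ", "))
  }
  subjects <- read_subjects(inputs$subjects)
  list(subjects = subjects,
       calls = read_variant_calls(inputs$vcf, subjects),
       annotations = read_annotations(inputs$annotations),
       gene_sets = read_gene_sets(inputs$gene_sets),
       dgcr8_genes = if (!is.null(inputs$dgcr8_genes)) {
         read_gene_list(inputs$dgcr8_genes)
       },
       regions_22q11 = if (!is.null(inputs$exclusion_bed)) {
         read_regions(inputs$exclusion_bed)
       } else REGION_22Q11,
       prs_records = if (!is.null(inputs$prs_table)) {
         read_prs_table(inputs$prs_table)
       },
       ref_intervals = if (!is.null(inputs$ref_intervals_dir)) {
         read_reference_intervals(inputs$ref_intervals_dir, subjects)
       },
       ncrna_catalog = if (!is.null(inputs$ncrna_catalog)) {
         read_ncrna_catalog(inputs$ncrna_catalog)
       },
       config = list(seed = NA))
}

# Cohen's d per screened set and category (on percent burdens), projected
# over the configured n grid.
pipeline_power <- function(pvs, gene_sets, burden, params) {
  sets <- intersect(burden$screened, names(gene_sets))
  ds <- numeric()
  grp <- pvs$subjects$group
  for (nm in sets) {
    for (category in CATEGORIES) {
      bm <- burden_matrix(pvs, gene_sets[[nm]], category)
      d <- cohens_d(bm$percent[grp == "CASE"], bm$percent[grp == "CONTROL"])
      if (!d$undefined) ds[paste(nm, category, sep = ":")] <- d$d
    }
  }
  power_table(ds, n_grid = params$power_n_grid, alpha = params$power_alpha,
              sided = params$power_sided)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Write the pipeline report bundle
#'
#' Deterministic file set with stable column order: a Table-2-style burden
#' TSV (`burden_table.tsv`, means and ratios to 2 decimals, p to 3, `nc`
#' for non-calculable ratios), `joint_tests.tsv`, `power_table.tsv`,
#' `prs_comparison.tsv`/`prs_scores.tsv`, `noncoding_burden.tsv`, a JSON
#' result bundle and `manifest.json`.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- result$burden$results
  tab <- data.frame(
    gene_set = sub("\\|restricted$", "", res$gene_set),
    restricted = ifelse(res$restricted, "yes", "no"),
    category = res$category,
    total_n = res$n_genes,
    n_case_genes = res$n_case_genes,
    mean_case = sprintf("%.2f", res$mean_case),
    mean_control = sprintf("%.2f", res$mean_control),
    p = sprintf("%.3f", res$p),
    effect_ratio = ifelse(is.na(res$effect_ratio), "nc",
                          sprintf("%.2f", res$effect_ratio)),
    display = ifelse(res$display, "yes", "no"),
    stringsAsFactors = FALSE)
  write_tsv(tab, file.path(out_dir, "burden_table.tsv"))
  write_tsv(result$burden$joint, file.path(out_dir, "joint_tests.tsv"))
  write_tsv(result$power, file.path(out_dir, "power_table.tsv"))
  if (!is.null(result$prs)) {
    write_tsv(result$prs$comparison, file.path(out_dir, "prs_comparison.tsv"))
    write_tsv(result$prs$scores, file.path(out_dir, "prs_scores.tsv"))
  }
  if (!is.null(result$noncoding)) {
    nc <- merge(result$noncoding$lincRNA$per_subject,
                result$noncoding$mirna$per_subject[
                  , c("subject_id", "n_mirna_variants")],
                by = "subject_id", sort = FALSE)
    write_tsv(nc, file.path(out_dir, "noncoding_burden.tsv"))
  }
  json <- list(
    burden = result$burden$results,
    joint = result$burden$joint,
    screened = result$burden$screened,
    power = result$power,
    prs = if (!is.null(result$prs)) result$prs$comparison,
    noncoding = if (!is.null(result$noncoding)) {
      list(test_p = result$noncoding$lincRNA$test$p %||% NA,
           effect_ratio = result$noncoding$lincRNA$effect_ratio,
           mirna_decision = result$noncoding$mirna$decision)
    })
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

input_checksums <- function(inputs) {
  paths <- unlist(inputs, use.names = TRUE)
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p) &&
                          !dir.exists(p), logical(1))]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:\n")
  print(x$burden)
  if (!is.null(x$prs)) {
    cat("  PRS bins:", paste(x$prs$comparison$threshold, collapse = ", "), "\n")
  }
  if (!is.null(x$noncoding)) {
    cat("  lincRNA conserved-burden p:",
        format(x$noncoding$lincRNA$test$p %||% NA, digits = 3), "\n")
  }
  invisible(x)
}
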