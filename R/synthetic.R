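# Synthetic cohort generator. Emulates the statistical structure the burden
# analysis assumes — per-subject Poisson variant loads with configurable
# case:control rate ratios inside gene sets, a biallelic PRS SNP panel with
# optional between-group effect-allele frequency shifts, and an ncRNA
# catalog with Beta-distributed conservation — on a toy genome with a
# designated 22q11.2 interval and chromosome X so the exclusion logic is
# exercised. Coordinates carry no signal beyond region membership.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions of the emulated cohort: 6 cases vs
#' 3 controls, 13.8 LoF and 94.3 missense variants per subject, lincRNA
#' hit means 2.0 (case) and 1.3 (control). Counts are Poisson by default;
#' a negative-binomial option adds overdispersion.
#'
#' @param n_case,n_control Group sizes (defaults 6 and 3).
#' @param seed Integer RNG seed; a fixed seed makes the generated bundle
#'   (and written files) identical across runs.
#' @param lof_rate,missense_rate,splice_rate Mean genome-wide qualifying
#'   variants per subject per category (defaults 13.8, 94.3, 20).
#' @param damaging_fraction Share of missense passing the 5-of-7 tool
#'   consensus (default 0.35).
#' @param n_genes Coding gene universe size (default 1000).
#' @param gene_set_sizes Named integer vector of set sizes.
#' @param geneset_effect Named case:control rate-ratio vector; names must
#'   be gene sets from `gene_set_sizes`, and effect sets are generated on
#'   disjoint gene pools. 1 = null.
#' @param region22_rate,chrx_rate Mean qualifying variants per subject in
#'   the 22q11.2 interval / on chromosome X (defaults 0.35, 0.9).
#' @param noise_rate Mean non-qualifying variants per subject (common,
#'   low-quality, synonymous; exercises the filters).
#' @param prs_n_snps,prs_causal_fraction,prs_freq_shift PRS panel size
#'   (500), causal share (0.1) and case effect-allele frequency shift of
#'   causal SNPs (0.15); causal SNPs get `assoc_p <= 0.001` and positive
#'   log odds ratios.
#' @param lincRNA_hit_rates Named vector `c(case=, control=)` of mean
#'   distinct lincRNA genes hit per subject (defaults 2.0, 1.3).
#' @param n_lincRNA,n_mirna Catalog sizes (60, 15).
#' @param mirna_rate Mean miRNA variants per subject (default 0.1).
#' @param conservation_shape Beta shape parameters for regional
#'   conservation (default c(2, 5)).
#' @param nb_dispersion NULL for Poisson counts (default), or a positive
#'   `size` parameter for negative-binomial counts.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 6, n_control = 3, seed = 1,
                             lof_rate = 13.8, missense_rate = 94.3,
                             splice_rate = 20, damaging_fraction = 0.35,
                             n_genes = 1000,
                             gene_set_sizes = c(neuron_projection = 53,
                                                synaptic_pathways = 15,
                                                abnormal_sensory = 58,
                                                postsynaptic_density = 120),
                             geneset_effect = NULL,
                             region22_rate = 0.35, chrx_rate = 0.9,
                             noise_rate = 10,
                             prs_n_snps = 500, prs_causal_fraction = 0.1,
                             prs_freq_shift = 0.15,
                             lincRNA_hit_rates = c(case = 2.0, control = 1.3),
                             n_lincRNA = 60, n_mirna = 15, mirna_rate = 0.1,
                             conservation_shape = c(2, 5),
                             nb_dispersion = NULL) {
  cfg <- list(n_case = n_case, n_control = n_control, seed = as.integer(seed),
              lof_rate = lof_rate, missense_rate = missense_rate,
              splice_rate = splice_rate,
              damaging_fraction = damaging_fraction, n_genes = n_genes,
              gene_set_sizes = gene_set_sizes,
              geneset_effect = geneset_effect,
              region22_rate = region22_rate, chrx_rate = chrx_rate,
              noise_rate = noise_rate, prs_n_snps = prs_n_snps,
              prs_causal_fraction = prs_causal_fraction,
              prs_freq_shift = prs_freq_shift,
              lincRNA_hit_rates = lincRNA_hit_rates,
              n_lincRNA = n_lincRNA, n_mirna = n_mirna,
              mirna_rate = mirna_rate,
              conservation_shape = conservation_shape,
              nb_dispersion = nb_dispersion)
  rates <- c(cfg$lof_rate, cfg$missense_rate, cfg$splice_rate,
             cfg$region22_rate, cfg$chrx_rate, cfg$noise_rate,
             cfg$mirna_rate, cfg$lincRNA_hit_rates)
  if (any(rates < 0)) stop_rv("rates must be non-negative")
  if (cfg$n_case < 1 || cfg$n_control < 1) stop_rv("need >= 1 subject per group")
  if (cfg$damaging_fraction < 0 || cfg$damaging_fraction > 1) {
    stop_rv("damaging_fraction must be in [0,1]")
  }
  if (!is.null(cfg$geneset_effect)) {
    bad <- setdiff(names(cfg$geneset_effect), names(cfg$gene_set_sizes))
    if (length(bad)) {
      stop_rv("geneset_effect names unknown set(s): ",
              paste(bad, collapse = ", "))
    }
    if (any(cfg$geneset_effect <= 0)) stop_rv("rate ratios must be > 0")
  }
  structure(cfg, class = "synthetic_config")
}

REGION_22Q11 <- data.frame(chrom = "chr22", start = 18900000L,
                           end = 21500000L, stringsAsFactors = FALSE)

rcount <- function(n, mu, cfg) {
  if (is.null(cfg$nb_dispersion)) {
    rpois(n, mu)
  } else {
    stats::rnbinom(n, size = cfg$nb_dispersion, mu = mu)
  }
}

# position allocator: sequential unique positions per chromosome
make_allocator <- function() {
  counters <- new.env(parent = emptyenv())
  function(chrom, lo = 1000000L) {
    cur <- if (exists(chrom, counters)) get(chrom, counters) else lo
    assign(chrom, cur + 7L, counters)
    cur
  }
}

rand_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = unname(ref), alt = unname(alt))
}

# AF columns: rare variants observed in a random subset of 5 databases,
# all observed frequencies strictly below `cap`.
rare_afs <- function(n, cap = 0.01) {
  af <- matrix(NA_real_, n, 5, dimnames = list(NULL, paste0("af_db", 1:5)))
  for (j in 1:5) {
    obs <- runif(n) < 0.5
    af[obs, j] <- runif(sum(obs), 0, cap * 0.95)
  }
  af
}

tool_matrix <- function(n_deleterious) {
  t(vapply(n_deleterious, function(k) {
    v <- rep(FALSE, 7)
    if (k > 0) v[sample.int(7, k)] <- TRUE
    v
  }, logical(7)))
}

make_variant_rows <- function(n, subject_id, chrom, pos, genes, class,
                              n_deleterious = rep(0L, n),
                              splice_score = rep(NA_real_, n),
                              af = NULL, genotype = NULL,
                              high_quality = rep(TRUE, n)) {
  if (n == 0L) return(NULL)
  al <- rand_alleles(n)
  if (is.null(af)) af <- rare_afs(n)
  if (is.null(genotype)) {
    genotype <- ifelse(runif(n) < 0.05, "HOM_ALT", "HET")
  }
  tools <- tool_matrix(n_deleterious)
  colnames(tools) <- paste0("tool", 1:7)
  calls <- data.frame(subject_id = subject_id, chrom = chrom, pos = pos,
                      ref = al$ref, alt = al$alt, genotype = genotype,
                      high_quality = high_quality, stringsAsFactors = FALSE)
  ann <- data.frame(key = variant_key(chrom, pos, al$ref, al$alt),
                    chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
                    genes = genes, class = class, stringsAsFactors = FALSE)
  ann <- cbind(ann, as.data.frame(af), as.data.frame(tools),
               splice_score = splice_score)
  list(calls = calls, annotations = ann)
}

sample_n_del <- function(n, damaging_fraction) {
  dam <- runif(n) < damaging_fraction
  ifelse(dam, sample(5:7, n, replace = TRUE), sample(0:4, n, replace = TRUE))
}

category_rows <- function(n, subject_id, genes_pool, category, cfg, alloc,
                          chroms = paste0("chr", 1:4)) {
  if (n == 0L) return(NULL)
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- vapply(chrom, alloc, 0L)
  genes <- sample(genes_pool, n, replace = TRUE)
  switch(category,
    LOF = make_variant_rows(n, subject_id, chrom, pos, genes,
            class = sample(LOF_CLASSES, n, replace = TRUE)),
    MISSENSE = make_variant_rows(n, subject_id, chrom, pos, genes,
            class = "MISSENSE",
            n_deleterious = sample_n_del(n, cfg$damaging_fraction)),
    SPLICE = make_variant_rows(n, subject_id, chrom, pos, genes,
            class = "INTRONIC", splice_score = -runif(n, 5, 30)))
}

#' Generate a synthetic cohort bundle
#'
#' Draws the complete set of pipeline inputs in memory: subjects, variant
#' calls with annotations (coding categories, 22q11.2/X extras,
#' filter-exercising noise), gene sets, a DGCR8-style restriction list,
#' the 22q11.2 exclusion region, a PRS panel with per-subject calls and
#' reference intervals, and the ncRNA catalog with lincRNA/miRNA variant
#' hits. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort` with elements `subjects`,
#'   `calls`, `annotations`, `gene_sets`, `dgcr8_genes`, `regions_22q11`,
#'   `prs_records`, `ref_intervals`, `ncrna_catalog`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  subjects <- data.frame(
    id = c(sprintf("SCZ%d", seq_len(cfg$n_case)),
           sprintf("NP%d", seq_len(cfg$n_control))),
    group = rep(c("CASE", "CONTROL"), c(cfg$n_case, cfg$n_control)),
    sex = sample(c("MALE", "FEMALE"), cfg$n_case + cfg$n_control,
                 replace = TRUE),
    stringsAsFactors = FALSE)

  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  # effect sets get disjoint gene pools so their rate ratios are exact
  effect_names <- names(cfg$geneset_effect)
  gene_sets <- list()
  pool <- universe
  for (nm in names(cfg$gene_set_sizes)) {
    sz <- cfg$gene_set_sizes[[nm]]
    if (nm %in% effect_names) {
      gene_sets[[nm]] <- pool[seq_len(sz)]
      pool <- pool[-seq_len(sz)]
    } else {
      gene_sets[[nm]] <- sort(sample(universe, sz))
    }
  }
  attr(gene_sets, "sources") <- setNames(rep("synthetic", length(gene_sets)),
                                         names(gene_sets))
  background <- setdiff(pool, unlist(gene_sets[effect_names]))
  dgcr8_genes <- sort(sample(universe, min(300, cfg$n_genes)))

  genes_22q11 <- sprintf("Q22G%02d", 1:5)
  genes_x <- sprintf("XG%02d", 1:10)
  alloc <- make_allocator()
  alloc22 <- local({
    cur <- 19000000L
    function() { cur <<- cur + 11L; cur }
  })

  parts <- list()
  add <- function(x) if (!is.null(x)) parts[[length(parts) + 1L]] <<- x
  for (si in seq_len(nrow(subjects))) {
    id <- subjects$id[si]
    is_case <- subjects$group[si] == "CASE"
    for (categ in c("LOF", "MISSENSE", "SPLICE")) {
      rate <- switch(categ, LOF = cfg$lof_rate, MISSENSE = cfg$missense_rate,
                     SPLICE = cfg$splice_rate)
      share_bg <- length(background) / cfg$n_genes
      add(category_rows(rcount(1, rate * share_bg, cfg), id, background,
                        categ, cfg, alloc))
      for (nm in effect_names) {
        base <- rate * length(gene_sets[[nm]]) / cfg$n_genes
        mu <- if (is_case) base * cfg$geneset_effect[[nm]] else base
        add(category_rows(rcount(1, mu, cfg), id, gene_sets[[nm]], categ,
                          cfg, alloc))
      }
    }
    # a priori excluded regions: damaging missense inside 22q11.2 and on X
    n22 <- rcount(1, cfg$region22_rate, cfg)
    if (n22 > 0) {
      add(make_variant_rows(n22, id, "chr22",
                            vapply(seq_len(n22), function(i) alloc22(), 0L),
                            sample(genes_22q11, n22, replace = TRUE),
                            class = "MISSENSE",
                            n_deleterious = sample(5:7, n22, replace = TRUE)))
    }
    nx <- rcount(1, cfg$chrx_rate, cfg)
    if (nx > 0) {
      geno <- if (subjects$sex[si] == "MALE") rep("HEMI", nx) else NULL
      add(make_variant_rows(nx, id, "chrX",
                            vapply(rep("chrX", nx), alloc, 0L),
                            sample(genes_x, nx, replace = TRUE),
                            class = "MISSENSE",
                            n_deleterious = sample(5:7, nx, replace = TRUE),
                            genotype = geno))
    }
    # non-qualifying noise: common, low-quality, and synonymous variants
    nnoise <- rcount(1, cfg$noise_rate, cfg)
    if (nnoise > 0) {
      kind <- sample(c("common", "lowq", "syn"), nnoise, replace = TRUE)
      chrom <- sample(paste0("chr", 1:4), nnoise, replace = TRUE)
      pos <- vapply(chrom, alloc, 0L)
      genes <- sample(universe, nnoise, replace = TRUE)
      af <- rare_afs(nnoise)
      af[kind == "common", ] <- matrix(runif(5 * sum(kind == "common"),
                                             0.02, 0.5),
                                       ncol = 5)
      add(make_variant_rows(nnoise, id, chrom, pos, genes,
                            class = ifelse(kind == "syn", "SYNONYMOUS",
                                           "MISSENSE"),
                            n_deleterious = ifelse(kind == "syn", 0L,
                              sample(5:7, nnoise, replace = TRUE)),
                            af = af,
                            high_quality = kind != "lowq"))
    }
  }

  prs <- generate_prs_panel(cfg, subjects)
  nc <- generate_ncrna(cfg, subjects, alloc)

  calls <- do.call(rbind, c(lapply(parts, `[[`, "calls"),
                            list(prs$calls, nc$calls)))
  annotations <- do.call(rbind, c(lapply(parts, `[[`, "annotations"),
                                  list(prs$annotations, nc$annotations)))
  rownames(calls) <- rownames(annotations) <- NULL
  annotations <- annotations[!duplicated(annotations$key), , drop = FALSE]

  structure(list(subjects = subjects, calls = calls,
                 annotations = annotations, gene_sets = gene_sets,
                 dgcr8_genes = dgcr8_genes, regions_22q11 = REGION_22Q11,
                 prs_records = prs$records, ref_intervals = prs$ref_intervals,
                 ncrna_catalog = nc$catalog, config = cfg),
            class = "synthetic_cohort")
}

#' Generate a synthetic PRS panel with per-subject genotypes
#'
#' Biallelic SNPs with Hardy-Weinberg genotypes. Causal SNPs (share
#' `prs_causal_fraction`) get association p-values <= 0.001, positive log
#' odds ratios, and an effect-allele frequency raised by `prs_freq_shift`
#' in cases; the rest get `assoc_p ~ Uniform(0,1)` and no shift. Subjects
#' carry variant calls where they hold alternate alleles and one reference
#' interval per chromosome spanning the panel, so every panel SNP is
#' resolvable.
#'
#' @param config A [synthetic_config()].
#' @param subjects Subject table.
#' @return List with `records`, `calls`, `annotations`, `ref_intervals`,
#'   `causal` (logical per record), `counts` (subjects x SNPs effect-allele
#'   count matrix).
#' @export
generate_prs_panel <- function(config, subjects) {
  n <- config$prs_n_snps
  if (n == 0L) {
    return(list(records = NULL, calls = empty_calls(), annotations = NULL,
                ref_intervals = NULL, causal = logical(), counts = NULL))
  }
  chrom <- "chr9"
  pos <- 5000000L + 100L * seq_len(n)
  al <- rand_alleles(n)
  causal <- seq_len(n) <= round(n * config$prs_causal_fraction)
  # effect allele: alternate for causal (risk) SNPs, random otherwise
  effect_is_alt <- ifelse(causal, TRUE, runif(n) < 0.5)
  effect <- ifelse(effect_is_alt, al$alt, al$ref)
  other <- ifelse(effect_is_alt, al$ref, al$alt)
  log_or <- ifelse(causal, log(runif(n, 1.1, 1.3)),
                   log(runif(n, 0.85, 1.18)))
  assoc_p <- ifelse(causal, runif(n, 1e-6, 0.001), runif(n))
  records <- data.frame(chrom = chrom, pos = pos, effect_allele = effect,
                        other_allele = other, ref_allele = al$ref,
                        log_or = log_or, assoc_p = assoc_p,
                        stringsAsFactors = FALSE)

  p0 <- runif(n, 0.1, 0.9)  # effect-allele frequency, controls
  nsub <- nrow(subjects)
  counts <- matrix(0L, nsub, n, dimnames = list(subjects$id, NULL))
  for (si in seq_len(nsub)) {
    p <- p0
    if (subjects$group[si] == "CASE") {
      p[causal] <- pmin(pmax(p[causal] + config$prs_freq_shift, 0.01), 0.99)
    }
    counts[si, ] <- rbinom(n, 2L, p)
  }
  alt_counts <- counts
  alt_counts[, !effect_is_alt] <- 2L - counts[, !effect_is_alt]

  call_rows <- list()
  for (si in seq_len(nsub)) {
    carry <- which(alt_counts[si, ] > 0L)
    if (!length(carry)) next
    call_rows[[length(call_rows) + 1L]] <- data.frame(
      subject_id = subjects$id[si], chrom = chrom, pos = pos[carry],
      ref = al$ref[carry], alt = al$alt[carry],
      genotype = ifelse(alt_counts[si, carry] == 2L, "HOM_ALT", "HET"),
      high_quality = TRUE, stringsAsFactors = FALSE)
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else empty_calls()

  af <- matrix(rep(pmin(pmax(ifelse(effect_is_alt, p0, 1 - p0), 0.01), 0.99),
                   5), ncol = 5,
               dimnames = list(NULL, paste0("af_db", 1:5)))
  tools <- matrix(FALSE, n, 7, dimnames = list(NULL, paste0("tool", 1:7)))
  annotations <- cbind(
    data.frame(key = variant_key(chrom, pos, al$ref, al$alt), chrom = chrom,
               pos = pos, ref = al$ref, alt = al$alt, genes = "",
               class = "INTERGENIC", stringsAsFactors = FALSE),
    as.data.frame(af), as.data.frame(tools), splice_score = NA_real_)

  ref_intervals <- do.call(rbind, lapply(subjects$id, function(id) {
    data.frame(subject_id = id, chrom = chrom,
               start = min(pos) - 1L, end = max(pos) + 1L,
               stringsAsFactors = FALSE)
  }))
  list(records = records, calls = calls, annotations = annotations,
       ref_intervals = ref_intervals, causal = causal, counts = counts)
}

generate_ncrna <- function(config, subjects, alloc) {
  nl <- config$n_lincRNA; nm <- config$n_mirna
  linc <- do.call(rbind, lapply(seq_len(nl), function(i) {
    base <- 1000000L + i * 10000L
    data.frame(id = sprintf("LINC%03d", i), kind = "LINCRNA", chrom = "chr5",
               start = c(base, base + 5000L), end = c(base + 1500L, base + 6500L),
               conservation = NA_real_, stringsAsFactors = FALSE)
  }))
  if (is.null(linc)) {
    linc <- data.frame(id = character(), kind = character(),
                       chrom = character(), start = integer(),
                       end = integer(), conservation = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    linc_cons <- rbeta(nl, config$conservation_shape[1],
                       config$conservation_shape[2])
    linc$conservation <- rep(linc_cons, each = 2L)
  }
  mir <- if (nm == 0L) linc[0, ] else
    data.frame(id = sprintf("MIR%03d", seq_len(nm)), kind = "MIRNA",
                    chrom = "chr6",
                    start = 2000000L + seq_len(nm) * 5000L,
                    end = 2000000L + seq_len(nm) * 5000L + 80L,
                    conservation = rbeta(nm, config$conservation_shape[1],
                                         config$conservation_shape[2]),
                    stringsAsFactors = FALSE)
  catalog <- rbind(linc, mir)

  parts <- list()
  for (si in seq_len(nrow(subjects))) {
    id <- subjects$id[si]
    rate <- if (subjects$group[si] == "CASE") {
      config$lincRNA_hit_rates[["case"]]
    } else config$lincRNA_hit_rates[["control"]]
    nhit <- min(rcount(1, rate, config), nl)
    if (nhit > 0) {
      gidx <- sample.int(nl, nhit)  # distinct genes hit
      base <- 1000000L + gidx * 10000L
      pos <- base + sample.int(1500L, nhit, replace = TRUE)
      parts[[length(parts) + 1L]] <-
        make_variant_rows(nhit, id, "chr5", pos,
                          genes = sprintf("LINC%03d", gidx),
                          class = "NONCODING_EXONIC")
    }
    nmir <- rcount(1, config$mirna_rate, config)
    if (nmir > 0) {
      gidx <- sample.int(nm, nmir, replace = TRUE)
      pos <- 2000000L + gidx * 5000L + sample.int(80L, nmir, replace = TRUE)
      # half only rare under the broadened (<5%) miRNA threshold
      af <- rare_afs(nmir, cap = 0.01)
      broad <- runif(nmir) < 0.5
      af[broad, ] <- matrix(runif(5 * sum(broad), 0.011, 0.045),
                            ncol = 5)
      parts[[length(parts) + 1L]] <-
        make_variant_rows(nmir, id, "chr6", pos,
                          genes = sprintf("MIR%03d", gidx),
                          class = "NONCODING_EXONIC", af = af)
    }
  }
  calls <- do.call(rbind, lapply(parts, `[[`, "calls"))
  annotations <- do.call(rbind, lapply(parts, `[[`, "annotations"))
  if (is.null(calls)) {
    calls <- empty_calls(); annotations <- NULL
  }
  list(catalog = catalog, calls = calls, annotations = annotations)
}

#' Fast counts-level burden replicate
#'
#' Draws only the per-subject in-set counts `k` and genome-wide totals `K`
#' for one gene set and category (no variant materialization):
#' `k ~ Poisson(set_rate * ratio)` for cases, `Poisson(set_rate)` for
#' controls, and `K = k + Poisson(total_rate - set_rate)`. Used for
#' calibration and recovery simulations.
#'
#' @param n_case,n_control Group sizes.
#' @param total_rate Genome-wide mean count per subject.
#' @param set_rate In-set mean count per subject (controls).
#' @param ratio Case:control rate ratio (1 = null).
#' @return data.frame with `group`, `k`, `K`, `percent`.
#' @export
simulate_burden_replicate <- function(n_case, n_control, total_rate = 94.3,
                                      set_rate = 9, ratio = 1) {
  stopifnot(set_rate <= total_rate, ratio > 0)
  k <- c(rpois(n_case, set_rate * ratio), rpois(n_control, set_rate))
  K <- k + rpois(n_case + n_control, total_rate - set_rate)
  data.frame(group = rep(c("CASE", "CONTROL"), c(n_case, n_control)),
             k = k, K = K, percent = ifelse(K > 0, 100 * k / K, 0),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_case, "cases,", x$config$n_control,
      "controls;", nrow(x$calls), "calls,", nrow(x$annotations),
      "annotated variants\n")
  invisible(x)
}
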