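# PRS panel matching, threshold subsets, scoring, and group comparison.

prs_records <- function(pos, effect, other, ref = other, or = 1.1,
                        assoc_p = 0.5, chrom = "chr9") {
  data.frame(chrom = chrom, pos = pos, effect_allele = effect,
             other_allele = other, ref_allele = ref, log_or = log(or),
             assoc_p = assoc_p, stringsAsFactors = FALSE)
}

test_that("match_panel resolves variant matches, reference intervals, and mismatches", {
  subjects <- make_subjects(1, 1)
  rec <- rbind(
    prs_records(1000L, effect = "T", other = "A"),       # HET in SCZ1
    prs_records(2000L, effect = "G", other = "C"),       # HOM_ALT in SCZ1
    prs_records(3000L, effect = "A", other = "G", ref = "A"),  # effect = ref
    prs_records(4000L, effect = "T", other = "A"),       # allele mismatch
    prs_records(5000L, effect = "C", other = "T"))       # outside ref interval
  calls <- rbind(
    make_call("SCZ1", "chr9", 1000L, "A", "T", "HET"),
    make_call("SCZ1", "chr9", 2000L, "C", "G", "HOM_ALT"),
    make_call("SCZ1", "chr9", 4000L, "A", "C", "HET"))
  ri <- rbind(
    data.frame(subject_id = "SCZ1", chrom = "chr9", start = 0L, end = 4500L,
               stringsAsFactors = FALSE),
    data.frame(subject_id = "NP1", chrom = "chr9", start = 0L, end = 4500L,
               stringsAsFactors = FALSE))
  panel <- match_panel(calls, ri, rec, subjects)

  counts <- panel$allele_counts
  key <- function(p, e) paste("chr9", p, e, sep = ":")
  # HET of the effect allele -> 1; HOM_ALT -> 2
  expect_equal(counts["SCZ1", key(1000, "T")], 1L, ignore_attr = TRUE)
  expect_equal(counts["SCZ1", key(2000, "G")], 2L, ignore_attr = TRUE)
  # reference interval: 0 when the effect allele is the alternate
  expect_equal(counts["NP1", key(1000, "T")], 0L, ignore_attr = TRUE)
  # reference interval: 2 when the effect allele is the reference base
  expect_equal(counts["SCZ1", key(3000, "A")], 2L, ignore_attr = TRUE)
  expect_equal(counts["NP1", key(3000, "A")], 2L, ignore_attr = TRUE)
  # mismatching alleles leave the SNP unresolved -> not callable in all
  expect_false(key(4000, "T") %in% colnames(counts))
  # SNP outside every reference interval and with no call is not callable
  expect_false(key(5000, "C") %in% colnames(counts))
  expect_equal(nrow(panel$callable), 3)
})

test_that("threshold subsets follow the printed inclusive/strict rules and nest", {
  rec <- prs_records(1:6 * 100L, "A", "G",
                     assoc_p = c(0.0005, 0.005, 0.00005, 0.000005, 0.95, 0.6))
  expect_equal(subset_by_threshold(rec, 0.001, "le")$pos,
               c(100L, 300L, 400L))
  expect_equal(subset_by_threshold(rec, 0.9, "gt")$pos, 500L)
  expect_equal(nrow(subset_by_threshold(rec[0, ], 0.5, "gt")), 0)
  # boundary: assoc_p exactly at tau is included under le, excluded under gt
  rec_b <- prs_records(10L, "A", "G", assoc_p = 0.001)
  expect_equal(nrow(subset_by_threshold(rec_b, 0.001, "le")), 1)
  expect_equal(nrow(subset_by_threshold(rec_b, 0.001, "gt")), 0)

  # nesting property on a synthetic panel
  cfg <- synthetic_config(seed = 5)
  panel <- generate_prs_panel(cfg, make_subjects(3, 2))
  s3 <- prs_key_set <- function(r) paste(r$chrom, r$pos, r$effect_allele)
  t1 <- s3(subset_by_threshold(panel$records, 0.00001, "le"))
  t2 <- s3(subset_by_threshold(panel$records, 0.0001, "le"))
  t3 <- s3(subset_by_threshold(panel$records, 0.001, "le"))
  expect_true(all(t1 %in% t2))
  expect_true(all(t2 %in% t3))
})

test_that("score_subjects is an order-invariant weighted allele-count sum", {
  subjects <- make_subjects(1, 1)
  rec <- rbind(prs_records(1000L, "T", "A", or = 1.2, assoc_p = 0.0004),
               prs_records(2000L, "G", "C", or = 0.9, assoc_p = 0.0004))
  calls <- rbind(make_call("SCZ1", "chr9", 1000L, "A", "T", "HOM_ALT"),
                 make_call("SCZ1", "chr9", 2000L, "C", "G", "HET"))
  ri <- expand.grid(subject_id = c("SCZ1", "NP1"), chrom = "chr9",
                    stringsAsFactors = FALSE)
  ri$start <- 0L; ri$end <- 5000L
  panel <- match_panel(calls, ri, rec, subjects)
  sc <- score_subjects(panel, panel$callable)
  expect_equal(sc$score[sc$subject_id == "SCZ1"],
               2 * log(1.2) + 1 * log(0.9), tolerance = 1e-12)
  expect_equal(sc$score[sc$subject_id == "NP1"], 0)
  expect_equal(sc$n_snps[1], 2)

  # permuting the record order leaves scores bit-identical
  panel_rev <- match_panel(calls, ri, rec[2:1, ], subjects)
  expect_identical(score_subjects(panel_rev, panel_rev$callable)$score,
                   sc$score)
  # doubling every beta doubles every score
  rec2 <- rec; rec2$log_or <- 2 * rec2$log_or
  panel2 <- match_panel(calls, ri, rec2, subjects)
  expect_equal(score_subjects(panel2, panel2$callable)$score, 2 * sc$score)
  # empty subset scores zero
  expect_equal(score_subjects(panel, panel$callable[0, ])$score, c(0, 0))
})

test_that("compare_groups: exact Wilcoxon, enumeration oracle, threshold sweep", {
  # complete separation, 6 cases above 3 controls: p = 1/84
  sc <- data.frame(score = c(4, 5, 6, 7, 8, 9, 1, 2, 3),
                   group = rep(c("CASE", "CONTROL"), c(6, 3)),
                   stringsAsFactors = FALSE)
  cmp <- compare_groups(sc)
  expect_equal(cmp$wilcoxon_p, 1 / 84, tolerance = 1e-12)
  expect_equal(cmp$wilcoxon_p,
               enumerate_wilcoxon_p(sc$score[1:6], sc$score[7:9]),
               tolerance = 1e-12)
  expect_equal(cmp$max_correct_pct, 100)

  # random (tie-free) configurations match the enumeration oracle
  set.seed(4)
  for (i in 1:10) {
    x <- sample(seq(1, 200), 6) + runif(6, 0, 0.4)
    y <- sample(seq(1, 200), 3) + runif(3, 0, 0.4)
    got <- compare_groups(data.frame(
      score = c(x, y), group = rep(c("CASE", "CONTROL"), c(6, 3))))
    expect_equal(got$wilcoxon_p, enumerate_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }

  # balanced-accuracy sweep: 6/6 cases and 2/3 controls at threshold 2.5
  sc2 <- data.frame(score = c(3, 4, 5, 6, 7, 8, 1, 2, 6.5),
                    group = rep(c("CASE", "CONTROL"), c(6, 3)),
                    stringsAsFactors = FALSE)
  cmp2 <- compare_groups(sc2)
  expect_equal(cmp2$max_correct_pct, (100 + 200 / 3) / 2, tolerance = 1e-9)
  expect_equal(cmp2$best_threshold, 2.5)

  # degenerate: identical scores
  sc3 <- data.frame(score = rep(1, 9),
                    group = rep(c("CASE", "CONTROL"), c(6, 3)))
  cmp3 <- compare_groups(sc3)
  expect_equal(cmp3$max_correct_pct, 50)
  expect_equal(cmp3$t_p, 0.5)

  # large sample falls back to the tie-corrected normal approximation
  set.seed(5)
  big <- data.frame(score = c(rnorm(15, 1), rnorm(15)),
                    group = rep(c("CASE", "CONTROL"), each = 15))
  ref <- suppressWarnings(
    wilcox.test(big$score[1:15], big$score[16:30],
                alternative = "greater", exact = FALSE, correct = TRUE))
  expect_equal(compare_groups(big)$wilcoxon_p, ref$p.value, tolerance = 1e-12)
})

test_that("negative-control bins stay null while the risk bin carries signal", {
  set.seed(6)
  cfg <- synthetic_config(seed = 6)  # 50 causal SNPs, freq shift 0.15
  subjects <- make_subjects(6, 3)
  reps <- 400
  rej_ctrl <- rej_causal <- logical(reps)
  for (r in seq_len(reps)) {
    pan <- generate_prs_panel(cfg, subjects)
    counts <- pan$counts
    score_bin <- function(keep) {
      s <- as.vector(counts[, keep, drop = FALSE] %*%
                       pan$records$log_or[keep])
      data.frame(score = s, group = subjects$group)
    }
    causal_bin <- pan$records$assoc_p <= 0.001
    ctrl_bin <- pan$records$assoc_p > 0.5
    rej_causal[r] <- compare_groups(score_bin(causal_bin))$t_p < 0.05
    rej_ctrl[r] <- compare_groups(score_bin(ctrl_bin))$t_p < 0.05
  }
  # control bin rejects at about alpha (band = 0.05 +/- 3 MC SEs at 400 reps)
  expect_gt(mean(rej_ctrl), 0.017)
  expect_lt(mean(rej_ctrl), 0.083)
  # the shifted bin rejects far above alpha
  expect_gt(mean(rej_causal), 0.5)
})
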