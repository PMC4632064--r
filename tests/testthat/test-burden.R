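# Burden matrices, one-sided t, ratio of means, screening, Hotelling.

test_that("one-sided pooled t matches t.test and handles degenerate input", {
  # hand example: pooled variance 78/7, t ~ 2.12, p ~ 0.036
  res <- one_sided_t_test(c(10, 12, 14, 16, 18, 20), c(8, 10, 12))
  oracle <- t.test(c(10, 12, 14, 16, 18, 20), c(8, 10, 12),
                   alternative = "greater", var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$p, 0.036, tolerance = 0.02)

  # parameterised cross-check against stats::t.test on random draws
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1), mean = runif(1, -2, 2))
    y <- rnorm(sample(3:10, 1))
    o <- t.test(x, y, alternative = "greater", var.equal = TRUE)
    r <- one_sided_t_test(x, y)
    expect_equal(r$p, o$p.value, tolerance = 1e-12)
    w <- t.test(x, y, alternative = "greater")
    expect_equal(one_sided_t_test(x, y, welch = TRUE)$p, w$p.value,
                 tolerance = 1e-12)
  }

  # identical groups sit at the symmetric null point
  r <- one_sided_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 0.5, tolerance = 1e-12)
  # wrong-direction shift gives p > 0.5
  expect_gt(one_sided_t_test(c(0, 1, 2), c(1, 2, 3))$p, 0.5)
  # zero pooled variance
  expect_equal(one_sided_t_test(c(2, 2), c(2, 2))$p, 0.5)
  deg <- one_sided_t_test(c(3, 3), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("ratio_of_means reproduces worked ratios and the nc convention", {
  expect_equal(ratio_of_means(c(9, 9, 9, 9, 9, 9), c(5, 5, 5)), 1.80)
  expect_true(is.na(ratio_of_means(c(1, 2), c(0, 0))))
  expect_true(is.na(ratio_of_means(c(0, 0), c(0, 0))))
  expect_equal(ratio_of_means(c(2, 4), c(2, 4)), 1.0)
})

test_that("burden_matrix counts match a brute-force recount", {
  cfg <- synthetic_config(seed = 13, n_case = 4, n_control = 3,
                          missense_rate = 40, lof_rate = 10, splice_rate = 10,
                          noise_rate = 5, prs_n_snps = 0, n_lincRNA = 4,
                          n_mirna = 2)
  b <- generate_cohort(cfg)
  pvs <- prioritize(b$calls, b$annotations, b$regions_22q11, b$subjects)
  set_genes <- b$gene_sets$neuron_projection
  bm <- burden_matrix(pvs, set_genes, "DAMAGING_MISSENSE")

  for (i in seq_len(nrow(b$subjects))) {
    id <- b$subjects$id[i]
    ret <- pvs$retained
    k_brute <- 0L
    K_brute <- 0L
    for (j in seq_len(nrow(ret))) {
      if (ret$subject_id[j] != id) next
      genes <- trimws(strsplit(ret$genes[j], "[,;]")[[1]])
      if (ret$category[j] == "DAMAGING_MISSENSE" &&
          any(genes %in% set_genes)) k_brute <- k_brute + 1L
      if (ret$class[j] == "MISSENSE") K_brute <- K_brute + 1L
    }
    expect_equal(bm$k[bm$subject_id == id], k_brute)
    expect_lte(bm$k[bm$subject_id == id], bm$K[bm$subject_id == id])
  }
  expect_true(all(bm$percent >= 0 & bm$percent <= 100))

  # a variant hitting two set genes counts once
  subjects <- make_subjects(1, 1)
  calls <- rbind(make_call("SCZ1"), make_call("NP1", pos = 101L))
  anns <- rbind(make_ann(pos = 100L, genes = "A,C"),
                make_ann(pos = 101L, genes = "B"))
  pvs2 <- prioritize(calls, anns, NULL, subjects)
  bm2 <- burden_matrix(pvs2, c("A", "C"), "DAMAGING_MISSENSE")
  expect_equal(bm2$k[bm2$subject_id == "SCZ1"], 1L)
  expect_equal(bm2$k[bm2$subject_id == "NP1"], 0L)
})

test_that("screen_gene_sets uses per-category thresholds strictly", {
  res <- data.frame(
    gene_set = c("a", "b", "b", "c", "d"),
    category = c("DAMAGING_MISSENSE", "LOF", "DAMAGING_MISSENSE", "LOF",
                 "SPLICE_REG"),
    p = c(0.009, 0.128, 0.2, 0.047, 0.10), stringsAsFactors = FALSE)
  screened <- screen_gene_sets(res)
  expect_true("a" %in% screened)   # missense 0.009 < 0.05
  expect_false("b" %in% screened)  # LoF 0.128 >= 0.10, missense 0.2
  expect_true("c" %in% screened)   # LoF 0.047 < 0.10
  expect_false("d" %in% screened)  # boundary: 0.10 is not < 0.10

  res$p <- 1
  expect_equal(length(screen_gene_sets(res)), 0)
})

test_that("Hotelling T2 reduces to the squared pooled t for one variable", {
  set.seed(2)
  for (i in 1:10) {
    x <- matrix(rnorm(6, mean = 1), ncol = 1)
    y <- matrix(rnorm(4), ncol = 1)
    ht <- hotelling_t2(x, y)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(ht$t2, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_lt(abs(ht$p_value - tt$p.value), 1e-10)
  }
})

test_that("Hotelling T2 matches an independent MANOVA computation on fixed data", {
  x <- matrix(c(3.2, 4.1, 5.0, 2.8, 3.9, 4.4,
                1.0, 1.5, 0.8, 1.2, 0.5, 1.1,
                0.2, 0.6, 0.4, 0.3, 0.9, 0.1), ncol = 3)
  y <- matrix(c(2.0, 2.5, 3.1,
                0.9, 0.4, 0.7,
                0.5, 0.2, 0.6), ncol = 3)
  ht <- hotelling_t2(x, y)
  # independent route: two-group MANOVA's Hotelling-Lawley trace equals
  # T2 / (n1 + n2 - 2)
  grp <- factor(rep(c("case", "ctrl"), c(6, 3)))
  fit <- stats::manova(rbind(x, y) ~ grp)
  hl <- summary(fit, test = "Hotelling-Lawley")$stats[1, "Hotelling-Lawley"]
  expect_equal(ht$t2, hl * (9 - 2), tolerance = 1e-8)
  p_manova <- summary(fit, test = "Hotelling-Lawley")$stats[1, "Pr(>F)"]
  expect_equal(ht$p_value, unname(p_manova), tolerance = 1e-8)

  # equal group mean vectors: T2 ~ 0, p ~ 1
  set.seed(7)
  xm <- x
  ym <- sweep(x[1:3, ], 2, colMeans(x[1:3, ])) +
    matrix(colMeans(x), 3, 3, byrow = TRUE) +
    matrix(rnorm(9, sd = 1e-7), 3)
  ht0 <- hotelling_t2(xm, ym)
  expect_lt(ht0$t2, 1e-6)

  # singular pooled covariance names the degenerate variable
  xz <- cbind(x, 0); yz <- cbind(y, 0)
  colnames(xz) <- colnames(yz) <- c("a", "b", "c", "zerovar")
  expect_error(hotelling_t2(xz, yz), "zerovar")
  ht_drop <- hotelling_t2(xz, yz, drop_degenerate = TRUE)
  expect_equal(ht_drop$dropped, "zerovar")
  expect_equal(ht_drop$t2, ht$t2, tolerance = 1e-12)
})

test_that("percent burdens and tests are invariant to count rescaling", {
  bm <- simulate_burden_replicate(6, 3, total_rate = 90, set_rate = 10,
                                  ratio = 2)
  scale_test <- function(mult) {
    k <- bm$k * mult; K <- bm$K * mult
    pct <- ifelse(K > 0, 100 * k / K, 0)
    tt <- one_sided_t_test(pct[bm$group == "CASE"],
                           pct[bm$group == "CONTROL"])
    c(tt$t, tt$p,
      ratio_of_means(pct[bm$group == "CASE"], pct[bm$group == "CONTROL"]))
  }
  expect_equal(scale_test(1), scale_test(7), tolerance = 1e-12)
})

test_that("run_burden_analysis screens and runs the joint stage end to end", {
  we <- generate_worked_example()
  pvs <- prioritize(we$calls, we$annotations, we$regions_22q11, we$subjects)
  ba <- run_burden_analysis(pvs, we$gene_sets, restriction = we$dgcr8_genes)

  expect_s3_class(ba, "burden_analysis")
  expect_true("neuron_projection" %in% ba$screened)
  joint_np <- ba$joint[ba$joint$gene_set == "neuron_projection", ]
  expect_equal(nrow(joint_np), 1)
  expect_gt(joint_np$t2, 0)
  expect_true(joint_np$p_value > 0 && joint_np$p_value <= 1)
  # restricted twin present with the restriction list configured
  expect_true("neuron_projection|restricted" %in% ba$results$gene_set)

  # empty collection -> empty table
  ba0 <- run_burden_analysis(pvs, list())
  expect_equal(nrow(ba0$results), 0)
})
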