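# Readers: validation, coordinate conventions, and write/read round trips.

test_that("read_subjects validates groups, aliases and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tgroup\tsex",
               paste(sprintf("SCZ%d", 1:6), "SCZ", "MALE", sep = "\t"),
               paste(sprintf("NP%d", 1:3), "NP", "FEMALE", sep = "\t")), f)
  s <- read_subjects(f)
  expect_equal(nrow(s), 9)
  expect_equal(unname(table(s$group)[c("CASE", "CONTROL")]),
               c(6L, 3L), ignore_attr = TRUE)
  expect_equal(s$id[1], "SCZ1")  # order preserved

  writeLines("id\tgroup\tsex", f)
  expect_equal(nrow(read_subjects(f)), 0)

  writeLines(c("id\tgroup\tsex", "S1\tCASE\tMALE", "S1\tCONTROL\tMALE"), f)
  expect_error(read_subjects(f), "S1")

  writeLines(c("id\tgroup\tsex", "S1\tPATIENT\tMALE"), f)
  expect_error(read_subjects(f), "group")
})

test_that("read_variant_calls decomposes genotypes and keeps failed filters", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tC\tA,G\t.\tPASS\t.\tGT\t1/2\t0/0",
    "chr1\t300\t.\tG\tC\t.\tLowQual\t.\tGT\t1/1\t0/1",
    "chrX\t400\t.\tT\tA\t.\tPASS\t.\tGT\t1\t0/0"), f)
  subjects <- data.frame(id = c("S1", "S2"), group = c("CASE", "CONTROL"),
                         sex = "UNKNOWN", stringsAsFactors = FALSE)
  calls <- read_variant_calls(f, subjects)

  het <- calls[calls$pos == 100, ]
  expect_equal(nrow(het), 1)
  expect_equal(het$genotype, "HET")

  # multi-allelic 1/2 decomposes into one biallelic call per alt
  multi <- calls[calls$pos == 200, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("A", "G"))
  expect_true(all(multi$genotype == "HET"))

  lowq <- calls[calls$pos == 300, ]
  expect_equal(nrow(lowq), 2)
  expect_false(any(lowq$high_quality))
  expect_equal(lowq$genotype[lowq$subject_id == "S1"], "HOM_ALT")

  expect_equal(calls$genotype[calls$pos == 400], "HEMI")
})

test_that("read_variant_calls rejects unknown samples and malformed records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS9",
               "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"), f)
  subjects <- data.frame(id = "S1", group = "CASE", sex = "UNKNOWN",
                         stringsAsFactors = FALSE)
  expect_error(read_variant_calls(f, subjects), "S9")

  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t100\t.\tA"), f)
  expect_error(read_variant_calls(f, subjects), "line 3")
})

test_that("read_annotations enforces the 7-tool contract and the class enum", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("chrom", "pos", "ref", "alt", "genes", "class",
                 paste0("af_db", 1:3), paste0("tool", 1:7), "splice_score"),
               collapse = "\t")
  writeLines(c(hdr,
               paste(c("chr3", "500", "G", "A", "BSN", "stop_gain",
                       "0.001", "", "", rep("0", 7), ""), collapse = "\t"),
               paste(c("chr3", "600", "C", "T", "g2", "missense",
                       "", "", "", rep("1", 7), "-2.5"), collapse = "\t")), f)
  ann <- read_annotations(f)
  expect_equal(ann$class[1], "STOP_GAIN")
  expect_equal(ann$genes[1], "BSN")
  # all-empty AF cells parse as absent (treated downstream as unobserved)
  expect_true(all(is.na(ann[2, grep("^af_", names(ann))])))
  expect_equal(sum(unlist(ann[2, grep("^tool", names(ann))])), 7)

  writeLines(c(sub("\ttool7", "", hdr),
               paste(c("chr3", "500", "G", "A", "BSN", "stop_gain",
                       "0.001", "", "", rep("0", 6), ""), collapse = "\t")), f)
  expect_error(read_annotations(f), "7 tool columns")

  writeLines(c(hdr,
               paste(c("chr3", "500", "G", "A", "BSN", "weird_class",
                       "0.001", "", "", rep("0", 7), ""), collapse = "\t")), f)
  expect_error(read_annotations(f), "class")
})

test_that("read_gene_sets upper-cases, de-duplicates, and rejects name clashes", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("NEURON_PROJECTION\tGO\tMYH9\tMYH10",
               "DUP_SET\tsrc\tGeneA\tgenea"), f)
  gs <- read_gene_sets(f)
  expect_equal(length(gs$NEURON_PROJECTION), 2)
  expect_equal(gs$DUP_SET, "GENEA")  # repeated symbol collapses
  expect_equal(attr(gs, "sources")[["NEURON_PROJECTION"]], "GO")

  writeLines(c("A\tsrc\tG1", "A\tsrc\tG2"), f)
  expect_error(read_gene_sets(f), "duplicate")

  writeLines(c("A\tsrc", "B\tsrc\tG1"), f)
  expect_warning(gs <- read_gene_sets(f), "skipped")
  expect_equal(names(gs), "B")
})

test_that("read_regions merges overlaps and rejects empty intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr22\t18900000\t21500000"), f)
  r <- read_regions(f)
  expect_equal(r$start, 18900000L)
  expect_equal(r$end, 21500000L)

  writeLines(c("chr1\t10\t30", "chr1\t20\t50", "chr2\t5\t8"), f)
  r <- read_regions(f)
  expect_equal(nrow(r), 2)
  expect_equal(r[r$chrom == "chr1", ]$end, 50L)

  writeLines("chr1\t5\t5", f)
  expect_error(read_regions(f), "start >= end")
})

test_that("read_prs_table computes log odds ratios and validates p-values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\teffect_allele\tother_allele\tor\tassoc_p",
               "chr9\t1000\tA\tG\t1.10\t0.0005",
               "chr9\t1000\tA\tG\t1.10\t0.0005"), f)
  rec <- read_prs_table(f)
  expect_equal(nrow(rec), 1)  # de-duplicated
  expect_equal(rec$log_or, log(1.10))
  expect_equal(rec$ref_allele, "G")  # other_allele default

  writeLines("chrom\tpos\teffect_allele\tother_allele\tor\tassoc_p", f)
  expect_equal(nrow(read_prs_table(f)), 0)

  writeLines(c("chrom\tpos\teffect_allele\tother_allele\tor\tassoc_p",
               "chr9\t1000\tA\tG\t1.10\t0"), f)
  expect_error(read_prs_table(f), "assoc_p")

  writeLines(c("chrom\tpos\teffect_allele\tother_allele\tor\tassoc_p",
               "chr9\t1000\tA\tG\t1.10\t0.5",
               "chr9\t1000\tC\tT\t1.10\t0.5"), f)
  expect_error(read_prs_table(f), "conflicting")
})

test_that("coordinate rule: VCF pos p overlaps BED [s,e) iff s < p <= e", {
  regions <- data.frame(chrom = "chr1", start = 100L, end = 110L,
                        stringsAsFactors = FALSE)
  # boundary sweep around both edges
  pos <- c(99L, 100L, 101L, 109L, 110L, 111L)
  hit <- rvburden:::pos_in_regions(rep("chr1", 6), pos, regions)
  expect_equal(hit, c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(rvburden:::pos_in_regions("chr2", 105L, regions))
})

test_that("a generated cohort round-trips through write and read", {
  cfg <- synthetic_config(seed = 42, n_case = 3, n_control = 2,
                          missense_rate = 20, lof_rate = 5, splice_rate = 5,
                          noise_rate = 4, prs_n_snps = 40, n_lincRNA = 10,
                          n_mirna = 4)
  b <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  b2 <- read_cohort(dir)

  expect_equal(b2$subjects, b$subjects)
  # calls survive modulo row order
  ord <- function(df) {
    df <- df[order(df$subject_id, df$chrom, df$pos, df$alt), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(b2$calls), ord(b$calls))
  a1 <- b$annotations[order(b$annotations$key), ]
  a2 <- b2$annotations[order(b2$annotations$key), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a2, a1, tolerance = 1e-12)
  expect_equal(b2$gene_sets, b$gene_sets, ignore_attr = TRUE)
  expect_equal(b2$regions_22q11, b$regions_22q11)
  expect_equal(b2$prs_records, b$prs_records, tolerance = 1e-12)
  expect_equal(b2$ncrna_catalog, b$ncrna_catalog, tolerance = 1e-12)

  # variant-key join is total: every call finds exactly one annotation
  keys <- variant_key(b2$calls$chrom, b2$calls$pos, b2$calls$ref, b2$calls$alt)
  expect_true(all(keys %in% b2$annotations$key))
  expect_false(anyDuplicated(b2$annotations$key) > 0)
})
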