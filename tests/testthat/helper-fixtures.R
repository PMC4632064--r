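# Small in-code fixtures shared across test files.

# minimal annotation row(s) with controllable fields
make_ann <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                     genes = "GENE1", class = "MISSENSE",
                     afs = c(NA, NA, NA, NA, NA),
                     tools = rep(TRUE, 7), splice_score = NA_real_) {
  af <- as.data.frame(matrix(afs, nrow = 1,
                             dimnames = list(NULL, paste0("af_db", 1:5))))
  tl <- as.data.frame(matrix(tools, nrow = 1,
                             dimnames = list(NULL, paste0("tool", 1:7))))
  cbind(data.frame(key = variant_key(chrom, pos, ref, alt), chrom = chrom,
                   pos = pos, ref = ref, alt = alt, genes = genes,
                   class = class, stringsAsFactors = FALSE),
        af, tl, splice_score = splice_score)
}

make_call <- function(subject_id = "S1", chrom = "chr1", pos = 100L,
                      ref = "A", alt = "T", genotype = "HET",
                      high_quality = TRUE) {
  data.frame(subject_id = subject_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, genotype = genotype, high_quality = high_quality,
             stringsAsFactors = FALSE)
}

make_subjects <- function(n_case = 2, n_control = 2) {
  data.frame(id = c(sprintf("SCZ%d", seq_len(n_case)),
                    sprintf("NP%d", seq_len(n_control))),
             group = rep(c("CASE", "CONTROL"), c(n_case, n_control)),
             sex = "UNKNOWN", stringsAsFactors = FALSE)
}

# brute-force re-filter used as the prioritization oracle: applies the
# quality, rarity, category and region rules variant by variant, entirely
# independently of prioritize()'s vectorized path
brute_force_prioritize <- function(calls, annotations, regions,
                                   threshold = 0.01, splice_cut = -5) {
  labels <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    a <- annotations[annotations$key == variant_key(
      calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i]), ]
    stopifnot(nrow(a) == 1)
    afs <- unlist(a[grep("^af_", names(a))])
    rare <- all(is.na(afs) | afs < threshold)
    categ <- NA_character_
    if (a$class %in% c("STOP_GAIN", "FRAMESHIFT", "CORE_SPLICE")) {
      categ <- "LOF"
    } else if (a$class == "MISSENSE" &&
               sum(unlist(a[grep("^tool", names(a))])) >= 5) {
      categ <- "DAMAGING_MISSENSE"
    } else if (!is.na(a$splice_score) && a$splice_score <= splice_cut) {
      categ <- "SPLICE_REG"
    }
    if (!calls$high_quality[i] || !rare || is.na(categ)) {
      labels[i] <- "discarded"
    } else {
      in22 <- FALSE
      if (!is.null(regions)) {
        for (r in seq_len(nrow(regions))) {
          if (calls$chrom[i] == regions$chrom[r] &&
              regions$start[r] < calls$pos[i] &&
              calls$pos[i] <= regions$end[r]) in22 <- TRUE
        }
      }
      labels[i] <- if (in22) "region22" else
        if (toupper(sub("chr", "", calls$chrom[i])) == "X") "chrX" else
          "retained"
    }
  }
  labels
}

# exact one-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (no ties assumed)
enumerate_wilcoxon_p <- function(case_values, control_values) {
  x <- c(case_values, control_values)
  n1 <- length(case_values)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(length(x), n1)
  ws <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(ws >= w_obs)
}
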