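# Readers and writers for every external input: subject table, variant calls
# (VCF), annotation table, gene sets (GMT), exclusion regions (BED), PRS SNP
# table, and the noncoding RNA catalog. All coordinate conversion happens
# here: BED stays 0-based half-open internally, VCF positions stay 1-based.

FUNCTIONAL_CLASSES <- c("STOP_GAIN", "FRAMESHIFT", "CORE_SPLICE", "MISSENSE",
                        "SYNONYMOUS", "INTRONIC", "INTERGENIC",
                        "NONCODING_EXONIC", "OTHER")
LOF_CLASSES <- c("STOP_GAIN", "FRAMESHIFT", "CORE_SPLICE")

#' Read the subject table
#'
#' Reads a TSV with columns `id`, `group`, `sex`. Group labels `SCZ` and `NP`
#' are accepted as aliases for `CASE` and `CONTROL` (the schizophrenia and
#' nonpsychotic study arms).
#'
#' @param path Path to a tab-separated subject table.
#' @return A data.frame with columns `id`, `group` (`CASE`/`CONTROL`) and
#'   `sex` (`MALE`/`FEMALE`/`UNKNOWN`), in file order.
#' @export
read_subjects <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  assert_cols(df, c("id", "group", "sex"), "subject table")
  if (nrow(df) == 0L) {
    return(data.frame(id = character(), group = character(),
                      sex = character(), stringsAsFactors = FALSE))
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop_rv("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  }
  grp <- toupper(df$group)
  grp[grp == "SCZ"] <- "CASE"
  grp[grp == "NP"] <- "CONTROL"
  bad <- setdiff(unique(grp), c("CASE", "CONTROL"))
  if (length(bad)) {
    stop_rv("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  sex <- toupper(df$sex)
  sex[!sex %in% c("MALE", "FEMALE")] <- "UNKNOWN"
  data.frame(id = df$id, group = grp, sex = sex, stringsAsFactors = FALSE)
}

#' Read per-subject variant calls from VCF
#'
#' Parses one or more (multi-sample) VCF files into a long call table with
#' one row per subject per alternate allele carried. Multi-allelic records
#' are decomposed into biallelic calls; any record whose FILTER is neither
#' `PASS` nor `.` is retained with `high_quality = FALSE`.
#'
#' @param paths Character vector of VCF paths.
#' @param subjects Subject table from [read_subjects()]; every VCF sample
#'   name must appear in it.
#' @return data.frame with columns `subject_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `genotype` (`HET`/`HOM_ALT`/`HEMI`), `high_quality`.
#' @export
read_variant_calls <- function(paths, subjects) {
  out <- lapply(paths, read_one_vcf, subjects = subjects)
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- empty_calls()
  }
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(subject_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             genotype = character(), high_quality = logical(),
             stringsAsFactors = FALSE)
}

read_one_vcf <- function(path, subjects) {
  validate_vcf_lines(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@gt) == 0L) return(empty_calls())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(samples, subjects$id)
  if (length(unknown)) {
    stop_rv("VCF sample(s) not in subject table: ",
            paste(unknown, collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rows <- list()
  n <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    filt <- fix$FILTER[i]
    hq <- is.na(filt) || filt %in% c("PASS", ".")
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      alleles <- strsplit(g, "[/|]")[[1]]
      alleles <- alleles[alleles != "."]
      if (!length(alleles)) next
      ploidy <- length(alleles)
      for (ai in seq_along(alts)) {
        cnt <- sum(alleles == as.character(ai))
        if (cnt == 0L) next
        geno <- if (ploidy == 1L) "HEMI" else if (cnt >= 2L) "HOM_ALT" else "HET"
        n <- n + 1L
        rows[[n]] <- data.frame(
          subject_id = s, chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[ai],
          genotype = geno, high_quality = hq, stringsAsFactors = FALSE)
      }
    }
  }
  if (!n) return(empty_calls())
  do.call(rbind, rows)
}

# Cheap structural scan so malformed lines are reported with their number;
# vcfR's own parser gives opaque errors otherwise.
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_rv("malformed VCF (no #CHROM header line): ", path)
  nfield <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- setdiff(seq_along(lines), grep("^#", lines))
  body <- body[nzchar(lines[body])]
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != nfield) {
      stop_rv(sprintf("malformed VCF record at line %d of %s: %d fields, expected %d",
                      i, path, nf, nfield))
    }
  }
  invisible(TRUE)
}

#' Read the per-variant annotation table
#'
#' The TSV must carry `chrom`, `pos`, `ref`, `alt`, `genes` (comma- or
#' semicolon-separated symbols), `class`, at least one `af_<database>`
#' column, exactly seven `tool<i>` deleteriousness columns (0/1, empty =
#' no call), and `splice_score` (negative values = predicted reduction of
#' exon inclusion; empty = unscored).
#'
#' @param path Path to the annotation TSV.
#' @return data.frame keyed by `key` (`chrom:pos:ref:alt`) with upper-cased
#'   `class`, `genes`, `af_*`, `tool1..tool7` (logical) and `splice_score`.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("chrom", "pos", "ref", "alt", "genes", "class",
                    "splice_score"), "annotation table")
  tool_cols <- grep("^tool[0-9]+$", names(df), value = TRUE)
  if (length(tool_cols) != 7L) {
    stop_rv(sprintf("annotation table must have exactly 7 tool columns, found %d",
                    length(tool_cols)))
  }
  af_cols <- grep("^af_", names(df), value = TRUE)
  if (!length(af_cols)) stop_rv("annotation table has no af_<database> columns")
  cls <- toupper(df$class)
  bad <- setdiff(unique(cls), FUNCTIONAL_CLASSES)
  if (length(bad)) {
    stop_rv("unknown functional class value(s): ", paste(bad, collapse = ", "))
  }
  for (cc in af_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop_rv("allele frequency outside [0,1] in column ", cc)
    }
    df[[cc]] <- v
  }
  for (tc in tool_cols) {
    df[[tc]] <- as.logical(as.integer(df[[tc]]))
  }
  df$splice_score <- suppressWarnings(as.numeric(df$splice_score))
  out <- data.frame(
    key = variant_key(df$chrom, df$pos, df$ref, df$alt),
    chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
    genes = toupper(df$genes), class = cls,
    stringsAsFactors = FALSE)
  out <- cbind(out, df[af_cols], df[sort(tool_cols)],
               splice_score = df$splice_score)
  if (anyDuplicated(out$key)) {
    stop_rv("duplicate annotation for variant key(s): ",
            paste(unique(out$key[duplicated(out$key)]), collapse = ", "))
  }
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>source<TAB>gene1<TAB>gene2...`.
#' Symbols are upper-cased and de-duplicated within a set. Lines without any
#' gene are skipped with a warning; duplicate set names are an error.
#' (The base parser here keeps the per-set source field, which generic GMT
#' readers drop.)
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols, with a
#'   `sources` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  sources <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      warning(sprintf("GMT line %d has no genes; skipped", i), call. = FALSE)
      next
    }
    nm <- parts[1]
    if (nm %in% names(sets)) stop_rv("duplicate gene-set name: ", nm)
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning(sprintf("GMT line %d has no genes; skipped", i), call. = FALSE)
      next
    }
    sets[[nm]] <- genes
    sources[nm] <- parts[2]
  }
  attr(sets, "sources") <- sources
  sets
}

#' Read genomic regions from BED
#'
#' 3+ column BED, 0-based half-open. Overlapping or bookended regions on the
#' same chromosome are merged.
#'
#' @param path Path to a BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end <- as.integer(vapply(parts, `[[`, "", 3L))
  if (any(is.na(start) | is.na(end))) stop_rv("non-numeric BED coordinates in ", path)
  if (any(start >= end)) {
    stop_rv("BED region with start >= end: ",
            paste(chrom[start >= end], start[start >= end], end[start >= end],
                  collapse = "; "))
  }
  merged <- lapply(split(seq_along(chrom), chrom), function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start[idx] + 1L,
                                           end = end[idx]))
    data.frame(chrom = chrom[idx][1],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read the polygenic risk score SNP table
#'
#' TSV with columns `chrom`, `pos`, `effect_allele`, `other_allele`, `or`
#' (odds ratio for the effect allele) and `assoc_p`; an optional
#' `ref_allele` column states which panel allele is the reference base
#' (used to resolve reference-interval matches). When absent,
#' `other_allele` is taken as the reference base.
#'
#' @param path Path to the PRS SNP TSV.
#' @return data.frame with `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `ref_allele`, `log_or` (= ln OR) and `assoc_p`, de-duplicated on
#'   (`chrom`, `pos`, `effect_allele`).
#' @export
read_prs_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("chrom", "pos", "effect_allele", "other_allele",
                    "or", "assoc_p"), "PRS table")
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      effect_allele = character(), other_allele = character(),
                      ref_allele = character(), log_or = numeric(),
                      assoc_p = numeric(), stringsAsFactors = FALSE))
  }
  p <- as.numeric(df$assoc_p)
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop_rv("assoc_p outside (0,1] at row(s): ",
            paste(which(is.na(p) | p <= 0 | p > 1), collapse = ", "))
  }
  if (any(df$effect_allele == df$other_allele)) {
    stop_rv("PRS record with effect_allele == other_allele")
  }
  ref <- if ("ref_allele" %in% names(df)) df$ref_allele else df$other_allele
  out <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                    effect_allele = df$effect_allele,
                    other_allele = df$other_allele,
                    ref_allele = ref,
                    log_or = log(as.numeric(df$or)), assoc_p = p,
                    stringsAsFactors = FALSE)
  key <- paste(out$chrom, out$pos, out$effect_allele)
  out <- out[!duplicated(key), , drop = FALSE]
  poskey <- paste(out$chrom, out$pos)
  if (anyDuplicated(poskey)) {
    stop_rv("conflicting PRS records (same position, different alleles) at: ",
            paste(unique(poskey[duplicated(poskey)]), collapse = "; "))
  }
  rownames(out) <- NULL
  out
}

#' Read the noncoding RNA catalog
#'
#' TSV with columns `id`, `kind` (`lincRNA`/`miRNA`), `chrom`, `start`,
#' `end` (0-based half-open exon/gene regions; multiple rows per gene
#' allowed) and `conservation` (regional score, one value per gene).
#'
#' @param path Path to the catalog TSV.
#' @return data.frame with one row per region: `id`, `kind`
#'   (`LINCRNA`/`MIRNA`), `chrom`, `start`, `end`, `conservation`.
#' @export
read_ncrna_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("id", "kind", "chrom", "start", "end", "conservation"),
              "ncRNA catalog")
  if (nrow(df) == 0L) {
    return(data.frame(id = character(), kind = character(), chrom = character(),
                      start = integer(), end = integer(),
                      conservation = numeric(), stringsAsFactors = FALSE))
  }
  kind <- toupper(df$kind)
  bad <- setdiff(unique(kind), c("LINCRNA", "MIRNA"))
  if (length(bad)) stop_rv("unknown ncRNA kind: ", paste(bad, collapse = ", "))
  start <- as.integer(df$start); end <- as.integer(df$end)
  if (any(start >= end)) stop_rv("ncRNA region with start >= end")
  cons <- as.numeric(df$conservation)
  by_id <- split(cons, df$id)
  inconsistent <- names(by_id)[vapply(by_id, function(x) length(unique(x)) > 1L,
                                      logical(1))]
  if (length(inconsistent)) {
    stop_rv("inconsistent conservation score within gene(s): ",
            paste(inconsistent, collapse = ", "))
  }
  data.frame(id = df$id, kind = kind, chrom = df$chrom,
             start = start, end = end, conservation = cons,
             stringsAsFactors = FALSE)
}

#' Read per-subject reference intervals
#'
#' Reads one BED per subject from a directory (`<subject id>.bed`); each BED
#' lists spans confidently called identical to the reference.
#'
#' @param dir Directory of `<id>.bed` files.
#' @param subjects Subject table.
#' @return data.frame with `subject_id`, `chrom`, `start`, `end`.
#' @export
read_reference_intervals <- function(dir, subjects) {
  out <- lapply(subjects$id, function(id) {
    f <- file.path(dir, paste0(id, ".bed"))
    if (!file.exists(f)) {
      return(data.frame(subject_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    }
    reg <- read_regions(f)
    if (nrow(reg) == 0L) {
      return(data.frame(subject_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    }
    cbind(subject_id = id, reg, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a plain gene list (one symbol per line)
#'
#' Used for the DGCR8-dysregulation restriction list.
#'
#' @param path Path to a text file with one gene symbol per line.
#' @return Character vector of upper-cased unique symbols.
#' @export
read_gene_list <- function(path) {
  g <- toupper(trimws(readLines(path)))
  unique(g[nzchar(g)])
}
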