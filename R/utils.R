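# Shared internal helpers: variant keys, coordinate rules, small validators.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` string used to join variant calls to their
#' annotations. `pos` is the 1-based VCF coordinate.
#'
#' @param chrom,pos,ref,alt Vectors describing variants.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# A 1-based position p overlaps a 0-based half-open region [s, e) iff
# s < p <= e. This is the single internal coordinate rule; BED readers keep
# 0-based half-open coordinates, VCF positions stay 1-based.
pos_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  hit <- rep(FALSE, length(pos))
  for (cc in unique(regions$chrom)) {
    reg <- regions[regions$chrom == cc, , drop = FALSE]
    idx <- which(chrom == cc)
    if (!length(idx)) next
    ir <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    qr <- IRanges::IRanges(start = pos[idx], width = 1L)
    hit[idx] <- IRanges::overlapsAny(qr, ir)
  }
  hit
}

is_chrx <- function(chrom) {
  tolower(sub("^chr", "", chrom)) == "x"
}

stop_rv <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_rv(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")))
  }
}
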