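# Trim an allele pair to its minimal representation: shared trailing bases
# first, then shared leading bases (keeping at least one base per allele,
# advancing pos). Records are never left-aligned.
trim_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a variant by its alleles
#'
#' Determines the variant type and length from a (normalized) REF/ALT
#' pair: a single-base substitution is a SNP of length 1; if one allele
#' is the other plus appended bases after a shared leading (anchor) base,
#' the record is a pure insertion or deletion whose length is the allele
#' length difference; anything else is complex (CPX), with length
#' `max(len(REF), len(ALT)) - 1`. Complex records are kept as single
#' units and never decomposed.
#'
#' @param ref_allele,alt_allele non-empty, differing allele strings.
#' @return a list with `type` (`"SNP"`, `"INS"`, `"DEL"` or `"CPX"`) and
#'   `len` (integer, >= 1).
#' @examples
#' classify_variant("A", "C")     # SNP, 1
#' classify_variant("ATTT", "A")  # DEL, 3
#' @export
classify_variant <- function(ref_allele, alt_allele) {
  nr <- nchar(ref_allele); na <- nchar(alt_allele)
  if (nr == 0L || na == 0L) stop("empty allele: records must be normalized upstream")
  if (ref_allele == alt_allele) stop("REF and ALT are identical")
  if (nr == 1L && na == 1L) return(list(type = "SNP", len = 1L))
  anchor_ok <- substr(ref_allele, 1L, 1L) == substr(alt_allele, 1L, 1L)
  if (na > nr && nr == 1L && anchor_ok)
    return(list(type = "INS", len = na - nr))
  if (nr > na && na == 1L && anchor_ok)
    return(list(type = "DEL", len = nr - na))
  list(type = "CPX", len = max(nr, na) - 1L)
}

#' Assign a size category and bin
#'
#' SNPs are their own category; insertions, deletions and complex records
#' are INDELs below `sv_threshold` bases and SVs at or above it (a 50-base
#' deletion is an SV at the default threshold).
#'
#' @param var_type `"SNP"`, `"INS"`, `"DEL"` or `"CPX"`.
#' @param var_len variant length in bases (>= 1).
#' @param sv_threshold INDEL/SV boundary, default 50.
#' @param bins bin edges for the size-bin label.
#' @return list with `category` (`"SNP"`, `"INDEL"`, `"SV"`) and
#'   `size_bin` (label).
#' @examples
#' categorize_variant("DEL", 49)  # INDEL
#' categorize_variant("DEL", 50)  # SV
#' @export
categorize_variant <- function(var_type, var_len, sv_threshold = 50L,
                               bins = c(1L, 50L, 500L, 5000L)) {
  stopifnot(var_len >= 1L)
  category <- if (var_type == "SNP") "SNP"
              else if (var_len >= sv_threshold) "SV" else "INDEL"
  k <- findInterval(var_len, bins, rightmost.closed = TRUE)
  size_bin <- if (k == 0L) paste0("<", bins[1L])
              else if (k >= length(bins)) paste0(">", bins[length(bins)])
              else if (k == length(bins) - 1L)
                paste0("[", bins[k], ",", bins[k + 1L], "]")
              else paste0("[", bins[k], ",", bins[k + 1L], ")")
  list(category = category, size_bin = size_bin)
}

#' Apply variants to a reference window
#'
#' Replaces each variant's REF span by its ALT allele, right to left so
#' that earlier offsets stay valid. The result length equals the window
#' length plus the summed length deltas.
#'
#' @param window_seq reference sequence of the window (character scalar).
#' @param window_start 0-based reference offset of the window start.
#' @param variants variant rows for one haplotype: columns `pos` (0-based),
#'   `ref`, `alt`; sorted by position, non-overlapping, contained in the
#'   window.
#' @return the haplotype sequence (character scalar).
#' @examples
#' apply_variants("ACGT", 0, data.frame(pos = integer(), ref = character(),
#'                                      alt = character()))  # "ACGT"
#' @export
apply_variants <- function(window_seq, window_start, variants) {
  n <- nrow(variants)
  if (n == 0L) return(window_seq)
  o <- order(variants$pos)
  variants <- variants[o, , drop = FALSE]
  wlen <- nchar(window_seq)
  out <- window_seq
  prev_end <- -1L
  for (k in seq_len(n)) {
    off <- variants$pos[k] - window_start
    rlen <- nchar(variants$ref[k])
    if (off < 0L || off + rlen > wlen)
      stop("variant at pos ", variants$pos[k], " outside window [",
           window_start, ",", window_start + wlen, ")")
    if (off < prev_end)
      stop("overlapping variants at window offset ", off)
    prev_end <- off + rlen
  }
  for (k in rev(seq_len(n))) {
    off <- variants$pos[k] - window_start
    rlen <- nchar(variants$ref[k])
    stopifnot(substr(out, off + 1L, off + rlen) == variants$ref[k])
    out <- paste0(str_slice(out, 1L, off), variants$alt[k],
                  str_slice(out, off + rlen + 1L, nchar(out)))
  }
  out
}

# record-based coordinate map: haplotype offset of reference position p
# (0-based, outside all footprints) given the haplotype's variants
hap_offset <- function(p, window_start, variants) {
  if (nrow(variants) == 0L) return(p - window_start)
  ends <- variants$pos + nchar(variants$ref)
  delta <- nchar(variants$alt) - nchar(variants$ref)
  (p - window_start) + sum(delta[ends <= p])
}
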