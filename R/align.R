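#' Unit-cost edit distance
#'
#' Levenshtein distance computed by wavefront expansion, so memory grows
#' with the distance and the number of active diagonals rather than with
#' the product of the sequence lengths.
#'
#' @param a,b character scalars (may be empty).
#' @return a non-negative integer.
#' @examples
#' edit_distance("ACGT", "ACGT")  # 0
#' edit_distance("AAA", "")       # 3
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  wfa_edit_cpp(a, b)
}

#' Global affine-gap alignment
#'
#' End-to-end alignment of `a` (query) against `b` (target) under
#' Gotoh-style affine gap costs: a gap of length k costs
#' `gap_open + k * gap_extend`. The backtracked cigar uses `=` (match),
#' `X` (mismatch), `I` (consumes query only) and `D` (consumes target
#' only), with a fixed deterministic tie order so that downstream
#' adjudication is reproducible.
#'
#' @param a,b character scalars.
#' @param penalties an [align_penalties()] object.
#' @param traceback if `FALSE`, skip the cigar (cost only).
#' @return a list with elements `cost` (integer) and `cigar` (character).
#' @examples
#' affine_align("ACGT", "AC", align_penalties(gap_open = 2, gap_extend = 1))
#' @export
affine_align <- function(a, b, penalties = align_penalties(), traceback = TRUE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  gotoh_cpp(a, b, penalties[["mismatch"]], penalties[["gap_open"]],
            penalties[["gap_extend"]], traceback)
}

# expand a run-length cigar into a per-op character vector
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "") return(character(0))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  rep(ops, lens)
}

# recompute affine cost of a cigar (used by tests and invariants)
cigar_cost <- function(cigar, penalties = align_penalties()) {
  ops <- cigar_ops(cigar)
  if (length(ops) == 0L) return(0L)
  r <- rle(ops)
  cost <- 0L
  for (k in seq_along(r$values)) {
    op <- r$values[k]; len <- r$lengths[k]
    cost <- cost + switch(op,
      "=" = 0L,
      "X" = len * penalties[["mismatch"]],
      "I" = penalties[["gap_open"]] + len * penalties[["gap_extend"]],
      "D" = penalties[["gap_open"]] + len * penalties[["gap_extend"]])
  }
  cost
}

# vertices (i, j) visited by a cigar path, as an integer matrix incl. (0, 0)
cigar_vertices <- function(cigar) {
  ops <- cigar_ops(cigar)
  n <- length(ops)
  di <- integer(n); dj <- integer(n)
  di[ops %in% c("=", "X", "I")] <- 1L
  dj[ops %in% c("=", "X", "D")] <- 1L
  cbind(i = c(0L, cumsum(di)), j = c(0L, cumsum(dj)))
}

#' Alignment cost of a variant cluster
#'
#' For each haplotype, the reference span of the cluster is compared with
#' the span after applying the haplotype's variants, under affine-gap
#' penalties; the cluster cost is the maximum over haplotypes. After a
#' merge the recomputed cost can only drop or stay (two adjacent one-base
#' deletions, say, become one two-base gap).
#'
#' @param variants a variant table (rows of a [load_variants()] result)
#'   covering the cluster, both haplotypes.
#' @param contig_seq reference sequence of the contig (character scalar).
#' @param span_start,span_end cluster reference span, 0-based half-open.
#' @param penalties an [align_penalties()] object.
#' @return integer cost.
#' @export
cluster_cost <- function(variants, contig_seq, span_start, span_end,
                         penalties = align_penalties()) {
  span_seq <- str_slice(contig_seq, span_start + 1L, span_end)
  costs <- vapply(1:2, function(h) {
    vh <- variants[variants$hap == h, , drop = FALSE]
    if (nrow(vh) == 0L) return(0L)
    hap <- apply_variants(span_seq, span_start, vh)
    as.integer(affine_align(hap, span_seq, penalties, traceback = FALSE)$cost)
  }, integer(1))
  max(costs)
}

#' Cost-budgeted cluster reach
#'
#' The furthest reference position, left or right of a cluster, where an
#' end-to-end alignment through the cluster's haplotype sequence can still
#' place a scored difference (mismatch or gap) at the boundary while
#' costing no more than `budget` (the cluster's current representation
#' cost). Candidate extension windows start at `init_window` bases and are
#' doubled until the feasible extension no longer touches the window edge
#' or the contig end is reached. A zero budget pins the reach to the span
#' edge. Within a homopolymer or tandem repeat, equivalently-placed gaps
#' keep the cost within budget, so the reach sweeps the whole run; this is
#' what lets interacting clusters find each other.
#'
#' @param variants variant rows of the cluster (both haplotypes).
#' @param contig_seq reference contig sequence (character scalar).
#' @param span_start,span_end cluster span, 0-based half-open.
#' @param budget non-negative integer cost budget.
#' @param direction `"left"` or `"right"`.
#' @param penalties an [align_penalties()] object.
#' @param init_window initial extension window (bases), doubled as needed.
#' @param max_window cap on the extension window.
#' @return integer reference position (0-based); `>= span_end` for right,
#'   `<= span_start` for left, clamped to contig bounds.
#' @export
compute_reach <- function(variants, contig_seq, span_start, span_end,
                          budget, direction = c("right", "left"),
                          penalties = align_penalties(),
                          init_window = 8L, max_window = 4096L) {
  direction <- match.arg(direction)
  stopifnot(budget >= 0L)
  clen <- nchar(contig_seq)
  span_seq <- str_slice(contig_seq, span_start + 1L, span_end)
  haps <- unique(variants$hap)
  best <- 0L
  for (h in haps) {
    vh <- variants[variants$hap == h, , drop = FALSE]
    if (nrow(vh) == 0L) next
    hap <- apply_variants(span_seq, span_start, vh)
    if (direction == "right") {
      avail <- clen - span_end
      hs <- hap; ss <- span_seq
      ext_at <- function(w) str_slice(contig_seq, span_end + 1L, span_end + w)
    } else {
      avail <- span_start
      hs <- str_rev(hap); ss <- str_rev(span_seq)
      ext_at <- function(w) str_rev(str_slice(contig_seq, span_start - w + 1L, span_start))
    }
    w <- min(init_window, avail)
    repeat {
      e <- reach_extend_cpp(hs, ss, ext_at(w), penalties[["mismatch"]],
                            penalties[["gap_open"]], penalties[["gap_extend"]],
                            as.integer(budget))
      if (e < w || w >= avail || w >= max_window) break
      w <- min(2L * w, avail, max_window)
    }
    best <- max(best, max(e, 0L))
  }
  if (direction == "right") min(span_end + best, clen) else max(span_start - best, 0L)
}
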