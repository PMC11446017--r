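#' Derive phase blocks from FORMAT:PS
#'
#' A new block begins wherever either VCF's PS value changes along a
#' contig; VCFs without PS give one block per contig. Reusing a PS id
#' after another id has appeared (non-monotone usage) is an error.
#'
#' @param truth_vs,query_vs `variant_set` objects.
#' @param contig_lens named integer vector of contig lengths.
#' @return named list (per contig) of data frames with `start`, `end`
#'   (0-based half-open block intervals partitioning the contig).
#' @export
assign_phase_blocks <- function(truth_vs, query_vs, contig_lens) {
  boundaries_of <- function(vs, contig) {
    v <- vs[vs$contig == contig & !is.na(vs$ps), , drop = FALSE]
    if (nrow(v) == 0L) return(integer(0))
    v <- v[order(v$pos), , drop = FALSE]
    ps <- v$ps
    chg <- which(ps[-1L] != ps[-length(ps)]) + 1L
    seen <- unique(ps)
    # non-monotone reuse: a PS id recurring after a different id
    for (u in seen) {
      idx <- which(ps == u)
      if (any(diff(idx) > 1L) && length(unique(ps[min(idx):max(idx)])) > 1L)
        stop("non-monotone PS usage for id ", u, " on ", contig,
             " near position ", v$pos[idx[which(diff(idx) > 1L)[1L] + 1L]] + 1L)
    }
    v$pos[chg]
  }
  out <- list()
  for (contig in names(contig_lens)) {
    b <- sort(unique(c(boundaries_of(truth_vs, contig),
                       boundaries_of(query_vs, contig))))
    b <- b[b > 0L & b < contig_lens[[contig]]]
    edges <- c(0L, b, contig_lens[[contig]])
    out[[contig]] <- data.frame(start = edges[-length(edges)], end = edges[-1L])
  }
  out
}

#' Phasing state of a supercluster
#'
#' With M = max(d_orig, d_swap) and m = min: UNPHASED when M = 0 or when
#' the relative reduction (M - m)/M falls below the threshold (inclusive
#' at the boundary); otherwise the state of the smaller distance.
#'
#' @param d_orig,d_swap orientation edit distances.
#' @param threshold phasing threshold in \[0,1\].
#' @return `"ORIG"`, `"SWAP"` or `"UNPHASED"`.
#' @examples
#' phase_state(0, 10)            # "ORIG"
#' phase_state(4, 10, 0.6)       # "ORIG" (reduction exactly 0.6)
#' phase_state(8, 10, 0.6)       # "UNPHASED"
#' @export
phase_state <- function(d_orig, d_swap, threshold = 0.6) {
  M <- max(d_orig, d_swap); m <- min(d_orig, d_swap)
  if (M == 0L) return("UNPHASED")
  if ((M - m) / M >= threshold) {
    if (d_orig <= d_swap) "ORIG" else "SWAP"
  } else "UNPHASED"
}

#' Minimum switch/flip decomposition of a block's phasing states
#'
#' Dynamic program over strand assignments: walking the phased
#' superclusters of one block in order, a state disagreeing with the
#' current orientation is either a flip (orientation unchanged) or a
#' switch (orientation changes from here on). Total errors are minimized,
#' ties broken toward fewer switches; no error is charged for the initial
#' orientation.
#'
#' @param states character vector of `"ORIG"`/`"SWAP"` (UNPHASED already
#'   removed), ordered by position.
#' @return list with `switches`, `flips`, `switch_after` (indices i such
#'   that a switch occurs between i and i+1) and `flip_at` (indices of
#'   flipped superclusters).
#' @export
count_switch_flip <- function(states) {
  n <- length(states)
  if (n == 0L)
    return(list(switches = 0L, flips = 0L, switch_after = integer(0),
                flip_at = integer(0)))
  s <- as.integer(states == "SWAP")  # 0 = ORIG, 1 = SWAP
  # DP cost is lexicographic (total errors, switches)
  INF <- c(1e9, 1e9)
  better <- function(a, b) a[1L] < b[1L] || (a[1L] == b[1L] && a[2L] < b[2L])
  from <- matrix(NA_integer_, nrow = n, ncol = 2L)
  c0 <- matrix(0, nrow = n, ncol = 2L)  # totals
  c1 <- matrix(0, nrow = n, ncol = 2L)  # switches
  for (o in 0:1) {
    c0[1L, o + 1L] <- as.numeric(s[1L] != o)  # flip at first position
    c1[1L, o + 1L] <- 0
  }
  for (i in seq_len(n)[-1L]) {
    for (o in 0:1) {
      best <- INF; arg <- NA_integer_
      for (op in 0:1) {
        step_switch <- as.numeric(op != o)
        step_flip <- as.numeric(s[i] != o)
        cand <- c(c0[i - 1L, op + 1L] + step_switch + step_flip,
                  c1[i - 1L, op + 1L] + step_switch)
        if (better(cand, best)) { best <- cand; arg <- op }
      }
      c0[i, o + 1L] <- best[1L]; c1[i, o + 1L] <- best[2L]
      from[i, o + 1L] <- arg
    }
  }
  endo <- if (better(c(c0[n, 1L], c1[n, 1L]), c(c0[n, 2L], c1[n, 2L]))) 0L else 1L
  a <- integer(n)
  a[n] <- endo
  for (i in rev(seq_len(n)[-1L])) a[i - 1L] <- from[i, a[i] + 1L]
  switch_after <- which(a[-1L] != a[-n])
  flip_at <- which(s != a)
  list(switches = length(switch_after), flips = length(flip_at),
       switch_after = switch_after, flip_at = flip_at)
}

#' NG50-family contiguity metric
#'
#' The largest segment length L such that segments of length >= L cover at
#' least half of `genome_length`; 0 when total coverage falls short of
#' half the genome.
#'
#' @param segment_lengths integer vector of segment lengths.
#' @param genome_length total genome length (> 0).
#' @return the NG50 value (integer).
#' @examples
#' ngc50(c(6, 4), 10)  # 6
#' ngc50(c(3, 3), 10)  # 3
#' ngc50(c(2, 2), 10)  # 0
#' @export
ngc50 <- function(segment_lengths, genome_length) {
  stopifnot(genome_length > 0)
  if (length(segment_lengths) == 0L) return(0L)
  ls <- sort(as.numeric(segment_lengths), decreasing = TRUE)
  cs <- cumsum(ls)
  i <- which(cs >= genome_length / 2)
  if (length(i) == 0L) return(0L)
  as.integer(ls[i[1L]])
}

# split block intervals at breakpoint positions; returns segment lengths
split_segments <- function(blocks, breakpoints) {
  lens <- numeric(0)
  for (contig in names(blocks)) {
    bl <- blocks[[contig]]
    bp <- sort(unique(breakpoints[[contig]]))
    for (k in seq_len(nrow(bl))) {
      inner <- bp[bp > bl$start[k] & bp < bl$end[k]]
      edges <- c(bl$start[k], inner, bl$end[k])
      lens <- c(lens, diff(edges))
    }
  }
  lens
}

#' Exact-match phasing baseline
#'
#' The naive one-to-one comparison used by conventional phasing
#' evaluators: for each heterozygous query call, an identical truth record
#' (same position, REF and ALT, also heterozygous) is looked up and its
#' haplotype compared. The resulting orientation string is decomposed into
#' switch and flip errors with the same dynamic program as the pipeline.
#' In tandem repeats this reports spurious flips for representation
#' differences that alignment-aware evaluation resolves; it is a
#' diagnostic, not a headline metric.
#'
#' @param truth_vs,query_vs `variant_set` objects.
#' @param blocks phase blocks from [assign_phase_blocks()].
#' @return list with `switches`, `flips` and the per-variant `states`
#'   table.
#' @export
compare_exact_match_baseline <- function(truth_vs, query_vs, blocks) {
  het_of <- function(vs) {
    key <- paste(vs$contig, vs$rec, vs$pos, vs$ref, vs$alt)
    tab <- table(key)
    vs[key %in% names(tab)[tab == 1L], , drop = FALSE]
  }
  th <- het_of(truth_vs)
  qh <- het_of(query_vs)
  states <- NULL
  if (nrow(qh) > 0L) {
    tkey <- paste(th$contig, th$pos, th$ref, th$alt)
    qkey <- paste(qh$contig, qh$pos, qh$ref, qh$alt)
    m <- match(qkey, tkey)
    hit <- !is.na(m)
    if (any(hit)) {
      states <- data.frame(
        contig = qh$contig[hit], pos = qh$pos[hit],
        state = ifelse(qh$hap[hit] == th$hap[m[hit]], "ORIG", "SWAP"),
        stringsAsFactors = FALSE)
      states <- states[order(states$contig, states$pos), , drop = FALSE]
    }
  }
  switches <- 0L; flips <- 0L
  if (!is.null(states)) {
    for (contig in unique(states$contig)) {
      bl <- blocks[[contig]]
      d <- states[states$contig == contig, , drop = FALSE]
      bi <- findInterval(d$pos, bl$start)
      for (b in unique(bi)) {
        r <- count_switch_flip(d$state[bi == b])
        switches <- switches + r$switches
        flips <- flips + r$flips
      }
    }
  }
  list(switches = switches, flips = flips,
       states = if (is.null(states)) data.frame(contig = character(),
                                                pos = integer(),
                                                state = character()) else states)
}
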