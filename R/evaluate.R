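#' Score the two phasing orientations of a supercluster
#'
#' Builds the four haplotype sequences over the padded window and computes
#' `d_orig = ED(T1,Q1) + ED(T2,Q2)` and `d_swap = ED(T1,Q2) + ED(T2,Q1)`
#' by unit-cost edit distance; the chosen orientation attains the minimum
#' (ties go to `orig`).
#'
#' @param wseq window reference sequence.
#' @param wstart 0-based window start.
#' @param tv,qv truth/query variant rows within the window.
#' @return list with `d_orig`, `d_swap`, `chosen`, and the four haplotype
#'   strings `T1`, `T2`, `Q1`, `Q2`.
#' @export
score_orientations <- function(wseq, wstart, tv, qv) {
  T1 <- apply_variants(wseq, wstart, tv[tv$hap == 1L, , drop = FALSE])
  T2 <- apply_variants(wseq, wstart, tv[tv$hap == 2L, , drop = FALSE])
  Q1 <- apply_variants(wseq, wstart, qv[qv$hap == 1L, , drop = FALSE])
  Q2 <- apply_variants(wseq, wstart, qv[qv$hap == 2L, , drop = FALSE])
  d11 <- edit_distance(T1, Q1); d22 <- edit_distance(T2, Q2)
  d12 <- edit_distance(T1, Q2); d21 <- edit_distance(T2, Q1)
  d_orig <- d11 + d22
  d_swap <- d12 + d21
  list(d_orig = d_orig, d_swap = d_swap,
       chosen = if (d_orig <= d_swap) "orig" else "swap",
       T1 = T1, T2 = T2, Q1 = Q1, Q2 = Q2)
}

# Sync-point decomposition for one truth/query haplotype pairing.
#
# A reference position p (0-based, within the window) is a sync point when
# (a) p lies strictly inside no variant footprint of either source, and
# (b) the vertex (t(p), q(p)) given by the record-based coordinate maps
# lies on the chosen optimal unit-cost truth-vs-query alignment path.
# Sync points tile the window into groups evaluated all-or-nothing.
sync_groups <- function(wseq, wstart, T_h, Q_h, tv, qv) {
  wend <- wstart + nchar(wseq)
  fp <- rbind(
    if (nrow(tv)) cbind(tv$pos, footprint_end(tv)) else NULL,
    if (nrow(qv)) cbind(qv$pos, footprint_end(qv)) else NULL)
  cand <- wstart:wend
  if (!is.null(fp) && nrow(fp) > 0L) {
    inside <- rep(FALSE, length(cand))
    for (r in seq_len(nrow(fp)))
      inside <- inside | (cand > fp[r, 1L] & cand < fp[r, 2L])
    cand <- cand[!inside]
  }
  aln <- affine_align(T_h, Q_h, align_penalties(1L, 0L, 1L))
  verts <- cigar_vertices(aln$cigar)
  nq <- nchar(Q_h)
  vkey <- verts[, 1L] * (nq + 1L) + verts[, 2L]
  tpos <- vapply(cand, hap_offset, integer(1), window_start = wstart, variants = tv)
  qpos <- vapply(cand, hap_offset, integer(1), window_start = wstart, variants = qv)
  on_path <- (tpos * (nq + 1L) + qpos) %in% vkey
  bnd <- sort(unique(c(wstart, cand[on_path], wend)))
  data.frame(gstart = bnd[-length(bnd)], gend = bnd[-1L])
}

# Evaluate one haplotype pairing of a supercluster: per sync group, credit
# is the fractional reduction in edit distance, and all members share the
# group decision.
eval_haplotype <- function(wseq, wstart, T_h, Q_h, tv, qv, credit_threshold) {
  groups <- sync_groups(wseq, wstart, T_h, Q_h, tv, qv)
  out <- NULL
  for (k in seq_len(nrow(groups))) {
    a <- groups$gstart[k]; b <- groups$gend[k]
    ti <- which(tv$pos >= a & footprint_end(tv) <= b)
    qi <- which(qv$pos >= a & footprint_end(qv) <= b)
    if (length(ti) == 0L && length(qi) == 0L) next
    R_seg <- str_slice(wseq, a - wstart + 1L, b - wstart)
    T_seg <- str_slice(T_h, hap_offset(a, wstart, tv) + 1L, hap_offset(b, wstart, tv))
    Q_seg <- str_slice(Q_h, hap_offset(a, wstart, qv) + 1L, hap_offset(b, wstart, qv))
    ed_ref <- edit_distance(T_seg, R_seg)
    ed_call <- edit_distance(T_seg, Q_seg)
    if (ed_ref > 0L) {
      credit <- max(0, (ed_ref - ed_call) / ed_ref)
    } else if (length(ti) > 0L) {
      # degenerate: truth variants cancel to the reference
      credit <- if (ed_call == 0L) 1 else 0
    } else {
      credit <- 0  # query-only group: spurious calls
    }
    tp <- credit >= credit_threshold
    rows <- rbind(
      if (length(ti)) data.frame(side = "truth", idx = ti,
                                 bd = ifelse(tp, "TP", "FN"), stringsAsFactors = FALSE) else NULL,
      if (length(qi)) data.frame(side = "query", idx = qi,
                                 bd = ifelse(tp, "TP", "FP"), stringsAsFactors = FALSE) else NULL)
    rows$bc <- credit
    rows$gstart <- a; rows$gend <- b
    rows$ed_ref <- ed_ref; rows$ed_call <- ed_call
    out <- rbind(out, rows)
  }
  out
}

# Evaluate a supercluster end to end: orientation choice, per-haplotype
# sync-group credit, classification rows.
evaluate_supercluster <- function(contig_seq, wstart, wend, tv, qv,
                                  credit_threshold) {
  wseq <- str_slice(contig_seq, wstart + 1L, wend)
  sc <- score_orientations(wseq, wstart, tv, qv)
  rows <- NULL
  for (h in 1:2) {
    qh <- if (sc$chosen == "orig") h else 3L - h
    T_h <- if (h == 1L) sc$T1 else sc$T2
    Q_h <- if (qh == 1L) sc$Q1 else sc$Q2
    tvh <- tv[tv$hap == h, , drop = FALSE]
    qvh <- qv[qv$hap == qh, , drop = FALSE]
    r <- eval_haplotype(wseq, wstart, T_h, Q_h, tvh, qvh, credit_threshold)
    if (!is.null(r)) {
      r$hap <- h
      r$row <- ifelse(r$side == "truth",
                      as.integer(rownames(tvh))[r$idx],
                      as.integer(rownames(qvh))[r$idx])
      rows <- rbind(rows, r)
    }
  }
  list(score = sc, rows = rows)
}

#' Genotype-mismatch bookkeeping
#'
#' Per-haplotype evaluation already yields the het/hom asymmetry (a
#' heterozygous truth call matching one haplotype of a homozygous query
#' call gives TP+TP plus one FP); this helper verifies it and counts
#' records whose per-haplotype decisions disagree (one TP, one FP/FN) as
#' genotype mismatches.
#'
#' @param classifications the per-call classification table of a run.
#' @return integer count of genotype-mismatched records.
#' @export
resolve_zygosity <- function(classifications) {
  if (is.null(classifications) || nrow(classifications) == 0L) return(0L)
  key <- paste(classifications$src, classifications$contig,
               classifications$rec)
  sum(vapply(split(classifications$bd, key), function(b)
    length(unique(b)) > 1L, logical(1)))
}

#' Summarize classifications into benchmarking metrics
#'
#' Per category (SNP/INDEL/SV) and size bin: truth true positives, false
#' negatives, query true positives, false positives, and the derived
#' FNR = FN/(TP_truth+FN), FDR = FP/(TP_query+FP), precision = 1-FDR,
#' recall = 1-FNR and F1. Zero denominators give NA.
#'
#' @param classifications per-call classification table with `src`, `bd`,
#'   `category`, `size_bin`.
#' @return data frame of metrics, including per-category `all` rows and a
#'   `TOTAL` row.
#' @export
summarize_metrics <- function(classifications) {
  count_block <- function(d, category, size_bin) {
    tp_t <- sum(d$src == "truth" & d$bd == "TP")
    fn <- sum(d$src == "truth" & d$bd == "FN")
    tp_q <- sum(d$src == "query" & d$bd == "TP")
    fp <- sum(d$src == "query" & d$bd == "FP")
    fnr <- if (tp_t + fn > 0L) fn / (tp_t + fn) else NA_real_
    fdr <- if (tp_q + fp > 0L) fp / (tp_q + fp) else NA_real_
    f1 <- if (!is.na(fnr) && !is.na(fdr) && (2 - fnr - fdr) > 0)
      2 * (1 - fdr) * (1 - fnr) / ((1 - fdr) + (1 - fnr)) else NA_real_
    data.frame(category = category, size_bin = size_bin,
               TP_truth = tp_t, FN = fn, TP_query = tp_q, FP = fp,
               FNR = fnr, FDR = fdr, precision = 1 - fdr, recall = 1 - fnr,
               F1 = f1, stringsAsFactors = FALSE)
  }
  cls <- classifications
  if (is.null(cls)) cls <- data.frame(src = character(), bd = character(),
                                      category = character(),
                                      size_bin = character())
  out <- NULL
  for (cat in c("SNP", "INDEL", "SV")) {
    d <- cls[cls$category == cat, , drop = FALSE]
    out <- rbind(out, count_block(d, cat, "all"))
    for (bin in sort(unique(d$size_bin)))
      out <- rbind(out, count_block(d[d$size_bin == bin, , drop = FALSE], cat, bin))
  }
  rbind(out, count_block(cls, "TOTAL", "all"))
}
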