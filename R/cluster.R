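# footprint end of each variant row (0-based half-open)
footprint_end <- function(v) v$pos + nchar(v$ref)

#' Gap-based variant clustering
#'
#' Two consecutive variants (haplotypes interleaved by position) share a
#' cluster when the gap between their reference footprints is smaller than
#' `n` bases; the relation is closed transitively.
#'
#' @param variants variant rows of one source on one contig.
#' @param n gap size in bases (> 0).
#' @return integer vector of cluster ids (1-based, increasing along the
#'   contig), one per variant row.
#' @export
gap_cluster <- function(variants, n) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("gap n must be a positive integer")
  m <- nrow(variants)
  if (m == 0L) return(integer(0))
  o <- order(variants$pos, variants$hap)
  starts <- variants$pos[o]
  ends <- footprint_end(variants)[o]
  id <- integer(m)
  cur <- 1L
  id[o[1L]] <- 1L
  max_end <- ends[1L]
  for (k in seq_len(m)[-1L]) {
    if (starts[k] - max_end >= n) cur <- cur + 1L
    id[o[k]] <- cur
    max_end <- max(max_end, ends[k])
  }
  id
}

# internal: cluster summary table from an id assignment
cluster_table <- function(variants, id) {
  if (length(id) == 0L)
    return(data.frame(cluster = integer(), start = integer(), end = integer(),
                      cost = integer(), left_reach = integer(),
                      right_reach = integer(), n = integer()))
  sp <- split(seq_along(id), id)
  data.frame(
    cluster = as.integer(names(sp)),
    start = vapply(sp, function(i) min(variants$pos[i]), integer(1)),
    end = vapply(sp, function(i) max(footprint_end(variants)[i]), integer(1)),
    cost = NA_integer_, left_reach = NA_integer_, right_reach = NA_integer_,
    n = lengths(sp), row.names = NULL)
}

#' Reach-based variant clustering
#'
#' Starts from one cluster per variant and merges neighbours whose
#' cost-budgeted reaches overlap, until a fixed point: for every adjacent
#' pair, the right reach of the left cluster lies strictly left of the
#' left reach of the right cluster. Runs of mutually overlapping reaches
#' are merged greedily in one pass; after each merge the cluster cost is
#' recalculated (it may drop) and only merged clusters have their reaches
#' recomputed. Clusters growing beyond `max_span` are frozen with a
#' warning.
#'
#' @param variants variant rows of one source on one contig (both
#'   haplotypes).
#' @param contig_seq reference contig sequence.
#' @param penalties an [align_penalties()] object.
#' @param max_span freeze threshold in bases.
#' @return list with `id` (cluster id per variant row) and `clusters`
#'   (table with span, cost and reaches).
#' @export
reach_cluster <- function(variants, contig_seq, penalties = align_penalties(),
                          max_span = 10000L) {
  m <- nrow(variants)
  if (m == 0L)
    return(list(id = integer(0), clusters = cluster_table(variants, integer(0))))
  o <- order(variants$pos, variants$hap)
  id <- integer(m)
  id[o] <- seq_len(m)
  cl <- cluster_table(variants, id)
  dirty <- rep(TRUE, nrow(cl))
  frozen <- rep(FALSE, nrow(cl))
  warned <- FALSE
  repeat {
    for (k in which(dirty)) {
      i <- which(id == cl$cluster[k])
      vs <- variants[i, , drop = FALSE]
      if (cl$end[k] - cl$start[k] > max_span) {
        if (!warned) {
          warning("cluster span exceeds ", max_span, " bases; frozen")
          warned <- TRUE
        }
        frozen[k] <- TRUE
        cl$cost[k] <- 0L
        cl$left_reach[k] <- cl$start[k]
        cl$right_reach[k] <- cl$end[k]
        next
      }
      cl$cost[k] <- cluster_cost(vs, contig_seq, cl$start[k], cl$end[k], penalties)
      cl$left_reach[k] <- compute_reach(vs, contig_seq, cl$start[k], cl$end[k],
                                        cl$cost[k], "left", penalties)
      cl$right_reach[k] <- compute_reach(vs, contig_seq, cl$start[k], cl$end[k],
                                         cl$cost[k], "right", penalties)
    }
    dirty <- rep(FALSE, nrow(cl))
    if (nrow(cl) == 1L) break
    # greedy: merge maximal runs of adjacent clusters with overlapping reaches
    ord <- order(cl$start, cl$end)
    cl <- cl[ord, , drop = FALSE]
    frozen <- frozen[ord]
    merged_any <- FALSE
    group <- integer(nrow(cl))
    g <- 1L
    group[1L] <- 1L
    for (k in seq_len(nrow(cl))[-1L]) {
      overlap <- cl$right_reach[k - 1L] >= cl$left_reach[k] ||
        cl$end[k - 1L] > cl$start[k]
      if (overlap && !frozen[k - 1L] && !frozen[k]) {
        group[k] <- g
        merged_any <- TRUE
      } else {
        g <- g + 1L
        group[k] <- g
      }
    }
    if (!merged_any) break
    sp <- split(seq_len(nrow(cl)), group)
    newcl <- data.frame(
      cluster = vapply(sp, function(i) min(cl$cluster[i]), integer(1)),
      start = vapply(sp, function(i) min(cl$start[i]), integer(1)),
      end = vapply(sp, function(i) max(cl$end[i]), integer(1)),
      cost = vapply(sp, function(i) if (length(i) == 1L) cl$cost[i] else NA_integer_, integer(1)),
      left_reach = vapply(sp, function(i) if (length(i) == 1L) cl$left_reach[i] else NA_integer_, integer(1)),
      right_reach = vapply(sp, function(i) if (length(i) == 1L) cl$right_reach[i] else NA_integer_, integer(1)),
      n = vapply(sp, function(i) sum(cl$n[i]), integer(1)),
      row.names = NULL)
    newfrozen <- vapply(sp, function(i) any(frozen[i]), logical(1))
    # remap variant ids
    remap <- setNames(rep(newcl$cluster, lengths(sp)), cl$cluster[unlist(sp)])
    id <- as.integer(remap[as.character(id)])
    dirty <- vapply(sp, function(i) length(i) > 1L, logical(1))
    cl <- newcl
    frozen <- newfrozen
  }
  ord <- order(cl$start, cl$end)
  cl <- cl[ord, , drop = FALSE]
  rownames(cl) <- NULL
  list(id = id, clusters = cl)
}

# run gap clustering but fill in the same cluster table shape
gap_cluster_table <- function(variants, contig_seq, n,
                              penalties = align_penalties()) {
  id <- gap_cluster(variants, n)
  cl <- cluster_table(variants, id)
  for (k in seq_len(nrow(cl))) {
    i <- which(id == cl$cluster[k])
    vs <- variants[i, , drop = FALSE]
    cl$cost[k] <- cluster_cost(vs, contig_seq, cl$start[k], cl$end[k], penalties)
    cl$left_reach[k] <- cl$start[k]
    cl$right_reach[k] <- cl$end[k]
  }
  list(id = id, clusters = cl)
}

#' Merge truth and query clusters into superclusters
#'
#' Transitive closure over clusters of either source whose
#' `[left_reach, right_reach)` intervals overlap (touching reaches merge,
#' consistent with the cluster fixed point). Every input variant belongs
#' to exactly one supercluster; a supercluster may contain only truth or
#' only query members. The evaluation window is the union of member spans
#' padded by `flank` bases, clamped to the contig.
#'
#' @param truth_cl,query_cl cluster tables from [reach_cluster()] or
#'   [gap_cluster_table()].
#' @param flank window padding in bases.
#' @param contig_len contig length for clamping.
#' @return data frame with one row per supercluster: window
#'   (`wstart`, `wend`), member span (`start`, `end`) and member cluster
#'   ids per source (list columns `truth`, `query`).
#' @export
build_superclusters <- function(truth_cl, query_cl, flank = 8L, contig_len) {
  tc <- if (nrow(truth_cl)) cbind(truth_cl, src = "truth") else NULL
  qc <- if (nrow(query_cl)) cbind(query_cl, src = "query") else NULL
  all_cl <- rbind(tc, qc)
  if (is.null(all_cl) || nrow(all_cl) == 0L)
    return(data.frame(sc = integer(), wstart = integer(), wend = integer(),
                      start = integer(), end = integer()))
  o <- order(all_cl$left_reach, all_cl$right_reach)
  all_cl <- all_cl[o, , drop = FALSE]
  g <- integer(nrow(all_cl))
  g[1L] <- 1L
  max_rr <- all_cl$right_reach[1L]
  for (k in seq_len(nrow(all_cl))[-1L]) {
    g[k] <- if (all_cl$left_reach[k] <= max_rr) g[k - 1L] else g[k - 1L] + 1L
    max_rr <- max(max_rr, all_cl$right_reach[k])
  }
  sp <- split(seq_len(nrow(all_cl)), g)
  out <- data.frame(
    sc = seq_along(sp),
    start = vapply(sp, function(i) min(all_cl$start[i]), integer(1)),
    end = vapply(sp, function(i) max(all_cl$end[i]), integer(1)),
    row.names = NULL)
  out$wstart <- pmax(out$start - flank, 0L)
  out$wend <- pmin(out$end + flank, contig_len)
  out$truth <- lapply(sp, function(i) all_cl$cluster[i][all_cl$src[i] == "truth"])
  out$query <- lapply(sp, function(i) all_cl$cluster[i][all_cl$src[i] == "query"])
  out
}
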