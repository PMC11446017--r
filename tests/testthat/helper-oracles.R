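# Independent pure-R oracles for the alignment, clustering and phasing
# engines. These deliberately use naive quadratic / exhaustive algorithms.

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# full-matrix Levenshtein DP
ed_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n; D[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1L, j + 1L] <- min(D[i, j] + (av[i] != bv[j]),
                             D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
  }
  D[n + 1L, m + 1L]
}

# three-matrix Gotoh DP, cost only; gap of length k costs o + k*e
gotoh_oracle <- function(a, b, x, o, e) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  INF <- 1e9
  M <- matrix(INF, n + 1L, m + 1L)
  D <- matrix(INF, n + 1L, m + 1L)  # consumes b
  I <- matrix(INF, n + 1L, m + 1L)  # consumes a
  M[1L, 1L] <- 0
  for (j in seq_len(m)) D[1L, j + 1L] <- o + j * e
  for (i in seq_len(n)) I[i + 1L, 1L] <- o + i * e
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- if (av[i] == bv[j]) 0 else x
    M[i + 1L, j + 1L] <- min(M[i, j], D[i, j], I[i, j]) + sub
    D[i + 1L, j + 1L] <- min(min(M[i + 1L, j], I[i + 1L, j]) + o + e,
                             D[i + 1L, j] + e)
    I[i + 1L, j + 1L] <- min(min(M[i, j + 1L], D[i, j + 1L]) + o + e,
                             I[i, j + 1L] + e)
  }
  min(M[n + 1L, m + 1L], D[n + 1L, m + 1L], I[n + 1L, m + 1L])
}

# minimum Gotoh cost among alignments whose FINAL operation is a scored
# difference (mismatch or gap); INF if none exists
gotoh_diff_end_oracle <- function(a, b, x, o, e) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  INF <- 1e9
  Mm <- matrix(INF, n + 1L, m + 1L)  # last op: match
  Mx <- matrix(INF, n + 1L, m + 1L)  # last op: mismatch
  D <- matrix(INF, n + 1L, m + 1L)
  I <- matrix(INF, n + 1L, m + 1L)
  Mm[1L, 1L] <- 0
  for (j in seq_len(m)) D[1L, j + 1L] <- o + j * e
  for (i in seq_len(n)) I[i + 1L, 1L] <- o + i * e
  for (i in seq_len(n)) for (j in seq_len(m)) {
    dmin <- min(Mm[i, j], Mx[i, j], D[i, j], I[i, j])
    if (av[i] == bv[j]) Mm[i + 1L, j + 1L] <- dmin
    else Mx[i + 1L, j + 1L] <- dmin + x
    D[i + 1L, j + 1L] <- min(min(Mm[i + 1L, j], Mx[i + 1L, j], I[i + 1L, j]) + o + e,
                             D[i + 1L, j] + e)
    I[i + 1L, j + 1L] <- min(min(Mm[i, j + 1L], Mx[i, j + 1L], D[i, j + 1L]) + o + e,
                             I[i, j + 1L] + e)
  }
  min(Mx[n + 1L, m + 1L], D[n + 1L, m + 1L], I[n + 1L, m + 1L])
}

# brute-force reach: for each extension e, ask whether some alignment of
# (hap + ref-extension) vs the extended reference window can end on a
# scored difference within budget; the reach is the largest feasible e
reach_oracle <- function(hap, span, ext, pen, budget) {
  emax <- -1L
  for (e in 0:nchar(ext)) {
    xe <- substr(ext, 1L, e)
    cost <- gotoh_diff_end_oracle(paste0(hap, xe), paste0(span, xe),
                                  pen[["mismatch"]], pen[["gap_open"]],
                                  pen[["gap_extend"]])
    if (cost <= budget) emax <- e
  }
  emax
}

# union-find oracle for the gap clustering relation
gap_union_oracle <- function(pos, ends, n) {
  m <- length(pos)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    gap <- max(pos[i], pos[j]) - min(ends[i], ends[j])
    if (gap < n) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(m), find, integer(1))
}

# exhaustive switch/flip minimization over all 2^n strand assignments
brute_switchflip <- function(states) {
  n <- length(states)
  if (n == 0L) return(c(switches = 0L, flips = 0L))
  s <- as.integer(states == "SWAP")
  best <- c(1e9, 1e9, 1e9)  # (total, switches, flips)
  for (mask in 0:(2^n - 1L)) {
    a <- as.integer(intToBits(mask)[1:n])
    sw <- if (n > 1L) sum(a[-1L] != a[-n]) else 0L
    fl <- sum(a != s)
    tot <- sw + fl
    if (tot < best[1L] || (tot == best[1L] && sw < best[2L])) {
      best <- c(tot, sw, fl)
    }
  }
  c(switches = best[2L], flips = best[3L])
}

# brute-force NG50: largest candidate L covering half the genome
ngc50_brute <- function(segs, G) {
  best <- 0L
  for (L in sort(unique(segs))) {
    if (sum(segs[segs >= L]) >= G / 2) best <- max(best, L)
  }
  as.integer(best)
}

# quick record constructor for hand-built fixtures
vrec <- function(pos, ref, alt, gt, ps = 1L, contig = "c1") {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             gt = gt, ps = as.integer(ps), stringsAsFactors = FALSE)
}
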