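mkvars <- function(pos, ref, alt, hap = 1L, contig = "c") {
  data.frame(contig = rep(contig, length(pos)), pos = as.integer(pos),
             ref = ref, alt = alt,
             hap = rep_len(as.integer(hap), length(pos)),
             stringsAsFactors = FALSE)
}

test_that("gap clustering follows the footprint-gap relation", {
  v <- mkvars(c(100L, 105L), c("A", "C"), c("G", "T"))
  expect_identical(gap_cluster(v, 10L), c(1L, 1L))
  v2 <- mkvars(c(100L, 111L), c("A", "C"), c("G", "T"))
  expect_identical(gap_cluster(v2, 10L), c(1L, 2L))
  expect_error(gap_cluster(v, 0L), "positive")
  # union-find oracle over random variant sets
  set.seed(41)
  for (k in 1:60) {
    m <- sample(2:12, 1)
    pos <- sort(sample(0:300, m))
    rl <- sample(1:5, m, replace = TRUE)
    v <- mkvars(pos, vapply(rl, function(l) random_seq(l), ""),
                rep("A", m), hap = sample(1:2, m, replace = TRUE))
    n <- sample(1:25, 1)
    got <- gap_cluster(v, n)
    want <- gap_union_oracle(v$pos, v$pos + nchar(v$ref), n)
    # same partition (ids may differ)
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(want, levels = unique(want))))
    # monotonicity: larger n never increases the cluster count
    expect_lte(length(unique(gap_cluster(v, n + 5L))),
               length(unique(got)))
  }
})

test_that("reach clustering merges interacting clusters and stabilizes", {
  p <- align_penalties()
  # two SNPs 500 bases apart in non-repetitive sequence: two clusters
  set.seed(42)
  ref <- random_seq(1200)
  v <- mkvars(c(300L, 800L), c(substr(ref, 301, 301), substr(ref, 801, 801)),
              c("N", "N"))
  v$alt <- vapply(v$ref, function(b) setdiff(BASES4, b)[1], "")
  rc <- reach_cluster(v, ref, p)
  expect_identical(nrow(rc$clusters), 2L)
  # adjacent 1-base deletions inside one homopolymer run: one cluster
  ref2 <- paste0(random_seq(30), strrep("T", 12), random_seq(30))
  v2 <- mkvars(c(30L, 35L), c("TT", "TT"), c("T", "T"))
  rc2 <- reach_cluster(v2, ref2, p)
  expect_identical(nrow(rc2$clusters), 1L)
  expect_identical(unique(rc2$id), rc2$clusters$cluster)
  # empty input
  rc0 <- reach_cluster(mkvars(integer(0), character(0), character(0)), ref, p)
  expect_identical(nrow(rc0$clusters), 0L)
  # fixed point: converged reaches of adjacent clusters do not overlap
  g <- make_diploid_genome(sim_config(seed = 42))
  vs <- load_variants(g$truth, g$reference)
  rc3 <- reach_cluster(vs, g$reference[[1]], p)
  cl <- rc3$clusters
  if (nrow(cl) > 1L)
    expect_true(all(cl$right_reach[-nrow(cl)] < cl$left_reach[-1L]))
  # partition: every variant in exactly one cluster
  expect_identical(sort(unique(rc3$id)), sort(cl$cluster))
  expect_identical(length(rc3$id), nrow(vs))
  # invariance to input row order
  perm <- sample(nrow(vs))
  rc4 <- reach_cluster(vs[perm, ], g$reference[[1]], p)
  expect_identical(rc4$clusters$start, cl$start)
  expect_identical(rc4$clusters$end, cl$end)
})

test_that("superclusters partition clusters by reach-interval components", {
  # disjoint truth and query clusters give singleton superclusters
  tc <- data.frame(cluster = 1L, start = 100L, end = 101L, cost = 3L,
                   left_reach = 100L, right_reach = 101L, n = 1L)
  qc <- data.frame(cluster = 1L, start = 500L, end = 501L, cost = 3L,
                   left_reach = 500L, right_reach = 501L, n = 1L)
  sc <- build_superclusters(tc, qc, flank = 8L, contig_len = 1000L)
  expect_identical(nrow(sc), 2L)
  # random cases vs interval-graph connected components
  set.seed(43)
  for (k in 1:40) {
    nt <- sample(0:6, 1); nq <- sample(0:6, 1)
    mk <- function(n) {
      if (n == 0L) return(data.frame(cluster = integer(), start = integer(),
                                     end = integer(), cost = integer(),
                                     left_reach = integer(),
                                     right_reach = integer(), n = integer()))
      st <- sort(sample(0:400, n))
      en <- st + sample(1:10, n, replace = TRUE)
      data.frame(cluster = seq_len(n), start = st, end = en, cost = 1L,
                 left_reach = pmax(st - sample(0:15, n, replace = TRUE), 0L),
                 right_reach = en + sample(0:15, n, replace = TRUE),
                 n = 1L)
    }
    tc <- mk(nt); qc <- mk(nq)
    sc <- build_superclusters(tc, qc, flank = 4L, contig_len = 500L)
    if (nt + nq == 0L) { expect_identical(nrow(sc), 0L); next }
    # oracle: connected components of the interval overlap graph
    iv <- rbind(cbind(tc$left_reach, tc$right_reach),
                cbind(qc$left_reach, qc$right_reach))
    n <- nrow(iv)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]))
    comp <- seq_len(n)
    repeat {
      new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), integer(1))
      if (identical(new, comp)) break
      comp <- new
    }
    expect_identical(nrow(sc), length(unique(comp)))
    # every cluster appears in exactly one supercluster
    expect_identical(sort(unname(unlist(sc$truth))), tc$cluster)
    expect_identical(sort(unname(unlist(sc$query))), qc$cluster)
  }
})

test_that("the cross-size decomposition lands in one supercluster", {
  g <- make_diploid_genome(sim_config(seed = 44, mode = "decomposed"))
  q <- make_decomposed_query(g)
  p <- q$manifest$truth_pos[q$manifest$kind == "sv_decomposition"][1]
  res <- run_benchmark(q$query, g$truth, g$reference)
  cl <- res$classifications
  at_site <- cl[cl$pos >= p & cl$pos <= p + 148, ]
  # the 145-base truth deletion and all four query pieces share one
  # supercluster and are all true positives
  expect_identical(length(unique(at_site$sc)), 1L)
  expect_identical(sum(at_site$src == "truth"), 1L)
  expect_identical(sum(at_site$src == "query"), 4L)
  expect_true(all(at_site$bd == "TP"))
  expect_setequal(unique(at_site$category), c("SNP", "INDEL", "SV"))
})
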