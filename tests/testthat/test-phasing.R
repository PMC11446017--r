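test_that("phase blocks follow PS boundaries of either VCF", {
  set.seed(71)
  ref <- c(c1 = random_seq(400))
  lens <- c(c1 = 400L)
  mk <- function(ps_vals, pos) {
    r <- do.call(rbind, lapply(seq_along(pos), function(i)
      vrec(pos[i], substr(ref, pos[i], pos[i]),
           setdiff(BASES4, substr(ref, pos[i], pos[i]))[1], "1|0",
           ps = ps_vals[i])))
    load_variants(r, ref)
  }
  # no PS changes: one block per contig
  v1 <- mk(c(1L, 1L, 1L), c(50, 150, 300))
  bl <- assign_phase_blocks(v1, v1, lens)
  expect_identical(nrow(bl$c1), 1L)
  expect_identical(bl$c1$end, 400L)
  # query PS changes at a position: two blocks split there
  v2 <- mk(c(1L, 1L, 2L), c(50, 150, 300))
  bl2 <- assign_phase_blocks(v1, v2, lens)
  expect_identical(nrow(bl2$c1), 2L)
  expect_identical(bl2$c1$start, c(0L, 299L))
  # random PS layouts match a brute-force boundary scan
  for (k in 1:20) {
    pos <- sort(sample(20:380, 6))
    ps <- cumsum(c(1L, sample(0:1, 5, replace = TRUE)))
    v <- mk(ps, pos)
    bl <- assign_phase_blocks(v, v1, lens)
    want <- (pos[which(diff(ps) != 0) + 1L]) - 1L  # 0-based change positions
    expect_identical(bl$c1$start, c(0L, want))
  }
  # non-monotone PS reuse is fatal
  v3 <- mk(c(1L, 2L, 1L), c(50, 150, 300))
  expect_error(assign_phase_blocks(v3, v1, lens), "non-monotone")
})

test_that("phase state uses the relative reduction with an inclusive threshold", {
  expect_identical(phase_state(0, 10), "ORIG")
  expect_identical(phase_state(10, 0), "SWAP")
  expect_identical(phase_state(4, 10, 0.6), "ORIG")   # exactly 0.6
  expect_identical(phase_state(10, 4, 0.6), "SWAP")
  expect_identical(phase_state(8, 10, 0.6), "UNPHASED")
  expect_identical(phase_state(0, 0), "UNPHASED")
})

test_that("switch/flip decomposition equals exhaustive minimization", {
  r <- count_switch_flip(c("ORIG", "ORIG", "ORIG"))
  expect_identical(c(r$switches, r$flips), c(0L, 0L))
  r <- count_switch_flip(c("ORIG", "SWAP", "ORIG"))
  expect_identical(c(r$switches, r$flips), c(0L, 1L))
  r <- count_switch_flip(c("ORIG", "ORIG", "SWAP", "SWAP"))
  expect_identical(c(r$switches, r$flips), c(1L, 0L))
  set.seed(72)
  for (k in 1:200) {
    n <- sample(1:12, 1)
    states <- sample(c("ORIG", "SWAP"), n, replace = TRUE)
    got <- count_switch_flip(states)
    want <- brute_switchflip(states)
    expect_identical(c(switches = got$switches, flips = got$flips), want)
    # reported positions are consistent with the counts
    expect_identical(length(got$switch_after), got$switches)
    expect_identical(length(got$flip_at), got$flips)
  }
})

test_that("NG50 family matches brute force and is ordered", {
  expect_identical(ngc50(10, 10), 10L)     # one block spans the genome
  expect_identical(ngc50(c(6, 4), 10), 6L)
  expect_identical(ngc50(c(3, 3), 10), 3L)
  expect_identical(ngc50(c(2, 2), 10), 0L)
  set.seed(73)
  for (k in 1:100) {
    segs <- sample(1:50, sample(1:10, 1), replace = TRUE)
    G <- sample(50:300, 1)
    expect_identical(ngc50(segs, G), ngc50_brute(segs, G))
  }
})

test_that("induced phasing errors are counted and break NGC50 segments", {
  set.seed(74)
  ref <- c(c1 = random_seq(500))
  snp_at <- function(pos, gt) vrec(pos, substr(ref, pos, pos),
                                   setdiff(BASES4, substr(ref, pos, pos))[1], gt)
  pos <- c(60, 160, 260, 360, 460)
  truth <- do.call(rbind, lapply(pos, snp_at, gt = "1|0"))
  # query flips the middle SNP only -> one flip
  query <- truth
  query$gt <- c("1|0", "1|0", "0|1", "1|0", "1|0")
  res <- run_benchmark(query, truth, ref)
  expect_identical(res$phasing$flip_count, 1L)
  expect_identical(res$phasing$switch_count, 0L)
  expect_lte(res$phasing$switchflip_ngc50, res$phasing$switch_ngc50)
  expect_lte(res$phasing$switch_ngc50, res$phasing$ng50)
  expect_lt(res$phasing$switchflip_ngc50, res$phasing$ng50)
  # query switches after the second SNP -> one switch, segments break
  query2 <- truth
  query2$gt <- c("1|0", "1|0", "0|1", "0|1", "0|1")
  res2 <- run_benchmark(query2, truth, ref)
  expect_identical(res2$phasing$switch_count, 1L)
  expect_identical(res2$phasing$flip_count, 0L)
  expect_lt(res2$phasing$switch_ngc50, res2$phasing$ng50)
  # all classifications stay TP: phasing errors are not call errors
  expect_true(all(res2$classifications$bd == "TP"))
  # orientation is relative: swapping every query genotype changes nothing
  query3 <- query2
  query3$gt <- c("0|1", "0|1", "1|0", "1|0", "1|0")
  res3 <- run_benchmark(query3, truth, ref)
  expect_identical(res3$phasing$switch_count, res2$phasing$switch_count)
  expect_identical(res3$phasing$flip_count, res2$phasing$flip_count)
})

test_that("errors are never counted across phase-block boundaries", {
  set.seed(75)
  ref <- c(c1 = random_seq(500))
  snp_at <- function(pos, gt, ps) vrec(pos, substr(ref, pos, pos),
                                       setdiff(BASES4, substr(ref, pos, pos))[1],
                                       gt, ps = ps)
  truth <- rbind(snp_at(60, "1|0", 1L), snp_at(160, "1|0", 1L),
                 snp_at(300, "1|0", 2L), snp_at(400, "1|0", 2L))
  # query phases the second block oppositely: consistent within each block
  query <- rbind(snp_at(60, "1|0", 1L), snp_at(160, "1|0", 1L),
                 snp_at(300, "0|1", 2L), snp_at(400, "0|1", 2L))
  res <- run_benchmark(query, truth, ref)
  expect_identical(res$phasing$switch_count, 0L)
  expect_identical(res$phasing$flip_count, 0L)
})

test_that("the exact-match baseline flags representation flips the pipeline resolves", {
  ft <- make_flip_trap(seed = 5)
  res <- run_benchmark(ft$query, ft$truth, ft$reference)
  lens <- setNames(nchar(ft$reference), names(ft$reference))
  blocks <- assign_phase_blocks(res$truth_set, res$query_set, lens)
  base <- compare_exact_match_baseline(res$truth_set, res$query_set, blocks)
  expect_gte(base$flips, 1L)
  expect_identical(res$phasing$flip_count, 0L)
  expect_identical(res$phasing$switch_count, 0L)
  expect_true(all(res$classifications$bd == "TP"))
  # identical VCFs: baseline reports no flips
  g <- make_diploid_genome(sim_config(seed = 76))
  v <- load_variants(g$truth, g$reference, source = "truth")
  blocks2 <- assign_phase_blocks(v, v, setNames(nchar(g$reference),
                                                names(g$reference)))
  base2 <- compare_exact_match_baseline(v, v, blocks2)
  expect_identical(base2$flips, 0L)
  expect_identical(base2$switches, 0L)
  # on unambiguous (repeat-free, identical-representation) fixtures the
  # baseline agrees with the pipeline
  set.seed(77)
  ref <- c(c1 = random_seq(400))
  snp_at <- function(pos, gt) vrec(pos, substr(ref, pos, pos),
                                   setdiff(BASES4, substr(ref, pos, pos))[1], gt)
  truth <- rbind(snp_at(50, "1|0"), snp_at(150, "1|0"), snp_at(250, "1|0"))
  query <- truth; query$gt <- c("1|0", "0|1", "1|0")
  res2 <- run_benchmark(query, truth, ref)
  tv <- res2$truth_set; qv <- res2$query_set
  b <- compare_exact_match_baseline(tv, qv,
                                    assign_phase_blocks(tv, qv, c(c1 = 400L)))
  expect_identical(b$flips, res2$phasing$flip_count)
  expect_identical(b$switches, res2$phasing$switch_count)
  expect_identical(b$flips, 1L)
})
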