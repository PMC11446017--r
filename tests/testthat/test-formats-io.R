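test_that("FASTA reading folds case, wraps lines and round-trips", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">c", "ACGT"), f)
  r <- read_reference(f)
  expect_identical(unname(r$seq["c"]), "ACGT")
  expect_identical(unname(r$len["c"]), 4L)
  writeLines(c(">c desc here", "ac", "gt"), f)
  r <- read_reference(f)
  expect_identical(unname(r$seq["c"]), "ACGT")
  # two-record round trip through the writer
  set.seed(21)
  seqs <- c(a = random_seq(83), b = random_seq(130))
  f2 <- tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  r2 <- read_reference(f2)
  expect_identical(r2$seq, seqs)
  # non-nucleotide letters (IUPAC ambiguity codes included) are fatal
  writeLines(c(">c", "ACGR"), f)
  expect_error(read_reference(f), "non-nucleotide")
})

test_that("BED regions are merged, validated, and match a bitmap oracle", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10", f)
  m <- read_regions(f)
  expect_equal(unname(m$chr1), cbind(start = 0L, end = 10L),
               ignore_attr = TRUE)
  writeLines(c("chr1\t0\t10", "chr1\t5\t20"), f)
  m <- read_regions(f)
  expect_identical(nrow(m$chr1), 1L)
  expect_identical(unname(m$chr1[1, ]), c(0L, 20L))
  writeLines("chr1\t10\t10", f)
  expect_error(read_regions(f), "start >= end")
  # 100 random intervals vs boolean-array coverage
  set.seed(22)
  st <- sample(0:500, 100, replace = TRUE)
  en <- st + sample(1:40, 100, replace = TRUE)
  m <- read_regions(data.frame(contig = "c", start = st, end = en))
  bitmap <- logical(600)
  for (i in seq_along(st)) bitmap[(st[i] + 1):en[i]] <- TRUE
  expect_identical(sum(m$c[, "end"] - m$c[, "start"]), sum(bitmap))
  # merged intervals are sorted, non-overlapping, non-abutting
  expect_true(all(diff(m$c[, "start"]) > 0))
  expect_true(all(m$c[-nrow(m$c), "end"] < m$c[-1, "start"]))
})

test_that("variant loading splits multiallelics and applies the skip rules", {
  ref <- c(c1 = paste0("A", strrep("ACGT", 40)))
  # multiallelic split: A -> C on hap1, A -> T on hap2
  recs <- vrec(2, "A", "C,T", "1|2")
  v <- load_variants(recs, ref)
  expect_identical(nrow(v), 2L)
  expect_identical(v$alt, c("C", "T"))
  expect_identical(v$hap, c(1L, 2L))
  cnt <- attr(v, "counters")
  expect_identical(unname(cnt["records_split"]), 1L)
  # spanning deletion allele is skipped
  v2 <- load_variants(vrec(2, "A", "*", "1|0"), ref)
  expect_identical(nrow(v2), 0L)
  expect_identical(unname(attr(v2, "counters")["skipped_spanning"]), 1L)
  # symbolic ALT skipped
  v3 <- load_variants(vrec(2, "A", "<DEL>", "1|0"), ref)
  expect_identical(unname(attr(v3, "counters")["skipped_symbolic"]), 1L)
  # oversized record dropped and counted
  big <- c(big = paste(rep("A", 7000), collapse = ""))
  dels <- vrec(1, paste(rep("A", 6001), collapse = ""), "A", "1|1", contig = "big")
  v4 <- load_variants(dels, big, max_size = 5000L)
  expect_identical(nrow(v4), 0L)
  expect_identical(unname(attr(v4, "counters")["filtered_size"]), 2L)
  # REF mismatch is fatal with coordinates
  expect_error(load_variants(vrec(2, "G", "C", "1|0"), ref), "REF mismatch")
  # duplicate record on one haplotype: keep first
  dup <- rbind(vrec(2, "A", "C", "1|0"), vrec(2, "A", "C", "1|0"))
  expect_warning(v5 <- load_variants(dup, ref), "duplicate")
  expect_identical(nrow(v5), 1L)
  expect_identical(unname(attr(v5, "counters")["skipped_duplicate"]), 1L)
})

test_that("call-level provenance counters are conserved", {
  set.seed(23)
  g <- make_diploid_genome(sim_config(seed = 23))
  v <- load_variants(g$truth, g$reference)
  cnt <- attr(v, "counters")
  buckets <- cnt[c("kept", "skipped_symbolic", "skipped_spanning",
                   "filtered_size", "masked_out", "skipped_overlap",
                   "skipped_duplicate")]
  expect_identical(unname(sum(buckets)), unname(cnt["calls"]))
  # masking with whole-contig intervals keeps exactly the unmasked records
  vm <- load_variants(g$truth, g$reference, mask = g$regions)
  expect_identical(nrow(vm), nrow(v))
  expect_identical(vm$pos, v$pos)
})

test_that("VCF round trip preserves kept records and classifications", {
  g <- make_diploid_genome(sim_config(seed = 24, mode = "decomposed"))
  q <- make_decomposed_query(g)
  d <- tempfile("rt"); dir.create(d)
  lens <- setNames(nchar(g$reference), names(g$reference))
  p1 <- file.path(d, "truth.vcf")
  write_vcf(g$truth, p1, sample = "TRUTH", contig_lens = lens)
  v1 <- load_variants(p1, g$reference, source = "truth")
  v0 <- load_variants(g$truth, g$reference, source = "truth")
  expect_identical(v1$pos, v0$pos)
  expect_identical(v1$ref, v0$ref)
  expect_identical(v1$alt, v0$alt)
  expect_identical(v1$hap, v0$hap)
  # annotated output reloads to identical classifications
  res <- run_benchmark(q$query, g$truth, g$reference)
  paths <- write_annotated_vcf(res, file.path(d, "t.vcf"), file.path(d, "q.vcf"))
  res2 <- run_benchmark(paths$query, paths$truth, g$reference)
  cols <- c("contig", "src", "hap", "pos", "ref", "alt", "bd", "bc")
  o1 <- res$classifications[do.call(order, res$classifications[cols]), cols]
  o2 <- res2$classifications[do.call(order, res2$classifications[cols]), cols]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
  # annotated records carry BD/BC with 4-decimal credit
  ann <- readLines(paths$query)
  body <- ann[!startsWith(ann, "#")]
  expect_true(all(grepl("GT:PS:BD:BC", body)))
  expect_true(any(grepl(":TP:1\\.0000", body)))
})

test_that("report TSVs are emitted and internally consistent", {
  g <- make_diploid_genome(sim_config(seed = 25, mode = "decomposed"))
  q <- make_decomposed_query(g)
  res <- run_benchmark(q$query, g$truth, g$reference)
  prefix <- tempfile("rep")
  paths <- write_reports(res, prefix)
  s <- read.table(paths$summary, sep = "\t", header = TRUE)
  # FNR column equals FN/(TP_truth+FN) recomputed from counts
  has <- s$TP_truth + s$FN > 0
  expect_equal(s$FNR[has], s$FN[has] / (s$TP_truth[has] + s$FN[has]))
  # totals row equals the sum of per-category "all" rows
  tot <- s[s$category == "TOTAL", ]
  per <- s[s$category != "TOTAL" & s$size_bin == "all", ]
  expect_identical(tot$TP_truth, sum(per$TP_truth))
  expect_identical(tot$FP, sum(per$FP))
  # per-bin rows sum to the category "all" row
  for (cat in c("SNP", "INDEL", "SV")) {
    rows <- s[s$category == cat, ]
    expect_identical(sum(rows$TP_truth[rows$size_bin != "all"]),
                     rows$TP_truth[rows$size_bin == "all"])
  }
  expect_true(file.exists(paths$superclusters))
  expect_true(file.exists(paths$phasing))
  # empty evaluation: header-only summary with zero counts
  empty <- run_benchmark(vrec(0, "A", "C", "1|0")[0, ],
                         vrec(0, "A", "C", "1|0")[0, ],
                         c(c1 = "ACGTACGT"))
  p2 <- write_reports(empty, tempfile("rep0"))
  s2 <- read.table(p2$summary, sep = "\t", header = TRUE)
  expect_true(all(s2$TP_truth + s2$FN + s2$TP_query + s2$FP == 0))
})
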