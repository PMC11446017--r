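#' Run the joint benchmarking pipeline
#'
#' Loads and normalizes both VCFs, clusters variants (reach-based by
#' default), merges truth and query clusters into superclusters, evaluates
#' every supercluster jointly across size categories (orientation choice,
#' sync-group decomposition, credit-thresholded TP/FP/FN), and performs the
#' representation-aware phasing evaluation (phase blocks, switch/flip
#' errors, NG50-family metrics).
#'
#' @param query,truth VCF path, record data frame, or `variant_set`.
#' @param reference FASTA path, named character vector, or
#'   `reference_index`.
#' @param bed optional BED path / data frame restricting evaluation.
#' @param config a [benchmark_config()].
#' @param truth_sample,query_sample sample names (default: only sample).
#' @return an object of class `vcfjoint_result`: `summary` (metrics per
#'   category and size bin), `classifications` (per-call decisions with
#'   credit), `superclusters`, `phasing`, provenance `counters`,
#'   `gt_mismatches`, and the loaded variant sets.
#' @seealso [run_stratified()], [write_reports()], [write_annotated_vcf()]
#' @export
run_benchmark <- function(query, truth, reference, bed = NULL,
                          config = benchmark_config(),
                          truth_sample = NULL, query_sample = NULL) {
  ref <- read_reference(reference)
  mask <- if (!is.null(bed)) read_regions(bed) else NULL
  tv <- if (inherits(truth, "variant_set")) truth else
    load_variants(truth, ref, sample = truth_sample, mask = mask,
                  max_size = config$largest, source = "truth",
                  pass_only = config$pass_only)
  qv <- if (inherits(query, "variant_set")) query else
    load_variants(query, ref, sample = query_sample, mask = mask,
                  max_size = config$largest, source = "query",
                  pass_only = config$pass_only)
  if (!is.null(config$max_eval_size)) {
    tv <- subset_variant_set(tv, tv$len <= config$max_eval_size)
    qv <- subset_variant_set(qv, qv$len <= config$max_eval_size)
  }
  if (config$realign_truth) {
    recs <- realign_records(tv, ref, config$penalties)
    tv <- load_variants(recs, ref, source = "truth")
  }
  if (config$realign_query) {
    recs <- realign_records(qv, ref, config$penalties)
    qv <- load_variants(recs, ref, source = "query")
  }

  contigs <- names(ref$seq)[names(ref$seq) %in% unique(c(tv$contig, qv$contig))]
  if (config$verbose)
    message("loaded ", nrow(tv), " truth and ", nrow(qv),
            " query calls on ", length(contigs), " contig(s)")
  cls <- NULL
  scs_all <- NULL
  sc_counter <- 0L
  for (contig in contigs) {
    cseq <- ref$seq[[contig]]
    tvc <- tv[tv$contig == contig, , drop = FALSE]
    qvc <- qv[qv$contig == contig, , drop = FALSE]
    cluster_of <- function(v) {
      if (config$cluster == "biwfa")
        reach_cluster(v, cseq, config$penalties, config$max_cluster_span)
      else
        gap_cluster_table(v, cseq, config$gap_n, config$penalties)
    }
    tcl <- cluster_of(tvc)
    qcl <- cluster_of(qvc)
    scs <- build_superclusters(tcl$clusters, qcl$clusters, config$flank,
                               ref$len[[contig]])
    if (config$verbose)
      message(contig, ": ", nrow(tcl$clusters), " truth clusters, ",
              nrow(qcl$clusters), " query clusters, ", nrow(scs),
              " superclusters")
    if (nrow(scs) == 0L) next
    for (k in seq_len(nrow(scs))) {
      sc_counter <- sc_counter + 1L
      tv_sc <- tvc[tcl$id %in% scs$truth[[k]], , drop = FALSE]
      qv_sc <- qvc[qcl$id %in% scs$query[[k]], , drop = FALSE]
      ev <- evaluate_supercluster(cseq, scs$wstart[k], scs$wend[k],
                                  tv_sc, qv_sc, config$credit_threshold)
      if (!is.null(ev$rows)) {
        ev$rows$sc <- sc_counter
        ev$rows$contig <- contig
        cls <- rbind(cls, ev$rows)
      }
      scs_all <- rbind(scs_all, data.frame(
        sc = sc_counter, contig = contig,
        start = scs$start[k], end = scs$end[k],
        wstart = scs$wstart[k], wend = scs$wend[k],
        n_truth = nrow(tv_sc), n_query = nrow(qv_sc),
        d_orig = ev$score$d_orig, d_swap = ev$score$d_swap,
        orientation = ev$score$chosen, stringsAsFactors = FALSE))
    }
  }

  # decorate classifications with variant metadata
  if (!is.null(cls)) {
    meta <- function(side, row) {
      v <- if (side == "truth") tv else qv
      v[row, c("rec", "pos", "ref", "alt", "type", "len")]
    }
    md <- do.call(rbind, lapply(seq_len(nrow(cls)), function(i)
      meta(cls$side[i], cls$row[i])))
    cat_bin <- lapply(seq_len(nrow(md)), function(i)
      categorize_variant(md$type[i], md$len[i], config$sv_threshold,
                         config$size_bins))
    classifications <- data.frame(
      contig = cls$contig, src = cls$side, rec = md$rec, hap = cls$hap,
      pos = md$pos + 1L, ref = md$ref, alt = md$alt, type = md$type,
      len = md$len,
      category = vapply(cat_bin, `[[`, character(1), "category"),
      size_bin = vapply(cat_bin, `[[`, character(1), "size_bin"),
      sc = cls$sc, bd = cls$bd, bc = cls$bc,
      ed_ref = cls$ed_ref, ed_call = cls$ed_call,
      row = cls$row, stringsAsFactors = FALSE)
  } else {
    classifications <- data.frame(
      contig = character(), src = character(), rec = integer(),
      hap = integer(), pos = integer(), ref = character(),
      alt = character(), type = character(), len = integer(),
      category = character(), size_bin = character(), sc = integer(),
      bd = character(), bc = numeric(), ed_ref = integer(),
      ed_call = integer(), row = integer(), stringsAsFactors = FALSE)
  }

  phasing <- evaluate_phasing(tv, qv, scs_all, ref, config)
  if (!is.null(scs_all)) {
    scs_all$phase_state <- phasing$sc_state[match(scs_all$sc, phasing$sc_id)]
    if (config$distance)
      scs_all$distance <- pmin(scs_all$d_orig, scs_all$d_swap)
  } else {
    scs_all <- data.frame(sc = integer(), contig = character(),
                          start = integer(), end = integer(),
                          wstart = integer(), wend = integer(),
                          n_truth = integer(), n_query = integer(),
                          d_orig = integer(), d_swap = integer(),
                          orientation = character(),
                          phase_state = character(), stringsAsFactors = FALSE)
  }

  structure(list(
    summary = summarize_metrics(classifications),
    classifications = classifications,
    superclusters = scs_all,
    phasing = phasing$report,
    gt_mismatches = resolve_zygosity(classifications),
    counters = list(truth = attr(tv, "counters"), query = attr(qv, "counters")),
    truth_set = tv, query_set = qv,
    config = config), class = "vcfjoint_result")
}

# Phasing evaluation over all superclusters: blocks, states, switch/flip
# DP per block, NG50 family.
evaluate_phasing <- function(tv, qv, scs, ref, config) {
  blocks <- assign_phase_blocks(tv, qv, ref$len)
  genome_length <- sum(ref$len)
  sc_id <- integer(0); sc_state <- character(0)
  block_rows <- NULL
  switch_bp <- list(); flip_bp <- list()
  total_sw <- 0L; total_fl <- 0L
  if (!is.null(scs) && nrow(scs) > 0L) {
    for (contig in unique(scs$contig)) {
      bl <- blocks[[contig]]
      d <- scs[scs$contig == contig, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      b_start <- findInterval(d$start, bl$start)
      b_end <- findInterval(pmax(d$end - 1L, d$start), bl$start)
      st <- vapply(seq_len(nrow(d)), function(i) {
        if (b_start[i] != b_end[i]) return("UNPHASED")  # straddles a block
        phase_state(d$d_orig[i], d$d_swap[i], config$phasing_threshold)
      }, character(1))
      sc_id <- c(sc_id, d$sc); sc_state <- c(sc_state, st)
      for (b in seq_len(nrow(bl))) {
        in_b <- which(b_start == b & b_end == b)
        phased <- in_b[st[in_b] %in% c("ORIG", "SWAP")]
        r <- count_switch_flip(st[phased])
        total_sw <- total_sw + r$switches
        total_fl <- total_fl + r$flips
        if (r$switches > 0L) {
          i <- phased[r$switch_after]
          j <- phased[r$switch_after + 1L]
          switch_bp[[contig]] <- c(switch_bp[[contig]],
                                   (d$end[i] + d$start[j]) %/% 2L)
        }
        if (r$flips > 0L) {
          i <- phased[r$flip_at]
          flip_bp[[contig]] <- c(flip_bp[[contig]],
                                 (d$start[i] + d$end[i]) %/% 2L)
        }
        block_rows <- rbind(block_rows, data.frame(
          contig = contig, start = bl$start[b], end = bl$end[b],
          n_superclusters = length(in_b), n_phased = length(phased),
          switches = r$switches, flips = r$flips, stringsAsFactors = FALSE))
      }
    }
  } else {
    for (contig in names(blocks)) {
      bl <- blocks[[contig]]
      block_rows <- rbind(block_rows, data.frame(
        contig = contig, start = bl$start, end = bl$end,
        n_superclusters = 0L, n_phased = 0L, switches = 0L, flips = 0L,
        stringsAsFactors = FALSE))
    }
  }
  ng50 <- ngc50(split_segments(blocks, list()), genome_length)
  sw_ng <- ngc50(split_segments(blocks, switch_bp), genome_length)
  swfl_bp <- lapply(union(names(switch_bp), names(flip_bp)), function(ct)
    c(switch_bp[[ct]], flip_bp[[ct]]))
  names(swfl_bp) <- union(names(switch_bp), names(flip_bp))
  swfl_ng <- ngc50(split_segments(blocks, swfl_bp), genome_length)
  list(sc_id = sc_id, sc_state = sc_state,
       report = list(blocks = block_rows, switch_count = total_sw,
                     flip_count = total_fl,
                     switch_positions = switch_bp, flip_positions = flip_bp,
                     ng50 = ng50, switch_ngc50 = sw_ng,
                     switchflip_ngc50 = swfl_ng,
                     genome_length = genome_length))
}

#' Stratified (separate) versus joint evaluation
#'
#' Replicates the small-only / SV-only / joint experimental design: the
#' variant sets are restricted to calls below the SV threshold, at or
#' above it, and unrestricted, each pair is benchmarked, and the
#' per-category error totals (FN+FP) are compared. Joint evaluation can
#' only discover more cross-size equivalences, so its error total is at
#' most the separate sum on constructed cases.
#'
#' @inheritParams run_benchmark
#' @return list with the three `vcfjoint_result`s (`joint`, `small`,
#'   `sv`) and a `reduction` table of per-category error totals and
#'   percent reductions.
#' @export
run_stratified <- function(query, truth, reference, bed = NULL,
                           config = benchmark_config(),
                           truth_sample = NULL, query_sample = NULL) {
  ref <- read_reference(reference)
  mask <- if (!is.null(bed)) read_regions(bed) else NULL
  tv <- load_variants(truth, ref, sample = truth_sample, mask = mask,
                      max_size = config$largest, source = "truth",
                      pass_only = config$pass_only)
  qv <- load_variants(query, ref, sample = query_sample, mask = mask,
                      max_size = config$largest, source = "query",
                      pass_only = config$pass_only)
  thr <- config$sv_threshold
  res <- list(
    joint = run_benchmark(qv, tv, ref, config = config),
    small = run_benchmark(subset_variant_set(qv, qv$len < thr),
                          subset_variant_set(tv, tv$len < thr),
                          ref, config = config),
    sv = run_benchmark(subset_variant_set(qv, qv$len >= thr),
                       subset_variant_set(tv, tv$len >= thr),
                       ref, config = config))
  errors_of <- function(r, cat) {
    s <- r$summary
    row <- s[s$category == cat & s$size_bin == "all", ]
    row$FN + row$FP
  }
  red <- NULL
  for (cat in c("SNP", "INDEL", "SV")) {
    sep <- if (cat == "SV") errors_of(res$sv, cat) else errors_of(res$small, cat)
    joint <- errors_of(res$joint, cat)
    red <- rbind(red, data.frame(
      category = cat, errors_separate = sep, errors_joint = joint,
      reduction_pct = if (sep > 0) 100 * (sep - joint) / sep else 0,
      stringsAsFactors = FALSE))
  }
  res$reduction <- red
  res
}

#' Write summary, supercluster and phasing reports as TSV
#'
#' @param result a `vcfjoint_result`.
#' @param prefix output path prefix; writes `<prefix>.summary.tsv`,
#'   `<prefix>.superclusters.tsv` and `<prefix>.phasing.tsv`.
#' @return named list of paths, invisibly.
#' @export
write_reports <- function(result, prefix) {
  paths <- list(summary = paste0(prefix, ".summary.tsv"),
                superclusters = paste0(prefix, ".superclusters.tsv"),
                phasing = paste0(prefix, ".phasing.tsv"))
  wt <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(result$summary, paths$summary)
  wt(result$superclusters[, setdiff(names(result$superclusters), c("truth", "query"))],
     paths$superclusters)
  ph <- result$phasing
  blocks <- ph$blocks
  ph_tail <- data.frame(
    contig = "ALL", start = NA_integer_, end = NA_integer_,
    n_superclusters = sum(blocks$n_superclusters),
    n_phased = sum(blocks$n_phased),
    switches = ph$switch_count, flips = ph$flip_count,
    stringsAsFactors = FALSE)
  out <- rbind(blocks, ph_tail)
  out$ng50 <- c(rep(NA_integer_, nrow(blocks)), ph$ng50)
  out$switch_ngc50 <- c(rep(NA_integer_, nrow(blocks)), ph$switch_ngc50)
  out$switchflip_ngc50 <- c(rep(NA_integer_, nrow(blocks)), ph$switchflip_ngc50)
  wt(out, paths$phasing)
  invisible(paths)
}

#' Write annotated truth and query VCFs
#'
#' Emits both input variant sets with their original POS/REF/ALT/GT
#' unchanged, adding FORMAT fields BD (benchmarking decision, per
#' evaluated haplotype) and BC (credit, 4 decimals).
#'
#' @param result a `vcfjoint_result`.
#' @param truth_path,query_path output VCF paths.
#' @return named list of paths, invisibly.
#' @export
write_annotated_vcf <- function(result, truth_path, query_path) {
  one <- function(vs, src, path, sample) {
    cl <- result$classifications
    cl <- cl[cl$src == src, , drop = FALSE]
    if (nrow(vs) == 0L) {
      write_vcf(data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gt = character(), stringsAsFactors = FALSE),
                path, sample = sample)
      return(path)
    }
    key <- paste(vs$contig, vs$rec)
    recs <- NULL
    for (u in unique(key)) {
      rows <- vs[key == u, , drop = FALSE]
      crows <- cl[cl$contig == rows$contig[1L] & cl$rec == rows$rec[1L], ,
                  drop = FALSE]
      crows <- crows[order(crows$hap), , drop = FALSE]
      bd <- if (nrow(crows)) paste(crows$bd, collapse = ",") else "."
      bc <- if (nrow(crows)) paste(sprintf("%.4f", crows$bc), collapse = ",")
            else "."
      recs <- rbind(recs, data.frame(
        contig = rows$contig[1L], pos = rows$orig_pos[1L],
        ref = rows$orig_ref[1L], alt = rows$orig_alt[1L],
        gt = rows$orig_gt[1L], ps = rows$ps[1L], bd = bd, bc = bc,
        stringsAsFactors = FALSE))
    }
    write_vcf(recs, path, sample = sample)
    path
  }
  invisible(list(truth = one(result$truth_set, "truth", truth_path, "TRUTH"),
                 query = one(result$query_set, "query", query_path, "QUERY")))
}

#' @export
print.vcfjoint_result <- function(x, ...) {
  cat("Joint variant benchmarking result\n")
  s <- x$summary
  s <- s[s$size_bin == "all", c("category", "TP_truth", "FN", "TP_query",
                                "FP", "FNR", "FDR", "F1")]
  print(s, row.names = FALSE, digits = 4)
  cat(sprintf("\nSuperclusters: %d | genotype mismatches: %d\n",
              nrow(x$superclusters), x$gt_mismatches))
  cat(sprintf("Phasing: %d switch, %d flip | NG50 %d | switch NGC50 %d | switchflip NGC50 %d\n",
              x$phasing$switch_count, x$phasing$flip_count,
              x$phasing$ng50, x$phasing$switch_ngc50,
              x$phasing$switchflip_ngc50))
  invisible(x)
}

#' @export
summary.vcfjoint_result <- function(object, ...) object$summary
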