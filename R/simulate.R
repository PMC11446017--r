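#' Simulation configuration
#'
#' Parameters for the seeded diploid-genome and truth/query VCF simulator.
#' The generator emulates the conditions under which representation
#' divergence arises in real callsets: homopolymer and tandem-repeat
#' tracts where indels admit several placements, large deletions that can
#' be written as several smaller ones, and SNP runs that can be merged
#' into a single complex record.
#'
#' @param seed integer; fully determines the output.
#' @param contig_len contig length in bases.
#' @param n_contigs number of contigs.
#' @param snp_per_kb,indel_per_kb,sv_per_kb event densities (per kb).
#' @param repeat_fraction approximate fraction of the contig covered by
#'   homopolymer/tandem tracts.
#' @param mode representation mode of the companion query:
#'   `"identical"`, `"decomposed"` or `"realigned"`.
#' @param penalties_alt penalties used by `"realigned"` mode.
#' @param hom_fraction fraction of homozygous variants.
#' @param sv_len_range SV deletion length range (bases).
#' @param ps_block_len if set, a new PS phase set starts every this many
#'   bases; default one phase set per contig.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, contig_len = 3000L, n_contigs = 1L,
                       snp_per_kb = 2, indel_per_kb = 1.2, sv_per_kb = 0.4,
                       repeat_fraction = 0.12,
                       mode = c("identical", "decomposed", "realigned"),
                       penalties_alt = align_penalties(2L, 3L, 2L),
                       hom_fraction = 0.3,
                       sv_len_range = c(60L, 160L),
                       ps_block_len = NULL) {
  mode <- match.arg(mode)
  stopifnot(snp_per_kb >= 0, indel_per_kb >= 0, sv_per_kb >= 0,
            contig_len >= 400L)
  structure(list(seed = as.integer(seed), contig_len = as.integer(contig_len),
                 n_contigs = as.integer(n_contigs),
                 snp_per_kb = snp_per_kb, indel_per_kb = indel_per_kb,
                 sv_per_kb = sv_per_kb, repeat_fraction = repeat_fraction,
                 mode = mode, penalties_alt = penalties_alt,
                 hom_fraction = hom_fraction,
                 sv_len_range = as.integer(sv_len_range),
                 ps_block_len = if (is.null(ps_block_len)) NULL else as.integer(ps_block_len)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

other_base <- function(b) sample(setdiff(BASES, b), 1L)

# find a free placement of `span` bases within [lo, hi]; occupied is a
# 2-column matrix of 1-based inclusive intervals with margins applied
place_interval <- function(span, occupied, lo, hi, margin = 8L, tries = 300L) {
  if (hi < lo) return(NA_integer_)
  for (t in seq_len(tries)) {
    p <- sample(lo:hi, 1L)
    a <- p - margin; b <- p + span + margin
    if (nrow(occupied) == 0L ||
        !any(occupied[, 1L] <= b & occupied[, 2L] >= a)) return(p)
  }
  NA_integer_
}

gt_of <- function(hom, hap) if (hom) "1|1" else if (hap == 1L) "1|0" else "0|1"

ps_of <- function(pos, cfg) {
  if (is.null(cfg$ps_block_len)) 1L else (pos - 1L) %/% cfg$ps_block_len + 1L
}

#' Simulate a diploid genome with phased truth variants
#'
#' Builds a reference with embedded homopolymer and tandem-repeat tracts,
#' then places SNPs, INDELs and SV deletions/insertions without
#' same-haplotype overlap. Indels that fall inside repeat tracts are
#' written right-aligned (a legal but non-canonical representation), and
#' at least one large deletion is laid out so that it can be rewritten as
#' a 47+1+97-base decomposition plus a SNP; both give downstream query
#' generators room to diverge in representation while preserving the
#' haplotype sequences. Output is deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_genome` with `reference` (named character),
#'   `truth` (record data frame: `contig`, `pos` 1-based, `ref`, `alt`,
#'   `gt`, `ps`), `regions` (whole-contig BED data frame), `meta`
#'   (tracts, decomposition layouts, repeat-indel bookkeeping) and `cfg`.
#' @export
make_diploid_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  refs <- list(); recs <- list(); meta <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    contig <- paste0("ctg", ci)
    L <- cfg$contig_len
    s <- sample(BASES, L, replace = TRUE)

    # repeat tracts (homopolymers and short tandem repeats)
    n_tracts <- max(0L, round(L * cfg$repeat_fraction / 25))
    tracts <- NULL
    occ <- matrix(integer(0), ncol = 2L)
    for (k in seq_len(n_tracts)) {
      kind <- sample(c("hp", "str"), 1L)
      if (kind == "hp") {
        tl <- sample(10:16, 1L)
        unit <- sample(BASES, 1L)
        seqs <- rep(unit, tl)
      } else {
        u <- sample(2:3, 1L)
        nrep <- sample(4:7, 1L)
        unit <- paste(sample(BASES, u, replace = TRUE), collapse = "")
        seqs <- strsplit(strrep(unit, nrep), "")[[1]]
        tl <- length(seqs)
      }
      p <- place_interval(tl, occ, 60L, L - tl - 60L, margin = 12L)
      if (is.na(p)) next
      s[p:(p + tl - 1L)] <- seqs
      # avoid accidental run extension at the borders
      if (s[p - 1L] == s[p]) s[p - 1L] <- other_base(s[p])
      if (s[p + tl] == s[p + tl - 1L]) s[p + tl] <- other_base(s[p + tl - 1L])
      tracts <- rbind(tracts, data.frame(start = p, end = p + tl - 1L,
                                         kind = kind, unit = unit,
                                         stringsAsFactors = FALSE))
      occ <- rbind(occ, c(p, p + tl - 1L))
    }

    n_snp <- round(L / 1000 * cfg$snp_per_kb)
    n_indel <- round(L / 1000 * cfg$indel_per_kb)
    n_sv <- round(L / 1000 * cfg$sv_per_kb)
    rows <- list(); decomp <- list(); rep_indels <- NULL

    add_row <- function(pos, ref, alt, gt, tag = "plain") {
      data.frame(contig = contig, pos = pos, ref = ref, alt = alt, gt = gt,
                 ps = ps_of(pos, cfg), tag = tag, stringsAsFactors = FALSE)
    }

    # --- SVs first (they need the most room); the first is decomposable
    for (k in seq_len(n_sv)) {
      decomposable <- (k == 1L)
      if (decomposable) {
        Lsv <- 145L
        p <- place_interval(Lsv + 10L, occ, 80L, L - Lsv - 120L, margin = 20L)
        if (is.na(p))
          stop("variant density too high to place the SV; lower densities or grow the contig")
        # reference equalities that make the 47+1+97 (+SNP) rewrite
        # haplotype-identical (0-based offsets from anchor p0 = p - 1)
        s[p + 147L] <- s[p + 49L]
        s[p + 148L] <- s[p + 51L]
        if (s[p + 146L] == s[p + 48L]) s[p + 146L] <- other_base(s[p + 48L])
        hom <- FALSE
        hap <- sample(1:2, 1L)
        refal <- paste(s[p:(p + Lsv)], collapse = "")
        rows[[length(rows) + 1L]] <- add_row(p, refal, s[p], gt_of(hom, hap),
                                             tag = "decomp_sv")
        decomp[[length(decomp) + 1L]] <- list(pos = p, len = Lsv, hap = hap,
                                              gt = gt_of(hom, hap))
        occ <- rbind(occ, c(p - 4L, p + Lsv + 8L))
      } else {
        Lsv <- sample(cfg$sv_len_range[1L]:cfg$sv_len_range[2L], 1L)
        is_del <- runif(1) < 0.7
        span <- if (is_del) Lsv + 2L else 2L
        p <- place_interval(span, occ, 80L, L - Lsv - 120L, margin = 20L)
        if (is.na(p))
          stop("variant density too high to place the SV; lower densities or grow the contig")
        hom <- runif(1) < cfg$hom_fraction
        hap <- sample(1:2, 1L)
        if (is_del) {
          refal <- paste(s[p:(p + Lsv)], collapse = "")
          rows[[length(rows) + 1L]] <- add_row(p, refal, s[p], gt_of(hom, hap))
          occ <- rbind(occ, c(p - 4L, p + Lsv + 4L))
        } else {
          ins <- paste(sample(BASES, Lsv, replace = TRUE), collapse = "")
          rows[[length(rows) + 1L]] <- add_row(p, s[p], paste0(s[p], ins),
                                               gt_of(hom, hap))
          occ <- rbind(occ, c(p - 4L, p + 4L))
        }
      }
    }

    # --- indels; about half of the available repeat tracts get one,
    # written right-aligned inside the run
    tract_idx <- if (is.null(tracts)) integer(0) else sample(seq_len(nrow(tracts)))
    n_rep_indel <- min(length(tract_idx), ceiling(n_indel / 2))
    for (k in seq_len(n_rep_indel)) {
      tr <- tracts[tract_idx[k], ]
      run_len <- tr$end - tr$start + 1L
      unit_len <- nchar(tr$unit)
      max_units <- (run_len %/% unit_len) - 2L
      if (max_units < 1L) next
      ku <- sample(seq_len(min(2L, max_units)), 1L)
      dlen <- ku * unit_len
      is_del <- runif(1) < 0.6
      hom <- runif(1) < cfg$hom_fraction
      hap <- sample(1:2, 1L)
      if (is_del) {
        # right-aligned: anchor so the deleted bases end at the tract end
        p <- tr$end - dlen
        refal <- paste(s[p:(p + dlen)], collapse = "")
        rows[[length(rows) + 1L]] <- add_row(p, refal, s[p], gt_of(hom, hap),
                                             tag = "repeat_indel")
      } else {
        p <- tr$end
        ins <- paste(rep(strsplit(tr$unit, "")[[1]], length.out = dlen),
                     collapse = "")
        rows[[length(rows) + 1L]] <- add_row(p, s[p], paste0(s[p], ins),
                                             gt_of(hom, hap),
                                             tag = "repeat_indel")
      }
      rep_indels <- rbind(rep_indels,
                          data.frame(tract = tract_idx[k],
                                     start = tr$start, end = tr$end,
                                     unit = tr$unit,
                                     stringsAsFactors = FALSE))
      occ <- rbind(occ, c(tr$start - 2L, tr$end + 2L))
    }

    # --- remaining indels at non-repetitive positions
    for (k in seq_len(max(0L, n_indel - n_rep_indel))) {
      dlen <- sample(1:6, 1L)
      is_del <- runif(1) < 0.5
      span <- if (is_del) dlen + 2L else 2L
      p <- place_interval(span, occ, 60L, L - 80L, margin = 6L)
      if (is.na(p)) next
      hom <- runif(1) < cfg$hom_fraction
      hap <- sample(1:2, 1L)
      if (is_del) {
        refal <- paste(s[p:(p + dlen)], collapse = "")
        rows[[length(rows) + 1L]] <- add_row(p, refal, s[p], gt_of(hom, hap))
        occ <- rbind(occ, c(p - 2L, p + dlen + 2L))
      } else {
        ins <- paste(sample(BASES, dlen, replace = TRUE), collapse = "")
        rows[[length(rows) + 1L]] <- add_row(p, s[p], paste0(s[p], ins),
                                             gt_of(hom, hap))
        occ <- rbind(occ, c(p - 2L, p + 2L))
      }
    }

    # --- SNPs: a fifth as close pairs (mergeable into one complex record)
    n_pair <- if (n_snp >= 4L) max(1L, round(n_snp * 0.2)) else 0L
    for (k in seq_len(n_pair)) {
      gap <- sample(2:5, 1L)
      p <- place_interval(gap + 1L, occ, 60L, L - 80L, margin = 6L)
      if (is.na(p)) next
      hom <- runif(1) < cfg$hom_fraction
      hap <- sample(1:2, 1L)
      for (pp in c(p, p + gap)) {
        rows[[length(rows) + 1L]] <- add_row(pp, s[pp], other_base(s[pp]),
                                             gt_of(hom, hap), tag = "snp_pair")
      }
      occ <- rbind(occ, c(p - 2L, p + gap + 2L))
    }
    for (k in seq_len(max(0L, n_snp - 2L * n_pair))) {
      p <- place_interval(1L, occ, 60L, L - 80L, margin = 4L)
      if (is.na(p)) next
      hom <- runif(1) < cfg$hom_fraction
      hap <- sample(1:2, 1L)
      rows[[length(rows) + 1L]] <- add_row(p, s[p], other_base(s[p]),
                                           gt_of(hom, hap))
      occ <- rbind(occ, c(p, p))
    }

    rec <- if (length(rows)) do.call(rbind, rows) else
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), gt = character(), ps = integer(),
                 tag = character(), stringsAsFactors = FALSE)
    rec <- rec[order(rec$pos), , drop = FALSE]
    rownames(rec) <- NULL
    refs[[contig]] <- paste(s, collapse = "")
    recs[[contig]] <- rec
    meta[[contig]] <- list(tracts = tracts, decomp = decomp,
                           rep_indels = rep_indels)
  }
  truth <- do.call(rbind, recs)
  rownames(truth) <- NULL
  reference <- unlist(refs)
  regions <- data.frame(contig = names(reference), start = 0L,
                        end = nchar(reference), stringsAsFactors = FALSE)
  structure(list(reference = reference, truth = truth, regions = regions,
                 meta = meta, cfg = cfg), class = "sim_genome")
}

# assert per-haplotype string equality of two record sets over a genome
check_hap_identical <- function(reference, truth, query) {
  ref <- read_reference(reference)
  tv <- load_variants(truth, ref, source = "truth")
  qv <- load_variants(query, ref, source = "query")
  for (contig in names(ref$seq)) {
    for (h in 1:2) {
      th <- tv[tv$contig == contig & tv$hap == h, , drop = FALSE]
      qh <- qv[qv$contig == contig & qv$hap == h, , drop = FALSE]
      a <- apply_variants(ref$seq[[contig]], 0L, th)
      b <- apply_variants(ref$seq[[contig]], 0L, qh)
      if (!identical(a, b))
        stop("generated query is not haplotype-identical on ", contig,
             " haplotype ", h)
    }
  }
  invisible(TRUE)
}

#' Rewrite truth variants under divergent but equivalent representations
#'
#' Produces a query VCF whose haplotype sequences equal the truth's while
#' the records differ: the decomposable large deletion becomes a 47-base,
#' a 1-base and a 97-base deletion plus one SNP; right-aligned repeat
#' indels are shifted to the left end of their runs; close SNP pairs are
#' merged into single complex records. Everything else is copied. The
#' generator verifies haplotype identity and fails loudly if violated.
#'
#' @param genome a `sim_genome`.
#' @return list with `query` (record data frame) and `manifest` (intended
#'   equivalences).
#' @export
make_decomposed_query <- function(genome) {
  if (genome$cfg$mode == "identical") {
    q <- genome$truth[, c("contig", "pos", "ref", "alt", "gt", "ps")]
    return(list(query = q, manifest = data.frame(kind = character(),
                                                 contig = character(),
                                                 truth_pos = integer())))
  }
  out <- list(); manifest <- NULL
  for (contig in names(genome$reference)) {
    s <- strsplit(genome$reference[[contig]], "")[[1]]
    rec <- genome$truth[genome$truth$contig == contig, , drop = FALSE]
    m <- genome$meta[[contig]]
    used_pair <- logical(nrow(rec))
    for (r in seq_len(nrow(rec))) {
      if (used_pair[r]) next
      row <- rec[r, ]
      if (row$tag == "decomp_sv") {
        p <- row$pos
        # 47-base deletion, SNP, 1-base deletion, 97-base deletion
        d1 <- data.frame(contig = contig, pos = p,
                         ref = paste(s[p:(p + 47L)], collapse = ""),
                         alt = s[p], gt = row$gt, ps = row$ps,
                         stringsAsFactors = FALSE)
        sn <- data.frame(contig = contig, pos = p + 48L, ref = s[p + 48L],
                         alt = s[p + 146L], gt = row$gt, ps = row$ps,
                         stringsAsFactors = FALSE)
        d2 <- data.frame(contig = contig, pos = p + 49L,
                         ref = paste(s[(p + 49L):(p + 50L)], collapse = ""),
                         alt = s[p + 49L], gt = row$gt, ps = row$ps,
                         stringsAsFactors = FALSE)
        d3 <- data.frame(contig = contig, pos = p + 51L,
                         ref = paste(s[(p + 51L):(p + 148L)], collapse = ""),
                         alt = s[p + 51L], gt = row$gt, ps = row$ps,
                         stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- rbind(d1, sn, d2, d3)
        manifest <- rbind(manifest, data.frame(kind = "sv_decomposition",
                                               contig = contig, truth_pos = p,
                                               stringsAsFactors = FALSE))
      } else if (row$tag == "repeat_indel") {
        tr <- m$tracts[vapply(seq_len(nrow(m$tracts)), function(i)
          m$tracts$start[i] <= row$pos & m$tracts$end[i] >= row$pos,
          logical(1)), ][1, ]
        # shift to the left end of the run (same haplotype string)
        if (nchar(row$ref) > nchar(row$alt)) {  # deletion
          dlen <- nchar(row$ref) - 1L
          p <- tr$start
          nref <- paste(s[p:(p + dlen)], collapse = "")
          out[[length(out) + 1L]] <- data.frame(contig = contig, pos = p,
                                                ref = nref, alt = s[p],
                                                gt = row$gt, ps = row$ps,
                                                stringsAsFactors = FALSE)
        } else {  # insertion: re-anchor at the base before the run
          ins <- substr(row$alt, 2L, nchar(row$alt))
          p <- tr$start - 1L
          out[[length(out) + 1L]] <- data.frame(contig = contig, pos = p,
                                                ref = s[p],
                                                alt = paste0(s[p], ins),
                                                gt = row$gt, ps = row$ps,
                                                stringsAsFactors = FALSE)
        }
        manifest <- rbind(manifest, data.frame(kind = "repeat_shift",
                                               contig = contig,
                                               truth_pos = row$pos,
                                               stringsAsFactors = FALSE))
      } else if (row$tag == "snp_pair") {
        # merge with its partner into one complex record
        partner <- which(rec$tag == "snp_pair" & !used_pair &
                         seq_len(nrow(rec)) > r &
                         rec$gt == row$gt & rec$pos - row$pos <= 6L)
        if (length(partner) >= 1L) {
          r2 <- partner[1L]
          used_pair[r2] <- TRUE
          p1 <- row$pos; p2 <- rec$pos[r2]
          refsp <- paste(s[p1:p2], collapse = "")
          altsp <- refsp
          substr(altsp, 1L, 1L) <- row$alt
          substr(altsp, p2 - p1 + 1L, p2 - p1 + 1L) <- rec$alt[r2]
          out[[length(out) + 1L]] <- data.frame(contig = contig, pos = p1,
                                                ref = refsp, alt = altsp,
                                                gt = row$gt, ps = row$ps,
                                                stringsAsFactors = FALSE)
          manifest <- rbind(manifest, data.frame(kind = "snp_merge",
                                                 contig = contig,
                                                 truth_pos = p1,
                                                 stringsAsFactors = FALSE))
        } else {
          out[[length(out) + 1L]] <- row[, c("contig", "pos", "ref", "alt",
                                             "gt", "ps")]
        }
      } else {
        out[[length(out) + 1L]] <- row[, c("contig", "pos", "ref", "alt",
                                           "gt", "ps")]
      }
    }
  }
  query <- do.call(rbind, out)
  query <- query[order(query$contig, query$pos), , drop = FALSE]
  rownames(query) <- NULL
  check_hap_identical(genome$reference, genome$truth, query)
  list(query = query,
       manifest = if (is.null(manifest)) data.frame(kind = character(),
                                                    contig = character(),
                                                    truth_pos = integer())
                  else manifest)
}

#' Re-emit truth variants from fresh alignments
#'
#' Reconstructs each truth haplotype cluster by cluster, realigns it to
#' the reference under `penalties` and emits variants from the cigar
#' (maximal non-match runs become records, anchored on the previous
#' reference base). The result is haplotype-identical to the truth but
#' representation-divergent wherever the truth records were not in the
#' aligner's canonical form (right-aligned repeat indels, adjacent
#' variants that merge into one record).
#'
#' @param genome a `sim_genome`.
#' @param penalties an [align_penalties()]; defaults to the config's
#'   alternative penalty set.
#' @return list with `query` (record data frame).
#' @export
make_realigned_query <- function(genome, penalties = NULL) {
  if (is.null(penalties)) penalties <- genome$cfg$penalties_alt
  ref <- read_reference(genome$reference)
  tv <- load_variants(genome$truth, ref, source = "truth")
  query <- realign_records(tv, ref, penalties)
  check_hap_identical(genome$reference, genome$truth, query)
  list(query = query)
}

# Re-emit a variant set as records from fresh cluster-by-cluster alignments
# under the given penalties; haplotype strings are preserved exactly.
realign_records <- function(tv, ref, penalties) {
  out <- list()
  for (contig in names(ref$seq)) {
    cseq <- ref$seq[[contig]]
    v <- tv[tv$contig == contig, , drop = FALSE]
    if (nrow(v) == 0L) next
    id <- gap_cluster(v, 40L)
    for (cl in unique(id)) {
      vc <- v[id == cl, , drop = FALSE]
      cstart <- min(vc$pos); cend <- max(footprint_end(vc))
      wstart <- max(cstart - 1L, 0L)
      wseq <- str_slice(cseq, wstart + 1L, cend)
      hrecs <- list()
      for (h in 1:2) {
        vh <- vc[vc$hap == h, , drop = FALSE]
        if (nrow(vh) == 0L) { hrecs[[h]] <- NULL; next }
        hap <- apply_variants(wseq, wstart, vh)
        aln <- affine_align(hap, wseq, penalties)
        ops <- cigar_ops(aln$cigar)
        recs <- NULL
        i <- 0L; j <- 0L; k <- 1L
        while (k <= length(ops)) {
          if (ops[k] == "=") {
            i <- i + 1L; j <- j + 1L; k <- k + 1L
            next
          }
          i0 <- i; j0 <- j
          while (k <= length(ops) && ops[k] != "=") {
            if (ops[k] %in% c("X", "I")) i <- i + 1L
            if (ops[k] %in% c("X", "D")) j <- j + 1L
            k <- k + 1L
          }
          rpiece <- str_slice(wseq, j0 + 1L, j)
          apiece <- str_slice(hap, i0 + 1L, i)
          # anchor on the previous reference base
          pos1 <- wstart + j0  # 1-based position of the anchor base
          stopifnot(pos1 >= 1L)
          anchor <- substr(cseq, pos1, pos1)
          recs <- rbind(recs, data.frame(
            contig = contig, pos = pos1, ref = paste0(anchor, rpiece),
            alt = paste0(anchor, apiece), hap = h,
            ps = vh$ps[1L], stringsAsFactors = FALSE))
        }
        hrecs[[h]] <- recs
      }
      # combine per-haplotype records into genotyped rows
      allr <- rbind(if (length(hrecs) >= 1L) hrecs[[1L]] else NULL,
                    if (length(hrecs) >= 2L) hrecs[[2L]] else NULL)
      if (is.null(allr)) next
      key <- paste(allr$pos, allr$ref, allr$alt)
      for (u in unique(key)) {
        rows <- allr[key == u, , drop = FALSE]
        haps <- sort(unique(rows$hap))
        gt <- if (length(haps) == 2L) "1|1" else if (haps == 1L) "1|0" else "0|1"
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, pos = rows$pos[1L], ref = rows$ref[1L],
          alt = rows$alt[1L], gt = gt, ps = rows$ps[1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  query <- do.call(rbind, out)
  if (is.null(query))
    query <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        gt = character(), ps = integer(),
                        stringsAsFactors = FALSE)
  query <- query[order(query$contig, query$pos), , drop = FALSE]
  rownames(query) <- NULL
  query
}

#' Construct a flip-error trap in a tandem repeat
#'
#' Builds a small contig with a homopolymer run where a two-base deletion
#' appears at the same POS/REF/ALT on opposite haplotypes of truth and
#' query, compensated by neighbouring records so that all four haplotype
#' sequences are string-identical. Naive exact-match phasing comparison
#' reports a flip here; alignment-aware evaluation must not. Flanking
#' heterozygous anchor SNPs (consistently phased) pin the block
#' orientation.
#'
#' @param seed integer seed.
#' @param contig_len contig length (bases).
#' @return list with `reference`, `truth`, `query`, `regions`.
#' @export
make_flip_trap <- function(seed = 1L, contig_len = 600L) {
  set.seed(seed)
  L <- as.integer(contig_len)
  stopifnot(L >= 400L)
  s <- sample(BASES, L, replace = TRUE)
  run_len <- 18L
  rs <- L %/% 2L - run_len %/% 2L  # run start, 1-based
  re <- rs + run_len - 1L
  s[rs:re] <- "T"
  if (s[rs - 1L] == "T") s[rs - 1L] <- "A"
  if (s[re + 1L] == "T") s[re + 1L] <- "A"
  snp1 <- rs - 80L; snp2 <- re + 80L
  mkrec <- function(pos, ref, alt, gt)
    data.frame(contig = "ctg1", pos = pos, ref = ref, alt = alt, gt = gt,
               ps = 1L, stringsAsFactors = FALSE)
  anchor_snps <- rbind(mkrec(snp1, s[snp1], other_base(s[snp1]), "1|0"),
                       mkrec(snp2, s[snp2], other_base(s[snp2]), "0|1"))
  del2 <- function(p) paste(s[p:(p + 2L)], collapse = "")
  del1 <- function(p) paste(s[p:(p + 1L)], collapse = "")
  truth <- rbind(anchor_snps,
                 mkrec(rs, del2(rs), s[rs], "1|0"),          # hap1, left
                 mkrec(re - 2L, del2(re - 2L), s[re - 2L], "0|1"))  # hap2, right
  query <- rbind(anchor_snps,
                 mkrec(rs, del1(rs), s[rs], "1|0"),          # hap1: 1-base del
                 mkrec(rs + 4L, del1(rs + 4L), s[rs + 4L], "1|0"),  # hap1: 1-base del
                 mkrec(rs, del2(rs), s[rs], "0|1"))          # hap2: the trap
  truth <- truth[order(truth$pos), ]; rownames(truth) <- NULL
  query <- query[order(query$pos), ]; rownames(query) <- NULL
  reference <- setNames(paste(s, collapse = ""), "ctg1")
  check_hap_identical(reference, truth, query)
  list(reference = reference, truth = truth, query = query,
       regions = data.frame(contig = "ctg1", start = 0L, end = L,
                            stringsAsFactors = FALSE))
}

#' Write a simulated genome and its query to files
#'
#' @param genome a `sim_genome`.
#' @param query a query record data frame (or NULL).
#' @param dir output directory (created if missing).
#' @return named list of paths.
#' @export
write_fixture <- function(genome, query = NULL, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- setNames(nchar(genome$reference), names(genome$reference))
  paths <- list(
    fasta = file.path(dir, "ref.fa"),
    truth = file.path(dir, "truth.vcf"),
    bed = file.path(dir, "regions.bed"))
  write_fasta(genome$reference, paths$fasta)
  write_vcf(genome$truth, paths$truth, sample = "TRUTH", contig_lens = lens)
  write_bed(genome$regions, paths$bed)
  if (!is.null(query)) {
    paths$query <- file.path(dir, "query.vcf")
    write_vcf(query, paths$query, sample = "QUERY", contig_lens = lens)
  }
  paths
}
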