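#' Read a reference genome
#'
#' Loads a FASTA file (optionally bgzipped/faidx-indexed) into an in-memory
#' index of uppercase sequences. A named character vector of sequences is
#' accepted as-is, so simulated references can be used without touching
#' disk.
#'
#' @param x path to a FASTA file, a named character vector of sequences,
#'   or an existing `reference_index`.
#' @return a `reference_index`: list with `seq` (named character, uppercase)
#'   and `len` (named integer).
#' @export
read_reference <- function(x) {
  if (inherits(x, "reference_index")) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- toupper(x)
  } else {
    stop("cannot interpret reference input")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in reference contig(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(seq = seqs, len = setNames(nchar(seqs), names(seqs))),
            class = "reference_index")
}

#' Write a reference index to FASTA
#'
#' @param ref a `reference_index` or named character vector.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  ref <- read_reference(ref)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$seq), path)
  invisible(path)
}

#' Read benchmarking regions from BED
#'
#' Reads a 3+ column BED (0-based, half-open), then sorts and merges
#' intervals per contig so the mask is non-overlapping and non-abutting.
#'
#' @param x BED file path, or a data frame with columns `contig`, `start`,
#'   `end` (0-based half-open).
#' @return a `region_mask`: named list of two-column integer matrices
#'   (`start`, `end`).
#' @export
read_regions <- function(x) {
  if (inherits(x, "region_mask")) return(x)
  if (is.character(x)) {
    bed <- read.table(x, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
    bed <- bed[, 1:3]
    names(bed) <- c("contig", "start", "end")
  } else {
    bed <- as.data.frame(x)[, c("contig", "start", "end")]
  }
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(bed$start >= bed$end))
    stop("BED interval with start >= end at line ",
         which(bed$start >= bed$end)[1L])
  mask <- lapply(split(bed, bed$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  structure(mask, class = "region_mask")
}

# does footprint [start, end) (0-based half-open) intersect the mask?
mask_overlaps <- function(mask, contig, start, end) {
  iv <- mask[[contig]]
  if (is.null(iv)) return(rep(FALSE, length(start)))
  q <- IRanges::IRanges(start = start + 1L, end = pmax(end, start + 1L))
  s <- IRanges::IRanges(start = iv[, "start"] + 1L, end = iv[, "end"])
  IRanges::overlapsAny(q, s)
}

# parse one GT string into a length-2 integer allele vector (NA = missing);
# returns NULL for fully missing genotypes
parse_gt <- function(gt) {
  if (is.na(gt) || gt == "." || gt == "./." || gt == ".|.") return(NULL)
  parts <- strsplit(gt, "[|/]")[[1]]
  al <- suppressWarnings(as.integer(parts))
  if (length(al) == 1L) al <- c(al, NA_integer_)
  if (length(al) != 2L) return(NULL)
  if (all(is.na(al))) return(NULL)
  al
}

#' Load and normalize variants from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped), extracts one sample, splits
#' multiallelic records into biallelic ones (one record per ALT with
#' genotypes remapped per haplotype), and applies the preprocessing rules:
#' symbolic ALTs, breakends, spanning-deletion `*` alleles and missing
#' genotypes are skipped with counts; records whose REF or ALT exceeds
#' `max_size` bases are dropped and counted; records outside the region
#' mask are dropped; same-haplotype overlapping records keep the earlier
#' record; exact duplicates keep the first. Haploid or half calls use the
#' called haplotype and treat the other as reference (with a count).
#' REF alleles are checked against the reference.
#'
#' @param x VCF path, or a data frame of records with columns `contig`,
#'   `pos` (1-based), `ref`, `alt`, `gt` and optional `ps`.
#' @param ref a reference accepted by [read_reference()].
#' @param sample sample name; defaults to the only sample in the file.
#' @param mask optional [read_regions()] mask.
#' @param max_size drop records with REF or ALT longer than this (bases).
#' @param contig_filter optional character vector of contigs to keep.
#' @param source `"truth"` or `"query"` tag.
#' @param pass_only keep only FILTER PASS/"." records.
#' @return a `variant_set`: data frame with one row per kept
#'   (record, haplotype) call, 0-based positions, minimal alleles, type,
#'   length, phase set and provenance counters in `attr(, "counters")`.
#' @export
load_variants <- function(x, ref, sample = NULL, mask = NULL,
                          max_size = 5000L, contig_filter = NULL,
                          source = "query", pass_only = FALSE) {
  ref <- read_reference(ref)
  if (is.character(x) && length(x) == 1L) {
    vc <- vcfR::read.vcfR(x, verbose = FALSE)
    fix <- vc@fix
    gt <- vc@gt
    if (nrow(fix) > 0L) {
      samples <- colnames(gt)[-1L]
      if (is.null(sample)) {
        if (length(samples) != 1L)
          stop("VCF has ", length(samples), " samples; specify one of: ",
               paste(samples, collapse = ", "))
        sample <- samples[1L]
      }
      if (!sample %in% samples) stop("sample '", sample, "' absent from VCF")
      fmt <- gt[, "FORMAT"]
      sdat <- gt[, sample]
      rec <- data.frame(contig = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        filter = fix[, "FILTER"],
                        stringsAsFactors = FALSE)
      keys <- strsplit(fmt, ":")
      vals <- strsplit(sdat, ":")
      rec$gt <- mapply(function(k, v) {
        i <- match("GT", k); if (is.na(i) || i > length(v)) NA_character_ else v[i]
      }, keys, vals, USE.NAMES = FALSE)
      rec$ps <- mapply(function(k, v) {
        i <- match("PS", k)
        if (is.na(i) || i > length(v)) NA_integer_
        else suppressWarnings(as.integer(v[i]))
      }, keys, vals, USE.NAMES = FALSE)
    } else {
      rec <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        filter = character(), gt = character(),
                        ps = integer(), stringsAsFactors = FALSE)
    }
  } else {
    rec <- as.data.frame(x, stringsAsFactors = FALSE)
    if (is.null(rec$ps)) rec$ps <- rep(NA_integer_, nrow(rec))
    if (is.null(rec$filter)) rec$filter <- rep(".", nrow(rec))
    rec$pos <- as.integer(rec$pos)
  }

  cnt <- c(records_read = nrow(rec), records_split = 0L, calls = 0L,
           kept = 0L, skipped_symbolic = 0L, skipped_spanning = 0L,
           skipped_missing_gt = 0L, half_calls = 0L, filtered_size = 0L,
           masked_out = 0L, skipped_overlap = 0L, skipped_duplicate = 0L,
           filtered_pass = 0L, contig_filtered = 0L)

  if (!is.null(contig_filter) && nrow(rec) > 0L) {
    drop <- !(rec$contig %in% contig_filter)
    cnt["contig_filtered"] <- sum(drop)
    rec <- rec[!drop, , drop = FALSE]
  }
  if (pass_only && nrow(rec) > 0L) {
    drop <- !(rec$filter %in% c("PASS", ".", NA))
    cnt["filtered_pass"] <- sum(drop)
    rec <- rec[!drop, , drop = FALSE]
  }

  out <- vector("list", nrow(rec))
  warn_half <- FALSE
  for (r in seq_len(nrow(rec))) {
    contig <- rec$contig[r]
    if (!contig %in% names(ref$seq))
      stop("contig '", contig, "' absent from reference")
    alts <- strsplit(rec$alt[r], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L) cnt["records_split"] <- cnt["records_split"] + 1L
    al <- parse_gt(rec$gt[r])
    if (is.null(al)) {
      cnt["skipped_missing_gt"] <- cnt["skipped_missing_gt"] + 1L
      next
    }
    if (anyNA(al)) {
      cnt["half_calls"] <- cnt["half_calls"] + 1L
      warn_half <- TRUE
      al[is.na(al)] <- 0L
    }
    refa <- rec$ref[r]
    ref_here <- substr(ref$seq[[contig]], rec$pos[r], rec$pos[r] + nchar(refa) - 1L)
    if (!identical(toupper(refa), ref_here))
      stop("REF mismatch at ", contig, ":", rec$pos[r], " (VCF '", refa,
           "' vs reference '", ref_here, "')")
    rows <- list()
    for (h in 1:2) {
      a <- al[h]
      if (a == 0L) next
      cnt["calls"] <- cnt["calls"] + 1L
      alta <- alts[a]
      if (is.na(alta)) {
        cnt["skipped_missing_gt"] <- cnt["skipped_missing_gt"] + 1L
        next
      }
      if (alta == "*") { cnt["skipped_spanning"] <- cnt["skipped_spanning"] + 1L; next }
      if (grepl("^<.*>$", alta) ||
          grepl("[\\[\\]]", alta) || alta %in% c(".", "")) {
        cnt["skipped_symbolic"] <- cnt["skipped_symbolic"] + 1L
        next
      }
      if (nchar(refa) > max_size || nchar(alta) > max_size) {
        cnt["filtered_size"] <- cnt["filtered_size"] + 1L
        next
      }
      tr <- trim_alleles(rec$pos[r], toupper(refa), toupper(alta))
      if (tr$ref == tr$alt) { cnt["skipped_symbolic"] <- cnt["skipped_symbolic"] + 1L; next }
      cl <- classify_variant(tr$ref, tr$alt)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, pos = tr$pos - 1L, ref = tr$ref, alt = tr$alt,
        hap = h, ps = rec$ps[r], type = cl$type, len = cl$len,
        rec = r, orig_pos = rec$pos[r], orig_ref = refa, orig_alt = rec$alt[r],
        orig_gt = rec$gt[r], stringsAsFactors = FALSE)
    }
    if (length(rows)) out[[r]] <- do.call(rbind, rows)
  }
  if (warn_half)
    warning("half-called/haploid genotypes present; missing haplotype treated as reference")
  v <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(v))
    v <- data.frame(contig = character(), pos = integer(), ref = character(),
                    alt = character(), hap = integer(), ps = integer(),
                    type = character(), len = integer(), rec = integer(),
                    orig_pos = integer(), orig_ref = character(),
                    orig_alt = character(), orig_gt = character(),
                    stringsAsFactors = FALSE)

  # region mask on reference footprints
  if (!is.null(mask) && nrow(v) > 0L) {
    mask <- read_regions(mask)
    keep <- logical(nrow(v))
    for (contig in unique(v$contig)) {
      i <- which(v$contig == contig)
      keep[i] <- mask_overlaps(mask, contig, v$pos[i], v$pos[i] + nchar(v$ref[i]))
    }
    cnt["masked_out"] <- sum(!keep)
    v <- v[keep, , drop = FALSE]
  }

  # sort and resolve same-haplotype overlaps/duplicates
  if (nrow(v) > 0L) {
    v <- v[order(v$contig, v$hap, v$pos, v$rec), , drop = FALSE]
    keep <- rep(TRUE, nrow(v))
    for (key in split(seq_len(nrow(v)), paste(v$contig, v$hap))) {
      prev_end <- -1L; prev_sig <- ""
      for (i in key) {
        sig <- paste(v$pos[i], v$ref[i], v$alt[i])
        if (identical(sig, prev_sig)) {
          keep[i] <- FALSE
          cnt["skipped_duplicate"] <- cnt["skipped_duplicate"] + 1L
          next
        }
        if (v$pos[i] < prev_end) {
          keep[i] <- FALSE
          cnt["skipped_overlap"] <- cnt["skipped_overlap"] + 1L
          next
        }
        prev_end <- v$pos[i] + nchar(v$ref[i])
        prev_sig <- sig
      }
    }
    if (any(!keep)) {
      warning(sum(!keep), " same-haplotype overlapping/duplicate record(s) skipped")
      v <- v[keep, , drop = FALSE]
    }
    v <- v[order(v$contig, v$pos, v$hap), , drop = FALSE]
    rownames(v) <- NULL
  }
  cnt["kept"] <- nrow(v)
  structure(v, counters = cnt, source = source,
            class = c("variant_set", "data.frame"))
}

# subset a variant_set keeping attributes
subset_variant_set <- function(vs, keep) {
  out <- vs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counters") <- attr(vs, "counters")
  attr(out, "source") <- attr(vs, "source")
  class(out) <- class(vs)
  out
}

#' Write records to a plain-text VCF
#'
#' Minimal single-sample VCF 4.2 writer used for simulated fixtures and
#' annotated outputs. Original POS/REF/ALT/GT are written unchanged.
#'
#' @param records data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `gt`, and optional `ps`, `bd`, `bc`.
#' @param path output path.
#' @param sample sample name for the header.
#' @param contig_lens optional named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample = "SAMPLE", contig_lens = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "##FORMAT=<ID=BD,Number=1,Type=String,Description=\"Benchmarking decision (per haplotype)\">",
    "##FORMAT=<ID=BC,Number=1,Type=String,Description=\"Benchmarking credit in [0,1] (per haplotype)\">"),
    con)
  if (!is.null(contig_lens))
    writeLines(paste0("##contig=<ID=", names(contig_lens), ",length=",
                      contig_lens, ">"), con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample, sep = "\t"), con)
  if (nrow(records) > 0L) {
    records <- records[order(records$contig, records$pos), , drop = FALSE]
    fmt <- "GT"
    val <- records$gt
    if (!is.null(records$ps)) {
      fmt <- paste0(fmt, ":PS")
      val <- paste0(val, ":", ifelse(is.na(records$ps), ".", records$ps))
    }
    if (!is.null(records$bd)) {
      fmt <- paste0(fmt, ":BD:BC")
      val <- paste0(val, ":", records$bd, ":", records$bc)
    }
    writeLines(paste(records$contig, records$pos, ".", records$ref,
                     records$alt, ".", ".", ".", fmt, val, sep = "\t"), con)
  }
  invisible(path)
}

#' Write regions to a BED file
#'
#' @param regions data frame with `contig`, `start`, `end` (0-based
#'   half-open) or a `region_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (inherits(regions, "region_mask")) {
    regions <- do.call(rbind, lapply(names(regions), function(ct)
      data.frame(contig = ct, start = regions[[ct]][, "start"],
                 end = regions[[ct]][, "end"], stringsAsFactors = FALSE)))
  }
  write.table(regions[, c("contig", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
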