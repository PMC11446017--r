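#' Alignment penalties
#'
#' Scoring parameters for affine-gap alignment: matches are free, a mismatch
#' costs `mismatch`, and a gap of length k costs `gap_open + k * gap_extend`.
#' These penalties drive cluster cost and reach computation; supercluster
#' evaluation itself uses unit-cost edit distance, since benchmarking credit
#' is defined as a fractional reduction in edit distance.
#'
#' @param mismatch positive integer substitution cost.
#' @param gap_open non-negative integer gap opening cost.
#' @param gap_extend positive integer per-base gap extension cost.
#' @return a named integer vector of class `align_penalties`.
#' @examples
#' align_penalties()
#' align_penalties(mismatch = 5, gap_open = 1, gap_extend = 1)
#' @export
align_penalties <- function(mismatch = 3L, gap_open = 2L, gap_extend = 1L) {
  mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (is.na(mismatch) || mismatch <= 0L) stop("mismatch must be a positive integer")
  if (is.na(gap_open) || gap_open < 0L) stop("gap_open must be non-negative")
  if (is.na(gap_extend) || gap_extend <= 0L) stop("gap_extend must be positive")
  structure(c(mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_penalties")
}

#' Benchmarking run configuration
#'
#' Collects every tunable of the benchmarking pipeline with its default.
#' Defaults follow the conventions of alignment-based variant benchmarking:
#' a variant group is a true positive when its credit (fractional reduction
#' in edit distance) is at least `credit_threshold`; a supercluster is
#' considered phased only when one phasing reduces edit distance by at least
#' `phasing_threshold` relative to the other; insertions and deletions of
#' `sv_threshold` bases or more are structural variants; records whose REF
#' or ALT exceeds `largest` bases are dropped before evaluation.
#'
#' @param credit_threshold minimum credit for a true positive, in \[0,1\]
#'   (inclusive). Default 0.7.
#' @param phasing_threshold minimum relative edit-distance reduction for a
#'   supercluster to count as phased, in \[0,1\] (inclusive). Default 0.6.
#' @param sv_threshold size boundary (bases) between INDELs and SVs.
#'   Default 50.
#' @param largest drop records with REF or ALT longer than this many bases.
#'   Default 5000.
#' @param max_eval_size optional additional ceiling on variant length
#'   (|len(ALT) - len(REF)|); variants larger than this are dropped.
#' @param cluster clustering mode: `"biwfa"` (reach-based, default) or
#'   `"gap"`.
#' @param gap_n gap size in bases for `cluster = "gap"`. Default 10.
#' @param penalties an [align_penalties()] object.
#' @param flank supercluster window padding in bases. Default 8.
#' @param size_bins bin edges (variant length, bases) for stratified
#'   reporting. Default `c(1, 50, 500, 5000)`.
#' @param max_cluster_span clusters growing beyond this span (bases) are
#'   frozen with a warning. Default 10000.
#' @param distance if `TRUE`, report total edit distance per supercluster.
#' @param realign_query,realign_truth if `TRUE`, re-emit the corresponding
#'   variant set from alignment cigars before evaluation (representation is
#'   rewritten; off by default).
#' @param pass_only if `TRUE`, keep only records with FILTER PASS or ".".
#' @param threads accepted for interface compatibility; results are
#'   independent of its value.
#' @param verbose emit per-stage progress messages.
#' @return a list of class `benchmark_config`.
#' @examples
#' cfg <- benchmark_config(credit_threshold = 0.7, cluster = "gap", gap_n = 10)
#' @export
benchmark_config <- function(credit_threshold = 0.7,
                             phasing_threshold = 0.6,
                             sv_threshold = 50L,
                             largest = 5000L,
                             max_eval_size = NULL,
                             cluster = c("biwfa", "gap"),
                             gap_n = 10L,
                             penalties = align_penalties(),
                             flank = 8L,
                             size_bins = c(1L, 50L, 500L, 5000L),
                             max_cluster_span = 10000L,
                             distance = FALSE,
                             realign_query = FALSE,
                             realign_truth = FALSE,
                             pass_only = FALSE,
                             threads = 1L,
                             verbose = FALSE) {
  cluster <- match.arg(cluster)
  if (credit_threshold < 0 || credit_threshold > 1)
    stop("credit_threshold must be in [0, 1]")
  if (phasing_threshold < 0 || phasing_threshold > 1)
    stop("phasing_threshold must be in [0, 1]")
  sv_threshold <- as.integer(sv_threshold)
  largest <- as.integer(largest)
  if (sv_threshold < 1L) stop("sv_threshold must be >= 1")
  if (largest < sv_threshold) stop("largest must be >= sv_threshold")
  gap_n <- as.integer(gap_n)
  if (cluster == "gap" && gap_n <= 0L) stop("gap_n must be positive")
  if (!inherits(penalties, "align_penalties")) penalties <- do.call(align_penalties, as.list(penalties))
  structure(list(
    credit_threshold = credit_threshold,
    phasing_threshold = phasing_threshold,
    sv_threshold = sv_threshold,
    largest = largest,
    max_eval_size = if (is.null(max_eval_size)) NULL else as.integer(max_eval_size),
    cluster = cluster,
    gap_n = gap_n,
    penalties = penalties,
    flank = as.integer(flank),
    size_bins = as.integer(size_bins),
    max_cluster_span = as.integer(max_cluster_span),
    distance = isTRUE(distance),
    realign_query = isTRUE(realign_query),
    realign_truth = isTRUE(realign_truth),
    pass_only = isTRUE(pass_only),
    threads = as.integer(threads),
    verbose = isTRUE(verbose)
  ), class = "benchmark_config")
}
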