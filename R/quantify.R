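#' Sample-level quality control
#'
#' A sample is flagged when its intergenic-to-coding read ratio exceeds 10%
#' (strictly): a high ratio indicates DNA contamination or degraded RNA and
#' makes intron-retention signals unreliable. Flagged samples are excluded
#' from every downstream cohort.
#'
#' @param summary An `alignment_summary`.
#' @param max_ratio Warning threshold on intergenic/coding reads (default
#'   0.10; a ratio exactly at the threshold passes).
#' @return `"pass"` or `"warn"`.
#' @export
sample_qc <- function(summary, max_ratio = 0.10) {
  if (is.null(summary$coding_reads) || summary$coding_reads == 0) {
    stop_fmt("sample %s: coding_reads must be > 0",
             summary$sample_id %||% "?")
  }
  ratio <- summary$intergenic_reads / summary$coding_reads
  if (ratio > max_ratio) "warn" else "pass"
}

#' Compute an intron's IRratio with its decision rules
#'
#' The retention level of an intron in one sample is
#' `IRratio = m / (m + junction_reads)` with `m` the median per-base read
#' depth across the intron. The raw ratio is only trusted when the evidence
#' supports a call:
#' \itemize{
#'   \item fewer than 4 junction (split) reads: the spliced isoform is not
#'     demonstrably expressed — state `missing`;
#'   \item intron coverage (fraction of bases with depth >= 1) below 20%:
#'     the intron is confidently spliced out — state `zero`, IRratio 0;
#'   \item coverage above 70% and median depth above 3: the intron is
#'     confidently (partly) retained — state `value`, IRratio kept;
#'   \item anything in between is undecidable — state `missing`.
#' }
#' All comparisons are strict, mirroring the wording of the rules
#' ("at least 4", "less than 20%", "above 70%", "above 3").
#'
#' @param depth_profile Integer vector of per-base read depths across the
#'   intron.
#' @param junction_reads Split-read count across the intron's flanking
#'   exon-exon junction.
#' @return An `ir_value`: list with `state` (`"value"`, `"zero"`,
#'   `"missing"`), `irratio` (`NA` when missing), `median_depth`,
#'   `coverage_fraction`, `junction_reads`.
#' @export
compute_irratio <- function(depth_profile, junction_reads) {
  if (length(depth_profile) == 0L) stop_fmt("empty depth profile")
  m <- stats::median(depth_profile)
  cov <- mean(depth_profile >= 1)
  x <- ir_decision(m, cov, junction_reads)
  state <- if (is.na(x)) {
    "missing"
  } else if (cov < 0.20) {
    "zero"
  } else {
    "value"
  }
  structure(list(state = state, irratio = x, median_depth = m,
                 coverage_fraction = cov,
                 junction_reads = as.integer(junction_reads)),
            class = "ir_value")
}

# The decision kernel: NA = missing, 0 = confidently spliced, positive =
# trusted IRratio. Vectorized over (m, cov, j).
ir_decision <- function(m, cov, j) {
  r <- ifelse(m + j > 0, m / (m + j), NA_real_)
  out <- rep(NA_real_, length(r))
  ok <- j >= 4
  out[ok & cov < 0.20] <- 0
  keep <- ok & cov > 0.70 & m > 3
  out[keep] <- r[keep]
  out
}

#' @export
print.ir_value <- function(x, ...) {
  cat(sprintf("ir_value[%s]: irratio=%s m=%.1f cov=%.2f junctions=%d\n",
              x$state, format(x$irratio), x$median_depth,
              x$coverage_fraction, x$junction_reads))
  invisible(x)
}

#' Build an IRratio matrix from alignment summaries
#'
#' Applies sample QC (flagged samples are dropped), excludes introns that
#' overlap known exons, and evaluates the IRratio decision rules for every
#' remaining (intron, sample) cell. The matrix encodes the three cell
#' states as: `NA` = missing (undecidable), `0` = confidently spliced,
#' positive = trusted IRratio (a trusted value is always > 0 because it
#' requires median depth > 3).
#'
#' @param summaries List of `alignment_summary` objects.
#' @param introns Intron table from [extract_introns()].
#' @param samples Optional sample metadata data frame (`sample_id`,
#'   `condition`, `pair_id`, `stranded`, `cancer_type`); defaults are taken
#'   from the summaries themselves.
#' @param exclude_exon_overlap Drop introns flagged `known_exon_overlap`
#'   (default `TRUE`).
#' @return An `ir_matrix`: list with `ir` (numeric introns x samples
#'   matrix) and `samples` (metadata for the retained samples; QC-flagged
#'   samples are absent).
#' @export
build_ir_matrix <- function(summaries, introns, samples = NULL,
                            exclude_exon_overlap = TRUE) {
  stopifnot(length(summaries) > 0L)
  keep_in <- if (exclude_exon_overlap) !introns$known_exon_overlap
             else rep(TRUE, nrow(introns))
  introns <- introns[keep_in, , drop = FALSE]
  if (nrow(introns) == 0L) stop_fmt("no introns left after exon-overlap filter")

  ids <- vapply(summaries, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop_fmt("duplicate sample_id in summaries")
  names(summaries) <- ids
  qc <- vapply(summaries, sample_qc, character(1))
  summaries <- summaries[order(ids)]
  summaries <- summaries[qc[order(ids)] == "pass"]
  if (length(summaries) == 0L) stop_fmt("all samples failed QC")

  mat <- matrix(NA_real_, nrow = nrow(introns), ncol = length(summaries),
                dimnames = list(introns$intron_id, names(summaries)))
  for (s in names(summaries)) {
    sm <- summaries[[s]]
    idx <- match(introns$intron_id, sm$intron_id)
    if (anyNA(idx)) {
      stop_fmt("sample %s lacks intron %s", s,
               introns$intron_id[which(is.na(idx))[1L]])
    }
    m <- vapply(sm$depth_profiles[idx], stats::median, numeric(1))
    cov <- vapply(sm$depth_profiles[idx], function(p) mean(p >= 1),
                  numeric(1))
    mat[, s] <- ir_decision(m, cov, sm$junction_reads[idx])
  }

  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = names(summaries),
      condition = NA_character_, pair_id = NA_character_,
      stranded = vapply(summaries, function(s) isTRUE(s$stranded),
                        logical(1)),
      cancer_type = NA_character_, stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(names(summaries), samples$sample_id), ,
                       drop = FALSE]
    if (anyNA(samples$sample_id)) {
      stop_fmt("sample metadata missing for some summaries")
    }
  }
  rownames(samples) <- NULL
  structure(list(ir = mat, samples = samples), class = "ir_matrix")
}

#' @export
print.ir_matrix <- function(x, ...) {
  st <- table(factor(ifelse(is.na(x$ir), "missing",
                            ifelse(x$ir == 0, "zero", "value")),
                     levels = c("value", "zero", "missing")))
  cat(sprintf("ir_matrix: %d introns x %d samples (%d value, %d zero, %d missing cells)\n",
              nrow(x$ir), ncol(x$ir), st[["value"]], st[["zero"]],
              st[["missing"]]))
  invisible(x)
}

#' Count retained introns in a sample
#'
#' An intron counts as retained when its cell holds a trusted IRratio
#' strictly above the threshold (default 0.1); spliced-zero and missing
#' cells never count.
#'
#' @param x Numeric vector of IRratio cells (one sample's column).
#' @param threshold Retention threshold (strict).
#' @return Integer count.
#' @export
count_retained <- function(x, threshold = 0.1) {
  sum(!is.na(x) & x > threshold)
}

#' Build the stranded-sample whitelist
#'
#' Unstranded libraries cannot assign reads to a strand, so apparent
#' retention can be antisense bleed-through. Introns whose maximum trusted
#' IRratio across strand-specific samples exceeds 0.08 (strictly) were
#' retained in at least one library where strand is unambiguous; the
#' whitelist restricts differential and prognostic calls to those introns.
#'
#' @param mat An `ir_matrix` whose samples include stranded libraries, or a
#'   plain numeric matrix (then all columns are assumed stranded).
#' @param threshold Whitelist threshold (strict; default 0.08).
#' @return Character vector of whitelisted intron ids.
#' @export
build_whitelist <- function(mat, threshold = 0.08) {
  if (inherits(mat, "ir_matrix")) {
    keep <- which(mat$samples$stranded)
    if (length(keep) == 0L) stop_fmt("no stranded samples in matrix")
    m <- mat$ir[, mat$samples$sample_id[keep], drop = FALSE]
  } else {
    m <- mat
    if (is.null(dim(m)) || ncol(m) == 0L) stop_fmt("no stranded samples")
  }
  mx <- apply(m, 1L, function(r) if (all(is.na(r))) NA_real_
              else max(r, na.rm = TRUE))
  rownames(m)[!is.na(mx) & mx > threshold]
}
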