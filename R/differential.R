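#' Call differentially retained introns between paired tumor/normal samples
#'
#' For each whitelisted intron, per-pair tumor-minus-normal IRratio
#' differences are tested with the Wilcoxon signed-rank test ("paired
#' Wilcoxon"): the exact null distribution is used below 25 usable pairs
#' (falling back to the approximation when ties make the exact distribution
#' unavailable) and the normal approximation with continuity correction
#' otherwise. A pair contributes only when both sides are decidable; a
#' confidently spliced cell participates as 0.0, a missing cell drops the
#' pair for that intron. An intron is reported as a DIR when `p < alpha`
#' and the difference of median IRratios exceeds `min_delta` in absolute
#' value (both strict). No multiple-testing correction is applied by
#' default; set `adjust = "BH"` for Benjamini-Hochberg on the p-values
#' before the alpha filter.
#'
#' @param mat An `ir_matrix` whose `samples` metadata carries `condition`
#'   ("tumor"/"normal") and `pair_id`.
#' @param whitelist Character vector of intron ids eligible for testing
#'   (see [build_whitelist()]); `NULL` tests every intron in the matrix.
#' @param alpha Significance threshold (default 0.05, strict).
#' @param min_delta Effect-size threshold on |median tumor - median normal|
#'   (default 0.1, strict).
#' @param min_pairs Minimum number of cohort pairs required (default 15,
#'   strict: the cohort must have more than `min_pairs` pairs).
#' @param all_results Return every tested intron (with a `is_dir` flag)
#'   instead of DIRs only.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param cancer_type Label copied into the output.
#' @return data frame: `intron_id`, `cancer_type`, `p_value`,
#'   `median_tumor`, `median_normal`, `delta`, `direction` ("up"/"down"),
#'   `category`, `n_pairs` (usable pairs for that intron), plus `is_dir`
#'   when `all_results = TRUE`. Introns with fewer than 2 usable pairs are
#'   skipped and listed in the `skipped` attribute.
#' @export
call_dirs <- function(mat, whitelist = NULL, alpha = 0.05, min_delta = 0.1,
                      min_pairs = 15L, all_results = FALSE,
                      adjust = c("none", "BH"), cancer_type = "NA") {
  stopifnot(inherits(mat, "ir_matrix"))
  adjust <- match.arg(adjust)
  smp <- mat$samples
  paired <- smp[!is.na(smp$pair_id), , drop = FALSE]
  pair_ids <- sort(unique(paired$pair_id))
  tum <- paired$sample_id[match(paste(pair_ids, "tumor"),
                                paste(paired$pair_id, paired$condition))]
  nor <- paired$sample_id[match(paste(pair_ids, "normal"),
                                paste(paired$pair_id, paired$condition))]
  ok <- !is.na(tum) & !is.na(nor)
  tum <- tum[ok]; nor <- nor[ok]
  if (length(tum) <= min_pairs) {
    stop_fmt("cohort has %d complete pairs; more than %d required",
             length(tum), min_pairs)
  }
  ids <- if (is.null(whitelist)) rownames(mat$ir)
         else intersect(rownames(mat$ir), whitelist)
  tmat <- mat$ir[ids, tum, drop = FALSE]
  nmat <- mat$ir[ids, nor, drop = FALSE]

  rows <- vector("list", length(ids))
  skipped <- character(0)
  for (i in seq_along(ids)) {
    tv <- tmat[i, ]; nv <- nmat[i, ]
    use <- !is.na(tv) & !is.na(nv)
    if (sum(use) < 2L) {
      skipped <- c(skipped, ids[i])
      next
    }
    tv <- tv[use]; nv <- nv[use]
    p <- paired_wilcox_p(tv, nv)
    mt <- stats::median(tv); mn <- stats::median(nv)
    rows[[i]] <- data.frame(
      intron_id = ids[i], cancer_type = cancer_type, p_value = p,
      median_tumor = mt, median_normal = mn, delta = mt - mn,
      n_pairs = sum(use), stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message(sprintf("call_dirs: skipped %d introns with < 2 usable pairs",
                    length(skipped)))
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L) {
    res <- empty_dir_table()
    attr(res, "skipped") <- skipped
    return(res)
  }
  if (adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$direction <- ifelse(res$delta > 0, "up", "down")
  res$category <- categorize_dir(res$median_tumor, res$median_normal)
  res$is_dir <- !is.na(res$p_value) & res$p_value < alpha &
    abs(res$delta) > min_delta
  if (!all_results) {
    res <- res[res$is_dir, , drop = FALSE]
    res$is_dir <- NULL
  }
  res <- res[, c("intron_id", "cancer_type", "p_value", "median_tumor",
                 "median_normal", "delta", "direction", "category",
                 "n_pairs", intersect("is_dir", names(res)))]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

empty_dir_table <- function() {
  data.frame(intron_id = character(), cancer_type = character(),
             p_value = numeric(), median_tumor = numeric(),
             median_normal = numeric(), delta = numeric(),
             direction = character(), category = character(),
             n_pairs = integer(), stringsAsFactors = FALSE)
}

# Signed-rank p-value on paired vectors; exact below 25 pairs when there
# are no ties or zero differences, approximate with continuity correction
# otherwise. All-zero differences carry no evidence: p = 1.
paired_wilcox_p <- function(tv, nv) {
  d <- tv - nv
  if (all(d == 0)) return(1)
  exact <- sum(d != 0) < 25L
  suppressWarnings(
    stats::wilcox.test(tv, nv, paired = TRUE, exact = exact,
                       correct = TRUE)$p.value)
}

#' Categorize a differential IR event
#'
#' A DIR is cancer-associated when the intron is confidently spliced in
#' normal samples (median IRratio exactly 0) yet retained in tumors
#' (median IRratio > 0.1); normal-associated in the mirror case; otherwise
#' it is retained on both sides at an altered level.
#'
#' @param median_tumor,median_normal Median IRratios (vectorized).
#' @param retained_threshold Retention threshold on the retained side
#'   (default 0.1, strict).
#' @return Character vector: `"cancer_associated"`, `"normal_associated"`
#'   or `"altered_level"`.
#' @export
categorize_dir <- function(median_tumor, median_normal,
                           retained_threshold = 0.1) {
  ifelse(median_normal == 0 & median_tumor > retained_threshold,
         "cancer_associated",
         ifelse(median_tumor == 0 & median_normal > retained_threshold,
                "normal_associated", "altered_level"))
}

#' Merge per-cancer DIR tables into a pan-cancer feature set
#'
#' Takes the union of DIRs across cancers, then drops introns called in
#' both directions in different cancers (inconsistent regulation) and
#' introns whose missing rate across all samples of the pan-cancer matrix
#' exceeds `max_missing` (strict). Spliced-zero cells count as observed.
#'
#' @param dir_tables List of DIR data frames from [call_dirs()] (or one
#'   row-bound data frame with a `cancer_type` column).
#' @param mat An `ir_matrix` spanning all samples, or a numeric matrix.
#' @param max_missing Missing-rate threshold (default 0.30).
#' @return data frame: `intron_id`, `direction`, one row per kept feature,
#'   in stable (first-seen) order.
#' @export
merge_dirs_pan_cancer <- function(dir_tables, mat, max_missing = 0.30) {
  d <- if (is.data.frame(dir_tables)) dir_tables
       else do.call(rbind, dir_tables)
  if (is.null(d) || nrow(d) == 0L) {
    return(data.frame(intron_id = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  ndir <- tapply(d$direction, d$intron_id, function(x) length(unique(x)))
  consistent <- names(ndir)[ndir == 1L]
  keep <- d[!duplicated(d$intron_id) & d$intron_id %in% consistent,
            c("intron_id", "direction"), drop = FALSE]
  m <- if (inherits(mat, "ir_matrix")) mat$ir else mat
  present <- keep$intron_id %in% rownames(m)
  keep <- keep[present, , drop = FALSE]
  miss <- rowMeans(is.na(m[keep$intron_id, , drop = FALSE]))
  keep <- keep[miss <= max_missing, , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Prepare a dense matrix for embedding / modeling
#'
#' Keeps introns whose missing rate is below `max_missing` (strict) and
#' imputes remaining missing cells with the row mean over observed cells
#' (spliced-zero cells are observations, not missing). The result has no
#' missing cells.
#'
#' @param mat An `ir_matrix` or numeric matrix (`NA` = missing).
#' @param max_missing Missing-rate threshold (default 0.30).
#' @return Dense numeric matrix (introns x samples).
#' @export
matrix_prep <- function(mat, max_missing = 0.30) {
  m <- if (inherits(mat, "ir_matrix")) mat$ir else mat
  miss <- rowMeans(is.na(m))
  m <- m[miss < max_missing, , drop = FALSE]
  if (nrow(m) == 0L) stop_fmt("no introns pass the missing-rate filter")
  imputed <- t(apply(m, 1L, function(r) {
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    r
  }))
  dimnames(imputed) <- dimnames(m)
  imputed
}

#' Correlate IR change with expression change
#'
#' Spearman rank correlation between per-gene differential-IR effect sizes
#' (delta of median IRratios) and log2 expression fold changes from an
#' external differential-expression table. Ties are handled by midranks;
#' with ties present the p-value comes from the t approximation rather
#' than the exact permutation distribution.
#'
#' @param delta_table data frame with `gene_id` and `delta`.
#' @param de_table data frame with `gene_id` and `log2fc`.
#' @return List with `rho`, `p` and `n` (genes in common).
#' @export
ir_expression_correlation <- function(delta_table, de_table) {
  merged <- merge(delta_table[, c("gene_id", "delta")],
                  de_table[, c("gene_id", "log2fc")], by = "gene_id")
  if (nrow(merged) < 3L) stop_fmt("fewer than 3 genes in common")
  if (stats::sd(merged$delta) == 0 || stats::sd(merged$log2fc) == 0) {
    stop_fmt("correlation undefined: constant input vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(merged$delta, merged$log2fc, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(merged))
}

#' Flag DIRs with somatic mutations near their splice sites
#'
#' A DIR is flagged for a sample when any variant lies within `window`
#' base pairs (inclusive, on either the intronic or exonic side) of either
#' splice site of the intron.
#'
#' @param dirs DIR table with `intron_id` (see [call_dirs()]).
#' @param introns Intron table supplying coordinates.
#' @param variants data frame with `sample_id`, `chrom`, `pos` (1-based
#'   position of the variant).
#' @param window Distance threshold in bp (default 20, inclusive).
#' @return data frame of flags: `intron_id`, `sample_id`, `pos`,
#'   `distance` (bp to the nearest splice site; 0 = at the site).
#' @export
mutation_proximity <- function(dirs, introns, variants, window = 20L) {
  idx <- match(dirs$intron_id, introns$intron_id)
  if (anyNA(idx)) stop_fmt("DIR intron missing from intron table")
  out <- list()
  for (k in seq_along(idx)) {
    it <- introns[idx[k], ]
    # 1-based positions of the first and last intronic base
    site5 <- it$start + 1L
    site3 <- it$end
    v <- variants[variants$chrom == it$chrom, , drop = FALSE]
    if (nrow(v) == 0L) next
    dist <- pmin(abs(v$pos - site5), abs(v$pos - site3))
    hit <- dist <= window
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        intron_id = it$intron_id, sample_id = v$sample_id[hit],
        pos = v$pos[hit], distance = dist[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(intron_id = character(), sample_id = character(),
                      pos = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
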