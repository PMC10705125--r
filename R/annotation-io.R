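#' Read a GTF gene annotation into gene models
#'
#' Parses `exon` (and, when present, `CDS`) features from an Ensembl/GENCODE
#' style GTF file and assembles per-transcript gene models. GTF coordinates
#' are 1-based inclusive; internally all coordinates are converted to 0-based
#' half-open so that interval arithmetic (lengths, overlaps, BED output) is
#' unambiguous.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{transcripts}{data frame with one row per transcript:
#'       `transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`,
#'       `cds_start`, `cds_end`. CDS bounds are in spliced-transcript
#'       coordinates (0-based half-open, 5' to 3'); `NA` when the transcript
#'       has no CDS features.}
#'     \item{exons}{data frame with one row per exon: `transcript_id`,
#'       `chrom`, `strand`, `start`, `end` (genomic 0-based half-open) and
#'       `ordinal` (1-based, 5' to 3' in transcript orientation).}
#'   }
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_fmt("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lnos <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_fmt("GTF file has no feature lines: %s", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- lnos[which(nf != 9L)[1L]]
    stop_fmt("malformed GTF line %d: expected 9 tab-separated fields", bad)
  }
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  type <- mat[, 3L]
  sel <- type %in% c("exon", "CDS")
  if (!any(sel)) stop_fmt("no exon features found in %s", path)
  mat <- mat[sel, , drop = FALSE]
  lno <- lnos[sel]
  type <- mat[, 3L]

  start1 <- suppressWarnings(as.integer(mat[, 4L]))
  end1 <- suppressWarnings(as.integer(mat[, 5L]))
  badc <- which(is.na(start1) | is.na(end1) | start1 > end1 | start1 < 1L)
  if (length(badc)) {
    stop_fmt("malformed GTF line %d: invalid coordinates", lno[badc[1L]])
  }
  strand <- mat[, 7L]
  bads <- which(!strand %in% c("+", "-"))
  if (length(bads)) {
    stop_fmt("malformed GTF line %d: strand must be '+' or '-'", lno[bads[1L]])
  }

  attr_field <- mat[, 9L]
  gid <- gtf_attr(attr_field, "gene_id")
  tid <- gtf_attr(attr_field, "transcript_id")
  bty <- gtf_attr(attr_field, "gene_biotype")
  bty2 <- gtf_attr(attr_field, "gene_type")  # GENCODE dialect
  bty[is.na(bty)] <- bty2[is.na(bty)]
  bada <- which(is.na(gid) | is.na(tid))
  if (length(bada)) {
    stop_fmt("malformed GTF line %d: missing gene_id/transcript_id attribute",
             lno[bada[1L]])
  }

  feat <- data.frame(
    chrom = mat[, 1L], type = type,
    start = start1 - 1L, end = end1,  # 0-based half-open
    strand = strand, gene_id = gid, transcript_id = tid,
    biotype = ifelse(is.na(bty), "unknown", bty),
    stringsAsFactors = FALSE
  )

  ex <- feat[feat$type == "exon", , drop = FALSE]
  cds <- feat[feat$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0L) stop_fmt("no exon features found in %s", path)

  # Canonical deterministic ordering of transcripts.
  tx_first <- ex[!duplicated(ex$transcript_id), , drop = FALSE]
  tx_start <- tapply(ex$start, ex$transcript_id, min)
  ord <- order(tx_first$chrom,
               tx_start[tx_first$transcript_id],
               tx_first$transcript_id)
  tx_ids <- tx_first$transcript_id[ord]

  exons_list <- vector("list", length(tx_ids))
  tx_rows <- vector("list", length(tx_ids))
  for (i in seq_along(tx_ids)) {
    t <- tx_ids[i]
    e <- ex[ex$transcript_id == t, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L) {
      stop_fmt("transcript %s: exons disagree on chromosome or strand", t)
    }
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop_fmt("transcript %s: overlapping exons", t)
    }
    minus <- e$strand[1L] == "-"
    e$ordinal <- if (minus) rev(seq_len(nrow(e))) else seq_len(nrow(e))

    cds_b <- c(NA_integer_, NA_integer_)
    ct <- cds[cds$transcript_id == t, , drop = FALSE]
    if (nrow(ct) > 0L) {
      cds_b <- cds_tx_bounds(e, ct, minus)
    }
    exons_list[[i]] <- e[, c("transcript_id", "chrom", "strand",
                             "start", "end", "ordinal")]
    tx_rows[[i]] <- data.frame(
      transcript_id = t, gene_id = e$gene_id[1L], chrom = e$chrom[1L],
      strand = e$strand[1L], biotype = e$biotype[1L],
      cds_start = cds_b[1L], cds_end = cds_b[2L],
      stringsAsFactors = FALSE
    )
  }
  out <- list(transcripts = do.call(rbind, tx_rows),
              exons = do.call(rbind, exons_list))
  rownames(out$transcripts) <- NULL
  rownames(out$exons) <- NULL
  class(out) <- "gene_models"
  out
}

# Extract a quoted or bare GTF attribute value; NA when absent.
gtf_attr <- function(attrs, key) {
  pat <- paste0(key, '[ =]+"?([^";]+)"?')
  m <- regexpr(pat, attrs, perl = TRUE)
  val <- rep(NA_character_, length(attrs))
  hit <- m > 0L
  val[hit] <- sub(pat, "\\1", regmatches(attrs, m), perl = TRUE)
  val
}

# Map genomic CDS segments into spliced-transcript coordinates and return
# c(cds_start, cds_end), 0-based half-open on the spliced transcript.
cds_tx_bounds <- function(exons_sorted, cds_rows, minus) {
  e <- exons_sorted
  widths <- e$end - e$start
  # transcript-orientation exon order
  idx <- order(e$ordinal)
  cum <- cumsum(c(0L, widths[idx]))[seq_len(nrow(e))]
  gmin <- min(cds_rows$start); gmax <- max(cds_rows$end)
  # 5'-most and 3'-most genomic CDS positions in transcript orientation
  pos5 <- if (minus) gmax - 1L else gmin         # first CDS base (genomic)
  pos3 <- if (minus) gmin else gmax - 1L         # last CDS base (genomic)
  t5 <- genomic_to_tx(pos5, e, idx, cum, minus)
  t3 <- genomic_to_tx(pos3, e, idx, cum, minus)
  if (is.na(t5) || is.na(t3)) {
    stop_fmt("transcript %s: CDS feature outside exons",
             e$transcript_id[1L])
  }
  c(t5, t3 + 1L)
}

# Transcript coordinate (0-based) of a genomic base (0-based position of the
# base itself), given exons sorted genomically, their transcript order `idx`
# and cumulative offsets `cum`.
genomic_to_tx <- function(gpos, e, idx, cum, minus) {
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (gpos >= e$start[i] && gpos < e$end[i]) {
      off <- if (minus) e$end[i] - 1L - gpos else gpos - e$start[i]
      return(cum[k] + off)
    }
  }
  NA_integer_
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

#' Extract introns from gene models
#'
#' Defines one intron per inter-exon gap per transcript, then deduplicates
#' identical genomic intervals (same chromosome, start, end and strand)
#' across transcripts, keeping ordinal and region from the first transcript
#' in canonical order. Each intron is checked for overlap against every exon
#' of every transcript in the annotation; overlapping introns are flagged
#' (`known_exon_overlap = TRUE`) and excluded from quantification downstream
#' by default.
#'
#' @param models A `gene_models` object from [read_gtf()].
#' @return data frame with one row per deduplicated intron: `intron_id`,
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end` (genomic
#'   0-based half-open), `ordinal` (1-based, 5' to 3' within the source
#'   transcript), `n_introns_in_gene`, `known_exon_overlap`, and `region`
#'   (`5UTR`, `CDS`, `3UTR`, `mixed` or `noncoding`).
#' @export
extract_introns <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  tx <- models$transcripts
  recs <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx$transcript_id[i]
    e <- ex[ex$transcript_id == t, , drop = FALSE]
    if (nrow(e) < 2L) next
    e <- e[order(e$start), , drop = FALSE]
    n_int <- nrow(e) - 1L
    gstart <- e$end[-nrow(e)]
    gend <- e$start[-1L]
    minus <- tx$strand[i] == "-"
    ordinal <- if (minus) rev(seq_len(n_int)) else seq_len(n_int)
    # spliced-transcript position of each intron's 5' boundary
    widths <- e$end - e$start
    idx <- order(e$ordinal)
    cum <- cumsum(widths[idx])
    # intron after exon with ordinal k sits at cum[k]
    p <- cum[ordinal]
    region <- intron_region(p, tx$cds_start[i], tx$cds_end[i])
    recs[[i]] <- data.frame(
      gene_id = tx$gene_id[i], transcript_id = t,
      chrom = tx$chrom[i], strand = tx$strand[i],
      start = gstart, end = gend,
      ordinal = ordinal, n_introns_in_gene = n_int,
      tx_pos = p, region = region,
      stringsAsFactors = FALSE
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    return(empty_intron_table())
  }
  introns <- do.call(rbind, recs)

  # Deduplicate identical genomic intervals; first transcript in canonical
  # order wins, but region conflicts across transcripts become "mixed".
  key <- paste(introns$chrom, introns$start, introns$end, introns$strand,
               sep = ":")
  first <- !duplicated(key)
  region_n <- tapply(introns$region, key, function(r) length(unique(r)))
  out <- introns[first, , drop = FALSE]
  out$region[region_n[key[first]] > 1L] <- "mixed"
  out$intron_id <- sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end,
                           out$strand)
  out$known_exon_overlap <- intervals_overlap_any(
    out$chrom, out$start, out$end, ex$chrom, ex$start, ex$end)
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("intron_id", "gene_id", "transcript_id", "chrom", "strand",
          "start", "end", "ordinal", "n_introns_in_gene", "tx_pos",
          "known_exon_overlap", "region")]
}

empty_intron_table <- function() {
  data.frame(intron_id = character(), gene_id = character(),
             transcript_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             ordinal = integer(), n_introns_in_gene = integer(),
             tx_pos = integer(), known_exon_overlap = logical(),
             region = character(), stringsAsFactors = FALSE)
}

# Region of an intron relative to the CDS of its own transcript, from its
# spliced-transcript boundary position p and the transcript CDS bounds.
intron_region <- function(p, cds_start, cds_end) {
  if (is.na(cds_start) || is.na(cds_end)) return(rep("noncoding", length(p)))
  ifelse(p <= cds_start, "5UTR", ifelse(p >= cds_end, "3UTR", "CDS"))
}

# For each query interval, does it overlap any subject interval on the same
# chromosome? Sorted sweep: among subjects with start < q_end, overlap exists
# iff the running max of their ends exceeds q_start.
intervals_overlap_any <- function(qc, qs, qe, sc, ss, se) {
  out <- logical(length(qs))
  for (ch in unique(qc)) {
    qi <- which(qc == ch)
    si <- which(sc == ch)
    if (length(si) == 0L) next
    o <- order(ss[si])
    s_start <- ss[si][o]
    s_endmax <- cummax(se[si][o])
    k <- findInterval(qe[qi] - 1e-9, s_start)  # subjects with start < q_end
    hit <- k > 0L
    hit[hit] <- s_endmax[k[hit]] > qs[qi][hit]
    out[qi] <- hit
  }
  out
}

#' Write introns to a BED6 file
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' are written as-is. Score column is ".".
#'
#' @param introns Intron table from [extract_introns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  bed <- data.frame(introns$chrom, introns$start, introns$end,
                    introns$intron_id, ".", introns$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read an IR matrix as TSV
#'
#' Introns as rows, samples as columns; missing values are encoded as the
#' literal string `NA` and round-trip losslessly. A zero cell means
#' "confidently spliced" and is distinct from missing.
#'
#' @param mat Numeric matrix with intron ids as rownames and sample ids as
#'   colnames (`NA` = missing state).
#' @param path File path.
#' @return `write_ir_matrix`: `path` invisibly; `read_ir_matrix`: the matrix.
#' @export
write_ir_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(intron_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_ir_matrix
#' @export
read_ir_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA", comment.char = "#")
  if (anyDuplicated(df$intron_id)) {
    stop_fmt("duplicate intron_id rows in %s", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$intron_id
  storage.mode(m) <- "double"
  m
}
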