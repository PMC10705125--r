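#' Classify introns into retention classes
#'
#' Four mutually exclusive classes: `constitutive` introns have a median
#' IRratio of 0 in tumor and normal samples across all cancers;
#' `unregulated_retained` introns are retained somewhere (a positive
#' median) but never called differential; `dir_up` / `dir_down` introns
#' appear in a DIR table with the corresponding direction.
#'
#' @param medians Numeric matrix of median IRratios, introns x groups (one
#'   column per cancer-condition combination); `NA` medians are treated as
#'   not retained.
#' @param dirs DIR table with `intron_id` and `direction` (introns called
#'   in both directions should have been removed upstream; if present,
#'   the first direction encountered wins).
#' @return Factor of class labels, one per row of `medians`.
#' @export
classify_introns <- function(medians, dirs) {
  stopifnot(is.matrix(medians), !is.null(rownames(medians)))
  dir_of <- dirs$direction[match(rownames(medians), dirs$intron_id)]
  retained <- apply(medians, 1L, function(r) any(!is.na(r) & r > 0))
  lab <- ifelse(!is.na(dir_of),
                ifelse(dir_of == "up", "dir_up", "dir_down"),
                ifelse(retained, "unregulated_retained", "constitutive"))
  factor(lab, levels = c("constitutive", "unregulated_retained",
                         "dir_up", "dir_down"))
}

#' Sequence features: GC content and intron length
#'
#' @param sequence Character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @return `gc_content`: numeric fraction of G/C bases per sequence.
#' @export
gc_content <- function(sequence) {
  s <- Biostrings::DNAStringSet(sequence)
  unname(Biostrings::letterFrequency(s, "GC", as.prob = TRUE)[, 1L])
}

#' @rdname gc_content
#' @param introns Intron table.
#' @return `intron_length`: integer lengths in bp.
#' @export
intron_length <- function(introns) {
  introns$end - introns$start
}

#' Relative position of an intron along its gene
#'
#' Percentile ranking of an intron among all introns of its gene, 5' to 3'
#' in transcript orientation: `(ordinal - 1) / (n - 1)`, so the first
#' intron maps to 0 and the last to 1. Genes with fewer than 3 introns are
#' excluded (`NA`), as a two-intron gene only admits the degenerate ranks
#' 0 and 1.
#'
#' @param ordinal 1-based intron index, 5' to 3'.
#' @param n_introns Number of introns in the gene.
#' @return Numeric fraction in `[0, 1]`, or `NA` when `n_introns < 3`.
#' @export
relative_gene_position <- function(ordinal, n_introns) {
  stopifnot(length(ordinal) == length(n_introns))
  ifelse(n_introns < 3L, NA_real_, (ordinal - 1) / (n_introns - 1))
}

#' Predict nonsense-mediated decay of an intron-retained transcript
#'
#' A retained intron in a coding transcript often introduces a premature
#' termination codon (PTC) and routes the transcript to NMD, unless an
#' escape condition applies. The rule chain is evaluated in order on the
#' retained-intron mRNA (all distances in transcript coordinates):
#' \enumerate{
#'   \item the intron lies in the 5' or 3' UTR — no NMD (`utr`);
#'   \item the intron's 5' end is fewer than 200 nt downstream of the
#'     start codon — no NMD (`near_start`);
#'   \item it is the transcript's last intron — no NMD (`last_intron`);
#'   \item translating the retained mRNA from the annotated start yields
#'     no stop before the normal stop — no NMD (`no_ptc`);
#'   \item the PTC lies within 55 nt upstream of the retained transcript's
#'     last exon-exon junction (the retained intron contributes no
#'     junction) — no NMD (`ptc_within_55`);
#'   \item otherwise — NMD (`ptc_triggers`).
#' }
#' The PTC position is the transcript coordinate of the first nucleotide
#' of the stop codon; "within 55 nt" means
#' `last_junction - ptc_position <= 55`, which also covers a PTC at or
#' downstream of the junction.
#'
#' @param models `gene_models` from [read_gtf()]; the transcript must have
#'   CDS annotation.
#' @param intron One row of the intron table (must belong to the
#'   transcript).
#' @param genome A `Biostrings::DNAStringSet` (or FASTA path) holding the
#'   genome.
#' @param transcript_id Transcript to evaluate; defaults to the intron's
#'   source transcript.
#' @return An `nmd_call`: list with `verdict` (`"NMD"`/`"no_NMD"`),
#'   `reason`, and diagnostic fields (`ptc_pos`, `last_junction`,
#'   `normal_stop`).
#' @export
predict_nmd <- function(models, intron, genome,
                        transcript_id = intron$transcript_id) {
  stopifnot(inherits(models, "gene_models"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  tx <- models$transcripts[models$transcripts$transcript_id ==
                             transcript_id, , drop = FALSE]
  if (nrow(tx) == 0L) stop_fmt("unknown transcript %s", transcript_id)
  if (is.na(tx$cds_start)) stop_fmt("transcript %s has no CDS", transcript_id)
  ex <- models$exons[models$exons$transcript_id == transcript_id, ,
                     drop = FALSE]
  ex <- ex[order(ex$ordinal), , drop = FALSE]
  minus <- tx$strand == "-"

  # locate the intron between consecutive exons of this transcript
  gap_start <- if (minus) ex$end[-1L] else ex$end[-nrow(ex)]
  gap_end <- if (minus) ex$start[-nrow(ex)] else ex$start[-1L]
  hit <- which(gap_start == intron$start & gap_end == intron$end)
  if (length(hit) != 1L) {
    stop_fmt("intron %s not found in transcript %s", intron$intron_id,
             transcript_id)
  }
  widths <- ex$end - ex$start
  cum <- cumsum(widths)
  p <- cum[hit]                       # spliced 5'-boundary of the intron
  L <- intron$end - intron$start
  n_introns <- nrow(ex) - 1L
  cds_start <- tx$cds_start

  # spliced mRNA and its normal stop (first in-frame stop from the start)
  exon_seqs <- fetch_seq(genome, tx$chrom, ex$start, ex$end, minus)
  spliced <- paste(exon_seqs, collapse = "")
  normal_stop <- first_inframe_stop(spliced, cds_start)
  if (is.na(normal_stop)) {
    stop_fmt("transcript %s: no stop codon in annotated frame",
             transcript_id)
  }

  mk <- function(verdict, reason, ptc = NA_integer_, lj = NA_integer_) {
    structure(list(verdict = verdict, reason = reason, ptc_pos = ptc,
                   last_junction = lj, normal_stop = normal_stop,
                   intron_tx_pos = p),
              class = "nmd_call")
  }

  if (p <= cds_start || p >= normal_stop + 3L) return(mk("no_NMD", "utr"))
  if (p - cds_start < 200L) return(mk("no_NMD", "near_start"))
  if (hit == n_introns) return(mk("no_NMD", "last_intron"))

  intron_seq <- fetch_seq(genome, tx$chrom, intron$start, intron$end, minus)
  retained <- paste0(substr(spliced, 1L, p), intron_seq,
                     substr(spliced, p + 1L, nchar(spliced)))
  q <- first_inframe_stop(retained, cds_start)
  if (is.na(q) || q >= normal_stop + L) return(mk("no_NMD", "no_ptc"))

  junctions <- cum[-length(cum)]           # spliced junction positions
  junctions <- junctions[junctions != p]   # retained intron: no junction
  junctions <- ifelse(junctions > p, junctions + L, junctions)
  last_jx <- max(junctions)
  if (last_jx - q <= 55L) return(mk("no_NMD", "ptc_within_55", q, last_jx))
  mk("NMD", "ptc_triggers", q, last_jx)
}

# Transcript-orientation sequence(s) of genomic intervals (0-based
# half-open); for minus-strand transcripts the caller passes exons in
# transcript order, and each is reverse complemented.
fetch_seq <- function(genome, chrom, start, end, minus) {
  if (!chrom %in% names(genome)) stop_fmt("chromosome %s not in genome",
                                          chrom)
  seqs <- as.character(Biostrings::subseq(
    rep(genome[chrom], length(start)), start = start + 1L, end = end))
  if (minus) {
    seqs <- vapply(seqs, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1), USE.NAMES = FALSE)
  }
  seqs
}

# 0-based position of the first nucleotide of the first in-frame stop
# codon at or downstream of `from` (0-based, frame anchored at `from`).
first_inframe_stop <- function(seq, from) {
  n <- nchar(seq)
  if (from + 3L > n) return(NA_integer_)
  starts <- seq.int(from + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]] - 1L
}

#' @export
print.nmd_call <- function(x, ...) {
  cat(sprintf("nmd_call: %s (%s)\n", x$verdict, x$reason))
  invisible(x)
}

#' Detect upstream open reading frames in a 5'UTR
#'
#' Scans the mRNA-sense 5'UTR (including any retained intron) for ATG
#' start codons strictly upstream of the main start codon and pairs each
#' with its first in-frame stop codon; the stop may lie at or beyond the
#' main start. ATGs with no downstream in-frame stop are open-ended and
#' excluded by default.
#'
#' @param utr_sequence Character: the 5' to 3' mRNA sequence from the
#'   transcript 5' end through at least the main start codon (longer is
#'   fine; downstream sequence is used to find stops).
#' @param main_start_offset 0-based offset of the main ORF's A of ATG.
#' @param include_incomplete Also report stop-less ATGs (with `NA` stop).
#' @return data frame in ascending start order: `start_offset`,
#'   `stop_offset` (0-based first nt of the stop codon), `length_codons`
#'   (codons strictly between start and stop).
#' @export
find_uorfs <- function(utr_sequence, main_start_offset,
                       include_incomplete = FALSE) {
  n <- nchar(utr_sequence)
  starts <- integer(0)
  at <- gregexpr("ATG", utr_sequence, fixed = TRUE)[[1L]]
  if (at[1L] != -1L) starts <- as.integer(at) - 1L  # 0-based
  starts <- starts[starts < main_start_offset]
  if (length(starts) == 0L) {
    return(data.frame(start_offset = integer(), stop_offset = integer(),
                      length_codons = integer(), stringsAsFactors = FALSE))
  }
  stops <- vapply(starts, function(s) first_inframe_stop(utr_sequence,
                                                         s + 3L),
                  integer(1))
  out <- data.frame(start_offset = starts, stop_offset = stops,
                    length_codons = as.integer((stops - starts) / 3L - 1L),
                    stringsAsFactors = FALSE)
  if (!include_incomplete) out <- out[!is.na(out$stop_offset), , drop = FALSE]
  out <- out[order(out$start_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
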