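# Fixtures and independent oracles used across test files.

# Write a tiny GTF from a list of feature rows (1-based inclusive coords).
write_tiny_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r) {
    sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            r$chrom, r$type, r$start, r$end, r$strand, r$gene, r$tx)
  }, character(1))
  writeLines(lines, path)
  path
}

feat <- function(type, start, end, strand = "+", gene = "g1", tx = "t1",
                 chrom = "chr1") {
  list(chrom = chrom, type = type, start = start, end = end,
       strand = strand, gene = gene, tx = tx)
}

# A synthetic intron table detached from any genome, for simulator-level
# tests where only ids and lengths matter.
fake_introns <- function(n, len = 100L) {
  data.frame(intron_id = sprintf("I%04d", seq_len(n)),
             gene_id = sprintf("G%04d", seq_len(n)),
             transcript_id = sprintf("T%04d", seq_len(n)),
             chrom = "chrF", strand = "+",
             start = seq_len(n) * (len + 50L),
             end = seq_len(n) * (len + 50L) + len,
             ordinal = 1L, n_introns_in_gene = 1L, tx_pos = 0L,
             known_exon_overlap = FALSE, region = "CDS",
             stringsAsFactors = FALSE)
}

# Hand-rolled alignment summary with explicit per-intron evidence.
manual_summary <- function(id, profiles, junctions, intergenic = 5000L,
                           coding = 100000L, stranded = FALSE) {
  structure(list(sample_id = id, stranded = stranded,
                 intergenic_reads = as.integer(intergenic),
                 coding_reads = as.integer(coding),
                 intron_id = names(profiles),
                 junction_reads = as.integer(junctions),
                 depth_profiles = profiles),
            class = "alignment_summary")
}

# ---------------------------------------------------------------------------
# Independent brute-force restatement of the IRratio decision rules, working
# from the raw depth profile: median and coverage computed with primitive
# code, then the worded rule chain applied literally.
oracle_irratio <- function(profile, junctions) {
  srt <- sort(profile)
  n <- length(srt)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  covered <- 0
  for (b in profile) if (b >= 1) covered <- covered + 1
  coverage <- covered / n
  if (junctions < 4) return(NA_real_)                 # isoform not shown expressed
  if (coverage < 0.20) return(0)                      # completely spliced
  if (coverage > 0.70 && med > 3) return(med / (med + junctions))
  NA_real_                                            # undecidable
}

# ---------------------------------------------------------------------------
# Independent NMD oracle: explicit mRNA string construction from the genome
# and annotation, stop discovery by linear codon walk, and the escape rules
# evaluated as one flat chain. Shares no code with predict_nmd.
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_nmd <- function(models, intron, genome_chr) {
  tx <- models$transcripts[models$transcripts$transcript_id ==
                             intron$transcript_id, ]
  ex <- models$exons[models$exons$transcript_id == intron$transcript_id, ]
  minus <- tx$strand == "-"
  ex <- ex[order(ex$start), ]
  chrom_seq <- genome_chr[[tx$chrom]]
  pull <- function(s, e) {
    x <- substr(chrom_seq, s + 1, e)
    if (minus) revcomp_chr(x) else x
  }
  # exon sequences in transcript orientation
  ord <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  exon_seqs <- vapply(ord, function(i) pull(ex$start[i], ex$end[i]),
                      character(1))
  spliced <- paste(exon_seqs, collapse = "")
  # transcript position of the intron: total width of exons genomically
  # 5' (plus strand) or 3' (minus strand) of it
  if (minus) {
    up <- ex$start >= intron$end
  } else {
    up <- ex$end <= intron$start
  }
  p <- sum((ex$end - ex$start)[up])
  iseq <- pull(intron$start, intron$end)
  L <- nchar(iseq)
  retained <- paste0(substr(spliced, 1, p), iseq,
                     substr(spliced, p + 1, nchar(spliced)))

  walk_stop <- function(seq, from0) {  # first stop codon at/after from0
    i <- from0
    while (i + 3 <= nchar(seq)) {
      cod <- substr(seq, i + 1, i + 3)
      if (cod == "TAA" || cod == "TAG" || cod == "TGA") return(i)
      i <- i + 3
    }
    NA_integer_
  }
  cds_start <- tx$cds_start
  normal_stop <- walk_stop(spliced, cds_start)

  n_ex <- length(exon_seqs)
  widths_tx <- nchar(exon_seqs)
  junctions_spliced <- cumsum(widths_tx)[-n_ex]
  is_last <- p == junctions_spliced[length(junctions_spliced)]

  if (p <= cds_start || p >= normal_stop + 3) {
    return(list(verdict = "no_NMD", reason = "utr"))
  }
  if (p - cds_start < 200) {
    return(list(verdict = "no_NMD", reason = "near_start"))
  }
  if (is_last) return(list(verdict = "no_NMD", reason = "last_intron"))
  q <- walk_stop(retained, cds_start)
  if (is.na(q) || q >= normal_stop + L) {
    return(list(verdict = "no_NMD", reason = "no_ptc"))
  }
  jx <- junctions_spliced[junctions_spliced != p]
  jx <- ifelse(jx > p, jx + L, jx)
  if (max(jx) - q <= 55) {
    return(list(verdict = "no_NMD", reason = "ptc_within_55"))
  }
  list(verdict = "NMD", reason = "ptc_triggers")
}

read_genome_chr <- function(fasta) {
  g <- Biostrings::readDNAStringSet(fasta)
  names(g) <- sub("\\s.*$", "", names(g))
  out <- lapply(seq_along(g), function(i) as.character(g[[i]]))
  names(out) <- names(g)
  out
}

# Codon-walk uORF enumeration oracle.
oracle_uorfs <- function(seq, main_start0) {
  out <- list()
  for (s in 0:(main_start0 - 1)) {
    if (s + 3 > nchar(seq)) break
    if (substr(seq, s + 1, s + 3) != "ATG") next
    i <- s + 3
    stop_at <- NA_integer_
    while (i + 3 <= nchar(seq)) {
      cod <- substr(seq, i + 1, i + 3)
      if (cod %in% c("TAA", "TAG", "TGA")) { stop_at <- i; break }
      i <- i + 3
    }
    if (!is.na(stop_at)) {
      out[[length(out) + 1]] <- c(start = s, stop = stop_at)
    }
  }
  out
}

# Seeded evaluation that restores the caller's RNG state.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
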