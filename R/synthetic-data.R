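#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators in one validated
#' object. Defaults describe a desk-scale cohort whose structure mirrors the
#' study design the pipeline targets: paired tumor/normal bulk RNA-seq with
#' a small strand-specific subset, per-intron retention fractions psi, and
#' exponential survival with planted hazards on IR-high group membership.
#'
#' @param n_genes Number of genes to simulate.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length Integer range of exon lengths (bp).
#' @param intron_length Integer range of intron lengths (bp).
#' @param gc Target intron GC fraction in `[0, 1]`.
#' @param depth Mean locus read depth `d`; at a retention fraction `psi`,
#'   intron base depth is Poisson(`d * psi`) i.i.d. per base and the flanking
#'   junction split-read count is Poisson(`d * (1 - psi)`), so the two
#'   isoforms share the locus depth budget and IRratio estimates `psi`.
#' @param n_pairs Number of tumor/normal pairs in a simulated cohort.
#' @param n_stranded Number of additional strand-specific samples (drawn from
#'   the tumor condition) used to build the whitelist.
#' @param psi_range Range from which per-intron baseline retention fractions
#'   are drawn when no explicit `psi` is supplied.
#' @param pair_effect_sd SD of the per-patient random effect on `logit(psi)`,
#'   shared by a patient's tumor and normal sample (induces the within-pair
#'   correlation a paired test exploits).
#' @param intergenic_rate Expected intergenic/coding read ratio per sample.
#' @param coding_reads Number of coding-region reads per sample.
#' @param uorf_atgs For [make_genome()]: number of ATG start codons planted
#'   in the dedicated 5'UTR intron of the first gene (0 disables it).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 30L,
                       exons_per_gene = c(3L, 8L),
                       exon_length = c(60L, 200L),
                       intron_length = c(80L, 300L),
                       gc = 0.45,
                       depth = 100,
                       n_pairs = 30L,
                       n_stranded = 4L,
                       psi_range = c(0.05, 0.5),
                       pair_effect_sd = 0.3,
                       intergenic_rate = 0.05,
                       coding_reads = 1e6,
                       uorf_atgs = 3L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              gc = gc, depth = depth,
              n_pairs = as.integer(n_pairs),
              n_stranded = as.integer(n_stranded),
              psi_range = psi_range,
              pair_effect_sd = pair_effect_sd,
              intergenic_rate = intergenic_rate,
              coding_reads = coding_reads,
              uorf_atgs = as.integer(uorf_atgs))
  if (cfg$n_genes < 1L) stop_fmt("n_genes must be >= 1")
  if (cfg$intron_length[1L] < 4L) {
    stop_fmt("intron_length must be >= 4 nt (splice dinucleotides)")
  }
  if (cfg$exon_length[1L] < 10L) stop_fmt("exon_length must be >= 10 nt")
  if (cfg$gc < 0 || cfg$gc > 1) stop_fmt("gc must be in [0, 1]")
  if (cfg$depth <= 0) stop_fmt("depth must be positive")
  if (any(cfg$psi_range < 0) || any(cfg$psi_range > 1)) {
    stop_fmt("psi_range must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Uniform integer draw from [lo, hi] that never collapses to sample()'s
# 1:n behaviour when lo == hi.
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Random DNA with an exact GC count: round(gc * n) G/C bases shuffled among
# A/T bases, so realized GC is within 1/n of the target.
random_dna <- function(n, gc) {
  ngc <- round(gc * n)
  base <- c(sample(c("G", "C"), ngc, replace = TRUE),
            sample(c("A", "T"), n - ngc, replace = TRUE))
  paste(sample(base), collapse = "")
}

# Remove ATG trinucleotides from a sequence by rewriting the G to C
# (repeat until clean); used where start codons must be controlled.
scrub_atg <- function(seq) {
  while (grepl("ATG", seq, fixed = TRUE)) {
    seq <- sub("ATG", "ATC", seq, fixed = TRUE)
  }
  seq
}

# Remove in-frame stop codons from a codon-aligned coding sequence.
scrub_stops_inframe <- function(seq) {
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
                      seq(3L, nchar(seq), by = 3L))
  codons[codons %in% c("TAA", "TAG", "TGA")] <- "GGC"
  paste(codons, collapse = "")
}

#' Generate a synthetic genome and annotation
#'
#' Emits a FASTA genome and a matching GTF with multi-exon protein-coding
#' genes on both strands. Intron GC content and length are controlled by the
#' configuration; introns carry canonical GT..AG splice dinucleotides. When
#' `uorf_atgs > 0`, the first gene is built with an intron inside its 5'UTR
#' containing exactly that many ATG start codons (each followed by an
#' in-frame stop), while the rest of its 5'UTR and the intron are scrubbed
#' of spurious ATGs — a positive control for uORF detection. Output is
#' deterministic given the seed.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `gtf` (paths), `models` (the `gene_models`
#'   re-read from the emitted GTF) and `uorf_gene` (id or `NA`).
#' @export
make_genome <- function(config, seed, dir = tempfile("genome")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    chrom <- "chrS"
    seqs <- character(0)
    gtf <- character(0)
    pos <- 0L  # 0-based genomic cursor
    spacer_len <- 200L
    uorf_gene <- NA_character_
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("G%04d", g)
      tid <- sprintf("T%04d", g)
      strand <- if (g %% 2L == 0L) "-" else "+"
      n_ex <- sample_range(config$exons_per_gene[1L],
                           config$exons_per_gene[2L], 1L)
      ex_len <- sample_range(config$exon_length[1L],
                             config$exon_length[2L], n_ex)
      in_len <- sample_range(config$intron_length[1L],
                             config$intron_length[2L],
                             max(n_ex - 1L, 0L))
      with_uorf <- g == 1L && config$uorf_atgs > 0L && n_ex >= 3L
      built <- build_gene_sequence(ex_len, in_len, config$gc, strand,
                                   uorf_atgs = if (with_uorf)
                                     config$uorf_atgs else 0L)
      if (with_uorf) uorf_gene <- gid
      spacer <- random_dna(spacer_len, 0.4)
      seqs <- c(seqs, spacer, built$gene_seq)
      gene_start0 <- pos + spacer_len
      pos <- gene_start0 + nchar(built$gene_seq)
      gtf <- c(gtf, gene_gtf_lines(chrom, gene_start0, built, gid, tid,
                                   strand))
    }
    genome <- paste(c(seqs, random_dna(spacer_len, 0.4)), collapse = "")
    fasta_path <- file.path(dir, "genome.fa")
    gtf_path <- file.path(dir, "annotation.gtf")
    dna <- Biostrings::DNAStringSet(genome)
    names(dna) <- chrom
    Biostrings::writeXStringSet(dna, fasta_path, width = 70L)
    writeLines(gtf, gtf_path)
    models <- read_gtf(gtf_path)
    list(fasta = fasta_path, gtf = gtf_path, models = models,
         uorf_gene = uorf_gene)
  })
}

# Build one gene's genomic sequence (gene/plus-strand orientation handled by
# the caller via reverse complement) plus its exon/intron/CDS layout in
# gene-local transcript-orientation coordinates.
#
# Layout in transcript orientation: exon1 starts with a 5'UTR, CDS begins
# inside exon1 (or exon2 for the uORF gene, whose first intron interrupts
# the 5'UTR), and the CDS stop codon lands in the last exon leaving a 3'UTR.
build_gene_sequence <- function(ex_len, in_len, gc, strand, uorf_atgs = 0L) {
  n_ex <- length(ex_len)
  utr5 <- max(0L, min(30L, ex_len[1L] - 20L))
  if (uorf_atgs > 0L) {
    # 5'UTR spans all of exon1 plus the start of exon2, so intron 1 lies
    # wholly within the 5'UTR.
    utr5 <- ex_len[1L] + 12L
  }
  tx_len <- sum(ex_len)
  utr3 <- max(0L, min(30L, ex_len[n_ex] - 20L))
  # keep at least a start, one sense codon and a stop in the CDS
  utr3 <- min(utr3, max(0L, tx_len - utr5 - 9L))
  cds_len <- tx_len - utr5 - utr3
  cds_len <- cds_len - cds_len %% 3L  # codon-aligned
  if (cds_len < 9L) stop_fmt("exons too short to host a CDS")
  utr3 <- tx_len - utr5 - cds_len

  exon_seqs <- vapply(ex_len, function(n) random_dna(n, 0.5), character(1))
  tx <- paste(exon_seqs, collapse = "")
  # Install ATG ... stop structure: scrub starts/stops then write codons.
  pre <- scrub_atg(substr(tx, 1L, utr5))
  cds <- substr(tx, utr5 + 1L, utr5 + cds_len)
  cds <- paste0("ATG", scrub_stops_inframe(substr(cds, 4L, cds_len - 3L)),
                "TAA")
  post <- substr(tx, utr5 + cds_len + 1L, tx_len)
  tx <- paste0(pre, cds, post)
  exon_seqs <- substring(tx, cumsum(c(1L, ex_len))[seq_len(n_ex)],
                         cumsum(ex_len))

  intron_seqs <- vapply(in_len, function(n) {
    s <- random_dna(n, gc)
    paste0("GT", substr(s, 3L, n - 2L), "AG")
  }, character(1))
  if (uorf_atgs > 0L && length(intron_seqs) >= 1L) {
    intron_seqs[1L] <- plant_uorfs(intron_seqs[1L], uorf_atgs)
  }

  parts <- character(2L * n_ex - 1L)
  parts[seq(1L, 2L * n_ex - 1L, by = 2L)] <- exon_seqs
  if (n_ex > 1L) parts[seq(2L, 2L * n_ex - 2L, by = 2L)] <- intron_seqs
  gene_tx_orient <- paste(parts, collapse = "")
  gene_seq <- if (strand == "-") revcomp(gene_tx_orient) else gene_tx_orient
  list(gene_seq = gene_seq, ex_len = ex_len, in_len = in_len,
       utr5 = utr5, cds_len = cds_len)
}

# Plant `k` ATG+in-frame-stop uORF cassettes in an intron sequence whose
# other ATGs are scrubbed; splice dinucleotides preserved. The cassette
# carries trailing CC so its final A cannot recombine with downstream
# sequence into a spurious start codon.
plant_uorfs <- function(intron_seq, k) {
  n <- nchar(intron_seq)
  body <- scrub_atg(substr(intron_seq, 3L, n - 2L))
  if (nchar(body) < k * 20L) {
    stop_fmt("intron too short to host %d uORFs", k)
  }
  slots <- floor(seq(1L, nchar(body) - 14L, length.out = k + 1L))[seq_len(k)]
  for (s in slots) {
    # ATG + two neutral codons + TAA, in frame with the ATG
    substr(body, s, s + 13L) <- "ATGGGCCACTAACC"
  }
  paste0("GT", body, "AG")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# GTF lines (1-based inclusive) for one gene given its transcript-orientation
# layout and 0-based genomic start of the gene.
gene_gtf_lines <- function(chrom, gene_start0, built, gid, tid, strand) {
  ex_len <- built$ex_len
  in_len <- built$in_len
  n_ex <- length(ex_len)
  # gene-local 0-based starts of exons in transcript orientation
  starts_local <- cumsum(c(0L, utils::head(ex_len, -1L) + in_len))
  ends_local <- starts_local + ex_len
  gene_len <- sum(ex_len) + sum(in_len)
  if (strand == "-") {
    tmp_s <- gene_len - ends_local
    ends_local <- gene_len - starts_local
    starts_local <- tmp_s
  }
  g_start <- gene_start0 + starts_local  # 0-based genomic
  g_end <- gene_start0 + ends_local
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding";',
                   gid, tid)
  exon_lines <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                        chrom, g_start + 1L, g_end, strand, attrs)
  # CDS in transcript coordinates -> genomic segments
  cds_lines <- cds_gtf_lines(chrom, gene_start0, built, strand, attrs,
                             gene_len)
  c(exon_lines, cds_lines)
}

cds_gtf_lines <- function(chrom, gene_start0, built, strand, attrs,
                          gene_len) {
  ex_len <- built$ex_len
  in_len <- built$in_len
  cds_from <- built$utr5                      # tx coords, 0-based half-open
  cds_to <- built$utr5 + built$cds_len
  starts_tx <- cumsum(c(0L, utils::head(ex_len, -1L)))  # spliced coords
  out <- character(0)
  for (i in seq_along(ex_len)) {
    s <- max(cds_from, starts_tx[i])
    e <- min(cds_to, starts_tx[i] + ex_len[i])
    if (s >= e) next
    # gene-local genomic (transcript orientation) offset of this exon
    gene_local <- cumsum(c(0L, utils::head(ex_len, -1L) + in_len))[i]
    ls <- gene_local + (s - starts_tx[i])
    le <- gene_local + (e - starts_tx[i])
    if (strand == "-") {
      tmp <- gene_len - le
      le <- gene_len - ls
      ls <- tmp
    }
    out <- c(out, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                          chrom, gene_start0 + ls + 1L, gene_start0 + le,
                          strand, attrs))
  }
  out
}

#' Simulate one sample's alignment summary
#'
#' Per-intron read evidence under a true retention fraction `psi`: intron
#' base depth is Poisson(`d * psi`) i.i.d. per base, the flanking junction
#' split-read count is Poisson(`d * (1 - psi)`), and the sample-level
#' intergenic read count is Binomial(`coding_reads`, `intergenic_rate`).
#'
#' @param introns Intron table from [extract_introns()].
#' @param psi True retention fraction(s): scalar or vector named by
#'   `intron_id`, each in `[0, 1]`.
#' @param depth Mean locus depth `d` (> 0).
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param stranded Logical; marks a strand-specific library (metadata only).
#' @param intergenic_rate,coding_reads Sample-level QC counts; see
#'   [sample_qc()].
#' @return An `alignment_summary`: list with `sample_id`, `stranded`,
#'   `intergenic_reads`, `coding_reads`, `intron_id`, `junction_reads` and
#'   `depth_profiles` (list of per-base integer depth vectors).
#' @export
simulate_sample <- function(introns, psi, depth, seed,
                            sample_id = "S1", stranded = FALSE,
                            intergenic_rate = 0.05, coding_reads = 1e6) {
  if (depth <= 0) stop_fmt("depth must be positive")
  n <- nrow(introns)
  if (n == 0L) stop_fmt("no introns to simulate")
  psi <- expand_psi(psi, introns$intron_id)
  if (any(psi < 0 | psi > 1)) stop_fmt("psi must lie in [0, 1]")
  lens <- introns$end - introns$start
  with_seed(seed, {
    all_depth <- stats::rpois(sum(lens), rep(depth * psi, lens))
    profiles <- split(all_depth, rep.int(seq_len(n), lens))
    names(profiles) <- introns$intron_id
    junc <- stats::rpois(n, depth * (1 - psi))
    inter <- stats::rbinom(1L, size = as.integer(coding_reads),
                           prob = intergenic_rate)
    structure(list(sample_id = sample_id, stranded = stranded,
                   intergenic_reads = inter,
                   coding_reads = as.integer(coding_reads),
                   intron_id = introns$intron_id,
                   junction_reads = junc,
                   depth_profiles = profiles),
              class = "alignment_summary")
  })
}

expand_psi <- function(psi, intron_ids) {
  if (length(psi) == 1L && is.null(names(psi))) {
    return(rep(psi, length(intron_ids)))
  }
  if (!is.null(names(psi))) {
    miss <- setdiff(intron_ids, names(psi))
    if (length(miss)) {
      stop_fmt("psi undefined for %d introns (e.g. %s)", length(miss),
               miss[1L])
    }
    return(unname(psi[intron_ids]))
  }
  if (length(psi) != length(intron_ids)) {
    stop_fmt("psi must be scalar, named, or one value per intron")
  }
  psi
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("alignment_summary %s: %d introns, stranded=%s, QC ratio %.3f\n",
              x$sample_id, length(x$intron_id), x$stranded,
              x$intergenic_reads / x$coding_reads))
  invisible(x)
}

#' Write / read an alignment summary TSV
#'
#' Columns: `intron_id`, `junction_reads`, `depth_profile` (comma-separated
#' per-base depths). Sample-level fields travel in `#key=value` header lines.
#'
#' @param summary An `alignment_summary`.
#' @param path File path.
#' @return `write_alignment_summary`: `path` invisibly;
#'   `read_alignment_summary`: the `alignment_summary`.
#' @export
write_alignment_summary <- function(summary, path) {
  hdr <- c(sprintf("#sample_id=%s", summary$sample_id),
           sprintf("#stranded=%s", summary$stranded),
           sprintf("#intergenic_reads=%d", summary$intergenic_reads),
           sprintf("#coding_reads=%d", summary$coding_reads),
           "intron_id\tjunction_reads\tdepth_profile")
  prof <- vapply(summary$depth_profiles, paste, character(1), collapse = ",")
  writeLines(c(hdr, sprintf("%s\t%d\t%s", summary$intron_id,
                            summary$junction_reads, prof)), path)
  invisible(path)
}

#' @rdname write_alignment_summary
#' @export
read_alignment_summary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  profiles <- lapply(parts, function(p) {
    as.integer(strsplit(p[3L], ",", fixed = TRUE)[[1L]])
  })
  ids <- vapply(parts, `[`, character(1), 1L)
  names(profiles) <- ids
  structure(list(sample_id = meta[["sample_id"]],
                 stranded = as.logical(meta[["stranded"]]),
                 intergenic_reads = as.integer(meta[["intergenic_reads"]]),
                 coding_reads = as.integer(meta[["coding_reads"]]),
                 intron_id = ids,
                 junction_reads = as.integer(vapply(parts, `[`,
                                                    character(1), 2L)),
                 depth_profiles = profiles),
            class = "alignment_summary")
}

#' Simulate a paired tumor/normal cohort with planted differential IR
#'
#' Baseline retention fractions are drawn per intron from
#' `config$psi_range`; planted introns get tumor `psi = normal psi + delta`.
#' Each patient carries a logit-normal random effect on `psi` shared by
#' their tumor and normal sample, inducing the within-pair correlation the
#' paired test relies on. A small strand-specific subset (tumor condition)
#' is emitted for whitelist construction.
#'
#' @param introns Intron table.
#' @param config A [sim_config()].
#' @param planted `NULL`, or data frame with `intron_id` and `delta`
#'   (tumor minus normal true retention; `psi + delta` must stay in
#'   `[0, 1]`).
#' @param seed Integer seed.
#' @return List with `summaries` (list of `alignment_summary`), `samples`
#'   (metadata data frame: `sample_id`, `condition`, `pair_id`, `stranded`,
#'   `cancer_type`) and `truth` (per-intron `psi_normal`, `delta`,
#'   `is_dir`).
#' @export
simulate_cohort <- function(introns, config, planted = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(introns)
  with_seed(seed, {
    psi_n <- stats::runif(n, config$psi_range[1L], config$psi_range[2L])
    names(psi_n) <- introns$intron_id
    delta <- stats::setNames(rep(0, n), introns$intron_id)
    if (!is.null(planted) && nrow(planted)) {
      bad <- setdiff(planted$intron_id, introns$intron_id)
      if (length(bad)) stop_fmt("planted intron not in table: %s", bad[1L])
      delta[planted$intron_id] <- planted$delta
    }
    psi_t <- psi_n + delta
    if (any(psi_t < 0 | psi_t > 1)) {
      stop_fmt("planted delta pushes psi outside [0, 1]")
    }

    summaries <- list()
    samples <- list()
    sub_seeds <- sample.int(.Machine$integer.max,
                            2L * config$n_pairs + config$n_stranded)
    k <- 0L
    for (p in seq_len(config$n_pairs)) {
      u <- stats::rnorm(1L, 0, config$pair_effect_sd)
      for (cond in c("tumor", "normal")) {
        k <- k + 1L
        base <- if (cond == "tumor") psi_t else psi_n
        psi_p <- jitter_psi(base, u)
        sid <- sprintf("P%03d_%s", p, cond)
        summaries[[sid]] <- simulate_sample(
          introns, psi_p, config$depth, seed = sub_seeds[k],
          sample_id = sid, stranded = FALSE,
          intergenic_rate = config$intergenic_rate,
          coding_reads = config$coding_reads)
        samples[[sid]] <- data.frame(
          sample_id = sid, condition = cond,
          pair_id = sprintf("P%03d", p), stranded = FALSE,
          cancer_type = "SIM", stringsAsFactors = FALSE)
      }
    }
    for (s in seq_len(config$n_stranded)) {
      k <- k + 1L
      u <- stats::rnorm(1L, 0, config$pair_effect_sd)
      sid <- sprintf("STR%02d", s)
      summaries[[sid]] <- simulate_sample(
        introns, jitter_psi(psi_t, u), config$depth, seed = sub_seeds[k],
        sample_id = sid, stranded = TRUE,
        intergenic_rate = config$intergenic_rate,
        coding_reads = config$coding_reads)
      samples[[sid]] <- data.frame(
        sample_id = sid, condition = "tumor", pair_id = NA_character_,
        stranded = TRUE, cancer_type = "SIM", stringsAsFactors = FALSE)
    }
    truth <- data.frame(intron_id = introns$intron_id,
                        psi_normal = unname(psi_n),
                        delta = unname(delta),
                        is_dir = unname(delta != 0),
                        stringsAsFactors = FALSE)
    samples_df <- do.call(rbind, unname(samples))
    rownames(samples_df) <- NULL
    list(summaries = summaries, samples = samples_df, truth = truth)
  })
}

# Patient random effect on the logit scale; psi of exactly 0 or 1 is left
# untouched (fully spliced / fully retained loci have no room to wobble).
jitter_psi <- function(psi, u) {
  inner <- psi > 0 & psi < 1
  psi[inner] <- stats::plogis(stats::qlogis(psi[inner]) + u)
  psi
}

#' Simulate survival outcomes with planted hazards on IR-high membership
#'
#' Event times are exponential with hazard
#' `h0 * exp(sum_j beta_j * x_ij)`, where `x_ij` indicates that patient `i`
#' is IR-high for intron `j` (median split over patients with IRratio > 0;
#' ties at the median go low — the same convention [median_split_cox()]
#' uses). Censoring is independent Uniform(0, c) with `c` solved
#' numerically so the expected censored fraction equals `censor_frac`.
#'
#' @param ir Numeric matrix of IRratios (introns x patients, `NA` allowed
#'   outside the planted rows).
#' @param beta_map Named numeric vector: log-hazard per IR-high membership,
#'   names are intron ids (empty vector = null model).
#' @param h0 Baseline hazard (> 0), per day.
#' @param censor_frac Target censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return data frame: `patient_id`, `time` (days), `event` (1 = event,
#'   0 = censored), `endpoint` ("OS").
#' @export
simulate_survival <- function(ir, beta_map = numeric(0), h0 = 0.001,
                              censor_frac = 0.3, seed = 1L) {
  if (is.null(dim(ir)) || ncol(ir) == 0L || nrow(ir) == 0L) {
    stop_fmt("ir matrix is empty")
  }
  if (h0 <= 0) stop_fmt("h0 must be positive")
  if (censor_frac < 0 || censor_frac >= 1) {
    stop_fmt("censor_frac must be in [0, 1)")
  }
  n <- ncol(ir)
  lp <- rep(0, n)
  if (length(beta_map)) {
    miss <- setdiff(names(beta_map), rownames(ir))
    if (length(miss)) stop_fmt("beta_map intron not in matrix: %s", miss[1L])
    for (id in names(beta_map)) {
      x <- ir[id, ]
      pos <- which(!is.na(x) & x > 0)
      if (length(pos) < 2L) stop_fmt("intron %s has < 2 positive values", id)
      grp <- rep(0L, n)
      grp[pos] <- as.integer(x[pos] > stats::median(x[pos]))
      lp <- lp + beta_map[[id]] * grp
    }
  }
  hazard <- h0 * exp(lp)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = hazard)
    if (censor_frac == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      cmax <- solve_censor_bound(hazard, censor_frac)
      cens <- stats::runif(n, 0, cmax)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    data.frame(patient_id = colnames(ir) %||% sprintf("PT%03d", seq_len(n)),
               time = time, event = event, endpoint = "OS",
               stringsAsFactors = FALSE)
  })
}

# For C ~ U(0, c) independent of T ~ Exp(lambda_i), the probability of
# censoring is P(T > C) = E[S(C)] = mean_i (1 - exp(-lambda_i c)) /
# (lambda_i c), decreasing in c; solve for c.
solve_censor_bound <- function(hazard, censor_frac) {
  f <- function(cc) {
    mean((1 - exp(-hazard * cc)) / (hazard * cc)) - censor_frac
  }
  upper <- 1 / min(hazard)
  while (f(upper) > 0) upper <- upper * 10
  stats::uniroot(f, c(1e-9 / max(hazard), upper), tol = 1e-10)$root
}
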