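test_that("intron classes are mutually exclusive and follow the medians", {
  med <- matrix(c(0, 0, 0, 0,
                  0.2, 0, 0, 0,
                  0.3, 0.1, 0.2, 0.2,
                  0.1, 0.3, 0.1, 0.1,
                  NA, 0, NA, 0), nrow = 5, byrow = TRUE,
                dimnames = list(paste0("i", 1:5), NULL))
  dirs <- data.frame(intron_id = c("i3", "i4"),
                     direction = c("up", "down"),
                     stringsAsFactors = FALSE)
  cls <- classify_introns(med, dirs)
  expect_equal(as.character(cls),
               c("constitutive", "unregulated_retained", "dir_up",
                 "dir_down", "constitutive"))
})

test_that("gc_content counts bases", {
  expect_equal(gc_content(c("GCGC", "ATAT", "ACGT")), c(1, 0, 0.5))
})

test_that("relative gene position maps first/last introns to 0/1", {
  expect_equal(relative_gene_position(1, 4), 0)
  expect_equal(relative_gene_position(4, 4), 1)
  expect_equal(relative_gene_position(3, 5), 0.5)
  expect_true(is.na(relative_gene_position(1, 2)))  # < 3 introns excluded
  # equal spacing across a gene
  expect_equal(relative_gene_position(1:5, rep(5, 5)), seq(0, 1, 0.25))
})

test_that("mirror symmetry of relative positions between strands", {
  cfg <- sim_config(n_genes = 8, exons_per_gene = c(5, 5))
  g <- make_genome(cfg, seed = 21, dir = tempfile())
  ins <- extract_introns(g$models)
  for (gene in unique(ins$gene_id)) {
    gi <- ins[ins$gene_id == gene, ]
    gi <- gi[order(gi$start), ]
    rp <- relative_gene_position(gi$ordinal, gi$n_introns_in_gene)
    if (gi$strand[1] == "+") {
      expect_equal(rp, sort(rp))
    } else {
      expect_equal(rp, rev(sort(rp)))
    }
    expect_equal(sort(rp), seq(0, 1, length.out = nrow(gi)))
  }
})

test_that("NMD escape rules fire in order on constructed cases", {
  # transcript: 4 exons of 300 nt, CDS starts at spliced position 30
  # (inside exon 1) and ends in exon 4
  ex <- list(feat("exon", 1, 300), feat("exon", 401, 700),
             feat("exon", 801, 1100), feat("exon", 1201, 1500))
  gm <- read_gtf(write_tiny_gtf(c(ex, list(feat("CDS", 31, 300),
                                           feat("CDS", 401, 700),
                                           feat("CDS", 801, 1100),
                                           feat("CDS", 1201, 1233)))))
  ins <- extract_introns(gm)
  ins <- ins[order(ins$start), ]
  # synthetic chromosome: no stop codons in frame anywhere except planted
  chr <- paste(rep("GGC", 500), collapse = "")
  # normal stop at spliced 930 (in exon 4): plant TAA at genomic 1231-1233
  substr(chr, 1231, 1233) <- "TAA"
  genome <- Biostrings::DNAStringSet(chr)
  names(genome) <- "chr1"

  # intron 1 at spliced 300: 300 - 30 = 270 nt from start, not last,
  # intron is all GGC -> no PTC introduced
  expect_equal(predict_nmd(gm, ins[1, ], genome)$reason, "no_ptc")
  # the last intron escapes regardless
  expect_equal(predict_nmd(gm, ins[3, ], genome)$reason, "last_intron")

  # plant an early in-frame TAA inside intron 1 (genomic 304-306, phase 0
  # relative to CDS frame): PTC at retained position ~303, far upstream of
  # the last junction -> NMD
  chr2 <- chr
  substr(chr2, 304, 306) <- "TAA"
  genome2 <- Biostrings::DNAStringSet(chr2)
  names(genome2) <- "chr1"
  call <- predict_nmd(gm, ins[1, ], genome2)
  expect_equal(call$verdict, "NMD")
  expect_equal(call$reason, "ptc_triggers")

  # PTC close to the last junction: retaining intron 2 (spliced pos 600,
  # length 100) shifts the last junction (spliced 900) to 1000; a stop
  # late in exon 3 — genomic 1097-1099, retained position 996, in frame
  # after the 100-nt shift — leaves 4 nt to the junction
  chr3 <- chr
  substr(chr3, 1097, 1099) <- "TAA"
  genome3 <- Biostrings::DNAStringSet(chr3)
  names(genome3) <- "chr1"
  call3 <- predict_nmd(gm, ins[2, ], genome3)
  expect_equal(call3$reason, "ptc_within_55")
})

test_that("UTR and near-start introns escape NMD", {
  ex <- list(feat("exon", 1, 300), feat("exon", 401, 700),
             feat("exon", 801, 1100))
  # CDS starts at spliced 450 (genomic 551), normal stop planted in frame
  # at genomic 834-836 (spliced 633)
  gm <- read_gtf(write_tiny_gtf(c(ex, list(feat("CDS", 551, 700),
                                           feat("CDS", 801, 836)))))
  ins <- extract_introns(gm)
  ins <- ins[order(ins$start), ]
  chr <- paste(rep("GGC", 500), collapse = "")
  substr(chr, 834, 836) <- "TAA"
  genome <- Biostrings::DNAStringSet(chr)
  names(genome) <- "chr1"
  # intron 1 at spliced 300, CDS starts at 450: 5'UTR
  expect_equal(predict_nmd(gm, ins[1, ], genome)$reason, "utr")
  # intron 2 at spliced 600, 150 nt from the start codon: near_start
  expect_equal(predict_nmd(gm, ins[2, ], genome)$reason, "near_start")
  # missing CDS errors
  gm2 <- read_gtf(write_tiny_gtf(ex))
  expect_error(predict_nmd(gm2, ins[1, ], genome), "CDS")
})

test_that("predict_nmd agrees with the construction oracle on random genes", {
  n_checked <- 0L
  for (seed in 1:4) {
    cfg <- sim_config(n_genes = 15, exons_per_gene = c(3, 9),
                      intron_length = c(60, 400))
    g <- make_genome(cfg, seed = 100 + seed, dir = tempfile())
    ins <- extract_introns(g$models)
    chr <- read_genome_chr(g$fasta)
    genome <- Biostrings::readDNAStringSet(g$fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    for (i in seq_len(nrow(ins))) {
      got <- predict_nmd(g$models, ins[i, ], genome)
      want <- oracle_nmd(g$models, ins[i, ], chr)
      expect_equal(got$verdict, want$verdict, info = ins$intron_id[i])
      expect_equal(got$reason, want$reason, info = ins$intron_id[i])
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("find_uorfs enumerates ATG/stop pairs upstream of the main ORF", {
  expect_equal(nrow(find_uorfs("CCCCCCATGCCC", 9)), 0L)  # no upstream ATG
  u <- find_uorfs("AAATGGCTTAACCCATGCCC", 14)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start_offset, 2L)
  expect_equal(u$stop_offset, 8L)
  expect_equal(u$length_codons, 1L)
  # ATG with no in-frame stop is excluded by default, reported on request
  v <- find_uorfs("AAATGGCTGCTCCCCCC", 14)
  expect_equal(nrow(v), 0L)
  v2 <- find_uorfs("AAATGGCTGCTCCCCCC", 14, include_incomplete = TRUE)
  expect_equal(nrow(v2), 1L)
  expect_true(is.na(v2$stop_offset))
})

test_that("find_uorfs matches the codon-walk oracle on random UTRs", {
  set.seed(77)
  for (rep in 1:50) {
    utr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    main <- 250L
    got <- find_uorfs(utr, main)
    want <- oracle_uorfs(utr, main)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_offset, vapply(want, `[[`, 0, "start"))
      expect_equal(got$stop_offset, vapply(want, `[[`, 0, "stop"))
    }
  }
})

test_that("planted uORFs in the synthetic 5'UTR intron are all recovered", {
  cfg <- sim_config(n_genes = 3, uorf_atgs = 3)
  g <- make_genome(cfg, seed = 55, dir = tempfile())
  ins <- extract_introns(g$models)
  it <- ins[ins$gene_id == g$uorf_gene & ins$region == "5UTR", ][1, ]
  tx <- g$models$transcripts[g$models$transcripts$gene_id == g$uorf_gene, ]
  ex <- g$models$exons[g$models$exons$transcript_id == tx$transcript_id, ]
  ex <- ex[order(ex$ordinal), ]
  chr <- read_genome_chr(g$fasta)
  minus <- tx$strand == "-"
  pull <- function(s, e) {
    x <- substr(chr[[tx$chrom]], s + 1, e)
    if (minus) revcomp_chr(x) else x
  }
  spliced <- paste(vapply(seq_len(nrow(ex)), function(i)
    pull(ex$start[i], ex$end[i]), character(1)), collapse = "")
  retained <- paste0(substr(spliced, 1, it$tx_pos),
                     pull(it$start, it$end),
                     substr(spliced, it$tx_pos + 1, nchar(spliced)))
  main_start <- tx$cds_start + (it$end - it$start)
  u <- find_uorfs(retained, main_start)
  expect_equal(nrow(u), 3L)
  expect_true(all(u$start_offset < main_start))
})
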