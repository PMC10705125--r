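# Construct an ir_matrix object directly from a value matrix plus pairing
# metadata, bypassing the simulator, for precise control of cell patterns.
toy_ir_matrix <- function(values, n_pairs) {
  samples <- data.frame(
    sample_id = colnames(values),
    condition = rep(c("tumor", "normal"), n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), each = 2),
    stranded = FALSE, cancer_type = "TST", stringsAsFactors = FALSE)
  structure(list(ir = values, samples = samples), class = "ir_matrix")
}

make_cols <- function(n_pairs) {
  as.vector(rbind(sprintf("P%02d_t", seq_len(n_pairs)),
                  sprintf("P%02d_n", seq_len(n_pairs))))
}

test_that("call_dirs detects a planted shift and honors the delta filter", {
  set.seed(5)
  np <- 20
  cols <- make_cols(np)
  base <- stats::runif(np, 0.1, 0.3)
  strong <- rbind(as.vector(rbind(base + 0.3, base)))          # delta .3
  weak <- rbind(as.vector(rbind(base + 0.05, base)))           # delta .05
  flat <- rbind(stats::runif(2 * np, 0.1, 0.4))                # null
  m <- rbind(strong, weak, flat)
  dimnames(m) <- list(c("strong", "weak", "flat"), cols)
  mat <- toy_ir_matrix(m, np)
  res <- call_dirs(mat, all_results = TRUE, cancer_type = "TST")
  expect_true(res$is_dir[res$intron_id == "strong"])
  expect_equal(res$direction[res$intron_id == "strong"], "up")
  # significant but small effect is not a DIR
  expect_lt(res$p_value[res$intron_id == "weak"], 0.05)
  expect_false(res$is_dir[res$intron_id == "weak"])
  dirs_only <- call_dirs(mat, cancer_type = "TST")
  expect_equal(dirs_only$intron_id, "strong")
})

test_that("call_dirs drops missing pairs, treats zero as 0, skips thin introns", {
  np <- 16
  cols <- make_cols(np)
  v <- as.vector(rbind(rep(0.4, np), rep(0, np)))   # tumor .4, normal zero
  m <- rbind(v, v)
  m[2, 3:30] <- NA                                  # only 2 usable pairs
  dimnames(m) <- list(c("ok", "thin"), cols)
  mat <- toy_ir_matrix(m, np)
  res <- call_dirs(mat, all_results = TRUE, min_pairs = 10)
  expect_equal(attr(res, "skipped"), character(0))
  expect_true("thin" %in% res$intron_id)            # 2 pairs: tested
  expect_equal(res$n_pairs[res$intron_id == "thin"], 2L)
  m[2, 3:32] <- NA                                  # 1 usable pair
  mat <- toy_ir_matrix(m, np)
  expect_message(res <- call_dirs(mat, all_results = TRUE, min_pairs = 10),
                 "skipped 1")
  expect_false("thin" %in% res$intron_id)
  expect_equal(res$category[res$intron_id == "ok"], "cancer_associated")
})

test_that("cohort-size precondition is enforced", {
  np <- 10
  m <- matrix(0.2, 1, 2 * np, dimnames = list("i", make_cols(np)))
  expect_error(call_dirs(toy_ir_matrix(m, np)), "more than 15")
  expect_silent(suppressMessages(
    call_dirs(toy_ir_matrix(m, np), min_pairs = 5)))
})

test_that("call_dirs is invariant to sample column order", {
  set.seed(8)
  np <- 18
  cols <- make_cols(np)
  m <- matrix(stats::runif(3 * 2 * np, 0, 0.5), nrow = 3,
              dimnames = list(paste0("i", 1:3), cols))
  mat1 <- toy_ir_matrix(m, np)
  perm <- sample(ncol(m))
  mat2 <- structure(list(ir = m[, perm], samples = mat1$samples[perm, ]),
                    class = "ir_matrix")
  r1 <- call_dirs(mat1, all_results = TRUE)
  r2 <- call_dirs(mat2, all_results = TRUE)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("DIR categories follow the median-zero rule", {
  expect_equal(categorize_dir(0.15, 0), "cancer_associated")
  expect_equal(categorize_dir(0, 0.15), "normal_associated")
  expect_equal(categorize_dir(0.35, 0.2), "altered_level")
  expect_equal(categorize_dir(0.05, 0), "altered_level")  # tumor side <= 0.1
})

test_that("pan-cancer merge drops inconsistent and high-missing introns", {
  d <- data.frame(
    intron_id = c("a", "a", "b", "b", "c"),
    cancer_type = c("A", "C", "A", "B", "B"),
    direction = c("up", "up", "up", "down", "down"),
    stringsAsFactors = FALSE)
  m <- matrix(0.2, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  m["c", 1:4] <- NA  # 40% missing
  keep <- merge_dirs_pan_cancer(d, m)
  expect_equal(keep$intron_id, "a")
  m["c", ] <- 0.2
  keep <- merge_dirs_pan_cancer(d, m)
  expect_setequal(keep$intron_id, c("a", "c"))
})

test_that("matrix_prep drops high-missing rows and mean-imputes the rest", {
  m <- matrix(c(0.2, NA, 0.4,
                NA, NA, 0.3,
                0.1, 0.2, 0.3), nrow = 3, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), c("a", "b", "c")))
  d <- matrix_prep(m, max_missing = 0.5)
  expect_false("r2" %in% rownames(d))  # 2/3 missing
  expect_equal(unname(d["r1", ]), c(0.2, 0.3, 0.4))
  expect_equal(unname(d["r3", ]), c(0.1, 0.2, 0.3))
  expect_false(anyNA(d))
  full <- matrix_prep(m[3, , drop = FALSE])
  expect_equal(full, m[3, , drop = FALSE])
})

test_that("IR-expression correlation recovers planted dependence", {
  # perfectly anti-monotone
  d <- data.frame(gene_id = letters[1:10], delta = 1:10 / 10)
  e <- data.frame(gene_id = letters[1:10], log2fc = -(1:10))
  r <- ir_expression_correlation(d, e)
  expect_equal(r$rho, -1)
  # constant vector undefined
  e2 <- data.frame(gene_id = letters[1:10], log2fc = rep(1, 10))
  expect_error(ir_expression_correlation(d, e2), "constant")
  # planted weak negative correlation (population rho = -0.2)
  set.seed(31)
  n <- 500
  z <- stats::rnorm(n)
  dd <- data.frame(gene_id = sprintf("g%d", 1:n), delta = z)
  ee <- data.frame(gene_id = sprintf("g%d", 1:n),
                   log2fc = -0.2 * z + sqrt(1 - 0.04) * stats::rnorm(n))
  r2 <- ir_expression_correlation(dd, ee)
  expect_lt(abs(r2$rho - (-0.2)), 0.1)
})

test_that("mutation proximity uses a 20 bp inclusive window at both sites", {
  ins <- fake_introns(1)
  ins$start <- 1000L; ins$end <- 1500L
  ins$intron_id <- "I1"
  dirs <- data.frame(intron_id = "I1", stringsAsFactors = FALSE)
  vars <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    chrom = "chrF",
    pos = c(1016L,   # 15 bp inside from the 5' site (site at 1001)
            1026L,   # 25 bp inside: too far
            1021L,   # exactly 20 bp: inclusive boundary
            981L,    # 20 bp on the exonic side
            1490L),  # 10 bp from the 3' site (site at 1500)
    stringsAsFactors = FALSE)
  got <- mutation_proximity(dirs, ins, vars)
  expect_setequal(got$sample_id, c("s1", "s3", "s4", "s5"))
  expect_equal(got$distance[got$sample_id == "s1"], 15L)
})

test_that("null cohorts yield approximately uniform p-values", {
  ins <- fake_introns(400)
  cfg <- sim_config(n_pairs = 20, n_stranded = 0, depth = 100)
  co <- simulate_cohort(ins, cfg, NULL, seed = 13)
  mat <- build_ir_matrix(co$summaries, ins, samples = co$samples)
  res <- call_dirs(mat, all_results = TRUE)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(res$is_dir), 0L)
})
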