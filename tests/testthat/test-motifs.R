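# independent reverse complement for oracles (no Biostrings)
rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, "")
}

test_that("canonicalization picks the lexicographic minimum of the pair", {
  expect_equal(canonicalize("AAACGTTT"), "AAACGTTT")   # palindrome
  expect_equal(canonicalize("CTTCGAAA"), "CTTCGAAA")   # < TTTCGAAG
  expect_equal(canonicalize("TTTCGAAG"), "CTTCGAAA")
  # idempotence and brute-force agreement on random valid 8-mers
  set.seed(5)
  b <- c("A", "C", "G", "T")
  km <- replicate(200, paste0(paste(sample(b, 3, TRUE), collapse = ""),
                              "CG",
                              paste(sample(b, 3, TRUE), collapse = "")))
  can <- canonicalize(km)
  expect_identical(canonicalize(can), can)
  expect_identical(can, pmin(km, rc_oracle(km)))
  # validation
  expect_error(canonicalize("ACTT"), "central CG")
  expect_error(canonicalize("AAAACGTTT"), "even")
  expect_error(canonicalize("AANCGTTT"), "ACGT")
  expect_error(canonicalize("AAATGTTT"), "central CG")
})

test_that("canonical motif enumeration matches brute force and the formula", {
  expect_equal(canonical_kmers(2), "CG")
  k4 <- canonical_kmers(4)
  expect_length(k4, 10L)
  # brute force for k = 4: all 16 xCGy words collapsed by reverse complement
  b <- c("A", "C", "G", "T")
  all4 <- as.vector(outer(b, b, function(x, y) paste0(x, "CG", y)))
  expect_setequal(k4, unique(pmin(all4, rc_oracle(all4))))
  for (k in c(4L, 6L, 8L)) {
    expect_length(canonical_kmers(k), (4^(k - 2) + 4^((k - 2) / 2)) / 2)
  }
  expect_error(canonical_kmers(5), "even")
})

test_that("motif counting anchors windows on covered mCpGs", {
  #          0123456789
  g <- tiny_genome(cw = "TAAACGTTTA", cn = "TTTNCGAAAT")
  m <- methylome(data.frame(chrom = c("cw", "cn"), pos = c(4L, 4L),
                            meth_count = 5L, total_count = 10L))
  rs <- region_set(c("cw", "cn"), c(0L, 0L), c(10L, 10L))
  cnt <- suppressMessages(count_motifs(rs, g, m))
  expect_equal(attr(cnt, "n_total"), 1L)     # the N window is skipped
  expect_equal(unname(cnt["AAACGTTT"]), 1L)
  expect_equal(sum(cnt), 1L)
  expect_length(cnt, 2080L)
})

test_that("motif counts are strand symmetric", {
  set.seed(31)
  cfg <- generator_config("promoter", n_regions = 12L, n_cell_lines = 1L,
                          seed = 77L, n_chromosomes = 1L)
  sim <- simulate_dataset(cfg)
  m <- sim$methylomes[[1L]]
  fwd <- suppressMessages(count_motifs(sim$regions, sim$genome, m))
  # reverse-complement the genome; a CpG at pos p maps to L - 2 - p
  L <- Biostrings::width(sim$genome)[1L]
  g_rc <- Biostrings::reverseComplement(sim$genome)
  names(g_rc) <- names(sim$genome)
  m_rc <- methylome(data.frame(chrom = m$chrom, pos = L - 2L - m$pos,
                               meth_count = m$meth_count,
                               total_count = m$total_count))
  # the C of a CpG at p maps to L - 2 - p, so the interval shifts by one
  rs_rc <- region_set(sim$regions$chrom, L - sim$regions$end - 1L,
                      L - sim$regions$start - 1L,
                      region_id = sim$regions$region_id)
  rev <- suppressMessages(count_motifs(rs_rc, g_rc, m_rc))
  expect_identical(as.integer(fwd), as.integer(rev))
})

test_that("binomial tail matches closed-form special cases", {
  expect_equal(motif_pvalue(10, 10, 0.5), 0)      # full sum: P(X > n) = 0
  expect_equal(motif_pvalue(0, 2, 0.5), 0.75)     # 1 - P(X = 0)
  expect_equal(motif_pvalue(0, 1, 0.3), 0.3)
  expect_equal(motif_pvalue(c(0, 1), 2, 0.5), c(0.75, 0.25))
  expect_error(motif_pvalue(3, 2, 0.5), "within")
  expect_error(motif_pvalue(1, 2, 1.5), "within")
})

test_that("motif classification: null is ns, caps hold, tails exclusive", {
  # equal fg/bg frequency at large n: not significant
  fg <- c(m1 = 500L, m2 = 100L); attr(fg, "n_total") <- 10000L
  bg <- c(m1 = 5000L, m2 = 1000L); attr(bg, "n_total") <- 100000L
  mt <- classify_motifs(fg, bg, n_tests = 2080)
  expect_true(all(mt$status == "ns"))
  expect_true(all(mt$pvalue_bonferroni <= 1))
  expect_true(all(mt$pvalue_under_bonferroni <= 1))
  # over and under are mutually exclusive across random tables
  set.seed(13)
  for (i in 1:20) {
    nm <- sprintf("k%02d", 1:30)
    fg <- stats::setNames(rpois(30, 5), nm); attr(fg, "n_total") <- 400L
    bg <- stats::setNames(rpois(30, 50), nm); attr(bg, "n_total") <- 4000L
    mt <- classify_motifs(fg, bg, alpha = 0.4, correct = FALSE)
    expect_equal(sum(mt$status == "over" & mt$status == "under"), 0L)
    expect_lte(sum(mt$pvalue_raw < 0.4 & mt$pvalue_under < 0.4), 0L)
  }
  expect_error(classify_motifs(fg, structure(bg, n_total = 0L)),
               "background")
})

test_that("motif composition summary counts GC and CpG neighbors", {
  s <- motif_composition_summary("CCCCGGGG")
  expect_equal(s$gc_content, 1)
  expect_equal(s$both_neighbors_cg, 1)
  s2 <- motif_composition_summary("AAACGTTT")
  expect_equal(s2$gc_content, 0.25)
  expect_equal(s2$either_neighbor_cg, 0)
  s3 <- motif_composition_summary(c("CCCCGGGG", "AAACGTTT"))
  expect_equal(s3$gc_content, 0.625)
  expect_equal(s3$n, 2L)
  expect_error(motif_composition_summary(character()), "empty")
})

test_that("motif scores average -log10 of window p-values", {
  g <- tiny_genome(cw = "TAAACGTTTA")
  m <- methylome(data.frame(chrom = "cw", pos = 4L, meth_count = 5L,
                            total_count = 10L))
  rs <- region_set("cw", 0L, 10L, region_id = c("r1"))
  mk_table <- function(p) {
    mt <- data.table::data.table(motif = "AAACGTTT", pvalue_raw = p)
    data.table::setattr(mt, "class", c("motif_table", "data.table",
                                       "data.frame"))
    mt
  }
  expect_equal(motif_score_feature(rs, g, m, mk_table(1))$motif_score, 0)
  s <- motif_score_feature(rs, g, m, mk_table(1e-5))
  expect_equal(s$motif_score, 5)
  expect_false(s$imputed)
  # region with no covered site: imputed 0 with flag
  rs2 <- region_set("cw", c(0L, 0L), c(10L, 2L),
                    region_id = c("r1", "empty"))
  s2 <- motif_score_feature(rs2, g, m, mk_table(1e-5))
  expect_equal(s2$motif_score, c(5, 0))
  expect_identical(s2$imputed, c(FALSE, TRUE))
  # the -log10 p floor keeps scores finite
  expect_true(is.finite(
    motif_score_feature(rs, g, m, mk_table(0))$motif_score))
})
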