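test_that("p-distance follows the pairwise-deletion convention", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACGN", "ACTA"), 1 / 3)   # N column excluded
  expect_equal(p_distance("AC-T", "ACGT"), 0)       # gap column excluded
  expect_equal(p_distance("MKLV", "MKIV", mode = "aa"), 0.25)
  expect_equal(p_distance("MKXV", "MKIV", mode = "aa"), 0)
  expect_error(p_distance("ACG", "ACGT"), "length")
  # symmetry and range on random pairs
  set.seed(11)
  for (i in 1:20) {
    a <- rand_dna(60); b <- rand_dna(60)
    p <- p_distance(a, b)
    expect_equal(p, p_distance(b, a))
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("identical sequences give zero divergence and undefined omega", {
  cds <- "ATGAAACCCGGGTTTCAT"
  r <- nei_gojobori(codon_alignment(cds, cds))
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_false(r$omega_defined)
  expect_true(is.na(r$omega))
})

test_that("hand-enumerated single-codon pairs are reproduced exactly", {
  # TTT vs TTC: both Phe under table 5; only position 3 varies and only
  # TTT<->TTC is synonymous there, so S = 1/3 per codon, Sd = 1
  r <- nei_gojobori(codon_alignment("TTT", "TTC"), correction = "none")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S_sites, 1 / 3)
  expect_equal(r$pS, 3)             # proportion exceeds 1, flagged
  expect_true(r$pS_saturated)
  expect_equal(r$pN, 0)
  expect_equal(jukes_cantor(r$pS), NA_real_)  # correction undefined
  # GAA vs GAT: Glu vs Asp, one nonsynonymous difference, dS = 0
  r2 <- nei_gojobori(codon_alignment("GAA", "GAT"))
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  expect_false(r2$omega_defined)
})

test_that("site and difference counts match the enumeration oracle on all sense-codon pairs", {
  code <- oracle_code()
  sense <- names(code)[code != "*"]
  sites <- mitorfan:::ng_syn_sites(5)
  for (cd in sense)
    expect_equal(sites[[cd]], oracle_syn_sites(cd), tolerance = 1e-12)
  # exhaustive pathway check over the full 60x60 sense-codon table
  set.seed(1)
  for (c1 in sense) for (c2 in sense) {
    got <- mitorfan:::ng_pair_diffs(c1, c2)
    want <- oracle_pair_diffs(c1, c2)
    expect_equal(unname(got), want, tolerance = 1e-12)
    ndif <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(sum(got), ndif, tolerance = 1e-12)  # Sd + Nd = diffs
  }
})

test_that("S + N sites always sum to 3 per compared codon", {
  set.seed(12)
  for (i in 1:10) {
    n <- 30
    a <- paste(replicate(n, {
      repeat { cd <- rand_dna(3); if (oracle_code()[[cd]] != "*") break }
      cd
    }), collapse = "")
    r <- nei_gojobori(codon_alignment(a, a))
    expect_equal(r$S_sites + r$N_sites, 3 * n, tolerance = 1e-9)
  }
})

test_that("codon alignments reject malformed input", {
  expect_error(codon_alignment("ATGAA", "ATGAA"), "divisible")
  expect_error(codon_alignment("ATG-AATAC", "ATGAAATAC"), "whole-codon")
  expect_error(codon_alignment("ATGTAAAAA", "ATGAAAAAA"), "internal stop")
  # gapped codon columns are excluded from the counts
  r <- nei_gojobori(codon_alignment("ATG---AAA", "ATGCCCAAA"))
  expect_equal(r$n_codons, 2)
})

test_that("protein alignment threads codons correctly", {
  # identical CDS up to a whole-codon deletion
  a <- "ATGAAACCCGGGTGTCATTAA"
  b <- "ATGAAAGGGTGTCATTAA"       # CCC codon missing
  aln <- build_codon_alignment(a, b, gene = "toy")
  expect_equal(nchar(aln$a), nchar(aln$b))
  expect_equal(gsub("-", "", aln$b), strip_stop <- substr(b, 1, 15))
  expect_equal(sum(mitorfan:::split_codons(aln$b) == "---"), 1)
})

test_that("RSCU matches direct counting", {
  # a two-codon family used equally -> both 1.0
  r <- rscu("AAAAAG")              # Lys: AAA, AAG
  expect_equal(r$rscu[r$codon %in% c("AAA", "AAG")], c(1, 1))
  # a four-codon family used through one codon -> 4, 0, 0, 0
  r2 <- rscu("GGGGGGGGG")          # Gly x3, all GGG
  expect_equal(r2$rscu[r2$codon == "GGG"], 4)
  expect_equal(sum(r2$rscu[r2$aa == "G"]), 4)
  expect_true("K" %in% attr(r2, "unused_families"))
  # random CDS set against an independent counting script
  set.seed(13)
  cds <- vapply(1:5, function(i) paste(replicate(50, {
    repeat { cd <- rand_dna(3); if (oracle_code()[[cd]] != "*") break }
    cd
  }), collapse = ""), character(1))
  got <- rscu(cds)
  cods <- unlist(lapply(cds, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  code <- oracle_code()
  for (i in seq_len(nrow(got))) {
    fam <- names(code)[code == got$aa[i] & code != "*"]
    tot <- sum(cods %in% fam)
    want <- if (tot == 0) 0 else
      sum(cods == got$codon[i]) * length(fam) / tot
    expect_equal(got$rscu[i], want)
  }
})

test_that("base composition fractions, AT% and skews are exact", {
  c1 <- base_composition("AATT")
  expect_equal(c1$AT_percent, 100)
  expect_equal(c1$AT_skew, 0)
  expect_equal(base_composition("GGGC")$GC_skew, 0.5)
  set.seed(14)
  s <- rand_dna(500)
  cc <- base_composition(s)
  ch <- strsplit(s, "")[[1]]
  expect_equal(cc$fA + cc$fC + cc$fG + cc$fT, 1)
  expect_equal(cc$fA, mean(ch == "A"))
  expect_equal(cc$AT_skew,
               (sum(ch == "A") - sum(ch == "T")) /
                 (sum(ch == "A") + sum(ch == "T")))
})

test_that("F-vs-M report: self-comparison is all zeros, rRNA rows are nt-only", {
  g <- mini_ancestor()
  expect_no_warning(rep <- fm_divergence_report(g, g))
  pcg <- rep[!is.na(rep$n_codons), ]
  expect_equal(max(pcg$p_nt), 0)
  expect_equal(max(pcg$dN), 0)
  expect_true("concatenated_PCG" %in% rep$gene)
  rr <- rep[rep$gene %in% c("rrnS", "rrnL"), ]
  expect_equal(nrow(rr), 2)
  expect_equal(rr$p_nt, c(0, 0))
  expect_true(all(is.na(rr$omega)))
})

test_that("estimated omega recovers the generator's target", {
  # 10,000-codon single-gene genome, moderate divergence; the
  # generator's accept/reject control should be recovered by the
  # counting estimator within 0.1
  set.seed(15)
  w <- c(A = .325, C = .175, G = .175, T = .325)
  cds <- mitorfan:::rand_cds(30003, w)
  g <- annotated_genome(
    "BIG", cds, data.frame(name = "cox1", start = 0L, end = 30003L,
                           strand = "+"))
  for (om in c(0.1, 0.33, 1.0)) {
    m <- evolve_genome(g, 0.25, target_omega = om,
                       seed = 500 + round(om * 100))
    aln <- codon_alignment(substr(g$sequence, 4, 30000),
                           substr(m$sequence, 4, 30000))
    r <- nei_gojobori(aln)
    expect_true(r$omega_defined)
    expect_lt(abs(r$omega - om), 0.1)
  }
})
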