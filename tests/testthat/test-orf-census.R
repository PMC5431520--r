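# Naive ORF oracle: every start codon runs to its nearest in-frame
# stop; longest ORF per stop; both strands.
oracle_orfs <- function(seq, min_nt = 33) {
  code <- Biostrings::getGeneticCode("5")
  starts <- c("ATG", "ATA", "ATT", "ATC", "GTG", "TTG")
  stops <- names(code)[code == "*"]
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    by_stop <- list()
    for (i in seq_len(max(n - 5, 0))) {
      if (!substr(s, i, i + 2) %in% starts) next
      j <- i + 3
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (cod %in% stops) {
          key <- paste(strand, j)
          if (is.null(by_stop[[key]]) || by_stop[[key]] > i)
            by_stop[[key]] <- i
          break
        }
        j <- j + 3
      }
    }
    for (key in names(by_stop)) {
      i <- by_stop[[key]]
      j <- as.integer(strsplit(key, " ")[[1]][2])
      len <- j + 2 - i + 1
      if (len < min_nt) next
      out[[length(out) + 1]] <- data.frame(
        strand = strand, nt_length = len,
        nt = substr(s, i, j + 2), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(strand = character(),
                                      nt_length = integer(),
                                      nt = character()))
  do.call(rbind, out)
}

test_that("translation under the invertebrate code honours both start policies", {
  expect_equal(translate_mt("ATGAAATAA"), "MK")
  expect_equal(translate_mt("ATGAAATAA", start_policy = "force_met"), "MK")
  expect_equal(translate_mt("ATTAAATAA"), "IK")
  expect_equal(translate_mt("ATTAAATAA", start_policy = "force_met"), "MK")
  # table-5 idiosyncrasies: AGA/AGG = Ser, ATA = Met, TGA = Trp
  expect_equal(translate_mt("AGAAGGATATGATAA"), "SSMW")
  expect_equal(translate_mt("ATGANATAA"), "MX")
  expect_error(translate_mt("ATGTAAAAATAA"), "internal stop")
  expect_equal(translate_mt("ATGTAAAAATAA", allow_internal_stop = TRUE),
               "M*K")
  expect_error(translate_mt("ATGAAAT"), "divisible")
  expect_error(translate_mt("ATGAAUTAA"), "non-ACGTN")
})

test_that("ORF finder honours the 33-nt minimum with a stop inside the UR", {
  # 32-nt UR: longest conceivable ORF is 30 nt -> nothing
  ur32 <- paste0("ATG", paste(rep("AAA", 8), collapse = ""), "TAAGC")
  expect_equal(nrow(find_orfs(substr(ur32, 1, 32))), 0)
  # the same construct at 33 nt qualifies
  ur <- paste0("CC", "ATG", paste(rep("AAA", 9), collapse = ""), "TAA",
               "GG")
  orfs <- find_orfs(ur)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$nt_length, 33)
  expect_equal(orfs$protein_as_coded, "MKKKKKKKKK")
  expect_equal(orfs$start, 2)
  expect_equal(orfs$end, 35)
  # an ORF whose stop falls outside the UR is not called
  expect_equal(nrow(find_orfs(paste0(
    "CC", "ATG", paste(rep("AAA", 9), collapse = "")))), 0)
})

test_that("ORF finder matches the brute-force oracle on random URs", {
  set.seed(31)
  for (rep in 1:15) {
    ur <- rand_dna(300)
    got <- find_orfs(ur)
    want <- oracle_orfs(ur)
    expect_equal(nrow(got), nrow(want))
    key <- function(df) sort(paste(df$strand, df$nt_length, df$nt))
    expect_equal(key(got), key(want))
    # every call re-translates to its stored proteins
    if (nrow(got)) {
      expect_equal(got$protein_as_coded,
                   vapply(got$nt, translate_mt, character(1),
                          USE.NAMES = FALSE))
      expect_true(all(got$nt_length %% 3 == 0))
      expect_true(all(nchar(got$protein_as_coded) ==
                        got$nt_length / 3 - 1))
      expect_true(all(nchar(got$protein_as_coded) >= 10))
    }
  }
})

test_that("reverse-complementing a UR swaps strands but keeps the ORF set", {
  set.seed(32)
  ur <- rand_dna(400)
  a <- find_orfs(ur)
  b <- find_orfs(revcomp(ur))
  expect_equal(nrow(a), nrow(b))
  key <- function(df, flip = FALSE) {
    strand <- if (flip) chartr("+-", "-+", df$strand) else df$strand
    sort(paste(strand, df$nt_length, df$nt))
  }
  expect_equal(key(a), key(b, flip = TRUE))
  # and coordinates mirror: forward-strand starts become end offsets
  aplus <- a[a$strand == "+", ]
  bminus <- b[b$strand == "-", ]
  expect_equal(sort(aplus$start), sort(nchar(ur) - bminus$end))
})

test_that("ORF count is monotone non-increasing in min_codons", {
  set.seed(33)
  ur <- rand_dna(600)
  counts <- vapply(c(10, 15, 20, 30, 50),
                   function(k) nrow(find_orfs(ur, min_codons = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("census recovers planted ORFs and matches the scan oracle", {
  # genome whose URs carry three planted ORFs (12, 15, 40 codons) plus
  # whatever chance ORFs the random sequence contains: the census must
  # agree with the independent oracle scan and contain every plant
  set.seed(34)
  mk_orf <- function(ncod)
    paste0("ATG", paste(replicate(ncod - 2, {
      repeat {
        c3 <- rand_dna(3)
        if (!c3 %in% c("TAA", "TAG")) break
      }
      c3
    }), collapse = ""), "TAA")
  cox1 <- rand_dna(90)
  spacer <- function(n) paste(rep("C", n), collapse = "")
  planted <- c(mk_orf(12), mk_orf(15), mk_orf(40))
  seq <- paste0(spacer(40), cox1, spacer(10), planted[1], spacer(10),
                planted[2], spacer(10), planted[3], spacer(40))
  g <- annotated_genome(
    "PLANT", seq,
    features = data.frame(name = "cox1", start = 40L,
                          end = 40L + 90L, strand = "+"),
    organism = "PLANT")
  cen <- orf_census(g)
  urs <- extract_unassigned_regions(g)
  want <- do.call(rbind, lapply(urs$sequence, oracle_orfs))
  expect_equal(cen$total, nrow(want))
  expect_setequal(cen$orfs$nt, want$nt)
  # each planted ORF is called, possibly extended to an upstream start
  # codon sharing its stop (the longest-per-stop rule)
  for (p in planted)
    expect_true(any(endsWith(cen$orfs$nt, p)))
  expect_match(cen$orfs$id, "^PLANT_UR_\\d+_\\d+$")
  # annotated ORFan genes are features, not UR content
  g2 <- g
  g2$features <- rbind(g2$features,
                       data.frame(name = "M-orf", kind = "ORFan",
                                  start = 150L, end = 186L, strand = "+",
                                  codon_table = 5L, copy_index = 1L))
  g2$features <- mitorfan:::as_feature_table(g2$features)
  cen2 <- orf_census(g2)
  expect_lt(cen2$total, cen$total)
  expect_false(any(grepl("M-orf", cen2$orfs$id)))
  # zero-UR genome: zero ORFs
  tiled <- annotated_genome(
    "TILED", rand_dna(60),
    features = data.frame(name = "cox1", start = 0L, end = 60L,
                          strand = "+"))
  expect_equal(orf_census(tiled)$total, 0)
})

test_that("census IDs follow <prefix>_UR_<index>_<k> with 5'-3' ordinals", {
  st <- mini_study()
  cen <- orf_census(st$genomes[1:2])
  expect_true(all(grepl("^S(alp|bra|cha)[FMH]_UR_\\d+_\\d+$",
                        cen$orfs$id)))
  for (gid in unique(cen$orfs$genome_id)) {
    o <- cen$orfs[cen$orfs$genome_id == gid, ]
    for (u in unique(o$ur_index)) {
      ou <- o[o$ur_index == u, ]
      expect_equal(ou$k, seq_len(nrow(ou)))
      plus <- ou[ou$strand == "+", ]
      if (nrow(plus) > 1) expect_false(is.unsorted(plus$start))
    }
  }
})
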