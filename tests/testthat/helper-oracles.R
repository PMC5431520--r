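# Independent brute-force oracles used across the suite. Each oracle is
# deliberately naive: direct enumeration with no shared code path with
# the package implementation it checks.

# ---- Nei-Gojobori oracle ----------------------------------------------

oracle_code <- function() Biostrings::getGeneticCode("5")

# Synonymous site count of one codon: enumerate the 9 single-nt changes.
oracle_syn_sites <- function(codon) {
  code <- oracle_code()
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mut <- ch; mut[p] <- b
    m <- paste(mut, collapse = "")
    if (code[[m]] != "*" && code[[m]] == code[[codon]]) s <- s + 1 / 3
  }
  s
}

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# Pathway-averaged (sd, nd) for a codon pair; pathways through stop
# codons excluded, all pathways used if every one is blocked.
oracle_pair_diffs <- function(c1, c2) {
  code <- oracle_code()
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(0, 0))
  res <- list()
  for (path in perms_of(pos)) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (k in seq_along(path)) {
      nxt <- cur; nxt[path[k]] <- b[path[k]]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && k < length(path)) blocked <- TRUE
      if (aa1 != "*" && aa2 != "*" && aa1 == aa2) sd <- sd + 1 else
        nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(sd, nd, blocked)
  }
  m <- do.call(rbind, res)
  use <- if (all(m[, 3] == 1)) rep(TRUE, nrow(m)) else m[, 3] == 0
  c(mean(m[use, 1]), mean(m[use, 2]))
}

# ---- TDRL oracle -------------------------------------------------------

# All orders reachable from `tokens` (linear) by one tandem duplication
# of a contiguous block followed by loss of one copy of each gene.
oracle_tdrl_reachable <- function(tokens) {
  n <- length(tokens)
  seen <- new.env(parent = emptyenv())
  assign(paste(tokens, collapse = " "), TRUE, envir = seen)  # empty block
  for (i in seq_len(n)) for (j in i:n) {
    blk <- tokens[i:j]; b <- length(blk)
    pre <- if (i > 1) tokens[1:(i - 1)] else character()
    post <- if (j < n) tokens[(j + 1):n] else character()
    for (mask in 0:(2^b - 1)) {
      first <- as.logical(bitwAnd(mask, 2^(seq_len(b) - 1)))
      out <- c(pre, blk[first], blk[!first], post)
      assign(paste(out, collapse = " "), TRUE, envir = seen)
    }
  }
  seen
}

oracle_tdrl_feasible <- function(source_tokens, target_tokens) {
  seen <- oracle_tdrl_reachable(source_tokens)
  exists(paste(target_tokens, collapse = " "), envir = seen)
}

# ---- Smith-Waterman oracle --------------------------------------------

# Exhaustive local alignment: enumerate every set of aligned columns
# (strictly increasing index pairs); gap of length L costs
# gap_open + gap_ext * L on each sequence independently.
oracle_sw_score <- function(a, b, submat, gap_open, gap_ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  gap_cost <- function(g) if (g == 0) 0 else gap_open + gap_ext * g
  best <- -Inf
  for (k in 1:min(m, n)) {
    ia_sets <- utils::combn(m, k, simplify = FALSE)
    ib_sets <- utils::combn(n, k, simplify = FALSE)
    for (ia in ia_sets) for (ib in ib_sets) {
      sc <- sum(submat[cbind(ca[ia], cb[ib])])
      if (k > 1) {
        sc <- sc - sum(vapply(seq_len(k - 1), function(t)
          gap_cost(ia[t + 1] - ia[t] - 1) + gap_cost(ib[t + 1] - ib[t] - 1),
          numeric(1)))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# ---- misc --------------------------------------------------------------

rand_dna <- function(n, at = 0.65) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}
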