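# Sequence divergence and composition statistics: p-distances,
# Nei-Gojobori dN/dS with Jukes-Cantor correction, RSCU, base composition.

#' Proportion of differing sites between two aligned sequences
#'
#' Columns containing a gap (`-`) in either sequence, or an ambiguous
#' symbol (`N` for nucleotides, `X` for amino acids), are excluded from
#' both numerator and denominator (pairwise deletion).
#'
#' @param a,b Aligned sequences of equal length.
#' @param mode `"nt"` or `"aa"`.
#' @return Fraction of compared sites that differ, in `[0, 1]`; `NaN`
#'   when no site is comparable.
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
p_distance <- function(a, b, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length; align first")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  excl <- if (mode == "nt") c("-", "N", "?") else c("-", "X", "?")
  ok <- !(ca %in% excl) & !(cb %in% excl)
  if (!any(ok)) return(NaN)
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Jukes-Cantor distance correction
#'
#' @param p Proportion of differing sites.
#' @return `-3/4 * log(1 - 4/3 * p)`; `NA` where `p >= 3/4` (correction
#'   undefined).
#' @export
jukes_cantor <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

#' Pair of aligned coding sequences
#'
#' Container for a codon-aware pairwise alignment: equal-length gapped
#' coding sequences whose gaps occur only in whole-codon units and whose
#' ungapped sequences contain no internal stop codons.
#'
#' @param a,b Gapped coding sequences of equal length.
#' @param gene Source gene name.
#' @param table NCBI translation table id used for validation.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(a, b, gene = NA_character_, table = 5) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("alignment length not divisible by 3")
  for (s in c(a, b)) {
    cods <- split_codons(s)
    partial <- grepl("-", cods) & cods != "---"
    if (any(partial)) stop("gaps must occur in whole-codon units")
    ung <- gsub("-", "", s)
    if (nchar(ung) >= 3L)
      translate_mt(ung, table = table)       # errors on internal stops
  }
  structure(list(a = a, b = b, gene = gene, table = table),
            class = "codon_alignment")
}

# Strip a terminal stop codon from a CDS, if present.
strip_terminal_stop <- function(nt, table = 5) {
  code <- mt_genetic_code(table)
  if (nchar(nt) %% 3L == 0L && nchar(nt) >= 3L) {
    last <- substr(nt, nchar(nt) - 2L, nchar(nt))
    if (!grepl("N", last) && code[[last]] == "*")
      nt <- substr(nt, 1L, nchar(nt) - 3L)
  }
  nt
}

#' Build a codon alignment from two unaligned coding sequences
#'
#' Proteins are aligned globally (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()], BLOSUM62, gap open 11 / extend 1)
#' and the codons are threaded through the protein alignment. Terminal
#' stop codons are stripped first.
#'
#' @param cds_a,cds_b Coding sequences, lengths divisible by 3.
#' @param gene Gene name recorded on the result.
#' @param table NCBI translation table id.
#' @return A `codon_alignment`.
#' @export
build_codon_alignment <- function(cds_a, cds_b, gene = NA_character_,
                                  table = 5) {
  cds_a <- strip_terminal_stop(toupper(cds_a), table)
  cds_b <- strip_terminal_stop(toupper(cds_b), table)
  pa <- translate_mt(cds_a, table, allow_internal_stop = TRUE)
  pb <- translate_mt(cds_b, table, allow_internal_stop = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  thread <- function(gapped_aa, cds) {
    cods <- split_codons(cds)
    out <- character(length(gapped_aa)); j <- 0L
    for (i in seq_along(gapped_aa)) {
      if (gapped_aa[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- cods[j] }
    }
    paste(out, collapse = "")
  }
  codon_alignment(thread(ga, cds_a), thread(gb, cds_b), gene = gene,
                  table = table)
}

# Translate a gapped coding sequence codon-wise; '---' columns become
# '-' so protein p-distance can exclude them.
translate_gapped <- function(s, table = 5) {
  code <- mt_genetic_code(table)
  cods <- split_codons(s)
  aa <- unname(code[cods])
  aa[cods == "---"] <- "-"
  aa[is.na(aa) & grepl("N", cods)] <- "X"
  aa[is.na(aa)] <- "-"
  paste(aa, collapse = "")
}

# ---- Nei-Gojobori machinery -------------------------------------------

.ng_env <- new.env(parent = emptyenv())

small_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in small_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# Per-codon expected synonymous site count (NG86): at each position the
# fraction of the three single-nt changes that are synonymous; changes to
# stop codons count as nonsynonymous so that S + N = 3 per codon.
ng_syn_sites <- function(table = 5) {
  key <- paste0("sites", table)
  if (!is.null(.ng_env[[key]])) return(.ng_env[[key]])
  code <- mt_genetic_code(table)
  bases <- c("A", "C", "G", "T")
  out <- stats::setNames(numeric(length(code)), names(code))
  for (cd in names(code)) {
    if (code[[cd]] == "*") { out[[cd]] <- NA_real_; next }
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, ch[p])) {
      mut <- ch; mut[p] <- b
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] != "*" && code[[mutc]] == code[[cd]]) s <- s + 1 / 3
    }
    out[[cd]] <- s
  }
  .ng_env[[key]] <- out
  out
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one
# codon pair. Mutation orderings are weighted equally; pathways passing
# through a stop codon are excluded (when every pathway is blocked, all
# are used and steps through stops count as nonsynonymous).
ng_pair_diffs <- function(c1, c2, table = 5) {
  key <- paste0("pair", table)
  if (is.null(.ng_env[[key]]))
    .ng_env[[key]] <- new.env(parent = emptyenv())
  memo <- .ng_env[[key]]
  id <- paste0(c1, c2)
  hit <- memo[[id]]
  if (!is.null(hit)) return(hit)
  code <- mt_genetic_code(table)
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- small_perms(pos)
  tally <- matrix(NA_real_, length(paths), 2)
  blocked <- logical(length(paths))
  for (i in seq_along(paths)) {
    cur <- ch1; sd <- 0; nd <- 0
    for (step in seq_along(paths[[i]])) {
      p <- paths[[i]][step]
      nxt <- cur; nxt[p] <- ch2[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && step < length(paths[[i]])) blocked[i] <- TRUE
      if (aa_cur != "*" && aa_nxt != "*" && aa_cur == aa_nxt) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    tally[i, ] <- c(sd, nd)
  }
  use <- if (all(blocked)) rep(TRUE, length(paths)) else !blocked
  res <- c(sd = mean(tally[use, 1]), nd = mean(tally[use, 2]))
  memo[[id]] <- res
  res
}

#' Nei-Gojobori dN/dS for a codon alignment
#'
#' The counting estimator of synonymous and nonsynonymous divergence:
#' expected synonymous site fractions per codon come from enumerating all
#' single-nucleotide changes under the translation table (changes to stop
#' codons count as nonsynonymous, so sites sum to 3 per codon); observed
#' differences at multi-hit codons are averaged over all mutation
#' orderings, excluding pathways through stop codons; the Jukes-Cantor
#' correction `d = -3/4 log(1 - 4/3 p)` is applied by default. Codon
#' columns containing a gap or `N` in either sequence are excluded
#' (pairwise deletion).
#'
#' @param aln A `codon_alignment` (or a length-2 character vector of
#'   equal-length coding sequences).
#' @param table NCBI translation table id.
#' @param correction `"jukes_cantor"` or `"none"`.
#' @return An object of class `divergence_result`: list with `p_nt`,
#'   `p_aa`, `n_codons`, `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega` (NA with `omega_defined = FALSE` when `dS` is 0
#'   or a correction is undefined) and flags.
#' @export
nei_gojobori <- function(aln, table = 5,
                         correction = c("jukes_cantor", "none")) {
  correction <- match.arg(correction)
  if (!inherits(aln, "codon_alignment")) {
    stopifnot(is.character(aln), length(aln) == 2L)
    aln <- codon_alignment(aln[1], aln[2], table = table)
  }
  table <- aln$table
  ca <- split_codons(aln$a); cb <- split_codons(aln$b)
  ok <- !grepl("[-N]", ca) & !grepl("[-N]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  n_codons <- length(ca)
  sites <- ng_syn_sites(table)
  S <- sum((sites[ca] + sites[cb]) / 2)
  N <- 3 * n_codons - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(n_codons)) {
    if (ca[i] == cb[i]) next
    d <- ng_pair_diffs(ca[i], cb[i], table)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  if (correction == "jukes_cantor") {
    dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)
  } else {
    dS <- pS; dN <- pN
  }
  omega_defined <- !is.na(dS) && !is.na(dN) && dS > 0
  p_aa <- p_distance(translate_gapped(aln$a, table),
                     translate_gapped(aln$b, table), "aa")
  res <- list(gene = aln$gene,
              p_nt = p_distance(aln$a, aln$b, "nt"), p_aa = p_aa,
              n_codons = n_codons, S_sites = S, N_sites = N,
              Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
              omega = if (omega_defined) dN / dS else NA_real_,
              omega_defined = omega_defined,
              pS_saturated = !is.na(pS) && pS >= 0.75,
              pN_saturated = !is.na(pN) && pN >= 0.75)
  class(res) <- "divergence_result"
  res
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("<divergence_result>%s %d codons\n",
              if (is.na(x$gene)) "" else paste0(" ", x$gene), x$n_codons))
  cat(sprintf("  p_nt %.4f  p_aa %.4f\n", x$p_nt, x$p_aa))
  cat(sprintf("  S %.2f N %.2f  Sd %.2f Nd %.2f  pS %.4f pN %.4f\n",
              x$S_sites, x$N_sites, x$Sd, x$Nd, x$pS, x$pN))
  cat(sprintf("  dS %.4f dN %.4f  omega %s\n", x$dS, x$dN,
              if (x$omega_defined) sprintf("%.4f", x$omega) else
                "undefined (dS = 0)"))
  invisible(x)
}

as_row.divergence_result <- function(x) {
  data.frame(gene = x$gene, n_codons = x$n_codons, p_nt = x$p_nt,
             p_aa = x$p_aa, S_sites = x$S_sites, N_sites = x$N_sites,
             Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN, dS = x$dS,
             dN = x$dN, omega = x$omega, stringsAsFactors = FALSE)
}

#' Relative synonymous codon usage
#'
#' `RSCU(codon) = count(codon) * family_size / family_total`, computed
#' over all coding sequences pooled; stop codons are excluded. A family
#' with zero usage gets RSCU 0 for all members and is flagged.
#'
#' @param cds_set Character vector of coding sequences (lengths divisible
#'   by 3).
#' @param table NCBI translation table id.
#' @return Data frame with columns `codon`, `aa`, `count`, `rscu`, and an
#'   attribute `unused_families` naming amino acids never observed.
#' @export
rscu <- function(cds_set, table = 5) {
  code <- mt_genetic_code(table)
  if (any(nchar(cds_set) %% 3L != 0L))
    stop("coding sequence length not divisible by 3")
  cods <- unlist(lapply(toupper(cds_set), split_codons))
  cods <- cods[!grepl("N", cods)]
  sense <- names(code)[code != "*"]
  counts <- table(factor(cods, levels = sense))
  aa <- code[sense]
  rscu_val <- numeric(length(sense))
  unused <- character()
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    tot <- sum(counts[fam])
    if (tot == 0) { rscu_val[match(fam, sense)] <- 0; unused <- c(unused, a) }
    else rscu_val[match(fam, sense)] <- as.numeric(counts[fam]) *
        length(fam) / tot
  }
  out <- data.frame(codon = sense, aa = unname(aa),
                    count = as.integer(counts), rscu = rscu_val,
                    stringsAsFactors = FALSE)
  attr(out, "unused_families") <- unused
  out
}

#' Base composition, AT content and strand skews
#'
#' @param seq Nucleotide sequence; `N` symbols are excluded from all
#'   counts.
#' @return A one-row data frame: `fA`, `fC`, `fG`, `fT` (fractions summing
#'   to 1), `AT_percent`, `AT_skew` = (A - T)/(A + T) and `GC_skew` =
#'   (G - C)/(G + C).
#' @export
base_composition <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (!length(ch)) stop("no unambiguous bases")
  n <- length(ch)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(ch == b), numeric(1))
  data.frame(fA = cnt[["A"]] / n, fC = cnt[["C"]] / n,
             fG = cnt[["G"]] / n, fT = cnt[["T"]] / n,
             AT_percent = 100 * (cnt[["A"]] + cnt[["T"]]) / n,
             AT_skew = (cnt[["A"]] - cnt[["T"]]) /
               max(cnt[["A"]] + cnt[["T"]], 1),
             GC_skew = (cnt[["G"]] - cnt[["C"]]) /
               max(cnt[["G"]] + cnt[["C"]], 1))
}

#' F-versus-M divergence report
#'
#' Pairs the orthologous protein-coding genes of a female- and a
#' male-transmitted genome by name, computes per-gene p-distances and
#' Nei-Gojobori statistics, and adds the headline row computed on the
#' concatenation of all 13 codon alignments. rRNA genes (rrnS, rrnL)
#' contribute nucleotide p-distances only. Genes missing from either
#' genome are skipped with a warning.
#'
#' @param f,m `mito_genome` objects (typically routes F and M of one
#'   species).
#' @param alignments Optional named list of pre-built `codon_alignment`
#'   objects per gene; otherwise alignments are built with
#'   [build_codon_alignment()].
#' @param table NCBI translation table id.
#' @return Data frame with one row per gene, rRNA p-distance rows, and a
#'   `concatenated_PCG` row.
#' @export
fm_divergence_report <- function(f, m, alignments = NULL, table = 5) {
  stopifnot(inherits(f, "mito_genome"), inherits(m, "mito_genome"))
  rows <- list(); cat_a <- character(); cat_b <- character()
  for (gene in .PCG_NAMES) {
    fi <- which(f$features$name == gene & f$features$kind == "PCG")
    mi <- which(m$features$name == gene & m$features$kind == "PCG")
    if (!length(fi) || !length(mi)) {
      warning("gene ", gene, " missing from one genome; skipped",
              call. = FALSE)
      next
    }
    aln <- if (!is.null(alignments) && gene %in% names(alignments))
      alignments[[gene]]
    else build_codon_alignment(feature_seq(f, fi[1]), feature_seq(m, mi[1]),
                               gene = gene, table = table)
    rows[[gene]] <- as_row.divergence_result(nei_gojobori(aln, table))
    cat_a <- c(cat_a, aln$a); cat_b <- c(cat_b, aln$b)
  }
  out <- do.call(rbind, rows)
  if (length(cat_a)) {
    conc <- codon_alignment(paste(cat_a, collapse = ""),
                            paste(cat_b, collapse = ""),
                            gene = "concatenated_PCG", table = table)
    out <- rbind(out, as_row.divergence_result(nei_gojobori(conc, table)))
  }
  for (rg in .RRNA_NAMES) {
    fi <- which(f$features$name == rg)
    mi <- which(m$features$name == rg)
    if (!length(fi) || !length(mi)) next
    sa <- feature_seq(f, fi[1]); sb <- feature_seq(m, mi[1])
    if (nchar(sa) != nchar(sb)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(sa), Biostrings::DNAString(sb),
        type = "global")
      sa <- as.character(Biostrings::alignedPattern(aln))
      sb <- as.character(Biostrings::alignedSubject(aln))
    }
    out <- rbind(out, data.frame(
      gene = rg, n_codons = NA_integer_, p_nt = p_distance(sa, sb, "nt"),
      p_aa = NA_real_, S_sites = NA_real_, N_sites = NA_real_,
      Sd = NA_real_, Nd = NA_real_, pS = NA_real_, pN = NA_real_,
      dS = NA_real_, dN = NA_real_, omega = NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
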