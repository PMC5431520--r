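# ORF census in unassigned regions under the invertebrate mitochondrial
# genetic code, with the dual start-codon translation policies and the
# local-alignment homology-screen ladder.

#' Genetic code and start codons for a translation table
#'
#' Thin accessors over [Biostrings::getGeneticCode()]. Table 5 (the
#' invertebrate mitochondrial code: AGA/AGG = Ser, ATA = Met, TGA = Trp)
#' is the default throughout the package.
#'
#' @param table NCBI translation table id.
#' @return `mt_genetic_code()`: named character vector codon -> amino
#'   acid; `mt_start_codons()`: character vector of initiation codons.
#' @export
mt_genetic_code <- function(table = 5) {
  Biostrings::getGeneticCode(as.character(table))
}

#' @rdname mt_genetic_code
#' @export
mt_start_codons <- function(table = 5) {
  code <- mt_genetic_code(table)
  alt <- attr(code, "alt_init_codons")
  sort(unique(c("ATG", names(code)[code == "M"], alt)))
}

split_codons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

# All resolutions of a codon containing N; codons without N return
# themselves.
codon_could_be_stop <- function(codon, stops) {
  if (!grepl("N", codon)) return(codon %in% stops)
  chars <- strsplit(codon, "")[[1]]
  opts <- lapply(chars, function(ch) if (ch == "N") c("A", "C", "G", "T")
                 else ch)
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  any(apply(grid, 1, paste, collapse = "") %in% stops)
}

#' Translate a mitochondrial coding sequence
#'
#' Two start-codon policies mirror the two protein sets used for ORF
#' screening: `"as_coded"` translates an alternative initiation codon with
#' its ordinary amino acid, while `"force_met"` always writes methionine
#' as the first residue regardless of the first codon.
#'
#' @param nt Coding nucleotide sequence, length divisible by 3.
#' @param table NCBI translation table id (default 5).
#' @param start_policy `"as_coded"` or `"force_met"`.
#' @param allow_internal_stop If `TRUE`, internal stops become `*` instead
#'   of raising an error.
#' @return Amino acid string; a terminal stop codon is dropped. Codons
#'   containing `N` translate to `X`.
#' @export
#' @examples
#' translate_mt("ATTAAATAA")                          # "IK"
#' translate_mt("ATTAAATAA", start_policy = "force_met")  # "MK"
translate_mt <- function(nt, table = 5,
                         start_policy = c("as_coded", "force_met"),
                         allow_internal_stop = FALSE) {
  start_policy <- match.arg(start_policy)
  nt <- toupper(nt)
  if (grepl("[^ACGTN]", nt)) stop("sequence contains non-ACGTN symbols")
  if (nchar(nt) %% 3L != 0L) stop("length not divisible by 3")
  code <- mt_genetic_code(table)
  codons <- split_codons(nt)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"                    # codons containing N
  n <- length(aa)
  if (n && aa[n] == "*") { aa <- aa[-n]; codons <- codons[-n]; n <- n - 1L }
  if (any(aa == "*")) {
    if (!allow_internal_stop)
      stop("internal stop codon at codon ",
           paste(which(aa == "*"), collapse = ","))
  }
  if (n && start_policy == "force_met") aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Find open reading frames in an unassigned region
#'
#' Scans both strands and all three frames of a UR sequence. Under the
#' default `"start_to_stop"` mode an ORF runs from an initiation codon of
#' the translation table to the nearest in-frame stop, both fully inside
#' the UR; when several start codons share a stop only the longest ORF is
#' kept. The `"stop_to_stop"` mode instead takes the whole region between
#' consecutive in-frame stops. The minimum length of 10 encoded amino
#' acids plus the stop codon corresponds to 33 nt.
#'
#' @param ur A one-row UR data frame from [extract_unassigned_regions()]
#'   or a plain sequence string.
#' @param min_codons Minimum number of amino-acid-encoding codons
#'   (default 10; the stop codon is additional).
#' @param table NCBI translation table id (default 5).
#' @param mode ORF definition, `"start_to_stop"` (default) or
#'   `"stop_to_stop"`.
#' @return A data frame of ORF calls with 0-based half-open coordinates on
#'   the forward strand of the UR, strand, strand-local frame, nucleotide
#'   length (including the stop codon), the nucleotide sequence and both
#'   protein translations. Ordinals `k` run 5' to 3' on the plus strand,
#'   then 5' to 3' on the minus strand.
#' @export
find_orfs <- function(ur, min_codons = 10L, table = 5,
                      mode = c("start_to_stop", "stop_to_stop")) {
  mode <- match.arg(mode)
  if (is.data.frame(ur)) {
    seqs <- ur$sequence; ur_index <- ur$index
  } else {
    seqs <- as.character(ur); ur_index <- rep(NA_integer_, length(seqs))
  }
  code <- mt_genetic_code(table)
  stops <- names(code)[code == "*"]
  starts_set <- mt_start_codons(table)
  min_nt <- (min_codons + 1L) * 3L
  out <- list()
  for (u in seq_along(seqs)) {
    s_fwd <- toupper(seqs[u])
    L <- nchar(s_fwd)
    calls <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") s_fwd else revcomp(s_fwd)
      for (frame in 0:2) {
        ncod <- (L - frame) %/% 3L
        if (ncod < min_codons + 1L) next
        cod <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                         frame + 3L * seq_len(ncod))
        is_stop <- cod %in% stops
        ambiguous_stop <- !is_stop & grepl("N", cod) &
          vapply(cod, codon_could_be_stop, logical(1), stops = stops)
        prev_end <- 0L                 # codon index of last boundary
        for (st in which(is_stop)) {
          if (st <= prev_end) next
          first <- prev_end + 1L
          if (mode == "start_to_stop") {
            if (st - 1L < first) { prev_end <- st; next }
            cand <- which(cod[first:(st - 1L)] %in% starts_set)
            if (!length(cand)) { prev_end <- st; next }
            first <- first + cand[1] - 1L
          }
          prev_end <- st
          nt_len <- (st - first + 1L) * 3L
          if (nt_len < min_nt) next
          if (any(ambiguous_stop[first:st])) next   # stop-ambiguous codon
          loc_start <- frame + (first - 1L) * 3L    # 0-based, strand-local
          loc_end <- frame + st * 3L
          orf_nt <- substr(s, loc_start + 1L, loc_end)
          if (strand == "+") {
            fs <- loc_start; fe <- loc_end
          } else {
            fs <- L - loc_end; fe <- L - loc_start
          }
          calls[[length(calls) + 1L]] <- data.frame(
            ur_index = ur_index[u], strand = strand, frame = frame,
            start = fs, end = fe, nt_length = nt_len, nt = orf_nt,
            protein_as_coded = translate_mt(orf_nt, table, "as_coded"),
            protein_force_met = translate_mt(orf_nt, table, "force_met"),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(calls)) {
      df <- do.call(rbind, calls)
      # 5'->3' on +, then 5'->3' on - (descending forward coordinate)
      plus <- df[df$strand == "+", , drop = FALSE]
      plus <- plus[order(plus$start), , drop = FALSE]
      minus <- df[df$strand == "-", , drop = FALSE]
      minus <- minus[order(-minus$end), , drop = FALSE]
      df <- rbind(plus, minus)
      df$k <- seq_len(nrow(df))
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) {
    return(data.frame(ur_index = integer(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      nt_length = integer(), nt = character(),
                      protein_as_coded = character(),
                      protein_force_met = character(), k = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Census of new ORFs in the unassigned regions of a genome set
#'
#' Extracts the URs of each genome, finds all ORFs of at least
#' `min_codons` encoded amino acids and reports per-genome UR and ORF
#' counts plus a grand total. Annotated F-orf/M-orf/H-orf genes are
#' features, not URs, so they are excluded from the "new" ORF counts by
#' construction. ORF identifiers follow the
#' `<GenomePrefix>_UR_<index>_<k>` convention (see [genome_prefix()]).
#'
#' @param genomes A `mito_genome` or list of them.
#' @param min_codons,table,mode Passed to [find_orfs()].
#' @param anchor Anchor gene for UR numbering.
#' @return An object of class `orf_census`: list with `summary` (one row
#'   per genome: `genome_id`, `n_urs`, `n_orfs`), `orfs` (all calls with
#'   IDs) and `total`.
#' @export
orf_census <- function(genomes, min_codons = 10L, table = 5,
                       mode = c("start_to_stop", "stop_to_stop"),
                       anchor = "cox1") {
  mode <- match.arg(mode)
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  summaries <- list(); all_orfs <- list()
  for (g in genomes) {
    urs <- extract_unassigned_regions(g, anchor = anchor)
    orfs <- find_orfs(urs, min_codons = min_codons, table = table,
                      mode = mode)
    if (nrow(orfs)) {
      orfs$genome_id <- g$id
      orfs$id <- sprintf("%s_UR_%d_%d", genome_prefix(g), orfs$ur_index,
                         orfs$k)
      all_orfs[[length(all_orfs) + 1L]] <- orfs
    }
    summaries[[length(summaries) + 1L]] <- data.frame(
      genome_id = g$id, n_urs = nrow(urs), n_orfs = nrow(orfs),
      stringsAsFactors = FALSE)
  }
  orfs <- if (length(all_orfs)) do.call(rbind, all_orfs) else
    cbind(find_orfs(character()), genome_id = character(),
          id = character())
  rownames(orfs) <- NULL
  res <- list(summary = do.call(rbind, summaries), orfs = orfs,
              total = nrow(orfs))
  class(res) <- "orf_census"
  res
}

#' @export
print.orf_census <- function(x, ...) {
  cat("<orf_census>\n")
  print(x$summary, row.names = FALSE)
  cat("total new ORFs:", x$total, "\n")
  invisible(x)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment via [Biostrings::pairwiseAlignment()],
#' reported as a screen hit when the score reaches `threshold`. The
#' default protein scoring (BLOSUM62, gap open 11 / extend 1, score >= 40)
#' is the package's acceptance proxy for the E-value cutoffs used by
#' profile-search tools; a gap of length L costs `gap_opening +
#' gap_extension * L`.
#'
#' @param a,b Query and subject sequences (plain strings).
#' @param type `"protein"` or `"dna"`.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @param substitution Substitution matrix name or matrix; defaults to
#'   BLOSUM62 for protein, +1/-1 for DNA.
#' @param threshold Minimum score for a hit; `NULL` reports regardless.
#' @param query_id,subject_id Labels carried into the hit row.
#' @return A one-row data frame (`query_id`, `subject_id`, `score`,
#'   `identity`, `q_start`, `q_end`, `s_start`, `s_end`; 1-based inclusive
#'   alignment spans) or `NULL` when the score is below `threshold`.
#' @export
smith_waterman <- function(a, b, type = c("protein", "dna"),
                           gap_opening = NULL, gap_extension = NULL,
                           substitution = NULL, threshold = NULL,
                           query_id = "query", subject_id = "subject") {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (type == "protein") {
    if (is.null(substitution)) substitution <- "BLOSUM62"
    if (is.null(gap_opening)) gap_opening <- 11
    if (is.null(gap_extension)) gap_extension <- 1
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = substitution, gapOpening = gap_opening,
      gapExtension = gap_extension, type = "local")
  } else {
    if (grepl("[^ACGTN]", toupper(a)) || grepl("[^ACGTN]", toupper(b)))
      stop("invalid DNA alphabet")
    if (is.null(substitution))
      substitution <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    if (is.null(gap_opening)) gap_opening <- 0
    if (is.null(gap_extension)) gap_extension <- 2
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
      substitutionMatrix = substitution, gapOpening = gap_opening,
      gapExtension = gap_extension, type = "local")
  }
  sc <- Biostrings::score(pa)
  if (!is.null(threshold) && sc < threshold) return(NULL)
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  data.frame(query_id = query_id, subject_id = subject_id, score = sc,
             identity = Biostrings::nmatch(pa) /
               max(Biostrings::nchar(pa), 1L),
             q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
             s_start = Biostrings::start(sub), s_end = Biostrings::end(sub),
             stringsAsFactors = FALSE)
}

#' Reference protein sets for the homology-screen ladder
#'
#' Builds the default ladder steps from a genome set: the 13 standard
#' mtDNA-encoded proteins of each genome, the annotated ORFan proteins
#' (F-/M-/H-orf) and, appended by [screen_ladder()], the ORF protein set
#' itself.
#'
#' @param genomes A `mito_genome` or list of them.
#' @param table NCBI translation table id.
#' @return Named list of named character vectors of protein sequences.
#' @export
ladder_references <- function(genomes, table = 5) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  std <- character(); orfan <- character()
  for (g in genomes) {
    f <- g$features
    for (i in which(f$kind == "PCG")) {
      nt <- feature_seq(g, i)
      if (nchar(nt) %% 3L != 0L) next
      std[paste0(g$id, ":", f$name[i])] <-
        translate_mt(nt, table, allow_internal_stop = TRUE)
    }
    for (i in which(f$kind == "ORFan")) {
      nt <- feature_seq(g, i)
      if (nchar(nt) %% 3L != 0L) next
      orfan[paste0(g$id, ":", f$name[i])] <-
        translate_mt(nt, table, allow_internal_stop = TRUE)
    }
  }
  list(standard_proteins = std, known_orfans = orfan)
}

#' Homology-screen ladder for ORF proteins
#'
#' Compares every ORF protein against each reference step in turn --
#' typically (1) the genomes' 13 standard proteins, (2) known F/M/H-ORF
#' proteins and finally the ORF set itself -- recording the best local
#' alignment hit per step, or an explicit no-hit row. Both translation
#' policies of each ORF are screened and the better score is kept.
#'
#' @param orfs An `orf_census` object or a data frame with columns `id`,
#'   `protein_as_coded`, `protein_force_met`.
#' @param references Named list of ladder steps, each a named character
#'   vector of protein sequences (see [ladder_references()]). Empty steps
#'   are skipped with a warning. A step named `"self"` is added
#'   automatically unless `self = FALSE`.
#' @param threshold Minimum alignment score for a hit (default 40).
#' @param self Include the ORF-set-vs-itself step (self-hits of an ORF to
#'   its own entry are excluded).
#' @return Data frame with one row per (ORF, step): `query_id`, `step`,
#'   `subject_id`, `score`, `identity`, `hit`.
#' @export
screen_ladder <- function(orfs, references, threshold = 40, self = TRUE) {
  if (inherits(orfs, "orf_census")) orfs <- orfs$orfs
  stopifnot(all(c("id", "protein_as_coded", "protein_force_met") %in%
                  names(orfs)))
  prots <- stats::setNames(orfs$protein_as_coded, orfs$id)
  prots_met <- stats::setNames(orfs$protein_force_met, orfs$id)
  if (self) references <- c(references, list(self = prots))
  out <- list()
  for (step in names(references)) {
    refs <- references[[step]]
    if (!length(refs)) {
      warning("empty reference set for ladder step '", step,
              "'; step skipped", call. = FALSE)
      next
    }
    for (q in names(prots)) {
      best <- NULL
      for (r in names(refs)) {
        if (step == "self" && r == q) next
        for (qs in unique(c(prots[[q]], prots_met[[q]]))) {
          h <- smith_waterman(qs, refs[[r]], type = "protein",
                              query_id = q, subject_id = r)
          if (is.null(best) || h$score > best$score) best <- h
        }
      }
      if (is.null(best)) {
        best <- data.frame(query_id = q, subject_id = NA_character_,
                           score = NA_real_, identity = NA_real_,
                           q_start = NA_integer_, q_end = NA_integer_,
                           s_start = NA_integer_, s_end = NA_integer_,
                           stringsAsFactors = FALSE)
      }
      best$step <- step
      best$hit <- !is.na(best$score) && best$score >= threshold
      out[[length(out) + 1L]] <- best
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("query_id", "step", "subject_id", "score", "identity",
          "q_start", "q_end", "s_start", "s_end", "hit")]
}
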