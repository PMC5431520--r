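# Data model for annotated circular mitogenomes.
#
# Coordinates are 0-based half-open everywhere inside the package; a
# feature on a circular genome may wrap the origin, in which case
# end > genome length and the feature occupies [start, length) plus
# [0, end - length). GenBank 1-based inclusive coordinates exist only at
# the I/O boundary (read_genbank / write_genbank).

#' Construct an annotated mitochondrial genome
#'
#' The central container of the package: a (usually circular) mtDNA
#' sequence plus an ordered table of typed gene features. Transmission
#' route records whether the molecule is female-transmitted (`F`),
#' male-transmitted (`M`), hermaphrodite-retained (`H`), from a species
#' without doubly uniparental inheritance (`nonDUI`), or `unknown`.
#'
#' @param id Accession or synthetic label.
#' @param sequence Nucleotide sequence (single string over `A,C,G,T,N`).
#' @param features Data frame with columns `name`, `start`, `end`,
#'   `strand` and optionally `kind`, `codon_table`, `copy_index`.
#'   Coordinates are 0-based half-open; `end` may exceed the genome
#'   length for a feature wrapping the origin of a circular genome.
#' @param organism Organism name.
#' @param route One of `"F"`, `"M"`, `"H"`, `"nonDUI"`, `"unknown"`.
#' @param topology `"circular"` or `"linear_with_gaps"`.
#' @return An object of class `mito_genome`.
#' @export
annotated_genome <- function(id, sequence, features = NULL,
                             organism = "synthetic organism",
                             route = "unknown",
                             topology = "circular") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  route <- match.arg(route, c("F", "M", "H", "nonDUI", "unknown"))
  topology <- match.arg(topology, c("circular", "linear_with_gaps"))
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains symbols outside {A,C,G,T,N}")
  if (is.null(features)) {
    features <- empty_features()
  } else {
    features <- as_feature_table(features)
  }
  g <- structure(
    list(id = id, organism = organism, route = route,
         length = nchar(sequence), topology = topology,
         sequence = sequence, features = features),
    class = "mito_genome")
  validate_genome(g)
}

empty_features <- function() {
  data.frame(name = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             codon_table = integer(), copy_index = integer(),
             stringsAsFactors = FALSE)
}

as_feature_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end", "strand") %in% names(df)))
  if (is.null(df$kind)) df$kind <- infer_kind(df$name)
  if (is.null(df$codon_table)) df$codon_table <- 5L
  if (is.null(df$copy_index)) df$copy_index <- NA_integer_
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df <- df[order(df$start, df$end), , drop = FALSE]
  # distinct copy indices for duplicated gene names (e.g. a second trnE)
  for (nm in unique(df$name)) {
    sel <- which(df$name == nm)
    need <- is.na(df$copy_index[sel])
    if (any(need)) {
      taken <- df$copy_index[sel][!need]
      free <- setdiff(seq_len(length(sel) + length(taken)), taken)
      df$copy_index[sel[need]] <- free[seq_len(sum(need))]
    }
  }
  rownames(df) <- NULL
  df[, c("name", "kind", "start", "end", "strand",
         "codon_table", "copy_index")]
}

#' Validate a `mito_genome` object
#'
#' Checks the structural invariants: sequence length bookkeeping, feature
#' coordinates inside the genome (with circular wrap permitted only on
#' circular molecules), feature table sorted by start, and uniqueness of
#' `(name, start, strand)`.
#'
#' @param g A `mito_genome`.
#' @return `g`, invisibly usable, after passing all checks.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "mito_genome"))
  if (g$length != nchar(g$sequence))
    stop("length field does not match sequence length")
  f <- g$features
  if (nrow(f)) {
    if (any(f$start < 0L) || any(f$start >= g$length))
      stop("feature start outside [0, length)")
    if (any(f$end <= f$start))
      stop("feature end must exceed start (wrap is encoded as end > length)")
    wraps <- f$end > g$length
    if (any(wraps) && g$topology != "circular")
      stop("wrapping feature on a non-circular genome")
    if (any(f$end - f$start > g$length))
      stop("feature longer than the genome")
    if (is.unsorted(f$start)) stop("features not sorted by start")
    key <- paste(f$name, f$start, f$strand)
    if (anyDuplicated(key)) stop("duplicate (name, start, strand) feature")
    bad <- f$kind == "PCG" & ((f$end - f$start) %% 3L != 0L)
    if (any(bad))
      warning("PCG length not divisible by 3 (incomplete stop?): ",
              paste(f$name[bad], collapse = ", "), call. = FALSE)
  }
  g
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s, route %s)\n", x$id, x$organism, x$route))
  cat(sprintf("  %d bp, %s, %d features\n", x$length, x$topology,
              nrow(x$features)))
  kinds <- table(x$features$kind)
  if (length(kinds))
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.mito_genome <- function(object, ...) {
  urs <- tryCatch(extract_unassigned_regions(object),
                  error = function(e) NULL)
  out <- list(id = object$id, organism = object$organism,
              route = object$route, length = object$length,
              n_features = nrow(object$features),
              kind_counts = table(object$features$kind),
              n_urs = if (is.null(urs)) NA_integer_ else nrow(urs),
              ur_bp = if (is.null(urs)) NA_integer_ else
                sum(nchar(urs$sequence)))
  class(out) <- "summary.mito_genome"
  out
}

#' @export
print.summary.mito_genome <- function(x, ...) {
  cat(sprintf("%s (%s, route %s): %d bp, %d features, %s URs (%s bp unassigned)\n",
              x$id, x$organism, x$route, x$length, x$n_features,
              x$n_urs, x$ur_bp))
  invisible(x)
}

# Wrap-aware subsequence on the forward strand, 0-based half-open.
genome_subseq <- function(g, start, end) {
  n <- g$length
  if (end <= n) {
    substr(g$sequence, start + 1L, end)
  } else {
    paste0(substr(g$sequence, start + 1L, n),
           substr(g$sequence, 1L, end - n))
  }
}

#' Reverse complement of a nucleotide string
#' @param s Character vector of sequences over `A,C,G,T,N`.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the sequence of an annotated feature
#'
#' @param g A `mito_genome`.
#' @param which Row index in `g$features`, or a gene name (first copy).
#' @return The feature's nucleotide sequence, reverse-complemented for
#'   minus-strand features so that the result reads 5' to 3'.
#' @export
feature_seq <- function(g, which) {
  if (is.character(which)) {
    which <- which(g$features$name == which)[1]
    if (is.na(which)) stop("no such feature")
  }
  f <- g$features[which, ]
  s <- genome_subseq(g, f$start, f$end)
  if (f$strand == "-") s <- revcomp(s)
  s
}

#' Feature and unassigned-region table of a genome
#'
#' @param g A `mito_genome`.
#' @param include_urs Also append the unassigned regions as rows of kind
#'   `"UR"` (requires a cox1 anchor; see [extract_unassigned_regions()]).
#' @return A data frame suitable for writing as TSV.
#' @export
features_table <- function(g, include_urs = FALSE) {
  f <- g$features
  f$genome_id <- g$id
  f <- f[, c("genome_id", "name", "kind", "start", "end", "strand",
             "codon_table", "copy_index")]
  if (include_urs) {
    u <- extract_unassigned_regions(g)
    if (nrow(u)) {
      f <- rbind(f, data.frame(
        genome_id = g$id, name = paste0("UR_", u$index), kind = "UR",
        start = u$start, end = u$end, strand = "+",
        codon_table = NA_integer_, copy_index = NA_integer_))
    }
  }
  f
}

#' Extract unassigned regions of an annotated genome
#'
#' Unassigned regions (URs) are the maximal intervals covered by no
#' annotated feature. They are numbered sequentially: number 1 is the UR
#' immediately upstream of `cox1` on the forward strand and numbering then
#' proceeds clockwise (in ascending coordinate direction), wrapping around
#' the origin for circular genomes.
#'
#' @param g A `mito_genome` with at least one feature.
#' @param anchor Gene name anchoring the numbering (default `"cox1"`).
#'   An error is raised when the anchor is absent unless another anchor
#'   present in the genome is supplied.
#' @return A data frame with columns `genome_id`, `index`, `start`, `end`
#'   (0-based half-open; `end` may exceed the genome length for the single
#'   UR allowed to wrap the origin) and `sequence`.
#' @export
extract_unassigned_regions <- function(g, anchor = "cox1") {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  if (!nrow(f)) stop("genome has no features; cannot anchor UR numbering")
  a <- which(f$name == anchor)
  if (!length(a))
    stop("anchor gene '", anchor, "' not annotated; supply another anchor")
  n <- g$length
  covered <- logical(n)
  for (i in seq_len(nrow(f))) {
    idx <- seq.int(f$start[i], f$end[i] - 1L) %% n
    covered[idx + 1L] <- TRUE
  }
  if (all(covered)) {
    return(data.frame(genome_id = character(), index = integer(),
                      start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  # maximal uncovered runs on the circle
  free <- which(!covered) - 1L            # 0-based free positions
  if (length(free) == n) {
    runs <- data.frame(start = 0L, end = n)
  } else {
    brk <- which(diff(free) != 1L)
    starts <- free[c(1L, brk + 1L)]
    ends <- free[c(brk, length(free))] + 1L
    runs <- data.frame(start = starts, end = ends)
    if (g$topology == "circular" && nrow(runs) > 1L &&
        runs$start[1] == 0L && runs$end[nrow(runs)] == n) {
      # merge the two flanking runs into one wrapping UR
      runs$end[nrow(runs)] <- n + runs$end[1]
      runs <- runs[-1L, , drop = FALSE]
    }
  }
  # UR 1: the run whose end is nearest upstream of the anchor start
  anchor_start <- f$start[a[1]]
  gap_to_anchor <- (anchor_start - runs$end) %% n
  first <- which.min(gap_to_anchor)
  ord <- c(first:nrow(runs), if (first > 1L) 1:(first - 1L))
  runs <- runs[ord, , drop = FALSE]
  data.frame(genome_id = g$id,
             index = seq_len(nrow(runs)),
             start = runs$start, end = runs$end,
             sequence = vapply(seq_len(nrow(runs)), function(i)
               genome_subseq(g, runs$start[i], runs$end[i]), character(1)),
             stringsAsFactors = FALSE)
}

#' Short prefix used in ORF identifiers for a genome
#'
#' Builds the genome prefix of the ORF ID convention
#' `<prefix>_UR_<index>_<k>`: the first letter of the genus plus the first
#' three letters of the species epithet, with the route appended for F/M/H
#' molecules (for example *Cumberlandia monodonta* M becomes `CmonM`).
#' Falls back to the genome id when the organism name is not binomial.
#'
#' @param g A `mito_genome`.
#' @return A single string.
#' @export
genome_prefix <- function(g) {
  parts <- strsplit(trimws(g$organism), "\\s+")[[1]]
  if (length(parts) >= 2L) {
    pre <- paste0(toupper(substr(parts[1], 1, 1)), substr(parts[2], 1, 3))
  } else {
    pre <- g$id
  }
  if (g$route %in% c("F", "M", "H")) pre <- paste0(pre, g$route)
  pre
}
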