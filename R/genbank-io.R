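# GenBank flat-file input/output for annotated mitogenomes.
#
# Only at this boundary are coordinates GenBank-style (1-based inclusive);
# everything inside the package is 0-based half-open. A feature wrapping
# the circular origin is written as join(x..N,1..y) and read back into a
# single wrap-encoded feature. No installed R package parses annotated
# GenBank flat files offline, so the (small) dialect needed here is
# implemented directly.

.GENBANK_KEYS <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   misc_feature = "misc_feature")

kind_to_key <- function(kind) {
  switch(kind,
         PCG = "CDS", ORFan = "CDS", tRNA = "tRNA", rRNA = "rRNA",
         "misc_feature")
}

parse_location <- function(loc, genome_length, what = "feature") {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    iv <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
      if (length(m) != 3) stop("unparseable location for ", what, ": ", loc)
      as.integer(m[2:3])
    })
    if (length(iv) == 2 && iv[[1]][2] == genome_length && iv[[2]][1] == 1L) {
      # wrap around the origin
      return(list(start = iv[[1]][1] - 1L,
                  end = genome_length + iv[[2]][2], strand = strand))
    }
    stop("unparseable location for ", what, ": ", loc,
         " (only origin-spanning joins are supported)")
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3) {
    m <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
    if (length(m) == 2) return(list(start = as.integer(m[2]) - 1L,
                                    end = as.integer(m[2]), strand = strand))
    stop("unparseable location for ", what, ": ", loc)
  }
  list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
}

format_location <- function(start, end, strand, genome_length) {
  loc <- if (end > genome_length) {
    sprintf("join(%d..%d,1..%d)", start + 1L, genome_length,
            end - genome_length)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses the LOCUS length and topology, the organism, the feature table
#' (CDS, tRNA, rRNA, misc_feature entries; `gene` and `source` entries are
#' skipped as redundant) and the ORIGIN sequence. Feature labels are
#' mapped into the controlled vocabulary via [normalize_gene_name()];
#' unknown labels are kept with kind `"other"` and a warning. The
#' transmission route is recovered from a `route ...` phrase in the
#' DEFINITION line when present.
#'
#' @param path Path to a GenBank flat file.
#' @return A `mito_genome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line)")
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  topology <- if (grepl("circular", locus[1])) "circular" else
    "linear_with_gaps"

  def <- grep("^DEFINITION", lines, value = TRUE)
  route <- "unknown"
  if (length(def)) {
    m <- regmatches(def[1],
                    regexec("route (F|M|H|nonDUI|unknown)", def[1]))[[1]]
    if (length(m) == 2) route <- m[2]
  }
  orgl <- grep("^  ORGANISM", lines, value = TRUE)
  organism <- if (length(orgl)) trimws(sub("^  ORGANISM", "", orgl[1])) else
    locus_id

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty ORIGIN sequence")
  n <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart) && fstart[1] + 1L <= ori[1] - 1L) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # group physical lines into feature entries
    is_key <- grepl("^ {2,8}\\S", block) & !grepl("^ {10,}", block)
    entry_id <- cumsum(is_key)
    keep <- entry_id > 0L
    block <- block[keep]; entry_id <- entry_id[keep]; is_key <- is_key[keep]
    rows <- list()
    for (e in unique(entry_id)) {
      el <- block[entry_id == e]
      key <- strsplit(trimws(el[1]), "\\s+")[[1]][1]
      if (key %in% c("source", "gene")) next
      body <- paste(c(sub("^\\s*\\S+\\s*", "", el[1]), trimws(el[-1])),
                    collapse = "\n")
      toks <- strsplit(body, "\n", fixed = TRUE)[[1]]
      qual_start <- grep("^/", toks)
      loc <- paste(toks[seq_len(if (length(qual_start))
        qual_start[1] - 1L else length(toks))], collapse = "")
      quals <- if (length(qual_start)) toks[qual_start] else character()
      getq <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      label <- getq("gene")
      if (is.na(label)) label <- getq("product")
      if (is.na(label)) label <- getq("note")
      if (is.na(label)) label <- key
      pl <- parse_location(loc, n, what = label)
      tab <- getq("transl_table")
      note <- grep("^/note=", quals, value = TRUE)
      copy <- NA_integer_
      ci <- regmatches(note, regexec("copy_index:(\\d+)", note))
      ci <- unlist(lapply(ci, function(x) if (length(x) == 2) x[2] else NULL))
      if (length(ci)) copy <- as.integer(ci[1])
      rows[[length(rows) + 1L]] <- data.frame(
        name = normalize_gene_name(label),
        kind = NA_character_, start = pl$start, end = pl$end,
        strand = pl$strand,
        codon_table = if (is.na(tab)) 5L else as.integer(tab),
        copy_index = copy, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      feats <- do.call(rbind, rows)
      feats$kind <- infer_kind(feats$name)
    }
  }
  annotated_genome(id = locus_id, sequence = sequence, features = feats,
                   organism = organism, route = route, topology = topology)
}

#' Write an annotated mitogenome as a GenBank flat file
#'
#' @param g A `mito_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "mito_genome"))
  if (!nrow(g$features))
    warning("writing a sequence-only GenBank record (no features)",
            call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (g$topology == "circular") "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s     UNA",
                     g$id, g$length, topo), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, route %s, complete genome.",
                     g$organism, g$route), con)
  writeLines(sprintf("ACCESSION   %s", g$id), con)
  writeLines("SOURCE      mitochondrion", con)
  writeLines(sprintf("  ORGANISM  %s", g$organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", g$length), con)
  writeLines(sprintf('                     /organism="%s"', g$organism), con)
  writeLines('                     /organelle="mitochondrion"', con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    key <- kind_to_key(f$kind[i])
    loc <- format_location(f$start[i], f$end[i], f$strand[i], g$length)
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
    if (key == "CDS")
      writeLines(sprintf("                     /transl_table=%d",
                         f$codon_table[i]), con)
    writeLines(sprintf('                     /note="copy_index:%d"',
                       f$copy_index[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write sequences or a genome to FASTA
#'
#' @param x A `mito_genome` (written as a single record) or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "mito_genome")) {
    seqs <- stats::setNames(x$sequence,
                            sprintf("%s %s route=%s", x$id, x$organism,
                                    x$route))
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    seqs <- x
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read FASTA sequences as a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
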