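# Per-column keep/drop masks over a multiple alignment and their k-of-n
# consensus combination.

#' Construct a site mask
#'
#' @param keep Logical vector: `TRUE` for columns retained.
#' @param source Label of the masking program or rule.
#' @return Object of class `site_mask`.
#' @export
site_mask <- function(keep, source = "mask") {
  stopifnot(is.logical(keep), !anyNA(keep))
  structure(list(source = source, keep = keep,
                 n_columns = length(keep)), class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat(sprintf("<site_mask> %s: %d/%d columns kept\n", x$source,
              sum(x$keep), x$n_columns))
  invisible(x)
}

#' Combine site masks by k-of-n consensus
#'
#' A column is retained iff it is kept by at least `k` of the supplied
#' masks -- with four maskers and the default `k = 3` this is the
#' "three out of four" consensus rule.
#'
#' @param masks List of `site_mask` objects of equal `n_columns`.
#' @param k Minimum number of sources that must keep a column.
#' @return A `site_mask` labelled `"consensus(k-of-n)"`. When
#'   `k > length(masks)` the result keeps nothing, with a warning.
#' @export
combine_masks <- function(masks, k = 3L) {
  stopifnot(length(masks) >= 1L)
  masks <- lapply(masks, function(m) {
    if (!inherits(m, "site_mask")) site_mask(as.logical(m)) else m
  })
  nc <- vapply(masks, function(m) m$n_columns, integer(1))
  if (length(unique(nc)) != 1L) stop("masks differ in column count")
  votes <- Reduce(`+`, lapply(masks, function(m) as.integer(m$keep)))
  if (k > length(masks))
    warning("k exceeds the number of masks; empty consensus", call. = FALSE)
  site_mask(votes >= k,
            source = sprintf("consensus(%d-of-%d)", k, length(masks)))
}

# Rows of an alignment as a character matrix.
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (!is.character(alignment) || !length(alignment))
    stop("empty alignment")
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment is not rectangular")
  do.call(rbind, strsplit(toupper(alignment), ""))
}

#' Built-in site maskers
#'
#' Two simple, self-contained column filters for testing the consensus
#' machinery without external masking programs: a gap-fraction mask
#' (keep columns with gap fraction at most `max_gap`) and a Shannon
#' entropy mask (keep columns whose residue entropy, gaps excluded, is at
#' most `max_entropy` bits).
#'
#' @param alignment Character vector of equal-length gapped sequences, or
#'   a character matrix.
#' @param max_gap Maximum tolerated gap fraction (default 0.5).
#' @param max_entropy Maximum column entropy in bits (default 1.5).
#' @return List of two `site_mask` objects (`gap_fraction`, `entropy`).
#' @export
builtin_masks <- function(alignment, max_gap = 0.5, max_entropy = 1.5) {
  m <- alignment_matrix(alignment)
  if (!ncol(m)) stop("empty alignment")
  gap_frac <- colMeans(m == "-")
  entropy <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(Inf)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
  list(site_mask(gap_frac <= max_gap, "gap_fraction"),
       site_mask(entropy <= max_entropy, "entropy"))
}

#' Apply a site mask to an alignment
#'
#' @param alignment Character vector of aligned sequences or character
#'   matrix.
#' @param mask A `site_mask` with `n_columns` matching the alignment
#'   width.
#' @return The masked alignment, kept columns concatenated in order, in
#'   the input representation.
#' @export
apply_mask <- function(alignment, mask) {
  stopifnot(inherits(mask, "site_mask"))
  m <- alignment_matrix(alignment)
  if (ncol(m) != mask$n_columns)
    stop("mask length does not match alignment width")
  kept <- m[, mask$keep, drop = FALSE]
  if (is.matrix(alignment)) return(kept)
  out <- apply(kept, 1, paste, collapse = "")
  if (!is.character(out) || !length(out))
    out <- rep("", nrow(m))
  stats::setNames(out, names(alignment))
}

#' Read site masks from a text file
#'
#' One mask per line in either dialect: a string of `0`/`1` per column,
#' or a comma/space-separated list of kept 1-based column indices (the
#' latter requires `n_columns`). Lines may be prefixed with a
#' `label:` source name; `#` comments are ignored.
#'
#' @param path Path to the mask file.
#' @param n_columns Alignment width, required for the index dialect.
#' @return List of `site_mask` objects.
#' @export
read_masks <- function(path, n_columns = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    label <- sprintf("mask%d", i)
    if (grepl("^[^:]+:", ln)) {
      label <- sub(":.*$", "", ln)
      ln <- trimws(sub("^[^:]+:", "", ln))
    }
    if (grepl("^[01]+$", ln)) {
      keep <- strsplit(ln, "")[[1]] == "1"
    } else {
      idx <- as.integer(strsplit(ln, "[,[:space:]]+")[[1]])
      if (anyNA(idx)) stop("unparseable mask line: ", lines[i])
      if (is.null(n_columns))
        stop("index-dialect mask requires n_columns")
      keep <- rep(FALSE, n_columns); keep[idx] <- TRUE
    }
    out[[length(out) + 1L]] <- site_mask(keep, label)
  }
  out
}

#' Write a site mask as a 0/1 line
#'
#' @param mask A `site_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "site_mask"))
  writeLines(sprintf("%s: %s", mask$source,
                     paste(as.integer(mask$keep), collapse = "")), path)
  invisible(path)
}
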