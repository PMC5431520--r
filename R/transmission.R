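# Distance-based trees over F/M/H sequence sets and classification of
# the transmission pattern: gender-joining (reciprocal monophyly of the
# male- and female-transmitted lineages) versus taxon-joining (F and M
# of each species cluster together).

#' Pairwise distance matrix of an aligned sequence set
#'
#' Pairwise p-distances, optionally Jukes-Cantor corrected. For deeply
#' diverged sequence sets (such as F versus M mitogenomes at ~40%
#' divergence) raw p-distances saturate and are no longer additive;
#' tree building should then use `correction = "jukes_cantor"`.
#'
#' @param sequences Named character vector of aligned sequences.
#' @param mode `"nt"` or `"aa"` (see [p_distance()]).
#' @param correction `"none"` (raw p-distances) or `"jukes_cantor"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(sequences, mode = c("nt", "aa"),
                              correction = c("none", "jukes_cantor")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  stopifnot(is.character(sequences), length(sequences) >= 2L,
            !is.null(names(sequences)))
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- p_distance(sequences[[i]], sequences[[j]], mode)
    if (correction == "jukes_cantor") {
      p <- jukes_cantor(p)
      if (is.na(p)) stop("Jukes-Cantor correction undefined (p >= 3/4) ",
                         "between ", names(sequences)[i], " and ",
                         names(sequences)[j])
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei Q-criterion) via [ape::nj()].
#' Additive matrices are recovered exactly; negative branch lengths
#' arising from non-additive noise are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix (or `dist`) with >= 3 tips.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 tips")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0", call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Compose / parse `species|route` tip labels
#'
#' Tip labels of transmission-pattern trees encode the species and the
#' transmission route (`F`, `M` or `H`) separated by `|`.
#'
#' @param species Character vector of species names.
#' @param route Character vector of routes.
#' @return `tip_label()`: character vector; `parse_tip_labels()`: data
#'   frame with columns `label`, `species`, `route`.
#' @export
tip_label <- function(species, route) paste(species, route, sep = "|")

#' @rdname tip_label
#' @param labels Character vector of `species|route` labels.
#' @export
parse_tip_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("tip labels without a route: ",
         paste(labels[bad], collapse = ", "))
  data.frame(label = labels,
             species = vapply(parts, `[`, character(1), 1L),
             route = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Classify a tree as gender-joining, taxon-joining or mixed
#'
#' Purely topological classification of an unrooted tree whose tips carry
#' transmission routes. The tree is *gender-joining* when some edge
#' bipartition separates all M tips from all F and H tips (H molecules
#' are F-derived, so they group with F); it is *taxon-joining* when, for
#' every species with both routes, the species' tips form a cherry
#' (adjacent leaf pair); otherwise it is *mixed*. The bipartition test
#' has priority, so a tree that could satisfy both definitions (possible
#' only degenerately) is called gender-joining.
#'
#' @param tree A `phylo` tree, or an object with a `$tree` element.
#' @param tips Optional data frame with columns `label`, `species`,
#'   `route`; by default parsed from `species|route` tip labels.
#' @return List of class `transmission_pattern` with elements `pattern`
#'   (`"gender_joining"`, `"taxon_joining"` or `"mixed"`) and `evidence`.
#' @export
classify_pattern <- function(tree, tips = NULL) {
  if (!inherits(tree, "phylo") && !is.null(tree$tree)) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L)
    stop("classification needs at least 4 tips")
  if (is.null(tips)) tips <- parse_tip_labels(tree$tip.label)
  if (!all(tips$route %in% c("F", "M", "H")))
    stop("routes must be F, M or H")
  m_tips <- tips$label[tips$route == "M"]
  fh_tips <- tips$label[tips$route %in% c("F", "H")]
  if (length(m_tips) >= 1L && length(fh_tips) >= 1L) {
    rooted <- ape::root(tree, outgroup = fh_tips[1], resolve.root = TRUE)
    mono_m <- length(m_tips) == 1L ||
      ape::is.monophyletic(rooted, m_tips)
    if (mono_m) {
      return(structure(list(
        pattern = "gender_joining",
        evidence = sprintf(
          "edge separating the %d M tip(s) {%s} from all F/H tips",
          length(m_tips), paste(m_tips, collapse = ", "))),
        class = "transmission_pattern"))
    }
  }
  # cherry test per species having both an F/H and an M tip
  parent_of <- function(lab) {
    i <- match(lab, tree$tip.label)
    tree$edge[tree$edge[, 2] == i, 1]
  }
  violators <- character()
  tested <- character()
  for (sp in unique(tips$species)) {
    lab <- tips$label[tips$species == sp]
    has_m <- any(tips$route[tips$species == sp] == "M")
    has_fh <- any(tips$route[tips$species == sp] %in% c("F", "H"))
    if (!(has_m && has_fh)) next
    tested <- c(tested, sp)
    parents <- vapply(lab, parent_of, numeric(1))
    if (length(unique(parents)) != 1L) violators <- c(violators, sp)
  }
  if (length(tested) && !length(violators)) {
    return(structure(list(
      pattern = "taxon_joining",
      evidence = sprintf("F and M tips form a cherry in each of: %s",
                         paste(tested, collapse = ", "))),
      class = "transmission_pattern"))
  }
  structure(list(
    pattern = "mixed",
    evidence = sprintf(
      "M tips not separable from F/H by one edge; non-cherry species: %s",
      if (length(violators)) paste(violators, collapse = ", ") else
        "(none with both routes)")),
    class = "transmission_pattern")
}

#' @export
print.transmission_pattern <- function(x, ...) {
  cat(sprintf("<transmission_pattern> %s\n  %s\n", x$pattern, x$evidence))
  invisible(x)
}

#' Write or read a labelled tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; tip
#' labels carry `species|route`.
#'
#' @param tree A `phylo`.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read / write a PHYLIP-style distance matrix
#'
#' Square format: first line the number of taxa, then one row per taxon
#' (label, whitespace, distances). Labels may exceed the classic
#' 10-character limit; they must not contain whitespace.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path File path.
#' @return `write_phylip_dist()` returns `path` invisibly;
#'   `read_phylip_dist()` the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  stopifnot(!is.null(rownames(d)))
  lab <- gsub("\\s", "_", rownames(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(lab[i], format(d[i, ], digits = 10)),
                     collapse = "  "), con)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  lab <- vapply(rows, `[`, character(1), 1L)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(lab, lab)
  if (max(abs(d - t(d))) > 1e-8) stop("matrix is not symmetric")
  d
}
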