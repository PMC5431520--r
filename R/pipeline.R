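# End-to-end analysis pipeline: annotation summary -> URs -> ORF census
# -> homology screen -> divergence -> gene order / TDRL / repeats ->
# transmission pattern.

#' Run configuration for the analysis pipeline
#'
#' @param input Directory of GenBank files, a character vector of file
#'   paths, or a named list of `mito_genome` objects.
#' @param out_dir Output directory for report tables (`NULL` for none).
#' @param min_codons Minimum ORF length in encoded amino acids.
#' @param screen_threshold Local-alignment score threshold of the
#'   homology screen.
#' @param run_screen Run the (slower) homology-screen ladder stage.
#' @param fragment_threshold Score threshold of the pseudogene-fragment
#'   scan.
#' @param min_period,max_period,min_identity Tandem-repeat scanner
#'   parameters.
#' @param mask_k k of the k-of-n mask consensus (recorded in the
#'   manifest; masks are only combined when supplied to the masking
#'   stage directly).
#' @param seed Seed applied before any stochastic stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input, out_dir = NULL, min_codons = 10L,
                       screen_threshold = 40, run_screen = FALSE,
                       fragment_threshold = 16, min_period = 50L,
                       max_period = 500L, min_identity = 0.8,
                       mask_k = 3L, seed = 1L) {
  cfg <- list(input = input, out_dir = out_dir,
              min_codons = as.integer(min_codons),
              screen_threshold = screen_threshold,
              run_screen = isTRUE(run_screen),
              fragment_threshold = fragment_threshold,
              min_period = as.integer(min_period),
              max_period = as.integer(max_period),
              min_identity = min_identity, mask_k = as.integer(mask_k),
              seed = as.integer(seed))
  stopifnot(cfg$min_codons >= 1L, cfg$min_period >= 1L,
            cfg$min_identity > 0, cfg$min_identity <= 1)
  class(cfg) <- "run_config"
  cfg
}

load_genomes <- function(input) {
  if (is.list(input) && all(vapply(input, inherits, logical(1),
                                   "mito_genome"))) {
    gs <- input
  } else if (is.character(input) && length(input) == 1L &&
             dir.exists(input)) {
    paths <- sort(list.files(input, pattern = "\\.gb$", full.names = TRUE))
    if (!length(paths)) stop("no .gb files in ", input)
    gs <- lapply(paths, read_genbank)
  } else if (is.character(input)) {
    gs <- lapply(input, read_genbank)
  } else stop("unsupported input")
  stats::setNames(gs, vapply(gs, function(g) g$id, character(1)))
}

write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir) || is.null(df) || !nrow(df)) return(invisible())
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full comparative mitogenomics pipeline
#'
#' Executes every analysis stage on a set of annotated genomes and
#' returns a report bundle: per-genome summary (length, gene counts,
#' composition), unassigned regions, the ORF census, optionally the
#' homology-screen ladder, F-versus-M divergence per species, gene
#' orders with breakpoint distances and single-TDRL feasibility against
#' the reference genome, pseudogene-fragment and tandem-repeat scans,
#' and the neighbor-joining transmission-pattern classification. All
#' stages are pure functions of (input, config, seed); rerunning a
#' configuration reproduces the reports byte for byte.
#'
#' @param config A [run_config()].
#' @return A list of class `mitorfan_run` with one element per stage
#'   plus the `config`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- load_genomes(config$input)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # 1. genome summaries
  summary_df <- stage("summary", do.call(rbind, lapply(genomes, function(g) {
    comp <- base_composition(g$sequence)
    data.frame(genome_id = g$id, organism = g$organism, route = g$route,
               length = g$length, n_features = nrow(g$features),
               n_pcg = sum(g$features$kind == "PCG"),
               n_trna = sum(g$features$kind == "tRNA"),
               n_rrna = sum(g$features$kind == "rRNA"),
               n_orfan = sum(g$features$kind == "ORFan"),
               AT_percent = comp$AT_percent, AT_skew = comp$AT_skew,
               GC_skew = comp$GC_skew, stringsAsFactors = FALSE)
  })))
  write_stage(summary_df, out_dir, "genome_summary")
  # 2. unassigned regions
  urs <- stage("urs", do.call(rbind, lapply(genomes, function(g) {
    u <- extract_unassigned_regions(g)
    u$length <- nchar(u$sequence)
    u[, c("genome_id", "index", "start", "end", "length")]
  })))
  write_stage(urs, out_dir, "unassigned_regions")
  # 3. ORF census
  census <- stage("census", orf_census(genomes,
                                       min_codons = config$min_codons))
  write_stage(census$summary, out_dir, "orf_census")
  write_stage(census$orfs[, setdiff(names(census$orfs), "nt")],
              out_dir, "orf_calls")
  # 4. homology screen (optional)
  screen <- NULL
  if (config$run_screen && nrow(census$orfs)) {
    screen <- stage("screen",
                    screen_ladder(census, ladder_references(genomes),
                                  threshold = config$screen_threshold))
    write_stage(screen, out_dir, "screen_hits")
  }
  # 5. F-vs-M divergence per species with both routes
  divergence <- NULL
  orgs <- vapply(genomes, function(g) g$organism, character(1))
  routes <- vapply(genomes, function(g) g$route, character(1))
  for (sp in unique(orgs)) {
    fi <- which(orgs == sp & routes %in% c("F", "H"))
    mi <- which(orgs == sp & routes == "M")
    if (!length(fi) || !length(mi)) next
    rep <- stage("divergence",
                 fm_divergence_report(genomes[[fi[1]]], genomes[[mi[1]]]))
    rep$species <- sp
    divergence <- rbind(divergence, rep)
  }
  write_stage(divergence, out_dir, "fm_divergence")
  # 6. gene order, breakpoints, TDRL vs the reference (first F genome)
  ref_idx <- c(which(routes == "F"), 1L)[1]
  ref_order <- gene_order(genomes[[ref_idx]])
  gene_orders <- stage("gene_order", do.call(rbind, lapply(genomes,
    function(g) {
      go <- gene_order(g)
      shared_only <- length(intersect(sub("^-", "", go$tokens),
                                      sub("^-", "", ref_order$tokens))) > 0
      td <- tdrl_feasible(
        gene_order_perm(
          ref_order$tokens[sub("^-", "", ref_order$tokens) %in%
                             sub("^-", "", go$tokens)],
          ref_order$circular),
        gene_order_perm(
          go$tokens[sub("^-", "", go$tokens) %in%
                      sub("^-", "", ref_order$tokens)], go$circular))
      data.frame(genome_id = g$id,
                 order = paste(go$tokens, collapse = " "),
                 breakpoints_vs_ref = if (shared_only)
                   breakpoint_distance(go, ref_order) else NA_integer_,
                 tdrl_from_ref = td$feasible, stringsAsFactors = FALSE)
    })))
  write_stage(gene_orders, out_dir, "gene_orders")
  # 7. tandem repeats
  repeats <- stage("repeats", do.call(rbind, lapply(genomes, function(g) {
    r <- find_tandem_repeats(g$sequence, min_period = config$min_period,
                             max_period = config$max_period,
                             min_identity = config$min_identity)
    if (nrow(r)) cbind(genome_id = g$id, r)
  })))
  write_stage(repeats, out_dir, "tandem_repeats")
  # 8. pseudogene fragments: each genome's URs scanned against its own
  #    functional gene copies (decayed duplicates stay recognizable
  #    against the intact paralogue, not against a diverged orthologue)
  fragments <- stage("fragments", do.call(rbind, lapply(genomes,
    function(g) {
      keep <- g$features$kind %in% c("PCG", "tRNA")
      refs <- stats::setNames(
        lapply(which(keep), function(i) feature_seq(g, i)),
        g$features$name[keep])
      u <- extract_unassigned_regions(g)
      u <- u[nchar(u$sequence) >= 40L, , drop = FALSE]
      if (!nrow(u)) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(u)), function(i) {
        h <- find_pseudogene_fragments(u[i, ], unlist(refs),
                                       threshold =
                                         config$fragment_threshold)
        if (nrow(h)) cbind(genome_id = g$id, ur_index = u$index[i], h)
      }))
    })))
  write_stage(fragments, out_dir, "pseudogene_fragments")
  # 9. transmission pattern from the NJ tree of the PCG supermatrix
  pattern <- NULL
  if (length(genomes) >= 4L && all(routes %in% c("F", "M", "H"))) {
    pattern <- stage("pattern", {
      aln <- pcg_supermatrix(genomes)
      names(aln) <- tip_label(orgs, routes)
      d <- p_distance_matrix(aln, "nt", correction = "jukes_cantor")
      tr <- neighbor_joining(d)
      cl <- classify_pattern(tr)
      list(tree = tr, classification = cl)
    })
    if (!is.null(out_dir))
      write_newick(pattern$tree, file.path(out_dir, "nj_tree.nwk"))
  }
  if (!is.null(out_dir)) {
    manifest <- c(sprintf("mitorfan: %s",
                          as.character(utils::packageVersion("mitorfan"))),
                  sprintf("seed: %d", config$seed),
                  sprintf("min_codons: %d", config$min_codons),
                  sprintf("screen_threshold: %s", config$screen_threshold),
                  sprintf("fragment_threshold: %s",
                          config$fragment_threshold),
                  sprintf("repeat_scan: period %d..%d identity %s",
                          config$min_period, config$max_period,
                          config$min_identity),
                  sprintf("mask_k: %d", config$mask_k))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  res <- list(summary = summary_df, urs = urs, census = census,
              screen = screen, divergence = divergence,
              gene_orders = gene_orders, repeats = repeats,
              fragments = fragments, pattern = pattern, config = config)
  class(res) <- "mitorfan_run"
  res
}

#' @export
print.mitorfan_run <- function(x, ...) {
  cat("<mitorfan_run>\n")
  print(x$summary[, c("genome_id", "route", "length", "n_features",
                      "AT_percent")], row.names = FALSE)
  cat(sprintf("URs: %d, new ORFs: %d\n", nrow(x$urs), x$census$total))
  if (!is.null(x$divergence)) {
    conc <- x$divergence[x$divergence$gene == "concatenated_PCG", ]
    for (i in seq_len(nrow(conc)))
      cat(sprintf("%s: F-M p_nt %.3f, dN/dS %.3f\n", conc$species[i],
                  conc$p_nt[i], conc$omega[i]))
  }
  if (!is.null(x$pattern))
    cat("transmission pattern:", x$pattern$classification$pattern, "\n")
  invisible(x)
}
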