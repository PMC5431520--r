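# Synthetic palaeoheterodont-like mitogenomes with known ground truth:
# template gene order, controlled F/M divergence with tunable dN/dS,
# planted ORFan genes, M-type cox2 3' extension, a TDRL rearrangement
# with decayed pseudogene copies, and large tandem repeats.

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic mitogenome generator. The
#' defaults are the study conditions the package emulates: circular
#' ~16 kb genomes with the standard 37 genes, intraspecific F-versus-M
#' nucleotide divergence 0.40 with dN/dS 0.33, a 500 bp in-frame 3'
#' extension of the M cox2, ORFan genes at their observed positions
#' (M-orf next to nad4L, the optional second M-orf between tRNA-Asp and
#' atp8, F-orf upstream of nad2), one TDRL of the trnD-atp8-nad6 block
#' with 15% pseudogene decay, and a ~320 bp tandem repeat in three
#' copies. `scale = "mini"` shrinks gene lengths (not the biology) for
#' fast tests.
#'
#' @param seed Integer seed; the same configuration (seed included)
#'   yields byte-identical outputs.
#' @param n_species Number of species simulated by [simulate_study()].
#' @param scale `"study"` (~16 kb) or `"mini"` (~6 kb).
#' @param target_p_nt Intraspecific F-M nucleotide p-distance on the
#'   concatenated protein-coding genes.
#' @param target_omega Target dN/dS in protein-coding genes.
#' @param tip_p Per-tip-branch p-distance in [simulate_study()].
#' @param kappa Transition/transversion proposal ratio.
#' @param at_percent Target AT content of the ancestor.
#' @param cox2_extension M-type in-frame 3' cox2 extension, bp
#'   (divisible by 3).
#' @param m_orf_codons,m_orf2_codons,f_orf_codons ORFan lengths in
#'   codons (including start and stop).
#' @param tdrl_block,tdrl_assignment Duplicated gene block and retained
#'   copy (1 = first, 2 = second) per gene.
#' @param pseudo_decay Per-base decay rate of unretained TDRL gene
#'   copies.
#' @param repeat_unit,repeat_copies,repeat_decay Tandem repeat unit
#'   length (bp), copy number and per-copy decay rate.
#' @param pattern Transmission-pattern truth, `"gender_joining"` or
#'   `"taxon_joining"`.
#' @param include_h Make the last species hermaphroditic (single
#'   H-route genome carrying the TDRL and the planted repeat, no M).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 3L,
                       scale = c("study", "mini"),
                       target_p_nt = 0.40, target_omega = 0.33,
                       tip_p = 0.03, kappa = 2, at_percent = 65,
                       cox2_extension = NULL,
                       m_orf_codons = NULL, m_orf2_codons = NULL,
                       f_orf_codons = NULL,
                       tdrl_block = c("trnD", "atp8", "nad6"),
                       tdrl_assignment = c(trnD = 2L, atp8 = 2L, nad6 = 1L),
                       pseudo_decay = 0.15,
                       repeat_unit = NULL, repeat_copies = 3L,
                       repeat_decay = 0.05,
                       pattern = c("gender_joining", "taxon_joining"),
                       include_h = TRUE) {
  scale <- match.arg(scale)
  pattern <- match.arg(pattern)
  mini <- scale == "mini"
  cfg <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    scale = scale, target_p_nt = target_p_nt,
    target_omega = target_omega, tip_p = tip_p, kappa = kappa,
    at_percent = at_percent,
    cox2_extension = if (is.null(cox2_extension))
      (if (mini) 99L else 501L) else as.integer(cox2_extension),
    m_orf_codons = if (is.null(m_orf_codons)) (if (mini) 60L else 220L)
      else as.integer(m_orf_codons),
    m_orf2_codons = if (is.null(m_orf2_codons)) (if (mini) 30L else 60L)
      else as.integer(m_orf2_codons),
    f_orf_codons = if (is.null(f_orf_codons)) (if (mini) 40L else 120L)
      else as.integer(f_orf_codons),
    tdrl_block = tdrl_block, tdrl_assignment = tdrl_assignment,
    pseudo_decay = pseudo_decay,
    repeat_unit = if (is.null(repeat_unit)) (if (mini) 80L else 320L)
      else as.integer(repeat_unit),
    repeat_copies = as.integer(repeat_copies),
    repeat_decay = repeat_decay, pattern = pattern,
    include_h = isTRUE(include_h))
  stopifnot(cfg$target_p_nt >= 0, cfg$target_p_nt < 0.75,
            cfg$pseudo_decay >= 0, cfg$pseudo_decay <= 1,
            cfg$repeat_decay >= 0, cfg$repeat_decay <= 1,
            cfg$cox2_extension %% 3L == 0L,
            setequal(names(cfg$tdrl_assignment), cfg$tdrl_block))
  class(cfg) <- "sim_config"
  cfg
}

# Gene template: the synthetic ancestral (F-like) gene order with gene
# lengths and strands; spacer_after is the UR length following the gene
# (deterministic; three junctions reserved for ORFan insertion get 60 bp,
# the control-region-like UR upstream of cox1 closes the circle).
mt_gene_template <- function(scale = c("study", "mini")) {
  scale <- match.arg(scale)
  mini <- scale == "mini"
  g <- function(name, kind, strand, len_study, len_mini)
    data.frame(name = name, kind = kind, strand = strand,
               length = if (mini) len_mini else len_study,
               stringsAsFactors = FALSE)
  tpl <- rbind(
    g("cox1", "PCG", "+", 1536, 402), g("cox2", "PCG", "+", 690, 300),
    g("nad3", "PCG", "+", 351, 150), g("trnH", "tRNA", "+", 66, 66),
    g("trnA", "tRNA", "+", 66, 66), g("trnS1", "tRNA", "-", 66, 66),
    g("trnE", "tRNA", "+", 66, 66), g("rrnS", "rRNA", "+", 850, 220),
    g("trnM", "tRNA", "+", 66, 66), g("trnC", "tRNA", "-", 66, 66),
    g("cox3", "PCG", "+", 780, 201), g("trnK", "tRNA", "+", 66, 66),
    g("trnF", "tRNA", "+", 66, 66), g("nad4L", "PCG", "+", 273, 102),
    g("trnD", "tRNA", "+", 66, 66), g("atp8", "PCG", "+", 120, 99),
    g("nad6", "PCG", "+", 480, 240), g("trnQ", "tRNA", "-", 66, 66),
    g("nad1", "PCG", "+", 906, 300), g("trnV", "tRNA", "+", 66, 66),
    g("rrnL", "rRNA", "+", 1250, 300), g("trnL1", "tRNA", "+", 66, 66),
    g("nad4", "PCG", "+", 1320, 300), g("trnL2", "tRNA", "+", 66, 66),
    g("nad5", "PCG", "+", 1653, 402), g("trnW", "tRNA", "+", 66, 66),
    g("trnG", "tRNA", "+", 66, 66), g("trnY", "tRNA", "-", 66, 66),
    g("trnT", "tRNA", "+", 66, 66), g("cytb", "PCG", "+", 1140, 300),
    g("trnP", "tRNA", "+", 66, 66), g("trnS2", "tRNA", "+", 66, 66),
    g("atp6", "PCG", "+", 702, 300), g("trnN", "tRNA", "+", 66, 66),
    g("trnI", "tRNA", "+", 66, 66), g("nad2", "PCG", "+", 960, 300),
    g("trnR", "tRNA", "+", 66, 66))
  n <- nrow(tpl)
  tpl$spacer_after <- ((seq_len(n) * 37L) %% 29L) + 2L   # 2..30 bp
  tpl$spacer_after[tpl$name %in% c("nad4L", "trnD", "trnI")] <- 60L
  tpl$spacer_after[n] <- if (mini) 300L else 800L        # control region
  tpl
}

base_weights <- function(at_percent) {
  at <- at_percent / 100
  c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
}

rand_bases <- function(n, w) {
  if (n <= 0L) return(character())
  sample(names(w), n, replace = TRUE, prob = w)
}

# Random CDS: ATG + sense codons + TAA (no in-frame stops).
rand_cds <- function(len, w, table = 5) {
  stopifnot(len %% 3L == 0L, len >= 6L)
  code <- mt_genetic_code(table)
  ncod <- len %/% 3L - 2L
  out <- character(ncod)
  if (ncod > 0L) {
    fill <- seq_len(ncod)
    while (length(fill)) {
      m <- matrix(rand_bases(3L * length(fill), w), nrow = 3L)
      cods <- apply(m, 2, paste, collapse = "")
      ok <- code[cods] != "*"
      out[fill[ok]] <- cods[ok]
      fill <- fill[!ok]
    }
  }
  paste0("ATG", paste(out, collapse = ""), "TAA")
}

rand_orf_nt <- function(codons, w, table = 5) {
  rand_cds(3L * codons, w, table)
}

#' Build the synthetic ancestral mitogenome
#'
#' Lays out the 37 standard genes in the template order on a circular
#' molecule, with random intergenic unassigned regions, base composition
#' at the configured AT content, and a large control-region-like UR
#' immediately upstream of cox1 (so that UR numbering starts there).
#'
#' @param config A [sim_config()].
#' @return A `mito_genome` (route `unknown`).
#' @export
make_ancestor <- function(config = sim_config()) {
  with_seed(config$seed, .make_ancestor(config))
}

.make_ancestor <- function(config) {
  tpl <- mt_gene_template(config$scale)
  w <- base_weights(config$at_percent)
  segs <- character(); feats <- list(); pos <- 0L
  for (i in seq_len(nrow(tpl))) {
    len <- tpl$length[i]
    s <- switch(tpl$kind[i],
                PCG = rand_cds(len, w),
                paste(rand_bases(len, w), collapse = ""))
    if (tpl$strand[i] == "-") s <- revcomp(s)
    feats[[i]] <- data.frame(name = tpl$name[i], kind = tpl$kind[i],
                             start = pos, end = pos + len,
                             strand = tpl$strand[i],
                             stringsAsFactors = FALSE)
    segs <- c(segs, s); pos <- pos + len
    sp <- tpl$spacer_after[i]
    if (sp > 0L) {
      segs <- c(segs, paste(rand_bases(sp, w), collapse = ""))
      pos <- pos + sp
    }
  }
  annotated_genome(id = "SYNANC", sequence = paste(segs, collapse = ""),
                   features = do.call(rbind, feats),
                   organism = "Synthetica exemplaris", route = "unknown",
                   topology = "circular")
}

# Raw acceptance ratio a such that accepting nonsynonymous proposals
# with probability min(1, a) and synonymous ones with min(1, 1/a) makes
# the realized (Nd/N)/(Sd/S) ratio match the target omega under the
# kappa-weighted proposal process and Nei-Gojobori site counting.
ng_alpha <- function(g, omega, kappa, table = 5) {
  code <- mt_genetic_code(table)
  sites <- ng_syn_sites(table)
  is_transition <- function(a, b)
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  S <- 0; N <- 0; WS <- 0; WN <- 0
  bases <- c("A", "C", "G", "T")
  for (r in which(g$features$kind == "PCG")) {
    cods <- split_codons(feature_seq(g, r))
    cods <- cods[-c(1L, length(cods))]          # start/stop protected
    for (cd in unique(cods)) {
      k <- sum(cods == cd)
      if (grepl("N", cd) || code[[cd]] == "*") next
      S <- S + k * sites[[cd]]; N <- N + k * (3 - sites[[cd]])
      ch <- strsplit(cd, "")[[1]]
      for (p in 1:3) for (b in setdiff(bases, ch[p])) {
        mut <- ch; mut[p] <- b
        aam <- code[[paste(mut, collapse = "")]]
        if (aam == "*") next                    # proposals to stops rejected
        wgt <- if (is_transition(ch[p], b)) kappa else 1
        if (aam == code[[cd]]) WS <- WS + k * wgt else WN <- WN + k * wgt
      }
    }
  }
  if (WN == 0 || S == 0) return(1)
  omega * (WS / S) * (N / WN)
}

#' Evolve a genome to a target divergence with controlled dN/dS
#'
#' Applies single-nucleotide substitutions (transition/transversion
#' proposal ratio `kappa`) until the p-distance to the input, measured
#' over all protein-coding sites, reaches `target_p`. In protein-coding
#' genes, proposals creating stop codons are rejected, start and stop
#' codons are immutable, and nonsynonymous proposals are accepted with a
#' probability tuned so the realized dN/dS matches `target_omega`;
#' rRNA, tRNA and unassigned sites evolve without coding constraint.
#' No indels are introduced, so gene coordinates are preserved.
#'
#' @param g A `mito_genome` whose PCGs are on the plus strand.
#' @param target_p Target p-distance over protein-coding sites
#'   (`< 0.75`).
#' @param target_omega Target dN/dS.
#' @param kappa Transition/transversion proposal ratio.
#' @param table NCBI translation table id.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return The evolved `mito_genome`.
#' @export
evolve_genome <- function(g, target_p, target_omega = 0.33, kappa = 2,
                          table = 5, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, .evolve(g, target_p, target_omega, kappa,
                                   table)))
  .evolve(g, target_p, target_omega, kappa, table)
}

.evolve <- function(g, target_p, target_omega, kappa, table = 5) {
  stopifnot(target_p >= 0, target_p < 0.75)
  if (target_p == 0) return(g)
  f <- g$features
  pcg_rows <- which(f$kind %in% c("PCG", "ORFan"))
  stopifnot(all(f$strand[pcg_rows] == "+"),
            all(f$end[pcg_rows] <= g$length))
  s <- strsplit(g$sequence, "")[[1]]
  n <- length(s)
  site_pcg <- integer(n); codon_start <- integer(n)
  protected <- logical(n)
  for (r in pcg_rows) {
    span <- (f$start[r] + 1L):f$end[r]
    site_pcg[span] <- r
    rel <- seq_along(span) - 1L
    codon_start[span] <- f$start[r] + (rel %/% 3L) * 3L + 1L
    protected[f$start[r] + (1:3)] <- TRUE
    protected[f$end[r] - (0:2)] <- TRUE
  }
  pcg_sites <- site_pcg > 0L
  npcg <- sum(pcg_sites)
  target_diff <- ceiling(target_p * npcg)
  orig <- s
  code <- mt_genetic_code(table)
  a_raw <- ng_alpha(g, target_omega, kappa, table)
  alpha_n <- min(1, a_raw); alpha_s <- min(1, 1 / a_raw)
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), C = c("A", "G"),
                G = c("C", "T"), T = c("A", "G"))
  p_ts <- kappa / (kappa + 2)
  ndiff <- 0L; it <- 0L; max_it <- 2000L * n
  while (ndiff < target_diff && it < max_it) {
    it <- it + 1L
    i <- sample.int(n, 1L)
    if (protected[i]) next
    b <- s[i]
    if (b == "N") next
    new <- if (stats::runif(1) < p_ts) ts_of[[b]] else
      sample(tv_of[[b]], 1L)
    r <- site_pcg[i]
    if (r > 0L) {
      cs <- codon_start[i]
      cod <- s[cs:(cs + 2L)]
      ncod <- cod; ncod[i - cs + 1L] <- new
      aan <- code[[paste(ncod, collapse = "")]]
      if (aan == "*") next
      acc <- if (aan == code[[paste(cod, collapse = "")]]) alpha_s else
        alpha_n
      if (acc < 1 && stats::runif(1) > acc) next
    }
    was_diff <- s[i] != orig[i]
    s[i] <- new
    if (r > 0L)
      ndiff <- ndiff + (s[i] != orig[i]) - was_diff
  }
  if (ndiff < target_diff)
    stop("target divergence not reached (unreachable target?)")
  g$sequence <- paste(s, collapse = "")
  g
}

#' Evolve an F/M genome pair from a common ancestor
#'
#' The female-transmitted genome is the (relabelled) ancestor; the
#' male-transmitted genome is evolved to the target p-distance with the
#' target dN/dS, so the realized F-M divergence equals the target by
#' construction (up to the last-substitution granularity).
#'
#' @param ancestor A `mito_genome`.
#' @param target_p_nt Target F-M p-distance over protein-coding sites.
#' @param target_omega Target dN/dS.
#' @param seed Integer seed.
#' @param kappa Transition/transversion proposal ratio.
#' @return List with `f`, `m` (`mito_genome`s) and `truth` (per-gene
#'   realized nucleotide p-distances).
#' @export
evolve_pair <- function(ancestor, target_p_nt = 0.40, target_omega = 0.33,
                        seed = 1L, kappa = 2) {
  with_seed(seed, {
    f <- ancestor
    f$id <- paste0(ancestor$id, "F"); f$route <- "F"
    m <- .evolve(ancestor, target_p_nt, target_omega, kappa)
    m$id <- paste0(ancestor$id, "M"); m$route <- "M"
    pcg <- which(f$features$kind == "PCG")
    truth <- data.frame(
      gene = f$features$name[pcg],
      p_nt = vapply(pcg, function(r)
        p_distance(feature_seq(f, r), feature_seq(m, r), "nt"),
        numeric(1)),
      stringsAsFactors = FALSE)
    list(f = f, m = m, truth = truth)
  })
}

# Insert `seq` at 0-based position `pos`; features starting at or after
# pos shift, features whose span contains pos stretch (used only for the
# in-frame cox2 extension). Optionally annotate the insert.
genome_insert <- function(g, pos, seq, feature = NULL,
                          allow_inside = character()) {
  stopifnot(pos >= 0L, pos <= g$length)
  f <- g$features
  inside <- which(f$start < pos & f$end > pos)
  bad <- setdiff(f$name[inside], allow_inside)
  if (length(bad))
    stop("insertion position falls inside feature(s): ",
         paste(bad, collapse = ", "))
  len <- nchar(seq)
  f$end[f$end > pos] <- f$end[f$end > pos] + len
  f$start[f$start >= pos] <- f$start[f$start >= pos] + len
  if (!is.null(feature)) {
    f <- rbind(f, data.frame(
      name = feature$name, kind = feature$kind, start = pos,
      end = pos + len, strand = feature$strand, codon_table = 5L,
      copy_index = NA_integer_, stringsAsFactors = FALSE))
    f$copy_index[nrow(f)] <- 1L
  }
  g$sequence <- paste0(substr(g$sequence, 1L, pos), seq,
                       substr(g$sequence, pos + 1L, g$length))
  g$length <- nchar(g$sequence)
  g$features <- as_feature_table(f)
  validate_genome(g)
}

# Position inside the UR between two named adjacent features.
junction_pos <- function(g, left, right) {
  f <- g$features
  li <- which(f$name == left)[1]; ri <- which(f$name == right)[1]
  if (is.na(li) || is.na(ri)) stop("junction genes not found")
  if (f$start[ri] < f$end[li]) stop("no gap between ", left, " and ", right)
  f$end[li] + (f$start[ri] - f$end[li]) %/% 2L
}

decay_bases <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  chars
}

# Apply a tandem duplication-random loss event: the region spanning the
# block genes (including internal URs) is duplicated in tandem; in copy
# c only genes with assignment c stay annotated, the other copies decay
# into unannotated pseudogene fragments.
plant_tdrl <- function(g, block, assignment, decay) {
  f <- g$features
  idx <- vapply(block, function(nm) which(f$name == nm)[1], integer(1))
  stopifnot(!anyNA(idx))
  idx <- idx[order(f$start[idx])]
  if (max(idx) - min(idx) + 1L != length(idx))
    stop("TDRL block genes are not contiguous")
  r_start <- f$start[idx[1]]; r_end <- f$end[idx[length(idx)]]
  stopifnot(r_end <= g$length)
  region <- substr(g$sequence, r_start + 1L, r_end)
  rlen <- nchar(region)
  mk_copy <- function(copy, offset) {
    chars <- strsplit(region, "")[[1]]
    feats <- list(); frags <- list()
    for (j in idx) {
      rs <- f$start[j] - r_start; re <- f$end[j] - r_start
      if (assignment[[f$name[j]]] == copy) {
        feats[[length(feats) + 1L]] <- data.frame(
          name = f$name[j], kind = f$kind[j], start = offset + rs,
          end = offset + re, strand = f$strand[j],
          codon_table = f$codon_table[j], copy_index = NA_integer_,
          stringsAsFactors = FALSE)
      } else {
        span <- (rs + 1L):re
        chars[span] <- decay_bases(chars[span], decay)
        frags[[length(frags) + 1L]] <- data.frame(
          gene = f$name[j], start = offset + rs, end = offset + re,
          copy = copy, stringsAsFactors = FALSE)
      }
    }
    list(seq = paste(chars, collapse = ""),
         feats = if (length(feats)) do.call(rbind, feats),
         frags = if (length(frags)) do.call(rbind, frags))
  }
  c1 <- mk_copy(1L, r_start)
  c2 <- mk_copy(2L, r_start + rlen)
  spans_boundary <- which((f$start < r_start & f$end > r_start) |
                            (f$start < r_end & f$end > r_end))
  if (length(spans_boundary)) stop("feature spans the TDRL region boundary")
  pre <- f[f$end <= r_start, , drop = FALSE]
  post <- f[f$start >= r_end, , drop = FALSE]
  post$start <- post$start + rlen; post$end <- post$end + rlen
  newf <- rbind(pre, c1$feats, c2$feats, post)
  g$sequence <- paste0(substr(g$sequence, 1L, r_start), c1$seq, c2$seq,
                       substr(g$sequence, r_end + 1L, g$length))
  g$length <- nchar(g$sequence)
  g$features <- as_feature_table(newf)
  g <- validate_genome(g)
  frags <- rbind(c1$frags, c2$frags)
  list(genome = g, fragments = frags,
       witness = list(block = block, assignment = assignment))
}

# Shift recorded 0-based coordinates for an insertion of `len` at `pos`.
shift_coords <- function(df, pos, len, cols = c("start", "end")) {
  if (is.null(df) || !nrow(df)) return(df)
  for (cl in cols) df[[cl]][df[[cl]] >= pos] <- df[[cl]][df[[cl]] >= pos] + len
  df
}

#' Plant lineage-specific features into a genome
#'
#' Adds the features that distinguish the mtDNA lineages of DUI
#' freshwater mussels, with the planting truth returned alongside:
#' an ORFan gene (M-orf between nad4L and tRNA-Asp, F-orf/H-orf upstream
#' of nad2), a single-step TDRL of the configured block with decay of the
#' unretained copies, an optional second M-orf between tRNA-Asp and atp8,
#' an in-frame 3' extension of cox2 (M route), and a tandem repeat in the
#' large control-region-like UR.
#'
#' @param g A `mito_genome`.
#' @param config A [sim_config()].
#' @param orfan ORFan gene to insert (`"F-orf"`, `"M-orf"`, `"H-orf"`,
#'   `"none"`); default chosen from the genome's route.
#' @param tdrl Apply the configured TDRL (default for routes M and H).
#' @param m_orf2 Insert the second M-orf (post-TDRL, between tRNA-Asp
#'   and atp8).
#' @param cox2_extension Extension length in bp (default: the configured
#'   value for route M, otherwise 0).
#' @param repeats Plant the tandem repeat.
#' @param seed Optional seed (otherwise the current RNG stream).
#' @return List with `genome` and `truth` (planted ORFans, TDRL witness,
#'   pseudogene fragment coordinates, repeat coordinates, cox2 lengths).
#' @export
plant_features <- function(g, config = sim_config(), orfan = NULL,
                           tdrl = NULL, m_orf2 = FALSE,
                           cox2_extension = NULL, repeats = FALSE,
                           seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, plant_features(g, config, orfan, tdrl, m_orf2,
                                          cox2_extension, repeats)))
  if (is.null(orfan))
    orfan <- switch(g$route, F = "F-orf", M = "M-orf", H = "H-orf", "none")
  if (is.null(tdrl)) tdrl <- g$route %in% c("M", "H")
  if (is.null(cox2_extension))
    cox2_extension <- if (g$route == "M") config$cox2_extension else 0L
  w <- base_weights(config$at_percent)
  truth <- list(orfans = NULL, tdrl = NULL, fragments = NULL,
                repeats = NULL, cox2 = NULL)
  # 1. primary ORFan
  if (orfan != "none") {
    codons <- switch(orfan, `M-orf` = config$m_orf_codons,
                     config$f_orf_codons)
    junction <- if (orfan == "M-orf") c("nad4L", "trnD") else
      c("trnI", "nad2")
    pos <- junction_pos(g, junction[1], junction[2])
    g <- genome_insert(g, pos, rand_orf_nt(codons, w),
                       feature = list(name = orfan, kind = "ORFan",
                                      strand = "+"))
  }
  # 2. TDRL with pseudogene decay
  if (isTRUE(tdrl)) {
    res <- plant_tdrl(g, config$tdrl_block, config$tdrl_assignment,
                      config$pseudo_decay)
    g <- res$genome
    truth$fragments <- res$fragments
    truth$tdrl <- res$witness
  }
  # 3. second M-orf between trnD and atp8 (their adjacency survives the
  #    TDRL by construction of the default assignment)
  if (isTRUE(m_orf2)) {
    pos <- junction_pos(g, "trnD", "atp8")
    truth$fragments <- shift_coords(truth$fragments, pos,
                                    3L * config$m_orf2_codons)
    g <- genome_insert(g, pos, rand_orf_nt(config$m_orf2_codons, w),
                       feature = list(name = "M-orf2", kind = "ORFan",
                                      strand = "+"))
  }
  # 4. in-frame 3' cox2 extension (inserted before the stop codon)
  if (cox2_extension > 0L) {
    ci <- which(g$features$name == "cox2")[1]
    old_len <- g$features$end[ci] - g$features$start[ci]
    pos <- g$features$end[ci] - 3L
    ext <- substr(rand_cds(cox2_extension + 6L, w), 4L,
                  cox2_extension + 3L)       # sense codons only
    truth$fragments <- shift_coords(truth$fragments, pos, cox2_extension)
    g <- genome_insert(g, pos, ext, allow_inside = "cox2")
    truth$cox2 <- list(old_length = old_len,
                       new_length = old_len + cox2_extension)
  }
  # 5. tandem repeat in the large control-region-like UR
  if (isTRUE(repeats)) {
    urs <- extract_unassigned_regions(g)
    big <- urs[which.max(urs$end - urs$start), ]
    pos <- big$start + (big$end - big$start) %/% 2L
    if (pos >= g$length) pos <- big$start  # wrapping UR: insert at its head
    unit <- paste(rand_bases(config$repeat_unit, w), collapse = "")
    copies <- vapply(seq_len(config$repeat_copies), function(i)
      paste(decay_bases(strsplit(unit, "")[[1]], config$repeat_decay),
            collapse = ""), character(1))
    rep_seq <- paste(copies, collapse = "")
    truth$fragments <- shift_coords(truth$fragments, pos, nchar(rep_seq))
    g <- genome_insert(g, pos, rep_seq)
    truth$repeats <- data.frame(
      genome_id = g$id, start = pos, end = pos + nchar(rep_seq),
      period = config$repeat_unit, copies = config$repeat_copies,
      stringsAsFactors = FALSE)
  }
  if (!is.null(truth$fragments)) truth$fragments$genome_id <- g$id
  orfan_rows <- g$features[g$features$kind == "ORFan", , drop = FALSE]
  if (nrow(orfan_rows)) {
    truth$orfans <- data.frame(genome_id = g$id, name = orfan_rows$name,
                               start = orfan_rows$start,
                               end = orfan_rows$end,
                               stringsAsFactors = FALSE)
  }
  list(genome = g, truth = truth)
}

#' Simulate a multi-species DUI study with known truth
#'
#' Generates a full F/M(/H) data set from one synthetic ancestor under
#' the configured transmission-pattern truth. Under gender-joining the
#' male-transmitted lineage diverges once at the root (so all M genomes
#' form a clade); under taxon-joining each species' M genome is derived
#' independently from that species' F genome. Branch targets are
#' composed through the Jukes-Cantor model so the realized intraspecific
#' F-M p-distance matches `target_p_nt`. M genomes receive the cox2
#' extension, the M-orf and the TDRL; the first species' M genome also
#' carries the second M-orf; the hermaphrodite (or, without one, the
#' first M genome) carries the planted tandem repeat.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: GenBank files, a labels table and
#'   truth tables are written there.
#' @return List of class `sim_study`: `genomes` (named list of
#'   `mito_genome`s), `labels` (data frame), `truth` (planted features,
#'   TDRL witness, fragments, repeats, expected pattern, ORF inventory)
#'   and `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  with_seed(config$seed, {
    anc <- .make_ancestor(config)
    d_target <- jukes_cantor(config$target_p_nt)
    d_tip <- jukes_cantor(config$tip_p)
    d_stem <- d_target - 2 * d_tip
    if (d_stem < 0) stop("tip_p too large for target_p_nt")
    p_stem <- 0.75 * (1 - exp(-4 / 3 * d_stem))
    gender <- config$pattern == "gender_joining"
    m_root <- if (gender)
      .evolve(anc, p_stem, config$target_omega, config$kappa)
    species <- paste("Synthetica",
                     c("alpha", "bravo", "charlie", "delta", "echo",
                       "foxtrot", "golf", "hotel")[seq_len(config$n_species)])
    genomes <- list(); labels <- list()
    truth <- list(orfans = NULL, fragments = NULL, repeats = NULL,
                  tdrl = NULL, pattern = config$pattern)
    add_truth <- function(tr) {
      truth$orfans <<- rbind(truth$orfans, tr$orfans)
      truth$fragments <<- rbind(truth$fragments, tr$fragments)
      truth$repeats <<- rbind(truth$repeats, tr$repeats)
      if (!is.null(tr$tdrl)) truth$tdrl <<- tr$tdrl
    }
    for (i in seq_len(config$n_species)) {
      herm <- config$include_h && i == config$n_species
      route_f <- if (herm) "H" else "F"
      gf <- .evolve(anc, config$tip_p, config$target_omega, config$kappa)
      gf$id <- sprintf("SYN%02d%s", i, route_f)
      gf$organism <- species[i]; gf$route <- route_f
      gm <- NULL
      if (!herm) {
        gm <- if (gender)
          .evolve(m_root, config$tip_p, config$target_omega, config$kappa)
        else
          .evolve(gf, config$target_p_nt, config$target_omega,
                  config$kappa)
        gm$id <- sprintf("SYN%02dM", i)
        gm$organism <- species[i]; gm$route <- "M"
      }
      pf <- plant_features(gf, config, repeats = herm)
      add_truth(pf$truth)
      genomes[[gf$id]] <- pf$genome
      labels[[length(labels) + 1L]] <- data.frame(
        genome_id = gf$id, organism = species[i], route = route_f,
        stringsAsFactors = FALSE)
      if (!is.null(gm)) {
        pm <- plant_features(gm, config, m_orf2 = i == 1L,
                             repeats = !config$include_h && i == 1L)
        add_truth(pm$truth)
        genomes[[gm$id]] <- pm$genome
        labels[[length(labels) + 1L]] <- data.frame(
          genome_id = gm$id, organism = species[i], route = "M",
          stringsAsFactors = FALSE)
      }
    }
    labels <- do.call(rbind, labels)
    truth$orf_inventory <- orf_census(genomes)$summary
    out <- list(genomes = genomes, labels = labels, truth = truth,
                config = config)
    class(out) <- "sim_study"
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (g in genomes)
        write_genbank(g, file.path(out_dir, paste0(g$id, ".gb")))
      utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in c("orfans", "fragments", "repeats"))
        if (!is.null(truth[[nm]]))
          utils::write.table(truth[[nm]],
                             file.path(out_dir,
                                       paste0("truth_", nm, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(c(paste("pattern:", truth$pattern),
                   paste("seed:", config$seed),
                   paste("scale:", config$scale)),
                 file.path(out_dir, "manifest.txt"))
    }
    out
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d genomes, %s truth, seed %d (%s scale)\n",
              length(x$genomes), x$truth$pattern, x$config$seed,
              x$config$scale))
  print(x$labels, row.names = FALSE)
  invisible(x)
}

#' Concatenated protein-coding supermatrix of a genome set
#'
#' Concatenates the shared protein-coding genes of all genomes, each
#' truncated to the shortest copy (which removes the M cox2 3'
#' extension), producing an aligned matrix for distance and tree
#' building when the sequences are indel-free orthologues. atp8 is
#' excluded by default as too variable to align reliably.
#'
#' @param genomes Named list of `mito_genome`s.
#' @param exclude Gene names to drop.
#' @return Named character vector of equal-length sequences.
#' @export
pcg_supermatrix <- function(genomes, exclude = "atp8") {
  stopifnot(length(genomes) >= 2L)
  genes <- setdiff(.PCG_NAMES, exclude)
  out <- stats::setNames(rep("", length(genomes)), names(genomes))
  for (gene in genes) {
    seqs <- lapply(genomes, function(g) {
      i <- which(g$features$name == gene & g$features$kind == "PCG")
      if (!length(i)) return(NULL)
      feature_seq(g, i[1])
    })
    if (any(vapply(seqs, is.null, logical(1)))) next
    len <- min(vapply(seqs, nchar, integer(1)))
    for (nm in names(genomes))
      out[[nm]] <- paste0(out[[nm]], substr(seqs[[nm]], 1L, len))
  }
  out
}
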