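test_that("the ancestor realizes the template: 37 genes, AT content, UR 1", {
  g <- mini_ancestor()
  expect_equal(nrow(g$features), 37)
  expect_equal(sum(g$features$kind == "PCG"), 13)
  expect_equal(sum(g$features$kind == "tRNA"), 22)
  expect_equal(sum(g$features$kind == "rRNA"), 2)
  expect_equal(g$topology, "circular")
  cfg <- sim_config(seed = 7, scale = "mini")
  expect_lte(abs(base_composition(g$sequence)$AT_percent -
                   cfg$at_percent), 2)
  # the control-region-like UR is UR 1, immediately upstream of cox1
  urs <- extract_unassigned_regions(g)
  expect_equal(urs$end[urs$index == 1] %% g$length,
               g$features$start[g$features$name == "cox1"])
  expect_equal(which.max(urs$end - urs$start), 1L)
  # every PCG translates cleanly: starts ATG, no internal stops
  for (r in which(g$features$kind == "PCG")) {
    nt <- feature_seq(g, r)
    expect_equal(substr(nt, 1, 3), "ATG")
    expect_no_error(translate_mt(nt))
  }
})

test_that("generation is deterministic: same config, same bytes", {
  cfg <- sim_config(seed = 123, scale = "mini", n_species = 2,
                    include_h = FALSE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # and a different seed changes the sequences
  g3 <- make_ancestor(sim_config(seed = 124, scale = "mini"))
  expect_false(identical(g3$sequence,
                         make_ancestor(cfg)$sequence))
})

test_that("evolve_pair hits the divergence target with zero as identity", {
  anc <- mini_ancestor()
  none <- evolve_pair(anc, target_p_nt = 0, seed = 5)
  expect_identical(none$f$sequence, none$m$sequence)
  pair <- evolve_pair(anc, target_p_nt = 0.40, target_omega = 0.33,
                      seed = 5)
  rep <- fm_divergence_report(pair$f, pair$m)
  conc <- rep[rep$gene == "concatenated_PCG", ]
  expect_lte(abs(conc$p_nt - 0.40), 0.02)
  expect_lte(abs(conc$omega - 0.33), 0.1)
  # truth table carries per-gene realized divergence
  expect_setequal(pair$truth$gene,
                  anc$features$name[anc$features$kind == "PCG"])
  expect_true(all(pair$truth$p_nt > 0.2))
  expect_error(evolve_genome(anc, 0.9), "0.75|target_p")
})

test_that("planted features land where the biology says they should", {
  cfg <- sim_config(seed = 7, scale = "mini")
  anc <- mini_ancestor()
  pair <- evolve_pair(anc, 0.3, seed = 9)
  pm <- plant_features(pair$m, cfg, m_orf2 = TRUE, repeats = TRUE,
                       seed = 10)
  g <- pm$genome
  f <- g$features
  # cox2 extended in frame, still a clean ORF
  expect_equal(f$end[f$name == "cox2"] - f$start[f$name == "cox2"],
               300 + cfg$cox2_extension)
  expect_no_error(translate_mt(feature_seq(g, "cox2")))
  # M-orf sits after nad4L; M-orf2 between trnD and atp8
  ord <- gene_order(g)$tokens
  expect_equal(ord[which(ord == "nad4L") + 1], "M-orf")
  expect_equal(ord[which(ord == "M-orf2") - 1], "trnD")
  expect_equal(ord[which(ord == "M-orf2") + 1], "atp8")
  expect_no_error(translate_mt(feature_seq(g, "M-orf")))
  # TDRL result: nad6 now precedes trnD (block reordered)
  expect_lt(which(ord == "nad6"), which(ord == "trnD"))
  # F genome gets its F-orf upstream of nad2
  pf <- plant_features(pair$f, cfg, seed = 11)
  ordf <- gene_order(pf$genome)$tokens
  expect_equal(ordf[which(ordf == "F-orf") + 1], "nad2")
  # extension 0 leaves cox2 untouched
  p0 <- plant_features(pair$f, cfg, orfan = "none", tdrl = FALSE,
                       cox2_extension = 0, seed = 12)
  expect_equal(p0$genome$features, pair$f$features)
})

test_that("every planted signal is recovered by its analysis stage", {
  st <- mini_study()
  cfg <- st$config
  anc_order <- gene_order(st$genomes[["SYN01F"]],
                          include = c("PCG", "rRNA", "tRNA"))
  for (gid in names(st$genomes)) {
    g <- st$genomes[[gid]]
    if (!g$route %in% c("M", "H")) next
    # TDRL: feasible from the F order with the planted witness shape
    go <- gene_order(g, include = c("PCG", "rRNA", "tRNA"))
    res <- tdrl_feasible(anc_order, go)
    expect_true(res$feasible)
    expect_setequal(res$witness$block, cfg$tdrl_block)
    expect_equal(res$witness$assignment[names(cfg$tdrl_assignment)],
                 cfg$tdrl_assignment)
    expect_true(go_equal(tdrl_replay(anc_order, res$witness), go))
    # pseudogene fragments recovered against the genome's own genes
    frag_truth <- st$truth$fragments[st$truth$fragments$genome_id == gid, ]
    refs <- sapply(cfg$tdrl_block, function(nm) feature_seq(g, nm))
    urs <- extract_unassigned_regions(g)
    hits <- find_pseudogene_fragments(urs, refs)
    for (k in seq_len(nrow(frag_truth))) {
      got <- hits[hits$reference == frag_truth$gene[k], ]
      expect_gte(nrow(got), 1)
    }
  }
  # planted repeat recovered with the right period
  rp <- st$truth$repeats
  g <- st$genomes[[rp$genome_id[1]]]
  found <- find_tandem_repeats(g$sequence, min_period = 50,
                               max_period = 200)
  ov <- found[found$end > rp$start[1] & found$start < rp$end[1], ]
  expect_gte(nrow(ov), 1)
  expect_lte(abs(ov$period[1] - rp$period[1]) / rp$period[1], 0.1)
  # census equals the inventory recorded at emission time
  cen <- orf_census(st$genomes)
  expect_identical(cen$summary, st$truth$orf_inventory)
})

test_that("gender- and taxon-joining truths are recovered by the NJ classifier", {
  # gender-joining at the deep F/M divergence of DUI unionids;
  # taxon-joining at the shallow divergence of a recent masculinization
  # (at deep divergence the convergent saturation of the two independent
  # M lineages erases the taxon-joining signal)
  for (pat in c("gender_joining", "taxon_joining")) {
    st <- mini_study(seed = 7, pattern = pat,
                     target_p_nt = if (pat == "taxon_joining") 0.20
                                   else 0.40)
    aln <- pcg_supermatrix(st$genomes)
    names(aln) <- tip_label(st$labels$organism, st$labels$route)
    tr <- neighbor_joining(p_distance_matrix(aln, correction = "jukes_cantor"))
    expect_equal(classify_pattern(tr)$pattern, pat)
    # intraspecific F-M divergence hits the target for every species
    d <- p_distance_matrix(aln)
    for (sp in unique(st$labels$organism)) {
      ids <- st$labels$genome_id[st$labels$organism == sp]
      if (length(ids) < 2) next
      lab <- tip_label(st$labels$organism[match(ids, st$labels$genome_id)],
                       st$labels$route[match(ids, st$labels$genome_id)])
      expect_lte(abs(d[lab[1], lab[2]] - st$config$target_p_nt), 0.02)
    }
  }
})
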