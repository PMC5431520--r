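# Shared fixtures. The mini simulated study is expensive enough to be
# worth computing once per test run.

.fixture_env <- new.env(parent = emptyenv())

mini_study <- function(seed = 7, pattern = "gender_joining",
                       target_p_nt = 0.40) {
  key <- paste0("study", seed, pattern, target_p_nt)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_study(
      sim_config(seed = seed, scale = "mini", pattern = pattern,
                 target_p_nt = target_p_nt))
  .fixture_env[[key]]
}

mini_ancestor <- function(seed = 7) {
  key <- paste0("anc", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_ancestor(sim_config(seed = seed,
                                                    scale = "mini"))
  .fixture_env[[key]]
}

# A tiny hand-built genome: length 1000, cox1 at [200, 500), trnD at
# [600, 666), atp8 at [700, 790), gaps elsewhere.
toy_genome <- function(seed = 1) {
  set.seed(seed)
  seq <- rand_dna(1000)
  annotated_genome(
    "TOY1", seq,
    features = data.frame(
      name = c("cox1", "trnD", "atp8"),
      start = c(200L, 600L, 700L), end = c(500L, 666L, 790L),
      strand = c("+", "+", "+")),
    organism = "Toyus exemplum", route = "F")
}
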