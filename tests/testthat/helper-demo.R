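# One cached demo run shared by the non-acceptance suite (the acceptance file
# runs its own full-default demos). Small config keeps the suite fast.
.demo_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 11L) {
  sim_config(
    lineages = data.frame(
      label = c("outgroup_eukaryote", "rhodophyte", "glaucophyte",
                "chlorophyte", "zygnematophyceae", "embryophyte"),
      n_species = c(2L, 2L, 1L, 3L, 2L, 4L),
      stringsAsFactors = FALSE),
    seed = seed, n_ogs = 80L, n_pog = 15L, n_mog = 10L, n_dual = 3L,
    n_rna_ogs = 6L)
}

get_demo <- function() {
  if (!is.null(.demo_env$demo)) return(.demo_env$demo)
  out <- file.path(tempdir(), "orgatlas-demo-cache")
  res <- run_demo(seed = 11L, out_dir = out, config = small_sim_config())
  .demo_env$demo <- list(out = out, fixture = file.path(out, "fixture"),
                         results = file.path(out, "results"), res = res)
  .demo_env$demo
}

# Small cached fixture (simulate_dataset only, no pipeline)
get_fixture <- function() {
  if (!is.null(.demo_env$fixture)) return(.demo_env$fixture)
  out <- file.path(tempdir(), "orgatlas-fixture-cache")
  sim <- simulate_dataset(small_sim_config(seed = 23L), out)
  .demo_env$fixture <- list(dir = out, sim = sim)
  .demo_env$fixture
}
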