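# Shared fixtures, built once per test run. The large runs reproduce the
# study conditions (1e6-read libraries, packaged profiles, fixed seeds);
# the small runs are decoy-free error-free round-trip fixtures.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_ref <- function() cached("ref_default", build_reference())

test_ref_nodecoys <- function() {
  cached("ref_nodecoys",
         build_reference(reference_config(n_perfect_decoys = 0L,
                                          n_near_decoys = 0L)))
}

# Error-free, decoy-free library: pipeline output must equal truth exactly.
clean_run <- function() {
  cached("clean_run", {
    ref <- test_ref_nodecoys()
    profs <- default_library_profiles(ref, read_count = 2e4, error_rate = 0)
    sim <- simulate_library(profs$bj_ev, ref, seed = 7L)
    aln <- align_reads(sim, ref)
    list(ref = ref, profile = profs$bj_ev, sim = sim, aln = aln,
         counts = count_genes(aln, ref, "bj_ev_clean"))
  })
}

# Study-condition runs: packaged profiles at 1e6 reads, fixed seeds.
big_run <- function(name, seed) {
  cached(paste0("big_", name), {
    ref <- test_ref()
    profs <- cached("profiles_1e6",
                    default_library_profiles(ref, read_count = 1e6))
    sim <- simulate_library(profs[[name]], ref, seed = seed)
    aln <- align_reads(sim, ref)
    list(sim = sim, aln = aln,
         counts = count_genes(aln, ref, name))
  })
}

big_bj_ev <- function() big_run("bj_ev", 201L)
big_bj_cell <- function() big_run("bj_cell", 202L)
big_k562_ev <- function() big_run("k562_ev", 203L)
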