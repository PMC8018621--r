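# Seeding discipline: one master seed per experiment. Replication r runs on
# the r-th L'Ecuyer-CMRG substream derived from the master seed with
# parallel::nextRNGStream(), so replications are mutually independent and
# each one is individually reproducible (re-deriving stream r gives the
# same replication regardless of how many others were run).

replication_streams <- function(master_seed, n) {
  with_preserved_rng({
    set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG")
    state <- get(".Random.seed", envir = globalenv())
    streams <- vector("list", n)
    for (i in seq_len(n)) {
      state <- parallel::nextRNGStream(state)
      streams[[i]] <- state
    }
    streams
  })
}

# evaluate code with the global RNG state saved and restored afterwards
with_preserved_rng <- function(code) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
      rm(".Random.seed", envir = ge)
    }
  })
  force(code)
}

# evaluate code under a specific full .Random.seed state (a substream)
with_rng_state <- function(state, code) {
  with_preserved_rng({
    assign(".Random.seed", state, envir = globalenv())
    force(code)
  })
}
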