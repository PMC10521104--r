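# Shared fixtures. The synthetic corpus set and the two end-to-end
# pipeline runs are expensive, so they are generated once per session
# and memoized for every test that needs them.

.fixture_env <- new.env(parent = emptyenv())

fixture_synth_dir <- function() {
  if (is.null(.fixture_env$synth_dir)) {
    d <- file.path(tempdir(), "lbvs-synth")
    unlink(d, recursive = TRUE)
    suppressMessages(generate_corpora(synthetic_config(seed = 1L), d))
    .fixture_env$synth_dir <- d
  }
  .fixture_env$synth_dir
}

fixture_manifest <- function() {
  jsonlite::fromJSON(file.path(fixture_synth_dir(), "manifest.json"),
                     simplifyVector = FALSE)
}

# full pipeline run n (1 or 2), memoized
fixture_run <- function(n = 1L) {
  key <- paste0("run", n)
  if (is.null(.fixture_env[[key]])) {
    outdir <- file.path(tempdir(), paste0("lbvs-run", n))
    unlink(outdir, recursive = TRUE)
    cfg <- synthetic_pipeline_config(fixture_synth_dir(), seed = 1L)
    suppressMessages(run_pipeline(cfg, outdir))
    .fixture_env[[key]] <- outdir
  }
  .fixture_env[[key]]
}

# deterministic sample of drug-like molecules from the shipped vocabulary
fixture_decoys <- function(n, from = 1L) {
  v <- decoy_vocabulary()
  v[seq(from, length.out = n), , drop = FALSE]
}

# naive reference Tanimoto on 0/1 vectors
naive_tanimoto <- function(x, y) {
  i <- sum(x == 1 & y == 1)
  u <- sum(x == 1 | y == 1)
  if (u == 0) 1 else i / u
}

as_dense <- function(fp) {
  v <- integer(attr(fp, "nbits"))
  v[unclass(fp) + 1L] <- 1L
  v
}

make_fp <- function(bits, nbits = 64L) {
  structure(as.integer(bits), nbits = as.integer(nbits), kind = "test",
            class = "lbvs_fp")
}
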