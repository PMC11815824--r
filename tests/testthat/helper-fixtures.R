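# Shared fixture builders.  Everything is generated in code; no binary data.

trehalose_spec <- function()
  disaccharide_spec("GLC", "GLC", linkage_spec(1L, "ALPHA", "ALPHA"))

maltose_spec <- function()
  disaccharide_spec("GLC", "GLC", linkage_spec(4L, "ALPHA", "BETA"))

all_specs <- function() enumerate_disaccharides(c("GLC", "MAN"))

# small trehalose pseudo-AA trajectory (memoised per session)
.fix_env <- new.env(parent = emptyenv())
small_traj <- function(n_frames = 5000L, seed = 11L) {
  key <- paste0("t", n_frames, "_", seed)
  if (is.null(.fix_env[[key]]))
    .fix_env[[key]] <- gen_pseudo_aa_traj(
      generator_spec(n_frames = n_frames, seed = seed))
  .fix_env[[key]]
}

# per-molecule bead sets from a single-bead-per-molecule frame
expect_sizes <- function(record, sizes)
  expect_identical(record$sizes, as.integer(sort(sizes, decreasing = TRUE)))
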