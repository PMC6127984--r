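# Reference simulation reused across tests: 50 scaffolds per class, 10 kb,
# 20X, overdispersion 0.2, two replicate pairs. Built once per test run.
.acc_cache <- new.env(parent = emptyenv())

acc_sim <- function() {
  if (is.null(.acc_cache$sim)) {
    spec <- sim_spec(n_autosomal = 50, n_z = 50, n_w = 50,
                     length_bp = 10000, coverage = 20, overdispersion = 0.2,
                     seed = 42)
    .acc_cache$sim <- simulate_depth(spec = spec)
  }
  .acc_cache$sim
}

acc_annotation <- function() {
  if (is.null(.acc_cache$ann)) {
    sim <- acc_sim()
    depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
    .acc_cache$ann <- annotate_genome(depth)
  }
  .acc_cache$ann
}

# per-scaffold AD-ratio averaged over replicate pairs, joined to the truth
acc_ratios <- function() {
  ann <- copy(acc_annotation())
  rt <- grep("^ratio_", names(ann), value = TRUE)
  ann[, mean_ratio := rowMeans(.SD), .SDcols = rt]
  merge(ann, acc_sim()$truth, by = "scaffold_id")
}

# multiply every count of one library by an integer factor, and its
# mapped-read count to match: the exact scale-invariance transformation
scale_sync_library <- function(sim, library_index, factor) {
  sync <- copy(sim$sync)
  col <- paste0("lib", library_index)
  cnt <- adratio::sync_counts(sync, library_index) * factor
  sync[, (col) := apply(cnt, 1, paste, collapse = ":")]
  setattr(sync, "n_libraries", attr(sim$sync, "n_libraries"))
  libs <- copy(sim$libraries)
  libs$mapped_read_count[library_index] <- libs$mapped_read_count[library_index] * factor
  list(sync = sync, index = sim$index, truth = sim$truth, libraries = libs)
}
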