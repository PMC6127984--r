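test_that("AD-ratio matches the 1/2/0 expectations and flags undefined cases", {
  expect_equal(ad_ratio(10, 10), 1)   # autosomal: equal depth in both sexes
  expect_equal(ad_ratio(10, 5), 2)    # Z: males carry two copies, females one
  expect_equal(ad_ratio(0, 5), 0)     # W: absent from ZZ males
  expect_true(is.na(ad_ratio(10, 0))) # undefined, never inferred to a class
  expect_error(ad_ratio(-1, 5), ">= 0")
  expect_error(ad_ratio(5, -1), ">= 0")
})

test_that("provisional labels follow the log2-symmetric bands with closed edges", {
  cfg <- classifier_config()
  expect_equal(provisional_label(1, cfg), "autosomal")
  expect_equal(provisional_label(2, cfg), "Z")
  expect_equal(provisional_label(0, cfg), "W")
  expect_equal(provisional_label(0.3, cfg), "W")
  # shared band edge sqrt(2) resolves to autosomal (closed interval, tested first)
  expect_equal(provisional_label(2^0.5, cfg), "autosomal")
  expect_equal(provisional_label(2^-0.5, cfg), "autosomal")
  expect_equal(provisional_label(2 * 2^0.5, cfg), "Z")
  expect_equal(provisional_label(NA_real_, cfg), "unclassified")
  expect_equal(provisional_label(c(0.5, 3), cfg), c("unclassified", "unclassified"))
})

test_that("with female depth fixed, labels move W -> unclassified -> autosomal -> Z without reversal", {
  cfg <- classifier_config()
  male <- seq(0, 40, by = 0.05)
  lab <- provisional_label(ad_ratio(male, rep(10, length(male))), cfg)
  order_idx <- c(W = 1, unclassified = 2, autosomal = 3, Z = 4)
  steps <- order_idx[lab]
  # allowed transitions: stay, move up by one, or drop from Z/autosomal back to
  # unclassified only after the top band (no reversal into a lower class band)
  runs <- rle(lab)$values
  expect_equal(runs, c("W", "unclassified", "autosomal", "Z", "unclassified"))
  expect_true(all(diff(match(runs[1:4], names(order_idx))) > 0))
  expect_equal(unname(steps[1]), 1)
})

test_that("config bands must be ordered and non-overlapping", {
  expect_error(classifier_config(w_max_ratio = 0.8), "w_max_ratio < low")
  expect_error(classifier_config(autosomal_band = c(0.7, 2.5)), "low\\(z_band\\)")
  expect_error(classifier_config(min_mean_depth_x = -1), ">= 0")
  expect_silent(classifier_config(min_mean_depth_x = 0))
})

test_that("final label applies depth filter, then replicate concordance", {
  cfg <- classifier_config()
  expect_equal(finalize_label(c("autosomal", "autosomal"), c(5, 6, 7, 8), cfg), "autosomal")
  expect_equal(finalize_label(c("Z", "autosomal"), c(5, 6, 7, 8), cfg), "ambiguous")
  expect_equal(finalize_label(c("Z", "Z"), c(5, 6, 3.9, 8), cfg), "unannotated")
  expect_equal(finalize_label(c("W", "W"), c(5, 6, 7, 8), cfg), "W")
  expect_equal(finalize_label(c("unclassified", "unclassified"), c(5, 6, 7, 8), cfg),
               "ambiguous")
  expect_error(finalize_label(character(0), c(5, 6), cfg), "at least one")
})

test_that("annotate_genome recovers the simulated truth on well-covered scaffolds", {
  spec <- sim_spec(n_autosomal = 50, n_z = 10, n_w = 5, length_bp = 10000,
                   coverage = 20, low_coverage_fraction = 0, seed = 1)
  sim <- simulate_depth(spec = spec)
  depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
  ann <- annotate_genome(depth, classifier_config(min_mean_depth_x = 0))
  m <- merge(ann, sim$truth, by = "scaffold_id")
  expect_equal(nrow(m), 65L)
  expect_true(all(m[true_class == "Z", final_label] == "Z"))
  expect_true(all(m[true_class == "autosomal", final_label] == "autosomal"))
  expect_true(all(m[true_class == "W", final_label] == "W"))
  # at the default 4X filter, W scaffolds are un-annotated (zero male depth)
  ann4 <- annotate_genome(depth)
  m4 <- merge(ann4, sim$truth, by = "scaffold_id")
  expect_true(all(m4[true_class == "W", final_label] == "unannotated"))
  expect_true(all(m4[true_class == "Z", final_label] == "Z"))
})

test_that("a single replicate pair warns and cannot produce discordance ambiguity", {
  spec <- sim_spec(n_autosomal = 10, n_z = 3, n_w = 0, length_bp = 10000,
                   n_pairs = 1, low_coverage_fraction = 0, seed = 2)
  sim <- simulate_depth(spec = spec)
  depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
  expect_warning(ann <- annotate_genome(depth), "one male/female pair")
  expect_false(any(ann$final_label == "ambiguous"))
})

test_that("all-pairs mode crosses every male with every female", {
  sim <- simulate_depth(spec = sim_spec(n_autosomal = 3, n_z = 1, n_w = 0,
                                        length_bp = 2000, low_coverage_fraction = 0,
                                        seed = 13))
  depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
  ann <- annotate_genome(depth, pairing = "all")
  expect_length(grep("^ratio_", names(ann)), 4L)
  expect_setequal(attr(ann, "pairs")$pair_id, c("M1xF1", "M1xF2", "M2xF1", "M2xF2"))
})

test_that("every scaffold gets exactly one label and the partition conserves totals", {
  for (seed in c(4, 14)) {
    sim <- simulate_depth(spec = sim_spec(n_autosomal = 12, n_z = 4, n_w = 2,
                                          length_bp = c(500, 3000), seed = seed))
    depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
    ann <- annotate_genome(depth)
    expect_equal(nrow(ann), nrow(sim$index))
    expect_true(all(ann$final_label %in%
                      c("autosomal", "Z", "ambiguous", "W", "unannotated")))
    s <- summarize_partition(ann)
    expect_equal(sum(s$n_scaffolds), nrow(sim$index))
    expect_equal(sum(s$total_mb), sum(sim$index$length_bp) / 1e6)
    expect_equal(attr(s, "total_scaffolds"), nrow(sim$index))
  }
})

test_that("partition summary reports counts and megabases per label", {
  ann <- data.table::data.table(scaffold_id = c("a", "b"),
                                length_bp = c(500000L, 500000L),
                                final_label = "autosomal")
  s <- summarize_partition(ann)
  expect_equal(s[s$final_label == "autosomal", ]$n_scaffolds, 2L)
  expect_equal(s[s$final_label == "autosomal", ]$total_mb, 1.0)
  expect_output(print(s), "putatively Z-heterosomal")

  s0 <- summarize_partition(ann[0])
  expect_equal(sum(s0$n_scaffolds), 0L)
  expect_equal(sum(s0$total_mb), 0)
})
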