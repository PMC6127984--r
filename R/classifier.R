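#' Classifier configuration
#'
#' The AD-ratio expectations are 1 (autosomal), 2 (Z) and 0 (W); the bands
#' that turn a noisy ratio into a provisional label are symmetric on the log2
#' scale: autosomal when `|log2(ratio)| <= 0.5`, Z when `|log2(ratio/2)| <=
#' 0.5`, W when `ratio <= w_max_ratio`. Bands are closed intervals; the
#' autosomal and Z defaults share the edge `sqrt(2)`, which resolves to
#' autosomal (the autosomal band is tested first). Scaffolds whose raw mean
#' depth is below `min_mean_depth_x` (X units, not normalized depth) in any
#' library are left un-annotated.
#'
#' @param min_mean_depth_x minimum raw mean depth per library, in X (default 4).
#' @param autosomal_band closed ratio interval for the autosomal call.
#' @param z_band closed ratio interval for the Z call.
#' @param w_max_ratio maximum ratio for the W call.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(min_mean_depth_x = 4,
                              autosomal_band = c(2^-0.5, 2^0.5),
                              z_band = c(2 * 2^-0.5, 2 * 2^0.5),
                              w_max_ratio = 0.3) {
  stopifnot(length(autosomal_band) == 2L, length(z_band) == 2L,
            length(w_max_ratio) == 1L, length(min_mean_depth_x) == 1L)
  if (min_mean_depth_x < 0) stop("min_mean_depth_x must be >= 0")
  if (autosomal_band[1] > autosomal_band[2] || z_band[1] > z_band[2])
    stop("band bounds must be ordered low <= high")
  if (!(w_max_ratio < autosomal_band[1]))
    stop("bands must be ordered: w_max_ratio < low(autosomal_band)")
  if (!(autosomal_band[2] <= z_band[1]))
    stop("bands must be ordered: high(autosomal_band) <= low(z_band)")
  structure(list(min_mean_depth_x = min_mean_depth_x,
                 autosomal_band = autosomal_band,
                 z_band = z_band,
                 w_max_ratio = w_max_ratio),
            class = "classifier_config")
}

#' AD-ratio between a male and a female library
#'
#' Ratio of normalized depth, male (homogametic, ZZ) over female
#' (heterogametic, ZW). Expectation: 1 for autosomal scaffolds, 2 for Z, 0
#' for W. When the female depth is 0 the ratio is undefined and `NA` is
#' returned (never inferred to be Z or W); scaffolds with zero depth in every
#' library are removed upstream by the minimum-depth filter.
#'
#' @param norm_depth_male,norm_depth_female normalized depths (vectorized).
#' @return numeric vector of ratios, `NA` where undefined.
#' @examples
#' ad_ratio(10, 10)  # 1: autosomal expectation
#' ad_ratio(10, 5)   # 2: Z expectation
#' ad_ratio(0, 5)    # 0: W expectation
#' @export
ad_ratio <- function(norm_depth_male, norm_depth_female) {
  if (any(norm_depth_male < 0) || any(norm_depth_female < 0))
    stop("depths must be >= 0")
  fifelse(norm_depth_female > 0, norm_depth_male / norm_depth_female, NA_real_)
}

#' Provisional label from one AD-ratio
#'
#' @param ratio numeric vector of AD-ratios (`NA` = undefined).
#' @param config a [classifier_config()].
#' @return character vector in `autosomal`, `Z`, `W`, `unclassified`.
#' @export
provisional_label <- function(ratio, config = classifier_config()) {
  out <- rep("unclassified", length(ratio))
  def <- !is.na(ratio)
  out[def & ratio <= config$w_max_ratio] <- "W"
  out[def & ratio >= config$autosomal_band[1] & ratio <= config$autosomal_band[2]] <- "autosomal"
  out[def & out == "unclassified" & ratio >= config$z_band[1] & ratio <= config$z_band[2]] <- "Z"
  out
}

#' Final label from per-pair provisional labels and raw depths
#'
#' Rules, in order: (1) raw mean depth below the threshold in one or several
#' libraries leaves the scaffold un-annotated; (2) identical provisional
#' labels across all replicate pairs (and not `unclassified`) give that
#' label; (3) anything else — including discordant pairs, the lack of
#' AD-ratio reproducibility between replicates — is ambiguous.
#'
#' @param labels character vector of per-pair provisional labels.
#' @param raw_depths numeric vector of per-library raw mean depths (X).
#' @param config a [classifier_config()].
#' @return one of `autosomal`, `Z`, `ambiguous`, `W`, `unannotated`.
#' @export
finalize_label <- function(labels, raw_depths, config = classifier_config()) {
  if (length(labels) < 1L) stop("at least one replicate pair is required")
  if (any(raw_depths < config$min_mean_depth_x)) return("unannotated")
  u <- unique(labels)
  if (length(u) == 1L && u != "unclassified") return(u)
  "ambiguous"
}

# derive male/female pairs from library metadata
.make_pairs <- function(libraries, pairing = c("replicate", "all")) {
  pairing <- match.arg(pairing)
  libraries <- as.data.table(libraries)
  if (pairing == "replicate") {
    pairs <- merge(libraries[sex == "male", .(replicate_pair_id, male = library_id)],
                   libraries[sex == "female", .(replicate_pair_id, female = library_id)],
                   by = "replicate_pair_id")
    setnames(pairs, "replicate_pair_id", "pair_id")
  } else {
    pairs <- CJ(male = libraries[sex == "male", library_id],
                female = libraries[sex == "female", library_id])
    pairs[, pair_id := paste0(male, "x", female)]
  }
  setorder(pairs, pair_id)
  pairs[, .(pair_id, male, female)]
}

#' Annotate every scaffold of a genome
#'
#' Computes the AD-ratio and provisional label for every male/female
#' replicate pair and combines them into the final 5-way annotation
#' (`autosomal`, `Z`, `ambiguous`, `W`, `unannotated`).
#'
#' @param depth a `scaffold_depth` object from [sync_scaffold_depth()].
#' @param config a [classifier_config()].
#' @param pairing `"replicate"` (default) pairs libraries by their
#'   `replicate_pair_id`, following the one-male-plus-one-female pool design;
#'   `"all"` crosses every male with every female library.
#' @return a `data.table` with one row per scaffold: `scaffold_id`,
#'   `length_bp`, per-library `raw_*` and `norm_*` depths, per-pair `ratio_*`
#'   and `label_*`, and `final_label`. The pair table is attached as the
#'   `pairs` attribute.
#' @export
annotate_genome <- function(depth, config = classifier_config(),
                            pairing = c("replicate", "all")) {
  stopifnot(inherits(depth, "scaffold_depth"))
  if (any(!is.finite(depth$raw)) || any(!is.finite(depth$norm)))
    stop("depth data error: every scaffold needs a finite depth for every library")
  pairs <- .make_pairs(depth$libraries, pairing)
  if (nrow(pairs) == 1L)
    warning("only one male/female pair: the replicate-reproducibility rule is inoperative; ",
            "two independent biological replicates are needed to flag ambiguous scaffolds")

  ann <- data.table(scaffold_id = depth$scaffolds$scaffold_id,
                    length_bp = depth$scaffolds$length_bp)
  for (lib in depth$libraries$library_id) ann[, (paste0("raw_", lib)) := depth$raw[, lib]]
  for (lib in depth$libraries$library_id) ann[, (paste0("norm_", lib)) := depth$norm[, lib]]

  lab <- matrix(NA_character_, nrow = nrow(ann), ncol = nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    r <- ad_ratio(depth$norm[, pairs$male[k]], depth$norm[, pairs$female[k]])
    ann[, (paste0("ratio_", pairs$pair_id[k])) := r]
    lab[, k] <- provisional_label(r, config)
    ann[, (paste0("label_", pairs$pair_id[k])) := lab[, k]]
  }

  low <- apply(depth$raw < config$min_mean_depth_x, 1L, any)
  concordant <- lab[, 1L]
  for (k in seq_len(ncol(lab))[-1L])
    concordant[concordant != lab[, k]] <- "<discordant>"
  final <- fifelse(low, "unannotated",
                   fifelse(concordant %in% c("<discordant>", "unclassified"),
                           "ambiguous", concordant))
  ann[, final_label := final]
  setattr(ann, "pairs", pairs)
  setattr(ann, "config", config)
  ann[]
}

#' Summarize the assembly partition
#'
#' Scaffold counts and megabases per final label, in the fixed order
#' autosomal, Z, ambiguous, W, unannotated. The ambiguous class (replicate
#' pairs in disagreement) is also known as "putatively Z-heterosomal".
#'
#' @param annotations annotation `data.table` from [annotate_genome()].
#' @return a `partition_summary` `data.table` with columns `final_label`,
#'   `n_scaffolds`, `total_mb`; totals are in the `total_scaffolds` and
#'   `total_mb` attributes.
#' @export
summarize_partition <- function(annotations) {
  ann <- as.data.table(annotations)
  s <- ann[, .(n_scaffolds = .N, total_mb = sum(as.numeric(length_bp)) / 1e6),
           by = final_label]
  out <- data.table(final_label = .FINAL_LABELS)
  out <- s[out, on = "final_label"]
  out[is.na(n_scaffolds), `:=`(n_scaffolds = 0L, total_mb = 0)]
  setattr(out, "total_scaffolds", nrow(ann))
  setattr(out, "total_mb", sum(as.numeric(ann$length_bp)) / 1e6)
  setattr(out, "class", c("partition_summary", class(out)))
  out[]
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("Assembly partition by depth-based annotation\n")
  shown <- copy(as.data.table(x))
  shown[final_label == "ambiguous", final_label := "ambiguous (putatively Z-heterosomal)"]
  print(as.data.frame(shown), row.names = FALSE)
  cat(sprintf("total: %d scaffolds, %.2f Mb\n",
              attr(x, "total_scaffolds"), attr(x, "total_mb")))
  invisible(x)
}
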