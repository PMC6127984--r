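# Independent flat recomputation of the whole classification, written with
# plain loops and strsplit so it shares no code path with the package.
oracle_annotate <- function(sync, index, meta, config = list(
                              min_depth = 4,
                              a_lo = 2^-0.5, a_hi = 2^0.5,
                              z_lo = 2 * 2^-0.5, z_hi = 2 * 2^0.5,
                              w_max = 0.3)) {
  sync <- as.data.frame(sync); index <- as.data.frame(index); meta <- as.data.frame(meta)
  nlib <- nrow(meta)
  labels <- character(nrow(index))
  names(labels) <- index$scaffold_id
  pair_ids <- sort(unique(meta$replicate_pair_id))
  for (s in seq_len(nrow(index))) {
    sid <- index$scaffold_id[s]
    rows <- which(sync$scaffold_id == sid)
    raw <- norm <- numeric(nlib)
    for (j in seq_len(nlib)) {
      total <- 0
      for (r in rows) {
        cnt <- as.integer(strsplit(sync[[paste0("lib", j)]][r], ":")[[1]])
        total <- total + cnt[1] + cnt[2] + cnt[3] + cnt[4]
      }
      raw[j] <- total / index$length_bp[s]
      norm[j] <- raw[j] * 1e6 / meta$mapped_read_count[j]
    }
    if (any(raw < config$min_depth)) { labels[s] <- "unannotated"; next }
    plab <- character(0)
    for (p in pair_ids) {
      jm <- which(meta$replicate_pair_id == p & meta$sex == "male")
      jf <- which(meta$replicate_pair_id == p & meta$sex == "female")
      if (norm[jf] == 0) { plab <- c(plab, "unclassified"); next }
      r <- norm[jm] / norm[jf]
      lab <- if (r <= config$w_max) "W"
        else if (r >= config$a_lo && r <= config$a_hi) "autosomal"
        else if (r >= config$z_lo && r <= config$z_hi) "Z"
        else "unclassified"
      plab <- c(plab, lab)
    }
    labels[s] <- if (length(unique(plab)) == 1L && plab[1] != "unclassified") plab[1]
                 else "ambiguous"
  }
  labels
}

# random tiny sync dataset with known structure but arbitrary counts,
# exercising N/del columns, uncovered scaffolds and the depth filter
random_small_case <- function(seed) {
  set.seed(seed)
  n_scf <- sample(1:10, 1)
  index <- data.table::data.table(
    scaffold_id = sprintf("rs%02d", seq_len(n_scf)),
    length_bp = sample(5:100, n_scf, replace = TRUE))
  meta <- data.table::data.table(
    library_id = c("M1", "F1", "M2", "F2"),
    sex = c("male", "female", "male", "female"),
    mapped_read_count = sample(1e5:1e6, 4),
    replicate_pair_id = c("P1", "P1", "P2", "P2"))
  rows <- list()
  for (s in seq_len(n_scf)) {
    if (runif(1) < 0.15) next  # leave some scaffolds uncovered entirely
    pos <- sort(sample(seq_len(index$length_bp[s]),
                       sample(seq_len(index$length_bp[s]), 1)))
    piece <- data.table::data.table(
      scaffold_id = index$scaffold_id[s], pos = pos,
      ref = sample(c("A", "C", "G", "T"), length(pos), replace = TRUE))
    scale <- sample(c(0, 1, 2, 5), 1)  # per-scaffold depth regime
    for (j in 1:4) {
      cnt <- matrix(rpois(length(pos) * 6, lambda = c(8, 1, 1, 1, 2, 1) * scale),
                    ncol = 6, byrow = TRUE)
      piece[[paste0("lib", j)]] <- apply(cnt, 1, paste, collapse = ":")
    }
    rows[[length(rows) + 1L]] <- piece
  }
  sync <- if (length(rows)) data.table::rbindlist(rows) else {
    s <- data.table::data.table(scaffold_id = character(), pos = integer(),
                                ref = character())
    for (j in 1:4) s[[paste0("lib", j)]] <- character()
    s
  }
  data.table::setattr(sync, "n_libraries", 4L)
  list(sync = sync, index = index, meta = meta)
}
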