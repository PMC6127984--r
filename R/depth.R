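#' Mean depth of a scaffold
#'
#' Mean over the FULL scaffold length: positions absent from the depth stream
#' count as depth 0, so sparsely covered scaffolds get a low mean (and fall
#' below the minimum-depth filter) rather than appearing deep.
#'
#' @param base_depths a `data.frame`/`data.table` with columns `pos` and
#'   `depth` (at most one row per position), or a bare numeric vector of
#'   depths at covered positions.
#' @param scaffold_length scaffold length in bp.
#' @param scaffold_id optional id used in error messages.
#' @return mean depth in X units (mean sequenced bases per position).
#' @examples
#' scaffold_mean_depth(data.frame(pos = 1:5, depth = rep(10, 5)), 10)  # 5
#' @export
scaffold_mean_depth <- function(base_depths, scaffold_length, scaffold_id = "?") {
  if (scaffold_length < 1L) stop("scaffold_length must be >= 1")
  if (is.numeric(base_depths)) {
    depths <- base_depths
  } else {
    base_depths <- as.data.table(base_depths)
    if (nrow(base_depths)) {
      bad <- base_depths[pos < 1L | pos > scaffold_length]
      if (nrow(bad))
        stop(sprintf("depth data error: scaffold %s has position %d outside [1, %d]",
                     scaffold_id, bad$pos[1L], as.integer(scaffold_length)))
      if (anyDuplicated(base_depths$pos))
        stop("depth data error: scaffold ", scaffold_id, " has duplicate positions")
    }
    depths <- base_depths$depth
  }
  if (any(depths < 0)) stop("depth data error: negative depth on scaffold ", scaffold_id)
  sum(as.numeric(depths)) / scaffold_length
}

#' Standardize mean depth by library size
#'
#' Depth per million mapped reads: `raw_mean * 1e6 / mapped_reads`. Any fixed
#' constant cancels in the male/female ratio; 1e6 keeps the numbers readable.
#'
#' @param raw_mean raw mean depth (X units).
#' @param mapped_reads mapped-read count of the library (>= 1).
#' @return normalized depth.
#' @export
normalize_depth <- function(raw_mean, mapped_reads) {
  if (any(mapped_reads < 1)) stop("mapped_reads must be >= 1")
  if (any(raw_mean < 0)) stop("raw_mean must be >= 0")
  raw_mean * 1e6 / mapped_reads
}

#' Aggregate a sync table into per-scaffold depth per library
#'
#' Computes each library's raw mean depth over every scaffold of the index
#' (scaffolds absent from the sync data get mean 0) and the normalized depth
#' per million mapped reads.
#'
#' @param sync a sync `data.table` from [read_sync()] or [simulate_depth()],
#'   a path to a sync file, or a vector of paths whose library columns,
#'   concatenated in order, follow the order of `libraries` (one file per
#'   sequencing pool).
#' @param index scaffold index from [read_scaffold_index()] (or a path).
#' @param libraries library metadata from [read_library_meta()] (or a path);
#'   row order defines the library column order of `sync`.
#' @return a `scaffold_depth` object: a list with `scaffolds` (the index),
#'   `libraries` (the metadata), and matrices `raw` and `norm`
#'   (scaffold x library).
#' @export
sync_scaffold_depth <- function(sync, index, libraries) {
  if (is.character(index)) index <- read_scaffold_index(index)
  index <- as.data.table(index)
  if (is.character(libraries)) libraries <- read_library_meta(libraries)
  libraries <- as.data.table(libraries)
  validate_library_meta(libraries)

  syncs <- if (is.character(sync)) lapply(sync, read_sync) else list(sync)
  nlib_each <- vapply(syncs, function(s)
    attr(s, "n_libraries", exact = TRUE) %||% (ncol(s) - 3L), 1L)
  if (sum(nlib_each) != nrow(libraries))
    stop(sprintf("sync data carry %d library columns but metadata lists %d libraries",
                 sum(nlib_each), nrow(libraries)))

  raw <- matrix(0, nrow = nrow(index), ncol = nrow(libraries),
                dimnames = list(index$scaffold_id, libraries$library_id))
  off <- 0L
  for (s in syncs) {
    unknown <- setdiff(unique(s$scaffold_id), index$scaffold_id)
    if (length(unknown))
      stop("sync data mention scaffold(s) absent from the index: ",
           paste(head(unknown, 3L), collapse = ", "))
    dep <- sync_base_depth(s)
    # positions must lie within each scaffold
    chk <- dep[index, on = "scaffold_id", nomatch = NULL][pos > length_bp | pos < 1L]
    if (nrow(chk))
      stop(sprintf("depth data error: scaffold %s has position %d outside [1, %d]",
                   chk$scaffold_id[1L], chk$pos[1L], chk$length_bp[1L]))
    nlib <- ncol(dep) - 2L
    tot <- dep[, lapply(.SD, function(x) sum(as.numeric(x))),
               by = scaffold_id, .SDcols = paste0("depth", seq_len(nlib))]
    idx <- match(tot$scaffold_id, index$scaffold_id)
    for (j in seq_len(nlib))
      raw[idx, off + j] <- tot[[paste0("depth", j)]] / index$length_bp[idx]
    off <- off + nlib
  }
  norm <- sweep(raw, 2L, libraries$mapped_read_count / 1e6, "/")
  structure(list(scaffolds = index, libraries = libraries, raw = raw, norm = norm),
            class = "scaffold_depth")
}

#' @export
print.scaffold_depth <- function(x, ...) {
  cat(sprintf("<scaffold_depth> %d scaffolds x %d libraries (%s)\n",
              nrow(x$raw), ncol(x$raw),
              paste(sprintf("%s[%s]", x$libraries$library_id, substr(x$libraries$sex, 1, 1)),
                    collapse = ", ")))
  cat(sprintf("  raw mean depth range: %.2f-%.2fX\n", min(x$raw), max(x$raw)))
  invisible(x)
}
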