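#' Read a Popoolation2 synchronized allele-count file
#'
#' A sync file is tab-separated with no header: scaffold id, 1-based position,
#' reference base, then one colon-separated `A:T:C:G:N:del` count field per
#' library. Only covered positions are present; absent positions are depth 0.
#'
#' @param path path to a sync file.
#' @param n_libraries expected number of library columns; if `NULL`, inferred
#'   from the first line. A mismatch is a format error naming the line.
#' @return a `data.table` with columns `scaffold_id`, `pos`, `ref`, and one
#'   character count column per library named `lib1`, `lib2`, ...; the number
#'   of libraries is stored in the `n_libraries` attribute.
#' @examples
#' f <- tempfile(fileext = ".sync")
#' writeLines("scaf1\t5\tA\t10:0:0:0:0:0\t3:2:0:0:0:0", f)
#' read_sync(f)
#' @seealso [sync_base_depth()], [write_sync()]
#' @export
read_sync <- function(path, n_libraries = NULL) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  if (file.size(path) == 0L) {
    nlib <- if (is.null(n_libraries)) 0L else as.integer(n_libraries)
    return(.empty_sync(nlib))
  }
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
              fill = TRUE, quote = "", blank.lines.skip = FALSE)
  if (nrow(dt) == 0L) {
    nlib <- if (is.null(n_libraries)) 0L else as.integer(n_libraries)
    return(.empty_sync(nlib))
  }
  # drop a trailing empty line if present
  if (dt[[1L]][nrow(dt)] == "" && all(vapply(dt[nrow(dt)], function(x) x == "" | is.na(x), TRUE)))
    dt <- dt[-nrow(dt)]
  nlib_found <- ncol(dt) - 3L
  if (nlib_found < 1L)
    stop("sync format error: expected at least 4 tab-separated columns in ", path)
  if (!is.null(n_libraries) && nlib_found != n_libraries) {
    stop(sprintf("sync format error in %s, line 1: found %d library columns, expected %d",
                 path, nlib_found, as.integer(n_libraries)))
  }
  setnames(dt, c("scaffold_id", "pos", "ref", paste0("lib", seq_len(nlib_found))))
  # a short line leaves NA/"" in the trailing columns
  bad <- which(is.na(dt[[ncol(dt)]]) | dt[[ncol(dt)]] == "")
  if (length(bad))
    stop(sprintf("sync format error in %s, line %d: wrong number of columns", path, bad[1L]))
  pos_int <- suppressWarnings(as.integer(dt$pos))
  if (anyNA(pos_int))
    stop(sprintf("sync format error in %s, line %d: non-integer position '%s'",
                 path, which(is.na(pos_int))[1L], dt$pos[which(is.na(pos_int))[1L]]))
  if (any(pos_int < 1L))
    stop(sprintf("sync format error in %s, line %d: position < 1", path, which(pos_int < 1L)[1L]))
  set(dt, j = "pos", value = pos_int)
  for (j in seq_len(nlib_found)) {
    col <- dt[[paste0("lib", j)]]
    ok <- grepl("^[0-9]+(:[0-9]+){5}$", col)
    if (!all(ok))
      stop(sprintf("sync format error in %s, line %d: malformed count field '%s' (library %d)",
                   path, which(!ok)[1L], col[which(!ok)[1L]], j))
  }
  setattr(dt, "n_libraries", nlib_found)
  dt[]
}

.empty_sync <- function(n_libraries) {
  cols <- c(list(scaffold_id = character(), pos = integer(), ref = character()),
            setNames(rep(list(character()), n_libraries),
                     if (n_libraries > 0) paste0("lib", seq_len(n_libraries)) else character()))
  dt <- as.data.table(cols)
  setattr(dt, "n_libraries", as.integer(n_libraries))
  dt
}

#' Write a synchronized allele-count table to disk
#'
#' Inverse of [read_sync()]: writes tab-separated, no header, no quoting.
#'
#' @param sync a sync `data.table` as returned by [read_sync()] or
#'   [simulate_depth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  fwrite(sync, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand one library's count field into a 6-column integer matrix
#'
#' Columns are `A`, `T`, `C`, `G`, `N`, `del` in sync order.
#'
#' @param sync a sync `data.table`.
#' @param library_index 1-based library column index.
#' @return integer matrix with one row per sync record.
#' @export
sync_counts <- function(sync, library_index) {
  nlib <- attr(sync, "n_libraries", exact = TRUE) %||% (ncol(sync) - 3L)
  if (library_index < 1L || library_index > nlib)
    stop("library_index out of range: ", library_index, " (file has ", nlib, " libraries)")
  m <- matrix(0L, nrow = nrow(sync), ncol = 6L,
              dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
  if (nrow(sync) == 0L) return(m)
  parts <- tstrsplit(sync[[paste0("lib", library_index)]], ":", fixed = TRUE)
  for (k in seq_len(6L)) m[, k] <- as.integer(parts[[k]])
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequenced-base depth from an allele-count tuple
#'
#' Depth at a base is the sum of the `A`, `T`, `C`, `G` counts only: the `N`
#' column holds bases masked for low quality upstream (rejected evidence) and
#' deletions are not sequenced bases, so neither contributes.
#'
#' @param counts a numeric vector of 6 counts (`A,T,C,G,N,del`) or a matrix
#'   with 6 such columns.
#' @return a non-negative integer (or one per matrix row).
#' @examples
#' base_depth(c(10, 0, 0, 0, 0, 0))  # 10
#' base_depth(c(3, 2, 0, 0, 5, 1))   # 5: the N and del columns are ignored
#' @export
base_depth <- function(counts) {
  if (is.matrix(counts)) {
    if (ncol(counts) != 6L) stop("count matrix must have 6 columns (A,T,C,G,N,del)")
    if (any(counts < 0)) stop("negative allele count")
    return(as.integer(rowSums(counts[, 1:4, drop = FALSE])))
  }
  if (length(counts) != 6L) stop("count tuple must have 6 elements (A,T,C,G,N,del)")
  if (any(counts < 0)) stop("negative allele count")
  as.integer(sum(counts[1:4]))
}

#' Per-base depth for every library in a sync table
#'
#' @param sync a sync `data.table` from [read_sync()].
#' @return a `data.table` with `scaffold_id`, `pos`, and one integer depth
#'   column per library (`depth1`, `depth2`, ...).
#' @export
sync_base_depth <- function(sync) {
  nlib <- attr(sync, "n_libraries", exact = TRUE) %||% (ncol(sync) - 3L)
  out <- sync[, .(scaffold_id, pos)]
  for (j in seq_len(nlib))
    out[, (paste0("depth", j)) := base_depth(sync_counts(sync, j))]
  out[]
}
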