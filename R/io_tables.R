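#' Read scaffold lengths from a `.fai`-style table
#'
#' The first two tab-separated columns are taken as scaffold id and length in
#' bp; extra columns (as in a full `samtools faidx` index) are ignored. The
#' file may or may not carry a `scaffold_id<TAB>length_bp` header.
#'
#' @param path path to the index file.
#' @return a `data.table` with columns `scaffold_id` (character, unique) and
#'   `length_bp` (integer, >= 1).
#' @export
read_scaffold_index <- function(path) {
  if (!file.exists(path)) stop("scaffold index not found: ", path)
  if (file.size(path) == 0L)
    return(data.table(scaffold_id = character(), length_bp = integer()))
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L)
    return(data.table(scaffold_id = character(), length_bp = integer()))
  if (ncol(dt) < 2L) stop("scaffold index must have at least 2 tab-separated columns: ", path)
  dt <- dt[, 1:2]
  setnames(dt, c("scaffold_id", "length_bp"))
  if (identical(tolower(dt$scaffold_id[1L]), "scaffold_id")) dt <- dt[-1L]
  len <- suppressWarnings(as.integer(dt$length_bp))
  if (anyNA(len)) {
    i <- which(is.na(len))[1L]
    stop(sprintf("scaffold index format error in %s: non-integer length '%s' for scaffold '%s'",
                 path, dt$length_bp[i], dt$scaffold_id[i]))
  }
  if (any(len < 1L)) stop("scaffold index: length_bp must be >= 1 in ", path)
  dup <- dt$scaffold_id[duplicated(dt$scaffold_id)]
  if (length(dup)) stop("scaffold index: duplicate scaffold id(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  dt[, length_bp := len][]
}

#' Read library metadata
#'
#' A tab-separated table with header columns `library_id`, `sex` (`male` or
#' `female`), `mapped_read_count` (positive integer, used to standardize
#' depth), and `replicate_pair_id` grouping exactly one male and one female
#' library per replicate pair.
#'
#' @param path path to the metadata TSV.
#' @return a validated `data.table`.
#' @export
read_library_meta <- function(path) {
  if (!file.exists(path)) stop("library metadata not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("library_id", "sex", "mapped_read_count", "replicate_pair_id")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("library metadata ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, mapped_read_count := suppressWarnings(as.numeric(mapped_read_count))]
  validate_library_meta(dt)
  dt[]
}

#' @rdname read_library_meta
#' @param meta a library metadata `data.table`.
#' @export
validate_library_meta <- function(meta) {
  if (anyDuplicated(meta$library_id)) stop("duplicate library_id in metadata")
  bad_sex <- setdiff(unique(meta$sex), c("male", "female"))
  if (length(bad_sex)) stop("library sex must be 'male' or 'female', got: ",
                            paste(bad_sex, collapse = ", "))
  if (anyNA(meta$mapped_read_count) || any(meta$mapped_read_count < 1))
    stop("mapped_read_count must be a positive integer for every library")
  comp <- meta[, .(n_male = sum(sex == "male"), n_female = sum(sex == "female")),
               by = replicate_pair_id]
  bad <- comp[n_male != 1L | n_female != 1L]
  if (nrow(bad))
    stop("each replicate_pair_id must group exactly one male and one female library; offending pair(s): ",
         paste(bad$replicate_pair_id, collapse = ", "))
  invisible(meta)
}

#' Write library metadata
#' @param meta a library metadata `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library_meta <- function(meta, path) {
  fwrite(meta[, .(library_id, sex, mapped_read_count, replicate_pair_id)],
         path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write / read the per-scaffold annotation table
#'
#' The table has one row per scaffold: id, length, per-library raw mean depth
#' (X units) and normalized depth (depth per million mapped reads), per-pair
#' AD-ratio and provisional label, and the final 5-way label. Ratios and
#' depths are written with 4 decimal places; an undefined ratio (female depth
#' 0 with male depth > 0) is written as `NA`.
#'
#' @param annotations an annotation `data.table` from [annotate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- copy(as.data.table(annotations))
  num <- setdiff(names(out)[vapply(out, is.numeric, TRUE)], c("length_bp"))
  for (col in num) out[, (col) := sprintf("%.4f", get(col))]
  for (col in num) out[, (col) := fifelse(get(col) == "NA", NA_character_, get(col))]
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}

#' Export Z-labelled scaffolds as BED intervals
#'
#' Whole-scaffold intervals in 0-based half-open BED convention, one line per
#' scaffold with final label `Z`.
#'
#' @param annotations an annotation `data.table` from [annotate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_z_bed <- function(annotations, path) {
  z <- as.data.table(annotations)[final_label == "Z",
                                  .(chrom = scaffold_id, start = 0L, end = length_bp)]
  fwrite(z, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a candidate-gene localization table
#'
#' Tab-separated with header `gene_id`, `scaffold_id`, `known_class`
#' (`autosomal` or `Z`). The gene-to-scaffold mapping is assumed precomputed
#' (e.g. by blastn of the gene sequences against the assembly; the original
#' procedure used an e-value threshold of 1e-20).
#'
#' @param path path to the gene table.
#' @return a `data.table`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("gene_id", "scaffold_id", "known_class")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("gene table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$known_class), c("autosomal", "Z"))
  if (length(bad)) stop("known_class must be 'autosomal' or 'Z', got: ", paste(bad, collapse = ", "))
  dt[, need, with = FALSE]
}
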