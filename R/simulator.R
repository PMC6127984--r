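#' Specification for a synthetic ZW-genome depth simulation
#'
#' Emulates per-base shotgun depth over a toy genome of autosomal, Z and W
#' scaffolds sequenced in male (ZZ) and female (ZW) libraries. Expected depth
#' at a base is proportional to copy number (male A=2, Z=2, W=0; female A=2,
#' Z=1, W=1): a library with diploid-autosome target coverage `c` has
#' per-base mean `c * copy_number / 2`. Counts are Poisson when
#' `overdispersion = 0`, otherwise negative-binomial with variance
#' `mean * (1 + overdispersion)`.
#'
#' @param n_autosomal,n_z,n_w scaffold counts per class (default 50/10/5, a
#'   toy version of a karyotype where the Z is a small fraction of the
#'   genome).
#' @param length_bp scaffold length in bp: a single value (fixed length) or a
#'   `c(min, max)` range sampled uniformly.
#' @param coverage diploid-autosome target coverage per library, in X.
#' @param overdispersion count overdispersion (>= 0; 0 = Poisson).
#' @param n_pairs number of male+female replicate pairs (libraries are pooled
#'   one male plus one female, pair ids `P1`, `P2`, ...).
#' @param depth_multiplier per-library depth multiplier, recycled over the
#'   `2 * n_pairs` libraries (order M1, F1, M2, F2, ...); emulates unequal
#'   library sizes, with mapped-read counts scaling to match.
#' @param mapped_reads per-library mapped-read counts; `NULL` (default)
#'   derives them from the emitted depth totals divided by `read_length`.
#' @param read_length read length in bp used when deriving mapped-read counts
#'   (default 125).
#' @param base_noise per-base probability that a sequenced base is scattered
#'   from the reference count column into another base column (0 = all depth
#'   in the `A` column).
#' @param low_coverage_fraction fraction of scaffolds simulated at
#'   `low_coverage_x` instead of `coverage`, to exercise the minimum-depth
#'   filter.
#' @param low_coverage_x target coverage of low-coverage scaffolds (X).
#' @param seed integer seed; the whole simulation is reproducible given the
#'   spec.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_autosomal = 50, n_z = 10, n_w = 5,
                     length_bp = c(5000, 20000),
                     coverage = 20, overdispersion = 0.2,
                     n_pairs = 2, depth_multiplier = 1,
                     mapped_reads = NULL, read_length = 125,
                     base_noise = 0,
                     low_coverage_fraction = 0.05, low_coverage_x = 2,
                     seed = 42) {
  stopifnot(n_autosomal >= 0, n_z >= 0, n_w >= 0,
            length_bp >= 1, length(length_bp) %in% 1:2,
            coverage > 0, overdispersion >= 0, n_pairs >= 1,
            base_noise >= 0, base_noise <= 1,
            low_coverage_fraction >= 0, low_coverage_fraction <= 1,
            low_coverage_x > 0)
  if (n_autosomal + n_z + n_w == 0L) stop("at least one scaffold is required")
  nlib <- 2L * n_pairs
  structure(list(n_autosomal = as.integer(n_autosomal), n_z = as.integer(n_z),
                 n_w = as.integer(n_w),
                 length_bp = as.integer(length_bp),
                 coverage = coverage, overdispersion = overdispersion,
                 n_pairs = as.integer(n_pairs),
                 depth_multiplier = rep_len(depth_multiplier, nlib),
                 mapped_reads = mapped_reads, read_length = read_length,
                 base_noise = base_noise,
                 low_coverage_fraction = low_coverage_fraction,
                 low_coverage_x = low_coverage_x,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# library metadata implied by the spec (mapped counts filled by simulate_depth)
.spec_libraries <- function(spec) {
  data.table(
    library_id = paste0(rep(c("M", "F"), spec$n_pairs),
                        rep(seq_len(spec$n_pairs), each = 2L)),
    sex = rep(c("male", "female"), spec$n_pairs),
    mapped_read_count = NA_real_,
    replicate_pair_id = paste0("P", rep(seq_len(spec$n_pairs), each = 2L)))
}

#' Copy number of a scaffold class in one sex
#'
#' Males are ZZ, females ZW: autosomes are at 2 copies in both sexes, the Z
#' at 2 in males and 1 in females, the W at 0 in males and 1 in females.
#'
#' @param true_class `autosomal`, `Z` or `W` (vectorized).
#' @param sex `male` or `female`.
#' @return integer copy number in 0, 1, 2.
#' @export
copy_number <- function(true_class, sex) {
  stopifnot(all(true_class %in% .TRUE_CLASSES), all(sex %in% c("male", "female")))
  cn <- matrix(c(2L, 2L, 2L, 1L, 0L, 1L), nrow = 3L, byrow = TRUE,
               dimnames = list(.TRUE_CLASSES, c("male", "female")))
  cn[cbind(true_class, sex)]
}

#' Simulate a toy genome with known scaffold classes
#'
#' Scaffold ids are opaque (`scf0001`, ... assigned in shuffled class order)
#' so nothing downstream can read the class off the id; the truth table is
#' the only link.
#'
#' @param spec a [sim_spec()].
#' @return a list with `index` (a scaffold index `data.table`) and `truth`
#'   (`scaffold_id`, `true_class`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  classes <- sample(rep(.TRUE_CLASSES, times = c(spec$n_autosomal, spec$n_z, spec$n_w)))
  n <- length(classes)
  len <- if (length(spec$length_bp) == 1L) rep(spec$length_bp, n)
         else sample(spec$length_bp[1]:spec$length_bp[2], n, replace = TRUE)
  ids <- sprintf("scf%04d", seq_len(n))
  list(index = data.table(scaffold_id = ids, length_bp = as.integer(len)),
       truth = data.table(scaffold_id = ids, true_class = classes))
}

# one library's per-base depths for one scaffold
.draw_depths <- function(n, mu, overdispersion) {
  if (mu <= 0) return(integer(n))
  if (overdispersion > 0) rnbinom(n, mu = mu, size = mu / overdispersion)
  else rpois(n, mu)
}

# format depth d as an A:T:C:G:N:del count string, optionally scattering a
# base_noise fraction of bases from A into T/C/G
.count_strings <- function(d, base_noise) {
  if (base_noise <= 0) return(sprintf("%d:0:0:0:0:0", d))
  err <- rbinom(length(d), d, base_noise)
  t_ <- rbinom(length(d), err, 1 / 3)
  c_ <- rbinom(length(d), err - t_, 1 / 2)
  g_ <- err - t_ - c_
  sprintf("%d:%d:%d:%d:0:0", d - err, t_, c_, g_)
}

#' Simulate per-base depth and emit a synchronized count table
#'
#' Per base and per library, depth is drawn independently with mean
#' `coverage * copy_number / 2 * depth_multiplier` (times the low-coverage
#' factor for scaffolds in the low-coverage fraction). Positions with zero
#' depth in every library are omitted, as a pileup would omit them. By
#' default the whole depth sits in the `A` count column; `base_noise`
#' scatters a fraction into other columns. Mapped-read counts are derived
#' from each library's total emitted depth divided by the read length unless
#' given in the spec.
#'
#' @param genome output of [simulate_genome()] (or `NULL` to simulate one
#'   from `spec`).
#' @param spec a [sim_spec()].
#' @return an `adr_sim` list: `sync` (a sync `data.table` as from
#'   [read_sync()]), `index`, `truth`, `libraries` (metadata with mapped-read
#'   counts filled in), `low_coverage` (ids of low-coverage scaffolds) and
#'   `spec`.
#' @export
simulate_depth <- function(genome = NULL, spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(genome)) genome <- simulate_genome(spec)
  index <- genome$index; truth <- genome$truth
  libs <- .spec_libraries(spec)
  nlib <- nrow(libs)
  set.seed(spec$seed + 1L)

  n_scf <- nrow(index)
  low <- runif(n_scf) < spec$low_coverage_fraction
  cov_scf <- fifelse(low, spec$low_coverage_x, spec$coverage)
  cls <- truth$true_class[match(index$scaffold_id, truth$scaffold_id)]

  pieces <- vector("list", n_scf)
  totals <- numeric(nlib)
  for (i in seq_len(n_scf)) {
    L <- index$length_bp[i]
    dmat <- matrix(0L, nrow = L, ncol = nlib)
    for (j in seq_len(nlib)) {
      mu <- cov_scf[i] * copy_number(cls[i], libs$sex[j]) / 2 * spec$depth_multiplier[j]
      dmat[, j] <- .draw_depths(L, mu, spec$overdispersion)
    }
    totals <- totals + colSums(dmat)
    keep <- rowSums(dmat) > 0L
    if (!any(keep)) next
    piece <- data.table(scaffold_id = index$scaffold_id[i],
                        pos = which(keep),
                        ref = sample(c("A", "T", "C", "G"), sum(keep), replace = TRUE))
    for (j in seq_len(nlib))
      piece[, (paste0("lib", j)) := .count_strings(dmat[keep, j], spec$base_noise)]
    pieces[[i]] <- piece
  }
  sync <- rbindlist(pieces)
  if (is.null(sync) || nrow(sync) == 0L) sync <- .empty_sync(nlib)
  setattr(sync, "n_libraries", nlib)

  libs[, mapped_read_count := if (is.null(spec$mapped_reads))
    pmax(1, round(totals / spec$read_length))
    else rep_len(spec$mapped_reads, nlib)]
  structure(list(sync = sync, index = index, truth = truth, libraries = libs,
                 low_coverage = index$scaffold_id[low], spec = spec),
            class = "adr_sim")
}

#' @export
print.adr_sim <- function(x, ...) {
  cat(sprintf("<adr_sim> %d scaffolds (%d A / %d Z / %d W), %d libraries, %d sync records\n",
              nrow(x$index), sum(x$truth$true_class == "autosomal"),
              sum(x$truth$true_class == "Z"), sum(x$truth$true_class == "W"),
              nrow(x$libraries), nrow(x$sync)))
  invisible(x)
}

#' Write a simulation as an on-disk fixture directory
#'
#' Writes `scaffolds.fai` (id + length), `libraries.tsv`, `truth.tsv` and the
#' sync data: one combined `depth.sync` by default, or one
#' `depth_<pair>.sync` per sequencing pool (each holding that pair's male and
#' female columns) when `split_pools = TRUE`.
#'
#' @param sim an `adr_sim` from [simulate_depth()].
#' @param dir output directory (created if needed).
#' @param split_pools write one sync file per replicate pool.
#' @return named list of written paths, invisibly.
#' @export
write_sim_fixture <- function(sim, dir, split_pools = FALSE) {
  stopifnot(inherits(sim, "adr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    index = file.path(dir, "scaffolds.fai"),
    libraries = file.path(dir, "libraries.tsv"),
    truth = file.path(dir, "truth.tsv"))
  fwrite(sim$index, paths$index, sep = "\t", col.names = FALSE, quote = FALSE)
  write_library_meta(sim$libraries, paths$libraries)
  fwrite(sim$truth, paths$truth, sep = "\t", quote = FALSE)
  if (split_pools) {
    paths$sync <- character(0)
    for (p in unique(sim$libraries$replicate_pair_id)) {
      j <- which(sim$libraries$replicate_pair_id == p)
      sub <- sim$sync[, c("scaffold_id", "pos", "ref", paste0("lib", j)), with = FALSE]
      # drop positions uncovered in this pool
      cov <- rowSums(sapply(paste0("lib", j), function(cn)
        sub[[cn]] != "0:0:0:0:0:0")) > 0
      sub <- sub[cov]
      setnames(sub, paste0("lib", j), paste0("lib", seq_along(j)))
      f <- file.path(dir, paste0("depth_", p, ".sync"))
      write_sync(sub, f)
      paths$sync <- c(paths$sync, f)
    }
  } else {
    paths$sync <- file.path(dir, "depth.sync")
    write_sync(sim$sync, paths$sync)
  }
  invisible(paths)
}
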