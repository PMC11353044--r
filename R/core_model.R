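#' @keywords internal
"_PACKAGE"

# ---- genome dictionaries ----------------------------------------------------

#' hg19-style genome dictionary
#'
#' Chromosome lengths (bp) for the 22 autosomes plus X and Y, matching the
#' GRCh37/hg19 assembly. The pipeline is build-agnostic: any named integer
#' vector of chromosome lengths works wherever a `genome` argument appears.
#'
#' @return Named numeric vector of chromosome lengths in base pairs.
#' @export
#' @examples
#' hg19_genome()[["chr20"]]
hg19_genome <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Small toy genome for examples and fast tests
#'
#' @param n_chrom number of autosomes (chr1, chr2, ...)
#' @param chrom_length length of each autosome in bp
#' @param sex append a chrX of half the autosome length
#' @return Named numeric vector of chromosome lengths.
#' @export
toy_genome <- function(n_chrom = 3, chrom_length = 50e6, sex = TRUE) {
  g <- stats::setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom)))
  if (sex) g <- c(g, chrX = chrom_length / 2)
  g
}

#' Read / write a genome dictionary as two-column TSV (chrom, length)
#' @param path file path
#' @return named numeric vector (for `read_genome`); invisibly `path` for write
#' @export
read_genome <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("genome dictionary contains non-positive lengths")
  stats::setNames(df$length, df$chrom)
}

#' @rdname read_genome
#' @param genome named numeric vector of chromosome lengths
#' @export
write_genome <- function(genome, path) {
  utils::write.table(data.frame(chrom = names(genome), length = unname(genome)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

is_sex_chrom <- function(chrom) chrom %in% c("chrX", "chrY", "X", "Y")

# ---- genomic intervals ------------------------------------------------------

#' Construct a genomic interval
#'
#' Coordinates are 0-based, half-open (`start` inclusive, `end` exclusive),
#' the BED convention; VCF emission converts to 1-based.
#'
#' @param chrom chromosome name
#' @param start 0-based inclusive start (bp)
#' @param end exclusive end (bp); must satisfy 0 <= start < end
#' @param genome optional genome dictionary; when given, `chrom` must be
#'   declared and `end` must not exceed the chromosome length
#' @return A list of class `genomic_interval`.
#' @export
#' @examples
#' genomic_interval("chr20", 29370000, 30445000)
genomic_interval <- function(chrom, start, end, genome = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!is.null(genome)) {
    if (!chrom %in% names(genome))
      stop("unknown chromosome '", chrom, "' (not in genome dictionary)")
    if (end > genome[[chrom]])
      stop("interval end ", end, " exceeds length of ", chrom)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%.3f Mb)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              interval_size_mb(x)))
  invisible(x)
}

#' Overlap length of two genomic intervals
#'
#' @param a,b `genomic_interval` objects
#' @param genome optional genome dictionary; unknown chromosomes raise an error
#' @return Overlap length in bp; 0 when disjoint or on different chromosomes.
#' @export
#' @examples
#' interval_overlap(genomic_interval("chr1", 0, 100), genomic_interval("chr1", 50, 150))
interval_overlap <- function(a, b, genome = NULL) {
  if (!is.null(genome)) {
    for (iv in list(a, b))
      if (!iv$chrom %in% names(genome))
        stop("unknown chromosome '", iv$chrom, "'")
  }
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Interval size in Mb, rounded to 3 decimals (karyotype-report precision)
#' @param x a `genomic_interval`
#' @export
interval_size_mb <- function(x) round((x$end - x$start) / 1e6, 3)

# ---- pipeline configuration -------------------------------------------------

#' Default pipeline configuration
#'
#' Thresholds of the analysis: 50 kb coverage bins; the SNV retention cascade
#' (population frequency <= 1% in every population database, allele fraction
#' >= 3% for non-hotspot variants, facility recurrence <= 0.01%, >= 25 alt
#' reads, CDC27 excluded for pseudogene contamination); panel depth 1500x and
#' shallow-WGS coverage 0.1x used by the read-count simulator.
#'
#' @param ... named overrides of any default field
#' @return A list of class `stemdrift_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(min_af_nonhotspot = 0.05)
#' cfg$min_af_nonhotspot
pipeline_config <- function(...) {
  cfg <- list(
    bin_size = 50000L,
    pop_freq_max = 0.01,
    min_af_nonhotspot = 0.03,
    min_alt_reads = 25L,
    recurrence_max = 0.0001,
    excluded_genes = "CDC27",
    panel_depth = 1500L,
    shallow_coverage = 0.1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "stemdrift_config")
}

validate_config <- function(cfg) {
  num <- c("bin_size", "pop_freq_max", "min_af_nonhotspot", "min_alt_reads",
           "recurrence_max", "panel_depth", "shallow_coverage")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("config field '", f, "' must be a positive number")
  }
  for (f in c("pop_freq_max", "min_af_nonhotspot", "recurrence_max")) {
    if (cfg[[f]] >= 1) stop("config field '", f, "' must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Read / write pipeline configuration as YAML
#'
#' Round-trips bit-exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param path YAML file path
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a `stemdrift_config`
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

# ---- sample metadata --------------------------------------------------------

#' Validate a sample manifest
#'
#' A manifest holds one row per sequenced sample: `sample_id`, `line_id`,
#' `passage` (absolute passage number) and `rank` (ordinal position of the
#' sample within its line's series, 1 = earliest). Within a line, rank must be
#' a strictly increasing function of passage.
#'
#' @param manifest data.frame with at least the four columns above
#' @return The manifest, invisibly, after validation.
#' @export
validate_manifest <- function(manifest) {
  need <- c("sample_id", "line_id", "passage", "rank")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stop("manifest sample ids are not unique")
  if (any(manifest$passage < 1) || any(manifest$rank < 1))
    stop("passage and rank must be positive integers")
  for (ln in unique(manifest$line_id)) {
    sub <- manifest[manifest$line_id == ln, ]
    sub <- sub[order(sub$rank), ]
    if (is.unsorted(sub$passage, strictly = TRUE))
      stop("line ", ln, ": rank must increase strictly with passage")
  }
  invisible(manifest)
}

# ---- misc internals ---------------------------------------------------------

# 32-bit FNV-1a hash of a string, kept in double precision (R has no native
# unsigned 32-bit type). Used for reproducible sub-seeds and provenance hashes.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # XOR only touches the low byte
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536; hi <- h %/% 65536  # multiply by 16777619 mod 2^32
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# sub-seed in [0, 2^31): stable under (master_seed, labels...)
derive_seed <- function(seed, ...) {
  as.integer((seed + fnv1a(paste(c(...), collapse = "/"))) %% 2147483647)
}
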