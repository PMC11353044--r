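# Germline / de novo classification of variants across a line's ordered
# passage series, allele-fraction trajectories, and zygosity calls.
#
# "Detected" at a rank means the variant survived the retention cascade in
# that sample; a variant dropping below the detection floor is "absent" --
# true loss and sub-threshold mosaicism are indistinguishable at panel
# sensitivity, for this pipeline as for any other.

#' Classify a variant's origin from its per-rank detection series
#'
#' A variant is germline iff it is detected at the line's earliest tested
#' rank; otherwise it is de novo with its first detection rank recorded.
#' Lines with a single tested rank cannot anchor the series and return
#' `"ambiguous"`.
#'
#' @param af_series numeric vector of allele fractions ordered by rank,
#'   with `NA` where the variant was not detected
#' @return list(origin = "germline" | "de_novo" | "ambiguous",
#'   first_seen_rank).
#' @export
#' @examples
#' classify_origin(c(0.49, 0.51, 0.50))$origin   # germline
#' classify_origin(c(NA, 0.12, 0.10))$origin     # de_novo, first seen rank 2
classify_origin <- function(af_series) {
  if (length(af_series) < 2)
    return(list(origin = "ambiguous", first_seen_rank = NA_integer_))
  first <- which(!is.na(af_series))[1]
  if (is.na(first)) stop("variant never detected: nothing to classify")
  list(origin = if (first == 1) "germline" else "de_novo",
       first_seen_rank = as.integer(first))
}

#' Allele-fraction trajectory across ranks
#'
#' `lost` when the variant is absent at the final rank after having been
#' detected; otherwise `increasing` / `decreasing` when the last detected AF
#' differs from the first by more than `delta`, else `stable`. The default
#' `delta = 0.15` exceeds binomial AF noise at 1500x depth (sd ~ 0.013) by
#' an order of magnitude.
#'
#' @param af_series per-rank AFs with NA = not detected
#' @param delta minimum AF change called a trend
#' @return One of `"stable"`, `"increasing"`, `"decreasing"`, `"lost"`.
#' @export
call_trajectory <- function(af_series, delta = 0.15) {
  det <- which(!is.na(af_series))
  if (!length(det)) stop("variant never detected: no trajectory")
  if (is.na(af_series[length(af_series)])) return("lost")
  d <- af_series[det[length(det)]] - af_series[det[1]]
  if (d > delta) "increasing" else if (d < -delta) "decreasing" else "stable"
}

#' Zygosity call from allele fraction, copy number and clonal fraction
#'
#' Heterozygous when AF is within `tol` of 0.5 at copy number 2; homozygous
#' when AF >= 1 - `tol`; otherwise `cn_adjusted` when AF is within `tol` of
#' some expected AF achievable at the given copy number and clonal fraction
#' (mutant copies 0..cn in the mutant clone, 0..2 in the wild-type
#' population, via [expected_af()]); else `ambiguous`.
#'
#' @param af observed allele fraction in [0, 1]
#' @param local_copy_number total copy number at the locus (>= 1)
#' @param clonal_fraction fraction of the culture carrying the CNV
#' @param tol matching tolerance on AF
#' @return One of `"heterozygous"`, `"homozygous"`, `"cn_adjusted"`,
#'   `"ambiguous"`.
#' @export
#' @examples
#' call_zygosity(0.50, 2)                      # heterozygous
#' call_zygosity(0.98, 2)                      # homozygous
#' call_zygosity(0.70, 3, clonal_fraction = 1) # cn_adjusted (2/3)
call_zygosity <- function(af, local_copy_number, clonal_fraction = 1,
                          tol = 0.10) {
  if (!is.numeric(af) || is.na(af) || af < 0 || af > 1)
    stop("allele fraction must lie in [0, 1]")
  if (local_copy_number < 1) stop("local copy number must be >= 1")
  if (abs(af - 0.5) <= tol && local_copy_number == 2) return("heterozygous")
  if (af >= 1 - tol) return("homozygous")
  for (m in 0:local_copy_number) for (m0 in 0:2) {
    if (m == 0 && m0 == 0) next
    e <- expected_af(m = m, c = local_copy_number, m0 = m0,
                     f = clonal_fraction)
    if (abs(af - e) <= tol) return("cn_adjusted")
  }
  "ambiguous"
}

#' Classify all variants of one line across its passage series
#'
#' Joins per-sample filtered variant tables into per-variant AF series (by
#' gene/chrom/pos/ref/alt key, ordered by rank) and derives origin,
#' trajectory and zygosity for each. Zygosity uses the copy number implied
#' by an overlapping CNV segment of the variant's first-detection sample
#' when `segments_by_sample` is given, else copy number 2.
#'
#' @param variants_by_rank named list of filtered variant data.frames, one
#'   per rank, in rank order (names = sample ids)
#' @param line_id line identifier
#' @param segments_by_sample optional list of segment tables parallel to
#'   `variants_by_rank`
#' @param delta trajectory threshold, see [call_trajectory()]
#' @param tol zygosity tolerance, see [call_zygosity()]
#' @return data.frame, one row per variant, with key columns, `origin`,
#'   `first_seen_rank`, `trajectory`, `zygosity`, and `af_rankN` columns.
#' @export
classify_line <- function(variants_by_rank, line_id = "",
                          segments_by_sample = NULL, delta = 0.15,
                          tol = 0.10) {
  n_ranks <- length(variants_by_rank)
  key_of <- function(v) paste(v$gene, v$chrom, v$pos, v$ref, v$alt, sep = ":")
  all_keys <- unique(unlist(lapply(variants_by_rank, key_of)))
  if (!length(all_keys)) return(empty_classified(n_ranks))
  af_mat <- matrix(NA_real_, nrow = length(all_keys), ncol = n_ranks,
                   dimnames = list(all_keys, NULL))
  meta <- list()
  for (r in seq_len(n_ranks)) {
    v <- variants_by_rank[[r]]
    if (!nrow(v)) next
    k <- key_of(v)
    af_mat[k, r] <- v$af
    for (i in seq_along(k)) if (is.null(meta[[k[i]]])) meta[[k[i]]] <- v[i, ]
  }
  rows <- lapply(all_keys, function(k) {
    series <- af_mat[k, ]
    org <- classify_origin(series)
    first <- which(!is.na(series))[1]
    cn <- 2L; cf <- 1
    if (!is.null(segments_by_sample)) {
      segs <- segments_by_sample[[first]]
      if (!is.null(segs) && nrow(segs)) {
        m <- meta[[k]]
        hit <- segs$chrom == m$chrom & segs$start < m$pos & segs$end >= m$pos
        if (any(hit)) {
          l2r <- segs$mean_log2ratio[which(hit)[1]]
          cn <- max(1L, as.integer(round(2 * 2^l2r)))
        }
      }
    }
    m <- meta[[k]]
    out <- data.frame(
      line_id = line_id, gene = m$gene, chrom = m$chrom, pos = m$pos,
      ref = m$ref, alt = m$alt, origin = org$origin,
      first_seen_rank = if (is.na(org$first_seen_rank)) first else org$first_seen_rank,
      trajectory = call_trajectory(series, delta = delta),
      zygosity = call_zygosity(series[first], cn, clonal_fraction = cf,
                               tol = tol),
      local_copy_number = cn)
    af <- as.data.frame(as.list(series))
    names(af) <- paste0("af_rank", seq_len(n_ranks))
    cbind(out, af)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_classified <- function(n_ranks) {
  out <- data.frame(line_id = character(), gene = character(),
                    chrom = character(), pos = numeric(), ref = character(),
                    alt = character(), origin = character(),
                    first_seen_rank = integer(), trajectory = character(),
                    zygosity = character(), local_copy_number = integer())
  for (r in seq_len(n_ranks)) out[[paste0("af_rank", r)]] <- numeric()
  out
}
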