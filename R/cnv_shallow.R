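# Copy-number calling from shallow-WGS 50 kb binned read counts:
# GC correction -> fold change / log2 ratio / robust z per bin ->
# run-based segmentation -> annotation against recurrent hPSC abnormalities.

#' Catalog of recurrent hPSC chromosomal abnormalities
#'
#' The classic recurrent gains (20q11.21 with driver BCL2L1, distal 1q with
#' driver MDM4, chromosome 12, 17q) and the recurrent 18q loss (SALL3),
#' with hg19-style coordinates. A segment is annotated with an entry's label
#' when it overlaps the driver locus with matching direction. `sim_weight`
#' sets the relative frequency at which the simulator draws each entry.
#'
#' @return data.frame with columns label, chrom, region_start, region_end,
#'   driver_gene, driver_start, driver_end, direction, sim_weight.
#' @export
recurrent_catalog <- function() {
  data.frame(
    label = c("20q11.21/BCL2L1", "1q/MDM4", "12/NANOG", "17q/BIRC5",
              "18q/SALL3"),
    chrom = c("chr20", "chr1", "chr12", "chr17", "chr18"),
    region_start = c(29370000, 145500000, 0, 25800000, 18500000),
    region_end = c(63025520, 249250621, 133851895, 81195210, 78077248),
    driver_gene = c("BCL2L1", "MDM4", "NANOG", "BIRC5", "SALL3"),
    driver_start = c(30252255, 204485511, 7941991, 76210344, 76740276),
    driver_end = c(30311792, 204527248, 7948657, 76221716, 76758969),
    direction = c("gain", "gain", "gain", "gain", "loss"),
    sim_weight = c(0.40, 0.30, 0.10, 0.10, 0.10))
}

#' GC-correct binned read counts
#'
#' Fits a smooth count-versus-GC curve by taking the median count within GC
#' deciles and interpolating between the stratum medians, divides raw counts
#' by the fitted value, then rescales so the autosomal median equals 1
#' (self-normalisation: no panel of normals, so whole-genome ploidy shifts
#' are invisible by construction). Blacklisted bins are removed before the
#' fit and are absent from the output.
#'
#' @param cov binned coverage: data.frame(chrom, start, end, gc, count) with
#'   optional logical `blacklisted` column
#' @param min_fit_bins minimum number of non-blacklisted covered bins
#'   required for a stable GC fit
#' @return The retained bins with a `corrected` column appended (autosomal
#'   median 1).
#' @export
gc_correct <- function(cov, min_fit_bins = 500) {
  if (!is.null(cov$blacklisted)) cov <- cov[!cov$blacklisted, ]
  if (nrow(cov) == 0 || all(cov$count == 0))
    stop("all-zero or empty coverage: nothing to correct")
  if (sum(cov$count > 0) < min_fit_bins)
    stop("need at least ", min_fit_bins, " covered bins for the GC fit, got ",
         sum(cov$count > 0))
  breaks <- unique(stats::quantile(cov$gc, probs = seq(0, 1, 0.1)))
  if (length(breaks) < 4) {
    warning("fewer than 3 populated GC strata; falling back to global ",
            "median normalisation")
    fitted <- rep(stats::median(cov$count), nrow(cov))
  } else {
    stratum <- cut(cov$gc, breaks = breaks, include.lowest = TRUE)
    gx <- tapply(cov$gc, stratum, stats::median)
    gy <- tapply(cov$count, stratum, stats::median)
    ok <- !is.na(gx) & !is.na(gy)
    if (sum(ok) < 3) {
      warning("fewer than 3 populated GC strata; falling back to global ",
              "median normalisation")
      fitted <- rep(stats::median(cov$count), nrow(cov))
    } else {
      fitted <- stats::approx(gx[ok], gy[ok], xout = cov$gc, rule = 2)$y
    }
  }
  if (any(fitted <= 0)) stop("degenerate GC fit (non-positive fitted counts)")
  corrected <- cov$count / fitted
  auto <- !is_sex_chrom(cov$chrom)
  med <- stats::median(corrected[if (any(auto)) auto else TRUE])
  if (med <= 0) stop("degenerate coverage: autosomal median is not positive")
  cov$corrected <- corrected / med
  cov
}

#' Per-bin fold change, log2 ratio and robust z score
#'
#' Fold change is the GC-corrected, median-normalised count (reference 1 =
#' diploid). The log2 ratio floors fold change at a pseudocount of
#' 0.5 / median raw count before taking logs; z is
#' (fold change - 1) / sigma with sigma the MAD (x 1.4826) of autosomal
#' fold change.
#'
#' @param corrected output of [gc_correct()]
#' @return Input with `fold_change`, `log2ratio`, `z` columns appended and a
#'   `sigma` attribute.
#' @export
compute_scores <- function(corrected) {
  if (is.null(corrected$corrected)) stop("run gc_correct() first")
  fc <- corrected$corrected
  pseudo <- 0.5 / stats::median(corrected$count)
  auto <- !is_sex_chrom(corrected$chrom)
  sigma <- stats::mad(fc[if (any(auto)) auto else TRUE], center = stats::median(fc[if (any(auto)) auto else TRUE]))
  if (sigma == 0) stop("degenerate input: zero robust scale of fold change")
  corrected$fold_change <- fc
  corrected$log2ratio <- log2(pmax(fc, pseudo))
  corrected$z <- (fc - 1) / sigma
  attr(corrected, "sigma") <- sigma
  corrected
}

#' Segment per-bin z scores into copy-number calls
#'
#' A call is a maximal run of bins exceeding the z threshold in one
#' direction (gain: z > `z_thresh`; loss: z < -`z_thresh`), allowing
#' interruptions of at most `merge_gap` non-qualifying bins (which must not
#' qualify in the opposite direction), and spanning at least `min_bins`
#' bins. Breakpoints are the outer boundaries of the first and last
#' qualifying bins. With 50 kb bins the default `min_bins = 10` sets a
#' 0.5 Mb detection floor, below the smallest abnormality of interest but
#' above single-bin noise.
#'
#' @param scores output of [compute_scores()]
#' @param min_bins minimum run span, in bins
#' @param z_thresh per-bin |z| threshold
#' @param merge_gap maximum run interruption, in bins
#' @param call_sex also call on chrX/chrY (off by default: line sexes differ
#'   and self-normalisation does not model them)
#' @return data.frame of segments (chrom, start, end, direction,
#'   mean_log2ratio, n_bins, size_mb, recurrent_label), non-overlapping and
#'   sorted; zero rows when nothing is called.
#' @export
segment_cnvs <- function(scores, min_bins = 10, z_thresh = 3.0,
                         merge_gap = 2, call_sex = FALSE) {
  if (is.null(scores$z)) stop("run compute_scores() first")
  if (!is.null(scores$blacklisted)) scores <- scores[!scores$blacklisted, ]
  if (!call_sex) scores <- scores[!is_sex_chrom(scores$chrom), ]
  segs <- list()
  for (ch in unique(scores$chrom)) {
    sub <- scores[scores$chrom == ch, ]
    for (dir in c("gain", "loss")) {
      qual <- if (dir == "gain") sub$z > z_thresh else sub$z < -z_thresh
      anti <- if (dir == "gain") sub$z < -z_thresh else sub$z > z_thresh
      idx <- which(qual)
      if (!length(idx)) next
      # split runs where the gap is too long or an opposite-direction bin
      # sits in the gap
      grp <- cumsum(c(1, vapply(seq_along(idx)[-1], function(k) {
        i <- idx[k - 1]; j <- idx[k]
        gap <- j - i - 1
        if (gap > merge_gap) return(1L)
        if (gap > 0 && any(anti[(i + 1):(j - 1)])) return(1L)
        0L
      }, 1L)))
      for (g in unique(grp)) {
        run <- idx[grp == g]
        first <- min(run); last <- max(run)
        span <- last - first + 1
        if (span < min_bins) next
        iv <- genomic_interval(ch, sub$start[first], sub$end[last])
        segs[[length(segs) + 1]] <- data.frame(
          chrom = ch, start = sub$start[first], end = sub$end[last],
          direction = dir,
          mean_log2ratio = mean(sub$log2ratio[first:last]),
          n_bins = span, size_mb = interval_size_mb(iv),
          recurrent_label = NA_character_)
      }
    }
  }
  if (!length(segs)) return(empty_segments())
  out <- do.call(rbind, segs)
  out <- out[order(match(out$chrom, unique(scores$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}

empty_segments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             direction = character(), mean_log2ratio = numeric(),
             n_bins = integer(), size_mb = numeric(),
             recurrent_label = character(), stringsAsFactors = FALSE)
}

#' Annotate segments against the recurrent-abnormality catalog
#'
#' A segment receives a catalog label when it overlaps that entry's driver
#' gene locus with matching direction; unlabelled segments are rare CNVs.
#'
#' @param segments output of [segment_cnvs()]
#' @param catalog see [recurrent_catalog()]
#' @export
annotate_recurrence <- function(segments, catalog = recurrent_catalog()) {
  if (nrow(segments) == 0) return(segments)
  segments$recurrent_label <- NA_character_
  for (i in seq_len(nrow(segments))) {
    seg <- genomic_interval(segments$chrom[i], segments$start[i],
                            segments$end[i])
    for (j in seq_len(nrow(catalog))) {
      if (catalog$direction[j] != segments$direction[i]) next
      drv <- genomic_interval(catalog$chrom[j], catalog$driver_start[j],
                              catalog$driver_end[j])
      if (interval_overlap(seg, drv) > 0) {
        segments$recurrent_label[i] <- catalog$label[j]
        break
      }
    }
  }
  segments
}

#' Karyotype status of a sample
#'
#' A sample is karyotypically abnormal iff at least one CNV segment was
#' called on it.
#'
#' @param segments segment table for one sample (possibly zero rows)
#' @return `"normal"` or `"abnormal"`.
#' @export
karyotype_status <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) "normal" else "abnormal"
}

#' Call CNVs for one sample, end to end
#'
#' Convenience wrapper: [gc_correct()] -> [compute_scores()] ->
#' [segment_cnvs()] -> [annotate_recurrence()].
#'
#' @param cov binned coverage data.frame
#' @param catalog recurrent-abnormality catalog
#' @param ... passed to [segment_cnvs()]
#' @export
call_cnvs <- function(cov, catalog = recurrent_catalog(), ...) {
  annotate_recurrence(segment_cnvs(compute_scores(gc_correct(cov)), ...),
                      catalog)
}
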