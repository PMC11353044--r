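# Panel-SNV retention cascade. Each rule is an independent predicate over an
# annotated variant call; a variant is retained iff it fails no rule, and the
# report tallies every failure independently (a variant can fail several).

.filter_rules <- c(
  R1 = "population frequency above threshold in some database",
  R2 = "non-hotspot variant below allele-fraction floor",
  R3 = "facility-recurrent artifact",
  R4 = "insufficient alt read support",
  R5 = "excluded gene",
  R6 = "in excluded genomic region")

required_variant_fields <- c("gene", "chrom", "pos", "af", "alt_reads",
                             "pop_freq_gnomad", "pop_freq_1000g",
                             "pop_freq_esp6500", "hotspot", "recurrence_freq")

#' Apply the variant-retention cascade
#'
#' Rules (all thresholds from the [pipeline_config()]):
#' \describe{
#'   \item{R1}{maximum population frequency across gnomAD / 1000G / ESP6500
#'     exceeds `pop_freq_max` (a variant common in any one database is
#'     removed).}
#'   \item{R2}{non-hotspot variant with allele fraction below
#'     `min_af_nonhotspot`; hotspot variants are kept at any AF.}
#'   \item{R3}{facility recurrence frequency above `recurrence_max`
#'     (sequencing artifacts recurring across unrelated samples).}
#'   \item{R4}{fewer than `min_alt_reads` alternate reads.}
#'   \item{R5}{gene in `excluded_genes` (CDC27 by default, for pseudogene
#'     contamination).}
#'   \item{R6}{optional: variant inside a user-supplied exclusion region
#'     list (stand-in for manual review of repeat/microsatellite artifacts;
#'     off when `exclude_regions` is NULL).}
#' }
#'
#' @param variants data.frame of annotated variant calls (see
#'   [render_variants()] for the column schema)
#' @param cfg a [pipeline_config()]
#' @param exclude_regions optional data.frame(chrom, start, end), 0-based
#'   half-open, activating rule R6
#' @return list(retained = data.frame, report = list(per_variant =
#'   data.frame with `retained` flag and comma-separated `failed` rules,
#'   removed_by_rule = named integer vector, n_in, n_retained)).
#' @export
apply_filters <- function(variants, cfg = pipeline_config(),
                          exclude_regions = NULL) {
  miss <- setdiff(required_variant_fields, names(variants))
  if (length(miss))
    stop("variant table missing required field(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(variants)
  for (f in required_variant_fields) {
    bad <- which(is.na(variants[[f]]))
    if (length(bad))
      stop("missing annotation '", f, "' for variant ",
           variants$gene[bad[1]], ":", variants$pos[bad[1]],
           " (row ", bad[1], ")")
  }
  pop_max <- pmax(variants$pop_freq_gnomad, variants$pop_freq_1000g,
                  variants$pop_freq_esp6500)
  fails <- cbind(
    R1 = pop_max > cfg$pop_freq_max,
    R2 = !variants$hotspot & variants$af < cfg$min_af_nonhotspot,
    R3 = variants$recurrence_freq > cfg$recurrence_max,
    R4 = variants$alt_reads < cfg$min_alt_reads,
    R5 = variants$gene %in% cfg$excluded_genes,
    R6 = if (is.null(exclude_regions)) rep(FALSE, n) else
      in_regions(variants$chrom, variants$pos, exclude_regions))
  retained <- rowSums(fails) == 0
  per_variant <- data.frame(
    gene = variants$gene, chrom = variants$chrom, pos = variants$pos,
    retained = retained,
    failed = apply(fails, 1, function(r)
      paste(colnames(fails)[r], collapse = ",")))
  list(retained = variants[retained, , drop = FALSE],
       report = list(per_variant = per_variant,
                     removed_by_rule = colSums(fails),
                     n_in = n, n_retained = sum(retained)))
}

# is each 1-based position inside any 0-based half-open region?
in_regions <- function(chrom, pos, regions) {
  vapply(seq_along(pos), function(i) {
    any(regions$chrom == chrom[i] & regions$start < pos[i] &
          regions$end >= pos[i])
  }, NA)
}

#' Contingency counts of variants by effect class, deleteriousness and
#' COSMIC status
#'
#' @param variants data.frame with `effect`, `deleterious`, `cosmic` columns
#' @return data.frame of counts (one row per populated combination, plus an
#'   `n` column); total equals `nrow(variants)`. Zero-row input yields a
#'   zero-row table.
#' @export
summarize_effects <- function(variants) {
  lv_eff <- c("missense", "synonymous", "stop_gain", "splice", "utr5",
              "intronic", "inframe_del")
  if (nrow(variants) == 0)
    return(data.frame(effect = character(), deleterious = logical(),
                      cosmic = character(), n = integer()))
  tab <- as.data.frame(table(
    effect = factor(variants$effect, levels = unique(c(lv_eff, variants$effect))),
    deleterious = variants$deleterious,
    cosmic = variants$cosmic), stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab <- tab[tab$n > 0, ]
  tab$deleterious <- as.logical(tab$deleterious)
  rownames(tab) <- NULL
  tab
}
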