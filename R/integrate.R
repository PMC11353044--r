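# CNV-SNV integration: the expected-allele-fraction model under copy number
# and clonal fraction, grid matching of observed AFs, and the association
# between karyotype status and de novo SNV carriage.

#' Expected allele fraction under copy number and clonal fraction
#'
#' A culture is modelled as a mutant clone at fraction `f` with `c` total
#' copies of the locus, `m` of them carrying the variant, mixed with a
#' wild-type population at fraction `1 - f` that is diploid at the locus
#' with `m0` mutant copies (0 for a variant private to the clone, 1 for a
#' germline heterozygote, 2 for a germline homozygote). The expected alt
#' allele fraction is the mutant-copy dosage over the total copy dosage:
#'
#'   AF = (f * m + (1 - f) * m0) / (f * c + (1 - f) * 2)
#'
#' At `f = 1` this reduces to m/c (e.g. 2/3 for a germline heterozygote
#' whose haplotype was duplicated; 1/3 for a de novo variant present as a
#' single copy in a triplicated locus); at `f = 0` it is m0/2.
#'
#' @param m mutant copies in the mutant clone, integer in [0, c]
#' @param c total copies of the locus in the mutant clone, >= 1
#' @param m0 mutant copies in the wild-type (diploid) population: 0, 1 or 2
#' @param f clonal fraction in [0, 1]
#' @return Expected allele fraction in [0, 1].
#' @export
#' @examples
#' expected_af(m = 1, c = 2, m0 = 1, f = 0.3)  # balanced heterozygote: 0.5
#' expected_af(m = 2, c = 3, m0 = 1, f = 1)    # duplicated het haplotype: 2/3
#' expected_af(m = 1, c = 3, m0 = 0, f = 1)    # single copy in triplicated locus: 1/3
expected_af <- function(m, c, m0, f) {
  if (c < 1) stop("total copy number c must be >= 1")
  if (m < 0 || m > c) stop("mutant copies m must lie in [0, c]")
  if (!m0 %in% 0:2) stop("wild-type mutant copies m0 must be 0, 1 or 2")
  if (f < 0 || f > 1) stop("clonal fraction f must lie in [0, 1]")
  denom <- f * c + (1 - f) * 2
  if (denom <= 0) stop("degenerate locus: zero total copy dosage")
  (f * m + (1 - f) * m0) / denom
}

#' Match an observed allele fraction to the expected-AF model
#'
#' Grid search over mutant copies `m` in 0..c, wild-type mutant copies `m0`
#' in {0, 1}, and clonal fraction `f` in {0.1, ..., 1.0}; the observed AF is
#' "CNV-explained" when the best fit lies within `tol`. The loose default
#' tolerance mirrors the verbal matching used in practice (an observed 0.25
#' against an analytic 1/3 is reconciled only through sub-clonality, which
#' the `f` grid operationalises).
#'
#' @param observed_af observed allele fraction
#' @param copy_number total copy number at the locus from the overlapping
#'   segment (2 when none overlaps)
#' @param tol explanation tolerance on |observed - expected|
#' @param m0_values candidate wild-type mutant copy numbers (set to 0 for a
#'   variant known to be absent from the wild-type population)
#' @return list(best_m, best_m0, best_f, expected_af, abs_error,
#'   cnv_explained).
#' @export
match_af <- function(observed_af, copy_number, tol = 0.10, m0_values = 0:1) {
  if (observed_af < 0 || observed_af > 1)
    stop("observed allele fraction must lie in [0, 1]")
  best <- list(abs_error = Inf)
  for (m in 0:copy_number) for (m0 in m0_values) for (f in seq(0.1, 1, 0.1)) {
    e <- expected_af(m = m, c = copy_number, m0 = m0, f = f)
    err <- abs(observed_af - e)
    if (err < best$abs_error - 1e-12) {
      best <- list(best_m = m, best_m0 = m0, best_f = f, expected_af = e,
                   abs_error = err)
    }
  }
  best$cnv_explained <- best$abs_error <= tol
  best
}

#' Integrate classified variants with called segments
#'
#' For each classified variant, finds the overlapping segment of its
#' first-detection sample (copy number 2 when none), runs [match_af()] on
#' the first detected AF, and records the best-fit configuration. Germline
#' variants allow wild-type mutant copies m0 in {0, 1}; de novo variants
#' are matched with m0 = 0.
#'
#' @param classified output of [classify_line()]
#' @param segments_by_rank list of segment tables, one per rank (may be NULL)
#' @param tol explanation tolerance, see [match_af()]
#' @return `classified` with `segment_label`, `segment_log2ratio`,
#'   `copy_number`, `best_m`, `best_m0`, `best_f`, `expected_af`,
#'   `cnv_explained` columns appended.
#' @export
integrate_line <- function(classified, segments_by_rank = NULL, tol = 0.10) {
  n <- nrow(classified)
  add <- data.frame(segment_label = rep(NA_character_, n),
                    segment_log2ratio = NA_real_, copy_number = 2L,
                    best_m = NA_integer_, best_m0 = NA_integer_,
                    best_f = NA_real_, expected_af = NA_real_,
                    cnv_explained = rep(NA, n))
  af_cols <- grep("^af_rank", names(classified))
  for (i in seq_len(n)) {
    first <- classified$first_seen_rank[i]
    segs <- if (!is.null(segments_by_rank) && first <= length(segments_by_rank))
      segments_by_rank[[first]] else NULL
    cn <- 2L
    if (!is.null(segs) && nrow(segs)) {
      hit <- segs$chrom == classified$chrom[i] &
        segs$start < classified$pos[i] & segs$end >= classified$pos[i]
      if (any(hit)) {
        j <- which(hit)[1]
        add$segment_label[i] <- segs$recurrent_label[j]
        add$segment_log2ratio[i] <- segs$mean_log2ratio[j]
        cn <- max(1L, as.integer(round(2 * 2^segs$mean_log2ratio[j])))
      }
    }
    add$copy_number[i] <- cn
    obs <- classified[i, af_cols][[first]]
    fit <- match_af(obs, cn, tol = tol,
                    m0_values = if (classified$origin[i] == "de_novo") 0 else 0:1)
    add$best_m[i] <- fit$best_m; add$best_m0[i] <- fit$best_m0
    add$best_f[i] <- fit$best_f; add$expected_af[i] <- fit$expected_af
    add$cnv_explained[i] <- fit$cnv_explained
  }
  cbind(classified, add)
}

#' Karyotype status versus de novo SNV carriage, as a 2x2 table
#'
#' Rows are karyotype status (normal, abnormal), columns de novo SNV
#' carriage (carrier = at least one de novo SNV detected in that sample,
#' non-carrier otherwise). Margins equal the sample count.
#'
#' @param samples data.frame with one row per sample and columns
#'   `karyotype` ("normal"/"abnormal") and `has_de_novo` (logical)
#' @return 2x2 integer matrix with dimnames
#'   (karyotype: normal/abnormal; de_novo: carrier/none).
#' @export
#' @examples
#' association_table(data.frame(
#'   karyotype = c("normal", "abnormal", "abnormal"),
#'   has_de_novo = c(FALSE, TRUE, TRUE)))
association_table <- function(samples) {
  need <- c("karyotype", "has_de_novo")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(samples$karyotype)) || any(is.na(samples$has_de_novo)))
    stop("unlabeled sample: karyotype and de novo carriage must be known")
  if (!all(samples$karyotype %in% c("normal", "abnormal")))
    stop("karyotype labels must be 'normal' or 'abnormal'")
  k <- factor(samples$karyotype, levels = c("normal", "abnormal"))
  d <- factor(ifelse(samples$has_de_novo, "carrier", "none"),
              levels = c("carrier", "none"))
  tab <- table(karyotype = k, de_novo = d)
  matrix(as.integer(tab), nrow = 2,
         dimnames = list(karyotype = c("normal", "abnormal"),
                         de_novo = c("carrier", "none")))
}
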