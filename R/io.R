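# Readers/writers for the interchange formats (VCF, TSV, BED, YAML, JSON)
# and the end-to-end pipeline: coverage -> CNV calls -> filtered SNVs ->
# lineage classification -> CNV-SNV integration -> cohort statistics.

.vcf_info_keys <- c(AF = "af", AD = "alt_reads", DP = "depth",
                    POPFREQ_GNOMAD = "pop_freq_gnomad",
                    POPFREQ_1000G = "pop_freq_1000g",
                    POPFREQ_ESP6500 = "pop_freq_esp6500",
                    EFFECT = "effect", SIFT = "deleterious",
                    COSMIC = "cosmic", HOTSPOT = "hotspot",
                    RECUR = "recurrence_freq", GENE = "gene")

#' Write variant calls as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 with the panel annotations as INFO keys (AF, AD,
#' DP, POPFREQ_*, EFFECT, SIFT, COSMIC, HOTSPOT, RECUR, GENE). Positions
#' are 1-based per the VCF convention.
#'
#' @param variants variant-call data.frame (see [render_variants()])
#' @param path output path
#' @param sample_id recorded as a `##sample=` header line
#' @export
write_variants_vcf <- function(variants, path,
                               sample_id = variants$sample_id[1]) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##sample=", if (is.null(sample_id) || is.na(sample_id))
             "NA" else sample_id),
           paste0("##INFO=<ID=", names(.vcf_info_keys),
                  ",Number=1,Type=String,Description=\"",
                  .vcf_info_keys, "\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(variants)) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      paste0("AF=", format(v$af, digits = 15), ";AD=", v$alt_reads,
             ";DP=", v$depth,
             ";POPFREQ_GNOMAD=", format(v$pop_freq_gnomad, digits = 15),
             ";POPFREQ_1000G=", format(v$pop_freq_1000g, digits = 15),
             ";POPFREQ_ESP6500=", format(v$pop_freq_esp6500, digits = 15),
             ";EFFECT=", v$effect,
             ";SIFT=", if (isTRUE(v$deleterious)) "D" else "T",
             ";COSMIC=", v$cosmic,
             ";HOTSPOT=", as.integer(v$hotspot),
             ";RECUR=", format(v$recurrence_freq, digits = 15),
             ";GENE=", v$gene)
    }, "")
    recs <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read variant calls from VCF or TSV
#'
#' The VCF dialect parses the INFO keys written by [write_variants_vcf()]
#' (any other INFO content is preserved verbatim in an `info_extra`
#' column); the TSV dialect expects the variant-call column schema
#' directly. Both yield identical records for identical content.
#'
#' @param path input file
#' @param dialect "auto" (by extension), "vcf" or "tsv"
#' @param sample_id overrides the sample id recorded in the file
#' @return Variant-call data.frame.
#' @export
read_variants <- function(path, dialect = c("auto", "vcf", "tsv"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (dialect == "vcf") read_variants_vcf(path, sample_id)
  else read_variants_tsv(path, sample_id)
}

read_variants_vcf <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  if (is.null(sample_id)) {
    sm <- grep("^##sample=", meta, value = TRUE)
    sample_id <- if (length(sm)) sub("^##sample=", "", sm[1]) else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    out <- empty_variant_calls()
    return(out)
  }
  get_info <- function(key) vcfR::extract.info(vcf, element = key)
  vals <- lapply(names(.vcf_info_keys), get_info)
  names(vals) <- names(.vcf_info_keys)
  for (key in names(vals)) {
    bad <- which(is.na(vals[[key]]))
    if (length(bad))
      stop("record ", bad[1], " of ", basename(path),
           ": missing required INFO field ", key)
  }
  pos <- suppressWarnings(as.numeric(fix$POS))
  if (any(is.na(pos)))
    stop("record ", which(is.na(pos))[1], " of ", basename(path),
         ": malformed coordinate")
  known <- paste0("(^|;)(", paste(names(.vcf_info_keys), collapse = "|"),
                  ")=[^;]*")
  extra <- gsub("^;+|;+$", "", gsub(known, "", fix$INFO))
  data.frame(sample_id = sample_id, line_id = NA_character_,
             gene = vals$GENE, chrom = fix$CHROM, pos = pos,
             ref = fix$REF, alt = fix$ALT,
             af = as.numeric(vals$AF), alt_reads = as.integer(vals$AD),
             depth = as.integer(vals$DP),
             pop_freq_gnomad = as.numeric(vals$POPFREQ_GNOMAD),
             pop_freq_1000g = as.numeric(vals$POPFREQ_1000G),
             pop_freq_esp6500 = as.numeric(vals$POPFREQ_ESP6500),
             effect = vals$EFFECT, deleterious = vals$SIFT == "D",
             cosmic = vals$COSMIC, hotspot = vals$HOTSPOT == "1",
             recurrence_freq = as.numeric(vals$RECUR),
             info_extra = extra, stringsAsFactors = FALSE)
}

#' @rdname read_variants
#' @param variants variant-call data.frame
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_variants_tsv <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_variant_fields, names(df))
  if (length(miss))
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(sample_id)) df$sample_id <- sample_id
  df
}

#' Read / write binned coverage as TSV (chrom, start, end, gc, count)
#' @param path file path
#' @param sample_id sample identifier attached as an attribute
#' @export
read_coverage <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(basename(path), ": missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$blacklisted)) df$blacklisted <- FALSE
  attr(df, "sample_id") <- sample_id %||%
    sub("\\.(tsv|txt)$", "", basename(path))
  df
}

#' @rdname read_coverage
#' @param cov binned-coverage data.frame
#' @export
write_coverage <- function(cov, path) {
  utils::write.table(cov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV segments as BED (0-based) and as a 1-based report TSV
#' @param segments segment data.frame from [segment_cnvs()]
#' @param path output path
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = segments$chrom, start = segments$start,
                   end = segments$end,
                   name = paste0(segments$direction, "_",
                                 ifelse(is.na(segments$recurrent_label),
                                        "rare", segments$recurrent_label)),
                   score = round(1000 * abs(segments$mean_log2ratio)),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
write_segments_tsv <- function(segments, path) {
  df <- segments
  df$start_1based <- df$start + 1          # karyotype-style printed coords
  df <- df[, c("chrom", "start_1based", "end", "direction", "mean_log2ratio",
               "n_bins", "size_mb", "recurrent_label")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind data.frames whose column sets may differ (lines with different
# numbers of ranks have different af_rank columns); missing columns fill NA
rbind_fill <- function(dfs) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, dfs)
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  }))
}

# ---- cohort materialisation -------------------------------------------------

#' Write a simulated cohort to disk
#'
#' Renders coverage (TSV) and panel variants (VCF) for every sampled
#' passage of every line, plus the manifest (TSV) and the ground truth
#' (JSON). The returned manifest carries the file paths and feeds
#' [run_pipeline()] directly.
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @param seed master seed for the render substreams
#' @param ... passed to [render_coverage()]
#' @return The manifest with `coverage_path` and `variants_path` columns.
#' @export
write_cohort <- function(cohort, dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$coverage_path <- file.path(dir, paste0(man$sample_id, ".coverage.tsv"))
  man$variants_path <- file.path(dir, paste0(man$sample_id, ".vcf"))
  for (i in seq_len(nrow(man))) {
    h <- cohort$histories[[man$line_id[i]]]
    cov <- render_coverage(h, man$passage[i], seed = seed, ...)
    write_coverage(cov, man$coverage_path[i])
    v <- render_variants(h, man$passage[i], seed = seed)
    write_variants_vcf(v, man$variants_path[i], sample_id = man$sample_id[i])
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- lapply(cohort$histories, function(h) {
    list(line_id = h$line_id, clones = h$clones, events = h$events,
         fractions = h$fractions, germline = h$germline)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(man)
}

# ---- pipeline orchestration -------------------------------------------------

provenance_block <- function(config, seed) {
  cfg_yaml <- yaml::as.yaml(unclass(config))
  list(config_hash = sprintf("%08x", fnv1a(cfg_yaml)), seed = seed,
       tool = "stemdrift",
       version = as.character(utils::packageVersion("stemdrift")))
}

#' Run the full analysis pipeline over a cohort manifest
#'
#' For every sample: CNV calling ([call_cnvs()]) on the binned coverage and
#' the retention cascade ([apply_filters()]) on the variant calls. Per
#' line: germline / de novo classification ([classify_line()]) and CNV-SNV
#' integration ([integrate_line()]). Cohort level: the karyotype-vs-de-novo
#' association table with its exact Fisher p, Poisson load regressions on
#' rank and passage, and logistic acquisition regressions on rank and
#' passage. Any stage error is rethrown with the stage and sample id.
#'
#' @param manifest manifest with sample_id/line_id/passage/rank and
#'   coverage_path/variants_path columns (see [write_cohort()])
#' @param config a [pipeline_config()]
#' @param out_dir optional directory for per-stage outputs
#' @param seed recorded in the provenance block
#' @return A bundle: list(segments, filter_reports, classified, integrated,
#'   sample_summary, association, stats, provenance).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir = NULL,
                         seed = NA_integer_) {
  validate_manifest(manifest)
  if (is.null(manifest$coverage_path) || is.null(manifest$variants_path))
    stop("manifest must carry coverage_path and variants_path columns")
  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for sample ", sid, ": ",
           conditionMessage(e), call. = FALSE))
  }
  segments <- list(); filtered <- list(); reports <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    cov <- stage("read-coverage", sid,
                 read_coverage(manifest$coverage_path[i], sample_id = sid))
    segments[[sid]] <- stage("call-cnv", sid, call_cnvs(cov))
    v <- stage("read-variants", sid,
               read_variants(manifest$variants_path[i], sample_id = sid))
    v$line_id <- rep(manifest$line_id[i], nrow(v))
    fl <- stage("filter-snv", sid, apply_filters(v, config))
    filtered[[sid]] <- fl$retained
    reports[[sid]] <- fl$report
  }

  classified <- list(); integrated <- list()
  for (ln in unique(manifest$line_id)) {
    sub <- manifest[manifest$line_id == ln, ]
    sub <- sub[order(sub$rank), ]
    vbr <- filtered[sub$sample_id]
    sbr <- segments[sub$sample_id]
    cl <- stage("classify", ln,
                classify_line(vbr, line_id = ln, segments_by_sample = sbr))
    classified[[ln]] <- cl
    integrated[[ln]] <- if (nrow(cl))
      stage("integrate", ln, integrate_line(cl, segments_by_rank = sbr))
    else NULL
  }
  classified_all <- rbind_fill(classified)
  integrated_all <- rbind_fill(integrated)

  # per-sample summary: karyotype status, de novo carriage, de novo load,
  # new-event acquisition relative to the previous rank
  summ <- manifest[, c("sample_id", "line_id", "passage", "rank")]
  summ$karyotype <- vapply(summ$sample_id,
                           function(s) karyotype_status(segments[[s]]), "")
  summ$n_segments <- vapply(summ$sample_id,
                            function(s) nrow(segments[[s]]), 0L)
  de_novo_at <- function(line, rank) {
    cl <- classified[[line]]
    if (is.null(cl) || !nrow(cl)) return(0L)
    dn <- cl[cl$origin == "de_novo", , drop = FALSE]
    if (!nrow(dn)) return(0L)
    sum(!is.na(dn[[paste0("af_rank", rank)]]))
  }
  summ$de_novo_load <- mapply(de_novo_at, summ$line_id, summ$rank)
  summ$has_de_novo <- summ$de_novo_load > 0
  acquired_at <- function(line, rank) {
    cl <- classified[[line]]
    if (is.null(cl) || !nrow(cl)) return(0L)
    sum(cl$origin == "de_novo" & cl$first_seen_rank == rank)
  }
  summ$n_acquired <- mapply(acquired_at, summ$line_id, summ$rank)

  association <- association_table(summ)
  try_stat <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  stats_out <- list(
    fisher_karyotype_de_novo = list(
      table = association, p = try_stat(fisher_exact_2x2(association))),
    poisson_load_rank = try_stat(
      poisson_load_regression(summ$rank, summ$de_novo_load, "rank")),
    poisson_load_passage = try_stat(
      poisson_load_regression(summ$passage, summ$de_novo_load, "passage")),
    logistic_acquisition_passage = try_stat({
      later <- summ[summ$rank > 1, ]
      logistic_acquisition_regression(later$passage, later$n_acquired > 0,
                                      "passage")
    }),
    logistic_acquisition_rank = try_stat({
      later <- summ[summ$rank > 1, ]
      logistic_acquisition_regression(later$rank, later$n_acquired > 0,
                                      "rank")
    }))

  bundle <- list(segments = segments, filter_reports = reports,
                 classified = classified_all, integrated = integrated_all,
                 sample_summary = summ, association = association,
                 stats = stats_out,
                 provenance = provenance_block(config, seed))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

strip_fit <- function(s) {
  if (inherits(s, "stemdrift_regression"))
    s[c("model", "predictor", "intercept", "slope", "se", "p", "n",
        "excluded_points")]
  else s
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(bundle$segments)) {
    segs <- bundle$segments[[sid]]
    if (nrow(segs)) {
      write_segments_bed(segs, file.path(out_dir, paste0(sid, ".segments.bed")))
      write_segments_tsv(segs, file.path(out_dir, paste0(sid, ".segments.tsv")))
    }
  }
  if (!is.null(bundle$classified))
    utils::write.table(bundle$classified,
                       file.path(out_dir, "classified_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$integrated))
    utils::write.table(bundle$integrated,
                       file.path(out_dir, "integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$sample_summary,
                     file.path(out_dir, "sample_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_json <- list(association = bundle$association,
                     stats = lapply(bundle$stats, function(s) {
                       if (is.list(s) && !is.null(s$p) && is.list(s$table %||% NULL))
                         list(table = s$table, p = s$p)
                       else strip_fit(s)
                     }),
                     provenance = bundle$provenance)
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                       force = TRUE)
  invisible(out_dir)
}
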