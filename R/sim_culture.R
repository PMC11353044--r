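# Serial-passage clonal-evolution simulator.
#
# A culture is a set of clones; each passage applies (1) selection -- clone
# fractions are reweighted by fitness, (2) drift -- multinomial resampling at
# the bottleneck size, (3) mutation -- each surviving clone may spawn a child
# clone carrying one new event (recurrent driver CNV, rare passenger CNV, or
# panel SNV). Ground truth (clones, events, per-passage fractions) is kept so
# downstream calling, filtering and classification can be scored exactly.

#' Simulation parameters for a serial-passage culture
#'
#' Defaults emulate the study conditions of a long-term hPSC culture
#' experiment: ~50 passages with three sampled time points, constant
#' per-passage mutation probabilities, strong growth advantage for recurrent
#' driver CNVs (20q11.21, 1q, ...) and neutral passenger CNVs/SNVs. Mutation
#' probabilities are order-of-magnitude choices calibrated so a simulated
#' line accumulates a handful of panel-detectable de novo SNVs and most lines
#' undergo a driver takeover, matching reported per-line counts; they are not
#' measurable quantities of any real culture.
#'
#' @param n_passages number of passages to simulate
#' @param sample_passages passages at which samples are drawn (define ranks)
#' @param bottleneck_size effective number of cells surviving each split;
#'   small relative to the physical culture, encoding drift at a 1:10-1:100
#'   split ratio
#' @param p_cnv_recurrent,p_cnv_rare,p_snv per-clone per-passage acquisition
#'   probabilities of each event class (constant over time)
#' @param s_recurrent per-passage relative growth advantage (1 + s) of a
#'   clone carrying a recurrent driver CNV
#' @param s_rare growth advantage of rare passenger CNVs (0 = neutral)
#' @param snv_rate_multiplier_given_driver multiplies `p_snv` for clones
#'   carrying a driver CNV (1 = no built-in association)
#' @param n_germline number of germline panel variants per line; `NULL`
#'   draws uniformly from 6..17
#' @param genome genome dictionary (named lengths)
#' @param catalog recurrent-abnormality catalog, see [recurrent_catalog()]
#' @param panel panel gene table, see [default_panel()]
#' @param seed master seed; all per-line / per-render substreams derive from it
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_passages = 50,
                       sample_passages = c(10, 30, 50),
                       bottleneck_size = 200,
                       p_cnv_recurrent = 0.05,
                       p_cnv_rare = 0.05,
                       p_snv = 0.15,
                       s_recurrent = 0.5,
                       s_rare = 0,
                       snv_rate_multiplier_given_driver = 1,
                       n_germline = NULL,
                       genome = hg19_genome(),
                       catalog = recurrent_catalog(),
                       panel = default_panel(),
                       seed = 1L) {
  p <- as.list(environment())
  for (f in c("p_cnv_recurrent", "p_cnv_rare", "p_snv")) {
    v <- p[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("probability '", f, "' must lie in [0, 1]")
  }
  if (p$bottleneck_size < 10) stop("bottleneck_size must be >= 10")
  if (p$s_recurrent < 0 || p$s_rare < 0) stop("fitness advantages must be >= 0")
  if (p$snv_rate_multiplier_given_driver < 1)
    stop("snv_rate_multiplier_given_driver must be >= 1")
  if (any(p$sample_passages > p$n_passages))
    stop("sample_passages beyond n_passages")
  structure(p, class = "sim_params")
}

# effect-class frequencies observed for germline and culture-acquired panel
# SNVs (missense split into deleterious / tolerated)
.effect_profiles <- list(
  germline = data.frame(
    effect = c("missense", "missense", "synonymous", "stop_gain", "splice",
               "utr5", "inframe_del", "intronic"),
    deleterious = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    w = c(29, 23, 28, 1, 5, 1, 2, 7)),
  de_novo = data.frame(
    effect = c("missense", "missense", "synonymous", "stop_gain", "splice",
               "inframe_del", "intronic"),
    deleterious = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    w = c(13, 3, 7, 12, 1, 1, 3))
)

# cosmic-status frequencies: tier1 / reported (non-tier1) / none
.cosmic_profiles <- list(
  germline = c(tier1 = 14, reported = 10, none = 72),
  de_novo = c(tier1 = 8, reported = 3, none = 17)
)

draw_effect <- function(n, origin) {
  prof <- .effect_profiles[[origin]]
  i <- sample.int(nrow(prof), n, replace = TRUE, prob = prof$w)
  cw <- .cosmic_profiles[[origin]]
  data.frame(effect = prof$effect[i], deleterious = prof$deleterious[i],
             cosmic = sample(names(cw), n, replace = TRUE, prob = cw),
             hotspot = stats::runif(n) < 0.05)
}

.bases <- c("A", "C", "G", "T")

#' Toy cancer-gene panel
#'
#' A deterministic table of gene footprints spread across the genome,
#' emulating a solid/haematological-tumour panel. A few well-known
#' culture-relevant genes (TP53, EP300, KMT2C, DOCK8, CDKN2B, PMS2, ...) are
#' pinned to their approximate hg19 loci when the genome contains their
#' chromosome; the remainder are placeholders.
#'
#' @param n_genes total number of panel genes
#' @param genome genome dictionary
#' @return data.frame with columns gene, chrom, start, end (0-based half-open).
#' @export
default_panel <- function(n_genes = 380, genome = hg19_genome()) {
  pinned <- data.frame(
    gene = c("TP53", "EP300", "KMT2C", "DOCK8", "CDKN2B", "PMS2", "ASXL1",
             "CREBBP", "FAT1", "BRCA2", "APC"),
    chrom = c("chr17", "chr22", "chr7", "chr9", "chr9", "chr7", "chr20",
              "chr16", "chr4", "chr13", "chr5"),
    start = c(7565097, 41488614, 151832010, 204193, 21994790, 6012870,
              30946147, 3775055, 187508937, 32889616, 112043201),
    end = c(7590856, 41576081, 152133090, 465259, 22001000, 6048737,
            31027122, 3930121, 187647876, 32973809, 112181936))
  pinned <- pinned[pinned$chrom %in% names(genome) &
                     pinned$end <= genome[pinned$chrom], ]
  n_extra <- max(0, n_genes - nrow(pinned))
  if (n_extra > 0) {
    # deterministic placement: evenly spaced across the genome
    tot <- sum(genome)
    pos <- (seq_len(n_extra) - 0.5) / n_extra * tot
    cum <- cumsum(as.numeric(genome))
    ci <- findInterval(pos, c(0, cum), rightmost.closed = TRUE)
    off <- pos - c(0, cum)[ci]
    len <- 5e4
    start <- pmin(pmax(round(off), 0), genome[ci] - len - 1)
    extra <- data.frame(gene = sprintf("PANG%03d", seq_len(n_extra)),
                        chrom = names(genome)[ci],
                        start = start, end = start + len)
    pinned <- rbind(pinned, extra)
  }
  rownames(pinned) <- NULL
  pinned
}

# draw one CNV event interval for a recurrent-catalog entry: a random
# sub-interval of the catalog region that spans the driver locus
draw_recurrent_cnv <- function(catalog) {
  i <- sample.int(nrow(catalog), 1, prob = catalog$sim_weight)
  e <- catalog[i, ]
  start <- floor(stats::runif(1, e$region_start, e$driver_start))
  end <- ceiling(stats::runif(1, e$driver_end, e$region_end))
  list(chrom = e$chrom, start = start, end = end,
       copies_delta = if (e$direction == "gain") 1L else -1L,
       label = e$label, s = NA_real_)
}

draw_rare_cnv <- function(genome) {
  auto <- genome[!is_sex_chrom(names(genome))]
  chrom <- sample(names(auto), 1, prob = auto)
  size <- min(round(10^stats::runif(1, log10(7e5), log10(5e7))), auto[[chrom]] - 1)
  start <- floor(stats::runif(1, 0, auto[[chrom]] - size))
  list(chrom = chrom, start = start, end = start + size,
       copies_delta = if (stats::runif(1) < 0.8) 1L else -1L,
       label = NA_character_, s = NA_real_)
}

empty_events <- function() {
  data.frame(event_id = integer(), clone = integer(), passage = integer(),
             kind = character(), chrom = character(), start = numeric(),
             end = numeric(), copies_delta = integer(), haplotype = integer(),
             gene = character(), pos = numeric(), ref = character(),
             alt = character(), effect = character(), deleterious = logical(),
             cosmic = character(), hotspot = logical(), s = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

#' Simulate one cell line over serial passages
#'
#' @param params a [sim_params()] object
#' @param line_id line identifier used for seeding and labelling
#' @return A list of class `culture_history` with elements `clones`
#'   (clone/parent/birth passage/fitness), `events` (full event log, one row
#'   per acquired mutation), `fractions` (matrix passage x clone of
#'   population fractions; row "0" is the founding state), `germline`
#'   (germline panel variants with haplotype and zygosity), `params`,
#'   `line_id`.
#' @export
simulate_line <- function(params, line_id = "LINE1") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, line_id, "simulate"))
  N <- params$bottleneck_size
  n_gl <- if (is.null(params$n_germline)) sample(6:17, 1) else params$n_germline

  germline <- local({
    if (n_gl == 0) return(NULL)
    gi <- sample.int(nrow(params$panel), n_gl)
    g <- params$panel[gi, ]
    pos <- floor(stats::runif(n_gl, g$start, g$end - 1)) + 1  # 1-based
    ann <- draw_effect(n_gl, "germline")
    ref <- sample(.bases, n_gl, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1), "")
    data.frame(gene = g$gene, chrom = g$chrom, pos = pos, ref = ref, alt = alt,
               haplotype = sample(1:2, n_gl, replace = TRUE),
               zygosity = ifelse(stats::runif(n_gl) < 2 / 96,
                                 "homozygous", "heterozygous"),
               ann,
               pop_freq_gnomad = stats::runif(n_gl, 0, 0.005),
               pop_freq_1000g = stats::runif(n_gl, 0, 0.005),
               pop_freq_esp6500 = stats::runif(n_gl, 0, 0.005),
               row.names = NULL)
  })

  # clone state kept in parallel vectors; events accumulated as a list of
  # one-row lists and assembled into a data.frame once at the end
  parent_v <- NA_integer_; birth_v <- 0L
  fitness <- 1
  has_driver <- FALSE            # per clone: carries a recurrent CNV
  counts <- N                    # per clone cell counts at the bottleneck
  frac_rows <- list("0" = c("1" = 1))
  ev_rows <- list()
  next_clone <- 2L
  next_event <- 1L

  spawn <- function(parent, passage, kind) {
    ev <- switch(kind,
      cnv_recurrent = {
        d <- draw_recurrent_cnv(params$catalog); d$s <- params$s_recurrent; d
      },
      cnv_rare = {
        d <- draw_rare_cnv(params$genome); d$s <- params$s_rare; d
      },
      snv = {
        gi <- sample.int(nrow(params$panel), 1)
        g <- params$panel[gi, ]
        ref <- sample(.bases, 1)
        list(chrom = g$chrom, start = NA_real_, end = NA_real_,
             copies_delta = NA_integer_, gene = g$gene,
             pos = floor(stats::runif(1, g$start, g$end - 1)) + 1,
             ref = ref, alt = sample(setdiff(.bases, ref), 1),
             label = NA_character_, s = 0)
      })
    row <- list(event_id = next_event, clone = next_clone, passage = passage,
                kind = if (kind == "snv") "snv" else
                  if (ev$copies_delta > 0) "cnv_gain" else "cnv_loss",
                chrom = ev$chrom, start = NA_real_, end = NA_real_,
                copies_delta = NA_integer_, haplotype = sample(1:2, 1),
                gene = NA_character_, pos = NA_real_, ref = NA_character_,
                alt = NA_character_, effect = NA_character_,
                deleterious = NA, cosmic = NA_character_, hotspot = NA,
                s = ev$s, label = ev$label)
    if (kind == "snv") {
      ann <- draw_effect(1, "de_novo")
      row$gene <- ev$gene; row$pos <- ev$pos; row$ref <- ev$ref; row$alt <- ev$alt
      row$effect <- ann$effect; row$deleterious <- ann$deleterious
      row$cosmic <- ann$cosmic; row$hotspot <- ann$hotspot
    } else {
      row$start <- ev$start; row$end <- ev$end; row$copies_delta <- ev$copies_delta
    }
    ev_rows[[next_event]] <<- row
    parent_v[next_clone] <<- parent
    birth_v[next_clone] <<- passage
    fitness[next_clone] <<- fitness[parent] * (1 + row$s)
    has_driver[next_clone] <<- has_driver[parent] || kind == "cnv_recurrent"
    counts[next_clone] <<- 1
    counts[parent] <<- counts[parent] - 1
    next_clone <<- next_clone + 1L
    next_event <<- next_event + 1L
  }

  for (p in seq_len(params$n_passages)) {
    frac <- counts / sum(counts)
    w <- frac * fitness
    frac <- w / sum(w)                                  # selection
    counts <- as.vector(stats::rmultinom(1, N, frac))   # bottleneck drift
    alive <- which(counts > 0)
    for (cl in alive) {                                 # mutation
      p_snv_eff <- min(1, params$p_snv *
        if (has_driver[cl]) params$snv_rate_multiplier_given_driver else 1)
      for (kind in c("cnv_recurrent", "cnv_rare", "snv")) {
        pk <- switch(kind, cnv_recurrent = params$p_cnv_recurrent,
                     cnv_rare = params$p_cnv_rare, snv = p_snv_eff)
        if (counts[cl] >= 1 && stats::runif(1) < pk) spawn(cl, p, kind)
      }
    }
    fr <- counts / sum(counts)
    names(fr) <- as.character(seq_along(fr))
    frac_rows[[as.character(p)]] <- fr[fr > 0]
  }

  n_clones <- next_clone - 1L
  fractions <- matrix(0, nrow = params$n_passages + 1, ncol = n_clones,
                      dimnames = list(c(0, seq_len(params$n_passages)),
                                      seq_len(n_clones)))
  for (pn in names(frac_rows)) fractions[pn, names(frac_rows[[pn]])] <- frac_rows[[pn]]

  events <- if (length(ev_rows)) {
    cols <- names(ev_rows[[1]])
    as.data.frame(stats::setNames(lapply(cols, function(cc)
      unlist(lapply(ev_rows, `[[`, cc), use.names = FALSE)), cols),
      stringsAsFactors = FALSE)
  } else empty_events()
  clones <- data.frame(clone = seq_len(n_clones), parent = parent_v,
                       birth_passage = birth_v)

  structure(list(line_id = line_id, params = params, clones = clones,
                 events = events, fractions = fractions, germline = germline),
            class = "culture_history")
}

#' @export
print.culture_history <- function(x, ...) {
  cat("culture_history", x$line_id, "-", nrow(x$clones), "clones,",
      nrow(x$events), "events,", nrow(x$fractions) - 1, "passages\n")
  invisible(x)
}

# clone ids from a clone up to the founding clone
clone_lineage <- function(history, clone) {
  out <- integer()
  while (!is.na(clone)) {
    out <- c(out, clone)
    clone <- history$clones$parent[history$clones$clone == clone]
  }
  out
}

# events carried by a clone (own + inherited), in acquisition order
clone_events <- function(history, clone) {
  ev <- history$events[history$events$clone %in% clone_lineage(history, clone), ]
  ev[order(ev$event_id), ]
}

# total copy number of a clone at a genomic point (chrom, 0-based bp)
clone_copy_number <- function(history, clone, chrom, bp) {
  ev <- clone_events(history, clone)
  ev <- ev[ev$kind %in% c("cnv_gain", "cnv_loss") & ev$chrom == chrom &
             ev$start <= bp & ev$end > bp, ]
  max(0L, 2L + sum(ev$copies_delta))
}

# copies of one haplotype at a point, optionally counting only CNV events
# acquired after a given event id (a duplication only copies alleles that
# were already on the haplotype)
hap_copies <- function(history, clone, chrom, bp, haplotype, after_event = 0) {
  ev <- clone_events(history, clone)
  ev <- ev[ev$kind %in% c("cnv_gain", "cnv_loss") & ev$chrom == chrom &
             ev$start <= bp & ev$end > bp & ev$haplotype == haplotype &
             ev$event_id > after_event, ]
  max(0L, 1L + sum(ev$copies_delta))
}

alive_fractions <- function(history, passage) {
  if (!as.character(passage) %in% rownames(history$fractions))
    stop("passage ", passage, " not recorded in history")
  fr <- history$fractions[as.character(passage), ]
  fr[fr > 0]
}

# ---- renders ----------------------------------------------------------------

#' Tile a genome into fixed-width bins
#' @param genome genome dictionary
#' @param bin_size bin width in bp (last bin of each chromosome may be short)
#' @return data.frame(chrom, start, end), 0-based half-open, in genome order.
#' @export
make_bins <- function(genome, bin_size = 50000) {
  out <- lapply(names(genome), function(ch) {
    s <- seq(0, genome[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = s, end = pmin(s + bin_size, genome[[ch]]))
  })
  do.call(rbind, out)
}

#' Smooth unimodal GC-bias curve (quadratic, peak at GC = 0.45)
#' @param gc GC fractions in [0, 1]
#' @param amp amplitude: bias is 1 + amp at the peak, 1 at GC 0 and 0.9
#' @export
gc_bias_curve <- function(gc, amp = 0.2) {
  pmax(0.05, 1 + amp * (1 - ((gc - 0.45) / 0.45)^2))
}

# deterministic smooth synthetic GC track (no RNG: phases hashed per chrom)
synthetic_gc_track <- function(bins) {
  mid <- (bins$start + bins$end) / 2
  chs <- unique(bins$chrom)
  ph <- stats::setNames(vapply(chs, function(ch) (fnv1a(ch) %% 628) / 100, 0),
                        chs)
  phase <- unname(ph[bins$chrom])
  0.42 + 0.06 * sin(2 * pi * mid / 7.3e6 + phase) +
    0.015 * sin(2 * pi * mid / 1.1e6)
}

#' Render a culture snapshot into shallow-WGS binned read counts
#'
#' Expected count per bin is `base_count` x (population-average copy number
#' / 2) x GC bias; counts are drawn negative-binomially with dispersion
#' `dispersion` (variance mu + dispersion * mu^2). `dispersion = 0` gives the
#' deterministic limit (counts equal to their expectation).
#'
#' @param history a `culture_history`
#' @param passage recorded passage to render
#' @param genome genome dictionary (defaults to the simulation genome)
#' @param bin_size bin width, bp
#' @param base_count expected diploid count per full bin; default derived
#'   from 0.1x coverage of 50 bp reads (coverage * bin_size / 50)
#' @param dispersion negative-binomial dispersion (0 = noiseless)
#' @param gc_amp GC-bias amplitude fed to [gc_bias_curve()]
#' @param gc optional per-bin GC fractions; default: smooth synthetic track
#' @param shallow_coverage target coverage used to derive `base_count`
#' @param seed integer seed for this render
#' @return data.frame(chrom, start, end, gc, count, blacklisted) with
#'   attribute `sample_id`.
#' @export
render_coverage <- function(history, passage, genome = history$params$genome,
                            bin_size = 50000, base_count = NULL,
                            dispersion = 0.002, gc_amp = 0.2, gc = NULL,
                            shallow_coverage = 0.1, seed = 1L) {
  fr <- alive_fractions(history, passage)
  bins <- make_bins(genome, bin_size)
  if (is.null(gc) ) gc <- synthetic_gc_track(bins)
  if (length(gc) != nrow(bins)) stop("gc track does not match the bin grid")
  if (is.null(base_count)) base_count <- round(shallow_coverage * bin_size / 50)

  dosage <- rep(2, nrow(bins))
  cnv <- history$events[history$events$kind %in% c("cnv_gain", "cnv_loss"), ]
  if (nrow(cnv)) {
    lineages <- lapply(as.integer(names(fr)), clone_lineage, history = history)
    for (i in seq_len(nrow(cnv))) {
      carrier <- sum(fr[vapply(lineages, function(l) cnv$clone[i] %in% l, NA)])
      if (carrier == 0) next
      hit <- bins$chrom == cnv$chrom[i] & bins$start < cnv$end[i] &
        bins$end > cnv$start[i]
      dosage[hit] <- dosage[hit] + carrier * cnv$copies_delta[i]
    }
  }
  dosage <- pmax(dosage, 0)
  frac_len <- (bins$end - bins$start) / bin_size
  mu <- base_count * frac_len * dosage / 2 * gc_bias_curve(gc, gc_amp)
  if (dispersion <= 0) {
    count <- mu
  } else {
    set.seed(derive_seed(seed, history$line_id, passage, "coverage"))
    count <- stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    gc = gc, count = count, blacklisted = FALSE)
  attr(out, "sample_id") <- paste0(history$line_id, "_P", passage)
  out
}

#' Render a culture snapshot into panel variant calls
#'
#' For every germline variant and every somatic panel SNV, the true allele
#' fraction is the clone-fraction-weighted mutant-copy dosage over the
#' clone-fraction-weighted total copy number (the same model as
#' [expected_af()], generalised to many clones, with haplotype-aware copy
#' counts: a duplication raises the AF of alleles on the duplicated
#' haplotype). Observed alt reads are Binomial(depth at site, AF) with
#' Poisson-distributed site depth. Variants with observed AF below
#' `af_floor` are dropped, emulating the panel's detection limit for
#' low-grade mosaicism.
#'
#' @param history a `culture_history`
#' @param passage recorded passage to render
#' @param depth target mean panel depth (reads)
#' @param af_floor detection floor on observed allele fraction
#' @param panel panel gene table; variants outside it are not observed
#' @param seed integer seed for this render
#' @return data.frame of variant calls (one row per detected variant) with
#'   annotation fields and ground-truth columns prefixed `true_`.
#' @export
render_variants <- function(history, passage, depth = 1500, af_floor = 0.005,
                            panel = history$params$panel, seed = 1L) {
  fr <- alive_fractions(history, passage)
  clones_alive <- as.integer(names(fr))
  lineages <- lapply(clones_alive, clone_lineage, history = history)
  cnv <- history$events[history$events$kind %in% c("cnv_gain", "cnv_loss"), ,
                        drop = FALSE]
  cnv_by_clone <- lapply(lineages, function(lin)
    cnv[cnv$clone %in% lin, , drop = FALSE])
  set.seed(derive_seed(seed, history$line_id, passage, "variants"))

  # candidate variants: germline + every somatic panel SNV ever acquired
  gl <- history$germline
  snv <- history$events[history$events$kind == "snv", , drop = FALSE]
  cand <- rbind(
    if (!is.null(gl) && nrow(gl)) data.frame(
      gene = gl$gene, chrom = gl$chrom, pos = gl$pos, ref = gl$ref,
      alt = gl$alt, haplotype = gl$haplotype, zygosity = gl$zygosity,
      owner = NA_integer_, event_id = 0, event_passage = NA_real_,
      effect = gl$effect, deleterious = gl$deleterious, cosmic = gl$cosmic,
      hotspot = gl$hotspot, pop_freq_gnomad = gl$pop_freq_gnomad,
      pop_freq_1000g = gl$pop_freq_1000g,
      pop_freq_esp6500 = gl$pop_freq_esp6500, origin = "germline"),
    if (nrow(snv)) data.frame(
      gene = snv$gene, chrom = snv$chrom, pos = snv$pos, ref = snv$ref,
      alt = snv$alt, haplotype = snv$haplotype, zygosity = "somatic",
      owner = snv$clone, event_id = snv$event_id,
      event_passage = snv$passage, effect = snv$effect,
      deleterious = snv$deleterious, cosmic = snv$cosmic,
      hotspot = snv$hotspot, pop_freq_gnomad = 0, pop_freq_1000g = 0,
      pop_freq_esp6500 = 0, origin = "de_novo"))
  if (is.null(cand) || nrow(cand) == 0) return(empty_variant_calls())
  cand <- cand[cand$gene %in% panel$gene, , drop = FALSE]  # outside panel: unobserved
  if (nrow(cand) == 0) return(empty_variant_calls())

  n <- nrow(cand)
  af_true <- numeric(n)
  for (i in seq_len(n)) {
    bp <- cand$pos[i] - 1
    m <- c_tot <- numeric(length(clones_alive))
    for (k in seq_along(clones_alive)) {
      ce <- cnv_by_clone[[k]]
      hit <- ce$chrom == cand$chrom[i] & ce$start <= bp & ce$end > bp
      c_tot[k] <- max(0, 2 + sum(ce$copies_delta[hit]))
      hap_hit <- hit & ce$haplotype == cand$haplotype[i] &
        ce$event_id > cand$event_id[i]
      m[k] <- if (cand$zygosity[i] == "homozygous") {
        c_tot[k]
      } else if (cand$origin[i] == "germline" ||
                 cand$owner[i] %in% lineages[[k]]) {
        min(max(0, 1 + sum(ce$copies_delta[hap_hit])), c_tot[k])
      } else 0
    }
    denom <- sum(fr * c_tot)
    af_true[i] <- if (denom > 0) sum(fr * m) / denom else 0
  }
  keep <- af_true > 0
  cand <- cand[keep, , drop = FALSE]; af_true <- af_true[keep]
  if (nrow(cand) == 0) return(empty_variant_calls())

  dp <- stats::rpois(nrow(cand), depth)
  alt_reads <- stats::rbinom(nrow(cand), dp, af_true)
  af <- ifelse(dp > 0, alt_reads / dp, 0)
  keep <- dp > 0 & alt_reads > 0 & af >= af_floor
  out <- data.frame(
    sample_id = paste0(history$line_id, "_P", passage),
    line_id = history$line_id, gene = cand$gene, chrom = cand$chrom,
    pos = cand$pos, ref = cand$ref, alt = cand$alt, af = af,
    alt_reads = alt_reads, depth = dp,
    pop_freq_gnomad = cand$pop_freq_gnomad,
    pop_freq_1000g = cand$pop_freq_1000g,
    pop_freq_esp6500 = cand$pop_freq_esp6500,
    effect = cand$effect, deleterious = cand$deleterious,
    cosmic = cand$cosmic, hotspot = cand$hotspot, recurrence_freq = 0,
    true_origin = cand$origin, true_event_passage = cand$event_passage,
    true_af = af_true)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_variant_calls <- function() {
  data.frame(sample_id = character(), line_id = character(), gene = character(),
             chrom = character(), pos = numeric(), ref = character(),
             alt = character(), af = numeric(), alt_reads = integer(),
             depth = integer(), pop_freq_gnomad = numeric(),
             pop_freq_1000g = numeric(), pop_freq_esp6500 = numeric(),
             effect = character(), deleterious = logical(), cosmic = character(),
             hotspot = logical(), recurrence_freq = numeric(),
             true_origin = character(), true_event_passage = numeric(),
             true_af = numeric(), stringsAsFactors = FALSE)
}

#' Simulate a cohort of lines and its sample manifest
#'
#' @param n_lines number of independent lines
#' @param params shared [sim_params()]; the per-line stream is derived from
#'   `params$seed` and the line id
#' @param line_prefix line ids are `sprintf("%s%02d", line_prefix, i)`
#' @return list(histories, manifest): manifest has one row per
#'   (line, sampled passage) with sample_id/line_id/passage/rank.
#' @export
simulate_cohort <- function(n_lines = 10, params = sim_params(),
                            line_prefix = "SIMLINE") {
  ids <- sprintf("%s%02d", line_prefix, seq_len(n_lines))
  histories <- lapply(ids, function(id) simulate_line(params, line_id = id))
  names(histories) <- ids
  manifest <- do.call(rbind, lapply(histories, function(h) {
    sp <- h$params$sample_passages
    data.frame(sample_id = paste0(h$line_id, "_P", sp), line_id = h$line_id,
               passage = sp, rank = seq_along(sp))
  }))
  rownames(manifest) <- NULL
  list(histories = histories, manifest = validate_manifest(manifest))
}

#' Minimal hand-built culture history for controlled renders
#'
#' Builds a two-clone history (wild type + one mutant clone at a fixed
#' fraction) carrying the given CNV events, plus optional germline variants.
#' Used to inject known copy-number profiles into the coverage and variant
#' renderers.
#'
#' @param cnvs data.frame(chrom, start, end, copies_delta) or NULL;
#'   optionally a `haplotype` column (default 1)
#' @param snvs optional data.frame(gene, chrom, pos, ref, alt) of somatic
#'   SNVs private to the mutant clone, acquired before its CNVs;
#'   optionally a `haplotype` column (default 1)
#' @param fraction mutant-clone population fraction at the final passage
#' @param germline optional germline table as in `culture_history$germline`
#' @param genome genome dictionary
#' @param line_id line identifier
#' @param panel panel gene table
#' @return a `culture_history` with passages 0 and 1; the mutant clone holds
#'   `fraction` of the culture at passage 1.
#' @export
synthetic_takeover_history <- function(cnvs = NULL, snvs = NULL, fraction = 1,
                                       germline = NULL,
                                       genome = hg19_genome(),
                                       line_id = "SYN1",
                                       panel = default_panel(genome = genome)) {
  stopifnot(fraction >= 0, fraction <= 1)
  events <- empty_events()
  k <- 0
  if (!is.null(snvs) && nrow(snvs)) {           # SNVs first: pre-date the CNVs
    if (is.null(snvs$haplotype)) snvs$haplotype <- 1L
    for (i in seq_len(nrow(snvs))) {
      k <- k + 1
      events[k, c("event_id", "clone", "passage")] <- list(k, 2L, 1L)
      events$kind[k] <- "snv"
      events$chrom[k] <- snvs$chrom[i]; events$gene[k] <- snvs$gene[i]
      events$pos[k] <- snvs$pos[i]
      events$ref[k] <- snvs$ref[i]; events$alt[k] <- snvs$alt[i]
      events$haplotype[k] <- as.integer(snvs$haplotype[i])
      events$effect[k] <- "missense"; events$deleterious[k] <- FALSE
      events$cosmic[k] <- "none"; events$hotspot[k] <- FALSE
      events$s[k] <- 0
    }
  }
  if (!is.null(cnvs) && nrow(cnvs)) {
    if (is.null(cnvs$haplotype)) cnvs$haplotype <- 1L
    for (i in seq_len(nrow(cnvs))) {
      k <- k + 1
      events[k, c("event_id", "clone", "passage")] <- list(k, 2L, 1L)
      events$kind[k] <- if (cnvs$copies_delta[i] > 0) "cnv_gain" else "cnv_loss"
      events$chrom[k] <- cnvs$chrom[i]
      events$start[k] <- cnvs$start[i]; events$end[k] <- cnvs$end[i]
      events$copies_delta[k] <- as.integer(cnvs$copies_delta[i])
      events$haplotype[k] <- as.integer(cnvs$haplotype[i])
      events$s[k] <- 0
    }
  }
  fractions <- matrix(c(1, 0, 1 - fraction, fraction), nrow = 2, byrow = TRUE,
                      dimnames = list(c("0", "1"), c("1", "2")))
  params <- sim_params(n_passages = 1, sample_passages = 1, genome = genome,
                       panel = panel)
  structure(list(line_id = line_id, params = params,
                 clones = data.frame(clone = 1:2, parent = c(NA, 1L),
                                     birth_passage = c(0L, 1L)),
                 events = events, fractions = fractions, germline = germline),
            class = "culture_history")
}
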