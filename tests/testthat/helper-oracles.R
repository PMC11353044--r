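# Independent oracles and fixture builders shared across the suite.

# Two-sided Fisher p by direct enumeration with choose() ratios -- a second,
# independent route to the hypergeometric sum (no log-space, no dhyper).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force segmentation oracle: O(n^2) enumeration of maximal qualifying
# runs on a single chromosome's z vector.
segment_brute_oracle <- function(z, min_bins = 10, z_thresh = 3,
                                 merge_gap = 2) {
  out <- list()
  for (dir in c("gain", "loss")) {
    qual <- if (dir == "gain") z > z_thresh else z < -z_thresh
    anti <- if (dir == "gain") z < -z_thresh else z > z_thresh
    idx <- which(qual)
    if (!length(idx)) next
    linked <- function(i, j) {             # can bins i < j sit in one run?
      gap <- j - i - 1
      gap <= merge_gap && (gap == 0 || !any(anti[(i + 1):(j - 1)]))
    }
    # chains of qualifying bins under the link relation
    used <- rep(FALSE, length(idx))
    for (s in seq_along(idx)) {
      if (used[s]) next
      chain <- s
      repeat {
        last <- chain[length(chain)]
        nxt <- which(!used & seq_along(idx) > last &
                       vapply(seq_along(idx), function(t)
                         t > last && linked(idx[last], idx[t]), NA))
        if (!length(nxt)) break
        chain <- c(chain, nxt[1])
      }
      used[chain] <- TRUE
      first <- idx[chain[1]]; lastb <- idx[chain[length(chain)]]
      if (lastb - first + 1 >= min_bins)
        out[[length(out) + 1]] <- list(first = first, last = lastb, dir = dir)
    }
  }
  out
}

# Maximum-likelihood slope via generic optimizer (independent of glm's IRLS)
glm_ml_oracle <- function(x, y, family = c("poisson", "binomial")) {
  family <- match.arg(family)
  if (family == "poisson") {
    nll <- function(b) sum(exp(b[1] + b[2] * x)) - sum(y * (b[1] + b[2] * x))
    grd <- function(b) {
      r <- exp(b[1] + b[2] * x) - y
      c(sum(r), sum(r * x))
    }
  } else {
    nll <- function(b) sum(log1p(exp(b[1] + b[2] * x))) -
      sum(y * (b[1] + b[2] * x))
    grd <- function(b) {
      r <- stats::plogis(b[1] + b[2] * x) - y
      c(sum(r), sum(r * x))
    }
  }
  fit <- stats::optim(c(0, 0), nll, gr = grd, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  fit <- stats::optim(fit$par, nll, gr = grd, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  fit$par[2]
}

# Fabricate a complete BinScores table on one chromosome from a z vector
# (fold change and log2 ratio consistent with a nominal sigma).
make_scores <- function(z, sigma = 0.1, chrom = "chr1", bin_size = 50000) {
  n <- length(z)
  fc <- 1 + z * sigma
  df <- data.frame(chrom = chrom, start = (0:(n - 1)) * bin_size,
                   end = (1:n) * bin_size, gc = 0.45, count = round(100 * fc),
                   blacklisted = FALSE, corrected = fc, fold_change = fc,
                   log2ratio = log2(pmax(fc, 0.005)), z = z)
  attr(df, "sigma") <- sigma
  df
}

# One annotated variant record with innocuous defaults; override per test
mk_var <- function(gene = "PANG001", af = 0.5, alt_reads = round(af * 1500),
                   depth = 1500, pop = 0, hotspot = FALSE, recur = 0,
                   pos = 1000, chrom = "chr1", effect = "missense",
                   deleterious = FALSE, cosmic = "none") {
  data.frame(sample_id = "S1", line_id = "L1", gene = gene, chrom = chrom,
             pos = pos, ref = "A", alt = "G", af = af, alt_reads = alt_reads,
             depth = depth, pop_freq_gnomad = pop, pop_freq_1000g = pop,
             pop_freq_esp6500 = pop, effect = effect,
             deleterious = deleterious, cosmic = cosmic, hotspot = hotspot,
             recurrence_freq = recur)
}

# The ten-record retention-cascade fixture: exactly four survive; R1 and R2
# remove two each (one record fails both), R3/R4/R5 one each.
filter_fixture <- function() {
  rbind(
    mk_var(pop = 0.05, pos = 1),                                   # R1
    mk_var(pop = 0.02, af = 0.02, alt_reads = 30, pos = 2),        # R1+R2
    mk_var(af = 0.02, alt_reads = 30, pos = 3),                    # R2
    mk_var(recur = 5e-4, pos = 4),                                 # R3
    mk_var(af = 0.0133, alt_reads = 20, hotspot = TRUE, pos = 5),  # R4
    mk_var(gene = "CDC27", pos = 6),                               # R5
    mk_var(pos = 7), mk_var(af = 0.45, pos = 8),
    mk_var(af = 0.031, alt_reads = 47, pos = 9),
    mk_var(hotspot = TRUE, af = 0.02, alt_reads = 30, pos = 10))   # kept: hotspot
}

# Toy-genome analogues for fast end-to-end runs
toy_catalog <- function() {
  data.frame(label = c("chr1-driver/GENA", "chr2-driver/GENB"),
             chrom = c("chr1", "chr2"),
             region_start = c(10e6, 0), region_end = c(45e6, 30e6),
             driver_gene = c("GENA", "GENB"),
             driver_start = c(20e6, 5e6), driver_end = c(20.06e6, 5.06e6),
             direction = c("gain", "loss"), sim_weight = c(0.7, 0.3))
}

toy_sim_params <- function(...) {
  g <- toy_genome()
  sim_params(genome = g, catalog = toy_catalog(),
             panel = default_panel(n_genes = 80, genome = g), ...)
}
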