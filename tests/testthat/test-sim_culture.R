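test_that("a mutation-free culture stays clonally pure wild type", {
  p <- toy_sim_params(p_cnv_recurrent = 0, p_cnv_rare = 0, p_snv = 0,
                      n_passages = 20, sample_passages = c(5, 20),
                      n_germline = 5, seed = 3)
  h <- simulate_line(p, "WT")
  expect_equal(nrow(h$clones), 1)
  expect_equal(nrow(h$events), 0)
  expect_true(all(h$fractions[, 1] == 1))
})

test_that("simulation is bit-reproducible from the seed and conserves mass", {
  p <- toy_sim_params(seed = 99, n_passages = 25, sample_passages = c(10, 25))
  h1 <- simulate_line(p, "L7")
  h2 <- simulate_line(p, "L7")
  expect_identical(h1, h2)
  h3 <- simulate_line(p, "L8")
  expect_false(identical(h1$fractions, h3$fractions))
  expect_true(all(abs(rowSums(h1$fractions) - 1) < 1e-9))
  # a clone's events always include its parent's (lineage superset)
  for (cl in h1$clones$clone) {
    par <- h1$clones$parent[cl]
    if (is.na(par)) next
    expect_true(all(stemdrift:::clone_events(h1, par)$event_id %in%
                      stemdrift:::clone_events(h1, cl)$event_id))
  }
})

test_that("driver clones sweep: mean trajectory rises and takeover completes", {
  # once a driver-CNV clone exists, its lineage fraction should grow in
  # expectation; pooled over replicate seeds the mean trajectory (aligned at
  # driver birth) must be non-decreasing, and the median final fraction
  # after 50 passages must exceed 0.9
  n_rep <- 60
  finals <- numeric(0)
  mean_traj <- matrix(NA_real_, nrow = n_rep, ncol = 31)
  for (r in seq_len(n_rep)) {
    p <- toy_sim_params(seed = 5000 + r, p_snv = 0, p_cnv_rare = 0,
                        p_cnv_recurrent = 0.3, s_recurrent = 0.5,
                        n_passages = 50, sample_passages = 50, n_germline = 0)
    h <- simulate_line(p, "DRV")
    drv_events <- h$events$clone[h$events$kind %in% c("cnv_gain", "cnv_loss") &
                                   !is.na(h$events$label)]
    if (!length(drv_events)) next
    carriers <- h$clones$clone[vapply(h$clones$clone, function(cl)
      any(drv_events %in% stemdrift:::clone_lineage(h, cl)), NA)]
    traj <- rowSums(h$fractions[, as.character(carriers), drop = FALSE])
    birth <- which(traj > 0)[1] - 1   # passage of first driver cells
    seg <- traj[(birth + 1):min(birth + 31, length(traj))]
    mean_traj[r, seq_along(seg)] <- seg
    finals[length(finals) + 1] <- traj[length(traj)]
  }
  expect_gt(length(finals), 40)
  expect_gt(stats::median(finals), 0.9)
  m <- colMeans(mean_traj, na.rm = TRUE)
  expect_true(all(diff(m) > -0.02))
})

test_that("de novo SNV burden grows with sample rank under constant rates", {
  counts <- data.frame(rank = integer(), n = integer())
  for (r in 1:60) {
    p <- toy_sim_params(seed = 7000 + r)
    h <- simulate_line(p, "B")
    for (k in seq_along(p$sample_passages)) {
      v <- render_variants(h, p$sample_passages[k], seed = 1)
      n <- sum(v$true_origin == "de_novo" & v$af >= 0.03 & v$alt_reads >= 25)
      counts <- rbind(counts, data.frame(rank = k, n = n))
    }
  }
  fit <- poisson_load_regression(counts$rank, counts$n)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p, 0.05)
})

test_that("coverage render hits its analytic dosage ratios", {
  g <- toy_genome()
  # deterministic limit: wild type, flat GC bias -> every count = base exactly
  h0 <- synthetic_takeover_history(genome = g, fraction = 0,
                                   panel = default_panel(50, g))
  cov0 <- render_coverage(h0, 1, dispersion = 0, gc_amp = 0, base_count = 100)
  expect_true(all(cov0$count == 100))
  # +1 gain at full clonality: mean count ratio 1.5; at half clonality 1.25
  gain <- data.frame(chrom = "chr1", start = 5e6, end = 10e6, copies_delta = 1)
  for (cs in list(c(1, 1.5), c(0.5, 1.25))) {
    h <- synthetic_takeover_history(cnvs = gain, fraction = cs[1], genome = g,
                                    panel = default_panel(50, g))
    cov <- render_coverage(h, 1, gc_amp = 0, seed = 42)
    inside <- cov$chrom == "chr1" & cov$start >= 5e6 & cov$end <= 10e6
    ratio <- mean(cov$count[inside]) / mean(cov$count[!inside])
    expect_equal(ratio, cs[2], tolerance = 0.02)
  }
  expect_error(render_coverage(h0, 1, gc = c(0.4, 0.5)), "bin grid|match")
})

test_that("variant render reproduces the expected-AF model with binomial noise", {
  g <- toy_genome()
  pan <- default_panel(50, g)
  gl <- data.frame(gene = pan$gene[1], chrom = pan$chrom[1],
                   pos = pan$start[1] + 100, ref = "A", alt = "G",
                   haplotype = 1L, zygosity = "heterozygous",
                   effect = "missense", deleterious = FALSE, cosmic = "none",
                   hotspot = FALSE, pop_freq_gnomad = 0, pop_freq_1000g = 0,
                   pop_freq_esp6500 = 0)
  # diploid heterozygote at 1500x: mean AF over draws within [0.49, 0.51]
  h <- synthetic_takeover_history(germline = gl, fraction = 1, genome = g,
                                  panel = pan)
  afs <- vapply(1:500, function(s) render_variants(h, 1, seed = s)$af, 0)
  expect_true(mean(afs) > 0.49 && mean(afs) < 0.51)

  # duplication of the variant haplotype in a full-takeover clone: AF -> 2/3
  dup <- data.frame(chrom = gl$chrom, start = gl$pos - 1000,
                    end = gl$pos + 1000, copies_delta = 1, haplotype = 1L)
  h2 <- synthetic_takeover_history(cnvs = dup, germline = gl, fraction = 1,
                                   genome = g, panel = pan)
  v2 <- render_variants(h2, 1, seed = 8)
  expect_equal(v2$true_af, 2 / 3)
  afs2 <- vapply(1:200, function(s) render_variants(h2, 1, seed = s)$af, 0)
  expect_equal(mean(afs2), 2 / 3, tolerance = 0.01)

  # de novo variant private to an extinct clone is never observed
  sn <- data.frame(gene = pan$gene[2], chrom = pan$chrom[2],
                   pos = pan$start[2] + 10, ref = "C", alt = "T")
  h3 <- synthetic_takeover_history(snvs = sn, fraction = 0, genome = g,
                                   panel = pan)
  expect_equal(nrow(render_variants(h3, 1, seed = 1)), 0)

  # renders are reproducible from the seed
  expect_identical(render_variants(h2, 1, seed = 4),
                   render_variants(h2, 1, seed = 4))
})

test_that("cohort simulation yields a valid manifest and per-line truth", {
  co <- simulate_cohort(3, toy_sim_params(seed = 21, n_germline = 6))
  expect_length(co$histories, 3)
  expect_equal(nrow(co$manifest), 9)
  expect_silent(validate_manifest(co$manifest))
  expect_true(all(vapply(co$histories, function(h)
    all(abs(rowSums(h$fractions) - 1) < 1e-9), NA)))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(p_snv = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(bottleneck_size = 5), ">= 10")
  expect_error(sim_params(snv_rate_multiplier_given_driver = 0.5), ">= 1")
  expect_error(sim_params(sample_passages = 100, n_passages = 50), "beyond")
  expect_error(render_variants(simulate_line(toy_sim_params(seed = 1), "X"),
                               passage = 999), "not recorded")
})
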