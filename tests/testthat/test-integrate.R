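test_that("the expected-AF model reproduces its analytic anchor points", {
  # balanced heterozygote: 0.5 at any clonal fraction
  for (f in c(0, 0.3, 0.7, 1)) expect_equal(expected_af(1, 2, 1, f), 0.5)
  # germline het on a duplicated haplotype at full takeover: 2/3
  expect_equal(expected_af(2, 3, 1, 1), 2 / 3)
  # de novo single copy in a triplicated locus at full clonality: 1/3
  expect_equal(expected_af(1, 3, 0, 1), 1 / 3)
  # sub-clonal de novo heterozygote: half the clone fraction
  expect_equal(expected_af(1, 2, 0, 0.5), 0.25)
  expect_error(expected_af(1, 0, 0, 1), ">= 1")
  expect_error(expected_af(3, 2, 0, 1), "\\[0, c\\]")
  expect_error(expected_af(1, 2, 3, 1), "m0")
  expect_error(expected_af(1, 2, 0, 1.4), "\\[0, 1\\]")
})

test_that("expected AF is monotone in clonal fraction with fixed endpoints", {
  set.seed(9)
  for (i in 1:40) {
    c <- sample(1:5, 1); m <- sample(0:c, 1); m0 <- sample(0:2, 1)
    expect_equal(expected_af(m, c, m0, 0), m0 / 2)
    expect_equal(expected_af(m, c, m0, 1), m / c)
    fs <- seq(0, 1, 0.05)
    vals <- vapply(fs, function(f) expected_af(m, c, m0, f), 0)
    if (m / c > m0 / 2) expect_true(all(diff(vals) >= -1e-12))
    else if (m / c < m0 / 2) expect_true(all(diff(vals) <= 1e-12))
    else expect_true(all(abs(vals - m0 / 2) < 1e-12))
  }
})

test_that("AF matching explains the canonical copy-number cases", {
  # PMS2-like: observed 0.63 on a trisomic locus -> two of three copies
  fit <- match_af(0.63, 3)
  expect_true(fit$cnv_explained)
  expect_equal(fit$best_m, 2)
  # trivial diploid het
  fit2 <- match_af(0.5, 2)
  expect_true(fit2$cnv_explained)
  expect_equal(fit2$abs_error, 0)
  # DOCK8-like: observed 0.25 on a trisomic locus, germline excluded:
  # single mutant copy at sub-clonal fraction
  fit3 <- match_af(0.25, 3, m0_values = 0)
  expect_true(fit3$cnv_explained)
  expect_equal(fit3$best_m, 1)
  expect_true(fit3$best_f >= 0.6 && fit3$best_f <= 1)
  # exhaustive grid check: the returned fit is the global best
  brute <- expand.grid(m = 0:3, m0 = 0, f = seq(0.1, 1, 0.1))
  errs <- abs(0.25 - mapply(function(m, m0, f) expected_af(m, 3, m0, f),
                            brute$m, brute$m0, brute$f))
  expect_equal(fit3$abs_error, min(errs), tolerance = 1e-12)
})

test_that("the karyotype-by-carriage table reproduces the cohort layout", {
  # 13 karyotypically normal samples of which 4 carry a de novo SNV;
  # 20 abnormal of which 17 carry one
  samples <- data.frame(
    karyotype = c(rep("normal", 13), rep("abnormal", 20)),
    has_de_novo = c(rep(TRUE, 4), rep(FALSE, 9), rep(TRUE, 17), rep(FALSE, 3)))
  tab <- association_table(samples)
  expect_equal(unname(tab), matrix(c(4L, 17L, 9L, 3L), nrow = 2))
  expect_equal(sum(tab), 33)
  expect_equal(round(fisher_exact_2x2(tab), 4), 0.0028)
  # permutation invariance
  perm <- samples[sample(nrow(samples)), ]
  expect_equal(association_table(perm), tab)
  # degenerate: nothing called, nothing carried -> Fisher p = 1
  degen <- association_table(data.frame(karyotype = rep("normal", 6),
                                        has_de_novo = FALSE))
  expect_equal(unname(degen), matrix(c(0L, 0L, 6L, 0L), nrow = 2))
  expect_equal(fisher_exact_2x2(degen), 1)
  expect_error(association_table(data.frame(karyotype = "odd",
                                            has_de_novo = TRUE)), "normal")
  expect_error(association_table(data.frame(karyotype = "normal",
                                            has_de_novo = NA)), "unlabeled|known")
})

test_that("a driver-linked mutator phenotype is detectable as association", {
  # with the de novo SNV rate multiplied in driver clones, the Fisher test
  # on karyotype x carriage should reject independence in most cohorts
  n_sig <- 0; n_coh <- 12
  for (r in seq_len(n_coh)) {
    p <- toy_sim_params(seed = 31000 + r,
                        snv_rate_multiplier_given_driver = 5)
    co <- simulate_cohort(10, p)
    rows <- lapply(co$histories, function(h) {
      vapply(p$sample_passages, function(pp) {
        v <- render_variants(h, pp, seed = 3)
        drv <- h$events[h$events$kind != "snv" & !is.na(h$events$label), ]
        fr <- h$fractions[as.character(pp), ]
        abn <- FALSE
        if (nrow(drv)) {
          alive <- as.integer(names(fr[fr > 0]))
          carr <- sum(fr[as.character(alive[vapply(alive, function(cl)
            any(drv$clone %in% stemdrift:::clone_lineage(h, cl)), NA)])])
          abn <- carr > 0.6     # detectable by shallow coverage
        }
        dn <- sum(v$true_origin == "de_novo" & v$af >= 0.03 & v$alt_reads >= 25)
        abn * 2 + (dn > 0)
      }, 0)
    })
    code <- unlist(rows)
    tab <- matrix(c(sum(code == 1), sum(code == 3),
                    sum(code == 0), sum(code == 2)), nrow = 2)
    if (sum(tab) > 0 && fisher_exact_2x2(tab) < 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / n_coh, 0.8)
})

test_that("integration joins variants to overlapping segments", {
  v1 <- mk_var(gene = "G1", chrom = "chr7", pos = 5e6, af = 0.63,
               alt_reads = 945)
  cl <- classify_line(list(v1, v1), line_id = "L")
  segs <- data.frame(chrom = "chr7", start = 0, end = 60e6,
                     direction = "gain", mean_log2ratio = log2(1.5),
                     n_bins = 1200, size_mb = 60,
                     recurrent_label = NA_character_)
  out <- integrate_line(cl, segments_by_rank = list(segs, segs))
  expect_equal(out$copy_number, 3L)
  expect_true(out$cnv_explained)
  expect_equal(out$best_m, 2)
  # no overlap: diploid expectation
  out2 <- integrate_line(cl, segments_by_rank = NULL)
  expect_equal(out2$copy_number, 2L)
  expect_true(out2$cnv_explained)   # 0.63 vs het 0.5 at f on the grid
})
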