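test_that("GC correction recovers a flat profile from pure GC bias", {
  # gc restricted to 10 distinct values: the decile-median fit must equal
  # the generating curve exactly at those values, so correction is exact
  gcs <- seq(0.30, 0.57, length.out = 10)
  gc <- rep(gcs, each = 100)
  bias <- gc_bias_curve(gc, amp = 0.2)
  cov <- data.frame(chrom = "chr1", start = (0:999) * 5e4,
                    end = (1:1000) * 5e4, gc = gc, count = 100 * bias)
  cor <- gc_correct(cov)
  expect_true(all(abs(cor$corrected - 1) < 1e-6))
})

test_that("GC correction with constant GC falls back to global scaling", {
  cov <- data.frame(chrom = "chr1", start = (0:999) * 5e4,
                    end = (1:1000) * 5e4, gc = 0.45, count = 200)
  expect_warning(cor <- gc_correct(cov), "GC strata")
  expect_true(all(cor$corrected == 1))
  cov0 <- cov; cov0$count <- 0
  expect_error(gc_correct(cov0), "all-zero")
  expect_error(gc_correct(cov[1:50, ]), "at least")
})

test_that("fold change, log2 ratio and z follow their closed forms", {
  set.seed(41)
  fc <- c(1 + stats::rnorm(600, 0, 0.05), 1.5, 0.5)
  sc <- make_scores(rep(0, 602), sigma = 0.1)
  sc$corrected <- fc; sc$count <- round(100 * fc)
  out <- compute_scores(sc[, c("chrom", "start", "end", "gc", "count",
                               "blacklisted", "corrected")])
  expect_equal(out$fold_change, fc)
  # closed forms: log2 of fold change (1.5 -> 0.585, 0.5 -> -1) and
  # (fc - 1) / MAD-sigma
  expect_equal(out$log2ratio[601], log2(1.5), tolerance = 1e-12)
  expect_equal(log2(1.5), 0.585, tolerance = 1e-3)
  expect_equal(out$log2ratio[602], -1)
  sig <- stats::mad(fc)
  expect_equal(attr(out, "sigma"), sig)
  expect_equal(out$z, (fc - 1) / sig)
  # pseudocount floors the log2 ratio for empty bins
  sc0 <- sc; sc0$corrected[1] <- 0
  out0 <- compute_scores(sc0)
  expect_equal(out0$log2ratio[1], log2(0.5 / stats::median(sc0$count)))
  flat <- sc; flat$corrected <- 1
  expect_error(compute_scores(flat), "zero robust scale")
})

test_that("a diploid render keeps the |z|>3 tail below one percent", {
  h <- synthetic_takeover_history(genome = toy_genome(), fraction = 0,
                                  panel = default_panel(50, toy_genome()))
  cov <- render_coverage(h, 1, seed = 31)
  sc <- compute_scores(gc_correct(cov))
  expect_lt(mean(abs(sc$z) > 3), 0.01)
})

test_that("segmentation recovers a noiseless injected gain exactly", {
  z <- rep(0, 200)
  z[61:100] <- 5                         # 40 contiguous bins, 2 Mb
  sc <- make_scores(z)
  sc$fold_change[61:100] <- 1.5
  sc$log2ratio <- log2(sc$fold_change)
  segs <- segment_cnvs(sc)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$direction, "gain")
  expect_equal(segs$start, 60 * 5e4)
  expect_equal(segs$end, 100 * 5e4)
  expect_equal(segs$n_bins, 40)
  expect_equal(segs$size_mb, 2)
  expect_equal(segs$mean_log2ratio, log2(1.5), tolerance = 1e-9)
  expect_equal(nrow(segment_cnvs(make_scores(rep(0, 200)))), 0)
})

test_that("segmentation matches the brute-force run enumeration on random inputs", {
  set.seed(77)
  for (rep in 1:25) {
    z <- stats::rnorm(200)
    hot <- sample(180, 1); z[hot:(hot + sample(5:30, 1))] <-
      stats::rnorm(1, ifelse(stats::runif(1) < 0.5, 6, -6), 0.5)
    sc <- make_scores(z)
    segs <- segment_cnvs(sc, min_bins = 8, z_thresh = 3, merge_gap = 2)
    oracle <- segment_brute_oracle(z, min_bins = 8, z_thresh = 3,
                                   merge_gap = 2)
    expect_equal(nrow(segs), length(oracle))
    if (length(oracle)) {
      oracle <- oracle[order(vapply(oracle, `[[`, 0, "first"))]
      for (k in seq_along(oracle)) {
        expect_equal(segs$start[k], (oracle[[k]]$first - 1) * 5e4)
        expect_equal(segs$end[k], oracle[[k]]$last * 5e4)
        expect_equal(segs$direction[k], oracle[[k]]$dir)
      }
    }
  }
})

test_that("segmentation ignores blacklisted bins and is monotone in z_thresh", {
  z <- rep(0, 150); z[41:60] <- 4.2
  sc <- make_scores(z)
  base <- segment_cnvs(sc, min_bins = 10)
  # appending blacklisted bins changes nothing
  extra <- make_scores(rep(8, 20), chrom = "chr1")
  extra$start <- extra$start + 150 * 5e4; extra$end <- extra$end + 150 * 5e4
  extra$blacklisted <- TRUE
  withbl <- rbind(sc, extra)
  expect_equal(segment_cnvs(withbl, min_bins = 10), base)
  # lowering the threshold never removes a called span
  lower <- segment_cnvs(sc, min_bins = 10, z_thresh = 2)
  for (i in seq_len(nrow(base))) {
    cover <- any(lower$chrom == base$chrom[i] & lower$start <= base$start[i] &
                   lower$end >= base$end[i] & lower$direction == base$direction[i])
    expect_true(cover)
  }
})

test_that("recurrent annotation keys on the driver locus with direction", {
  segs <- data.frame(
    chrom = c("chr20", "chr1", "chr9", "chr20"),
    start = c(29370000, 204000000, 100000, 29370000),
    end = c(30445000, 249250621, 40000000, 30445000),
    direction = c("gain", "gain", "gain", "loss"),
    mean_log2ratio = c(0.58, 0.58, 0.58, -1), n_bins = 20,
    size_mb = 1, recurrent_label = NA_character_)
  ann <- annotate_recurrence(segs)
  expect_equal(ann$recurrent_label[1], "20q11.21/BCL2L1")
  expect_equal(ann$recurrent_label[2], "1q/MDM4")
  expect_true(is.na(ann$recurrent_label[3]))   # 9p-like gain: rare CNV
  expect_true(is.na(ann$recurrent_label[4]))   # wrong direction: no label
})

test_that("karyotype status and the end-to-end caller agree with truth", {
  expect_equal(karyotype_status(stemdrift:::empty_segments()), "normal")
  expect_equal(karyotype_status(data.frame(chrom = "chr20")), "abnormal")
  # clonal 20q-like gain through the full caller on a real render
  gain <- data.frame(chrom = "chr20", start = 29350000, end = 53900000,
                     copies_delta = 1)
  h <- synthetic_takeover_history(cnvs = gain, fraction = 1)
  segs <- call_cnvs(render_coverage(h, 1, seed = 12))
  expect_equal(karyotype_status(segs), "abnormal")
  expect_equal(segs$recurrent_label[1], "20q11.21/BCL2L1")
  expect_lt(abs(segs$start[1] - 29350000), 1e5)
  expect_lt(abs(segs$end[1] - 53900000), 1e5)
})
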