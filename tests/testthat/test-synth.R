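test_that("site placement matches expectation and respects the centromere", {
  g <- genome_def(c("c1", "c2"), c(50e6, 30e6), c(25e6, NA))
  sites <- place_tag_sites(g, site_density = 100,
                           centromere_depletion = 0, seed = 3)
  n1 <- sum(sites$chrom == "c1")
  # Poisson expectation 5000, allow 5 sd
  expect_lt(abs(n1 - 5000), 5 * sqrt(5000))
  expect_true(all(sites$pos >= 0))
  expect_true(all(sites$pos[sites$chrom == "c2"] < 30e6))
  # full depletion empties the centromeric window
  s2 <- place_tag_sites(g, site_density = 100, centromere_depletion = 1,
                        centromere_radius_bp = 5e6, seed = 3)
  win <- s2$chrom == "c1" & abs(s2$pos - 25e6) <= 5e6
  expect_equal(sum(win), 0)
  # partial depletion thins the window to ~(1 - d) of flanking density
  s3 <- place_tag_sites(g, site_density = 400, centromere_depletion = 0.8,
                        centromere_radius_bp = 5e6, seed = 4)
  n_win <- sum(s3$chrom == "c1" & abs(s3$pos - 25e6) <= 5e6)
  expect_lt(abs(n_win - 0.2 * 400 * 10), 5 * sqrt(0.2 * 400 * 10))
  # determinism
  expect_identical(place_tag_sites(g, 100, 0.8, 5e6, seed = 7),
                   place_tag_sites(g, 100, 0.8, 5e6, seed = 7))
})

test_that("aberration specs validate bounds and overlaps", {
  g <- genome_def("c1", 50e6)
  expect_error(aberration_spec("s", -1), ">= 0")
  expect_error(aberration_spec("s", regions = data.frame(
    chrom = "c9", start = 0, end = 1e6, multiplier = 0), genome = g),
    "not in genome")
  expect_error(aberration_spec("s", regions = data.frame(
    chrom = "c1", start = 0, end = 60e6, multiplier = 0), genome = g),
    "bounds")
  expect_error(aberration_spec("s", regions = data.frame(
    chrom = c("c1", "c1"), start = c(0, 5e6), end = c(10e6, 15e6),
    multiplier = c(0, 2)), genome = g), "overlap")
  # NA start/end expand to the whole chromosome
  sp <- aberration_spec("s", regions = data.frame(
    chrom = "c1", start = NA, end = NA, multiplier = 0.5), genome = g)
  expect_equal(sp$regions$end, 50e6)
})

test_that("simulated samples honor multipliers and calibration", {
  g <- genome_def(c("c1", "c2"), c(50e6, 50e6))
  sites <- place_tag_sites(g, site_density = 400,
                           centromere_depletion = 0, seed = 1)
  null1 <- aberration_spec("n1", regions = data.frame(
    chrom = "c1", start = NA, end = NA, multiplier = 0), genome = g)
  t0 <- simulate_sample(sites, null1, mean_tags = 1e4, seed = 2)
  expect_equal(sum(t0$records$chrom == "c1"), 0)  # multiplier 0 -> no tags
  # euploid, dispersion 0 -> total within 5 sd of mean_tags (Bernoulli var)
  eu <- aberration_spec("eu")
  te <- simulate_sample(sites, eu, mean_tags = 1e4, dispersion = 0, seed = 5)
  p <- 1e4 / nrow(sites)
  expect_lt(abs(te$n_retained - 1e4), 5 * sqrt(1e4 * (1 - p)))
  # multiplier 2 on c2 doubles the c2:c1 tag ratio (Poisson tolerance)
  tet <- aberration_spec("tet", regions = data.frame(
    chrom = "c2", start = NA, end = NA, multiplier = 2), genome = g)
  tt <- simulate_sample(sites, tet, mean_tags = 1e4, dispersion = 0, seed = 6)
  n1 <- sum(tt$records$chrom == "c1"); n2 <- sum(tt$records$chrom == "c2")
  expect_lt(abs(n2 / n1 - 2), 6 * 2 * sqrt(1 / n1 + 1 / n2))
  # determinism: identical seeds give byte-identical tag tables
  expect_identical(simulate_sample(sites, eu, 1e4, 0.5, seed = 11),
                   simulate_sample(sites, eu, 1e4, 0.5, seed = 11))
})

test_that("cohort simulation produces a consistent truth table", {
  g <- genome_def(c("c1", "c2", "c3"), c(30e6, 30e6, 30e6))
  bins <- make_bins(g, 10e6, 5e6)
  specs <- c(euploid_specs(4),
             list(aberration_spec("ab", regions = data.frame(
               chrom = c("c1", "c2"), start = NA, end = NA,
               multiplier = c(0, 2)), genome = g)))
  sim <- simulate_cohort(g, specs, bins = bins, site_density = 50,
                         mean_tags = 5e3, seed = 8)
  expect_equal(colnames(sim$truth), c(sprintf("eu%02d", 1:4), "ab"))
  expect_true(all(sim$truth[, 1:4] == 2))
  expect_true(all(sim$truth[bins$chrom == "c1", "ab"] == 0))
  expect_true(all(sim$truth[bins$chrom == "c2", "ab"] == 4))
  expect_true(all(sim$truth[bins$chrom == "c3", "ab"] == 2))
  expect_error(simulate_cohort(g, specs[c(1, 1)], bins = bins),
               "duplicate")
  # straddling bins take the length-weighted majority multiplier
  half <- list(aberration_spec("h", regions = data.frame(
    chrom = "c1", start = 0, end = 12e6, multiplier = 0), genome = g))
  tr <- suppressWarnings(
    simulate_cohort(g, c(euploid_specs(2), half), bins = bins,
                    site_density = 50, mean_tags = 5e3, seed = 8)$truth)
  hb <- bins$chrom == "c1"
  # bin [10,20): 2 Mb deleted, 8 Mb disomic -> majority disomic
  expect_equal(tr[hb, "h"][bins$start[hb] == 10e6], 2)
  # bin [5,15): 7 Mb deleted -> majority deleted
  expect_equal(tr[hb, "h"][bins$start[hb] == 5e6], 0)
})

test_that("majority-aberrant cohorts trigger the median-assumption warning", {
  g <- genome_def("c1", 30e6)
  del <- lapply(1:3, function(i) aberration_spec(
    sprintf("d%d", i), regions = data.frame(chrom = "c1", start = 0,
                                            end = 10e6, multiplier = 0),
    genome = g))
  expect_warning(
    simulate_cohort(g, c(euploid_specs(2), del),
                    bins = make_bins(g, 10e6, 5e6), site_density = 50,
                    mean_tags = 1e3, seed = 1),
    "more than half")
})

test_that("simulated SAM output exercises the ingest filter", {
  g <- genome_def(c("c1", "c2"), c(30e6, 30e6))
  sites <- place_tag_sites(g, site_density = 20, centromere_depletion = 0,
                           seed = 2)
  tt <- simulate_sample(sites, aberration_spec("s1"), mean_tags = 300,
                        dispersion = 0, seed = 3)
  p <- tempfile(fileext = ".sam")
  write_sam(tt, g, p, multimapper_rate = 0.3, seed = 4)
  back <- filter_alignments(p, g, sample_id = "s1")
  expect_equal(back$n_retained, tt$n_retained)      # XS:i records dropped
  expect_gt(back$n_raw_alignments, tt$n_retained)   # but were present
  o1 <- tt$records[order(tt$records$chrom, tt$records$pos), c("chrom", "pos")]
  o2 <- back$records[order(back$records$chrom, back$records$pos),
                     c("chrom", "pos")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("aberration specs round-trip through TSV", {
  g <- genome_def(c("c1", "c2"), c(30e6, 30e6))
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\tmultiplier",
               "eu1\t\t\t\t1",
               "ab\tc1\t\t\t0",
               "ab\tc2\t0\t10000000\t2"), p)
  specs <- read_aberration_specs(p, g)
  expect_equal(length(specs), 2)
  expect_equal(specs[[1]]$default_multiplier, 1)
  expect_equal(specs[[2]]$regions$multiplier, c(0, 2))
  expect_equal(specs[[2]]$regions$end, c(30e6, 10e6))
})

test_that("pipeline recovers simulated dosage truth across seeds", {
  # compact full-scale genome: 10 chromosomes of 300-600 Mb, 100/50 Mb bins
  g <- genome_def(paste0("c", 1:10), seq(300e6, 600e6, length.out = 10),
                  seq(120e6, 250e6, length.out = 10))
  bins <- make_bins(g)
  specs <- c(euploid_specs(17), list(
    aberration_spec("mono", regions = data.frame(
      chrom = "c3", start = NA, end = NA, multiplier = 0.5), genome = g),
    aberration_spec("tri", regions = data.frame(
      chrom = "c7", start = NA, end = NA, multiplier = 1.5), genome = g),
    aberration_spec("null", regions = data.frame(
      chrom = "c9", start = NA, end = NA, multiplier = 0), genome = g)))
  acc <- vapply(1:10, function(seed) {
    sim <- simulate_cohort(g, specs, bins = bins, site_density = 32,
                           mean_tags = 1e5, seed = seed)
    fit <- gbs_karyotype(sim$tags, g)
    ok <- fit$dosage == sim$truth
    # outside centromere-depleted windows, on unmasked bins
    cen <- g$centromere[match(fit$bins$chrom, g$chrom)]
    core <- abs((fit$bins$start + fit$bins$end) / 2 - cen) > 50e6
    mean(ok[core & !fit$norm$mask, ], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(acc >= 0.99))
})

test_that("normalized values concentrate near the dosage multiplier", {
  g <- genome_def(paste0("c", 1:5), rep(200e6, 5))
  bins <- make_bins(g, 20e6, 10e6)
  specs <- c(euploid_specs(9), list(aberration_spec("tri",
    regions = data.frame(chrom = "c5", start = NA, end = NA,
                         multiplier = 1.5), genome = g)))
  sim <- simulate_cohort(g, specs, bins = bins, site_density = 300,
                         mean_tags = 5e4, dispersion = 0.2, seed = 13)
  norm <- normalize_bin_medians(count_bins(sim$tags, bins, g))
  v <- norm$values[norm$bins$chrom == "c5", "tri"]
  # expected value is the multiplier divided by the sample's genome-wide
  # depth share (total normalization sees the extra c5 tags):
  # share = (4*1 + 1.5) / 5
  expected <- 1.5 / ((4 + 1.5) / 5)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - expected), 3 * se + 0.02)
  # and the euploid chromosomes of the same sample sit near 1/share
  u <- norm$values[norm$bins$chrom != "c5", "tri"]
  expect_lt(abs(mean(u) - 1 / ((4 + 1.5) / 5)),
            3 * sd(u) / sqrt(length(u)) + 0.02)
})
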