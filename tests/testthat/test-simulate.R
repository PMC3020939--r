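small_cfg <- function(...) {
  sim_config(n_samples = 40, plate_size = 20, n_regions = 40,
             chrom_lengths = c(chr1 = 2e7, chr2 = 2e7), ...)
}

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- simulate_truth(cfg, seed = 11)
  b <- simulate_truth(cfg, seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(a$regions, b$regions)
  expect_identical(a$probes, b$probes)
  prof <- caller_profile("c1")
  expect_identical(simulate_caller(a, prof, seed = 3),
                   simulate_caller(b, prof, seed = 3))
  c2 <- simulate_truth(cfg, seed = 12)
  expect_false(identical(a$truth, c2$truth))
})

test_that("truth structure respects the configured frequency spectrum", {
  all_single <- simulate_truth(small_cfg(frac_singleton = 1), seed = 4)
  expect_true(all(all_single$regions$n_carriers == 1))
  expect_equal(nrow(all_single$truth), nrow(all_single$regions))

  # regions never overlap and keep at least one carrier
  sim <- simulate_truth(small_cfg(frac_singleton = 0.3), seed = 5)
  expect_true(all(sim$regions$n_carriers >= 1))
  by_chrom <- split(sim$regions, sim$regions$chrom)
  for (rg in by_chrom) {
    rg <- rg[order(rg$start), ]
    if (nrow(rg) > 1) expect_true(all(rg$start[-1] >= rg$end[-nrow(rg)]))
  }
  # probe map invariant: strictly increasing positions within chromosome
  for (p in split(sim$probes$pos, sim$probes$chrom)) {
    expect_true(all(diff(p) > 0))
  }

  # binomial bound on carriers of a fixed-frequency region
  cfg_common <- sim_config(n_samples = 1000, plate_size = 100, n_regions = 12,
                           chrom_lengths = c(chr1 = 2e7), frac_singleton = 0,
                           freq_shape1 = 5e4, freq_shape2 = 5e4)  # freq = 0.5
  simc <- simulate_truth(cfg_common, seed = 6)
  expect_true(all(abs(simc$regions$n_carriers - 500) <= 3 * sqrt(250) + 10))

  expect_error(
    simulate_truth(sim_config(n_regions = 500,
                              chrom_lengths = c(chr1 = 1e6),
                              size_range = c(5e4, 5e4)), seed = 1),
    "capacity|non-overlapping"
  )
})

test_that("an identity caller reproduces the truth carriers exactly", {
  cfg <- small_cfg(size_range = c(5e4, 5e5))  # every region has probes
  sim <- simulate_truth(cfg, seed = 9)
  ident <- caller_profile("perfect", sensitivity = rep(1, 5), jitter_sd = 0,
                          flip_prob = 0, fp_per_sample = 0, dup_penalty = 1)
  calls <- simulate_caller(sim, ident, seed = 10)
  expect_equal(nrow(calls), nrow(sim$truth))
  key <- function(x) paste(x$sample_id, x$chrom, x$start, x$end)
  expect_setequal(key(calls), key(sim$truth))
  expect_identical(cn_state(calls$copy_number)[order(key(calls))],
                   sim$truth$state[order(key(sim$truth))])

  blind <- caller_profile("blind", sensitivity = rep(0, 5), fp_per_sample = 0)
  expect_equal(nrow(simulate_caller(sim, blind, seed = 10)), 0)
})

test_that("emission counts follow the binomial bound at sensitivity 0.8", {
  cfg <- sim_config(n_samples = 100, plate_size = 50, n_regions = 60,
                    chrom_lengths = c(chr1 = 4e7, chr2 = 4e7),
                    frac_singleton = 0.2, size_range = c(5e4, 5e5))
  sim <- simulate_truth(cfg, seed = 13)
  n_carriers <- nrow(sim$truth)
  expect_gte(n_carriers, 300)
  prof <- caller_profile("p8", sensitivity = rep(0.8, 5), jitter_sd = 0,
                         flip_prob = 0, fp_per_sample = 0, dup_penalty = 1)
  calls <- simulate_caller(sim, prof, seed = 14)
  expect_lte(abs(nrow(calls) - 0.8 * n_carriers),
             3 * sqrt(n_carriers * 0.8 * 0.2))
})

test_that("jittered breakpoints stay valid and inside the chromosome", {
  cfg <- small_cfg(size_range = c(2e3, 2e4))
  sim <- simulate_truth(cfg, seed = 15)
  prof <- caller_profile("wobbly", sensitivity = rep(1, 5), jitter_sd = 5000,
                         flip_prob = 0, fp_per_sample = 0, dup_penalty = 1)
  calls <- simulate_caller(sim, prof, seed = 16)
  expect_true(all(calls$start < calls$end))
  expect_true(all(calls$start >= 0))
  expect_true(all(calls$end <= cfg$chrom_lengths[calls$chrom]))
})

test_that("the frequency effect emerges when common regions skew to duplications", {
  cfg <- sim_config(
    n_samples = 100, plate_size = 50, n_regions = 300,
    chrom_lengths = c(chr1 = 8e7, chr2 = 8e7),
    frac_singleton = 0.1, freq_shape1 = 0.6, freq_shape2 = 0.6,
    size_range = c(5e4, 4e5),
    p_deletion = function(f) 1 - f
  )
  sim <- simulate_truth(cfg, seed = 17)
  prof <- caller_profile("dupblind", sensitivity = rep(0.9, 5), jitter_sd = 0,
                         flip_prob = 0, fp_per_sample = 0, dup_penalty = 0.4)
  calls <- simulate_caller(sim, prof, seed = 18)
  m <- match_reference(sim$truth, calls)
  mr <- merge_into_regions(sim$truth, cfg$n_samples)
  tab <- recovery_by_frequency_bin(m, mr$regions, mr$membership)
  expect_true(all(tab$n_ref > 0))
  expect_true(all(diff(tab$rate) < 0))
})

test_that("qPCR simulation inverts delta-delta-Ct exactly at zero noise", {
  truth_cn <- tibble::tibble(
    sample_id = sprintf("S%d", 1:4), assay_id = "A1", true_cn = c(2, 1, 3, 0)
  )
  q <- simulate_qpcr(truth_cn, noise_sd = 0, seed = 19)
  expect_equal(q$ct_target[q$sample_id == "S2"] - q$ct_target[q$sample_id == "S1"], 1)
  est <- ddct_copy_number(q)
  got <- setNames(est$copy_number, est$sample_id)
  expect_equal(got[["S1"]], 2)
  expect_equal(got[["S2"]], 1)
  expect_equal(got[["S3"]], 3)
  expect_equal(got[["S4"]], 0.25)  # zero copies floored, flagged below
  expect_true(q$floored[q$sample_id == "S4"])
  expect_error(simulate_qpcr(truth_cn, noise_sd = -0.1), "noise_sd")

  # noisy quantification stays near the true copy number on average
  many <- tibble::tibble(sample_id = sprintf("S%03d", 1:200),
                         assay_id = "A1", true_cn = 3)
  qn <- simulate_qpcr(many, noise_sd = 0.1, seed = 20)
  estn <- ddct_copy_number(qn)
  expect_lt(abs(mean(estn$copy_number[estn$sample_id != "CALIBRATOR"]) - 3), 0.1)
})

test_that("an injected plate artifact is visible to the plate scan", {
  cfg <- sim_config(n_samples = 480, plate_size = 48, n_regions = 12,
                    chrom_lengths = c(chr1 = 4e7), frac_singleton = 0,
                    freq_shape1 = 20, freq_shape2 = 30,  # freq ~ 0.4
                    size_range = c(1e5, 3e5))
  sim <- simulate_truth(cfg, seed = 21)
  target <- sim$regions$region_id[1]
  prof <- caller_profile("artifact", sensitivity = rep(0.95, 5), jitter_sd = 0,
                         flip_prob = 0, fp_per_sample = 0, dup_penalty = 1,
                         plate_artifact = list(plate = "P01", region_id = target,
                                               prob = 0.9))
  calls <- simulate_caller(sim, prof, seed = 22)
  cs <- call_carrier_status(calls, sim$regions, sim$samples)
  out <- plate_effect_scan(cs, sim$plates)
  flagged <- out$per_region$flagged[out$per_region$region_id == target]
  expect_true(flagged)
})
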