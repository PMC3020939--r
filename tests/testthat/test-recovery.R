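ref1 <- function(state = "deletion") {
  tibble::tibble(ref_id = "r1", sample_id = "S1", chrom = "chr1",
                 start = 0, end = 1000, state = state)
}
call1 <- function(start, end, cn) {
  tibble::tibble(sample_id = "S1", chrom = "chr1", start = start, end = end,
                 copy_number = cn, lod = 10, caller = "t")
}

test_that("match_reference applies the combined-span criterion with state consistency", {
  # identical deletion call: recovered under both criteria
  m <- match_reference(ref1(), call1(0, 1000, 1))
  expect_true(m$recovered_korn)
  expect_true(m$recovered_state)
  expect_equal(m$best_fraction, 1)

  # 100 bp shared of 2000 combined = 0.05 < 0.25: not recovered
  m <- match_reference(ref1(), call1(900, 2000, 1))
  expect_false(m$recovered_korn)
  expect_equal(m$best_fraction, 100 / 2000)

  # 500 of 1400 = 0.357 but wrong direction: overlap-only yes, state no
  m <- match_reference(ref1(), call1(500, 1400, 3))
  expect_true(m$recovered_korn)
  expect_false(m$recovered_state)
  expect_equal(m$best_fraction, 500 / 1400, tolerance = 1e-12)

  # normal-copy calls never participate
  m <- match_reference(ref1(), call1(0, 1000, 2))
  expect_false(m$recovered_korn)
  expect_equal(m$n_matched, 0L)

  # unknown-state references are evaluable only without the state requirement
  m <- match_reference(ref1("unknown"), call1(0, 1000, 1), require_state = TRUE)
  expect_true(is.na(m$recovered))
  m <- match_reference(ref1("unknown"), call1(0, 1000, 1), require_state = FALSE)
  expect_true(m$recovered)

  expect_error(match_reference(ref1(), call1(0, 1000, 1), threshold = 0), "threshold")
  expect_error(match_reference(ref1(), call1(0, 1000, 1), threshold = 1.2), "threshold")
})

test_that("match_reference agrees with the exhaustive per-basepair oracle", {
  withr::with_seed(101, {
    for (rep in 1:8) {
      refs <- random_truthset(30, samples = c("S1", "S2", "S3"))
      calls <- random_callset(50, samples = c("S1", "S2", "S3"))
      for (rs in c(FALSE, TRUE)) {
        got <- match_reference(refs, calls, threshold = 0.25, require_state = rs)
        want <- oracle_match(refs, calls, threshold = 0.25, require_state = rs)
        expect_identical(got$recovered, want)
      }
    }
  })
})

test_that("recovery is monotone in threshold and under state consistency", {
  withr::with_seed(55, {
    refs <- random_truthset(80, samples = c("S1", "S2"))
    calls <- random_callset(120, samples = c("S1", "S2"))
    rates <- vapply(c(0.1, 0.25, 0.5, 0.75, 1), function(th) {
      mean(match_reference(refs, calls, threshold = th)$recovered)
    }, numeric(1))
    expect_true(all(diff(rates) <= 0))
    korn <- mean(match_reference(refs, calls)$recovered)
    strict <- mean(match_reference(refs, calls, require_state = TRUE)$recovered)
    expect_lte(strict, korn)
    # the state requirement can only remove matches, per reference
    m <- match_reference(refs, calls)
    expect_true(all(!m$recovered_state | m$recovered_korn))
  })
})

test_that("probe-count bins partition references and report per-bin rates", {
  probes <- tibble::tibble(chrom = "chr1", pos = seq(0, 99999, by = 100),
                           probe_id = sprintf("p%d", 1:1000))
  # probe counts: lengths 100 -> 1, 400 -> 4, 800 -> 8, 1500 -> 15, 3000 -> 30
  refs <- tibble::tibble(
    ref_id = sprintf("r%d", 1:5), sample_id = "S1", chrom = "chr1",
    start = c(0, 10000, 20000, 30000, 40000),
    end = c(0, 10000, 20000, 30000, 40000) + c(100, 400, 800, 1500, 3000),
    state = "deletion"
  )
  matches <- tibble::tibble(ref_id = refs$ref_id,
                            recovered = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  tab <- recovery_by_probe_bin(matches, refs, probes)
  expect_equal(tab$n_ref, rep(1L, 5))
  expect_equal(tab$n_recovered, c(1L, 0L, 1L, 1L, 0L))
  expect_equal(tab$rate, c(1, 0, 1, 1, 0))
  expect_equal(sum(tab$n_ref), nrow(refs))

  # zero-probe references are excluded, not binned as single-probe
  refs0 <- dplyr::bind_rows(refs, tibble::tibble(
    ref_id = "r6", sample_id = "S1", chrom = "chr1",
    start = 50001, end = 50050, state = "deletion"
  ))
  matches0 <- dplyr::bind_rows(matches,
                               tibble::tibble(ref_id = "r6", recovered = TRUE))
  expect_message(tab0 <- recovery_by_probe_bin(matches0, refs0, probes),
                 "0 probes")
  expect_equal(sum(tab0$n_ref), 5)
  expect_equal(attr(tab0, "n_zero_probe"), 1)

  # empty bin reports NA rate
  tab1 <- recovery_by_probe_bin(matches[2, ], refs[2, ], probes)
  expect_true(is.na(tab1$rate[tab1$label == ">20"]))
  expect_equal(tab1$rate[tab1$label == "2-5"], 0)

  bad_bins <- tibble::tibble(label = c("a", "b"), lo = c(1, 5), hi = c(10, 20))
  expect_error(recovery_by_probe_bin(matches, refs, probes, bins = bad_bins),
               "overlap")
})

test_that("frequency bins inherit region frequency and use (lo, hi] edges", {
  refs <- tibble::tibble(
    ref_id = sprintf("r%d", 1:4),
    sample_id = c("S1", "S2", "S3", "S4"),
    chrom = "chr1",
    start = c(0, 0, 5000, 5000), end = c(1000, 1000, 6000, 6000),
    state = "deletion"
  )
  mr <- merge_into_regions(refs, total_samples = 10)  # freqs 0.2 and 0.2
  matches <- tibble::tibble(ref_id = refs$ref_id,
                            recovered = c(TRUE, TRUE, FALSE, TRUE))
  tab <- recovery_by_frequency_bin(matches, mr$regions, mr$membership)
  expect_equal(tab$n_ref[tab$label == "<=20%"], 4L)  # 0.2 falls in (0, 0.2]
  expect_equal(tab$n_recovered[tab$label == "<=20%"], 3L)
  expect_equal(sum(tab$n_ref), 4L)
})

test_that("a uniform-sensitivity caller yields flat frequency-bin rates", {
  s <- 0.7
  cfg <- sim_config(n_samples = 100, n_regions = 120, frac_singleton = 0.1,
                    freq_shape1 = 0.6, freq_shape2 = 0.6,
                    size_range = c(5e4, 5e5))
  sim <- simulate_truth(cfg, seed = 202)
  prof <- caller_profile("flat", sensitivity = rep(s, 5), jitter_sd = 0,
                         flip_prob = 0, fp_per_sample = 0, dup_penalty = 1)
  calls <- simulate_caller(sim, prof, seed = 203)
  m <- match_reference(sim$truth, calls)
  mr <- merge_into_regions(sim$truth, cfg$n_samples)
  tab <- recovery_by_frequency_bin(m, mr$regions, mr$membership)
  big <- tab[tab$n_ref >= 200, ]
  expect_gte(nrow(big), 2)
  expect_true(all(abs(big$rate - s) <= 3 * sqrt(s * (1 - s) / big$n_ref)))
})

test_that("per-region sensitivity summarises the recovery distribution", {
  refs <- tibble::tibble(
    ref_id = sprintf("r%d", 1:10),
    sample_id = sprintf("S%d", 1:10),
    chrom = "chr1",
    start = c(rep(0, 2), rep(5000, 8)),
    end = c(rep(1000, 2), rep(6000, 8)),
    state = "deletion"
  )
  mr <- merge_into_regions(refs, total_samples = 10)
  matches <- tibble::tibble(
    ref_id = refs$ref_id,
    recovered = c(TRUE, TRUE, rep(TRUE, 6), FALSE, FALSE)
  )
  out <- per_region_sensitivity(matches, mr$regions, mr$membership)
  sens <- sort(out$per_region$sensitivity)
  expect_equal(sens, c(0.75, 1))  # 6 of 8 carriers; both of 2 carriers
  expect_equal(out$summary$share_gt_90, 0.5)
  expect_equal(out$summary$share_le_10, 0)

  all_missed <- tibble::tibble(ref_id = refs$ref_id, recovered = FALSE)
  out0 <- per_region_sensitivity(all_missed, mr$regions, mr$membership)
  expect_equal(out0$summary$share_le_10, 1)
})
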