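#' Simulation configuration for synthetic CNV benchmarking data
#'
#' Defines the cohort, genome, probe manifest and truth-set frequency
#' spectrum used by [simulate_truth()]. Defaults emulate the structure of
#' an array-based CNV study: a singleton-dominated frequency spectrum with
#' a long tail of common polymorphic regions, 48-sample genotyping plates,
#' and SNP-array-like probe density (about 0.6 probes per kb).
#'
#' @param n_samples Cohort size.
#' @param plate_size Samples per genotyping plate (last plate may be short).
#' @param n_regions Number of truth CNV regions to place (non-overlapping).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param probe_per_kb Probe density of the simulated manifest.
#' @param size_range Length-2 vector: log-uniform bounds (bp) for region
#'   sizes.
#' @param frac_singleton Fraction of regions carried by exactly one sample.
#' @param freq_shape1,freq_shape2 Beta parameters for the carrier frequency
#'   of non-singleton (polymorphic) regions.
#' @param p_deletion Probability that a region is a deletion (else
#'   duplication): either a single number or a function of the region's
#'   realised carrier frequency, e.g. `function(f) 1 - f` to make common
#'   regions predominantly duplications.
#' @return A `cnv_sim_config` list.
#' @export
sim_config <- function(n_samples = 96,
                       plate_size = 48,
                       n_regions = 100,
                       chrom_lengths = c(chr1 = 6e7, chr2 = 6e7),
                       probe_per_kb = 0.6,
                       size_range = c(5e3, 5e5),
                       frac_singleton = 0.6,
                       freq_shape1 = 0.4,
                       freq_shape2 = 0.8,
                       p_deletion = 0.5) {
  stopifnot(
    n_samples >= 1, plate_size >= 1, n_regions >= 1,
    all(chrom_lengths > 0), probe_per_kb > 0,
    length(size_range) == 2, size_range[1] > 0, size_range[1] <= size_range[2],
    frac_singleton >= 0, frac_singleton <= 1,
    freq_shape1 > 0, freq_shape2 > 0,
    is.function(p_deletion) ||
      (is.numeric(p_deletion) && p_deletion >= 0 && p_deletion <= 1)
  )
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(
    list(
      n_samples = n_samples, plate_size = plate_size, n_regions = n_regions,
      chrom_lengths = chrom_lengths, probe_per_kb = probe_per_kb,
      size_range = size_range, frac_singleton = frac_singleton,
      freq_shape1 = freq_shape1, freq_shape2 = freq_shape2,
      p_deletion = p_deletion
    ),
    class = "cnv_sim_config"
  )
}

#' Performance profile of a simulated CNV caller
#'
#' Encodes the empirical behaviour of array-based callers: detection
#' probability that rises with probe support, breakpoint jitter, occasional
#' deletion/duplication confusion, random false calls, log-normal LOD
#' scores, a sensitivity penalty for duplications (a duplication is a
#' 1.5-fold intensity change versus 2-fold for a deletion, so it is harder
#' to detect), and an optional plate-restricted artifact.
#'
#' @param name Caller label.
#' @param sensitivity Five detection probabilities, one per probe-count bin
#'   of [probe_bins()] (1, 2-5, 6-10, 11-20, >20 probes).
#' @param jitter_sd Gaussian SD (bp) of breakpoint jitter; jittered
#'   intervals are re-ordered, clipped to the chromosome, and dropped (a
#'   miss) if they collapse below 1 bp.
#' @param flip_prob Probability of reporting the opposite state
#'   (deletion as duplication or vice versa).
#' @param fp_per_sample Poisson mean of false calls per sample, placed at
#'   random non-truth loci.
#' @param lod_meanlog,lod_sdlog Log-normal LOD-score parameters.
#' @param dup_penalty Multiplier (in `[0, 1]`) applied to the sensitivity of
#'   duplication regions.
#' @param plate_artifact Optional list `(plate, region_id, prob)`: on the
#'   named plate, non-carrier samples receive an artifactual call covering
#'   the region with probability `prob`.
#' @return A `cnv_caller_profile` list.
#' @export
caller_profile <- function(name,
                           sensitivity = c(0.05, 0.3, 0.5, 0.6, 0.85),
                           jitter_sd = 500,
                           flip_prob = 0.02,
                           fp_per_sample = 1,
                           lod_meanlog = 2.3,
                           lod_sdlog = 0.6,
                           dup_penalty = 0.8,
                           plate_artifact = NULL) {
  stopifnot(
    length(sensitivity) == nrow(probe_bins()),
    all(sensitivity >= 0 & sensitivity <= 1),
    jitter_sd >= 0, flip_prob >= 0, flip_prob <= 1,
    fp_per_sample >= 0, dup_penalty >= 0, dup_penalty <= 1
  )
  if (!is.null(plate_artifact)) {
    stopifnot(all(c("plate", "region_id", "prob") %in% names(plate_artifact)))
  }
  structure(
    list(
      name = name, sensitivity = sensitivity, jitter_sd = jitter_sd,
      flip_prob = flip_prob, fp_per_sample = fp_per_sample,
      lod_meanlog = lod_meanlog, lod_sdlog = lod_sdlog,
      dup_penalty = dup_penalty, plate_artifact = plate_artifact
    ),
    class = "cnv_caller_profile"
  )
}

#' Simulate a truth set, probe manifest and plate structure
#'
#' Places `n_regions` non-overlapping CNV regions uniformly on the
#' simulated genome with log-uniform sizes, draws carriers per region
#' (one carrier for singleton regions; Bernoulli with a Beta-distributed
#' frequency otherwise, re-drawn so every region keeps at least one
#' carrier), assigns each region a deletion or duplication state, and
#' generates a sorted probe manifest and a plate map. Deterministic for a
#' given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return List: `config`, `truth` (per-carrier reference tibble with
#'   `ref_id`, `sample_id`, `chrom`, `start`, `end`, `state`, `region_id`),
#'   `regions` (tibble with `region_id`, interval, `state`, `n_carriers`,
#'   `frequency`, `n_probes`), `probes` (probe map), `plates`
#'   (sample-to-plate tibble), `samples` (character vector).
#' @export
simulate_truth <- function(config, seed = 1) {
  stopifnot(inherits(config, "cnv_sim_config"))
  withr::with_seed(seed, {
    samples <- sprintf("S%04d", seq_len(config$n_samples))
    plates <- tibble::tibble(
      sample_id = samples,
      plate = sprintf("P%02d", ceiling(seq_along(samples) / config$plate_size))
    )

    probes <- lapply(names(config$chrom_lengths), function(chr) {
      len <- config$chrom_lengths[[chr]]
      n <- max(1L, round(len / 1000 * config$probe_per_kb))
      tibble::tibble(chrom = chr, pos = sort(sample.int(len, n)) - 1)
    })
    probes <- dplyr::bind_rows(probes)
    probes$probe_id <- sprintf("probe%07d", seq_len(nrow(probes)))

    sizes <- round(exp(runif(config$n_regions,
                             log(config$size_range[1]),
                             log(config$size_range[2]))))
    if (sum(sizes) > 0.5 * sum(config$chrom_lengths)) {
      rlang::abort("requested regions exceed genome capacity at the size bounds")
    }
    placed <- vector("list", config$n_regions)
    occupied <- lapply(names(config$chrom_lengths), function(chr) NULL)
    names(occupied) <- names(config$chrom_lengths)
    chrom_prob <- config$chrom_lengths / sum(config$chrom_lengths)
    for (i in seq_len(config$n_regions)) {
      ok <- FALSE
      for (try in seq_len(200)) {
        chr <- sample(names(config$chrom_lengths), 1, prob = chrom_prob)
        len <- config$chrom_lengths[[chr]]
        if (sizes[i] >= len) next
        s <- floor(runif(1, 0, len - sizes[i]))
        e <- s + sizes[i]
        occ <- occupied[[chr]]
        if (is.null(occ) || all(e <= occ[, 1] | s >= occ[, 2])) {
          occupied[[chr]] <- rbind(occ, c(s, e))
          placed[[i]] <- tibble::tibble(chrom = chr, start = s, end = e)
          ok <- TRUE
          break
        }
      }
      if (!ok) rlang::abort("could not place non-overlapping regions; reduce n_regions or sizes")
    }
    regions <- dplyr::bind_rows(placed)
    regions$region_id <- sprintf("R%04d", seq_len(nrow(regions)))
    singleton <- runif(nrow(regions)) < config$frac_singleton

    carrier_sets <- lapply(seq_len(nrow(regions)), function(i) {
      if (singleton[i]) {
        sample(samples, 1)
      } else {
        f <- rbeta(1, config$freq_shape1, config$freq_shape2)
        carriers <- samples[runif(length(samples)) < f]
        if (length(carriers) == 0) carriers <- sample(samples, 1)
        carriers
      }
    })
    regions$n_carriers <- lengths(carrier_sets)
    regions$frequency <- regions$n_carriers / config$n_samples
    p_del <- if (is.function(config$p_deletion)) {
      vapply(regions$frequency, config$p_deletion, numeric(1))
    } else {
      rep(config$p_deletion, nrow(regions))
    }
    regions$state <- ifelse(runif(nrow(regions)) < p_del,
                            "deletion", "duplication")
    regions$n_probes <- count_probes(regions[, c("chrom", "start", "end")], probes)

    truth <- tibble::tibble(
      sample_id = unlist(carrier_sets),
      region_id = rep(regions$region_id, regions$n_carriers)
    ) |>
      dplyr::left_join(
        regions[, c("region_id", "chrom", "start", "end", "state")],
        by = "region_id"
      )
    truth <- ensure_id(truth, "ref_id", "ref")
    truth <- truth[, c("ref_id", "sample_id", "chrom", "start", "end",
                       "state", "region_id")]

    list(config = config, truth = truth, regions = regions, probes = probes,
         plates = plates, samples = samples)
  })
}

probe_bin_of <- function(n_probes) {
  bins <- probe_bins()
  bin_index(n_probes, bins$lo, bins$hi, closed_left = TRUE)
}

#' Simulate one caller's output over a simulated truth set
#'
#' Each carrier's CNV is emitted with probability equal to the profile's
#' sensitivity for the region's probe-count bin (times `dup_penalty` for
#' duplications; regions spanning zero probes are never emitted). Emitted
#' breakpoints are jittered, states flipped with the configured
#' probability, LOD scores drawn log-normally, false calls added per sample
#' at random non-truth loci, and the plate artifact (if any) injected.
#' Deterministic for a given `seed`.
#'
#' @param sim Output of [simulate_truth()].
#' @param profile A [caller_profile()].
#' @param seed Integer seed.
#' @return Call-set tibble `sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`, `lod`, `caller`.
#' @export
simulate_caller <- function(sim, profile, seed = 1) {
  stopifnot(inherits(profile, "cnv_caller_profile"))
  config <- sim$config
  withr::with_seed(seed, {
    truth <- dplyr::left_join(
      sim$truth,
      sim$regions[, c("region_id", "n_probes")],
      by = "region_id"
    )
    bin <- probe_bin_of(truth$n_probes)
    p_emit <- ifelse(is.na(bin), 0, profile$sensitivity[bin])
    p_emit <- p_emit * ifelse(truth$state == "duplication", profile$dup_penalty, 1)
    emit <- runif(nrow(truth)) < p_emit
    em <- truth[emit, , drop = FALSE]

    calls <- NULL
    if (nrow(em) > 0) {
      s <- em$start + round(rnorm(nrow(em), 0, profile$jitter_sd))
      e <- em$end + round(rnorm(nrow(em), 0, profile$jitter_sd))
      lo <- pmin(s, e); hi <- pmax(s, e)
      clen <- config$chrom_lengths[em$chrom]
      lo <- pmax(0, lo); hi <- pmin(clen, hi)
      keep <- hi - lo >= 1   # collapsed intervals are dropped (a missed CNV)
      em <- em[keep, , drop = FALSE]
      lo <- lo[keep]; hi <- hi[keep]
      state <- em$state
      flip <- runif(nrow(em)) < profile$flip_prob
      state[flip] <- ifelse(state[flip] == "deletion", "duplication", "deletion")
      cn <- ifelse(state == "deletion",
                   ifelse(runif(nrow(em)) < 0.3, 0L, 1L),
                   ifelse(runif(nrow(em)) < 0.15, 4L, 3L))
      calls <- tibble::tibble(
        sample_id = em$sample_id, chrom = em$chrom, start = lo, end = hi,
        copy_number = cn,
        lod = rlnorm(nrow(em), profile$lod_meanlog, profile$lod_sdlog)
      )
    }

    # false calls at loci free of truth regions
    n_fp <- rpois(length(sim$samples), profile$fp_per_sample)
    fp_rows <- list()
    chrom_prob <- config$chrom_lengths / sum(config$chrom_lengths)
    regions_by_chrom <- split(sim$regions, sim$regions$chrom)
    for (i in seq_along(sim$samples)) {
      for (j in seq_len(n_fp[i])) {
        for (try in seq_len(50)) {
          chr <- sample(names(config$chrom_lengths), 1, prob = chrom_prob)
          len <- round(exp(runif(1, log(2e3), log(5e4))))
          clen <- config$chrom_lengths[[chr]]
          if (len >= clen) next
          s <- floor(runif(1, 0, clen - len))
          e <- s + len
          occ <- regions_by_chrom[[chr]]
          if (!is.null(occ) && any(s < occ$end & e > occ$start)) next
          fp_rows[[length(fp_rows) + 1]] <- tibble::tibble(
            sample_id = sim$samples[i], chrom = chr, start = s, end = e,
            copy_number = sample(c(1L, 3L), 1),
            lod = rlnorm(1, profile$lod_meanlog, profile$lod_sdlog)
          )
          break
        }
      }
    }
    calls <- dplyr::bind_rows(c(list(calls), fp_rows))

    if (!is.null(profile$plate_artifact)) {
      pa <- profile$plate_artifact
      reg <- sim$regions[sim$regions$region_id == pa$region_id, , drop = FALSE]
      if (nrow(reg) != 1) rlang::abort("plate_artifact region_id not found")
      on_plate <- sim$plates$sample_id[sim$plates$plate == pa$plate]
      carriers <- sim$truth$sample_id[sim$truth$region_id == pa$region_id]
      targets <- setdiff(on_plate, carriers)
      hit <- targets[runif(length(targets)) < pa$prob]
      if (length(hit) > 0) {
        art <- tibble::tibble(
          sample_id = hit, chrom = reg$chrom, start = reg$start, end = reg$end,
          copy_number = ifelse(reg$state == "deletion", 1L, 3L),
          lod = rlnorm(length(hit), profile$lod_meanlog, profile$lod_sdlog)
        )
        calls <- dplyr::bind_rows(calls, art)
      }
    }

    if (is.null(calls) || nrow(calls) == 0) {
      calls <- tibble::tibble(
        sample_id = character(0), chrom = character(0), start = numeric(0),
        end = numeric(0), copy_number = integer(0), lod = numeric(0)
      )
    }
    calls$caller <- profile$name
    calls
  })
}

#' Simulate qPCR Ct measurements for known copy numbers
#'
#' Inverts the delta-delta-Ct relation: for a true copy number `CN`,
#' `ddCt = -log2(CN / 2)` plus Gaussian noise, realised as Ct values with a
#' flat control Ct and a per-assay 2-copy calibrator sample. A true copy
#' number of 0 cannot produce a finite Ct and is floored at 0.25 copies
#' (flagged in the `floored` column).
#'
#' @param truth_cn Tibble `sample_id`, `assay_id`, `true_cn` (>= 0).
#' @param noise_sd Gaussian SD of the ddCt noise, in cycles; must be >= 0.
#' @param seed Integer seed.
#' @return qPCR tibble compatible with [ddct_copy_number()]:
#'   `sample_id`, `assay_id`, `ct_target`, `ct_control`, `calibrator`,
#'   `floored`.
#' @export
simulate_qpcr <- function(truth_cn, noise_sd = 0.15, seed = 1) {
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  if (any(truth_cn$true_cn < 0)) rlang::abort("true copy numbers must be >= 0")
  withr::with_seed(seed, {
    floored <- truth_cn$true_cn == 0
    cn_eff <- ifelse(floored, 0.25, truth_cn$true_cn)
    ddct <- -log2(cn_eff / 2) + rnorm(nrow(truth_cn), 0, noise_sd)
    ct_control <- 20
    dct_cal <- 1   # calibrator target runs one cycle behind its control
    meas <- tibble::tibble(
      sample_id = truth_cn$sample_id,
      assay_id = truth_cn$assay_id,
      ct_target = ct_control + dct_cal + ddct,
      ct_control = ct_control,
      calibrator = FALSE,
      floored = floored
    )
    cal <- tibble::tibble(
      sample_id = "CALIBRATOR",
      assay_id = unique(truth_cn$assay_id),
      ct_target = ct_control + dct_cal,
      ct_control = ct_control,
      calibrator = TRUE,
      floored = FALSE
    )
    dplyr::bind_rows(meas, cal)
  })
}
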