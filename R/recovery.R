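#' Default probe-count bins for recovery stratification
#'
#' The conventional marker-count strata: 1, 2–5, 6–10, 11–20, >20 probes.
#' The printed "10–20" stratum is resolved as 11–20 so the bins partition
#' the positive integers.
#'
#' @return Tibble with `label`, `lo`, `hi` (inclusive bounds).
#' @export
probe_bins <- function() {
  tibble::tibble(
    label = c("1", "2-5", "6-10", "11-20", ">20"),
    lo = c(1, 2, 6, 11, 21),
    hi = c(1, 5, 10, 20, Inf)
  )
}

#' Default frequency bins for recovery stratification
#'
#' Half-open `(lo, hi]` bins over region carrier frequency:
#' (0, 0.2], (0.2, 0.4], (0.4, 0.6], (0.6, 0.8], (0.8, 1].
#'
#' @return Tibble with `label`, `lo`, `hi`.
#' @export
frequency_bins <- function() {
  tibble::tibble(
    label = c("<=20%", "20-40%", "40-60%", "60-80%", ">80%"),
    lo = c(0, 0.2, 0.4, 0.6, 0.8),
    hi = c(0.2, 0.4, 0.6, 0.8, 1)
  )
}

check_bins <- function(bins, closed_left = TRUE) {
  if (!all(c("label", "lo", "hi") %in% names(bins))) {
    rlang::abort("bins must have columns label, lo, hi")
  }
  if (any(bins$lo > bins$hi)) rlang::abort("bin lo must be <= hi")
  o <- order(bins$lo)
  hi_prev <- bins$hi[o][-nrow(bins)]
  lo_next <- bins$lo[o][-1]
  overlapping <- if (closed_left) hi_prev >= lo_next else hi_prev > lo_next
  if (any(overlapping)) rlang::abort("bins must not overlap")
  bins[o, , drop = FALSE]
}

#' Match reference CNVs against a call set
#'
#' A reference CNV is recovered when at least one call in the same sample
#' with copy number different from 2 shares at least `threshold` of the
#' combined span of the pair ([overlap_fraction()]). With
#' `require_state = TRUE`, a matching call must additionally be in the same
#' direction as the reference (copy number 0 or 1 for a deletion, >2 for a
#' duplication). Matching is many-to-many: several calls may recover one
#' reference and one call may recover several references.
#'
#' References with state `"unknown"` are evaluable only without the state
#' requirement; their `recovered_state` is `NA`.
#'
#' @param refs Reference tibble (`ref_id`, `sample_id`, `chrom`, `start`,
#'   `end`, `state`); `ref_id` is added if absent.
#' @param calls Call-set tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`, ...).
#' @param threshold Overlap-fraction threshold in (0, 1]; default 0.25.
#' @param require_state If `TRUE`, `recovered` reports the state-consistent
#'   criterion; otherwise the overlap-only criterion.
#' @return One row per reference: `ref_id`, `sample_id`, `n_matched`,
#'   `best_fraction`, `recovered_korn` (overlap-only), `recovered_state`
#'   (with state consistency), `recovered` (the criterion selected by
#'   `require_state`).
#' @export
match_reference <- function(refs, calls, threshold = 0.25, require_state = FALSE) {
  if (threshold <= 0 || threshold > 1) {
    rlang::abort("threshold must be in (0, 1]")
  }
  refs <- ensure_id(refs, "ref_id", "ref")
  if (!"state" %in% names(refs)) refs$state <- "unknown"
  calls <- calls[calls$copy_number != 2, , drop = FALSE]

  res <- tibble::tibble(
    ref_id = refs$ref_id,
    sample_id = refs$sample_id,
    n_matched = 0L,
    best_fraction = 0,
    recovered_korn = FALSE,
    recovered_state = ifelse(refs$state == "unknown", NA, FALSE)
  )
  if (nrow(calls) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(refs), as_granges(calls))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    same_sample <- refs$sample_id[qi] == calls$sample_id[si]
    qi <- qi[same_sample]; si <- si[same_sample]
    if (length(qi) > 0) {
      frac <- overlap_fraction(refs[qi, c("chrom", "start", "end")],
                               calls[si, c("chrom", "start", "end")])
      state_ok <- cn_state(calls$copy_number[si]) == refs$state[qi]
      pass <- frac >= threshold
      agg_max <- tapply(frac, qi, max)
      res$best_fraction[as.integer(names(agg_max))] <- as.numeric(agg_max)
      nm <- tapply(pass, qi, sum)
      res$n_matched[as.integer(names(nm))] <- as.integer(nm)
      res$recovered_korn <- res$n_matched > 0
      ok <- tapply(pass & state_ok, qi, any)
      idx <- as.integer(names(ok))
      res$recovered_state[idx] <- ifelse(is.na(res$recovered_state[idx]),
                                         NA, as.logical(ok))
    }
  }
  res$recovered <- if (require_state) res$recovered_state else res$recovered_korn
  attr(res, "threshold") <- threshold
  attr(res, "require_state") <- require_state
  res
}

summarise_bins <- function(x, bins) {
  # x: tibble with bin index column `.bin` and logical `recovered`
  out <- bins
  out$n_ref <- 0L
  out$n_recovered <- 0L
  tab <- x |>
    dplyr::filter(!is.na(.data$.bin)) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      n_ref = sum(!is.na(.data$recovered)),
      n_recovered = sum(.data$recovered, na.rm = TRUE),
      .groups = "drop"
    )
  out$n_ref[tab$.bin] <- tab$n_ref
  out$n_recovered[tab$.bin] <- tab$n_recovered
  out$rate <- ifelse(out$n_ref > 0, out$n_recovered / out$n_ref, NA_real_)
  out
}

#' Recovery rates stratified by probe support
#'
#' Assigns each reference to exactly one probe-count bin and reports
#' recovered / total per bin. References spanning zero probes of the
#' manifest are excluded (reported via the `n_zero_probe` attribute and a
#' message) — they are invisible to an array-based caller and are not
#' evaluated.
#'
#' @param matches Output of [match_reference()].
#' @param refs The reference tibble given to [match_reference()].
#' @param probes Probe map (see [read_probe_manifest()]).
#' @param bins Bin table with `label`, `lo`, `hi` (inclusive integer
#'   bounds); default [probe_bins()]. Overlapping bins are an error.
#' @return Tibble `label`, `lo`, `hi`, `n_ref`, `n_recovered`, `rate`
#'   (NA for empty bins), with attribute `n_zero_probe`.
#' @export
recovery_by_probe_bin <- function(matches, refs, probes, bins = probe_bins()) {
  bins <- check_bins(bins)
  refs <- ensure_id(refs, "ref_id", "ref")
  np <- count_probes(refs[, c("chrom", "start", "end")], probes)
  x <- dplyr::left_join(matches, tibble::tibble(ref_id = refs$ref_id, np = np),
                        by = "ref_id")
  n_zero <- sum(x$np == 0)
  if (n_zero > 0) {
    rlang::inform(sprintf(
      "recovery_by_probe_bin: %d reference(s) span 0 probes and are excluded", n_zero
    ))
  }
  x <- x[x$np > 0, , drop = FALSE]
  x$.bin <- bin_index(x$np, bins$lo, bins$hi, closed_left = TRUE)
  out <- summarise_bins(x, bins)
  attr(out, "n_zero_probe") <- n_zero
  out
}

bin_index <- function(v, lo, hi, closed_left = TRUE) {
  idx <- rep(NA_integer_, length(v))
  for (i in seq_along(lo)) {
    inb <- if (closed_left) v >= lo[i] & v <= hi[i] else v > lo[i] & v <= hi[i]
    idx[inb] <- i
  }
  idx
}

#' Recovery rates stratified by CNV region frequency
#'
#' Each per-sample reference inherits the carrier frequency of its region
#' (from [merge_into_regions()]); bins are half-open `(lo, hi]`. The bin
#' rate is recovered / total within the bin.
#'
#' @param matches Output of [match_reference()].
#' @param regions,membership The two elements returned by
#'   [merge_into_regions()].
#' @param bins Frequency bin table; default [frequency_bins()].
#' @return Tibble `label`, `lo`, `hi`, `n_ref`, `n_recovered`, `rate`.
#' @export
recovery_by_frequency_bin <- function(matches, regions, membership,
                                      bins = frequency_bins()) {
  bins <- check_bins(bins, closed_left = FALSE)
  if (any(regions$n_members == 0)) rlang::abort("region without members")
  x <- matches |>
    dplyr::inner_join(membership, by = "ref_id") |>
    dplyr::inner_join(regions[, c("region_id", "frequency")], by = "region_id")
  x$.bin <- bin_index(x$frequency, bins$lo, bins$hi, closed_left = FALSE)
  summarise_bins(x, bins)
}

#' Per-region sensitivity distribution
#'
#' For each CNV region, the fraction of its member (per-carrier) references
#' that were recovered, plus the share of regions with sensitivity above 0.9
#' and at or below 0.1 — the bimodality summary used to characterise caller
#' behaviour on common CNVs.
#'
#' @param matches Output of [match_reference()].
#' @param regions,membership From [merge_into_regions()].
#' @return List with `per_region` (tibble `region_id`, `n_members`,
#'   `n_recovered`, `sensitivity`) and `summary` (tibble `share_gt_90`,
#'   `share_le_10`).
#' @export
per_region_sensitivity <- function(matches, regions, membership) {
  per <- matches |>
    dplyr::inner_join(membership, by = "ref_id") |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      n_members = sum(!is.na(.data$recovered)),
      n_recovered = sum(.data$recovered, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(sensitivity = ifelse(.data$n_members > 0,
                                       .data$n_recovered / .data$n_members,
                                       NA_real_))
  ok <- !is.na(per$sensitivity)
  summary <- tibble::tibble(
    share_gt_90 = mean(per$sensitivity[ok] > 0.9),
    share_le_10 = mean(per$sensitivity[ok] <= 0.1)
  )
  list(per_region = per, summary = summary)
}
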