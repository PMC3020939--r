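# Exact two-sided p-value for a 2x2 table under the hypergeometric null.
#
# x carriers observed on the plate, out of m carriers and n non-carriers in
# the cohort, with k samples on the plate. Two-sided by the probability
# method (all tables at most as probable as the observed one). The mid-p
# variant subtracts half the probability of the observed table, which keeps
# the discrete test close to its nominal level; the conventional Fisher
# p-value is obtained with midp = FALSE.
exact_2x2_p <- function(x, m, n, k, midp = TRUE) {
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  dobs <- stats::dhyper(x, m, n, k)
  p <- sum(d[d <= dobs * (1 + 1e-7)])
  if (midp) p <- p - 0.5 * dobs
  min(1, max(p, .Machine$double.xmin))
}

#' Scan CNV regions for genotyping plate effects
#'
#' For every region and every plate, compares the carrier frequency on the
#' plate against the rest of the cohort with an exact 2x2 test
#' (carriers/non-carriers x on-plate/off-plate). A region is flagged when
#' its smallest per-plate p-value falls below `alpha`; the default `alpha`
#' is 0.05 divided by the number of plates (Bonferroni within region).
#'
#' The default test is the mid-p exact hypergeometric test, which holds its
#' nominal level well on discrete tables; `method = "fisher"` gives the
#' conventional (conservative) Fisher exact p-value.
#'
#' @param carrier_status Tibble `sample_id`, `region_id`, `carrier`
#'   (logical), with a status for every sample in `plates` at every region.
#' @param plates Plate map tibble `sample_id`, `plate` (see
#'   [read_plate_map()]); at least two plates, none empty.
#' @param alpha Flagging threshold; default `0.05 / n_plates`.
#' @param method `"midp"` (default) or `"fisher"`.
#' @return List with `per_plate` (tibble `region_id`, `plate`, `n_plate`,
#'   `carriers_plate`, `n_off`, `carriers_off`, `p_value`) and `per_region`
#'   (tibble `region_id`, `min_p`, `flagged`).
#' @export
plate_effect_scan <- function(carrier_status, plates, alpha = NULL,
                              method = c("midp", "fisher")) {
  method <- match.arg(method)
  plate_levels <- unique(plates$plate)
  if (length(plate_levels) < 2) rlang::abort("need at least two plates")
  plate_sizes <- table(plates$plate)
  if (any(plate_sizes == 0)) rlang::abort("plate with zero samples")
  if (is.null(alpha)) alpha <- 0.05 / length(plate_levels)

  x <- dplyr::inner_join(carrier_status, plates, by = "sample_id")
  by_region <- split(x, x$region_id)
  n_total <- nrow(plates)
  rows <- lapply(names(by_region), function(rid) {
    xr <- by_region[[rid]]
    if (nrow(xr) != n_total) {
      rlang::abort(sprintf(
        "region %s: carrier status defined for %d of %d plated samples",
        rid, nrow(xr), n_total
      ))
    }
    m <- sum(xr$carrier)
    n <- n_total - m
    per_plate <- lapply(plate_levels, function(pl) {
      on <- xr$plate == pl
      k <- sum(on)
      cx <- sum(xr$carrier[on])
      p <- if (method == "midp") {
        exact_2x2_p(cx, m, n, k, midp = TRUE)
      } else {
        tab <- matrix(c(cx, k - cx, m - cx, n - (k - cx)), nrow = 2)
        stats::fisher.test(tab)$p.value
      }
      tibble::tibble(
        region_id = rid, plate = pl, n_plate = k, carriers_plate = cx,
        n_off = n_total - k, carriers_off = m - cx, p_value = p
      )
    })
    dplyr::bind_rows(per_plate)
  })
  per_plate <- dplyr::bind_rows(rows)
  per_region <- per_plate |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(min_p = min(.data$p_value), .groups = "drop") |>
    dplyr::mutate(flagged = .data$min_p < alpha)
  list(per_plate = per_plate, per_region = per_region, alpha = alpha)
}

#' Per-sample carrier status of CNV regions from a call set
#'
#' A sample carries a region when at least one of its variant calls
#' (copy number different from 2) shares at least `threshold` of the
#' combined span with the region interval. With `threshold = 0` any
#' overlapping base pair counts.
#'
#' @param calls Call-set tibble.
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`.
#' @param samples Character vector of all cohort sample ids (samples with no
#'   calls get `carrier = FALSE` everywhere).
#' @param threshold Combined-span overlap fraction required; default 0.5,
#'   the common-CNV matching rule.
#' @return Tibble `sample_id`, `region_id`, `carrier` covering every
#'   sample-by-region combination.
#' @export
call_carrier_status <- function(calls, regions, samples, threshold = 0.5) {
  grid <- tidyr::expand_grid(sample_id = samples, region_id = regions$region_id)
  x <- calls[calls$copy_number != 2, , drop = FALSE]
  if (nrow(x) == 0) {
    grid$carrier <- FALSE
    return(grid)
  }
  hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(regions))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (threshold > 0 && length(qi) > 0) {
    frac <- overlap_fraction(x[qi, c("chrom", "start", "end")],
                             regions[si, c("chrom", "start", "end")])
    keep <- frac >= threshold
    qi <- qi[keep]; si <- si[keep]
  }
  carriers <- dplyr::distinct(tibble::tibble(
    sample_id = x$sample_id[qi],
    region_id = regions$region_id[si]
  ))
  carriers$carrier <- TRUE
  grid |>
    dplyr::left_join(carriers, by = c("sample_id", "region_id")) |>
    dplyr::mutate(carrier = !is.na(.data$carrier))
}
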