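#' Default size bins (kb) for cross-set concordance tables
#' @return Tibble `label`, `lo`, `hi` in kb; bins are half-open `(lo, hi]`.
#' @export
size_bins_kb <- function() {
  tibble::tibble(
    label = c("<=5", "5-10", "10-50", "50-100", "100-1000"),
    lo = c(0, 5, 10, 50, 100),
    hi = c(5, 10, 50, 100, 1000)
  )
}

#' Concordance between two CNV sets on shared samples
#'
#' Many-to-many matching between two call/truth sets restricted to their
#' common samples: a CNV is "detected by the other study" when at least one
#' same-sample CNV in the other set shares at least `threshold` of the
#' combined span. No state consistency is required, and one CNV may match
#' several partners. Results are tabulated per interval-size bin, in both
#' directions.
#'
#' @param set_a,set_b Interval tables with `sample_id`, `chrom`, `start`,
#'   `end` (internal 0-based half-open coordinates).
#' @param threshold Overlap-fraction threshold; default 0.25.
#' @param bins Size bins in kb (half-open `(lo, hi]`); default
#'   [size_bins_kb()]. Sizes beyond the last edge fall in an extra
#'   overflow bin.
#' @param labels Length-2 character vector naming the two sets.
#' @return Tibble with `direction` (e.g. `"A->B"`), `label`, `total`,
#'   `matched`, `pct`.
#' @export
cross_dataset_consistency <- function(set_a, set_b, threshold = 0.25,
                                      bins = size_bins_kb(),
                                      labels = c("A", "B")) {
  bins <- check_bins(bins, closed_left = FALSE)
  common <- intersect(unique(set_a$sample_id), unique(set_b$sample_id))
  if (length(common) == 0) rlang::abort("no samples in common between the two sets")
  a <- set_a[set_a$sample_id %in% common, , drop = FALSE]
  b <- set_b[set_b$sample_id %in% common, , drop = FALSE]

  matched_flags <- function(x, y) {
    out <- logical(nrow(x))
    if (nrow(x) == 0 || nrow(y) == 0) return(out)
    hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- x$sample_id[qi] == y$sample_id[si]
    qi <- qi[keep]; si <- si[keep]
    if (length(qi) == 0) return(out)
    frac <- overlap_fraction(x[qi, c("chrom", "start", "end")],
                             y[si, c("chrom", "start", "end")])
    hit_ref <- unique(qi[frac >= threshold])
    out[hit_ref] <- TRUE
    out
  }

  tab_one <- function(x, flags, direction) {
    kb <- interval_length(x) / 1000
    bidx <- bin_index(kb, bins$lo, bins$hi, closed_left = FALSE)
    lab <- c(bins$label, sprintf(">%g", bins$hi[nrow(bins)]))
    bidx[is.na(bidx) & kb > bins$hi[nrow(bins)]] <- nrow(bins) + 1L
    res <- tibble::tibble(.bin = bidx, matched = flags) |>
      dplyr::filter(!is.na(.data$.bin)) |>
      dplyr::group_by(.data$.bin) |>
      dplyr::summarise(total = dplyr::n(), matched = sum(.data$matched),
                       .groups = "drop")
    full <- tibble::tibble(.bin = seq_along(lab), label = lab)
    full |>
      dplyr::left_join(res, by = ".bin") |>
      dplyr::mutate(
        direction = direction,
        total = ifelse(is.na(.data$total), 0L, .data$total),
        matched = ifelse(is.na(.data$matched), 0L, .data$matched),
        pct = ifelse(.data$total > 0, 100 * .data$matched / .data$total, NA_real_)
      ) |>
      dplyr::select("direction", "label", "total", "matched", "pct")
  }

  dplyr::bind_rows(
    tab_one(a, matched_flags(a, b), paste0(labels[1], "->", labels[2])),
    tab_one(b, matched_flags(b, a), paste0(labels[2], "->", labels[1]))
  )
}

#' Identify singleton CNVs within one caller's call set
#'
#' A singleton is a deletion or duplication that occurs exactly once in the
#' whole cohort: it overlaps no other variant call made by the same caller,
#' in any sample. Under the default `scope = "any_class"` an overlap with a
#' call of either class disqualifies; `scope = "same_class"` restricts the
#' disqualifying overlaps to the same class. Normal-copy (CN = 2) calls are
#' ignored throughout.
#'
#' @param calls One caller's call-set tibble over the full cohort.
#' @param cnv_class `"deletion"` or `"duplication"` — the class of
#'   singletons to return.
#' @param scope Which other calls can disqualify a singleton (see above).
#' @param overlap_rule_fraction Overlap rule for "overlaps": 0 (default)
#'   means any shared base pair disqualifies; a value `f > 0` only counts
#'   overlaps with combined-span fraction `>= f`, which can only enlarge
#'   the singleton set.
#' @return The subset of `calls` that are singletons of the requested class.
#' @export
find_singletons <- function(calls, cnv_class = c("deletion", "duplication"),
                            scope = c("any_class", "same_class"),
                            overlap_rule_fraction = 0) {
  cnv_class <- match.arg(cnv_class)
  scope <- match.arg(scope)
  x <- calls[calls$copy_number != 2, , drop = FALSE]
  if (nrow(x) == 0) return(x)
  x$.state <- cn_state(x$copy_number)
  cand <- which(x$.state == cnv_class)
  if (length(cand) == 0) return(x[integer(0), setdiff(names(x), ".state"), drop = FALSE])

  gr <- as_granges(x)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (scope == "same_class") {
    keep <- x$.state[si] == x$.state[qi]
    qi <- qi[keep]; si <- si[keep]
  }
  if (overlap_rule_fraction > 0 && length(qi) > 0) {
    frac <- overlap_fraction(x[qi, c("chrom", "start", "end")],
                             x[si, c("chrom", "start", "end")])
    keep <- frac >= overlap_rule_fraction
    qi <- qi[keep]
  }
  disqualified <- unique(qi)
  singleton_rows <- setdiff(cand, disqualified)
  out <- x[singleton_rows, , drop = FALSE]
  out$.state <- NULL
  out
}

#' Classify singletons as shared or program-specific across callers
#'
#' A singleton from one caller is "shared" when it overlaps, by at least one
#' base pair, a singleton of the same class from any other caller; otherwise
#' it is program-specific. Shared + program-specific partitions each
#' caller's singletons.
#'
#' @param singletons_by_caller Named list (>= 2 entries) of singleton
#'   call-set tibbles, one per caller, as returned by [find_singletons()]
#'   for a single class.
#' @param cnv_class The class the singletons belong to (recorded in the
#'   output).
#' @return Tibble per caller: `caller`, `class`, `total`, `shared`,
#'   `program_specific`, `pct_shared`, `pct_specific`.
#' @export
classify_program_specific <- function(singletons_by_caller,
                                      cnv_class = c("deletion", "duplication")) {
  cnv_class <- match.arg(cnv_class)
  if (length(singletons_by_caller) < 2) {
    rlang::abort("need singleton sets from at least two callers")
  }
  if (is.null(names(singletons_by_caller)) || any(names(singletons_by_caller) == "")) {
    rlang::abort("singletons_by_caller must be a named list")
  }
  callers <- names(singletons_by_caller)
  rows <- lapply(callers, function(cl) {
    own <- singletons_by_caller[[cl]]
    others <- dplyr::bind_rows(singletons_by_caller[setdiff(callers, cl)])
    shared <- logical(nrow(own))
    if (nrow(own) > 0 && nrow(others) > 0) {
      hits <- GenomicRanges::findOverlaps(as_granges(own), as_granges(others))
      shared[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    tibble::tibble(
      caller = cl, class = cnv_class,
      total = nrow(own),
      shared = sum(shared),
      program_specific = sum(!shared)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      pct_shared = ifelse(.data$total > 0, 100 * .data$shared / .data$total, NA_real_),
      pct_specific = ifelse(.data$total > 0, 100 * .data$program_specific / .data$total, NA_real_)
    )
}

#' Mean CNV count per individual by size bin
#'
#' For each caller label present in `calls`, the total number of variant
#' calls per size bin divided by the cohort size (samples with no calls
#' count in the denominator).
#'
#' @param calls Call-set tibble (may contain several `caller` labels).
#' @param n_samples Cohort size (> 0).
#' @param bins Size bins in kb, half-open `(lo, hi]`, with an overflow bin
#'   beyond the last edge; default [size_bins_kb()].
#' @return Tibble `caller`, `label`, `n_calls`, `mean_per_individual`.
#' @export
size_profile <- function(calls, n_samples, bins = size_bins_kb()) {
  if (n_samples <= 0) rlang::abort("n_samples must be > 0")
  bins <- check_bins(bins, closed_left = FALSE)
  x <- calls[calls$copy_number != 2, , drop = FALSE]
  lab <- c(bins$label, sprintf(">%g", bins$hi[nrow(bins)]))
  grid <- tidyr::expand_grid(caller = unique(calls$caller), .bin = seq_along(lab))
  if (nrow(x) > 0) {
    kb <- interval_length(x) / 1000
    x$.bin <- bin_index(kb, bins$lo, bins$hi, closed_left = FALSE)
    x$.bin[is.na(x$.bin) & kb > bins$hi[nrow(bins)]] <- nrow(bins) + 1L
    counts <- x |>
      dplyr::filter(!is.na(.data$.bin)) |>
      dplyr::group_by(.data$caller, .data$.bin) |>
      dplyr::summarise(n_calls = dplyr::n(), .groups = "drop")
  } else {
    counts <- tibble::tibble(caller = character(0), .bin = integer(0),
                             n_calls = integer(0))
  }
  grid |>
    dplyr::left_join(counts, by = c("caller", ".bin")) |>
    dplyr::mutate(
      label = lab[.data$.bin],
      n_calls = ifelse(is.na(.data$n_calls), 0L, .data$n_calls),
      mean_per_individual = .data$n_calls / n_samples
    ) |>
    dplyr::select("caller", "label", "n_calls", "mean_per_individual")
}
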