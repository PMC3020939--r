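#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open: an interval covers base pairs
#' `start, start+1, ..., end-1`. Zero- and negative-length intervals are
#' rejected.
#'
#' @param chrom Chromosome labels (character).
#' @param start,end Integer coordinates, 0-based half-open (`start < end`).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr1", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end))) {
    rlang::abort("intervals must have non-missing chrom, start, end")
  }
  if (any(start < 0)) rlang::abort("start coordinates must be >= 0")
  if (any(start >= end)) {
    rlang::abort("invalid interval: start must be < end (zero-length intervals rejected)")
  }
  tibble::tibble(chrom = as.character(chrom), start = start, end = end)
}

#' Interval length in base pairs
#' @param x A tibble with `start`, `end` columns (0-based half-open).
#' @return Numeric vector of lengths `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

recycle2 <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) a <- a[rep(1L, nb), , drop = FALSE]
  else if (nb == 1L) b <- b[rep(1L, na), , drop = FALSE]
  else rlang::abort("interval tables must have equal length (or length 1)")
  list(a = a, b = b)
}

#' Intersection length of two intervals
#'
#' Vectorised over rows; pairs on different chromosomes or disjoint pairs
#' yield 0.
#'
#' @param a,b Interval tables (see [genomic_interval()]); recycled if one has
#'   a single row.
#' @return Integer base pairs of overlap, `>= 0`.
#' @examples
#' intersection_length(genomic_interval("1", 0, 100), genomic_interval("1", 50, 150))
#' @export
intersection_length <- function(a, b) {
  r <- recycle2(a, b)
  same <- r$a$chrom == r$b$chrom
  len <- pmax(0, pmin(r$a$end, r$b$end) - pmax(r$a$start, r$b$start))
  ifelse(same, len, 0)
}

#' Combined-span (set-union) length of two same-chromosome intervals
#'
#' The denominator of the matching statistic: total number of base pairs
#' covered by either interval. Both intervals must lie on the same
#' chromosome; callers comparing across chromosomes must pre-filter.
#'
#' @inheritParams intersection_length
#' @return Integer base pairs covered by the union of the pair.
#' @export
combined_span_length <- function(a, b) {
  r <- recycle2(a, b)
  if (any(r$a$chrom != r$b$chrom)) {
    rlang::abort("combined_span_length requires intervals on the same chromosome")
  }
  interval_length(r$a) + interval_length(r$b) - intersection_length(r$a, r$b)
}

#' Combined-span overlap fraction
#'
#' Intersection length divided by set-union length of the pair — the fraction
#' of the length spanned by the two intervals together that they share.
#' Symmetric in its arguments; 0 for pairs on different chromosomes.
#'
#' Two CNVs are conventionally considered "the same" when this fraction is at
#' least 0.25 (truth-set recovery) or 0.5 (cross-program common-CNV
#' matching).
#'
#' @inheritParams intersection_length
#' @return Numeric fraction in `[0, 1]`.
#' @examples
#' overlap_fraction(genomic_interval("1", 0, 100), genomic_interval("1", 50, 150))
#' @export
overlap_fraction <- function(a, b) {
  r <- recycle2(a, b)
  same <- r$a$chrom == r$b$chrom
  inter <- pmax(0, pmin(r$a$end, r$b$end) - pmax(r$a$start, r$b$start))
  uni <- interval_length(r$a) + interval_length(r$b) - inter
  ifelse(same, inter / uni, 0)
}

#' Count array probes falling inside an interval
#'
#' Counts manifest positions `p` with `start <= p < end`, by binary search.
#'
#' @param x Interval table (one or more rows).
#' @param probes A probe map: tibble with `chrom`, `pos` (and optionally
#'   `probe_id`), positions strictly increasing within each chromosome (see
#'   [read_probe_manifest()]).
#' @return Integer vector of probe counts per interval row. Intervals on a
#'   chromosome absent from the map count 0, with a warning.
#' @export
count_probes <- function(x, probes) {
  pos_by_chrom <- split(probes$pos, probes$chrom)
  out <- integer(nrow(x))
  missing_chroms <- character(0)
  for (chr in unique(x$chrom)) {
    idx <- which(x$chrom == chr)
    p <- pos_by_chrom[[chr]]
    if (is.null(p)) {
      missing_chroms <- c(missing_chroms, chr)
      next
    }
    # start <= pos < end, half-open
    out[idx] <- findInterval(x$end[idx] - 1, p) - findInterval(x$start[idx] - 1, p)
  }
  if (length(missing_chroms) > 0) {
    rlang::warn(paste0(
      "chromosome(s) absent from probe map (counted as 0 probes): ",
      paste(unique(missing_chroms), collapse = ", ")
    ))
  }
  out
}

# GRanges view of an interval table (1-based closed, as IRanges expects).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Cluster per-sample reference CNVs into regions
#'
#' Single-linkage clustering of reference CNVs on the same chromosome. Under
#' the default `rule = "any_overlap"`, two CNVs sharing at least 1 bp join
#' the same region; under `rule = "fraction"` an edge requires a
#' combined-span [overlap_fraction()] of at least `threshold`. The region
#' interval is the union span of its members, and the region frequency is the
#' number of distinct carrier samples divided by `total_samples`.
#'
#' @param refs Reference CNV table: `chrom`, `start`, `end`, `sample_id`, and
#'   optionally `state`, `source`, `ref_id`.
#' @param total_samples Cohort size; must be at least the number of distinct
#'   sample ids in `refs`.
#' @param rule Clustering rule, `"any_overlap"` (default) or `"fraction"`.
#' @param threshold Overlap-fraction threshold when `rule = "fraction"`.
#' @return A list with `regions` (tibble: `region_id`, `chrom`, `start`,
#'   `end`, `n_members`, `n_carriers`, `frequency`) and `membership` (tibble:
#'   `ref_id`, `region_id`). Every input reference appears in exactly one
#'   region.
#' @export
merge_into_regions <- function(refs, total_samples,
                               rule = c("any_overlap", "fraction"),
                               threshold = 0.25) {
  rule <- match.arg(rule)
  empty <- list(
    regions = tibble::tibble(
      region_id = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), n_members = integer(0), n_carriers = integer(0),
      frequency = numeric(0)
    ),
    membership = tibble::tibble(ref_id = character(0), region_id = character(0))
  )
  if (nrow(refs) == 0) return(empty)
  if (total_samples < dplyr::n_distinct(refs$sample_id)) {
    rlang::abort("total_samples is smaller than the number of distinct sample ids")
  }
  refs <- ensure_id(refs, "ref_id", "ref")

  if (rule == "any_overlap") {
    gr <- as_granges(refs)
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, red)
    comp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  } else {
    gr <- as_granges(refs)
    hit <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
    frac <- overlap_fraction(refs[qi, , drop = FALSE], refs[si, , drop = FALSE])
    keep <- frac >= threshold
    g <- igraph::graph_from_edgelist(
      cbind(qi[keep], si[keep]),
      directed = FALSE
    )
    g <- igraph::add_vertices(g, max(0, nrow(refs) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }

  refs$region_id <- sprintf("R%04d", as.integer(factor(comp, levels = unique(comp))))
  regions <- refs |>
    dplyr::group_by(.data$region_id, .data$chrom) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_members = dplyr::n(),
      n_carriers = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(frequency = .data$n_carriers / total_samples) |>
    dplyr::arrange(.data$region_id)
  list(
    regions = regions,
    membership = tibble::tibble(ref_id = refs$ref_id, region_id = refs$region_id)
  )
}

# Adds a unique id column if absent.
ensure_id <- function(x, col, prefix) {
  if (!col %in% names(x)) {
    x[[col]] <- sprintf("%s%05d", prefix, seq_len(nrow(x)))
  } else if (anyDuplicated(x[[col]])) {
    rlang::abort(sprintf("column '%s' must be unique", col))
  }
  x
}

#' Derive deletion/duplication state from integer copy number
#'
#' Copy number below 2 is a deletion, above 2 a duplication, exactly 2 the
#' normal diploid state.
#'
#' @param copy_number Integer vector of copy numbers (`>= 0`).
#' @return Character vector: `"deletion"`, `"normal"`, or `"duplication"`.
#' @export
cn_state <- function(copy_number) {
  if (any(copy_number < 0, na.rm = TRUE)) rlang::abort("copy numbers must be >= 0")
  dplyr::case_when(
    copy_number < 2 ~ "deletion",
    copy_number > 2 ~ "duplication",
    TRUE ~ "normal"
  )
}
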