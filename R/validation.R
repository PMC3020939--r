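#' Copy-number estimates from qPCR Ct values (delta-delta-Ct)
#'
#' For each assay, replicate Ct rows per sample are averaged, then
#' `dCt = Ct_target - Ct_control` is computed for every sample and for the
#' 2-copy calibrator, and `ddCt = dCt_sample - dCt_calibrator`. The quantity
#' of target relative to the calibrator is `2^-ddCt`, so the estimated copy
#' number is `2 * 2^-ddCt`. Estimates are classified into
#' deletion/normal/duplication by [classify_cn()].
#'
#' @param measurements qPCR tibble (see [read_qpcr()]): `sample_id`,
#'   `assay_id`, `ct_target`, `ct_control`, `calibrator`.
#' @param t_del,t_dup Classification thresholds passed to [classify_cn()].
#' @return Tibble `sample_id`, `assay_id`, `ddct`, `rel_quantity`,
#'   `copy_number`, `state`. Calibrator rows are evaluated like any other
#'   sample (their ddCt is 0 by construction).
#' @export
ddct_copy_number <- function(measurements, t_del = 1.5, t_dup = 2.5) {
  n_cal <- tapply(measurements$calibrator, measurements$assay_id, sum)
  if (any(n_cal == 0)) {
    rlang::abort(paste0("assay(s) without calibrator: ",
                        paste(names(n_cal)[n_cal == 0], collapse = ", ")))
  }
  miss <- !is.finite(measurements$ct_control)
  if (any(miss)) {
    rlang::warn(sprintf("skipping %d measurement(s) without a control Ct", sum(miss)))
    measurements <- measurements[!miss, , drop = FALSE]
  }
  per_sample <- measurements |>
    dplyr::group_by(.data$assay_id, .data$sample_id, .data$calibrator) |>
    dplyr::summarise(
      ct_target = mean(.data$ct_target),
      ct_control = mean(.data$ct_control),
      .groups = "drop"
    ) |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_control)
  cal <- per_sample |>
    dplyr::filter(.data$calibrator) |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(dct_cal = mean(.data$dct), .groups = "drop")
  per_sample |>
    dplyr::left_join(cal, by = "assay_id") |>
    dplyr::mutate(
      ddct = .data$dct - .data$dct_cal,
      rel_quantity = 2^(-.data$ddct),
      copy_number = 2 * .data$rel_quantity,
      state = classify_cn(.data$copy_number, t_del, t_dup)
    ) |>
    dplyr::select("sample_id", "assay_id", "ddct", "rel_quantity",
                  "copy_number", "state")
}

#' Classify a continuous copy-number estimate
#'
#' Strict thresholds: `cn < t_del` is a deletion, `cn > t_dup` a
#' duplication, anything in `[t_del, t_dup]` (boundaries included) normal.
#'
#' @param cn Numeric copy-number estimates.
#' @param t_del,t_dup Thresholds with `0 < t_del < 2 < t_dup`.
#' @return Character vector of states.
#' @export
classify_cn <- function(cn, t_del = 1.5, t_dup = 2.5) {
  if (!(t_del > 0 && t_del < 2 && t_dup > 2)) {
    rlang::abort("thresholds must satisfy 0 < t_del < 2 < t_dup")
  }
  dplyr::case_when(
    cn < t_del ~ "deletion",
    cn > t_dup ~ "duplication",
    TRUE ~ "normal"
  )
}

#' Positive predictive value
#'
#' `TP / (TP + FP)`; `NA` when no positives were tested.
#'
#' @param tp,fp True- and false-positive counts (vectorised).
#' @return Fraction in `[0, 1]`, or `NA` where `tp + fp == 0`.
#' @export
ppv <- function(tp, fp) {
  if (any(c(tp, fp) < 0)) rlang::abort("counts must be non-negative")
  ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
}

#' False-positive and false-negative rates against a qPCR truth
#'
#' Compares per-sample program call states with qPCR-derived states, taking
#' qPCR as truth. A sample is a "variant" when its state is not normal. By
#' default direction is ignored (a deletion call on a qPCR-duplication
#' sample still counts as a true positive for carrier status);
#' `require_state = TRUE` demands the same direction, otherwise the variant
#' sample counts as missed.
#'
#' Rates use the standard definitions: FP rate = FP / (FP + TN) over
#' qPCR-normal samples, FN rate = FN / (FN + TP) over qPCR-variant samples.
#'
#' @param program_states Tibble `sample_id`, `state` as called by a program
#'   (`"deletion"`, `"normal"`, `"duplication"`).
#' @param qpcr_states Tibble `sample_id`, `state` from
#'   [ddct_copy_number()].
#' @param require_state See above.
#' @return One-row tibble `n`, `tp`, `fp`, `tn`, `fn`, `ppv`, `fpr`, `fnr`
#'   (rates as fractions; `NA` where the truth stratum is empty).
#' @export
fp_fn_rates <- function(program_states, qpcr_states, require_state = FALSE) {
  x <- dplyr::inner_join(
    dplyr::rename(program_states, call_state = "state"),
    dplyr::rename(qpcr_states, truth_state = "state"),
    by = "sample_id"
  )
  if (nrow(x) < nrow(program_states) || nrow(x) < nrow(qpcr_states)) {
    rlang::abort("every sample must have both a program call state and a qPCR state")
  }
  truth_var <- x$truth_state != "normal"
  call_var <- x$call_state != "normal"
  tp <- if (require_state) {
    sum(truth_var & call_var & x$call_state == x$truth_state)
  } else {
    sum(truth_var & call_var)
  }
  fn <- sum(truth_var) - tp
  fp <- sum(!truth_var & call_var)
  tn <- sum(!truth_var & !call_var)
  stopifnot(tp + fp + tn + fn == nrow(x))
  tibble::tibble(
    n = nrow(x), tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = ppv(tp, fp),
    fpr = ifelse(fp + tn > 0, fp / (fp + tn), NA_real_),
    fnr = ifelse(fn + tp > 0, fn / (fn + tp), NA_real_)
  )
}

#' Match common-CNV calls across callers
#'
#' Pairwise matching of calls from different callers at a combined-span
#' overlap fraction of at least `threshold` (default 0.5 — the stricter rule
#' used when a single qPCR probe must represent all callers' versions of a
#' common CNV), followed by transitive closure into cross-caller
#' equivalence classes usable for per-caller frequency tabulation.
#'
#' @param calls Call-set tibble with a `caller` column (two or more
#'   labels). Matching is positional: sample identity is ignored, since a
#'   common-CNV region is a property of the locus.
#' @param threshold Overlap-fraction threshold; default 0.5.
#' @return `calls` with an added `group` column (integer equivalence-class
#'   id).
#' @export
match_common_cnv <- function(calls, threshold = 0.5) {
  n <- nrow(calls)
  calls$group <- seq_len(n)
  if (n == 0) return(calls)
  hits <- GenomicRanges::findOverlaps(as_granges(calls), drop.self = TRUE,
                                      drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- calls$caller[qi] != calls$caller[si]
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) > 0) {
    frac <- overlap_fraction(calls[qi, c("chrom", "start", "end")],
                             calls[si, c("chrom", "start", "end")])
    keep <- frac >= threshold
    qi <- qi[keep]; si <- si[keep]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(qi) > 0) g <- igraph::add_edges(g, rbind(qi, si))
  calls$group <- as.integer(igraph::components(g)$membership)
  calls
}
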