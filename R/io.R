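#' Read a CNV call set
#'
#' Two explicit dialects are supported; the coordinate convention is never
#' auto-detected (off-by-one mistakes are the dominant failure mode when
#' comparing CNV sets):
#'
#' * `"bed"`: headerless, tab-separated, 0-based half-open columns
#'   `chrom start end sample_id copy_number lod`.
#' * `"tsv"`: headered, tab-separated, 1-based inclusive coordinates, with
#'   columns `sample_id`, `chrom`, `start`, `end`, `copy_number` and
#'   optionally `lod`. Converted to the internal 0-based half-open
#'   convention on load.
#'
#' Exact duplicate records (same sample, interval and copy number) are
#' dropped with a message. Missing mandatory columns are a hard error;
#' unknown chromosome labels are kept verbatim (subject to `chrom_style`).
#'
#' @param path File to read.
#' @param caller Caller label attached to every record.
#' @param dialect `"bed"` or `"tsv"` (see above).
#' @param chrom_style `"keep"` (default), `"chr"` (ensure `chr` prefix) or
#'   `"plain"` (strip it).
#' @return A call-set tibble: `sample_id`, `chrom`, `start`, `end`,
#'   `copy_number`, `lod`, `caller`, with attribute `source_path`.
#' @export
read_callset <- function(path, caller, dialect = c("tsv", "bed"),
                         chrom_style = c("keep", "chr", "plain")) {
  dialect <- match.arg(dialect)
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (dialect == "bed") {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 5) {
      rlang::abort("BED dialect needs >= 5 columns: chrom start end sample_id copy_number [lod]")
    }
    if (ncol(raw) < 6) raw$V6 <- NA_real_
    x <- tibble::tibble(
      sample_id = as.character(raw[[4]]),
      chrom = as.character(raw[[1]]),
      start = as.numeric(raw[[2]]),
      end = as.numeric(raw[[3]]),
      copy_number = as.integer(raw[[5]]),
      lod = suppressWarnings(as.numeric(raw[[6]]))
    )
  } else {
    raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(raw) <- tolower(names(raw))
    if ("sample" %in% names(raw) && !"sample_id" %in% names(raw)) {
      raw$sample_id <- raw$sample
    }
    if ("cn" %in% names(raw) && !"copy_number" %in% names(raw)) {
      raw$copy_number <- raw$cn
    }
    need <- c("sample_id", "chrom", "start", "end", "copy_number")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      rlang::abort(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")))
    }
    if (!"lod" %in% names(raw)) raw$lod <- NA_real_
    x <- tibble::tibble(
      sample_id = as.character(raw$sample_id),
      chrom = as.character(raw$chrom),
      # 1-based inclusive -> 0-based half-open
      start = as.numeric(raw$start) - 1,
      end = as.numeric(raw$end),
      copy_number = as.integer(raw$copy_number),
      lod = suppressWarnings(as.numeric(raw$lod))
    )
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start >= x$end |
                 is.na(x$copy_number) | x$copy_number < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed call rows (invalid interval or copy number) at line(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  x$chrom <- normalize_chrom(x$chrom, chrom_style)
  x$caller <- as.character(caller)
  n_in <- nrow(x)
  x <- dplyr::distinct(x, .data$sample_id, .data$caller, .data$chrom,
                       .data$start, .data$end, .data$copy_number,
                       .keep_all = TRUE)
  if (nrow(x) < n_in) {
    rlang::inform(sprintf("read_callset: dropped %d exact duplicate record(s)", n_in - nrow(x)))
  }
  attr(x, "source_path") <- path
  x
}

#' Write a call set in a given dialect
#'
#' Inverse of [read_callset()]: `"bed"` writes headerless 0-based half-open,
#' `"tsv"` writes headered 1-based inclusive coordinates.
#'
#' @param calls Call-set tibble.
#' @param path Output file.
#' @param dialect `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_callset <- function(calls, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    out <- data.frame(
      chrom = calls$chrom, start = calls$start, end = calls$end,
      sample_id = calls$sample_id, copy_number = calls$copy_number,
      lod = calls$lod
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    out <- data.frame(
      sample_id = calls$sample_id, chrom = calls$chrom,
      start = calls$start + 1, end = calls$end,
      copy_number = calls$copy_number, lod = calls$lod
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

normalize_chrom <- function(x, style = c("keep", "chr", "plain")) {
  style <- match.arg(style)
  switch(style,
    keep = x,
    chr = ifelse(grepl("^chr", x), x, paste0("chr", x)),
    plain = sub("^chr", "", x)
  )
}

#' Filter a call set by LOD score
#'
#' Retains calls with `lod >= min_lod`. Calls without a LOD value are
#' retained by default — segmentation-based callers emit none — unless
#' `strict = TRUE`. Input, output and removed counts are reported.
#'
#' @param calls Call-set tibble.
#' @param min_lod Non-negative threshold (the conventional values are 5 for
#'   recovery testing and 10 for cohort-level filtering).
#' @param strict If `TRUE`, calls lacking a LOD are removed too.
#' @return The filtered call-set tibble.
#' @export
filter_by_lod <- function(calls, min_lod, strict = FALSE) {
  if (min_lod < 0) rlang::abort("min_lod must be >= 0")
  n_in <- nrow(calls)
  keep <- if (strict) {
    !is.na(calls$lod) & calls$lod >= min_lod
  } else {
    is.na(calls$lod) | calls$lod >= min_lod
  }
  out <- calls[keep, , drop = FALSE]
  n_missing <- sum(is.na(calls$lod))
  rlang::inform(sprintf(
    "filter_by_lod(min_lod=%g, strict=%s): %d in, %d retained, %d removed (%d without LOD)",
    min_lod, strict, n_in, nrow(out), n_in - nrow(out), n_missing
  ))
  stopifnot(n_in == nrow(out) + (n_in - nrow(out)))
  out
}

#' Read a probe manifest
#'
#' Headered TSV with columns `chrom`, `pos` (1-based position; stored
#' 0-based) and `probe_id`. Positions are sorted on load; duplicate probe
#' ids are a hard error.
#'
#' @param path File to read.
#' @return Probe-map tibble `chrom`, `pos`, `probe_id`, sorted by chromosome
#'   then position.
#' @export
read_probe_manifest <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if ("position" %in% names(raw) && !"pos" %in% names(raw)) raw$pos <- raw$position
  need <- c("chrom", "pos", "probe_id")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("probe manifest missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(raw$probe_id)) rlang::abort("duplicate probe ids in manifest")
  tibble::tibble(
    chrom = as.character(raw$chrom),
    pos = as.numeric(raw$pos) - 1,
    probe_id = as.character(raw$probe_id)
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

state_synonyms <- c(
  deletion = "deletion", del = "deletion", loss = "deletion",
  duplication = "duplication", dup = "duplication", gain = "duplication",
  unknown = "unknown", cnv = "unknown", na = "unknown"
)

#' Read a reference (truth-set) CNV table
#'
#' Headered TSV with columns `sample_id`, `chrom`, `start`, `end` (1-based
#' inclusive) and `state`. State tokens are mapped through a synonym table
#' (`loss`/`del` -> deletion, `gain`/`dup` -> duplication, `cnv`/`na` ->
#' unknown); unrecognised tokens are an error.
#'
#' @param path File to read.
#' @param source Label recorded in the `source` column (e.g. a truth-set
#'   name).
#' @return Reference tibble `ref_id`, `sample_id`, `chrom`, `start`, `end`,
#'   `state`, `source`.
#' @export
read_truthset <- function(path, source) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if ("sample" %in% names(raw) && !"sample_id" %in% names(raw)) raw$sample_id <- raw$sample
  need <- c("sample_id", "chrom", "start", "end", "state")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("truth set missing column(s): ", paste(miss, collapse = ", ")))
  }
  tok <- tolower(trimws(as.character(raw$state)))
  state <- unname(state_synonyms[tok])
  if (any(is.na(state))) {
    rlang::abort(paste0(
      "unrecognised state token(s): ",
      paste(unique(tok[is.na(state)]), collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    sample_id = as.character(raw$sample_id),
    chrom = as.character(raw$chrom),
    start = as.numeric(raw$start) - 1,
    end = as.numeric(raw$end),
    state = state,
    source = as.character(source)
  )
  if (any(out$start >= out$end)) rlang::abort("truth set contains zero/negative-length intervals")
  ensure_id(out, "ref_id", "ref")
}

#' Read a sample-to-plate assignment table
#'
#' Headered TSV with columns `sample_id` and `plate`. A sample appearing on
#' more than one plate is a hard error.
#'
#' @param path File to read.
#' @return Tibble `sample_id`, `plate`.
#' @export
read_plate_map <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("sample_id", "plate")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("plate map missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(raw$sample_id)) {
    rlang::abort("plate map assigns some sample to more than one plate")
  }
  tibble::tibble(sample_id = as.character(raw$sample_id),
                 plate = as.character(raw$plate))
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample_id`, `assay_id`, `ct_target`, `ct_control`,
#' `calibrator` (logical or 0/1 marking the 2-copy reference sample).
#' Ct values must be finite and positive; every assay needs at least one
#' calibrator row.
#'
#' @param path File to read.
#' @return Tibble of qPCR measurements.
#' @export
read_qpcr <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("sample_id", "assay_id", "ct_target", "ct_control", "calibrator")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("qPCR table missing column(s): ", paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = as.character(raw$sample_id),
    assay_id = as.character(raw$assay_id),
    ct_target = as.numeric(raw$ct_target),
    ct_control = as.numeric(raw$ct_control),
    calibrator = as.logical(raw$calibrator)
  )
  ct <- c(out$ct_target, out$ct_control)
  if (any(!is.finite(ct) | ct <= 0)) {
    rlang::abort("Ct values must be finite and > 0")
  }
  n_cal <- tapply(out$calibrator, out$assay_id, sum)
  if (any(n_cal == 0)) {
    rlang::abort(paste0(
      "assay(s) without a calibrator sample: ",
      paste(names(n_cal)[n_cal == 0], collapse = ", ")
    ))
  }
  out
}

#' @importFrom utils read.csv
NULL
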