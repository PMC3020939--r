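# Brute-force per-basepair oracles, independent of the interval arithmetic
# they check: an interval [start, end) is represented as the explicit set of
# covered base pairs.

bp_set <- function(start, end) seq.int(start, end - 1)

oracle_intersection <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(bp_set(a$start, a$end), bp_set(b$start, b$end)))
}

oracle_union <- function(a, b) {
  length(union(bp_set(a$start, a$end), bp_set(b$start, b$end)))
}

oracle_fraction <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  oracle_intersection(a, b) / oracle_union(a, b)
}

# Exhaustive all-pairs matcher: a reference is recovered iff some variant
# call in the same sample passes the per-basepair fraction threshold (and,
# optionally, matches the reference state).
oracle_match <- function(refs, calls, threshold = 0.25, require_state = FALSE) {
  vapply(seq_len(nrow(refs)), function(i) {
    r <- refs[i, ]
    hit <- FALSE
    for (j in seq_len(nrow(calls))) {
      cl <- calls[j, ]
      if (cl$copy_number == 2) next
      if (cl$sample_id != r$sample_id) next
      if (cl$chrom != r$chrom) next
      if (oracle_fraction(r, cl) < threshold) next
      if (require_state) {
        st <- if (cl$copy_number < 2) "deletion" else "duplication"
        if (st != r$state) next
      }
      hit <- TRUE
      break
    }
    hit
  }, logical(1))
}

# Random intervals on a toy chromosome set.
random_intervals <- function(n, chroms = c("chrA", "chrB"), chrom_len = 10000,
                             max_len = 2000) {
  start <- floor(runif(n, 0, chrom_len - 2))
  len <- pmax(1, floor(runif(n, 1, max_len)))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = pmin(chrom_len, start + len)
  )
}

random_callset <- function(n, samples, chroms = c("chrA", "chrB"),
                           chrom_len = 10000) {
  x <- random_intervals(n, chroms, chrom_len)
  x$sample_id <- sample(samples, n, replace = TRUE)
  x$copy_number <- sample(c(0L, 1L, 2L, 3L, 4L), n, replace = TRUE)
  x$lod <- stats::rlnorm(n, 2, 0.5)
  x$caller <- "sim"
  x
}

random_truthset <- function(n, samples, chroms = c("chrA", "chrB"),
                            chrom_len = 10000) {
  x <- random_intervals(n, chroms, chrom_len)
  x$sample_id <- sample(samples, n, replace = TRUE)
  x$state <- sample(c("deletion", "duplication"), n, replace = TRUE)
  x$ref_id <- sprintf("ref%05d", seq_len(n))
  x
}
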