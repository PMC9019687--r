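# Tandem-repeat array detection (telomeric and rDNA-scale), telomere calls,
# and copy-number estimation from spanning long reads.
#
# Two-tier detection: small periods (<= 64 bp) by per-position lag matching
# with single-mismatch bridging; large periods by self k-mer spacing
# histograms verified with lag profiles. Array boundaries are maximal runs
# of lag matches, with trailing partial units kept only when at least half
# a unit is present.

#' Canonical form of a tandem-repeat unit
#'
#' The lexicographically smallest string among all rotations of the unit and
#' of its reverse complement; idempotent, and identical for the two strand
#' readings of the same array (e.g. the 5'-telomere unit `ACCCCGCC` and the
#' 3' unit `GGCGGGGT` share one canonical form).
#'
#' @param unit Non-empty DNA string.
#' @return Canonical unit string.
#' @export
canonical_unit <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1, nchar(unit) > 0)
  u <- toupper(unit)
  min(c(rotations(u), rotations(revcomp(u))))
}

rotations <- function(s) {
  n <- nchar(s)
  if (n == 1) return(s)
  d <- paste0(s, s)
  substring(d, 1:n, n:(2 * n - 1))
}

#' Find tandem-repeat arrays in a sequence
#'
#' @param seq DNA string (one contig or window).
#' @param min_unit,max_unit Unit-length search range (bp).
#' @param min_copies Minimum copy number (the large-period tier additionally
#'   requires at least 3 copies so that two-copy segmental duplications are
#'   not reported as tandem arrays).
#' @param min_purity Minimum identity of the array to a perfect repeat of
#'   its unit.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `unit` (canonical), `unit_length`, `copy_number` (1 decimal), `purity`,
#'   `strand` (strand of the reported unit).
#' @export
find_tandem_arrays <- function(seq, min_unit = 4L, max_unit = 10000L,
                               min_copies = 3, min_purity = 0.9) {
  stopifnot(nchar(seq) >= 2 * min_unit)
  n <- nchar(seq)
  cand <- list()
  small_max <- min(64L, max_unit)
  if (min_unit <= small_max) {
    df <- cpp_small_period_arrays(seq, as.integer(min_unit),
                                  as.integer(small_max), min_copies,
                                  min_purity)
    if (nrow(df) > 0) cand[[length(cand) + 1L]] <- df
  }
  if (max_unit > 64L && n >= 2L * 65L) {
    sp <- cpp_kmer_self_spacings(seq, 13L, 65L, as.integer(max_unit), 2048L)
    if (nrow(sp) > 0) {
      tab <- table(sp$d)
      dv <- as.integer(names(tab))
      dv <- dv[as.integer(tab) >= pmax(30, 0.6 * dv)]
      rows <- list()
      for (d in dv) {
        pos <- sort(sp$pos[sp$d == d])
        grp <- cumsum(c(TRUE, diff(pos) > d))
        for (gi in unique(grp)) {
          pp <- pos[grp == gi]
          if (length(pp) < 0.5 * d) next
          L <- min(pp)
          R <- max(pp) + 13L   # exclusive end of lag-matched stretch
          lag_ok <- function(i) {
            substr(seq, i + 1L, i + 1L) == substr(seq, i + d + 1L, i + d + 1L)
          }
          while (L > 0L && lag_ok(L - 1L)) L <- L - 1L
          while (R + d < n && lag_ok(R)) R <- R + 1L
          v <- cpp_lag_matches(seq, d, L, R + d)
          mism <- sum(!v)
          rows[[length(rows) + 1L]] <-
            data.frame(start = L, end = R + d, period = d, mismatch = mism)
        }
      }
      if (length(rows)) cand[[length(cand) + 1L]] <- do.call(rbind, rows)
    }
  }
  if (length(cand) == 0) return(empty_tandem_df())
  df <- do.call(rbind, cand)
  # keep trailing partial units only when at least half a unit is present
  span <- df$end - df$start
  rem <- span %% df$period
  trim <- ifelse(rem < df$period / 2, rem, 0L)
  df$end <- df$end - trim
  span <- df$end - df$start
  df$copy_number <- round(span / df$period, 1)
  df$purity <- 1 - df$mismatch / span
  df <- df[span >= pmax(min_copies, ifelse(df$period > 64L, 3, min_copies)) *
             df$period & df$purity >= min_purity, , drop = FALSE]
  if (nrow(df) == 0) return(empty_tandem_df())
  # resolve overlaps: highest purity, then longest, then smallest period
  df <- df[order(-df$purity, -(df$end - df$start), df$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      for (j in seq(i + 1L, nrow(df))) {
        if (!keep[j]) next
        ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
        if (ov > 0.5 * min(df$end[i] - df$start[i],
                           df$end[j] - df$start[j])) {
          keep[j] <- FALSE
        }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  units <- substring(seq, df$start + 1L, df$start + df$period)
  canon <- vapply(units, canonical_unit, character(1), USE.NAMES = FALSE)
  strand <- vapply(seq_along(units), function(i) {
    if (canon[i] %in% rotations(units[i])) "+" else "-"
  }, character(1))
  out <- data.frame(start = df$start, end = df$end, unit = canon,
                    unit_length = df$period, copy_number = df$copy_number,
                    purity = df$purity, strand = strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_tandem_df <- function() {
  data.frame(start = integer(0), end = integer(0), unit = character(0),
             unit_length = integer(0), copy_number = numeric(0),
             purity = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Call telomeric tandem-repeat arrays at chromosome ends
#'
#' Searches the terminal windows of every contig for a tandem array whose
#' canonical unit matches the expected telomere unit (or any unit of at most
#' 16 bp when `expected_unit` is `NULL`), anchored within `end_slack` of the
#' terminus; at most one call per end.
#'
#' @param g A `Genome`.
#' @param expected_unit Expected repeat unit, or `NULL`.
#' @param end_window Window searched at each terminus (bp).
#' @param end_slack Maximum distance of the array from the terminus (bp).
#' @return data.frame with one row per called end: `contig`, `side`,
#'   `start`, `end`, `length`, `unit`, `unit_length`, `copy_number`,
#'   `purity`.
#' @export
call_telomeres <- function(g, expected_unit = "ACCCCGCC",
                           end_window = 1000L, end_slack = 100L) {
  stopifnot(inherits(g, "Genome"))
  exp_canon <- if (is.null(expected_unit)) NULL else
    canonical_unit(expected_unit)
  calls <- list()
  for (nm in names(g$contigs)) {
    s <- g$contigs[[nm]]
    len <- nchar(s)
    win <- min(end_window, len)
    for (side in c("5prime", "3prime")) {
      wseq <- if (side == "5prime") substr(s, 1L, win) else
        substr(s, len - win + 1L, len)
      off <- if (side == "5prime") 0L else len - win
      arr <- find_tandem_arrays(wseq, min_unit = 4L, max_unit = 16L,
                                min_copies = 3, min_purity = 0.9)
      if (nrow(arr) == 0) next
      if (!is.null(exp_canon)) arr <- arr[arr$unit == exp_canon, ,
                                          drop = FALSE]
      arr <- if (side == "5prime") {
        arr[arr$start <= end_slack, , drop = FALSE]
      } else {
        arr[arr$end >= win - end_slack, , drop = FALSE]
      }
      if (nrow(arr) == 0) next
      arr <- arr[which.max(arr$end - arr$start), , drop = FALSE]
      calls[[length(calls) + 1L]] <- data.frame(
        contig = nm, side = side, start = arr$start + off,
        end = arr$end + off, length = arr$end - arr$start,
        unit = arr$unit, unit_length = arr$unit_length,
        copy_number = arr$copy_number, purity = arr$purity,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) {
    return(data.frame(contig = character(0), side = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), unit = character(0),
                      unit_length = integer(0), copy_number = numeric(0),
                      purity = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# greedy unit walk between 0-based positions from and to of s, tolerating
# one edit per unit for short units and proportionally (5%) for long units;
# indel drift is absorbed by fitting each unit into a slightly longer window
walk_units <- function(s, from, to, unit, tol = NULL) {
  ulen <- nchar(unit)
  if (is.null(tol)) tol <- max(1L, as.integer(ceiling(0.05 * ulen)))
  pos <- from
  count <- 0L
  while (to - pos >= ulen - tol) {
    wlen <- min(ulen + tol + 4L, nchar(s) - pos)
    if (wlen < ulen - tol) break
    f <- cpp_fit_align(substr(s, pos + 1L, pos + wlen), unit,
                       as.integer(tol + 8L))
    if (f$edit > tol || f$a_start > tol || f$a_end <= f$a_start) break
    count <- count + 1L
    pos <- pos + f$a_end
  }
  count
}

#' Estimate tandem-array copy number from spanning long reads
#'
#' For every read of at least `min_read_len` bases that contains both flank
#' sequences (on either strand), unit copies between the flanks are counted
#' by a greedy unit walk tolerating one edit per unit; the estimate is the
#' median of the per-read integer counts.
#'
#' @param reads A `ReadSet`.
#' @param unit Repeat unit.
#' @param flankL,flankR Unique flanking sequences (>= 20 bp) immediately
#'   outside the array, in genome orientation.
#' @param min_read_len Minimum read length considered.
#' @return A list of class `CopyNumberEstimate` with fields `unit`,
#'   `per_read_counts`, `median`, `mean_array_length`,
#'   `n_informative_reads`. When no read spans the array the median is `NA`
#'   (an explicit "no estimate").
#' @export
estimate_copy_number_from_reads <- function(reads, unit, flankL, flankR,
                                            min_read_len = 20000L) {
  stopifnot(inherits(reads, "ReadSet"), nchar(flankL) >= 20,
            nchar(flankR) >= 20)
  counts <- integer(0)
  spans <- integer(0)
  mmL <- max(1L, nchar(flankL) %/% 10L)
  mmR <- max(1L, nchar(flankR) %/% 10L)
  for (s in reads$seqs) {
    if (nchar(s) < min_read_len) next
    for (orient in 1:2) {
      q <- if (orient == 1L) s else revcomp(s)
      hitL <- Biostrings::matchPattern(flankL, Biostrings::DNAString(q),
                                       max.mismatch = mmL,
                                       with.indels = TRUE)
      if (length(hitL) == 0) next
      hitR <- Biostrings::matchPattern(flankR, Biostrings::DNAString(q),
                                       max.mismatch = mmR,
                                       with.indels = TRUE)
      if (length(hitR) == 0) next
      from <- Biostrings::end(hitL)[1]          # 0-based pos after flankL
      to <- Biostrings::start(hitR)[length(hitR)] - 1L  # 0-based start of flankR
      if (to <= from) next
      counts <- c(counts, walk_units(q, from, to, unit))
      spans <- c(spans, to - from)
      break
    }
  }
  structure(list(unit = unit, per_read_counts = counts,
                 median = if (length(counts)) stats::median(counts) else NA_real_,
                 mean_array_length = if (length(spans)) mean(spans) else NA_real_,
                 n_informative_reads = length(counts)),
            class = "CopyNumberEstimate")
}

#' @export
print.CopyNumberEstimate <- function(x, ...) {
  if (x$n_informative_reads == 0) {
    cat("CopyNumberEstimate: no estimate (no informative spanning read)\n")
  } else {
    cat(sprintf(
      "CopyNumberEstimate: median %.1f copies (%d informative reads, mean array %.0f bp)\n",
      x$median, x$n_informative_reads, x$mean_array_length))
  }
  invisible(x)
}
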