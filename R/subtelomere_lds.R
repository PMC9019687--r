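# Discovery of large duplicated segments (LDSs) near chromosome ends:
# shared k-mer anchoring between end windows, collinear chaining, banded
# global alignment for exact mismatch/gap accounting, and detection of
# telomere-like motifs at segment 3' ends.

#' Extract subtelomeric end windows
#'
#' @param g A `Genome`.
#' @param window Window size (bp); must be at most half the shortest contig.
#' @return data.frame `contig`, `start`, `end`, `side`.
#' @export
extract_end_windows <- function(g, window = 50000L) {
  stopifnot(inherits(g, "Genome"))
  if (window > min(nchar(g$contigs)) / 2) {
    stop("window exceeds half the shortest contig")
  }
  out <- do.call(rbind, lapply(names(g$contigs), function(nm) {
    len <- nchar(g$contigs[[nm]])
    data.frame(contig = nm, start = c(0L, len - as.integer(window)),
               end = c(as.integer(window), len),
               side = c("5prime", "3prime"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

empty_lds_df <- function() {
  data.frame(contig_a = character(0), start_a = integer(0),
             end_a = integer(0), contig_b = character(0),
             start_b = integer(0), end_b = integer(0),
             orientation = character(0), identity = numeric(0),
             n_mismatch = integer(0), n_gap_columns = integer(0),
             columns = integer(0), end_distance_a = integer(0),
             end_distance_b = integer(0), terminal_motif = character(0),
             terminal_motif_copies = numeric(0), stringsAsFactors = FALSE)
}

# chain anchors (apos,bpos) on one orientation into diagonal clusters;
# clusters additionally split at positional gaps larger than max_pos_gap so
# that distinct repeats on nearby diagonals stay distinct
chain_anchors <- function(apos, bpos, k, max_diag_gap = 50L,
                          min_anchors = 10L, max_pos_gap = Inf) {
  if (length(apos) == 0) return(list())
  diag <- apos - bpos
  ord <- order(diag, apos)
  diag <- diag[ord]; a <- apos[ord]; b <- bpos[ord]
  grp <- cumsum(c(TRUE, diff(diag) > max_diag_gap))
  out <- list()
  for (gi in unique(grp)) {
    sel <- which(grp == gi)
    sel <- sel[order(a[sel])]
    sub <- cumsum(c(TRUE, diff(a[sel]) > max_pos_gap))
    for (si in unique(sub)) {
      ss <- sel[sub == si]
      if (length(ss) < min_anchors) next
      # keep only a longest co-linear run (strictly increasing in both
      # coordinates): off-diagonal anchors from local tandem repeats would
      # otherwise corrupt the chain endpoints
      ss <- ss[order(a[ss], b[ss])]
      keep <- cpp_lis(as.integer(b[ss]))
      ss <- ss[keep]
      if (length(ss) < min_anchors) next
      first <- ss[1L]
      last <- ss[length(ss)]
      out[[length(out) + 1L]] <- list(
        a_start = a[first], a_end = a[last] + k,
        b_start = b[first], b_end = b[last] + k,
        n = length(ss))
    }
  }
  out
}

#' Find large duplicated segments between end windows
#'
#' All-vs-all comparison of distinct windows: shared k-mer anchors are
#' chained by diagonal (same or inverted orientation), chained spans are
#' extended to their maximal exact boundaries and aligned with a banded
#' global aligner; mismatch and gap-column counts come from that alignment
#' (identity = 1 - (mismatches + gap columns) / alignment columns). Mirror
#' duplicates are removed by canonical ordering (lexicographically smaller
#' (contig, start) first).
#'
#' @param g A `Genome`.
#' @param windows data.frame from [extract_end_windows()].
#' @param min_len Minimum segment length (bp).
#' @param min_identity Minimum identity.
#' @param k Anchor k-mer length.
#' @return data.frame of segments (see [empty_lds_df()] columns); inverted
#'   orientation duplications are reported but flagged.
#' @export
find_duplicated_segments <- function(g, windows = extract_end_windows(g),
                                     min_len = 2000L, min_identity = 0.99,
                                     k = 15L) {
  stopifnot(inherits(g, "Genome"))
  segs <- list()
  nw <- nrow(windows)
  for (i in seq_len(nw - 1L)) {
    for (j in seq(i + 1L, nw)) {
      wa <- windows[i, ]; wb <- windows[j, ]
      sa <- subseq_chr(g$contigs[[wa$contig]], wa$start, wa$end)
      sb <- subseq_chr(g$contigs[[wb$contig]], wb$start, wb$end)
      for (orient in c("same", "inverted")) {
        sb2 <- if (orient == "same") sb else revcomp(sb)
        anc <- cpp_kmer_matches(sa, sb2, as.integer(k), 4L)
        chains <- chain_anchors(anc$apos, anc$bpos, k)
        for (ch in chains) {
          if (ch$a_end - ch$a_start < 0.5 * min_len) next
          # maximal exact extension of the chained span
          as0 <- ch$a_start; ae <- ch$a_end
          bs0 <- ch$b_start; be <- ch$b_end
          while (as0 > 0 && bs0 > 0 &&
                 substr(sa, as0, as0) == substr(sb2, bs0, bs0)) {
            as0 <- as0 - 1L; bs0 <- bs0 - 1L
          }
          while (ae < nchar(sa) && be < nchar(sb2) &&
                 substr(sa, ae + 1L, ae + 1L) ==
                 substr(sb2, be + 1L, be + 1L)) {
            ae <- ae + 1L; be <- be + 1L
          }
          band <- abs((ae - as0) - (be - bs0)) + 32L
          al <- cpp_banded_align(substr(sa, as0 + 1L, ae),
                                 substr(sb2, bs0 + 1L, be), band)
          # terminal indel columns are boundary-phase artifacts of the
          # anchor chain, not segment divergence: trim them off
          ops <- parse_cigar(al$cigar)
          while (nrow(ops) > 0 && ops$op[1] %in% c("I", "D")) {
            if (ops$op[1] == "D") as0 <- as0 + ops$len[1]
            else bs0 <- bs0 + ops$len[1]
            al$n_gap_columns <- al$n_gap_columns - ops$len[1]
            al$columns <- al$columns - ops$len[1]
            ops <- ops[-1, , drop = FALSE]
          }
          while (nrow(ops) > 0 && ops$op[nrow(ops)] %in% c("I", "D")) {
            nop <- nrow(ops)
            if (ops$op[nop] == "D") ae <- ae - ops$len[nop]
            else be <- be - ops$len[nop]
            al$n_gap_columns <- al$n_gap_columns - ops$len[nop]
            al$columns <- al$columns - ops$len[nop]
            ops <- ops[-nop, , drop = FALSE]
          }
          identity <- 1 - (al$n_mismatch + al$n_gap_columns) / al$columns
          if (al$columns < min_len || identity < min_identity) next
          # map window-local to genome coordinates
          ga <- c(wa$start + as0, wa$start + ae)
          gb <- if (orient == "same") {
            c(wb$start + bs0, wb$start + be)
          } else {
            c(wb$start + nchar(sb) - be, wb$start + nchar(sb) - bs0)
          }
          segs[[length(segs) + 1L]] <- data.frame(
            contig_a = wa$contig, start_a = ga[1], end_a = ga[2],
            contig_b = wb$contig, start_b = gb[1], end_b = gb[2],
            orientation = orient, identity = identity,
            n_mismatch = al$n_mismatch, n_gap_columns = al$n_gap_columns,
            columns = al$columns, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(segs) == 0) return(empty_lds_df())
  df <- do.call(rbind, segs)
  # canonical ordering and duplicate removal (same pair found from both
  # directions or via overlapping chains): keep the longest alignment
  swap <- paste(df$contig_a, df$start_a) > paste(df$contig_b, df$start_b)
  if (any(swap)) {
    tmp <- df[swap, c("contig_a", "start_a", "end_a")]
    df[swap, c("contig_a", "start_a", "end_a")] <-
      df[swap, c("contig_b", "start_b", "end_b")]
    df[swap, c("contig_b", "start_b", "end_b")] <- tmp
  }
  df <- df[order(-df$columns), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (x in seq_len(nrow(df))) {
    if (!keep[x]) next
    if (x < nrow(df)) {
      for (y in seq(x + 1L, nrow(df))) {
        if (!keep[y]) next
        same_a <- df$contig_a[x] == df$contig_a[y] &&
          overlaps(df$start_a[x], df$end_a[x], df$start_a[y], df$end_a[y])
        same_b <- df$contig_b[x] == df$contig_b[y] &&
          overlaps(df$start_b[x], df$end_b[x], df$start_b[y], df$end_b[y])
        if (same_a && same_b) keep[y] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  lens <- nchar(g$contigs)
  df$end_distance_a <- pmin(df$start_a, lens[df$contig_a] - df$end_a)
  df$end_distance_b <- pmin(df$start_b, lens[df$contig_b] - df$end_b)
  df$terminal_motif <- "none"
  df$terminal_motif_copies <- 0
  df <- df[order(df$contig_a, df$start_a), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# count tandem copies of motif whose run ends exactly at the 3' end of the
# last 200 bp of the segment (searching the terminal window)
terminal_motif_copies <- function(seq3p, motif) {
  win <- 200L
  w <- substr(seq3p, max(1L, nchar(seq3p) - win + 1L), nchar(seq3p))
  m <- gregexpr(sprintf("(?:%s)+", motif), w)[[1]]
  if (m[1] == -1) return(0)
  max(attr(m, "match.length")) / nchar(motif)
}

#' Detect telomere-like motifs at segment 3' ends
#'
#' Searches the 3'-terminal 200 bp of each segment copy (on the segment's
#' own orientation) for a tandem run of the full telomere unit or its
#' degenerate 7-mer; a motif is called when strictly more than `min_copies`
#' copies are present.
#'
#' @param segments data.frame from [find_duplicated_segments()].
#' @param g The `Genome`.
#' @param motifs Candidate motifs, in priority order.
#' @param min_copies Copies required (exclusive bound; default 2 encodes
#'   "more than 2 copies").
#' @return `segments` with `terminal_motif` and `terminal_motif_copies`
#'   filled in.
#' @export
detect_terminal_motif <- function(segments, g,
                                  motifs = c("ACCCCGCC", "ACCCGCC"),
                                  min_copies = 2.0) {
  if (nrow(segments) == 0) return(segments)
  for (i in seq_len(nrow(segments))) {
    seqa <- subseq_chr(g$contigs[[segments$contig_a[i]]],
                       segments$start_a[i], segments$end_a[i])
    seqb <- subseq_chr(g$contigs[[segments$contig_b[i]]],
                       segments$start_b[i], segments$end_b[i])
    if (segments$orientation[i] == "inverted") seqb <- revcomp(seqb)
    for (motif in motifs) {
      copies <- terminal_motif_copies(seqa, motif)
      if (copies <= min_copies) copies <- terminal_motif_copies(seqb, motif)
      if (copies > min_copies) {
        segments$terminal_motif[i] <-
          if (motif == motifs[1]) "full_unit" else "degenerate_unit"
        segments$terminal_motif_copies[i] <- round(copies, 1)
        break
      }
    }
  }
  segments
}

#' Count long reads spanning a junction
#'
#' A junction passes when at least `policy$min_junction_span_reads` long
#' reads (of at least `policy$long_read_min` bases) have alignments covering
#' `position` plus `flank` on both sides.
#'
#' @param junction list with `contig`, `position`, and optional `flank`
#'   (defaults to `policy$junction_flank`).
#' @param read_alignments `Alignments` of long reads.
#' @param policy A [curation_policy()].
#' @param assembly Optional `Genome` for bounds checking.
#' @return list `n_spanning`, `pass`.
#' @export
verify_junction_support <- function(junction, read_alignments,
                                    policy = curation_policy(),
                                    assembly = NULL) {
  stopifnot(inherits(read_alignments, "Alignments"))
  flank <- if (is.null(junction$flank)) policy$junction_flank else
    junction$flank
  pos <- junction$position
  if (!is.null(assembly)) {
    len <- nchar(assembly$contigs[[junction$contig]])
    if (is.null(len) || pos < 0 || pos > len) {
      stop("junction position outside contig")
    }
  }
  df <- read_alignments$aln
  sel <- df$status == "mapped" & df$read_len >= policy$long_read_min &
    !is.na(df$contig) & df$contig == junction$contig &
    df$ref_start <= pos - flank & df$ref_end >= pos + flank
  n <- sum(sel, na.rm = TRUE)
  list(n_spanning = as.integer(n),
       pass = n >= policy$min_junction_span_reads)
}
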