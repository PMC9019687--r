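# Iterative short-read pileup-consensus polishing with poly(GC) protection,
# followed by long-read curation under explicit read-support thresholds.

#' Curation policy thresholds
#'
#' Encodes the evidence rules used throughout curation: a corrected base must
#' be confirmed by more than 5 long reads (`min_confirm_reads >= 6`), a
#' junction between large segments must be spanned by at least one long read,
#' poly(GC) regions are G/C runs of more than 10 bases
#' (`polygc_run_min >= 11`), and long reads are those above 20 kb
#' (30 kb for duplicated-segment verification).
#'
#' @param min_confirm_reads Minimum long reads confirming a curation edit.
#' @param min_junction_span_reads Minimum long reads spanning a junction.
#' @param junction_flank Flank (bp) a spanning read must cover on each side.
#' @param polygc_run_min Minimum G/C run length treated as poly(GC).
#' @param long_read_min Minimum long-read length (bp).
#' @param lds_read_min Minimum read length for duplicated-segment checks.
#' @param majority_fraction Plurality fraction required to apply a polish
#'   edit.
#' @param min_depth Minimum pileup depth to consider a column.
#' @param max_rounds Maximum polishing rounds.
#' @return A list of class `CurationPolicy`.
#' @export
curation_policy <- function(min_confirm_reads = 6L,
                            min_junction_span_reads = 1L,
                            junction_flank = 500L,
                            polygc_run_min = 11L,
                            long_read_min = 20000L,
                            lds_read_min = 30000L,
                            majority_fraction = 0.7,
                            min_depth = 4L,
                            max_rounds = 5L) {
  stopifnot(min_confirm_reads >= 6L,  # "more than 5" long reads
            polygc_run_min >= 11L,    # ">10 G or C"
            majority_fraction > 0.5, majority_fraction <= 1,
            min_depth >= 1L, max_rounds >= 1L)
  structure(list(min_confirm_reads = as.integer(min_confirm_reads),
                 min_junction_span_reads = as.integer(min_junction_span_reads),
                 junction_flank = as.integer(junction_flank),
                 polygc_run_min = as.integer(polygc_run_min),
                 long_read_min = as.integer(long_read_min),
                 lds_read_min = as.integer(lds_read_min),
                 majority_fraction = majority_fraction,
                 min_depth = as.integer(min_depth),
                 max_rounds = as.integer(max_rounds)),
            class = "CurationPolicy")
}

#' Detect poly(GC) regions
#'
#' Maximal runs over the alphabet `{G,C}` of at least `run_min` bases
#' (both pure homopolymers and mixed G/C runs; `homopolymer_only = TRUE`
#' restricts to single-base runs).
#'
#' @param g A `Genome`.
#' @param run_min Minimum run length (default 11, i.e. "more than 10").
#' @param homopolymer_only Restrict to pure G-runs/C-runs.
#' @return data.frame `contig`, `start`, `end` (0-based half-open).
#' @export
detect_polygc <- function(g, run_min = 11L, homopolymer_only = FALSE) {
  stopifnot(inherits(g, "Genome"))
  pat <- if (homopolymer_only) {
    sprintf("G{%d,}|C{%d,}", run_min, run_min)
  } else sprintf("[GC]{%d,}", run_min)
  out <- list()
  for (nm in names(g$contigs)) {
    m <- gregexpr(pat, g$contigs[[nm]])[[1]]
    if (m[1] == -1) next
    out[[length(out) + 1L]] <- data.frame(
      contig = nm, start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + attr(m, "match.length"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map reads to an assembly (internal toy mapper)
#'
#' Seed-and-extend mapping intended for synthetic data. Short mode places
#' each read by exact 21-mer seeds and banded fitting alignment; a tie
#' between distinct best loci leaves the read unmapped ("ambiguous") and is
#' counted. Long mode chains reference-unique 21-mer anchors and fills
#' between them with banded alignment, trimming read ends that stop
#' matching (X-drop), so reads from a donor genome do not spuriously span
#' junctions absent from it.
#'
#' @param assembly A `Genome`.
#' @param reads A `ReadSet`.
#' @param mode `"short"` or `"long"`.
#' @param k Seed length.
#' @param band Alignment band for short mode.
#' @param max_edit_frac Maximum edit fraction for a mapped read.
#' @param ext_max Maximum end-extension length in long mode (bp).
#' @return An `Alignments` object: `aln` data.frame (`read`, `contig`,
#'   `ref_start`, `ref_end`, `strand`, `edit`, `cigar`, `status`,
#'   `read_len`), plus the `ReadSet` for pileup.
#' @export
map_reads <- function(assembly, reads, mode = c("short", "long"), k = 21L,
                      band = 8L, max_edit_frac = 0.3, ext_max = 6000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(assembly, "Genome"), inherits(reads, "ReadSet"))
  if (length(reads$seqs) == 0) stop("empty ReadSet")
  df <- cpp_map_reads(unname(assembly$contigs), unname(reads$seqs), mode,
                      as.integer(k), as.integer(band), max_edit_frac,
                      as.integer(ext_max))
  df$read <- names(reads$seqs)
  df$read_len <- nchar(unname(reads$seqs))
  df$contig <- names(assembly$contigs)[df$contig_idx]
  if (!any(df$status == "mapped")) warning("no read mapped")
  structure(list(aln = df, mode = mode, reads = reads,
                 contig_names = names(assembly$contigs),
                 contig_lens = nchar(assembly$contigs)),
            class = "Alignments")
}

#' @export
print.Alignments <- function(x, ...) {
  tab <- table(x$aln$status)
  cat(sprintf("Alignments (%s mode): %d reads; %s\n", x$mode, nrow(x$aln),
              paste(names(tab), as.integer(tab), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# pileup over an assembly; returns list(counts = per-contig 5 x len matrix
# with rows A,C,G,T,del; insertions = data.frame)
pileup <- function(assembly, alignments) {
  stopifnot(inherits(alignments, "Alignments"))
  df <- alignments$aln
  cpp_pileup(unname(assembly$contigs), df$contig_idx, df$ref_start,
             df$strand, df$cigar, unname(alignments$reads$seqs))
}

BASES <- c("A", "C", "G", "T")

# consensus edits for one round; returns data.frame of candidate edits
consensus_edits <- function(assembly, pl, policy, max_ins_len = 50L) {
  out <- list()
  cn <- names(assembly$contigs)
  for (ci in seq_along(cn)) {
    cm <- pl$counts[[ci]]
    len <- ncol(cm)
    if (len == 0) next
    depth <- colSums(cm)
    refv <- match(strsplit(assembly$contigs[[ci]], "")[[1]], BASES)
    m <- t(cm)
    topval <- pmax(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
    refval <- m[cbind(seq_len(len), ifelse(is.na(refv), 1L, refv))]
    nties <- (m[, 1] == topval) + (m[, 2] == topval) + (m[, 3] == topval) +
      (m[, 4] == topval) + (m[, 5] == topval)
    cand <- which(depth >= policy$min_depth & nties == 1L &
                    topval > refval &
                    topval >= policy$majority_fraction * depth)
    if (length(cand)) {
      allele <- max.col(m[cand, , drop = FALSE], ties.method = "first")
      kind <- ifelse(allele == 5L, "del", "sub")
      out[[length(out) + 1L]] <- data.frame(
        contig = cn[ci], pos = cand - 1L, kind = kind,
        from = BASES[refv[cand]],
        to = ifelse(allele == 5L, "", BASES[pmin(allele, 4L)]),
        support = topval[cand], depth = depth[cand],
        stringsAsFactors = FALSE)
    }
  }
  ins <- pl$insertions
  if (nrow(ins) > 0) {
    # best insertion per column
    key <- paste(ins$contig_idx, ins$pos)
    best <- ins[order(key, -ins$count), ]
    best <- best[!duplicated(paste(best$contig_idx, best$pos)), ]
    for (i in seq_len(nrow(best))) {
      ci <- best$contig_idx[i]
      p <- best$pos[i]
      cm <- pl$counts[[ci]]
      if (p + 1L > ncol(cm)) next
      d <- sum(cm[, p + 1L])
      if (d >= policy$min_depth && nchar(best$seq[i]) <= max_ins_len &&
          best$count[i] >= policy$majority_fraction * d) {
        out[[length(out) + 1L]] <- data.frame(
          contig = names(assembly$contigs)[ci], pos = p, kind = "ins",
          from = "", to = best$seq[i], support = best$count[i], depth = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      kind = character(0), from = character(0),
                      to = character(0), support = integer(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$pos), , drop = FALSE]
}

in_protected <- function(edits, protected) {
  if (is.null(protected) || nrow(edits) == 0 ||
      is.null(nrow(protected)) || nrow(protected) == 0) {
    return(rep(FALSE, nrow(edits)))
  }
  vapply(seq_len(nrow(edits)), function(i) {
    p <- protected[protected$contig == edits$contig[i], , drop = FALSE]
    # an insertion keyed at the column before the run start still touches it
    any(edits$pos[i] >= p$start - 1L & edits$pos[i] < p$end)
  }, logical(1))
}

# apply edits (coordinates valid on g) from high to low position
apply_edits <- function(g, edits) {
  if (nrow(edits) == 0) return(g)
  edits <- edits[order(edits$contig, -edits$pos), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    s <- g$contigs[[edits$contig[i]]]
    p <- edits$pos[i]
    s <- switch(edits$kind[i],
                sub = splice_chr(s, p, p + 1L, edits$to[i]),
                del = splice_chr(s, p, p + 1L, ""),
                ins = splice_chr(s, p + 1L, p + 1L, edits$to[i]))
    g$contigs[[edits$contig[i]]] <- s
  }
  g
}

# shift intervals through applied edits (indels change coordinates)
lift_intervals <- function(intervals, edits) {
  if (is.null(intervals) || nrow(intervals) == 0 || nrow(edits) == 0) {
    return(intervals)
  }
  delta <- ifelse(edits$kind == "ins", nchar(edits$to),
                  ifelse(edits$kind == "del", -1L, 0L))
  for (i in seq_len(nrow(intervals))) {
    e <- edits$contig == intervals$contig[i]
    intervals$start[i] <- intervals$start[i] +
      sum(delta[e & edits$pos < intervals$start[i]])
    intervals$end[i] <- intervals$end[i] +
      sum(delta[e & edits$pos < intervals$end[i]])
  }
  intervals
}

#' Iterative short-read pileup-consensus polishing
#'
#' Per column, if depth and plurality thresholds are met and the plurality
#' allele (base, deletion, or insertion) differs from the reference, the
#' edit is applied; ties keep the reference. Edits inside protected
#' intervals (typically poly(GC) runs) are recorded as `deferred_polygc` and
#' not applied. Rounds repeat, remapping the reads each round, until no edit
#' is applied or `max_rounds` is reached. Edit-record coordinates refer to
#' the round's input assembly.
#'
#' @param assembly A `Genome` to polish.
#' @param alignments `Alignments` of short reads against `assembly`.
#' @param policy A [curation_policy()].
#' @param protected data.frame of protected intervals (`contig`, `start`,
#'   `end`), or `NULL`.
#' @return List with `genome` (polished), `records` (EditRecord data.frame
#'   with `status` in applied/deferred_polygc), `rounds` (number of rounds
#'   run).
#' @export
polish_consensus <- function(assembly, alignments, policy = curation_policy(),
                             protected = NULL) {
  stopifnot(inherits(assembly, "Genome"), inherits(alignments, "Alignments"))
  g <- assembly
  aln <- alignments
  records <- list()
  round <- 0L
  prot <- protected
  repeat {
    round <- round + 1L
    if (round > policy$max_rounds) { round <- policy$max_rounds; break }
    if (round > 1L) aln <- map_reads(g, alignments$reads, mode = "short")
    pl <- pileup(g, aln)
    edits <- consensus_edits(g, pl, policy)
    if (nrow(edits) > 0) {
      deferred <- in_protected(edits, prot)
      edits$round <- round
      edits$status <- ifelse(deferred, "deferred_polygc", "applied")
      records[[length(records) + 1L]] <- edits
      applied <- edits[!deferred, , drop = FALSE]
    } else {
      applied <- edits
    }
    if (nrow(applied) == 0) break
    g <- apply_edits(g, applied)
    prot <- lift_intervals(prot, applied)
  }
  recs <- if (length(records)) do.call(rbind, records) else
    data.frame(contig = character(0), pos = integer(0), kind = character(0),
               from = character(0), to = character(0), support = integer(0),
               depth = integer(0), round = integer(0), status = character(0),
               stringsAsFactors = FALSE)
  rownames(recs) <- NULL
  list(genome = g, records = recs, rounds = round)
}

#' Replay polish edit records on an assembly
#'
#' Applies the `applied` records round by round; the result must equal the
#' polished output (audit invariant).
#'
#' @param assembly The original input `Genome`.
#' @param records EditRecord data.frame from [polish_consensus()].
#' @return A `Genome`.
#' @export
replay_edits <- function(assembly, records) {
  g <- assembly
  for (r in sort(unique(records$round))) {
    g <- apply_edits(g, records[records$round == r &
                                  records$status == "applied", ,
                                drop = FALSE])
  }
  g
}

# read substring aligned across reference window [w0, w1); q must be in
# reference orientation; NA when the window is not fully covered
aligned_segment <- function(q, ref_start, cigar, w0, w1) {
  ops <- parse_cigar(cigar)
  g <- ref_start
  r <- 0L
  r0 <- NA_integer_
  r1 <- NA_integer_
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op == "S") { r <- r + len; next }
    if (op == "M") {
      if (is.na(r0) && g <= w0 && w0 < g + len) r0 <- r + (w0 - g)
      if (is.na(r1) && g < w1 && w1 <= g + len) r1 <- r + (w1 - g)
      g <- g + len; r <- r + len
    } else if (op == "D") {
      if (is.na(r0) && g <= w0 && w0 < g + len) r0 <- r
      if (is.na(r1) && g < w1 && w1 <= g + len) r1 <- r
      g <- g + len
    } else if (op == "I") {
      r <- r + len
    }
  }
  if (is.na(r0) || is.na(r1) || r1 < r0) return(NA_character_)
  substr(q, r0 + 1L, r1)
}

#' Curate protected regions with long reads
#'
#' Within each protected interval (padded by 3 bp), every long read of at
#' least `policy$long_read_min` bases whose alignment spans the window
#' votes with its aligned segment; the plurality segment is the long-read
#' consensus. A correction is applied only when the consensus differs from
#' the assembly and its supporting read count reaches
#' `policy$min_confirm_reads` (more than 5 reads). Corrections below that
#' support are recorded as `rejected_low_support` and the region is listed
#' as unresolved.
#'
#' @param assembly A `Genome`.
#' @param long_alignments `Alignments` of long reads against `assembly`.
#' @param protected data.frame of protected intervals.
#' @param policy A [curation_policy()].
#' @return List with `genome`, `records`, and `unresolved` (data.frame of
#'   regions left uncorrected for lack of support).
#' @export
curate_with_long_reads <- function(assembly, long_alignments, protected,
                                   policy = curation_policy()) {
  stopifnot(inherits(assembly, "Genome"),
            inherits(long_alignments, "Alignments"))
  df <- long_alignments$aln
  keep <- df$status == "mapped" & df$read_len >= policy$long_read_min
  df <- df[keep, , drop = FALSE]
  seqs <- long_alignments$reads$seqs[keep]
  edits <- list()
  unresolved <- list()
  if (!is.null(protected) && nrow(protected) > 0) {
    for (i in seq_len(nrow(protected))) {
      ci <- protected$contig[i]
      s <- assembly$contigs[[ci]]
      if (is.null(s)) next
      w0 <- max(0L, protected$start[i] - 3L)
      w1 <- min(nchar(s), protected$end[i] + 3L)
      if (w1 <= w0) next
      span <- which(df$contig == ci & df$ref_start <= w0 &
                      df$ref_end >= w1)
      if (length(span) == 0) next
      # each spanning read votes with its aligned segment over the window
      segs <- vapply(span, function(j) {
        q <- seqs[[j]]
        if (df$strand[j] == "-") q <- revcomp(q)
        aligned_segment(q, df$ref_start[j], df$cigar[j], w0, w1)
      }, character(1))
      segs <- segs[!is.na(segs)]
      if (length(segs) == 0) next
      tab <- sort(table(segs), decreasing = TRUE)
      modal <- names(tab)[1]
      support <- as.integer(tab[1])
      cur_seg <- subseq_chr(s, w0, w1)
      if (modal == cur_seg) next
      st <- if (support >= policy$min_confirm_reads) "applied"
            else "rejected_low_support"
      # decompose the replacement into base-level edit records
      al <- cpp_banded_align(cur_seg, modal,
                             abs(nchar(cur_seg) - nchar(modal)) + 16L)
      ops <- parse_cigar(al$cigar)
      gpos <- w0
      mpos <- 0L
      add_rec <- function(pos, kind, from, to) {
        edits[[length(edits) + 1L]] <<- data.frame(
          contig = ci, pos = pos, kind = kind, from = from, to = to,
          support = support, depth = length(segs), round = 1L,
          status = st, stringsAsFactors = FALSE)
      }
      for (r in seq_len(nrow(ops))) {
        len <- ops$len[r]
        if (ops$op[r] == "M") {
          va <- strsplit(substr(s, gpos + 1L, gpos + len), "")[[1]]
          vb <- strsplit(substr(modal, mpos + 1L, mpos + len), "")[[1]]
          for (t in which(va != vb)) {
            add_rec(gpos + t - 1L, "sub", va[t], vb[t])
          }
          gpos <- gpos + len; mpos <- mpos + len
        } else if (ops$op[r] == "D") {
          for (t in seq_len(len)) {
            add_rec(gpos, "del", substr(s, gpos + 1L, gpos + 1L), "")
            gpos <- gpos + 1L
          }
        } else {
          add_rec(gpos - 1L, "ins", "",
                  substr(modal, mpos + 1L, mpos + len))
          mpos <- mpos + len
        }
      }
      if (st == "rejected_low_support") {
        unresolved[[length(unresolved) + 1L]] <- protected[i, ]
      }
    }
  }
  recs <- if (length(edits)) do.call(rbind, edits) else
    data.frame(contig = character(0), pos = integer(0), kind = character(0),
               from = character(0), to = character(0), support = integer(0),
               depth = integer(0), round = integer(0), status = character(0),
               stringsAsFactors = FALSE)
  rownames(recs) <- NULL
  g <- apply_edits(assembly, recs[recs$status == "applied", , drop = FALSE])
  unres <- if (length(unresolved)) do.call(rbind, unresolved) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  rownames(unres) <- NULL
  list(genome = g, records = recs, unresolved = unres)
}

#' Audit feature junctions for long-read spanning support
#'
#' Runs [verify_junction_support()] for every junction (LTR element
#' boundaries, duplicated-segment boundaries, variant breakpoints).
#'
#' @param assembly A `Genome`.
#' @param junctions data.frame with columns `contig`, `position` (plus any
#'   id columns, carried through).
#' @param long_alignments `Alignments` of long reads against `assembly`.
#' @param policy A [curation_policy()].
#' @return The input data.frame with `n_spanning` and `pass` columns added.
#' @export
audit_junctions <- function(assembly, junctions, long_alignments,
                            policy = curation_policy()) {
  if (is.null(junctions) || nrow(junctions) == 0) {
    return(cbind(junctions, n_spanning = integer(0), pass = logical(0)))
  }
  res <- lapply(seq_len(nrow(junctions)), function(i) {
    verify_junction_support(
      list(contig = junctions$contig[i], position = junctions$position[i],
           flank = policy$junction_flank),
      long_alignments, policy, assembly = assembly)
  })
  junctions$n_spanning <- vapply(res, function(r) r$n_spanning, integer(1))
  junctions$pass <- vapply(res, function(r) r$pass, logical(1))
  junctions
}
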