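# Genome container and readers/writers for the standard formats the
# pipeline touches. All internal coordinates are 0-based half-open;
# conversions to 1-based happen only at format boundaries (GFF3).

#' Construct a Genome object
#'
#' A `Genome` is an ordered set of named contigs (DNA over `{A,C,G,T}`,
#' ambiguity codes tolerated but flagged) with per-contig circularity flags.
#' A released full-length assembly is expected to contain no ambiguous
#' bases; intermediate curation inputs may (see [ambiguity_report()]).
#'
#' @param contigs Named character vector of uppercase DNA sequences.
#' @param label Free-text label for the assembly.
#' @param circular Logical vector (recycled) marking circular contigs.
#' @return An object of class `Genome`.
#' @export
genome <- function(contigs, label = "genome", circular = FALSE) {
  stopifnot(is.character(contigs), length(contigs) > 0)
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig name: ",
         names(contigs)[duplicated(names(contigs))][1])
  }
  if (sum(nchar(contigs)) == 0) stop("genome has zero total length")
  circular <- rep_len(as.logical(circular), length(contigs))
  names(circular) <- names(contigs)
  structure(list(contigs = contigs, label = label, circular = circular),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d contig(s), %s bp total\n", x$label,
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  for (nm in names(x$contigs)) {
    cat(sprintf("  %s  %s bp%s\n", nm,
                format(nchar(x$contigs[[nm]]), big.mark = ","),
                if (x$circular[[nm]]) " (circular)" else ""))
  }
  invisible(x)
}

#' Total length of a Genome
#' @param g A `Genome`.
#' @return Integer total base count.
#' @export
genome_length <- function(g) sum(nchar(g$contigs))

contig_seq <- function(g, name) {
  s <- g$contigs[[name]]
  if (is.null(s)) stop("unknown contig: ", name)
  s
}

#' Read a FASTA file into a Genome
#'
#' Sequences are uppercased and `U` is mapped to `T`. IUPAC ambiguity codes
#' are preserved but flagged: the returned object carries a per-contig
#' ambiguity report (see [ambiguity_report()]).
#'
#' @param path Path to a FASTA file.
#' @param label Assembly label (defaults to the file name).
#' @return A `Genome` with an `ambiguity` attribute.
#' @export
read_fasta <- function(path, label = basename(path)) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0) stop("no records in ", path)
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA header: ", nms[duplicated(nms)][1])
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) {
    stop("empty FASTA record: ", nms[nchar(seqs) == 0][1])
  }
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- nms
  g <- genome(seqs, label = label)
  amb <- vapply(seqs, function(s) {
    nchar(gsub("[ACGT]", "", s))
  }, integer(1))
  attr(g, "ambiguity") <- data.frame(contig = nms, n_ambiguous = unname(amb),
                                     stringsAsFactors = FALSE)
  g
}

#' Per-contig ambiguity report of a Genome
#'
#' @param g A `Genome` (typically from [read_fasta()]).
#' @return data.frame with columns `contig`, `n_ambiguous`.
#' @export
ambiguity_report <- function(g) {
  rep <- attr(g, "ambiguity")
  if (is.null(rep)) {
    rep <- data.frame(
      contig = names(g$contigs),
      n_ambiguous = vapply(g$contigs,
                           function(s) nchar(gsub("[ACGT]", "", s)),
                           integer(1)),
      stringsAsFactors = FALSE)
    rownames(rep) <- NULL
  }
  rep
}

#' Write a Genome to FASTA
#'
#' @param g A `Genome`.
#' @param path Output path.
#' @param wrap Line width (>= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, wrap = 80L) {
  stopifnot(inherits(g, "Genome"), wrap >= 1)
  if (length(g$contigs) == 0) stop("empty Genome")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(g$contigs)) {
    writeLines(paste0(">", nm), con)
    s <- g$contigs[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ or FASTA file of sequencing reads
#'
#' @param path Path to the reads file.
#' @param format `"fastq"` or `"fasta"`.
#' @return A `ReadSet` (see [read_set()]).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  ss <- Biostrings::readBStringSet(path, format = format)
  read_set(setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss))))
}

#' Construct a ReadSet
#'
#' A `ReadSet` holds read names/sequences plus optional per-read truth
#' (origin interval, orientation, planted error counts) when produced by the
#' simulators.
#'
#' @param seqs Named character vector of read sequences.
#' @param truth Optional data.frame of per-read truth records.
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(seqs, truth = NULL) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  structure(list(seqs = seqs, truth = truth), class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, %s bp total\n", length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Write a ReadSet to FASTQ
#'
#' Constant placeholder qualities are used; the simulators do not model a
#' quality process.
#'
#' @param rs A `ReadSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(rs$seqs)) {
    writeLines(c(paste0("@", names(rs$seqs)[i]), rs$seqs[[i]], "+",
                 strrep("I", nchar(rs$seqs[[i]]))), con)
  }
  invisible(path)
}

#' Write located features to BED6, GFF3 or TSV
#'
#' Features use the package-wide 0-based half-open convention. BED6 output is
#' 0-based half-open; GFF3 output is 1-based inclusive. Attribute keys are
#' emitted sorted and rows are stably sorted by (contig, start, type) so the
#' output is deterministic.
#'
#' @param features data.frame with columns `contig`, `start`, `end`,
#'   `strand`, `type`, optionally `score`, `name`, `parent`, plus any extra
#'   columns (emitted as GFF3/TSV attributes).
#' @param format One of `"BED6"`, `"GFF3"`, `"TSV"`.
#' @param path Output path.
#' @param genome Optional `Genome` used to validate intervals.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, format = c("BED6", "GFF3", "TSV"), path,
                           genome = NULL) {
  format <- match.arg(format)
  req <- c("contig", "start", "end", "strand", "type")
  stopifnot(all(req %in% names(features)))
  if (!is.null(genome)) {
    lens <- nchar(genome$contigs)[features$contig]
    if (any(is.na(lens)) || any(features$start < 0) ||
        any(features$end > lens)) {
      stop("feature interval outside contig bounds")
    }
  }
  ord <- order(features$contig, features$start, features$type)
  features <- features[ord, , drop = FALSE]
  extra <- setdiff(names(features), c(req, "score", "name", "parent"))
  extra <- sort(extra)
  if (format == "BED6") {
    nm <- if ("name" %in% names(features)) features$name else features$type
    sc <- if ("score" %in% names(features)) features$score else 0
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", features$contig,
                     features$start, features$end, nm, format(sc), features$strand)
    writeLines(lines, path)
  } else if (format == "GFF3") {
    attrs <- vapply(seq_len(nrow(features)), function(i) {
      kv <- character(0)
      if ("name" %in% names(features)) {
        kv <- c(kv, paste0("ID=", features$name[i]))
      }
      if ("parent" %in% names(features) && !is.na(features$parent[i]) &&
          nzchar(features$parent[i])) {
        kv <- c(kv, paste0("Parent=", features$parent[i]))
      }
      for (k in extra) kv <- c(kv, paste0(k, "=", features[[k]][i]))
      if (length(kv) == 0) "." else paste(kv, collapse = ";")
    }, character(1))
    sc <- if ("score" %in% names(features)) format(features$score) else "."
    lines <- sprintf("%s\ttelosv\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                     features$contig, features$type, features$start + 1L,
                     features$end, sc, features$strand, attrs)
    writeLines(c("##gff-version 3", lines), path)
  } else {
    write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
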