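# Shared fixtures. The default-scale genome (3 x 300 kb) is built once per
# test run and cached; small configs keep unit tests fast.

.fixture_env <- new.env(parent = emptyenv())

default_build <- function(seed = 7L) {
  key <- paste0("default_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_genome(synthetic_config(seed = seed))
  }
  .fixture_env[[key]]
}

# one small chromosome with every feature class, scaled for speed
small_config <- function(seed = 3L, chrom_length = 120000L,
                         rdna_unit_length = 2000L) {
  synthetic_config(
    n_chromosomes = 1L, chrom_length = chrom_length,
    rdna_unit_length = rdna_unit_length,
    lds_specs = list(list(length = 8000L, n_mismatch = 4L, n_gap = 1L,
                          terminal_motif = "none")),
    mat_ir_length = 500L, mat_invertible_length = 4000L, seed = seed)
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k bases of a contig outside planted features (with margin)
corrupt_substitutions <- function(g, manifest, n_subs, seed, margin = 200L) {
  set.seed(seed)
  feats <- manifest$features
  out <- g
  pos_list <- list()
  for (nm in names(g$contigs)) {
    s <- g$contigs[[nm]]
    occupied <- logical(nchar(s))
    f <- feats[feats$contig == nm, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      occupied[seq(max(1L, f$start[i] - margin),
                   min(nchar(s), f$end[i] + margin))] <- TRUE
    }
    free <- which(!occupied)
    k <- round(n_subs * nchar(s) / genome_length(g))
    pos <- sort(sample(free, k))
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    out$contigs[[nm]] <- s
    pos_list[[nm]] <- pos
  }
  attr(out, "sub_positions") <- pos_list
  out
}

# delete one base inside the first n_runs poly(GC) runs (emulates a prior
# bad polish of those runs)
shrink_polygc_runs <- function(g, manifest, n_runs, which_runs = NULL) {
  runs <- manifest$features[manifest$features$type == "polygc", ,
                            drop = FALSE]
  if (is.null(which_runs)) which_runs <- seq_len(min(n_runs, nrow(runs)))
  runs <- runs[which_runs, , drop = FALSE]
  runs <- runs[order(runs$contig, -runs$start), , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    s <- g$contigs[[runs$contig[i]]]
    p <- runs$start[i] + 2L
    g$contigs[[runs$contig[i]]] <- paste0(substr(s, 1L, p),
                                          substr(s, p + 2L, nchar(s)))
  }
  g
}
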