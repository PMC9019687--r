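# Brute-force tandem-array oracle: maximal runs of lag-p matches, exact
# counting over every (period, phase). Independent of the scan-and-merge
# detector implementation.
oracle_tandem <- function(seq, min_unit = 4L, max_unit = 16L,
                          min_copies = 3) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  found <- list()
  for (p in min_unit:max_unit) {
    i <- 1L
    while (i <= n - p) {
      if (v[i] != v[i + p]) { i <- i + 1L; next }
      j <- i
      while (j <= n - p && v[j] == v[j + p]) j <- j + 1L
      span <- (j - i) + p
      if (span >= min_copies * p) {
        found[[length(found) + 1L]] <- data.frame(start = i - 1L,
                                                  end = i - 1L + span,
                                                  period = p)
      }
      i <- j + 1L
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0)))
  }
  do.call(rbind, found)
}
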