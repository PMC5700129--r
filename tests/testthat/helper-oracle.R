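# Independent alignment oracle: enumerate every global alignment of two short
# sequences as a lattice path (diagonal / ref-gap / query-gap moves), scoring
# incrementally with gap-state tracking so affine opens are charged exactly
# once per run. Exponential, so only usable for lengths <= ~8.
oracle_best_score <- function(ref, query, scoring) {
  r <- utf8ToInt(ref)
  q <- utf8ToInt(query)
  m <- length(r)
  n <- length(q)
  ma <- scoring$match; mi <- scoring$mismatch
  open <- scoring$gap_open; ext <- scoring$gap_extend
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i == m && j == n) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < m && j < n)
      rec(i + 1L, j + 1L, 0L, acc + (if (r[i + 1L] == q[j + 1L]) ma else mi))
    if (i < m)
      rec(i + 1L, j, 1L, acc + ext + (if (prev != 1L) open else 0))
    if (j < n)
      rec(i, j + 1L, 2L, acc + ext + (if (prev != 2L) open else 0))
    invisible(NULL)
  }
  rec(0L, 0L, 0L, 0)
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a random query derived from a reference by point mutations and small indels
mutate_dna <- function(ref, n_sub = 1L, n_indel = 1L) {
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_sub)) {
    p <- sample.int(length(ch), 1L)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  s <- paste(ch, collapse = "")
  for (k in seq_len(n_indel)) {
    n <- nchar(s)
    len <- sample.int(3L, 1L)
    if (stats::runif(1) < 0.5 && n > len + 1L) {
      p <- sample.int(n - len, 1L)
      s <- paste0(substr(s, 1L, p - 1L), substr(s, p + len, n))
    } else {
      p <- sample.int(n + 1L, 1L) - 1L
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      s <- paste0(substr(s, 1L, p), ins, substr(s, p + 1L, n))
    }
  }
  s
}
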