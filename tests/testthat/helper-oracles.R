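# Independent brute-force oracles used across tests. These re-derive
# quantities from first principles (explicit loops, direct formulas) and
# must stay independent of the package implementation paths they check.

oracle_moments <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  c2 <- sum((v - m)^2) / n
  c3 <- sum((v - m)^3) / n
  c4 <- sum((v - m)^4) / n
  c(mean = m, std = sqrt(c2), max = max(v), min = min(v),
    skew = c3 / c2^1.5, kurtosis = c4 / c2^2)
}

oracle_ntr_tally <- function(v, table) {
  counts <- numeric(nrow(table))
  for (x in v) {
    hit <- FALSE
    for (i in seq_len(nrow(table))) {
      if (x >= table$lo[i] && x < table$hi[i]) {
        counts[i] <- counts[i] + 1
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      if (x < table$lo[1]) counts[1] <- counts[1] + 1
      else counts[nrow(table)] <- counts[nrow(table)] + 1
    }
  }
  counts / length(v)
}

# exhaustive set-intersection + min-rank oracle for coincidence fusion
oracle_coincidence <- function(orders, window, max_rank) {
  fn <- orders[[1]]
  cand <- character(0)
  for (f in fn) {
    ok <- TRUE
    for (o in orders) if (match(f, o) > window) ok <- FALSE
    if (ok) cand <- c(cand, f)
  }
  final <- sapply(cand, function(f) min(sapply(orders, function(o) match(f, o))))
  keep <- final < max_rank
  cand <- cand[keep]
  final <- final[keep]
  ord <- order(final, cand)
  data.frame(feature = cand[ord], final_rank = as.integer(final[ord]),
             stringsAsFactors = FALSE)
}

# quick two-class subject pair with identical feet (for ETD-zero tests)
make_twin_subject <- function(seed = 1L) {
  s <- make_subject("healthy", foot_geometry(40L, 24L), seed = seed)
  s$right <- s$left
  s
}

small_ranking <- function(method, features, scores) {
  thermoselect:::new_ranking_result(method, stats::setNames(scores, features),
                                    stats::setNames(scores > 0, features))
}
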