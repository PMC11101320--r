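# Independent brute-force oracles used to cross-check the package
# implementations on small instances. These re-derive each quantity from
# first principles and share no code with the functions they check.

# --- phase-block segmentation -------------------------------------------------

# A block [i..j] (parent = parent of marker i) is admissible iff every prefix
# ending at an opposite-parent marker satisfies both bounds: at most
# max_switches opposite markers within the trailing window_bp span, and an
# opposite fraction of at most switch_rate.
oracle_block_valid <- function(pos, parent, i, j, max_switches, window_bp,
                               switch_rate) {
  p <- parent[i]
  opp <- integer(0)
  for (m in i:j) {
    if (parent[m] == p) next
    opp <- c(opp, pos[m])
    if (sum(opp > pos[m] - window_bp) > max_switches) return(FALSE)
    if (length(opp) / (m - i + 1) > switch_rate) return(FALSE)
  }
  TRUE
}

# The segmentation consistent with the left-to-right termination rule: every
# block is admissible and every internal boundary is *forced* (extending the
# block by the next marker violates a bound). Admissibility is prefix-closed,
# so this segmentation is unique; enumerating candidate block ends with the
# independent validity check above re-derives it from first principles.
oracle_forced_segmentation <- function(pos, parent, max_switches, window_bp,
                                       switch_rate) {
  n <- length(pos)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && oracle_block_valid(pos, parent, i, j + 1L, max_switches,
                                       window_bp, switch_rate)) {
      j <- j + 1L
    }
    out[[length(out) + 1L]] <-
      data.frame(start_idx = i, end_idx = j, parent = parent[i],
                 n_switched = sum(parent[i:j] != parent[i]))
    i <- j + 1L
  }
  do.call(rbind, out)
}

# --- Fisher's exact test ------------------------------------------------------

# hypergeometric pmf from log-binomial coefficients
oracle_hyper_pmf <- function(x, r1, c1, n) {
  exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
}

oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- oracle_hyper_pmf(xs, r1, c1, n)
  obs <- probs[match(a, xs)]
  if (alternative == "greater") return(sum(probs[xs >= a]))
  if (alternative == "less") return(sum(probs[xs <= a]))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- N50 ----------------------------------------------------------------------

oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# --- interval overlap ---------------------------------------------------------

oracle_overlap_flags <- function(genes, variants, types) {
  v <- variants[variants$type %in% types, , drop = FALSE]
  vapply(seq_len(nrow(genes)), function(i) {
    any(v$contig_id == genes$contig_id[i] &
          v$start < genes$end[i] & v$end > genes$start[i])
  }, logical(1))
}

# random marker track generator for property tests
random_track <- function(n, contig_length = 10000, p_flip = 0.3) {
  pos <- sort(sample.int(contig_length, n)) - 1L
  parent <- character(n)
  cur <- sample(c("P1", "P2"), 1)
  for (i in seq_len(n)) {
    if (runif(1) < p_flip) cur <- setdiff(c("P1", "P2"), cur)
    parent[i] <- cur
  }
  marker_track("chrT", pos, parent, contig_length)
}
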