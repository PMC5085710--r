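# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as naive reference implementations, separate from the
# package's computation paths.

# Exhaustive maximum base-pair count (Nussinov recursion, pure R, memoized).
# Pairs: A:T, G:C, G:T; minimum hairpin loop min_loop.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  pairable <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!pairable(ch[i], ch[k])) next
      cand <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
      if (cand > best) best <- cand
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# Brute-force Audic-Claverie two-sided p-value: term-by-term series
# summation of p(k|x) = (N2/N1)^k (x+k)! / (x! k! (1+N2/N1)^(x+k+1)) via the
# multiplicative recurrence, truncated when the upper-tail remainder is
# below 1e-14; doubled smaller tail capped at 1, symmetrized over the two
# conditioning directions.
oracle_ac_direction <- function(x, y, r) {
  # terms t_k: t_0 = (1+r)^-(x+1); t_k = t_{k-1} * r (x+k) / (k (1+r))
  kmax <- max(y + 10, ceiling((x + 1) * r + 30 * sqrt((x + 1) * r * (1 + r) + 1) + 300))
  k <- seq_len(kmax)
  t0 <- (1 + r)^(-(x + 1))
  terms <- c(t0, t0 * cumprod(r * (x + k) / (k * (1 + r))))
  while (terms[length(terms)] > 1e-14 * sum(terms)) {
    k2 <- (kmax + 1):(kmax + 300)
    terms <- c(terms, terms[length(terms)] *
                 cumprod(r * (x + k2) / (k2 * (1 + r))))
    kmax <- kmax + 300
  }
  lower <- sum(terms[seq_len(y + 1)])
  upper <- sum(terms[(y + 1):length(terms)])
  min(1, 2 * min(lower, upper))
}

oracle_ac_pvalue <- function(x, y, N1, N2) {
  min(oracle_ac_direction(x, y, N2 / N1),
      oracle_ac_direction(y, x, N1 / N2))
}

# Independent rule-based target-site enumerator for short transcripts:
# enumerates every window and every single-bulge variant, scores it with
# string operations, and applies the six rules directly from their
# definitions. Returns accepted sites as start/end/mismatch_total rows.
oracle_scan <- function(mirna, transcript) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mb <- strsplit(mirna, "")[[1]]
  tb <- strsplit(transcript, "")[[1]]
  m <- length(mb)
  L <- length(tb)
  col_state <- function(mchar, tchar) {
    if (tchar == comp[[mchar]]) return("M")
    if ((mchar == "G" && tchar == "T") || (mchar == "T" && tchar == "G"))
      return("G")
    "X"
  }
  out <- list()
  add_cand <- function(start, end, states, positions) {
    w <- c(M = 0, G = 0.5, X = 1, B = 1, b = 1)[states]
    total <- sum(w)
    runs <- rle(w > 0)
    adj <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
    seed <- positions >= 2 & positions <= 12
    runs2 <- rle(w > 0 & seed)
    adj_seed <- if (any(runs2$values)) max(runs2$lengths[runs2$values]) else 0
    st1011 <- states[positions %in% c(10, 11)]
    dup_mfe <- sum(c(A = 2, C = 3, G = 3, T = 2)[
      vapply(seq_along(states), function(i) {
        if (states[i] == "M") mb[positions[i]] else NA_character_
      }, character(1))], na.rm = TRUE) +
      sum(states == "G") * 1
    pm <- sum(c(A = 2, C = 3, G = 3, T = 2)[mb])
    ok <- total <= 4 && adj <= 2 && adj_seed <= 1 &&
      length(st1011) == 2 && all(st1011 %in% c("M", "G")) &&
      sum(w[positions >= 1 & positions <= 12]) <= 2.5 &&
      dup_mfe / pm >= 0.75
    if (ok)
      out[[length(out) + 1L]] <<- data.frame(
        site_start = start, site_end = end, mismatch_total = total,
        mfe_ratio = dup_mfe / pm)
  }
  for (e in seq(m, L)) {
    # ungapped
    if (e - m >= 0) {
      states <- character(m)
      for (p in 1:m) states[p] <- col_state(mb[p], tb[e - p + 1])
      add_cand(e - m, e, states, 1:m)
    }
    # one target bulge at alignment column g
    if (e - m - 1 >= 0) {
      for (g in 2:m) {
        states <- character(m + 1)
        positions <- integer(m + 1)
        ti <- e
        p <- 1
        for (col in 1:(m + 1)) {
          if (col == g) {
            states[col] <- "B"
            positions[col] <- min(g, m)
            ti <- ti - 1
          } else {
            states[col] <- col_state(mb[p], tb[ti])
            positions[col] <- p
            ti <- ti - 1
            p <- p + 1
          }
        }
        add_cand(e - m - 1, e, states, positions)
      }
    }
    # one miRNA bulge at column g
    if (e - m + 1 >= 0 && m >= 3) {
      for (g in 2:(m - 1)) {
        states <- character(m)
        positions <- 1:m
        ti <- e
        for (col in 1:m) {
          if (col == g) {
            states[col] <- "b"
          } else {
            states[col] <- col_state(mb[col], tb[ti])
            ti <- ti - 1
          }
        }
        add_cand(e - m + 1, e, states, positions)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(site_start = integer(0), site_end = integer(0),
               mismatch_total = numeric(0), mfe_ratio = numeric(0))
}

# dinucleotide count table of a sequence
dinuc_table <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
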