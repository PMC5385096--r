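# Shared fixtures and independent oracles.  The oracles are deliberately
# naive re-derivations (explicit enumeration) used to cross-check the
# package's implementations.

# Brute-force window classifier: given a duplex alignment, re-derive the
# expected token multiset by explicit enumeration of every 5-column
# window, with the region boundaries recomputed from first principles.
oracle_window_tokens <- function(aln) {
  st <- aln$state
  ts <- aln$target_sym
  ps <- aln$probe_sym
  nw <- length(st) - 4L
  plen <- sum(st != "probe_gap")
  # region = which third of the window index range, recomputed via cut()
  breaks <- c(0, nw / 3, 2 * nw / 3, nw)
  toks <- character(0)
  multi <- 0L
  for (w in seq_len(nw)) {
    cols <- seq(w, w + 4L)
    ev <- cols[st[cols] != "match"]
    reg <- as.integer(cut(w - 0.5, breaks))  # window index w-1 in [0, nw)
    if (length(ev) == 0L) {
      toks <- c(toks, sprintf("%s|%d|PM|%s", aln$orientation, reg,
                              paste(ts[cols], collapse = "")))
    } else if (length(ev) == 1L && st[ev] == "mismatch") {
      toks <- c(toks, sprintf("%s|%d|MM|%s|%d|%s", aln$orientation, reg,
                              paste(ts[cols], collapse = ""), ev - w, ps[ev]))
    } else if (length(ev) == 1L) {
      strand <- if (st[ev] == "probe_gap") "probe" else "target"
      toks <- c(toks, sprintf("%s|%d|GAP|%s|%d|%s", aln$orientation, reg,
                              paste(ts[cols[cols != ev]], collapse = ""),
                              ev - w, strand))
    } else {
      multi <- multi + 1L
    }
  }
  # interactions from scratch: probe coordinates of mismatched columns
  ppos <- cumsum(st != "probe_gap")
  mm <- ppos[st == "mismatch"]
  ints <- character(0)
  if (length(mm) >= 2L) {
    for (i in seq_len(length(mm) - 1L)) {
      for (j in seq(i + 1L, length(mm))) {
        d <- abs(mm[j] - mm[i])
        ints <- c(ints, paste0("int|", if (d <= 2) "adjacent"
                               else if (d <= 7) "near" else "far"))
      }
    }
  }
  list(tokens = toks, interactions = sort(unique(ints)), n_multi = multi)
}

# Exhaustive enumeration of all global alignments with at most one gap;
# returns a data frame of (gap_kind, gap_pos, cost) including the
# ungapped case when lengths match.
oracle_alignments_1gap <- function(pseq, tseq, gap_penalty = 1.5) {
  p <- strsplit(pseq, "")[[1]]
  t <- strsplit(tseq, "")[[1]]
  m <- length(p); n <- length(t)
  if (m == n) {
    return(data.frame(gap_kind = "none", gap_pos = NA_integer_,
                      cost = sum(p != t)))
  }
  if (n == m - 1L) {
    # one probe base unpaired (target gap) at probe position k
    cost <- vapply(seq_len(m), function(k) {
      sum(p[seq_len(k - 1L)] != t[seq_len(k - 1L)]) +
        (if (k <= n) sum(p[seq(k + 1L, m)] != t[seq(k, n)]) else 0) +
        gap_penalty
    }, numeric(1))
    return(data.frame(gap_kind = "target_gap", gap_pos = seq_len(m),
                      cost = cost))
  }
  if (n == m + 1L) {
    # one target base unpaired (probe gap) at target position k
    cost <- vapply(seq_len(n), function(k) {
      sum(p[seq_len(k - 1L)] != t[seq_len(k - 1L)]) +
        (if (k <= m) sum(p[seq(k, m)] != t[seq(k + 1L, n)]) else 0) +
        gap_penalty
    }, numeric(1))
    return(data.frame(gap_kind = "probe_gap", gap_pos = seq_len(n),
                      cost = cost))
  }
  stop("oracle handles length differences of at most 1")
}

# Exhaustive sliding-window hit scan: every target offset and window
# length, scored by the 1-gap alignment enumerator.
oracle_scan_hits <- function(pseq, tseq, max_mm = 3L, max_gaps = 1L,
                             gap_penalty = 1.5) {
  L <- nchar(pseq)
  hits <- list()
  for (s in 0:(nchar(tseq) - L + max_gaps)) {
    for (wl in (L - max_gaps):(L + max_gaps)) {
      if (abs(wl - L) > max_gaps || s + wl > nchar(tseq) || wl < 1L) next
      cand <- oracle_alignments_1gap(pseq, substr(tseq, s + 1L, s + wl),
                                     gap_penalty)
      cand$n_gap <- ifelse(cand$gap_kind == "none", 0L, 1L)
      cand$mm <- cand$cost - gap_penalty * cand$n_gap
      ok <- cand$mm <= max_mm & cand$n_gap <= max_gaps
      if (any(ok)) {
        hits[[length(hits) + 1L]] <- c(position = s,
                                       cost = min(cand$cost[ok]))
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(position = integer(0), cost = numeric(0)))
  }
  agg <- as.data.frame(do.call(rbind, hits))
  agg <- stats::aggregate(cost ~ position, agg, min)
  agg[order(agg$position), , drop = FALSE]
}

# A "flat" model whose coefficients depend only on token class, so
# affinities are easy to predict by hand: a perfect-match 25-mer scores
# 21 * pm; each mismatch converts up to 5 PM windows into MM windows.
flat_model <- function(pm = 1, mm = -0.5, gap = -0.75, delta = -0.5,
                       threshold = NA_real_, orientations = 1L) {
  voc <- enumerate_vocabulary(25L, orientations)
  cls <- vapply(strsplit(voc$tokens, "|", fixed = TRUE), `[`, character(1),
                3L)
  beta <- stats::setNames(
    ifelse(cls == "PM", pm, ifelse(cls == "MM", mm, gap)), voc$tokens)
  d <- stats::setNames(rep(delta, 3), voc$interaction_tokens)
  m <- pehm_model(beta = beta, delta = d, vocabulary = voc)
  if (!is.na(threshold)) m <- set_threshold(m, threshold)
  m
}

# Plant `k` substitutions into a sequence at well-separated positions.
plant_substitutions <- function(seq, positions) {
  for (p in positions) {
    ref <- substr(seq, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    substr(seq, p, p) <- alt
  }
  seq
}
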