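# Probe-target duplexes and their pentamer feature decomposition.
#
# A duplex is a global alignment of a short probe (default 25 nt) to a
# candidate target subsequence, with per-column states match / mismatch /
# probe_gap / target_gap.  Affinity features are pentamer tokens read off
# 5-column alignment windows, tagged by probe sub-region (three equal
# blocks of windows), plus duplex-wide mismatch-pair interaction flags.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a probe sequence record
#'
#' A validated description of one array probe: its sequence, optional
#' genomic coordinates (0-based half-open) and the orientation in which it
#' was synthesized.
#'
#' @param probe_id Unique probe identifier.
#' @param sequence DNA string (A/C/G/T only); default design length is 25 nt.
#' @param source_contig Contig/locus the probe was tiled from, or `NA`.
#' @param start,end 0-based half-open coordinates on `source_contig`, or `NA`.
#' @param strand `"+"` or `"-"`.
#' @param orientation `"sense"` or `"antisense"` synthesis orientation.
#' @return An object of class `probe_sequence`.
#' @examples
#' probe_sequence("p1", strrep("ACGTA", 5))
#' @export
probe_sequence <- function(probe_id, sequence, source_contig = NA_character_,
                           start = NA_integer_, end = NA_integer_,
                           strand = "+", orientation = "sense") {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("probe sequence must contain only A/C/G/T: ", probe_id)
  }
  strand <- match.arg(strand, c("+", "-"))
  orientation <- match.arg(orientation, c("sense", "antisense"))
  if (!is.na(start) && !is.na(end) && (end - start) != nchar(sequence)) {
    stop("end - start must equal sequence length for probe ", probe_id)
  }
  structure(
    list(probe_id = as.character(probe_id), sequence = sequence,
         source_contig = source_contig, start = start, end = end,
         strand = strand, orientation = orientation),
    class = "probe_sequence"
  )
}

stop_no_duplex <- function(probe_id, target_id, max_mm, max_gaps) {
  stop(structure(
    class = c("pehm_no_duplex", "error", "condition"),
    list(message = sprintf(
      "no duplex for %s vs %s within budget (max_mm = %d, max_gaps = %d); pair is non-hybridizing",
      probe_id, target_id, max_mm, max_gaps),
      call = NULL)
  ))
}

#' Globally align a probe to a candidate target
#'
#' Minimum-cost global alignment where a mismatch costs 1 and a gap costs
#' `gap_penalty` (default 1.5, so one gap is more disruptive than one
#' mismatch).  Ties are broken deterministically towards the leftmost gap
#' placement.  Pairs that cannot be aligned within the mismatch/gap budget
#' raise a `pehm_no_duplex` condition, signalling a non-hybridizing pair.
#'
#' @param probe A [probe_sequence()] or a plain DNA string.
#' @param target Target DNA string; its length must be within
#'   `probe length +/- max_gaps`.
#' @param max_mm Maximum number of mismatches allowed.
#' @param max_gaps Maximum number of gap columns allowed.
#' @param gap_penalty Cost of one gap column relative to a mismatch cost of 1.
#' @param target_id Identifier recorded on the alignment.
#' @param orientation Duplex orientation tag carried into feature tokens.
#' @return An object of class `duplex_alignment` with per-column
#'   probe/target symbols and states, `n_mismatches`, `n_gaps` and `cost`.
#' @examples
#' aln <- align_duplex(strrep("ACGTA", 5), strrep("ACGTA", 5))
#' aln$n_mismatches
#' @export
align_duplex <- function(probe, target, max_mm = 3L, max_gaps = 1L,
                         gap_penalty = 1.5, target_id = "target",
                         orientation = NULL) {
  if (inherits(probe, "probe_sequence")) {
    pid <- probe$probe_id
    if (is.null(orientation)) orientation <- probe$orientation
    pseq <- probe$sequence
  } else {
    pid <- "probe"
    if (is.null(orientation)) orientation <- "sense"
    pseq <- toupper(probe)
  }
  target <- toupper(target)
  p <- strsplit(pseq, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(p)
  n <- length(t)
  if (max_mm > m) max_mm <- m
  if (abs(m - n) > max_gaps) stop_no_duplex(pid, target_id, max_mm, max_gaps)

  if (m == n) {
    # fast path: the 0-gap alignment; optimal unless gaps could beat
    # mismatches, impossible for gap_penalty >= 1 on equal lengths
    mism <- p != t
    if (sum(mism) <= max_mm && gap_penalty >= 1) {
      state <- ifelse(mism, "mismatch", "match")
      return(new_duplex_alignment(pid, target_id, p, t, state,
                                  cost = sum(mism), orientation = orientation))
    }
    # equal lengths need gaps in pairs, so with a budget below 2 gaps
    # there is no alternative alignment to rescue the pair
    if (max_gaps < 2L && gap_penalty >= 1) {
      stop_no_duplex(pid, target_id, max_mm, max_gaps)
    }
  }

  if (abs(m - n) == 1L && max_gaps == 1L && gap_penalty >= 1) {
    # closed-form single-gap path: enumerate the gap position by prefix /
    # suffix mismatch sums (vectorized), leftmost minimum wins
    if (n == m - 1L) {
      # one probe base unpaired (target gap) at probe position k
      a <- c(p[seq_len(n)] != t, FALSE)            # pairing i <-> i
      b <- c(FALSE, p[seq_len(m)[-1L]] != t)       # pairing i <-> i-1
      pre <- cumsum(c(0, a))[seq_len(m)]           # sum a_i, i < k
      suf <- rev(cumsum(rev(c(b, 0))))[-1L]        # sum b_i, i > k
      mm_k <- pre + suf
      k <- which(mm_k == min(mm_k))[1L]
      if (min(mm_k) > max_mm) stop_no_duplex(pid, target_id, max_mm,
                                             max_gaps)
      ps <- p
      ts <- append(t, "-", after = k - 1L)
      st <- ifelse(ps == ts, "match", "mismatch")
      st[k] <- "target_gap"
      return(new_duplex_alignment(pid, target_id, ps, ts, st,
                                  cost = min(mm_k) + gap_penalty,
                                  orientation = orientation))
    } else {
      # one target base unpaired (probe gap) at target position k
      a <- c(t[seq_len(m)] != p, FALSE)
      b <- c(FALSE, t[seq_len(n)[-1L]] != p)
      pre <- cumsum(c(0, a))[seq_len(n)]
      suf <- rev(cumsum(rev(c(b, 0))))[-1L]
      mm_k <- pre + suf
      k <- which(mm_k == min(mm_k))[1L]
      if (min(mm_k) > max_mm) stop_no_duplex(pid, target_id, max_mm,
                                             max_gaps)
      ts <- t
      ps <- append(p, "-", after = k - 1L)
      st <- ifelse(ps == ts, "match", "mismatch")
      st[k] <- "probe_gap"
      return(new_duplex_alignment(pid, target_id, ps, ts, st,
                                  cost = min(mm_k) + gap_penalty,
                                  orientation = orientation))
    }
  }

  # layered DP: cost[g+1, i+1, j+1] = min cost aligning p[1..i], t[1..j]
  # with exactly g gap columns
  G <- as.integer(max_gaps)
  cost <- array(Inf, dim = c(G + 1L, m + 1L, n + 1L))
  cost[1L, 1L, 1L] <- 0
  for (g in 0:G) {
    for (i in 0:m) {
      for (j in 0:n) {
        if (i == 0L && j == 0L) next
        best <- Inf
        if (i > 0L && j > 0L) {
          best <- cost[g + 1L, i, j] + (p[i] != t[j])
        }
        if (g > 0L) {
          if (i > 0L) best <- min(best, cost[g, i, j + 1L] + gap_penalty)
          if (j > 0L) best <- min(best, cost[g, i + 1L, j] + gap_penalty)
        }
        cost[g + 1L, i + 1L, j + 1L] <- best
      }
    }
  }
  feas <- vapply(0:G, function(g) {
    cst <- cost[g + 1L, m + 1L, n + 1L]
    is.finite(cst) && (cst - g * gap_penalty) <= max_mm + 1e-9
  }, logical(1))
  if (!any(feas)) stop_no_duplex(pid, target_id, max_mm, max_gaps)
  totals <- cost[cbind(which(feas), m + 1L, n + 1L)]
  g_final <- (0:G)[feas][which.min(totals)]  # ties -> fewer gaps

  # traceback preferring diagonal, so equal-cost gaps land leftmost
  i <- m; j <- n; g <- g_final
  ps <- character(0); ts <- character(0); st <- character(0)
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    cur <- cost[g + 1L, i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        abs(cost[g + 1L, i, j] + (p[i] != t[j]) - cur) < eps) {
      ps <- c(p[i], ps); ts <- c(t[j], ts)
      st <- c(if (p[i] == t[j]) "match" else "mismatch", st)
      i <- i - 1L; j <- j - 1L
    } else if (g > 0L && i > 0L &&
               abs(cost[g, i, j + 1L] + gap_penalty - cur) < eps) {
      ps <- c(p[i], ps); ts <- c("-", ts); st <- c("target_gap", st)
      i <- i - 1L; g <- g - 1L
    } else if (g > 0L && j > 0L &&
               abs(cost[g, i + 1L, j] + gap_penalty - cur) < eps) {
      ps <- c("-", ps); ts <- c(t[j], ts); st <- c("probe_gap", st)
      j <- j - 1L; g <- g - 1L
    } else {
      stop("internal error: duplex traceback failed")  # nocov
    }
  }
  new_duplex_alignment(pid, target_id, ps, ts, st,
                       cost = cost[g_final + 1L, m + 1L, n + 1L],
                       orientation = orientation)
}

new_duplex_alignment <- function(probe_id, target_id, probe_sym, target_sym,
                                 state, cost, orientation) {
  structure(
    list(probe_id = probe_id, target_id = target_id,
         probe_sym = probe_sym, target_sym = target_sym, state = state,
         n_mismatches = sum(state == "mismatch"),
         n_gaps = sum(state %in% c("probe_gap", "target_gap")),
         cost = cost, orientation = orientation),
    class = "duplex_alignment"
  )
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("duplex %s vs %s (%s): %d columns, %d MM, %d gaps, cost %.1f\n",
              x$probe_id, x$target_id, x$orientation, length(x$state),
              x$n_mismatches, x$n_gaps, x$cost))
  cat(" probe : ", paste(x$probe_sym, collapse = ""), "\n", sep = "")
  cat(" target: ", paste(x$target_sym, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Assign a pentamer window to a probe sub-region
#'
#' Pentamer windows are split by start index into three equal contiguous
#' blocks; for a 25-mer (21 windows) starts 0-6 map to region 1, 7-13 to
#' region 2 and 14-20 to region 3.
#'
#' @param position 0-based window start index.
#' @param probe_length Probe length in nt.
#' @param n_windows Number of pentamer windows; defaults to
#'   `probe_length - 4` (gapless duplex), but gapped alignments have one
#'   extra window per probe gap.
#' @return Region index in `1:3`.
#' @examples
#' assign_region(0, 25)   # 1
#' assign_region(7, 25)   # 2
#' assign_region(20, 25)  # 3
#' @export
assign_region <- function(position, probe_length, n_windows = probe_length - 4L) {
  if (any(position < 0L | position >= n_windows)) {
    stop("window position out of range [0, ", n_windows - 1L, "]")
  }
  as.integer((position * 3L) %/% n_windows) + 1L
}

mm_interaction_class <- function(d) {
  ifelse(d <= 2L, "adjacent", ifelse(d <= 7L, "near", "far"))
}

#' Extract pentamer affinity features from a duplex alignment
#'
#' Slides a 5-column window over the alignment.  An event-free window emits
#' a perfect-match (PM) pentamer token (the target 5-mer); a window holding
#' exactly one mismatch emits an MM token (target 5-mer, mismatch offset in
#' the window, mismatching probe base); a window holding exactly one gap
#' emits a GAP token (the 4 paired target bases, gap offset, gapped
#' strand).  Windows with two or more events emit no k-mer token; their
#' effect is carried by duplex-wide mismatch-pair interaction flags keyed
#' by distance class (`adjacent` <= 2 nt, `near` 3-7 nt, `far` >= 8 nt).
#' Every k-mer token is tagged with the window's sub-region
#' ([assign_region()]) and the duplex orientation.
#'
#' @param alignment A `duplex_alignment` from [align_duplex()].
#' @param vocabulary Optional [enumerate_vocabulary()] result; if supplied,
#'   emitting a token absent from it is an error (orientation mismatch).
#' @return A named numeric vector of token counts (interaction flags are
#'   0/1), with attribute `n_multi_event_windows`.
#' @examples
#' fv <- extract_features(align_duplex(strrep("ACGTA", 5), strrep("ACGTA", 5)))
#' sum(fv)  # 21 PM pentamers
#' @export
extract_features <- function(alignment, vocabulary = NULL) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  st <- alignment$state
  ts <- alignment$target_sym
  ps <- alignment$probe_sym
  nc <- length(st)
  L <- sum(st != "probe_gap")  # probe length
  n_win <- nc - 4L
  if (n_win < 1L) stop("alignment too short for pentamer windows")
  orient <- alignment$orientation

  toks <- character(0)
  n_multi <- 0L
  for (w in seq_len(n_win)) {
    idx <- w:(w + 4L)
    ev <- idx[st[idx] != "match"]
    if (length(ev) == 0L) {
      reg <- assign_region(w - 1L, L, n_win)
      toks <- c(toks, paste(orient, reg, "PM",
                            paste(ts[idx], collapse = ""), sep = "|"))
    } else if (length(ev) == 1L) {
      reg <- assign_region(w - 1L, L, n_win)
      e <- ev
      off <- e - w  # 0-based offset within window
      if (st[e] == "mismatch") {
        toks <- c(toks, paste(orient, reg, "MM",
                              paste(ts[idx], collapse = ""), off, ps[e],
                              sep = "|"))
      } else {
        ctx <- paste(ts[setdiff(idx, e)], collapse = "")
        gstrand <- if (st[e] == "probe_gap") "probe" else "target"
        toks <- c(toks, paste(orient, reg, "GAP", ctx, off, gstrand,
                              sep = "|"))
      }
    } else {
      n_multi <- n_multi + 1L
    }
  }

  counts <- c(table(toks))
  counts <- stats::setNames(as.numeric(counts), names(counts))

  # duplex-wide mismatch-pair interactions (probe coordinates)
  probe_pos <- cumsum(st != "probe_gap")
  mm_pos <- probe_pos[st == "mismatch"]
  if (length(mm_pos) >= 2L) {
    prs <- utils::combn(mm_pos, 2L)
    cls <- unique(mm_interaction_class(abs(prs[2L, ] - prs[1L, ])))
    inter <- stats::setNames(rep(1, length(cls)), paste0("int|", cls))
    counts <- c(counts, inter)
  }

  if (!is.null(vocabulary)) {
    kmer <- names(counts)[!startsWith(names(counts), "int|")]
    missing <- setdiff(kmer, vocabulary$tokens)
    if (length(missing) > 0L) {
      stop("token(s) absent from vocabulary (orientation mismatch?): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    }
  }
  counts <- counts[order(names(counts))]
  attr(counts, "n_multi_event_windows") <- n_multi
  counts
}

#' Enumerate the full feature vocabulary
#'
#' Per orientation and sub-region the vocabulary holds 4^5 = 1024 PM
#' pentamer tokens, 4^5 x 5 offsets x 3 alternative probe bases = 15,360
#' mismatch tokens and 4^4 x 5 offsets x 2 gapped strands = 2,560 gap
#' tokens (18,944 in total); with two synthesis orientations and three
#' sub-regions the grand total is 113,664 k-mer parameters.  Interaction
#' tokens (mismatch-pair distance classes) are listed separately.
#'
#' @param probe_length Probe length in nt (must be at least 5).
#' @param orientations 1 (sense only) or 2 (sense + antisense).
#' @return An object of class `pehm_vocabulary`: ordered, duplicate-free
#'   token list, interaction tokens and per-class counts.
#' @examples
#' v <- enumerate_vocabulary(25, orientations = 2)
#' v$counts$total  # 113664
#' @export
enumerate_vocabulary <- function(probe_length = 25L, orientations = 2L) {
  stopifnot(probe_length >= 5L, orientations %in% c(1L, 2L))
  pent <- do.call(paste0, expand.grid(rep(list(DNA_BASES), 5L),
                                      stringsAsFactors = FALSE)[, 5:1])
  pent <- sort(pent)
  quad <- do.call(paste0, expand.grid(rep(list(DNA_BASES), 4L),
                                      stringsAsFactors = FALSE)[, 4:1])
  quad <- sort(quad)

  mm_grid <- expand.grid(pent = pent, off = 0:4, base = DNA_BASES,
                         stringsAsFactors = FALSE)
  mm_grid <- mm_grid[substr(mm_grid$pent, mm_grid$off + 1L, mm_grid$off + 1L)
                     != mm_grid$base, ]
  mm_payload <- paste(mm_grid$pent, mm_grid$off, mm_grid$base, sep = "|")
  gap_grid <- expand.grid(ctx = quad, off = 0:4,
                          strand = c("probe", "target"),
                          stringsAsFactors = FALSE)
  gap_payload <- paste(gap_grid$ctx, gap_grid$off, gap_grid$strand, sep = "|")

  ors <- c("sense", "antisense")[seq_len(orientations)]
  tokens <- character(0)
  for (o in ors) {
    for (r in 1:3) {
      tokens <- c(tokens,
                  paste(o, r, "PM", pent, sep = "|"),
                  paste(o, r, "MM", mm_payload, sep = "|"),
                  paste(o, r, "GAP", gap_payload, sep = "|"))
    }
  }
  tokens <- sort(tokens)
  structure(
    list(tokens = tokens,
         interaction_tokens = paste0("int|", c("adjacent", "near", "far")),
         counts = list(pm_per_region = length(pent),
                       mm_per_region = length(mm_payload),
                       gap_per_region = length(gap_payload),
                       per_region = length(pent) + length(mm_payload) +
                         length(gap_payload),
                       total = length(tokens)),
         probe_length = as.integer(probe_length),
         orientations = as.integer(orientations), regions = 3L),
    class = "pehm_vocabulary"
  )
}

#' @export
print.pehm_vocabulary <- function(x, ...) {
  cat(sprintf(
    "pehm vocabulary: %d k-mer tokens (%d orientation(s) x 3 regions x %d), %d interaction tokens\n",
    x$counts$total, x$orientations, x$counts$per_region,
    length(x$interaction_tokens)))
  invisible(x)
}

#' Export a vocabulary as an ordered token table
#'
#' Writes the deterministic (lexicographic) token ordering to TSV so that
#' coefficient vectors are reproducible across runs.
#'
#' @param vocabulary A `pehm_vocabulary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "pehm_vocabulary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pehm vocabulary; probe_length=%d; orientations=%d; tokens=%d",
            vocabulary$probe_length, vocabulary$orientations,
            vocabulary$counts$total),
    "index\ttoken"), con)
  idx <- seq_along(c(vocabulary$tokens, vocabulary$interaction_tokens))
  writeLines(paste(idx, c(vocabulary$tokens, vocabulary$interaction_tokens),
                   sep = "\t"), con)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings.
#' @return Reverse complement(s).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write duplex alignments to TSV
#'
#' One row per alignment: probe id, target id, a CIGAR-like state string
#' (`M`=match, `X`=mismatch, `P`=probe gap, `T`=target gap, run-length
#' encoded), mismatch and gap counts.
#'
#' @param alignments List of `duplex_alignment` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  rows <- vapply(alignments, function(a) {
    code <- c(match = "M", mismatch = "X", probe_gap = "P",
              target_gap = "T")[a$state]
    r <- rle(code)
    cig <- paste0(r$lengths, r$values, collapse = "")
    paste(a$probe_id, a$target_id, cig, a$n_mismatches, a$n_gaps, sep = "\t")
  }, character(1))
  writeLines(c("probe_id\ttarget_id\tstates\tn_mm\tn_gaps", rows), path)
  invisible(path)
}
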