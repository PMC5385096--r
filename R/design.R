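# Three-step probe/probeset design: tiling, probe selection under the
# affinity and specificity rules, probeset assembly.
#
# Probes are classified from their above-threshold hits: "specific" (one
# hit), "potentially_cross_hybridizing" (two or three), "non_specific"
# (four or more, excluded).  Probesets hold 3-6 probes within a 400 nt
# span, neighboring probes overlap at most 30% (>= 8 nt start separation
# for 25-mers), at least one probe is specific and cross-hybridizing
# members cross-react with pairwise distinct loci.

#' Tile a region of interest into candidate probes
#'
#' Candidate probes of `probe_length` nt at offsets 0, `step`,
#' 2 `step`, ... while the window fits in the region.  Windows containing
#' non-ACGT symbols (e.g. masked `N`s) are skipped.  With
#' `orientations = 2`, each window is also emitted as its reverse
#' complement in antisense orientation.
#'
#' @param region Target DNA string.
#' @param region_id Identifier used to build probe ids.
#' @param probe_length Probe length in nt (default 25).
#' @param step Tiling step in nt, between 1 and 4.
#' @param orientations 1 (sense only) or 2 (sense and antisense).
#' @return A data frame of candidate probes (probe_id, sequence,
#'   source_contig, start, end, strand, orientation).  A region shorter
#'   than the probe yields an empty frame with a warning.
#' @examples
#' nrow(tile_region(strrep("ACGT", 25), "r", step = 1))  # 76 sense probes
#' @export
tile_region <- function(region, region_id = "region", probe_length = 25L,
                        step = 1L, orientations = 1L) {
  stopifnot(step >= 1L, step <= 4L, orientations %in% c(1L, 2L))
  region <- toupper(region)
  n <- nchar(region)
  empty <- data.frame(probe_id = character(0), sequence = character(0),
                      source_contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      orientation = character(0), stringsAsFactors = FALSE)
  if (n < probe_length) {
    warning("region ", region_id, " shorter than probe length; no candidates")
    return(empty)
  }
  starts <- seq.int(0L, n - probe_length, by = step)
  seqs <- substring(region, starts + 1L, starts + probe_length)
  keep <- grepl("^[ACGT]+$", seqs)
  starts <- starts[keep]; seqs <- seqs[keep]
  if (length(starts) == 0L) return(empty)
  out <- data.frame(
    probe_id = sprintf("%s_%05d_s", region_id, starts),
    sequence = seqs, source_contig = region_id,
    start = starts, end = starts + probe_length,
    strand = "+", orientation = "sense", stringsAsFactors = FALSE)
  if (orientations == 2L) {
    anti <- data.frame(
      probe_id = sprintf("%s_%05d_a", region_id, starts),
      sequence = revcomp(seqs), source_contig = region_id,
      start = starts, end = starts + probe_length,
      strand = "-", orientation = "antisense", stringsAsFactors = FALSE)
    out <- rbind(out, anti)
    out <- out[order(out$start, out$orientation), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Perfect-match self-affinity of a probe sequence under a model.  Duplexes
# are represented on the sense-strand target window in both orientations
# (the orientation tag on the tokens separates the coefficient sets), so
# an antisense probe's features are those of its reverse complement.
self_affinity <- function(model, sequence, orientation = "sense") {
  tgt <- if (orientation == "antisense") revcomp(sequence) else sequence
  aln <- align_duplex(tgt, tgt, max_mm = 0L, max_gaps = 0L,
                      orientation = orientation)
  affinity(model, extract_features(aln))
}

#' Filter candidates on perfect-match self-affinity
#'
#' Computes each candidate's affinity with its own (perfect-match) target
#' and keeps those at or above the model's hybridization threshold;
#' boundary inclusive, so a probe exactly at the calibrated threshold is
#' retained.  Others are marked `rejected_low_affinity`.
#'
#' @param candidates Candidate data frame from [tile_region()].
#' @param model A calibrated `pehm_model` (threshold set).
#' @param inclusive Keep the boundary case `affinity == T` (default TRUE).
#' @return `candidates` with `self_affinity` and `status` columns
#'   (`"candidate"` or `"rejected_low_affinity"`).
#' @export
self_affinity_filter <- function(candidates, model, inclusive = TRUE) {
  stopifnot(inherits(model, "pehm_model"))
  T <- model$hybridization_threshold
  if (!is.finite(T)) {
    stop("model is not calibrated: hybridization threshold is not set")
  }
  if (nrow(candidates) == 0L) {
    candidates$self_affinity <- numeric(0)
    candidates$status <- character(0)
    return(candidates)
  }
  sa <- vapply(seq_len(nrow(candidates)), function(i) {
    self_affinity(model, candidates$sequence[i], candidates$orientation[i])
  }, numeric(1))
  pass <- if (inclusive) sa >= T else sa > T
  candidates$self_affinity <- sa
  candidates$status <- ifelse(pass, "candidate", "rejected_low_affinity")
  candidates
}

# Candidate probe-start offsets in one target via pigeonhole seeding:
# any alignment with <= max_mm mismatches and <= max_gaps gaps leaves at
# least one of (max_mm + max_gaps + 1) non-overlapping seeds intact, and
# that seed matches the target exactly within +/- max_gaps of its
# ungapped offset.
seed_candidate_starts <- function(pseq, tseq, max_mm, max_gaps) {
  L <- nchar(pseq)
  k <- max_mm + max_gaps + 1L
  seed_len <- max(4L, L %/% k)
  seed_off <- seq.int(0L, by = seed_len,
                      length.out = min(k, L %/% seed_len))
  starts <- integer(0)
  for (so in seed_off) {
    seed <- substr(pseq, so + 1L, so + seed_len)
    # overlapping exact matches via zero-width lookahead
    m <- gregexpr(paste0("(?=", seed, ")"), tseq, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    anchor <- as.integer(m) - 1L - so  # 0-based probe start
    for (shift in -max_gaps:max_gaps) {
      starts <- c(starts, anchor + shift)
    }
  }
  sort(unique(starts[starts >= 0L & starts <= nchar(tseq)]))
}

#' Find all hits of a probe in reference libraries
#'
#' The built-in backend is an exhaustive seed-and-scan: pigeonhole seeds
#' anchor candidate target offsets, each of which is verified by the
#' bounded alignment of [align_duplex()] over target windows of length
#' probe length +/- `max_gaps`.  It is complete within the mismatch/gap
#' budget.  Results are deduplicated by (target, position), keeping the
#' lowest-cost alignment, and merged across libraries.  The backend is a
#' pluggable contract: any function with this signature returning the
#' same hit-table shape (e.g. wrapping an external aligner) can stand in.
#'
#' @param probe A [probe_sequence()] or DNA string.
#' @param libraries A named character vector of reference sequences, or a
#'   list of such vectors (multiple libraries, e.g. the repetitive
#'   fraction of a genome and its complement).
#' @param max_mm Mismatch budget (default 3).
#' @param max_gaps Gap budget (default 1).
#' @return A data frame (target_id, position, width, n_mm, n_gaps, cost)
#'   with the per-hit `duplex_alignment`s in attribute `"alignments"`.
#'   Zero hits raise an error: every candidate must at minimum hit its
#'   origin.
#' @export
find_hits <- function(probe, libraries, max_mm = 3L, max_gaps = 1L) {
  if (inherits(probe, "probe_sequence")) {
    pseq <- probe$sequence; pid <- probe$probe_id
    orient <- probe$orientation
  } else {
    pseq <- toupper(probe); pid <- "probe"; orient <- "sense"
  }
  # antisense probes hybridize the sense strand: scan with the reverse
  # complement, keeping the orientation tag on the resulting features
  if (orient == "antisense") pseq <- revcomp(pseq)
  if (!is.list(libraries)) libraries <- list(libraries)
  L <- nchar(pseq)
  best <- new.env(parent = emptyenv())
  for (lib in libraries) {
    stopifnot(!is.null(names(lib)))
    for (tname in names(lib)) {
      tseq <- toupper(lib[[tname]])
      for (s in seed_candidate_starts(pseq, tseq, max_mm, max_gaps)) {
        for (wl in (L - max_gaps):(L + max_gaps)) {
          if (s + wl > nchar(tseq)) next
          aln <- tryCatch(
            align_duplex(pseq, substr(tseq, s + 1L, s + wl),
                         max_mm = max_mm, max_gaps = max_gaps,
                         target_id = tname, orientation = orient),
            pehm_no_duplex = function(e) NULL)
          if (is.null(aln)) next
          key <- paste(tname, s, sep = "\r")
          prev <- if (exists(key, best)) get(key, best) else NULL
          if (is.null(prev) || aln$cost < prev$aln$cost) {
            assign(key, list(target_id = tname, position = s, width = wl,
                             aln = aln), best)
          }
        }
      }
    }
  }
  keys <- ls(best)
  if (length(keys) == 0L) {
    stop("probe ", pid, " does not match its own source: zero hits in the ",
         "reference libraries within budget")
  }
  recs <- lapply(keys, get, envir = best)
  # one duplex, one hit: alignments at nearby offsets on the same target
  # (e.g. terminal-gap variants of the same site) are clustered and the
  # minimum-cost representative kept (ties toward the leftmost offset)
  tgt <- vapply(recs, `[[`, character(1), "target_id")
  pos <- vapply(recs, `[[`, integer(1), "position")
  cst <- vapply(recs, function(r) r$aln$cost, numeric(1))
  keep <- logical(length(recs))
  for (tn in unique(tgt)) {
    ix <- which(tgt == tn)
    ix <- ix[order(pos[ix])]
    cl_start <- pos[ix[1L]]
    cluster <- ix[1L]
    flush <- function(cluster) {
      b <- cluster[order(cst[cluster], pos[cluster])][1L]
      keep[b] <<- TRUE
    }
    for (k in ix[-1L]) {
      if (pos[k] - cl_start <= L %/% 2L) {
        cluster <- c(cluster, k)
      } else {
        flush(cluster)
        cluster <- k
        cl_start <- pos[k]
      }
    }
    flush(cluster)
  }
  recs <- recs[keep]
  out <- data.frame(
    target_id = vapply(recs, `[[`, character(1), "target_id"),
    position = vapply(recs, `[[`, integer(1), "position"),
    width = vapply(recs, `[[`, integer(1), "width"),
    n_mm = vapply(recs, function(r) r$aln$n_mismatches, integer(1)),
    n_gaps = vapply(recs, function(r) r$aln$n_gaps, integer(1)),
    cost = vapply(recs, function(r) r$aln$cost, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(out$cost, out$target_id, out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alignments") <- lapply(recs, `[[`, "aln")[ord]
  out
}

#' Classify a candidate probe from its hit affinities
#'
#' Evaluates the model affinity of every hit alignment and counts hits at
#' or above the hybridization threshold: 1 above-threshold hit is
#' `specific`, 2 or 3 are `potentially_cross_hybridizing`, 4 or more are
#' `non_specific` (excluded downstream).
#'
#' @param hits Hit table from [find_hits()] (with its alignments
#'   attribute).
#' @param model A calibrated `pehm_model`.
#' @param self_target Optional target id of the probe's own source, used
#'   to report partner (non-self) loci.
#' @return A list: `status`, `n_above`, `hits` (with an `affinity` column,
#'   sorted by descending affinity), `partner_loci` (distinct non-self
#'   above-threshold target ids).
#' @export
classify_probe <- function(hits, model, self_target = NULL) {
  T <- model$hybridization_threshold
  if (!is.finite(T)) stop("model is not calibrated")
  alns <- attr(hits, "alignments")
  aff <- vapply(alns, function(a) affinity(model, extract_features(a)),
                numeric(1))
  hits$affinity <- aff
  ord <- order(-hits$affinity)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "alignments") <- alns[ord]
  above <- hits[hits$affinity >= T, , drop = FALSE]
  n_above <- nrow(above)
  status <- if (n_above >= 4L) "non_specific"
  else if (n_above >= 2L) "potentially_cross_hybridizing"
  else if (n_above == 1L) "specific"
  else stop("internal inconsistency: candidate passed the self-affinity ",
            "filter but has no above-threshold hit")
  partners <- unique(above$target_id)
  if (!is.null(self_target)) partners <- setdiff(partners, self_target)
  list(status = status, n_above = n_above, hits = hits,
       partner_loci = partners)
}

# Structural invariants of an emitted probeset; returns TRUE or a reason.
probeset_ok <- function(probes, window = 400L, min_probes = 3L,
                        max_probes = 6L, min_separation = 8L) {
  n <- nrow(probes)
  if (n < min_probes || n > max_probes) return("size")
  span <- max(probes$end) - min(probes$start)
  if (span > window) return("span")
  if (n > 1L && any(diff(sort(probes$start)) < min_separation)) {
    return("separation")
  }
  if (!any(probes$status == "specific")) return("no specific probe")
  xh <- probes$partner_loci[probes$status == "potentially_cross_hybridizing"]
  if (length(xh) > 1L) {
    all_partners <- unlist(xh)
    if (anyDuplicated(all_partners)) return("shared cross-hybridization locus")
  }
  TRUE
}

#' Assemble probesets from classified candidates
#'
#' Greedy left-to-right scan over `window`-nt regions.  Within a window,
#' probes are admitted in position order; a probe starting closer than
#' `min_separation` to the previously admitted one competes with it
#' (higher self-affinity wins, ties leftmost).  A cross-hybridizing probe
#' is admitted only if its partner loci are disjoint from those already
#' used in the window.  A window yields a probeset only if at least
#' `min_probes` are admitted and at least one is specific; at most
#' `max_probes` are kept (highest self-affinity, ties leftmost).  Emitted
#' probesets are non-overlapping in genomic span, and every emitted
#' probeset is re-checked against the structural invariants.
#'
#' @param candidates Data frame with columns probe_id, start, end,
#'   self_affinity, status and a list-column `partner_loci`; rows with
#'   status `non_specific` or `rejected_low_affinity` are ignored.
#' @param locus_id Locus the candidates were tiled from.
#' @param window Maximum probeset span in nt (default 400).
#' @param min_probes,max_probes Probeset size bounds (defaults 3 and 6).
#' @param min_separation Minimum start separation in nt (default 8, i.e.
#'   at most 30% overlap for 25-mers).
#' @return A data frame of probesets (probeset_id, locus_id, n_probes,
#'   n_specific, span_start, span_end, probe_ids semicolon-collapsed),
#'   with the per-probeset member tables in attribute `"members"`.  Loci
#'   that cannot support a probeset yield zero rows.
#' @export
assemble_probesets <- function(candidates, locus_id, window = 400L,
                               min_probes = 3L, max_probes = 6L,
                               min_separation = 8L) {
  stopifnot(min_probes >= 1L, min_probes <= max_probes)
  usable <- candidates[candidates$status %in%
                         c("specific", "potentially_cross_hybridizing"), ,
                       drop = FALSE]
  empty <- data.frame(probeset_id = character(0), locus_id = character(0),
                      n_probes = integer(0), n_specific = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      probe_ids = character(0), stringsAsFactors = FALSE)
  attr(empty, "members") <- list()
  if (nrow(usable) < min_probes) return(empty)
  usable <- usable[order(usable$start, usable$probe_id), , drop = FALSE]
  rownames(usable) <- NULL
  if (is.null(usable$partner_loci)) {
    usable$partner_loci <- replicate(nrow(usable), character(0),
                                     simplify = FALSE)
  }

  admit_window <- function(win) {
    sel <- integer(0)       # row indices into win, admitted, position order
    used_partners <- character(0)
    for (r in seq_len(nrow(win))) {
      partners <- win$partner_loci[[r]]
      if (length(partners) && any(partners %in% used_partners)) next
      if (length(sel)) {
        last <- sel[length(sel)]
        if (win$start[r] - win$start[last] < min_separation) {
          # competition: higher self-affinity wins, ties keep the leftmost
          if (win$self_affinity[r] > win$self_affinity[last]) {
            prev <- if (length(sel) > 1L) sel[length(sel) - 1L] else NA
            if (is.na(prev) ||
                win$start[r] - win$start[prev] >= min_separation) {
              sel <- sel[-length(sel)]
              used_partners <- unique(unlist(win$partner_loci[sel]))
              if (length(partners) && any(partners %in% used_partners)) next
              sel <- c(sel, r)
              used_partners <- c(used_partners, partners)
            }
          }
          next
        }
      }
      sel <- c(sel, r)
      used_partners <- c(used_partners, partners)
    }
    sel
  }

  out <- empty
  members <- list()
  i <- 1L
  ps_n <- 0L
  while (i <= nrow(usable)) {
    w0 <- usable$start[i]
    in_win <- usable[usable$start >= w0 &
                       usable$end <= w0 + window, , drop = FALSE]
    sel <- admit_window(in_win)
    chosen <- in_win[sel, , drop = FALSE]
    if (nrow(chosen) > max_probes) {
      keep <- order(-chosen$self_affinity, chosen$start)[seq_len(max_probes)]
      chosen <- chosen[sort(keep), , drop = FALSE]
    }
    valid <- nrow(chosen) >= min_probes &&
      isTRUE(probeset_ok(chosen, window, min_probes, max_probes,
                         min_separation))
    if (valid) {
      ps_n <- ps_n + 1L
      ps_id <- sprintf("%s_ps%02d", locus_id, ps_n)
      out <- rbind(out, data.frame(
        probeset_id = ps_id, locus_id = locus_id,
        n_probes = nrow(chosen),
        n_specific = sum(chosen$status == "specific"),
        span_start = min(chosen$start), span_end = max(chosen$end),
        probe_ids = paste(chosen$probe_id, collapse = ";"),
        stringsAsFactors = FALSE))
      members[[ps_id]] <- chosen
      # the whole window is consumed: the next probeset starts beyond it,
      # so emitted probesets never overlap in genomic span
      nxt <- which(usable$start >= w0 + window)
      i <- if (length(nxt)) nxt[1L] else nrow(usable) + 1L
    } else {
      i <- i + 1L
    }
  }
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Run the full three-step design pipeline on one or more loci
#'
#' Tiling ([tile_region()]), perfect-match affinity filtering
#' ([self_affinity_filter()]), hit search and classification
#' ([find_hits()], [classify_probe()]) against the reference libraries,
#' and probeset assembly ([assemble_probesets()]).
#'
#' @param loci Named character vector of target region sequences.
#' @param libraries Reference libraries for the hit search (defaults to
#'   the loci themselves).
#' @param model A calibrated `pehm_model`.
#' @param probe_length,step,orientations Tiling parameters.
#' @param max_mm,max_gaps Hit-search budget.
#' @param window,min_probes,max_probes,min_separation Assembly parameters.
#' @return A list with `probes` (all candidates with status and hit
#'   counts) and `probesets` (rbind of per-locus [assemble_probesets()]
#'   output, member tables in attribute `"members"`).
#' @export
design_probes <- function(loci, libraries = list(loci), model,
                          probe_length = 25L, step = 1L, orientations = 1L,
                          max_mm = 3L, max_gaps = 1L, window = 400L,
                          min_probes = 3L, max_probes = 6L,
                          min_separation = 8L) {
  stopifnot(!is.null(names(loci)))
  all_probes <- list()
  all_sets <- list()
  all_members <- list()
  for (locus in names(loci)) {
    cand <- tile_region(loci[[locus]], locus, probe_length, step,
                        orientations)
    if (nrow(cand) == 0L) next
    cand <- self_affinity_filter(cand, model)
    cand$n_hits_above <- NA_integer_
    cand$partner_loci <- replicate(nrow(cand), character(0),
                                   simplify = FALSE)
    for (r in which(cand$status == "candidate")) {
      hits <- find_hits(probe_sequence(cand$probe_id[r], cand$sequence[r],
                                       orientation = cand$orientation[r]),
                        libraries, max_mm = max_mm, max_gaps = max_gaps)
      cls <- classify_probe(hits, model, self_target = locus)
      cand$status[r] <- cls$status
      cand$n_hits_above[r] <- cls$n_above
      cand$partner_loci[[r]] <- cls$partner_loci
    }
    sets <- assemble_probesets(cand, locus, window, min_probes, max_probes,
                               min_separation)
    if (nrow(sets) == 0L) {
      message("locus ", locus, ": no probeset satisfies the design rules")
    }
    all_probes[[locus]] <- cand
    all_sets[[locus]] <- sets
    all_members <- c(all_members, attr(sets, "members"))
  }
  probes <- do.call(rbind, c(all_probes, list(make.row.names = FALSE)))
  probesets <- do.call(rbind, c(all_sets, list(make.row.names = FALSE)))
  attr(probesets, "members") <- all_members
  list(probes = probes, probesets = probesets)
}
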