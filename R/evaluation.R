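# Platform-evaluation statistics for a titration design: two pure
# samples A and B, mixtures C = 0.75 A + 0.25 B and D = 0.25 A + 0.75 B,
# technical triplicates.  Covers background estimators, replicate CVs,
# monotonic titration response and its fold-change curve, mixture
# fraction estimation and the differential-expression filter.

#' Global background from tryptophan control probes
#'
#' The 15th percentile of the control-probe intensities, using the
#' linear-interpolation quantile definition (R type 7).
#'
#' @param control_intensities Numeric vector of control-probe intensities.
#' @param prob Percentile (default 0.15).
#' @return Background level.
#' @examples
#' background_trpn(1:100)  # 15.85
#' @export
background_trpn <- function(control_intensities, prob = 0.15) {
  if (length(control_intensities) == 0L) {
    stop("no control intensities supplied")
  }
  unname(stats::quantile(control_intensities, prob, type = 7))
}

#' Probe-level background from GC-matched antigenomic probes
#'
#' Median intensity of antigenomic probes whose GC count equals the
#' probe's; an empty GC bin falls back to the nearest populated bin, ties
#' toward the lower GC count.
#'
#' @param antigenomic Data frame with columns `gc_count` and `intensity`.
#' @param probe_gc GC count of the probe of interest.
#' @return Background level for that probe.
#' @export
background_gcbg <- function(antigenomic, probe_gc) {
  stopifnot(nrow(antigenomic) > 0L,
            all(c("gc_count", "intensity") %in% names(antigenomic)))
  bins <- sort(unique(antigenomic$gc_count))
  if (!(probe_gc %in% bins)) {
    d <- abs(bins - probe_gc)
    probe_gc <- min(bins[d == min(d)])  # ties toward lower GC
  }
  stats::median(antigenomic$intensity[antigenomic$gc_count == probe_gc])
}

#' Coefficient of variation across technical replicates
#'
#' Sample standard deviation over mean, on the linear intensity scale.
#'
#' @param values Replicate intensities (>= 2, positive mean).
#' @return The CV.
#' @examples
#' cv_replicates(c(8, 10, 12))  # 0.2
#' @export
cv_replicates <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m <= 0) stop("replicate mean must be positive for a CV")
  stats::sd(values) / m
}

#' Is a probeset's titration strictly monotonic?
#'
#' TRUE iff the four per-sample means follow the mixing order in either
#' direction: `a > c > d > b` (A more expressed) or `b > d > c > a`.
#' Ties fail.
#'
#' @param a,c,d,b Per-sample replicate-mean intensities.
#' @return Logical.
#' @examples
#' titration_monotonic(10, 8, 6, 4)  # TRUE
#' titration_monotonic(4, 6, 8, 10)  # TRUE (B direction)
#' @export
titration_monotonic <- function(a, c, d, b) {
  stopifnot(all(is.finite(c(a, c, d, b))))
  (a > c & c > d & d > b) | (b > d & d > c & c > a)
}

#' Summarize probe intensities into probeset summaries
#'
#' Median polish over the probes x arrays block of each probeset; the
#' summarized intensity per array is the overall effect plus the array
#' (column) effect.  Deterministic and robust to outlying probes.
#'
#' @param intensities Probes x arrays matrix with probe rownames.
#' @param probe_to_probeset Named probe -> probeset map.
#' @return Probesets x arrays matrix of summarized intensities.
#' @export
summarize_probesets <- function(intensities, probe_to_probeset) {
  probes <- rownames(intensities)
  stopifnot(!is.null(probes), all(probes %in% names(probe_to_probeset)))
  ps <- unname(probe_to_probeset[probes])
  sets <- sort(unique(ps))
  out <- matrix(NA_real_, length(sets), ncol(intensities),
                dimnames = list(sets, colnames(intensities)))
  for (s in sets) {
    block <- intensities[ps == s, , drop = FALSE]
    if (nrow(block) == 1L) {
      out[s, ] <- block[1L, ]
    } else {
      mp <- stats::medpolish(block, trace.iter = FALSE)
      out[s, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Per-probeset titration summary
#'
#' Averages summarized intensities across the technical replicates of
#' each sample and computes per-sample CVs, the A/B fold change (larger
#' mean over smaller) and the strict monotonicity indicator.
#'
#' @param summarized Probesets x arrays matrix (e.g. from
#'   [summarize_probesets()]).
#' @param sample_sheet Data frame with columns `array_id`, `sample`
#'   (A/B/C/D) and `replicate`.
#' @return Data frame: probeset_id, a, b, c, d (replicate means), cv_a,
#'   cv_b, cv_c, cv_d, fold_change, monotonic.
#' @export
titration_summary <- function(summarized, sample_sheet) {
  stopifnot(all(c("array_id", "sample") %in% names(sample_sheet)),
            all(sample_sheet$array_id %in% colnames(summarized)),
            all(c("A", "B", "C", "D") %in% sample_sheet$sample))
  cols <- function(s) sample_sheet$array_id[sample_sheet$sample == s]
  mean_of <- function(s) {
    rowMeans(summarized[, cols(s), drop = FALSE])
  }
  cv_of <- function(s) {
    block <- summarized[, cols(s), drop = FALSE]
    if (ncol(block) < 2L) return(rep(NA_real_, nrow(block)))
    apply(block, 1L, function(v) stats::sd(v) / mean(v))
  }
  a <- mean_of("A"); b <- mean_of("B"); c <- mean_of("C"); d <- mean_of("D")
  data.frame(
    probeset_id = rownames(summarized),
    a = a, b = b, c = c, d = d,
    cv_a = cv_of("A"), cv_b = cv_of("B"),
    cv_c = cv_of("C"), cv_d = cv_of("D"),
    fold_change = pmax(a, b) / pmin(a, b),
    monotonic = titration_monotonic(a, c, d, b),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Titration response as a function of the A/B fold change
#'
#' Bins probesets by fold change and reports, per bin, the percentage
#' with a strictly monotonic titration ordering.
#'
#' @param summaries Data frame from [titration_summary()].
#' @param bins Fold-change bin edges (increasing; values outside are
#'   dropped).
#' @return Data frame of class `titration_curve`: bin_lo, bin_hi, mid, n,
#'   pct_monotonic.
#' @export
titration_curve <- function(summaries, bins) {
  stopifnot(length(bins) >= 2L, !is.unsorted(bins))
  idx <- cut(summaries$fold_change, bins, include.lowest = TRUE,
             right = FALSE, labels = FALSE)
  lo <- bins[-length(bins)]
  hi <- bins[-1L]
  n <- tabulate(idx, nbins = length(lo))
  pct <- vapply(seq_along(lo), function(k) {
    if (n[k] == 0L) return(NA_real_)
    100 * mean(summaries$monotonic[which(idx == k)])
  }, numeric(1))
  structure(
    data.frame(bin_lo = lo, bin_hi = hi, mid = (lo + hi) / 2,
               n = n, pct_monotonic = pct, stringsAsFactors = FALSE),
    class = c("titration_curve", "data.frame"))
}

#' Fold-change ratio at which a titration level is attained
#'
#' Smallest fold change at which the titration curve first reaches
#' `level`, by linear interpolation between bin midpoints.  If the first
#' populated bin already meets the level its midpoint is returned; if the
#' curve never reaches the level, `NA` ("not attained") with a warning.
#'
#' @param curve A [titration_curve()] result.
#' @param level Required monotonic proportion (default 0.75).
#' @return Fold-change ratio, or `NA_real_` if not attained.
#' @export
ratio_at <- function(curve, level = 0.75) {
  lvl <- 100 * level
  cc <- curve[curve$n > 0L, , drop = FALSE]
  if (nrow(cc) == 0L) stop("titration curve has no populated bins")
  if (cc$pct_monotonic[1L] >= lvl) return(cc$mid[1L])
  for (k in 2:nrow(cc)) {
    if (cc$pct_monotonic[k] >= lvl) {
      x0 <- cc$mid[k - 1L]; x1 <- cc$mid[k]
      y0 <- cc$pct_monotonic[k - 1L]; y1 <- cc$pct_monotonic[k]
      return(x0 + (lvl - y0) * (x1 - x0) / (y1 - y0))
    }
  }
  warning("titration level not attained at any fold change")
  NA_real_
}

#' Estimate mixture fractions from titration samples
#'
#' Under the linearity assumption a mixture signal is
#' `mix = alpha * A + beta * B`.  The default (`method = "pooled"`) fits
#' one ordinary least-squares regression of the mixture summaries on the
#' A and B summaries across probesets, without intercept and without the
#' `alpha + beta = 1` constraint; it is exact on noiseless mixtures.
#' `method = "per_probeset"` instead solves the constrained
#' (`alpha + beta = 1`) estimate `beta = (a - mix) / (a - b)` separately
#' per probeset and reports the median, matching how per-probeset
#' mixture-fraction distributions are usually summarized; probesets with
#' nearly equal A and B (non-identifiable) are skipped with a warning,
#' which is why the estimate is conventionally restricted to probesets
#' passing the differential-expression filter.
#'
#' @param a,b,mix Numeric vectors over probesets: replicate-mean
#'   summaries of samples A, B and the mixture (C or D).
#' @param method `"pooled"` (default) or `"per_probeset"`.
#' @param min_denom Relative |a - b| below which a probeset is considered
#'   non-identifiable for the per-probeset method.
#' @return Named vector `c(alpha = ..., beta = ...)`.
#' @export
estimate_mixture <- function(a, b, mix, method = c("pooled", "per_probeset"),
                             min_denom = 1e-8) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(b) == length(mix),
            length(a) >= 2L)
  if (method == "pooled") {
    X <- cbind(a = a, b = b)
    if (qr(X)$rank < 2L) {
      stop("A and B summaries are collinear across probesets; ",
           "mixture fractions are not identifiable")
    }
    co <- stats::lm.fit(X, mix)$coefficients
    return(c(alpha = unname(co["a"]), beta = unname(co["b"])))
  }
  denom <- a - b
  ok <- abs(denom) > min_denom * pmax(abs(a), abs(b))
  if (!all(ok)) {
    warning(sum(!ok), " probeset(s) with collinear A and B skipped")
  }
  if (!any(ok)) stop("no identifiable probeset for mixture estimation")
  beta <- (a[ok] - mix[ok]) / denom[ok]
  c(alpha = 1 - stats::median(beta), beta = stats::median(beta))
}

#' Differential-expression filter between samples A and B
#'
#' Welch t-test per probeset on the replicate summaries, with
#' Benjamini-Hochberg adjustment across probesets.  A probeset is kept if
#' its q-value is at most `q_threshold`, its fold change (either
#' direction) is at least `fc_threshold`, and the median of its technical
#' replicates is at least `floor` in at least one sample (so that kept
#' probesets are out of the background noise).  Probesets with zero
#' variance in both samples get p = 0 when the means differ and p = 1
#' otherwise.
#'
#' @param a,b Probesets x replicates matrices of summarized intensities
#'   (>= 2 replicates each), linear scale.
#' @param q_threshold Q-value cutoff (default 0.01).
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param floor Median-intensity floor (default 16 = 2^4).
#' @return Data frame: probeset_id, mean_a, mean_b, fold_change, p, q,
#'   above_floor, keep.
#' @export
de_filter <- function(a, b, q_threshold = 0.01, fc_threshold = 2,
                      floor = 16) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b),
            ncol(a) >= 2L, ncol(b) >= 2L)
  ids <- rownames(a)
  if (is.null(ids)) ids <- paste0("ps", seq_len(nrow(a)))
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  ma <- rowMeans(a); mb <- rowMeans(b)
  fc <- pmax(ma, mb) / pmin(ma, mb)
  med_a <- apply(a, 1L, stats::median)
  med_b <- apply(b, 1L, stats::median)
  above <- med_a >= floor | med_b >= floor
  data.frame(
    probeset_id = ids, mean_a = ma, mean_b = mb, fold_change = fc,
    p = p, q = q, above_floor = above,
    keep = q <= q_threshold & fc >= fc_threshold & above,
    stringsAsFactors = FALSE, row.names = NULL)
}
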