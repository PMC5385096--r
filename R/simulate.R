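# Seed-deterministic synthetic data: degenerate probe training designs,
# ground-truth models, intensity matrices under the product-plus-noise
# intensity model, titration designs, and repetitive sequence families
# with planted paralogs.  Every generator emits its ground truth
# alongside the data so that round-trip fitting can be checked.

#' Random DNA sequence
#'
#' @param n Length in nt.
#' @param no_runs If TRUE, forbid equal adjacent bases (so every
#'   single-base deletion yields a distinct sequence).
#' @return A DNA string.  Uses the current RNG state.
#' @export
random_dna <- function(n, no_runs = FALSE) {
  if (!no_runs) return(paste(sample(DNA_BASES, n, replace = TRUE),
                             collapse = ""))
  s <- character(n)
  s[1] <- sample(DNA_BASES, 1L)
  for (i in seq_len(n - 1L) + 1L) {
    s[i] <- sample(setdiff(DNA_BASES, s[i - 1L]), 1L)
  }
  paste(s, collapse = "")
}

substitute_base <- function(seq, pos, base) {
  paste0(substr(seq, 1L, pos - 1L), base,
         substr(seq, pos + 1L, nchar(seq)))
}

delete_base <- function(seq, pos) {
  paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + 1L, nchar(seq)))
}

#' Generate a degenerate-probe training design
#'
#' For each perfect-match (PM) probe, emits all single-mismatch variants
#' (75 for a 25-mer: 25 positions x 3 alternative bases), all single-base
#' deletion variants (25, deduplicated by sequence with the leftmost
#' position label kept, since deletions inside a homopolymer run
#' coincide), and distinct random double-mismatch variants filling the
#' remainder up to `variants_per_pm`.  With the default
#' `variants_per_pm = 180` and 10 PM probes per probeset this reproduces
#' the 1800 degenerate probes per training probeset.
#'
#' @param pm_probes Character vector of PM probe sequences (25-mers by
#'   convention), named or not.
#' @param variants_per_pm Number of degenerate variants per PM probe; at
#'   least `3 * L + L` (all single MMs plus all deletions).
#' @param seed Integer seed; the design is a pure function of it.
#' @return A list of class `degenerate_design` with a `probes` data frame
#'   (probe_id, probeset_id, parent_id, type in pm/mm1/mm2/gap,
#'   positions, sequence) where each PM parent is its probeset's target.
#' @export
make_degenerate_design <- function(pm_probes, variants_per_pm = 180L,
                                   seed = 1L) {
  L <- unique(nchar(pm_probes))
  stopifnot(length(L) == 1L, all(grepl("^[ACGT]+$", pm_probes)))
  min_var <- 3L * L + L
  if (variants_per_pm < min_var) {
    stop("variants_per_pm must be at least ", min_var,
         " (all single MMs plus all single deletions)")
  }
  if (is.null(names(pm_probes))) {
    names(pm_probes) <- sprintf("pm%03d", seq_along(pm_probes))
  }
  set.seed(seed)
  rows <- list()
  for (pm_id in names(pm_probes)) {
    pm <- pm_probes[[pm_id]]
    seen <- pm
    cnt <- c(pm = 0L, mm1 = 0L, mm2 = 0L, gap = 0L)
    add <- function(type, positions, sequence) {
      cnt[type] <<- cnt[type] + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        probe_id = sprintf("%s_%s_%03d", pm_id, type, cnt[[type]]),
        probeset_id = pm_id, parent_id = pm_id, type = type,
        positions = positions, sequence = sequence,
        stringsAsFactors = FALSE)
    }
    add("pm", "", pm)
    # all single mismatches: 3L variants, always distinct
    for (pos in seq_len(L)) {
      ref <- substr(pm, pos, pos)
      for (alt in setdiff(DNA_BASES, ref)) {
        v <- substitute_base(pm, pos, alt)
        add("mm1", sprintf("%d%s", pos, alt), v)
        seen <- c(seen, v)
      }
    }
    # all single deletions, deduplicated by sequence (leftmost label)
    n_gap <- 0L
    for (pos in seq_len(L)) {
      v <- delete_base(pm, pos)
      if (v %in% seen) next
      add("gap", sprintf("d%d", pos), v)
      seen <- c(seen, v)
      n_gap <- n_gap + 1L
    }
    # distinct random double mismatches to fill the budget
    n_mm2 <- variants_per_pm - 3L * L - n_gap
    made <- 0L
    while (made < n_mm2) {
      pos <- sort(sample(L, 2L))
      alts <- vapply(pos, function(p) {
        sample(setdiff(DNA_BASES, substr(pm, p, p)), 1L)
      }, character(1))
      v <- substitute_base(substitute_base(pm, pos[1], alts[1]),
                           pos[2], alts[2])
      if (v %in% seen) next
      add("mm2", paste(sprintf("%d%s", pos, alts), collapse = ","), v)
      seen <- c(seen, v)
      made <- made + 1L
    }
  }
  probes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(probes = probes, pm_probes = pm_probes,
                 variants_per_pm = as.integer(variants_per_pm),
                 seed = as.integer(seed)),
            class = "degenerate_design")
}

#' @export
print.degenerate_design <- function(x, ...) {
  cat(sprintf(
    "degenerate design: %d probesets x (1 PM + %d variants) = %d probes (seed %d)\n",
    length(x$pm_probes), x$variants_per_pm, nrow(x$probes), x$seed))
  print(table(x$probes$type))
  invisible(x)
}

#' Feature vectors and target map for a degenerate design
#'
#' Aligns every probe of the design to its probeset's PM target and
#' extracts features.
#'
#' @param design A [make_degenerate_design()] result.
#' @param max_mm,max_gaps Alignment budget (double MMs need
#'   `max_mm >= 2`).
#' @return A list: `features` (named list of feature vectors),
#'   `probe_to_target` (named character).
#' @export
design_features <- function(design, max_mm = 3L, max_gaps = 1L) {
  pr <- design$probes
  features <- vector("list", nrow(pr))
  names(features) <- pr$probe_id
  for (i in seq_len(nrow(pr))) {
    aln <- align_duplex(pr$sequence[i], design$pm_probes[[pr$probeset_id[i]]],
                        max_mm = max_mm, max_gaps = max_gaps,
                        target_id = pr$probeset_id[i])
    features[[i]] <- extract_features(aln)
  }
  list(features = features,
       probe_to_target = stats::setNames(pr$probeset_id, pr$probe_id))
}

#' Draw a ground-truth model and expression matrix
#'
#' Draws sparse k-mer coefficients (PM tokens positive, MM and GAP tokens
#' shifted negative so that mispairing lowers affinity), negative
#' interaction coefficients, and positive expression levels renormalized
#' to the per-target constraint.
#'
#' @param tokens Character vector of k-mer tokens the truth is drawn over
#'   (e.g. the tokens observed in a design, or a vocabulary's `tokens`).
#' @param n_arrays,n_targets Dimensions of the expression matrix.
#' @param sparsity Fraction of tokens with a nonzero coefficient, in
#'   (0, 1].  The default 0.10 keeps the support well below the number
#'   of distinct probes in a typical training design (the sparse,
#'   identifiable regime parameter-recovery experiments presuppose).
#' @param pm_range Uniform range for PM token coefficients (positive).
#' @param mm_range Uniform range for MM/GAP token coefficients (negative).
#' @param delta_range Uniform range for interaction coefficients
#'   (negative).
#' @param seed Integer seed.
#' @return A list of class `sim_truth`: `model` (a [pehm_model()]),
#'   `theta` (arrays x targets, constraint-normalized), `seed`.
#' @export
sample_truth <- function(tokens, n_arrays, n_targets, sparsity = 0.10,
                         pm_range = c(0.05, 0.40),
                         mm_range = c(-0.50, -0.05),
                         delta_range = c(-0.40, -0.05), seed = 1L) {
  stopifnot(sparsity > 0, sparsity <= 1)
  set.seed(seed)
  is_pm <- grepl("\\|PM\\|", tokens)
  nz <- stats::runif(length(tokens)) <= sparsity
  co <- numeric(length(tokens))
  co[nz & is_pm] <- stats::runif(sum(nz & is_pm), pm_range[1], pm_range[2])
  co[nz & !is_pm] <- stats::runif(sum(nz & !is_pm), mm_range[1], mm_range[2])
  names(co) <- tokens
  delta <- stats::setNames(
    stats::runif(3, delta_range[1], delta_range[2]),
    paste0("int|", c("adjacent", "near", "far")))
  if (sparsity < 1) {
    keep <- stats::runif(3) <= sparsity
    delta[!keep] <- 0
  }
  theta <- matrix(abs(stats::rnorm(n_arrays * n_targets, 1, 0.4)) + 0.1,
                  n_arrays, n_targets)
  theta <- apply(theta, 2L, renormalize_theta, N = n_arrays)
  colnames(theta) <- sprintf("t%03d", seq_len(n_targets))
  model <- pehm_model(beta = co[co != 0], delta = delta[delta != 0])
  structure(list(model = model, theta = theta, seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate an intensity matrix under the product model
#'
#' `I[j, i] = theta[i, g(j)] * phi[j] + eps`, with independent Gaussian
#' noise of standard deviation `sigma`; `sigma = 0` gives the exact
#' products.
#'
#' @param truth A [sample_truth()] result (or any list with `model` and
#'   `theta`).
#' @param features Named list of probe feature vectors.
#' @param probe_to_target Named probe -> target map; targets must index
#'   columns of `truth$theta`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return Probes x arrays intensity matrix with attribute `phi` (the
#'   true affinities).
#' @export
simulate_intensities <- function(truth, features, probe_to_target,
                                 sigma = 0, seed = 1L) {
  stopifnot(sigma >= 0)
  probes <- names(features)
  phi <- affinity(truth$model, features)
  tcols <- match(unname(probe_to_target[probes]), colnames(truth$theta))
  stopifnot(!anyNA(tcols))
  n_arrays <- nrow(truth$theta)
  I <- matrix(phi, length(probes), n_arrays) *
    t(truth$theta[, tcols, drop = FALSE])
  if (sigma > 0) {
    set.seed(seed)
    I <- I + matrix(stats::rnorm(length(I), 0, sigma),
                    nrow(I), ncol(I))
  }
  dimnames(I) <- list(probes, sprintf("array%02d", seq_len(n_arrays)))
  attr(I, "phi") <- stats::setNames(phi, probes)
  I
}

#' Simulate a titration design
#'
#' Per-target abundances for pure samples A and B are mixed at the stated
#' concentration fractions (defaults: C = 0.75 A + 0.25 B,
#' D = 0.25 A + 0.75 B) and intensities are generated per technical
#' replicate under the product model with independent noise.
#'
#' @param phi Named numeric vector of probe affinities.
#' @param probe_to_target Named probe -> target map.
#' @param theta_a,theta_b Named per-target abundances in samples A and B.
#' @param fractions Named list of `c(alpha, beta)` per sample; each must
#'   sum to 1.
#' @param replicates Technical replicates per sample (default 3; a single
#'   replicate is flagged with a warning because downstream CVs need at
#'   least 2).
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return A list: `intensities` (probes x arrays), `sample_sheet`
#'   (array_id, sample, replicate), `theta` (targets x samples
#'   concentration levels).
#' @export
simulate_titration <- function(phi, probe_to_target, theta_a, theta_b,
                               fractions = list(A = c(1, 0), B = c(0, 1),
                                                C = c(0.75, 0.25),
                                                D = c(0.25, 0.75)),
                               replicates = 3L, sigma = 0, seed = 1L) {
  stopifnot(length(theta_a) == length(theta_b), sigma >= 0,
            replicates >= 1L)
  bad <- vapply(fractions, function(f) abs(sum(f) - 1) > 1e-12, logical(1))
  if (any(bad)) stop("mixture fractions must sum to 1: ",
                     paste(names(fractions)[bad], collapse = ", "))
  if (replicates < 2L) {
    warning("fewer than 2 replicates: downstream CVs are not computable")
  }
  targets <- names(theta_a)
  if (is.null(targets)) {
    targets <- sprintf("t%03d", seq_along(theta_a))
    names(theta_a) <- names(theta_b) <- targets
  }
  probes <- names(phi)
  tmix <- vapply(fractions, function(f) f[1] * theta_a + f[2] * theta_b,
                 numeric(length(theta_a)))
  rownames(tmix) <- targets
  sheet <- expand.grid(replicate = seq_len(replicates),
                       sample = names(fractions),
                       stringsAsFactors = FALSE)[, c("sample", "replicate")]
  sheet$array_id <- sprintf("%s_r%d", sheet$sample, sheet$replicate)
  set.seed(seed)
  I <- matrix(NA_real_, length(probes), nrow(sheet),
              dimnames = list(probes, sheet$array_id))
  tg <- unname(probe_to_target[probes])
  for (k in seq_len(nrow(sheet))) {
    mu <- phi * tmix[tg, sheet$sample[k]]
    I[, k] <- if (sigma > 0) mu + stats::rnorm(length(mu), 0, sigma) else mu
  }
  list(intensities = I, sample_sheet = sheet[, c("array_id", "sample",
                                                 "replicate")],
       theta = tmix)
}

#' Simulate a repetitive sequence family with planted paralogs
#'
#' One ancestral sequence is mutated independently into `n_loci` paralogs
#' at the stated per-site substitution rate; the planted substitution
#' positions are recorded for oracle checks.  Divergence 0 yields
#' identical loci (the worst case for cross-hybridization: with 4 or
#' more loci every probe is non-specific).
#'
#' @param n_loci Number of paralogous loci.
#' @param length Locus length in nt.
#' @param divergence Per-site substitution rate in \[0, 0.5\].
#' @param seed Integer seed.
#' @return Named character vector of locus sequences with attributes
#'   `ancestor` and `substitutions` (list of 1-based mutated positions
#'   per locus).
#' @export
simulate_family <- function(n_loci, length = 400L, divergence = 0.05,
                            seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.5, n_loci >= 1L)
  set.seed(seed)
  anc <- random_dna(length)
  anc_chars <- strsplit(anc, "")[[1]]
  loci <- character(n_loci)
  subs <- vector("list", n_loci)
  for (k in seq_len(n_loci)) {
    mut <- which(stats::runif(length) < divergence)
    chars <- anc_chars
    for (p in mut) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    loci[k] <- paste(chars, collapse = "")
    subs[[k]] <- mut
  }
  names(loci) <- sprintf("locus%02d", seq_len(n_loci))
  names(subs) <- names(loci)
  attr(loci, "ancestor") <- anc
  attr(loci, "substitutions") <- subs
  loci
}
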