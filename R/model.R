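# The intensity/affinity model.
#
# Intensity of probe j on array i:  I_ij = theta_i * phi_j + eps_ij,
# eps ~ N(0, sigma^2), with the identifiability constraint that for each
# target the sum of squared theta over arrays equals the number of arrays.
# Affinity phi_j is a sparse linear form over region-tagged pentamer
# tokens (beta) and mismatch-interaction indicators (delta), estimated by
# LASSO.  Estimation alternates a glmnet beta-step with a closed-form
# least-squares theta-step under the constraint.

#' Construct a hybridization model
#'
#' @param beta Named numeric vector of k-mer token coefficients
#'   (region-tagged PM/MM/GAP pentamer tokens); absent tokens are exactly
#'   zero.
#' @param delta Named numeric vector of mismatch-interaction coefficients.
#' @param lasso_penalty Nonnegative LASSO penalty used in fitting.
#' @param hybridization_threshold Calibrated affinity threshold `T`, or
#'   `NA` before calibration.
#' @param noise_sd Residual standard deviation estimate, or `NA`.
#' @param vocabulary Optional [enumerate_vocabulary()] reference.
#' @return An object of class `pehm_model`.
#' @export
pehm_model <- function(beta = numeric(0), delta = numeric(0),
                       lasso_penalty = 0,
                       hybridization_threshold = NA_real_,
                       noise_sd = NA_real_, vocabulary = NULL) {
  stopifnot(lasso_penalty >= 0, is.na(noise_sd) || noise_sd >= 0)
  beta <- beta[beta != 0]
  delta <- delta[delta != 0]
  co <- c(beta, delta)
  coef_env <- if (length(co)) list2env(as.list(co), hash = TRUE,
                                       size = length(co)) else NULL
  structure(
    list(beta = beta, delta = delta, lasso_penalty = lasso_penalty,
         hybridization_threshold = hybridization_threshold,
         noise_sd = noise_sd, vocabulary = vocabulary,
         coef_env = coef_env),
    class = "pehm_model"
  )
}

#' @export
print.pehm_model <- function(x, ...) {
  cat(sprintf(
    "pehm model: %d nonzero k-mer coefficients, %d interaction coefficients\n",
    length(x$beta), length(x$delta)))
  cat(sprintf("  lasso penalty %.4g; hybridization threshold %s; noise sd %s\n",
              x$lasso_penalty,
              format(x$hybridization_threshold, digits = 4),
              format(x$noise_sd, digits = 4)))
  invisible(x)
}

#' Set the hybridization threshold on a model
#'
#' @param model A `pehm_model`.
#' @param threshold Affinity threshold, typically from
#'   [calibrate_threshold()].
#' @return The model with `hybridization_threshold` set.
#' @export
set_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "pehm_model"), is.finite(threshold))
  model$hybridization_threshold <- threshold
  model
}

#' Predict the affinity of a duplex
#'
#' The exact linear form: sum over feature tokens of coefficient times
#' count, plus interaction terms.  Coefficients absent from the model are
#' zero.
#'
#' @param model A `pehm_model`.
#' @param features A named feature-count vector from [extract_features()],
#'   or a list of them.
#' @return Scalar affinity, or a numeric vector for a list of features.
#' @examples
#' m <- pehm_model(beta = c("sense|1|PM|AAAAA" = 0.5))
#' affinity(m, c("sense|1|PM|AAAAA" = 2))  # 1
#' @export
affinity <- function(model, features) {
  stopifnot(inherits(model, "pehm_model"))
  env <- model$coef_env
  one <- function(fv) {
    if (length(fv) == 0L || is.null(env)) return(0)
    v <- unlist(mget(names(fv), envir = env, ifnotfound = 0),
                use.names = FALSE)
    sum(as.numeric(fv) * v)
  }
  if (is.list(features)) {
    vapply(features, one, numeric(1))
  } else {
    one(features)
  }
}

#' Predict a noiseless intensity
#'
#' Expectation of the intensity model: expression level times affinity.
#'
#' @param model A `pehm_model`.
#' @param features Feature vector(s) as in [affinity()].
#' @param theta Expression level(s).
#' @return `theta * affinity`.
#' @export
predict_intensity <- function(model, features, theta) {
  stopifnot(all(is.finite(theta)))
  theta * affinity(model, features)
}

#' Renormalize a per-target expression vector to the model constraint
#'
#' Scales `theta_g` so that the sum of squares over arrays equals `N`.
#'
#' @param theta_g Numeric vector of expression levels over arrays for one
#'   target (not all zero).
#' @param N Constraint constant, conventionally the number of arrays.
#' @return Rescaled vector with `sum(theta^2) == N`.
#' @examples
#' renormalize_theta(c(3, 4), 2)
#' @export
renormalize_theta <- function(theta_g, N) {
  ss <- sum(theta_g^2)
  if (ss == 0) stop("cannot renormalize an all-zero expression vector")
  theta_g * sqrt(N / ss)
}

# Sparse probes x tokens design matrix from a feature list.
feature_matrix <- function(features) {
  stopifnot(is.list(features), length(features) > 0L)
  tokens <- sort(unique(unlist(lapply(features, names), use.names = FALSE)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(features)) {
    fv <- features[[j]]
    if (length(fv) == 0L) next
    ii <- c(ii, rep.int(j, length(fv)))
    jj <- c(jj, match(names(fv), tokens))
    xx <- c(xx, as.numeric(fv))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(features), length(tokens)),
                       dimnames = list(names(features), tokens))
}

#' Fit the hybridization model by alternating constrained estimation
#'
#' Alternates (a) a LASSO regression of linear-scale intensities on
#' feature counts scaled by the current expression levels, the penalty
#' chosen once by `n_folds`-fold cross-validation over probes (folds
#' stratified by target; CV-minimum rule by default, the 1-SE rule
#' available via `lambda_rule`), and (b) a closed-form
#' per-(array, target) least-squares expression step followed by
#' renormalization to the constraint `sum_i theta_{i,g}^2 = N`
#' (N = number of arrays).  Iterates until the relative change in residual
#' sum of squares falls below `tol` or `max_iter` is reached.  Expression
#' is initialized from per-(array, target) mean intensities.
#'
#' @param intensities Numeric matrix, probes in rows (named), arrays in
#'   columns, linear scale.
#' @param features Named list mapping probe id to its feature vector.
#' @param probe_to_target Named character vector mapping probe id to
#'   target (gene/locus) id.
#' @param n_folds Cross-validation folds for the penalty (>= 2).
#' @param seed Integer seed for fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation.  `0`
#'   gives an (essentially) unpenalized fit.
#' @param lambda_rule `"min"` (default) or `"1se"` for the CV choice;
#'   with the relaxed refit the CV-minimum penalty recovers sparse truth
#'   markedly better, the 1-SE rule being too aggressive a selector here.
#' @param max_iter,tol Convergence controls.
#' @param theta_init Optional arrays x targets start matrix.
#' @param relax Relaxed LASSO (default TRUE): the penalty selects the
#'   active token set, which is then refit by unpenalized least squares,
#'   removing the shrinkage bias on the retained coefficients.
#' @return A list of class `pehm_fit`: `model` (a [pehm_model()]),
#'   `theta` (arrays x targets, constraint-normalized), `phi` (fitted
#'   affinities per probe), `rss_trace`, `constraint_trace` (max relative
#'   constraint deviation after each iteration), `converged`,
#'   `iterations`, and `flagged_targets` (all-zero-signal targets whose
#'   expression was set to the constraint-satisfying constant).
#' @export
fit_pehm <- function(intensities, features, probe_to_target,
                     n_folds = 10L, seed = 1L, lambda = NULL,
                     lambda_rule = c("min", "1se"),
                     max_iter = 100L, tol = 1e-6, theta_init = NULL,
                     relax = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(intensities), ncol(intensities) >= 2L, n_folds >= 2L)
  probes <- rownames(intensities)
  stopifnot(!is.null(probes), all(probes %in% names(features)),
            all(probes %in% names(probe_to_target)))
  n_probes <- length(probes)
  n_arrays <- ncol(intensities)
  targets <- sort(unique(unname(probe_to_target[probes])))
  tidx <- match(probe_to_target[probes], targets)
  N <- n_arrays

  X <- feature_matrix(features[probes])
  tokens <- colnames(X)

  # theta init: per-(array, target) mean intensity, then renormalized
  flagged <- character(0)
  if (is.null(theta_init)) {
    theta <- matrix(0, n_arrays, length(targets),
                    dimnames = list(colnames(intensities), targets))
    for (g in seq_along(targets)) {
      mu <- colMeans(intensities[tidx == g, , drop = FALSE])
      if (all(mu == 0)) {
        mu <- rep(1, n_arrays)
        flagged <- c(flagged, targets[g])
      }
      theta[, g] <- renormalize_theta(mu, N)
    }
  } else {
    theta <- theta_init
    stopifnot(nrow(theta) == n_arrays, ncol(theta) == length(targets))
  }

  # fold assignment: per probe, stratified by target, seeded
  foldid_probe <- integer(n_probes)
  set.seed(seed)
  for (g in seq_along(targets)) {
    jg <- which(tidx == g)
    # a fresh permutation of the fold labels per target keeps folds
    # stratified even when a target has fewer probes than folds
    foldid_probe[jg] <- sample(rep_len(sample.int(n_folds), length(jg)))
  }
  # drop globally empty fold labels (possible for tiny designs)
  foldid_probe <- match(foldid_probe, sort(unique(foldid_probe)))
  foldid_big <- rep(foldid_probe, n_arrays)

  ybig <- as.numeric(intensities)  # stacked by array (column-major)
  rss_trace <- numeric(0)
  constraint_trace <- numeric(0)
  converged <- FALSE
  beta_vec <- numeric(ncol(X))
  lam <- lambda

  for (it in seq_len(max_iter)) {
    # beta-step: rows are (probe, array), scaled by theta_{i, g(j)};
    # ybig stacks arrays column-major, so transpose to probes x arrays
    w <- as.numeric(t(theta[, tidx, drop = FALSE]))
    wmat <- matrix(w, n_probes * n_arrays, 1L)
    Xbig <- X[rep(seq_len(n_probes), n_arrays), , drop = FALSE] *
      wmat[, rep(1L, ncol(X)), drop = FALSE]
    if (is.null(lam)) {
      cvf <- glmnet::cv.glmnet(Xbig, ybig, foldid = foldid_big,
                               intercept = FALSE, standardize = TRUE)
      lam <- if (lambda_rule == "1se") cvf$lambda.1se else cvf$lambda.min
      beta_vec <- as.numeric(stats::coef(cvf, s = lam))[-1L]
    } else if (lam == 0) {
      # unpenalized least squares (the model's lambda -> 0 limit)
      fitls <- stats::lm.fit(as.matrix(Xbig), ybig)
      beta_vec <- ifelse(is.na(fitls$coefficients), 0, fitls$coefficients)
    } else {
      gf <- glmnet::glmnet(Xbig, ybig, lambda = lam, intercept = FALSE,
                           standardize = TRUE)
      beta_vec <- as.numeric(stats::coef(gf))[-1L]
    }
    if (relax && lam > 0) {
      # relaxed LASSO: the penalty selects the support, the active set is
      # then refit by unpenalized least squares to remove shrinkage bias
      active <- which(beta_vec != 0)
      if (length(active) > 0L) {
        fitls <- stats::lm.fit(as.matrix(Xbig[, active, drop = FALSE]),
                               ybig)
        refit <- ifelse(is.na(fitls$coefficients), 0, fitls$coefficients)
        beta_vec[] <- 0
        beta_vec[active] <- refit
      }
    }
    phi <- as.numeric(X %*% beta_vec)

    # theta-step: closed-form LS per (array, target), then renormalize
    for (g in seq_along(targets)) {
      jg <- which(tidx == g)
      denom <- sum(phi[jg]^2)
      if (denom == 0) {
        th <- rep(1, n_arrays)
      } else {
        th <- as.numeric(crossprod(intensities[jg, , drop = FALSE],
                                   phi[jg])) / denom
        # abundances are nonnegative: projected least squares, which also
        # pins the sign of the (theta, phi) product decomposition
        th <- pmax(th, 0)
        if (all(th == 0)) th <- rep(1, n_arrays)
      }
      theta[, g] <- renormalize_theta(th, N)
    }
    constraint_trace <- c(constraint_trace,
                          max(abs(colSums(theta^2) - N)) / N)

    # pred[j, i] = phi[j] * theta[i, g(j)]
    pred <- matrix(phi, n_probes, n_arrays) * t(theta[, tidx, drop = FALSE])
    rss <- sum((intensities - pred)^2)
    rss_trace <- c(rss_trace, rss)
    if (it > 1L) {
      prev <- rss_trace[it - 1L]
      if (prev == 0 || abs(prev - rss) / max(prev, .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
    }
  }

  names(beta_vec) <- tokens
  is_int <- startsWith(tokens, "int|")
  sigma <- sqrt(rss / (n_probes * n_arrays))
  model <- pehm_model(beta = beta_vec[!is_int], delta = beta_vec[is_int],
                      lasso_penalty = if (is.null(lam)) 0 else lam,
                      noise_sd = sigma)
  structure(
    list(model = model,
         theta = theta, phi = stats::setNames(phi, probes),
         targets = targets, N = N,
         rss_trace = rss_trace, constraint_trace = constraint_trace,
         converged = converged, iterations = length(rss_trace),
         flagged_targets = flagged, seed = seed),
    class = "pehm_fit"
  )
}

#' @export
print.pehm_fit <- function(x, ...) {
  cat(sprintf(
    "pehm fit: %d probes, %d arrays, %d targets; %d iterations (%s)\n",
    length(x$phi), nrow(x$theta), ncol(x$theta), x$iterations,
    if (x$converged) "converged" else "max_iter reached"))
  print(x$model)
  invisible(x)
}

#' Calibrate the hybridization threshold
#'
#' Scans candidate thresholds at the observed affinity values and returns
#' the largest affinity `T` such that, among probes with affinity strictly
#' below `T`, at least 90% (or `prop`) have median intensity across arrays
#' below `background`.  Duplicate affinities collapse to one candidate, so
#' ties resolve toward the smaller threshold.
#'
#' @param model A `pehm_model`.
#' @param features Named list of feature vectors for the probes (rows of
#'   `intensities`), ignored when `affinities` is given.
#' @param intensities Probes x arrays intensity matrix.
#' @param background Background noise level (e.g. from
#'   [background_trpn()]).
#' @param prop Required sub-background fraction (default 0.90).
#' @param affinities Optional precomputed affinity vector (same order as
#'   rows of `intensities`).
#' @return The threshold `T`.
#' @export
calibrate_threshold <- function(model, features, intensities, background,
                                prop = 0.90, affinities = NULL) {
  stopifnot(is.finite(background))
  phi <- if (is.null(affinities)) {
    affinity(model, features[rownames(intensities)])
  } else {
    affinities
  }
  stopifnot(length(phi) == nrow(intensities))
  med <- apply(intensities, 1L, stats::median)
  sub_bg <- med < background
  cand <- sort(unique(phi))
  ok <- vapply(cand, function(T) {
    below <- phi < T
    sum(below) > 0L && mean(sub_bg[below]) >= prop
  }, logical(1))
  if (!any(ok)) {
    stop("threshold not calibratable: no affinity cutoff isolates ",
         "sub-background probes (degenerate training data)")
  }
  max(cand[ok])
}

#' Held-out goodness of fit of predicted intensities
#'
#' For each target (probeset), expression is estimated on two-thirds of
#' its probes by regressing intensities on model affinities, and
#' intensities of the remaining third are predicted as expression times
#' affinity.  Returns the squared Pearson correlation between observed
#' and predicted held-out intensities.
#'
#' @param model A `pehm_model`.
#' @param intensities Probes x arrays intensity matrix.
#' @param features Named list of probe feature vectors.
#' @param probe_to_target Named probe -> target map.
#' @param holdout Fraction of probes held out per target (default 1/3).
#' @param seed Seed for the probe split.
#' @return R-squared between observed and predicted held-out intensities.
#' @export
evaluate_fit <- function(model, intensities, features, probe_to_target,
                         holdout = 1 / 3, seed = 1L) {
  probes <- rownames(intensities)
  phi <- affinity(model, features[probes])
  tg <- probe_to_target[probes]
  obs <- numeric(0); prd <- numeric(0)
  set.seed(seed)
  for (g in unique(tg)) {
    jg <- which(tg == g)
    if (length(jg) < 3L) {
      warning("probeset ", g, " has fewer than 3 probes; skipped")
      next
    }
    n_hold <- max(1L, round(length(jg) * holdout))
    hold <- sample(jg, n_hold)
    train <- setdiff(jg, hold)
    denom <- sum(phi[train]^2)
    if (denom == 0) next
    th <- as.numeric(crossprod(intensities[train, , drop = FALSE],
                               phi[train])) / denom  # per array
    pred <- outer(phi[hold], th)
    obs <- c(obs, as.numeric(intensities[hold, , drop = FALSE]))
    prd <- c(prd, as.numeric(pred))
  }
  if (length(obs) == 0L) {
    warning("no probeset large enough to evaluate")
    return(NA_real_)
  }
  if (stats::sd(obs) == 0 || stats::sd(prd) == 0) return(0)
  stats::cor(obs, prd)^2
}

#' Serialize a model to a versioned text format
#'
#' Header lines carry the penalty, threshold, noise SD and vocabulary
#' summary; the body is sparse coefficient triples (class, token, value).
#'
#' @param model A `pehm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pehm_model <- function(model, path) {
  stopifnot(inherits(model, "pehm_model"))
  con <- file(path, "w")
  on.exit(close(con))
  vsum <- if (is.null(model$vocabulary)) "none" else
    sprintf("%d/%d", model$vocabulary$counts$total,
            model$vocabulary$orientations)
  writeLines(c(
    "# pehm_model v1",
    sprintf("# lasso_penalty\t%.17g", model$lasso_penalty),
    sprintf("# hybridization_threshold\t%.17g", model$hybridization_threshold),
    sprintf("# noise_sd\t%.17g", model$noise_sd),
    sprintf("# vocabulary\t%s", vsum),
    "class\ttoken\tvalue"), con)
  if (length(model$beta)) {
    writeLines(paste("beta", names(model$beta),
                     sprintf("%.17g", model$beta), sep = "\t"), con)
  }
  if (length(model$delta)) {
    writeLines(paste("delta", names(model$delta),
                     sprintf("%.17g", model$delta), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a model written by [write_pehm_model()]
#'
#' @param path Path to a `pehm_model v1` text file.
#' @return A `pehm_model`.
#' @export
read_pehm_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# pehm_model v1")) {
    stop("not a pehm_model v1 file: ", path)
  }
  hdr <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), lines, value = TRUE)[1]
    val <- sub(".*\t", "", ln)
    if (is.na(ln) || val %in% c("NA", "nan", "-nan")) return(NA_real_)
    as.numeric(val)
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L]  # column header
  beta <- numeric(0); delta <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    cls <- vapply(parts, `[[`, character(1), 1L)
    tok <- vapply(parts, function(p) paste(p[-c(1L, length(p))],
                                           collapse = "\t"), character(1))
    val <- as.numeric(vapply(parts, function(p) p[[length(p)]], character(1)))
    beta <- stats::setNames(val[cls == "beta"], tok[cls == "beta"])
    delta <- stats::setNames(val[cls == "delta"], tok[cls == "delta"])
  }
  pehm_model(beta = beta, delta = delta, lasso_penalty = hdr("lasso_penalty"),
             hybridization_threshold = hdr("hybridization_threshold"),
             noise_sd = hdr("noise_sd"))
}
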