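# Affinity arithmetic, constraint handling, the alternating fit,
# threshold calibration and held-out evaluation.

test_that("affinity is the exact sparse linear form", {
  m <- pehm_model(beta = c(tokA = 0.5, tokB = 0.5))
  expect_equal(affinity(m, numeric(0)), 0)
  expect_equal(affinity(m, c(tokA = 1, tokB = 3)), 2.0)
  # unknown tokens contribute zero
  expect_equal(affinity(m, c(tokA = 1, other = 100)), 0.5)
  # adding an MM token with negative coefficient strictly lowers affinity
  m2 <- pehm_model(beta = c(tokA = 0.5, mmX = -0.3))
  expect_lt(affinity(m2, c(tokA = 2, mmX = 1)),
            affinity(m2, c(tokA = 2)))
  # vectorized over a feature list
  expect_equal(affinity(m, list(a = c(tokA = 1), b = c(tokB = 2))),
               c(a = 0.5, b = 1.0))
})

test_that("predict_intensity is theta times affinity", {
  m <- pehm_model(beta = c(tokA = 3))
  expect_equal(predict_intensity(m, c(tokA = 1), 0), 0)
  expect_equal(predict_intensity(m, c(tokA = 1), 2), 6)
})

test_that("theta renormalization enforces the sum-of-squares constraint", {
  expect_equal(renormalize_theta(c(1, 1, 1, 1), 4), c(1, 1, 1, 1))
  expect_equal(renormalize_theta(c(3, 4), 2),
               c(3, 4) * sqrt(2 / 25), tolerance = 1e-12)
  expect_equal(renormalize_theta(c(2, 0, 0, 0), 4), c(2, 0, 0, 0))
  expect_error(renormalize_theta(c(0, 0), 2), "all-zero")
  set.seed(201)
  for (rep in 1:20) {
    v <- rnorm(sample(2:10, 1))
    if (all(v == 0)) next
    N <- sample(2:10, 1)
    expect_equal(sum(renormalize_theta(v, N)^2), N, tolerance = 1e-12)
  }
})

test_that("unpenalized small-system fit matches the normal equations", {
  # tiny instance: features few enough for a direct least-squares oracle
  set.seed(202)
  n_probes <- 12
  toknames <- paste0("tok", 1:8)
  features <- lapply(seq_len(n_probes), function(j) {
    k <- sample(3:6, 1)
    stats::setNames(sample(1:3, k, replace = TRUE), sample(toknames, k))
  })
  names(features) <- paste0("p", seq_len(n_probes))
  p2t <- stats::setNames(rep(c("g1", "g2"), each = 6), names(features))
  beta_true <- stats::setNames(runif(8, 0.2, 1), toknames)
  theta <- matrix(abs(rnorm(8, 1, 0.3)) + 0.2, 4, 2,
                  dimnames = list(NULL, c("g1", "g2")))
  theta <- apply(theta, 2, renormalize_theta, N = 4)
  phi <- vapply(features, function(fv)
    sum(fv * beta_true[names(fv)]), numeric(1))
  I <- matrix(phi, n_probes, 4) * t(theta[, p2t[names(features)]])
  rownames(I) <- names(features)

  fit <- fit_pehm(I, features, p2t, lambda = 0, max_iter = 1,
                  theta_init = theta)
  # oracle: solve the normal equations directly on the stacked system
  X <- matrix(0, n_probes, 8, dimnames = list(names(features), toknames))
  for (j in seq_len(n_probes)) X[j, names(features[[j]])] <- features[[j]]
  Xbig <- do.call(rbind, lapply(1:4, function(i)
    X * theta[i, p2t[names(features)]]))
  ybig <- as.numeric(I)
  beta_ne <- solve(crossprod(Xbig), crossprod(Xbig, ybig))[, 1]
  co <- c(fit$model$beta, fit$model$delta)
  expect_equal(unname(co[toknames]), unname(beta_ne), tolerance = 1e-8)
  expect_equal(unname(fit$phi), unname(phi), tolerance = 1e-8)
})

test_that("noiseless simulated data is recovered near-exactly", {
  set.seed(203)
  pms <- stats::setNames(replicate(8, random_dna(25, no_runs = TRUE)),
                         sprintf("t%02d", 1:8))
  dd <- make_degenerate_design(pms, variants_per_pm = 100, seed = 31)
  pr <- dd$probes
  keep <- unlist(lapply(split(seq_len(nrow(pr)), pr$probeset_id),
                        function(ix) {
    c(ix[pr$type[ix] == "pm"], sample(ix[pr$type[ix] != "pm"], 11))
  }))
  dd$probes <- pr[sort(keep), ]
  fx <- design_features(dd)
  tokens <- sort(unique(unlist(lapply(fx$features, names))))
  tokens <- tokens[!startsWith(tokens, "int|")]
  truth <- sample_truth(tokens, n_arrays = 8, n_targets = 8, seed = 32)
  colnames(truth$theta) <- names(pms)
  I <- simulate_intensities(truth, fx$features, fx$probe_to_target,
                            sigma = 0, seed = 33)
  fit <- fit_pehm(I, fx$features, fx$probe_to_target, seed = 34)
  expect_gte(cor(fit$phi, attr(I, "phi"))^2, 0.99)
  # constraint holds after every iteration
  expect_lt(max(fit$constraint_trace), 1e-9)
})

test_that("fitted affinities scale linearly with the intensity scale", {
  # theta is pinned by the constraint, so scaling I by c scales phi by c;
  # exact on an unpenalized fit
  set.seed(204)
  toknames <- paste0("tok", 1:6)
  features <- lapply(1:8, function(j) {
    stats::setNames(sample(1:2, 3, replace = TRUE), sample(toknames, 3))
  })
  names(features) <- paste0("p", 1:8)
  p2t <- stats::setNames(rep("g1", 8), names(features))
  beta_true <- stats::setNames(runif(6, 0.2, 1), toknames)
  phi <- vapply(features, function(fv)
    sum(fv * beta_true[names(fv)]), numeric(1))
  theta <- renormalize_theta(abs(rnorm(3, 1, 0.2)) + 0.2, 3)
  I <- outer(phi, theta)
  rownames(I) <- names(features)
  f1 <- fit_pehm(I, features, p2t, lambda = 0, max_iter = 5)
  f2 <- fit_pehm(10 * I, features, p2t, lambda = 0, max_iter = 5)
  expect_equal(unname(f2$phi), unname(10 * f1$phi), tolerance = 1e-6)
})

test_that("an all-zero-signal target is flagged and satisfies the constraint", {
  set.seed(205)
  features <- list(p1 = c(a = 1), p2 = c(b = 1), p3 = c(a = 1, b = 1),
                   p4 = c(a = 2))
  p2t <- stats::setNames(c("g1", "g1", "g2", "g2"), names(features))
  I <- rbind(p1 = c(1, 2), p2 = c(2, 4), p3 = c(0, 0), p4 = c(0, 0))
  fit <- fit_pehm(I, features, p2t, lambda = 0, max_iter = 3)
  expect_true("g2" %in% fit$flagged_targets)
  expect_equal(unname(colSums(fit$theta^2)), c(2, 2), tolerance = 1e-9)
})

test_that("threshold calibration returns the boundary of a step dataset", {
  # constructed step case: probes with affinity < 5 sit below background,
  # probes with affinity >= 5 above
  phi <- as.numeric(1:10)
  med <- ifelse(phi < 5, 1, 100)
  I <- cbind(med, med, med)
  rownames(I) <- paste0("p", seq_along(phi))
  m <- pehm_model()
  T <- calibrate_threshold(m, NULL, I, background = 50, affinities = phi)
  expect_equal(T, 5)
  # recount: the rule holds at the returned threshold
  expect_gte(mean(med[phi < T] < 50), 0.90)
  # raising the background never decreases the threshold
  T2 <- calibrate_threshold(m, NULL, I, background = 150, affinities = phi)
  expect_gte(T2, T)
  # degenerate data: nothing below background at any cutoff
  expect_error(
    calibrate_threshold(m, NULL, I, background = 0.5, affinities = phi),
    "not calibratable")
})

test_that("held-out evaluation is exact on noiseless data and degrades", {
  set.seed(206)
  pms <- stats::setNames(replicate(4, random_dna(25, no_runs = TRUE)),
                         sprintf("g%02d", 1:4))
  dd <- make_degenerate_design(pms, variants_per_pm = 100, seed = 61)
  pr <- dd$probes
  keep <- unlist(lapply(split(seq_len(nrow(pr)), pr$probeset_id),
                        function(ix) {
    c(ix[pr$type[ix] == "pm"], sample(ix[pr$type[ix] != "pm"], 8))
  }))
  dd$probes <- pr[sort(keep), ]
  fx <- design_features(dd)
  tokens <- sort(unique(unlist(lapply(fx$features, names))))
  truth <- sample_truth(tokens[!startsWith(tokens, "int|")],
                        n_arrays = 3, n_targets = 4, seed = 62)
  colnames(truth$theta) <- names(pms)
  I0 <- simulate_intensities(truth, fx$features, fx$probe_to_target,
                             sigma = 0, seed = 63)
  r2_clean <- evaluate_fit(truth$model, I0, fx$features,
                           fx$probe_to_target, seed = 64)
  expect_equal(r2_clean, 1.0, tolerance = 1e-9)
  In <- simulate_intensities(truth, fx$features, fx$probe_to_target,
                             sigma = 0.5 * mean(abs(I0)), seed = 63)
  r2_noisy <- evaluate_fit(truth$model, In, fx$features,
                           fx$probe_to_target, seed = 64)
  expect_lt(r2_noisy, r2_clean)
  # shuffling the probe -> feature assignment destroys the prediction
  shuffled <- fx$features[sample(length(fx$features))]
  names(shuffled) <- names(fx$features)
  # (array-to-array scale is still captured by the expression step, so
  # the null does not reach zero, but the sequence signal is gone)
  r2_null <- evaluate_fit(truth$model, I0, shuffled, fx$probe_to_target,
                          seed = 64)
  expect_lt(r2_null, r2_clean - 0.15)
})

test_that("a tiny probeset is skipped with a warning in evaluation", {
  m <- pehm_model(beta = c(a = 1))
  I <- rbind(p1 = c(1, 2), p2 = c(1, 2))
  feats <- list(p1 = c(a = 1), p2 = c(a = 2))
  expect_warning(
    expect_warning(r2 <- evaluate_fit(m, I, feats, c(p1 = "g", p2 = "g")),
                   "fewer than 3"),
    "no probeset")
  expect_true(is.na(r2))
})

test_that("model serialization round-trips through the text format", {
  m <- pehm_model(beta = c("sense|1|PM|ACGTA" = 0.25,
                           "sense|2|MM|ACGTA|3|G" = -0.5),
                  delta = c("int|adjacent" = -0.1),
                  lasso_penalty = 0.02, noise_sd = 0.3)
  m <- set_threshold(m, 4.25)
  path <- tempfile(fileext = ".tsv")
  write_pehm_model(m, path)
  m2 <- read_pehm_model(path)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$delta, m$delta)
  expect_equal(m2$lasso_penalty, m$lasso_penalty)
  expect_equal(m2$hybridization_threshold, 4.25)
  expect_equal(m2$noise_sd, 0.3)
})
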