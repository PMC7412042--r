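test_that("takens_embed produces shifted-coordinate trajectories", {
  x <- sin(seq(0, 20, length.out = 100))
  expect_equal(drop(takens_embed(x, 1)), x)          # d_E = 1 is the identity
  tr <- takens_embed(x, 3, 5)
  expect_equal(dim(tr), c(90, 3))
  set.seed(4)
  y <- rnorm(60)
  tr2 <- takens_embed(y, 4, 3)
  for (j in 1:4) expect_equal(tr2[, j], y[seq_len(51) + (j - 1) * 3])
  expect_error(takens_embed(y, 40, 3), "too short")
})

test_that("embedding estimation: sinusoid needs d_E = 2, constants error", {
  x <- sin(2 * pi * seq(0, 6, by = 0.01))
  cfg <- estimate_embedding(x)
  expect_lte(cfg$d_E, 2)
  expect_gte(cfg$tau, 1)
  expect_error(estimate_embedding(rep(1, 100)), "constant")
  # determinism on a fixed noisy beat train
  rec <- generate_dipole_record(dipole_params(duration = 4),
                                class_perturbation("HC"), seed = 5)
  s <- unclass(rec$ecg)[, "II"]
  expect_identical(estimate_embedding(s), estimate_embedding(s))
})

test_that("Poincare ensembles: periodic signals give equal-length segments", {
  P <- 50
  x <- rep(sin(2 * pi * (0:(P - 1)) / P), 8)
  tr <- takens_embed(x, 2, 1)
  sec <- poincare_section(c(1, 0), 0.5, "positive")
  ens <- extract_ensembles(x, tr, sec)
  expect_true(all(ens$lengths == P))
  expect_equal(ens$T_e, P)
  expect_error(extract_ensembles(seq_len(100), takens_embed(seq_len(100), 2, 1),
                                 poincare_section(c(1, 0), 1e6)),
               "insufficient beats")
  # 2.5-s synthetic ECG at 72 bpm carries 2 or 3 complete beats
  rec <- generate_dipole_record(dipole_params(hr_mean = 72, hr_sd = 0),
                                class_perturbation("HC", noise_sd = 0), seed = 1)
  s <- unclass(rec$ecg)[1:1250, "II"]
  sec2 <- pecgira:::adaptive_section(s, 3)
  ens2 <- extract_ensembles(s, takens_embed(s, 3, 1), sec2)
  expect_true(nrow(ens2$beats) %in% 2:3)
})

test_that("KL basis: rank structure, threshold, Parseval, oracle equivalence", {
  # identical segments -> rank-1, basis proportional to the common shape
  beat <- sin(seq(0, pi, length.out = 40))
  ens <- matrix(rep(beat, 5), 5, byrow = TRUE)
  kb <- compute_kl_basis(ens)
  expect_equal(kb$N, 1L)
  corr <- abs(sum(kb$phi[, 1] * beat) / sqrt(sum(beat^2)))
  expect_equal(corr, 1, tolerance = 1e-10)
  expect_equal(formals(compute_kl_basis)$threshold, 0.95)

  # known rank-2 mixture: N = 2, eigenvalues match an SVD oracle to 1e-8
  set.seed(8)
  u1 <- sin(seq(0, 2 * pi, length.out = 60)); u2 <- cos(seq(0, 6 * pi, length.out = 60))
  X <- cbind(rnorm(10, 1, 0.3)) %*% rbind(u1) + cbind(rnorm(10, 0.5, 0.2)) %*% rbind(u2)
  kb2 <- compute_kl_basis(X, threshold = 0.999)
  expect_equal(kb2$N, 2L)
  sv <- svd(X)$d^2 / nrow(X)              # oracle: singular values of the data
  expect_equal(kb2$theta[1:2], sv[1:2], tolerance = 1e-8)
  # Parseval: sum of eigenvalues = total ensemble variance (trace of K)
  expect_equal(sum(kb2$theta), sum(X^2) / nrow(X), tolerance = 1e-8)
  # PSD up to roundoff
  expect_true(all(eigen(kb2$K, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10 * sum(diag(kb2$K))))
  # monotonicity: raising the threshold never lowers N
  Ns <- vapply(c(0.5, 0.8, 0.95, 0.999),
               function(th) compute_kl_basis(X, th)$N, integer(1))
  expect_true(all(diff(Ns) >= 0))
})

test_that("beat projection obeys orthonormality and Pythagoras", {
  set.seed(9)
  X <- matrix(rnorm(5 * 30), 5)
  kb <- compute_kl_basis(X, threshold = 0.99)
  a <- project_beat(kb$phi[, 1], kb)
  expect_equal(a, c(1, rep(0, kb$N - 1)), tolerance = 1e-10, ignore_attr = TRUE)
  # orthogonal complement projects to zero
  v <- rnorm(30)
  v_perp <- v - kb$phi %*% crossprod(kb$phi, v)
  expect_equal(project_beat(drop(v_perp), kb), rep(0, kb$N),
               tolerance = 1e-8, ignore_attr = TRUE)
  # residual norm = out-of-basis energy
  b <- rnorm(30)
  ab <- project_beat(b, kb)
  recon <- drop(kb$phi[, seq_len(kb$N), drop = FALSE] %*% ab)
  expect_equal(sum((b - recon)^2), sum(b^2) - sum(ab^2), tolerance = 1e-8)
  expect_error(project_beat(rnorm(10), kb), "length")
})

test_that("rsquared implements the stated goodness of fit", {
  x <- c(1, 2, 3)
  expect_equal(rsquared(x, x), 1)
  expect_equal(rsquared(rep(0, 3), x), 0)
  expect_equal(rsquared(c(1, 1), c(1, 2)), 1 - 1 / 5)   # direct evaluation
  expect_error(rsquared(c(0, 0), c(0, 0)), "zero")
})

test_that("R-peak detector meets its contract", {
  p <- dipole_params(hr_mean = 60, hr_sd = 0)
  rec <- generate_dipole_record(p, class_perturbation("HC", noise_sd = 0.01),
                                seed = 10)
  s <- unclass(rec$ecg)[, "II"]
  pk <- detect_r_peaks(s, 500)
  expect_length(pk, length(rec$r_peaks))
  expect_lt(max(abs(pk / 500 - rec$r_peaks)), 0.02)
  expect_true(all(diff(pk) >= 0.2 * 500))              # refractory period
  expect_length(detect_r_peaks(rep(0, 1000), 500), 0)  # flat -> empty
  expect_length(detect_r_peaks(-s, 500), length(pk))   # polarity invariance
})

test_that("lead reconstruction: identity, rank-1, and held-out accuracy", {
  p <- dipole_params(hr_mean = 60, hr_sd = 0, duration = 10)
  rec <- generate_dipole_record(p, class_perturbation("HC", noise_sd = 0), seed = 1)
  truth <- unclass(rec$ecg)[1:5000, "V3"]
  ref <- unclass(rec$ecg)[1:5000, "II"]
  # fully observed lead passes through: R^2 = 1 exactly
  r_full <- reconstruct_lead(truth, 0, ref, 500)
  expect_identical(r_full$signal, truth)
  expect_equal(rsquared(r_full$signal, truth), 1)
  # identical-beat record, 7.5 s masked -> near-perfect reconstruction
  r <- reconstruct_lead(truth[2501:3750], 5, ref, 500)
  expect_gte(rsquared(r$signal, truth), 0.99)
  # observed window passes through exactly
  expect_identical(r$signal[2501:3750], truth[2501:3750])
  expect_error(reconstruct_lead(truth[1:1250], 0, rep(0, 5000), 500),
               "no R peaks")
})

test_that("full-record reconstruction recovers a masked jittered cohort", {
  co <- make_cohort(c(HC = 2, LAD = 1), dipole_params(), seed = 21)
  v <- validate_reconstruction(co)
  expect_gte(median(v$r2), 0.9)
  expect_equal(v$r2[, "II"], rep(1, 3), ignore_attr = TRUE)  # reference lead
})
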