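make_traj <- function(xyz, dt = 100) {
  trajectory3d(seq_len(nrow(xyz)) - 1L, (seq_len(nrow(xyz)) - 1) * dt,
               xyz[, 1], xyz[, 2], xyz[, 3], reference_frame = "plant")
}

test_that("per-frame distances follow the offset geometry", {
  set.seed(51)
  p <- matrix(rnorm(300, sd = 10), 100, 3)
  ta <- make_traj(p)
  expect_equal(max(per_frame_distance(ta, ta)$distances), 0)
  tb <- make_traj(sweep(p, 2, c(-3, 0, -4)))
  d <- per_frame_distance(ta, tb)
  expect_equal(unique(round(d$distances, 9)), 5)
  expect_equal(sum(d$histogram$count), 100)
  expect_equal(d$frac_below(6), 1)
  expect_equal(d$frac_below(4.99), 0)
  # disjoint frames are an error
  tc <- make_traj(p)
  tc$frame <- tc$frame + 1000L
  expect_error(per_frame_distance(ta, tc), "no frames")
})

test_that("isotropic noise gives the chi_3 mean distance", {
  set.seed(52)
  n <- 10000
  p <- matrix(rnorm(3 * n, sd = 10), n, 3)
  ta <- make_traj(p)
  tb <- make_traj(p + matrix(rnorm(3 * n, sd = 1), n, 3))
  d <- per_frame_distance(ta, tb)
  chi3_mean <- sqrt(2) * gamma(2) / gamma(1.5)  # = E|N(0,I_3)| ~ 1.5958
  expect_equal(mean(d$distances), chi3_mean, tolerance = 0.05)
})

test_that("axis correlations behave under identity, negation and noise", {
  set.seed(53)
  p <- matrix(rnorm(300, sd = 10), 100, 3)
  ta <- make_traj(p)
  expect_equal(unname(axis_correlation(ta, ta)), rep(1, 3))
  tb <- make_traj(-p)
  expect_equal(unname(axis_correlation(ta, tb)), rep(-1, 3))
  # noise at 10% of the coordinate SD attenuates r to 1/sqrt(1.01)
  n <- 10000
  q <- matrix(rnorm(3 * n, sd = 10), n, 3)
  qa <- make_traj(q)
  qb <- make_traj(q + matrix(rnorm(3 * n, sd = 1), n, 3))
  r <- axis_correlation(qa, qb)
  expect_true(all(abs(r - 1 / sqrt(1.01)) < 0.01))
  # zero-variance axis yields NA with a warning
  flat <- make_traj(cbind(p[, 1], rep(2, 100), p[, 3]))
  expect_warning(rf <- axis_correlation(flat, flat), "zero variance")
  expect_true(is.na(rf["y"]))
})

test_that("ICC(A,1) matches aov mean squares and known limits", {
  set.seed(54)
  subj <- rnorm(30, sd = 3)
  m <- cbind(subj + rnorm(30), subj + rnorm(30), subj + rnorm(30))
  res <- icc_a1(m)
  # independent route: two-way ANOVA mean squares via aov()
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(30), 3)),
    rater = factor(rep(1:3, each = 30))
  )
  tab <- summary(aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- 30; k <- 3
  expect_equal(res$MSR, msr, tolerance = 1e-10)
  expect_equal(res$MSC, msc, tolerance = 1e-10)
  expect_equal(res$MSE, mse, tolerance = 1e-10)
  expect_equal(res$icc,
               (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
               tolerance = 1e-10)
  # duplicated raters: perfect agreement
  expect_equal(icc_a1(cbind(subj, subj))$icc, 1)
  # degenerate matrix
  expect_error(icc_a1(matrix(2, 5, 2)), "zero total variance")
  expect_error(icc_a1(matrix(rnorm(4), 2, 2)), "n >= 3")
})

test_that("ICC recovers the simulated variance ratio and penalizes bias", {
  set.seed(55)
  subj <- rnorm(500, sd = 3)  # sigma_b^2 = 9, sigma_e^2 = 1 -> ICC 0.9
  m <- cbind(subj + rnorm(500), subj + rnorm(500))
  expect_equal(icc_a1(m)$icc, 0.9, tolerance = 0.03)
  # a large constant bias in one rater crushes absolute agreement
  mb <- cbind(subj, subj + 30)  # 10x the subject SD
  expect_lt(icc_a1(mb)$icc, 0.2)
  # invariant to a common affine rescaling of both raters
  expect_equal(icc_a1(2.5 * m + 7)$icc, icc_a1(m)$icc, tolerance = 1e-12)
})

test_that("feature agreement aligns tables and orders the report", {
  sim <- gen_trajectory(sim_params(n_cycles = 10, noise_sd_mm = 0.3,
                                   seed = 56))
  pair <- gen_rater_pair(sim$traj, rater_sd_mm = 0.5, seed = 57)
  cfg <- run_config(stimulus = stimulus(40, 0))
  feats <- lapply(pair, function(tr) {
    circs <- segment_circumnutations(tr, cfg)
    f <- circ_features(circs, cfg)
    cbind(f, stimulus_features(circs, f, cfg$stimulus)[-1])
  })
  # identical tables agree perfectly
  fa_same <- feature_agreement(feats$a, feats$a)
  expect_true(all(fa_same$icc[!is.na(fa_same$icc)] == 1))
  # the two operators share the full 19-feature report
  fa <- feature_agreement(feats$a, feats$b)
  expect_equal(nrow(fa), 19L)
  expect_equal(fa$feature, circumnut:::agreement_feature_order)
  # consistently permuting subjects leaves ICCs unchanged
  set.seed(58)
  perm <- sample(nrow(feats$a))
  fa_perm <- feature_agreement(feats$a[perm, ], feats$b[perm, ])
  expect_equal(fa_perm$icc, fa$icc, tolerance = 1e-12)
  # counts differing by more than 20% demand manual alignment
  expect_error(feature_agreement(feats$a, feats$b[1:5, ]), "20%")
})

test_that("mean estimated ICC tracks the theoretical variance ratio", {
  set.seed(59)
  iccs <- replicate(60, {
    s <- rnorm(500, sd = 3)
    icc_a1(cbind(s + rnorm(500), s + rnorm(500)))$icc
  })
  expect_equal(mean(iccs), 0.9, tolerance = 0.02)
})
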