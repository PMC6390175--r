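test_that("spearman_rsa matches the rank-then-Pearson oracle, with ties", {
  set.seed(51)
  for (k in 1:25) {
    a <- sample(1:5, 10, replace = TRUE)  # heavy ties
    b <- rnorm(10)
    expect_equal(spearman_rsa(a, b), spearman_oracle(a, b),
                 tolerance = 1e-12)
  }
  x <- rnorm(20)
  expect_equal(spearman_rsa(x, x), 1)
  # rank invariance under strictly monotone transforms
  y <- rnorm(20)
  expect_equal(spearman_rsa(exp(x), y), spearman_rsa(x, y))
  expect_equal(spearman_rsa(x, y^3 + 5 * y), spearman_rsa(x, y))
  expect_error(spearman_rsa(rep(1, 20), y), "constant")
})

test_that("partial_spearman matches closed-form and projection oracles", {
  set.seed(52)
  # empty control set reduces exactly to spearman_rsa
  a <- rnorm(30); b <- rnorm(30)
  expect_identical(partial_spearman(a, b, NULL), spearman_rsa(a, b))
  expect_identical(partial_spearman(a, b, list()), spearman_rsa(a, b))
  # single control: recursive closed-form oracle
  for (k in 1:25) {
    a <- rnorm(15); b <- rnorm(15); c <- rnorm(15)
    expect_equal(partial_spearman(a, b, c),
                 partial_recursive_oracle(a, b, c), tolerance = 1e-12)
  }
  # multiple controls: explicit projection-matrix oracle
  for (k in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    C <- matrix(rnorm(40), 20, 2)
    expect_equal(partial_spearman(a, b, C),
                 partial_projection_oracle(a, b, C), tolerance = 1e-12)
  }
  # shared-cause structure: partialing the cause kills the correlation
  rho_p <- replicate(40, {
    c0 <- rnorm(100)
    partial_spearman(c0 + rnorm(100), c0 + rnorm(100), c0)
  })
  expect_lt(abs(mean(rho_p)), 0.06)
  # collinear control errors
  a <- rnorm(12)
  expect_error(partial_spearman(a, rnorm(12), a), "collinear")
})

test_that("fisher_z is atanh with domain checking and odd symmetry", {
  expect_equal(fisher_z(0), 0)
  # independent series evaluation of (1/2) log((1+r)/(1-r))
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), ">= 1")
})

test_that("Butterworth smoothing is zero-phase, DC-preserving, and matches
           the transfer-function variance oracle on white noise", {
  co <- butter_lowpass(5, 10, 100)
  # DC gain exactly 1 -> constants unchanged
  expect_equal(sum(co$b) / sum(co$a), 1, tolerance = 1e-12)
  expect_equal(smooth_timecourse(rep(3, 100), 100), rep(3, 100),
               tolerance = 1e-9)
  # Nyquist-rate alternation is crushed
  alt <- rep(c(1, -1), 100)
  expect_lt(stats::sd(smooth_timecourse(alt, 100)[21:180]), 0.01)
  # white noise: output variance ~ mean |H|^4 over frequencies (the filter
  # is applied forward and backward)
  Hmag2 <- function(w) {
    num <- abs(sum(co$b * exp(-1i * w * (seq_along(co$b) - 1))))^2
    den <- abs(sum(co$a * exp(-1i * w * (seq_along(co$a) - 1))))^2
    num / den
  }
  w <- seq(0, pi, length.out = 2048)
  expect_ratio <- mean(sapply(w, Hmag2)^2)
  set.seed(53)
  ratios <- replicate(20, {
    x <- rnorm(4000)
    var(smooth_timecourse(x, 100)[501:3500]) / var(x)
  })
  expect_equal(mean(ratios), expect_ratio, tolerance = 0.05)
  # zero phase: a symmetric pulse stays symmetric about its centre
  pulse <- exp(-(seq(-200, 200))^2 / 200)
  y <- smooth_timecourse(pulse, 100)
  expect_equal(which.max(y), 201, tolerance = 1)
  expect_error(butter_lowpass(5, 60, 100), "Nyquist")
})

test_that("Gaussian TF smoothing: kernel shape, separability, edge mass", {
  # constant map unchanged everywhere (edge renormalisation)
  z <- matrix(2.5, 8, 30)
  expect_equal(smooth_tf_map(z, 2, 10), z, tolerance = 1e-12)
  # unit impulse reproduces the stated kernel, sum ~ 1 in the interior
  imp <- matrix(0, 15, 41)
  imp[8, 21] <- 1
  sm <- smooth_tf_map(imp, freq_step = 2, time_step = 10,
                      fwhm_freq = 4, fwhm_time = 20)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  sigma_f <- 4 / (2 * sqrt(2 * log(2))) / 2   # in freq-bin units
  want_col <- exp(-((seq_len(15) - 8)^2) / (2 * sigma_f^2))
  want_col <- want_col / sum(want_col)
  got_col <- sm[, 21] / sum(sm[, 21])
  # the implementation truncates the kernel at 4 sigma
  expect_equal(got_col, want_col, tolerance = 1e-6)
  # separability: 2-D pass equals sequential 1-D passes
  set.seed(54)
  z2 <- matrix(rnorm(10 * 25), 10, 25)
  byhand <- apply(z2, 2, function(colv)
    as.vector(smooth_tf_map(matrix(colv, ncol = 1), 2, 10, 4, 1e-9)))
  byhand <- t(apply(byhand, 1, function(rowv)
    as.vector(smooth_tf_map(matrix(rowv, nrow = 1), 2, 10, 1e-9, 20))))
  sm2 <- smooth_tf_map(z2, 2, 10, 4, 20)
  expect_equal(dim(sm2), dim(z2))
  expect_error(smooth_tf_map(z2, 2, 10, fwhm_freq = -1), "positive")
})

test_that("group_t_map matches the textbook formula and flags degeneracy", {
  set.seed(55)
  z <- matrix(rnorm(16 * 30), 16, 30)
  tmap <- group_t_map(z)
  for (j in c(1, 15, 30))
    expect_equal(tmap[j],
                 mean(z[, j]) / (sd(z[, j]) / sqrt(16)), tolerance = 1e-12)
  expect_equal(group_t_map(matrix(0, 4, 5)), rep(0, 5))
  const <- matrix(2, 4, 3)
  expect_true(all(is.infinite(group_t_map(const))))
})

test_that("TFCE matches the brute-force threshold-sum oracle in 1-D and 2-D
           and is monotone", {
  set.seed(56)
  for (k in 1:10) {
    m1 <- pmax(rnorm(40), 0) * 2
    expect_equal(tfce(m1, dh = 0.01), tfce_oracle(m1, dh = 0.01),
                 tolerance = 1e-9)
  }
  for (k in 1:5) {
    m2 <- matrix(pmax(rnorm(8 * 12), 0) * 2, 8, 12)
    expect_equal(tfce(m2, dh = 0.02), tfce_oracle(m2, dh = 0.02),
                 tolerance = 1e-9)
  }
  # all-zero map -> all-zero output; negatives contribute nothing
  expect_equal(tfce(rep(0, 10)), rep(0, 10))
  expect_equal(tfce(c(-3, -1, -2)), rep(0, 3))
  # monotonicity: pointwise-larger map gives pointwise >= enhancement
  base <- pmax(rnorm(50), 0)
  bigger <- base + runif(50, 0, 0.5)
  expect_true(all(tfce(bigger, dh = 0.01) >= tfce(base, dh = 0.01) - 1e-12))
})

test_that("permutation correction is reproducible, valid under the null and
           sensitive to planted effects", {
  set.seed(57)
  # planted strong effect at known coordinates, 16 participants
  z <- matrix(rnorm(16 * 60, 0, 0.1), 16, 60)
  z[, 25:35] <- z[, 25:35] + 0.5
  sc <- permutation_scheme(300L, seed = 9L)
  res <- permutation_correct(z, scheme = sc)
  expect_true(all(res$mask[25:35]))
  expect_true(all(res$p[25:35] <= 0.05))
  # fixed seed -> bit-identical p maps
  res2 <- permutation_correct(z, scheme = sc)
  expect_identical(res$p, res2$p)
  expect_identical(res$null_max, res2$null_max)
  # +1 correction keeps p in (0, 1]
  expect_true(all(res$p > 0 & res$p <= 1))
  # exhaustive enumeration warning for tiny groups
  z4 <- matrix(rnorm(4 * 10), 4, 10)
  expect_warning(permutation_correct(z4,
                                     scheme = permutation_scheme(100L, 1L)),
                 "exhaustively")
})

test_that("rsa_map and rsa_scan recover exact geometry in the noise-free
           case and partialing a model out of itself abolishes it", {
  set.seed(58)
  S <- 8L
  labs <- rep(c("p", "q"), each = 4)
  model <- category_model_matrix(labs, sprintf("s%d", 1:S))
  # response cells exactly equal to the model at every coordinate
  cells <- matrix(rep(vectorize(model), 5), ncol = 5)
  z <- rsa_map(cells, vectorize(model))
  expect_true(all(tanh(z) > 1 - 1e-6))   # rho = 1 at every coordinate
  # partialing the model out of its own matrix errors (zero residual)
  expect_error(rsa_map(cells, vectorize(model),
                       control_cells = list(vectorize(model))),
               "collinear")
  # noisy case: a correlate of the planted category structure shows an
  # apparent effect that partialing out the true category model abolishes
  n_cells <- length(vectorize(model))
  n_coord <- 30L
  noisy <- vectorize(model) +
    matrix(rnorm(n_cells * n_coord, 0, 0.4), n_cells, n_coord)
  correlate <- vectorize(model) + rnorm(n_cells, 0, 0.4)
  z_plain <- rsa_map(noisy, correlate)
  z_part <- rsa_map(noisy, correlate,
                    control_cells = list(vectorize(model)))
  expect_gt(mean(tanh(z_plain)), 0.3)
  expect_lt(abs(mean(tanh(z_part))), 0.15)
})
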