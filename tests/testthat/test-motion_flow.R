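test_that("fit_affine_from_triangle recovers exact transforms", {
  src <- rbind(c(0, 0), c(10, 0), c(0, 10))
  # identity
  expect_equal(fit_affine_from_triangle(src, src),
               rbind(c(1, 0), c(0, 1), c(0, 0)), tolerance = 1e-12)
  # rigid: rotation 30 degrees + translation (5, 2)
  dst <- rotate_translate(src, pi / 6, c(5, 2))
  A <- fit_affine_from_triangle(src, dst)
  expect_equal(A[1:2, 1:2],
               matrix(c(cos(pi / 6), sin(pi / 6),
                        -sin(pi / 6), cos(pi / 6)), 2, 2),
               tolerance = 1e-12)
  expect_equal(A[3, ], c(5, 2), tolerance = 1e-12)
  # random non-degenerate triangles match an explicit 6x6 solve oracle
  set.seed(21)
  for (k in 1:20) {
    s <- matrix(runif(6, 0, 100), 3, 2)
    d <- matrix(runif(6, 0, 100), 3, 2)
    if (abs(det(cbind(s, 1))) < 1) next
    A <- fit_affine_from_triangle(s, d)
    # oracle: block system M %*% theta = rhs over 6 unknowns
    M <- matrix(0, 6, 6)
    rhs <- numeric(6)
    for (i in 1:3) {
      M[2 * i - 1, 1:3] <- c(s[i, ], 1)
      M[2 * i, 4:6] <- c(s[i, ], 1)
      rhs[2 * i - 1] <- d[i, 1]; rhs[2 * i] <- d[i, 2]
    }
    th <- solve(M, rhs)   # (a1, b1, c1, a2, b2, c2) = column-major A
    expect_equal(as.vector(A), th, tolerance = 1e-8)
    # residual zero on the three points
    expect_equal(cbind(s, 1) %*% A, d, tolerance = 1e-9)
  }
  # collinear triangle rejected with diagnostics
  expect_error(fit_affine_from_triangle(rbind(c(0, 0), c(1, 1), c(2, 2)),
                                        src),
               "collinear")
})

test_that("rigid_correct removes pure rigid motion and keeps local motion", {
  set.seed(22)
  start <- matrix(runif(24, 0, 200), 12, 2)
  ids <- sprintf("lm%02d", 1:12)
  tri <- fiducial_triangle(ids[1:3])
  # pure rigid motion -> zero flow everywhere after correction
  rigid <- make_video(start, 6L,
                      displace = function(f, s)
                        rotate_translate(s, 0.05 * f, c(2 * f, -f)))
  corr <- rigid_correct(rigid, tri)
  expect_lte(max(landmark_flow(corr)), 1e-9)
  # fiducials of every corrected frame coincide with frame 1
  for (f in 2:6)
    expect_equal(corr$frames[[f]]$coords[1:3, ],
                 corr$frames[[1]]$coords[1:3, ], tolerance = 1e-9)
  # frame 1 unchanged
  expect_identical(corr$frames[[1]]$coords, rigid$frames[[1]]$coords)
  # idempotence
  corr2 <- rigid_correct(corr, tri)
  for (f in 1:6)
    expect_equal(corr2$frames[[f]]$coords, corr$frames[[f]]$coords,
                 tolerance = 1e-9)
  # planted local displacement survives correction exactly
  local_disp <- matrix(0, 12, 2)
  local_disp[7, ] <- c(3, -2)  # "mouth" landmark
  mixed <- make_video(start, 6L,
                      displace = function(f, s)
                        rotate_translate(s + (f - 1) * local_disp,
                                         0.05 * f, c(2 * f, -f)))
  mcorr <- rigid_correct(mixed, tri)
  for (f in 2:6)
    expect_equal(unname(mcorr$frames[[f]]$coords[7, ] -
                          mcorr$frames[[1]]$coords[7, ]),
                 (f - 1) * local_disp[7, ], tolerance = 1e-6)
})

test_that("landmark_flow returns per-transition displacement magnitudes", {
  start <- matrix(runif(12, 0, 100), 6, 2)
  static <- make_video(start, 5L)
  expect_equal(max(landmark_flow(static)), 0)
  # landmark translating (0.6, 0.8) per frame has flow exactly 1
  drift <- make_video(start, 5L,
                      displace = function(f, s) {
                        s[2, ] <- s[2, ] + (f - 1) * c(0.6, 0.8); s
                      })
  fl <- landmark_flow(drift)
  expect_equal(unname(fl[2, ]), rep(1, 4))
  expect_equal(max(fl[-2, ]), 0)
  # random walk matches independent step-norm oracle
  set.seed(23)
  steps <- lapply(1:4, function(f) matrix(rnorm(12), 6, 2))
  walk <- make_video(start, 5L,
                     displace = function(f, s)
                       s + Reduce(`+`, steps[seq_len(f - 1)]))
  fl <- landmark_flow(walk)
  for (t in 1:4)
    expect_equal(unname(fl[, t]), sqrt(rowSums(steps[[t]]^2)),
                 tolerance = 1e-12)
})

test_that("average_flow_by_feature is a per-feature arithmetic mean", {
  raw <- rbind(a = c(1, 2), b = c(3, 6), c = c(10, 0))
  fm <- feature_map(list(one = "a", two = c("b", "c")))
  avg <- average_flow_by_feature(raw, fm)
  expect_equal(unname(avg["one", ]), c(1, 2))
  expect_equal(unname(avg["two", ]), c(6.5, 3))
  set.seed(24)
  raw2 <- matrix(abs(rnorm(40)), 8, 5,
                 dimnames = list(letters[1:8], NULL))
  fm2 <- feature_map(list(f1 = letters[1:3], f2 = letters[4:8]))
  avg2 <- average_flow_by_feature(raw2, fm2)
  expect_equal(unname(avg2["f1", ]), colMeans(raw2[1:3, ]))
  expect_error(feature_map(list(f1 = character())), "empty feature")
})

test_that("motion pattern length and values match the exhaustive pair loop", {
  # 12 features x 56 frames (55 transitions) -> the full-design length
  expect_equal(choose(12L * 55L, 2L), 217470L)
  flow <- matrix(abs(rnorm(12 * 55)), 12, 55)
  expect_length(motion_pattern(flow), 217470L)
  # constant flow -> all-zero pattern
  expect_equal(unique(motion_pattern(matrix(2, 3, 4))), 0)
  # 2 features x 3 frames: C(4,2)=6 values, brute force
  fl <- matrix(c(1, 5, 2, 9), 2, 2)
  v <- as.vector(fl)
  oracle <- c()
  for (i in 1:3) for (j in (i + 1):4) oracle <- c(oracle, abs(v[i] - v[j]))
  expect_equal(as.numeric(motion_pattern(fl)), oracle)
})

test_that("motion similarity matrix separates expressions and matches the
           pairwise oracle; landmark permutation leaves it unchanged", {
  set.seed(25)
  fs <- generate_face_set(small_face_spec(seed = 31L,
                                          expression_motion_scale = 10,
                                          landmark_noise_sd = 0.2))
  sm <- build_motion_similarity_matrix(fs$videos, fs$fmap, fs$triangle)
  expect_equal(sm$values, t(sm$values))
  expect_equal(unname(diag(sm$values)), rep(1, 9))
  # pairwise oracle on a few cells
  p1 <- facersa:::video_motion_pattern(fs$videos[[1]], fs$fmap, fs$triangle)
  p2 <- facersa:::video_motion_pattern(fs$videos[[2]], fs$fmap, fs$triangle)
  expect_equal(sm$values[1, 2], pearson_oracle(p1, p2), tolerance = 1e-12)
  # within-expression > between-expression on average
  exl <- vapply(fs$videos, `[[`, "", "expression_label")
  same <- outer(exl, exl, `==`)[lower.tri(diag(9))]
  cells <- vectorize(sm)
  expect_gt(mean(cells[same]), mean(cells[!same]))
  # pipeline equivariance under landmark reordering
  perm <- sample(24L)
  videos_p <- lapply(fs$videos, function(v) {
    frames <- lapply(v$frames, function(fr)
      landmark_frame(fr$coords[perm, ], fr$landmark_ids[perm]))
    landmark_video(frames, v$frame_rate, v$stimulus_id,
                   v$identity_label, v$expression_label)
  })
  sm_p <- build_motion_similarity_matrix(videos_p, fs$fmap, fs$triangle)
  expect_equal(sm_p$values, sm$values, tolerance = 1e-9)
  form_p <- build_form_similarity_matrix(videos_p)
  form <- build_form_similarity_matrix(fs$videos)
  expect_equal(form_p$values, form$values, tolerance = 1e-9)
})
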