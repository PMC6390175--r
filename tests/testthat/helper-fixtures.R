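# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

# a frame of n random landmarks in a ~200 px box
random_frame <- function(n = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  landmark_frame(matrix(runif(2L * n, 0, 200), n, 2L),
                 sprintf("lm%02d", seq_len(n)))
}

rotate_translate <- function(coords, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  sweep(coords %*% R, 2L, shift, `+`)
}

# tiny video: start frame plus per-frame displacement function
make_video <- function(start, n_frames, displace = function(f, coords) coords,
                       ids = sprintf("lm%02d", seq_len(nrow(start))),
                       stimulus_id = "v1", identity = "idA",
                       expression = "exA", frame_rate = 28) {
  frames <- vector("list", n_frames)
  frames[[1L]] <- landmark_frame(start, ids)
  for (f in 2:n_frames)
    frames[[f]] <- landmark_frame(displace(f, start), ids)
  landmark_video(frames, frame_rate, stimulus_id, identity, expression)
}

# brute-force pairwise-distance oracle (double loop)
pairwise_dist_oracle <- function(coords) {
  n <- nrow(coords)
  out <- numeric(0)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      out <- c(out, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  out
}

# direct Pearson formula oracle
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# mid-rank + Pearson Spearman oracle
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

# single-control partial correlation via the recursive closed form
partial_recursive_oracle <- function(a, b, c) {
  rab <- spearman_oracle(a, b)
  rac <- spearman_oracle(a, c)
  rbc <- spearman_oracle(b, c)
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

# multi-control partial Spearman via explicit projection matrices
partial_projection_oracle <- function(a, b, controls) {
  X <- cbind(1, apply(as.matrix(controls), 2L, rank))
  P <- diag(length(a)) - X %*% solve(crossprod(X)) %*% t(X)
  pearson_oracle(P %*% rank(a), P %*% rank(b))
}

# brute-force TFCE: explicit threshold loop; components via rle (1-D) or
# igraph flood fill (2-D)
tfce_oracle <- function(map, E = 0.5, H = 2, dh) {
  dims <- if (is.matrix(map)) dim(map) else c(length(map), 1L)
  v <- as.numeric(map)
  out <- numeric(length(v))
  mx <- max(v, 0)
  if (mx <= 0) return(if (is.matrix(map)) matrix(out, dims[1]) else out)
  nsteps <- floor(mx / dh + 1e-9)
  for (s in seq_len(nsteps)) {
    h <- s * dh
    sup <- v >= h
    labels <- integer(length(v))
    if (dims[2L] == 1L) {
      r <- rle(sup)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      lab <- 0L
      for (k in seq_along(r$values)) if (r$values[k]) {
        lab <- lab + 1L
        labels[starts[k]:ends[k]] <- lab
      }
    } else {
      idx <- which(sup)
      g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
      pos <- match(seq_along(v), idx)
      edges <- c()
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        r0 <- (i - 1L) %% dims[1L] + 1L
        c0 <- (i - 1L) %/% dims[1L] + 1L
        if (r0 < dims[1L] && sup[i + 1L])
          edges <- c(edges, ii, pos[i + 1L])
        if (c0 < dims[2L] && sup[i + dims[1L]])
          edges <- c(edges, ii, pos[i + dims[1L]])
      }
      if (length(edges)) g <- igraph::add_edges(g, edges)
      comp <- igraph::components(g)
      labels[idx] <- comp$membership
    }
    sizes <- tabulate(labels)
    inc <- ifelse(labels > 0L, sizes[pmax(labels, 1L)]^E * h^H * dh, 0)
    out <- out + inc
  }
  if (is.matrix(map)) matrix(out, dims[1L]) else out
}

# small crossed design face set, fast to generate
small_face_spec <- function(seed = 1L, ...) {
  face_set_spec(n_identities = 3L, n_expressions = 3L, n_landmarks = 24L,
                n_interior = 18L, n_features = 4L, n_frames = 8L,
                seed = seed, ...)
}

# tiny epoch set with known content
tiny_epochs <- function(n_trials = 4L, n_channels = 3L, seed = 1L,
                        sampling_rate = 100, times = seq(-500, 2500, 10),
                        types = rep("axial", n_channels)) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * length(times)),
                c(n_trials, n_channels, length(times)))
  epoch_set(data, sampling_rate, times,
            rep(sprintf("s%d", 1:2), length.out = n_trials),
            channel_types = types)
}
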