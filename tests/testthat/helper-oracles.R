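# Independent oracles, deliberately written with different algorithms than
# the package implementations they check.

# O(N^2) brute-force sample-entropy template counter (explicit embedding
# matrices + pairwise Chebyshev distances; Richman-Moorman start convention)
sampen_counts_brute <- function(x, m, r, w = 1) {
  N <- length(x)
  ns <- N - m
  cheb_pairs <- function(E) {
    D <- matrix(0, nrow(E), nrow(E))
    for (k in seq_len(ncol(E))) {
      D <- pmax(D, abs(outer(E[, k], E[, k], "-")))
    }
    idx <- which(upper.tri(D), arr.ind = TRUE)
    keep <- (idx[, 2] - idx[, 1]) >= w
    sum(D[idx[keep, , drop = FALSE]] <= r)
  }
  Em <- sapply(0:(m - 1), function(k) x[(1:ns) + k])
  Ea <- sapply(0:m, function(k) x[(1:ns) + k])
  c(B = cheb_pairs(Em), A = cheb_pairs(Ea))
}

sampen_brute <- function(x, m, r, w = 1) {
  cnt <- sampen_counts_brute(x, m, r, w)
  if (cnt[["A"]] == 0 || cnt[["B"]] == 0) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

# trapezoidal quadrature of the perpendicular deviation along the chord:
# rotate the normalized frame so the chord lies on +x, integrate y dx;
# toward-the-alternative is +y for login and -y for back
auc_quadrature <- function(nt) {
  ang <- if (nt$response == "login") pi / 4 else 3 * pi / 4
  x <- cos(-ang) * nt$x - sin(-ang) * nt$y
  y <- sin(-ang) * nt$x + cos(-ang) * nt$y
  tz <- sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
  if (nt$response == "login") tz else -tz
}

# apply an arbitrary similarity transform (rotation + uniform scale +
# translation, no reflection) to a raw trajectory's screen coordinates
similarity_transform_raw <- function(raw, theta, scale, dx, dy) {
  rot <- function(x, y) list(x = cos(theta) * x - sin(theta) * y,
                             y = sin(theta) * x + cos(theta) * y)
  p <- rot(raw$x, raw$y)
  fc <- rot(raw$final_click[2], raw$final_click[3])
  raw$x <- scale * p$x + dx
  raw$y <- scale * p$y + dy
  raw$final_click <- c(raw$final_click[1], scale * fc$x + dx,
                       scale * fc$y + dy)
  raw$screen <- c(1e9, 1e9)  # keep the click in bounds under any transform
  raw
}

# quick raw-trajectory builder with evenly spaced timestamps; coordinates
# are shifted into the positive quadrant (normalization is translation
# invariant) so the click stays within the validator's screen bounds
make_raw <- function(x, y, response = "login", screen = c(1e9, 1e9),
                     pid = "p1", tid = "t1") {
  n <- length(x)
  x <- x + 1e5
  y <- y + 1e5
  raw_trajectory(pid, tid, t = seq(0, by = 20, length.out = n), x = x,
                 y = y, page_load_t = 0,
                 final_click = c(20 * n, x[n], y[n]),
                 response = response, screen = screen)
}

# random wandering raw path ending at a click position
random_raw <- function(n = 50, response = "login", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- cumsum(c(500, rnorm(n - 1, 3, 15)))
  y <- cumsum(c(500, rnorm(n - 1, -2, 15)))
  make_raw(x, y, response = response, screen = c(1e9, 1e9))
}

# small complete file set on disk; returns the directory
write_tiny_dataset <- function(dir, n_participants = 4, seed = 99,
                               rate = 12, model = "two_factor") {
  cfg <- synth_config(n_participants = n_participants, seed = seed,
                      model = model, rate = rate, n_unusable = 0)
  gen_dataset(cfg, dir)
  dir
}
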