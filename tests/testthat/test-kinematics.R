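test_that("normalization puts endpoints on the 45/135 degree unit rays", {
  # already on the 45-degree ray after the y-flip
  tr <- make_raw(c(0, 5), c(0, -5), response = "login")
  nt <- normalize_trajectory(tr)
  expect_equal(nt$x[1], 0, tolerance = 1e-12)
  expect_equal(nt$y[1], 0, tolerance = 1e-12)
  n <- length(nt$x)
  expect_equal(c(nt$x[n], nt$y[n]), c(sqrt(0.5), sqrt(0.5)),
               tolerance = 1e-9)

  # collinear points stay collinear: midpoint maps to half the chord
  tr2 <- make_raw(c(100, 250, 400), c(200, 350, 500), response = "back")
  nt2 <- normalize_trajectory(tr2)
  expect_equal(nt2$x[2], cos(3 * pi / 4) / 2, tolerance = 1e-9)
  expect_equal(nt2$y[2], sin(3 * pi / 4) / 2, tolerance = 1e-9)
  expect_equal(atan2(nt2$y[3], nt2$x[3]), 3 * pi / 4, tolerance = 1e-9)

  for (resp in c("login", "back")) {
    nt3 <- normalize_trajectory(random_raw(40, resp, seed = 7))
    k <- length(nt3$x)
    expect_equal(sqrt(nt3$x[k]^2 + nt3$y[k]^2), 1, tolerance = 1e-9)
    target <- if (resp == "login") pi / 4 else 3 * pi / 4
    expect_equal(atan2(nt3$y[k], nt3$x[k]), target, tolerance = 1e-9)
  }
})

test_that("normalization rejects degenerate zero-length chords", {
  tr <- make_raw(c(10, 50, 10), c(20, 80, 20))
  expect_error(normalize_trajectory(tr), class = "pd_degenerate_error")
})

test_that("normalized output is invariant to similarity transforms of the input", {
  set.seed(31)
  for (rep in 1:8) {
    raw <- random_raw(50, sample(c("login", "back"), 1))
    nt <- normalize_trajectory(raw)
    raw2 <- similarity_transform_raw(raw, theta = runif(1, -pi, pi),
                                     scale = runif(1, 0.1, 12),
                                     dx = runif(1, -4000, 4000),
                                     dy = runif(1, -4000, 4000))
    nt2 <- normalize_trajectory(raw2)
    expect_equal(nt2$x, nt$x, tolerance = 1e-9)
    expect_equal(nt2$y, nt$y, tolerance = 1e-9)
    expect_equal(compute_auc(nt2), compute_auc(nt), tolerance = 1e-9)
    expect_equal(distance_to_endpoint_series(nt2),
                 distance_to_endpoint_series(nt), tolerance = 1e-9)
  }
})

test_that("AUC: straight chords give 0, right triangle gives |0.5|", {
  chord <- normalize_trajectory(make_raw(seq(0, 90, by = 10),
                                         seq(0, -90, by = -10)))
  expect_equal(compute_auc(chord), 0, tolerance = 1e-12)

  # unnormalized frame: path (0,0) -> (1,0) -> (1,1), chord (0,0)-(1,1)
  tri <- structure(list(x = c(0, 1, 1), y = c(0, 0, 1),
                        response = "login"),
                   class = "normalized_trajectory")
  expect_equal(abs(compute_auc(tri)), 0.5, tolerance = 1e-12)
  # (1,0) lies away from the back-button side: negative by convention
  expect_lt(compute_auc(tri), 0)
})

test_that("AUC matches quadrature, flips under mirroring, negates on reversal", {
  set.seed(5)
  for (rep in 1:10) {
    resp <- sample(c("login", "back"), 1)
    nt <- normalize_trajectory(random_raw(200, resp))
    a <- compute_auc(nt)
    expect_equal(a, auc_quadrature(nt), tolerance = 1e-6)

    # mirror across the chord: reflect in the canonical frame
    ang <- if (resp == "login") pi / 4 else 3 * pi / 4
    rot <- function(x, y, th) list(x = cos(th) * x - sin(th) * y,
                                   y = sin(th) * x + cos(th) * y)
    p <- rot(nt$x, nt$y, -ang)
    m <- rot(p$x, -p$y, ang)
    mirrored <- structure(list(x = m$x, y = m$y, response = resp),
                          class = "normalized_trajectory")
    expect_equal(compute_auc(mirrored), -a, tolerance = 1e-9)

    reversed <- structure(list(x = rev(nt$x), y = rev(nt$y),
                               response = resp),
                          class = "normalized_trajectory")
    expect_equal(compute_auc(reversed), -a, tolerance = 1e-9)
  }
})

test_that("response time is click minus page load in seconds", {
  tr <- raw_trajectory("p", "t", t = c(0, 5000), x = c(0, 100),
                       y = c(0, 100), page_load_t = 0,
                       final_click = c(9040, 100, 100), response = "login")
  expect_equal(compute_rt(tr), 9.04)
  tr2 <- raw_trajectory("p", "t", t = c(500, 900), x = c(0, 100),
                        y = c(0, 100), page_load_t = 500,
                        final_click = c(1500, 100, 100), response = "back")
  expect_equal(compute_rt(tr2), 1.0)
  tr2$final_click[1] <- 500
  tr2$t <- c(500, 500)
  expect_error(compute_rt(tr2), class = "pd_validation_error")
})

test_that("distance-to-endpoint series matches pointwise brute force", {
  # chord-sampled straight path of 5 evenly spaced points
  nt <- structure(list(x = seq(0, 1, 0.25) * cos(pi / 4),
                       y = seq(0, 1, 0.25) * sin(pi / 4),
                       response = "login"),
                  class = "normalized_trajectory")
  expect_equal(distance_to_endpoint_series(nt), c(1, 0.75, 0.5, 0.25, 0))

  nt2 <- normalize_trajectory(random_raw(100, "back", seed = 2))
  d <- distance_to_endpoint_series(nt2)
  n <- length(nt2$x)
  brute <- vapply(seq_len(n), function(i)
    sqrt((nt2$x[i] - nt2$x[n])^2 + (nt2$y[i] - nt2$y[n])^2), numeric(1))
  expect_equal(d, brute, tolerance = 1e-12)
  expect_identical(d[n], 0)
})
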