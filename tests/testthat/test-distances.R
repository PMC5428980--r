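test_that("ground distances between diagram points", {
  expect_equal(diagram_point_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(diagram_point_distance(c(0, 0), c(3, 4), "chebyshev"), 4)
  expect_equal(diagram_point_distance(c(2, 7), c(2, 7)), 0)
})

test_that("directed average distance enumerates point-to-set minima", {
  A <- rbind(c(0, 0), c(10, 0)); B <- rbind(c(0, 0))
  expect_equal(directed_average_distance(A, B), 5)
  expect_equal(directed_average_distance(B, A), 0)      # subset direction
  expect_equal(directed_average_distance(rbind(c(1, 1)), rbind(c(4, 5), c(1, 2))), 1)
  expect_error(directed_average_distance(A, matrix(numeric(), 0, 2)),
               class = "actiph_validation_error")
})

test_that("modified Hausdorff and Hausdorff match hand-computed values", {
  A <- rbind(c(0, 0), c(10, 0)); B <- rbind(c(0, 0))
  expect_equal(modified_hausdorff(A, A), 0)
  expect_equal(modified_hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_equal(modified_hausdorff(A, B), 5)
  expect_equal(hausdorff_distance(A, B), 10)
  expect_equal(hausdorff_distance(A, A), 0)
  expect_equal(hausdorff_distance(rbind(c(1, 2)), rbind(c(4, 6))), 5)
})

test_that("empty diagrams are measured against the diagonal", {
  E <- matrix(numeric(), 0, 2)
  expect_equal(modified_hausdorff(E, E), 0)
  expect_equal(hausdorff_distance(E, E), 0)
  A <- rbind(c(0, 2), c(0, 4))          # diagonal gaps 2/sqrt(2), 4/sqrt(2)
  expect_equal(modified_hausdorff(A, E), 3 / sqrt(2))
  expect_equal(hausdorff_distance(A, E), 4 / sqrt(2))
  expect_equal(modified_hausdorff(E, A), modified_hausdorff(A, E))
  expect_equal(wasserstein_distance(E, E), 0)
})

test_that("Wasserstein distance on worked examples", {
  expect_equal(wasserstein_distance(rbind(c(0, 2)), matrix(numeric(), 0, 2), 1), 1)
  expect_equal(wasserstein_distance(rbind(c(0, 2)), rbind(c(0, 2), c(5, 7)), 1), 1)
  A <- rbind(c(0, 3), c(2, 8))
  expect_equal(wasserstein_distance(A, A, 2), 0)
  expect_error(wasserstein_distance(A, A, 0.5), class = "actiph_config_error")
})

test_that("Wasserstein equals brute-force enumeration over augmented matchings", {
  set.seed(50)
  for (i in 1:200) {
    A <- random_diagram(); B <- random_diagram()
    for (q in c(1, 2))
      expect_equal(wasserstein_distance(A, B, q), bf_wasserstein(A, B, q),
                   tolerance = 1e-10)
  }
})

test_that("modified Hausdorff satisfies the semimetric axioms", {
  set.seed(51)
  for (i in 1:200) {
    A <- random_diagram(6); B <- random_diagram(6)
    d <- modified_hausdorff(A, B)
    expect_gte(d, 0)
    expect_equal(d, modified_hausdorff(B, A))
    expect_equal(modified_hausdorff(A, A), 0)
  }
  # the triangle inequality genuinely fails for some triples (semimetric only)
  A <- rbind(c(2.5, 6.9), c(0.9, 1.6), c(0.0, 0.1))
  B <- rbind(c(0.8, 3.0), c(2.0, 4.6), c(2.3, 6.5))
  C <- rbind(c(3.4, 5.8), c(3.3, 8.1), c(3.3, 5.3))
  expect_gt(modified_hausdorff(A, C),
            modified_hausdorff(A, B) + modified_hausdorff(B, C))
})

test_that("Wasserstein satisfies the metric axioms on small diagrams", {
  set.seed(52)
  for (i in 1:120) {
    A <- random_diagram(); B <- random_diagram(); C <- random_diagram()
    for (q in c(1, 2)) {
      dab <- wasserstein_distance(A, B, q)
      expect_gte(dab, 0)
      expect_equal(dab, wasserstein_distance(B, A, q), tolerance = 1e-10)
      expect_equal(wasserstein_distance(A, A, q), 0)
      expect_lte(dab, wasserstein_distance(A, C, q) + wasserstein_distance(C, B, q) + 1e-9)
    }
  }
})

test_that("Hausdorff dominates modified Hausdorff and grows under translation", {
  set.seed(53)
  for (i in 1:200) {
    A <- random_diagram(6); B <- random_diagram(6)
    expect_gte(hausdorff_distance(A, B), modified_hausdorff(A, B) - 1e-12)
  }
  A <- random_diagram(5)
  B <- random_diagram(5)
  if (nrow(A) == 0) A <- rbind(c(0, 1))
  if (nrow(B) == 0) B <- rbind(c(0, 2))
  prev <- hausdorff_distance(A, B)
  for (t in c(5, 20, 100)) {
    Bt <- B; Bt[, 1] <- Bt[, 1] + t
    cur <- hausdorff_distance(A, Bt)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("distance signals compare corresponding windows", {
  set.seed(54)
  x <- round(runif(100, 0, 30)); y <- round(runif(100, 0, 30))
  dx <- windowed_diagrams(x, 20); dy <- windowed_diagrams(y, 20)
  ds <- distance_signal(dx, dy)
  expect_length(ds, 5)
  expect_true(all(ds$values >= 0))
  expect_equal(ds$values[3],
               modified_hausdorff(dx$diagrams[[3]], dy$diagrams[[3]]))
  expect_equal(distance_signal(dx, dx)$values, rep(0, 5))
  dw <- distance_signal(dx, dy, metric = "wasserstein", q = 1)
  expect_equal(dw$values[2], wasserstein_distance(dx$diagrams[[2]], dy$diagrams[[2]], 1))
  short <- windowed_diagrams(y[1:80], 20)
  expect_error(distance_signal(dx, short), class = "actiph_validation_error")
  other <- windowed_diagrams(y, 10)
  expect_error(distance_signal(dx, other), class = "actiph_validation_error")
})

test_that("a 7000-sample pair yields a 350-point distance signal", {
  set.seed(55)
  a <- round(runif(7000, 0, 100)); b <- round(runif(7000, 0, 100))
  ds <- distance_signal(windowed_diagrams(a), windowed_diagrams(b))
  expect_length(ds, 350)
})

test_that("mean_distance averages the window distances", {
  expect_equal(mean_distance(c(1, 2, 3)), 2)
  expect_equal(mean_distance(rep(0, 10)), 0)
  expect_equal(mean_distance(rep(2.5, 350)), 2.5)
  expect_error(mean_distance(numeric(0)), class = "actiph_validation_error")
})
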