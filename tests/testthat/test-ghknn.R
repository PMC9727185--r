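test_that("ghknn_params defaults reproduce the tuned values and validate", {
  p <- ghknn_params()
  expect_equal(p$lam, 0.01)
  expect_equal(p$gamma, 2^-15)
  expect_equal(p$mu, 0.1)
  expect_identical(p$k, 10L)
  expect_identical(p$kernel, "rbf")
  expect_error(ghknn_params(lam = 0))
  expect_error(ghknn_params(mu = -1))
})

test_that("rbf_kernel closed-form values and PSD Gram matrices", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), 0.5), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), 1e-12), 1, tolerance = 1e-9)
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "equal dimension")

  set.seed(6)
  A <- matrix(rnorm(8 * 3), 8, 3)
  K <- outer(seq_len(8), seq_len(8),
             Vectorize(function(i, j) rbf_kernel(A[i, ], A[j, ], 0.3)))
  expect_equal(K, t(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("select_neighbors matches a brute-force distance sort", {
  # 5 collinear points
  rows <- cbind(c(0, 1, 2, 3, 4), 0)
  expect_identical(select_neighbors(c(2.1, 0), rows, 2), c(3L, 4L))
  # k >= class size returns all rows
  expect_length(select_neighbors(c(0, 0), rows, 10), 5L)
  # coincident point, k = 1
  expect_identical(select_neighbors(c(3, 0), rows, 1), 4L)

  set.seed(7)
  for (i in 1:20) {
    inst <- random_instance()
    k <- sample(1:inst$kp, 1)
    got <- select_neighbors(inst$x, inst$V, k)
    d <- apply(inst$V, 1, function(r) sqrt(sum((r - inst$x)^2)))
    expect_identical(got, order(d)[seq_len(k)])
  }
})

test_that("graph Laplacian: structure and double-sum penalty identity", {
  expect_equal(build_graph_laplacian(rbind(c(1, 2)), 0.5),
               matrix(0, 1, 1))
  V2 <- rbind(c(0, 0), c(1, 0))
  w <- exp(-0.5)
  expect_equal(build_graph_laplacian(V2, 0.5),
               matrix(c(w, -w, -w, w), 2))

  set.seed(8)
  for (i in 1:10) {
    V <- matrix(rnorm(4 * 3), 4, 3)
    gamma <- runif(1, 0.05, 2)
    L <- build_graph_laplacian(V, gamma)
    expect_equal(L, t(L))
    expect_equal(unname(rowSums(L)), rep(0, 4), tolerance = 1e-10)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
    # a' L a = 1/2 sum_pq W_pq (a_p - a_q)^2, by direct double sum
    a <- rnorm(4)
    W <- -L; diag(W) <- 0
    dsum <- 0
    for (p in 1:4) for (q in 1:4) dsum <- dsum + W[p, q] * (a[p] - a[q])^2
    expect_equal(drop(crossprod(a, L %*% a)), dsum / 2, tolerance = 1e-10)
  }
})

test_that("solve_alpha: scalar case, residual contract, optimizer oracle", {
  # k' = 1, x equal to its neighbor, lambda = 0.01
  p1 <- ghknn_params(k = 1)
  x <- c(2, 3)
  hp <- solve_alpha(x, local_hyperplane(x, rbind(x), p1), p1)
  expect_equal(hp$alpha, 1 / 1.01)
  expect_equal(hyperplane_distance(x, hp, p1), (1 - 1 / 1.01)^2)

  set.seed(9)
  for (i in 1:12) {
    inst <- random_instance()
    params <- ghknn_params(lam = runif(1, 1e-3, 1), gamma = runif(1, 1e-3, 1),
                           mu = runif(1, 0, 1), k = inst$kp)
    hp <- solve_alpha(inst$x, local_hyperplane(inst$x, inst$V, params), params)
    # linear-system residual
    A <- hp$K + diag(params$lam, nrow(hp$K)) + params$mu * hp$L
    expect_lt(max(abs(A %*% hp$alpha - hp$kvec)), 1e-8)
    # independent numerical minimization of the regularized objective over
    # the selected neighbor matrix (rows in neighbor order)
    opt <- optim(rep(0, inst$kp), ghknn_objective, x = inst$x, V = hp$V,
                 params = params, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_lt(max(abs(opt$par - hp$alpha)), 1e-4)
  }
})

test_that("hyperplane_distance: symmetry, linear-kernel identity, clamping", {
  set.seed(10)
  inst <- random_instance(d = 5, kp = 4)
  params <- ghknn_params(k = 4)
  d0 <- ghknn_distance(inst$x, inst$V, params)
  expect_gte(d0, 0)
  # permuting neighbor rows leaves the distance unchanged
  d1 <- ghknn_distance(inst$x, inst$V[c(3, 1, 4, 2), ], params)
  expect_equal(d0, d1, tolerance = 1e-12)

  # mu = 0, linear kernel equals input-space squared residual with same alpha
  pl <- ghknn_params(lam = 0.2, mu = 0, k = 4, kernel = "linear")
  hp <- solve_alpha(inst$x, local_hyperplane(inst$x, inst$V, pl), pl)
  resid <- hp$xc - drop(crossprod(hp$Vc, hp$alpha))
  expect_equal(hyperplane_distance(inst$x, hp, pl), sum(resid^2),
               tolerance = 1e-10)
})

test_that("GHKNN(linear, mu=0) is exactly HKNN; exact-fit limit", {
  set.seed(12)
  for (i in 1:30) {
    inst <- random_instance()
    k <- sample(1:inst$kp, 1)
    lam <- runif(1, 1e-3, 1)
    pl <- ghknn_params(lam = lam, mu = 0, k = k, kernel = "linear")
    expect_equal(ghknn_distance(inst$x, inst$V, pl),
                 hknn_distance(inst$x, inst$V, k = k, lam = lam),
                 tolerance = 1e-10)
  }
  # x in the affine span of its neighbors: distance -> 0 as lambda -> 0
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  x <- 0.2 * V[2, ] + 0.3 * V[3, ] + 0.5 * V[1, ]
  expect_lt(hknn_distance(x, V, k = 3, lam = 1e-10), 1e-8)
  # k' = 1 with x = neighbor is 0 for any lambda
  expect_equal(hknn_distance(c(1, 1), rbind(c(1, 1)), k = 1, lam = 5), 0)
})

test_that("hyperplane_distance is non-decreasing in lambda", {
  set.seed(13)
  grid <- c(1e-3, 1e-2, 1e-1, 1, 10)
  for (i in 1:10) {
    inst <- random_instance()
    mu <- sample(c(0, 0.1), 1)
    dists <- vapply(grid, function(l) {
      ghknn_distance(inst$x, inst$V,
                     ghknn_params(lam = l, gamma = 0.3, mu = mu, k = inst$kp))
    }, numeric(1))
    expect_true(all(diff(dists) >= -1e-12))
  }
})

test_that("ghknn_predict: recovery, ties, determinism, contracts", {
  set.seed(14)
  # well-separated classes: a training row classifies to its own class
  A <- matrix(rnorm(30 * 4, sd = 0.1), 30, 4)
  B <- matrix(rnorm(30 * 4, sd = 0.1) + 5, 30, 4)
  X <- rbind(A, B); y <- rep(c("a", "b"), each = 30)
  p <- ghknn_params(gamma = 0.1, k = 5)
  got <- ghknn_predict(X[c(3, 45), ], X, y, p)
  expect_identical(got$labels, c("a", "b"))
  expect_identical(colnames(got$distances), c("a", "b"))

  # mirror-image tie goes to the first declared label
  V <- rbind(c(1, 0), c(2, 0), c(3, 0))
  Xm <- rbind(V, -V)
  ym <- rep(c("left", "right"), c(3, 3))  # "left" first alphabetically
  tie <- ghknn_predict(c(0, 0), Xm, ym, ghknn_params(k = 3))
  expect_equal(unname(tie$distances[1, "left"]),
               unname(tie$distances[1, "right"]), tolerance = 1e-12)
  expect_identical(tie$labels, "left")
  # declared order via factor levels flips the tie
  tie2 <- ghknn_predict(c(0, 0), Xm, factor(ym, levels = c("right", "left")),
                        ghknn_params(k = 3))
  expect_identical(tie2$labels, "right")

  # determinism
  r1 <- ghknn_predict(X[1:5, ], X, y, p)
  r2 <- ghknn_predict(X[1:5, ], X, y, p)
  expect_identical(r1, r2)

  expect_error(ghknn_predict(X[1, ], X, rep("a", 60), p), "2 classes")

  # mu=0 linear-kernel predictions match the HKNN baseline rule
  set.seed(15)
  Xs <- matrix(rnorm(40 * 3), 40, 3)
  ys <- rep(c("a", "b"), each = 20)
  pl <- ghknn_params(lam = 0.05, mu = 0, k = 4, kernel = "linear")
  pred <- ghknn_predict(Xs[1:10, ] + 0.1, Xs, ys, pl)
  hknn_pred <- vapply(1:10, function(i) {
    da <- hknn_distance(Xs[i, ] + 0.1, Xs[ys == "a", ], k = 4, lam = 0.05)
    db <- hknn_distance(Xs[i, ] + 0.1, Xs[ys == "b", ], k = 4, lam = 0.05)
    c("a", "b")[which.min(c(da, db))]
  }, character(1))
  expect_identical(pred$labels, hknn_pred)
})
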