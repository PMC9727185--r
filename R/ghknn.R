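# Graph-regularized kernel k-local hyperplane distance nearest neighbor
# (GHKNN) classifier, with the input-space HKNN baseline.
#
# Per class c, the k nearest class members V of a test point x define a local
# hyperplane through their centroid. After centering by the centroid
# (x_ = x - N, V_ = V - N), the hyperplane coefficients solve the
# positive-definite system
#     (K(V_,V_) + lambda*I + mu*L) alpha = K(V_, x_),
# where L is the unnormalized graph Laplacian of RBF similarities among the
# neighbors, and the squared kernel-space distance from x to the hyperplane is
#     K(x_,x_) + alpha' K(V_,V_) alpha - 2 K(V_,x_)' alpha.
# The predicted class minimizes this distance.

#' GHKNN parameter set
#'
#' @param lam ridge weight lambda > 0 (default 0.01).
#' @param gamma RBF bandwidth gamma > 0 (default `2^-15`).
#' @param mu graph-regularization weight mu >= 0 (default 0.1).
#' @param k neighborhood size (default 10); classes smaller than `k` use all
#'   their members.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return A list of class `ghknn_params`.
#' @export
ghknn_params <- function(lam = 0.01, gamma = 2^-15, mu = 0.1, k = 10L,
                         kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam), lam > 0,
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0,
            is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0,
            is.numeric(k), length(k) == 1L, k >= 1)
  structure(list(lam = lam, gamma = gamma, mu = mu, k = as.integer(k),
                 kernel = kernel),
            class = "ghknn_params")
}

#' RBF kernel value of a vector pair
#'
#' `exp(-gamma * ||xi - xj||^2)`, in (0, 1].
#'
#' @param xi,xj numeric vectors of equal length.
#' @param gamma bandwidth > 0.
#' @return A single kernel value.
#' @export
rbf_kernel <- function(xi, xj, gamma) {
  if (length(xi) != length(xj)) stop("xi and xj must have equal dimension")
  exp(-gamma * sum((xi - xj)^2))
}

# Squared Euclidean cross-distances between row sets (n_a x n_b).
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Kernel Gram matrix between row sets under params (rbf or linear).
kernel_matrix <- function(A, B, params) {
  A <- rbind(A)
  B <- rbind(B)
  switch(params$kernel,
         rbf = exp(-params$gamma * cross_dist2(A, B)),
         linear = tcrossprod(A, B))
}

kernel_self <- function(x, params) {
  switch(params$kernel, rbf = 1, linear = sum(x^2))
}

#' Indices of a test point's nearest class members
#'
#' The `min(k, nrow(class_rows))` rows nearest to `x` in input-space Euclidean
#' distance; ties broken by lower row index.
#'
#' @param x numeric vector.
#' @param class_rows numeric matrix of one class's training rows.
#' @param k neighborhood size.
#' @return Integer vector of row indices.
#' @export
select_neighbors <- function(x, class_rows, k) {
  class_rows <- rbind(class_rows)
  if (nrow(class_rows) == 0L) stop("class has no training rows")
  d2 <- colSums((t(class_rows) - x)^2)
  order(d2)[seq_len(min(k, nrow(class_rows)))]
}

#' Unnormalized graph Laplacian of a neighbor set
#'
#' Edge weights are RBF similarities among the neighbor rows
#' (`W[p,q] = exp(-gamma ||V_p - V_q||^2)` for `p != q`, zero diagonal, no
#' self-loops); `L = D - W` with `D = diag(rowSums(W))`. `L` is symmetric PSD
#' with zero row sums, and the pairwise coefficient penalty
#' `sum_pq W[p,q] (a_p - a_q)^2` equals `2 a' L a`.
#'
#' @param V numeric matrix of neighbor rows (k' x d).
#' @param gamma RBF bandwidth for the edge weights.
#' @return A k' x k' Laplacian matrix.
#' @export
build_graph_laplacian <- function(V, gamma) {
  V <- rbind(V)
  W <- exp(-gamma * cross_dist2(V, V))
  diag(W) <- 0
  diag(rowSums(W), nrow = nrow(W)) - W
}

#' Build a class-local hyperplane for a test point
#'
#' Selects neighbors, centers them by their centroid, and builds the graph
#' Laplacian; [solve_alpha()] completes it with the coefficient vector.
#'
#' @param x test point (numeric vector).
#' @param class_rows training rows of one class.
#' @param params a [ghknn_params()] object.
#' @return A list of class `local_hyperplane` with elements `V` (neighbors),
#'   `Nbar` (centroid), `Vc` (centered neighbors), `xc` (centered test point),
#'   and `L` (Laplacian).
#' @export
local_hyperplane <- function(x, class_rows, params = ghknn_params()) {
  class_rows <- rbind(class_rows)
  idx <- select_neighbors(x, class_rows, params$k)
  V <- class_rows[idx, , drop = FALSE]
  Nbar <- colMeans(V)
  structure(
    list(V = V, Nbar = Nbar,
         Vc = sweep(V, 2L, Nbar),
         xc = x - Nbar,
         L = build_graph_laplacian(V, params$gamma)),
    class = "local_hyperplane")
}

#' Solve for the hyperplane coefficients
#'
#' Solves `(K(Vc,Vc) + lambda I + mu L) alpha = K(Vc, xc)` by a
#' positive-definite linear solve (never an explicit inverse); `lambda > 0`
#' guarantees positive definiteness.
#'
#' @param x test point.
#' @param hp a [local_hyperplane()] object.
#' @param params a [ghknn_params()] object.
#' @return `hp` completed with `alpha`, the Gram matrix `K`, and the
#'   cross-kernel vector `kvec`.
#' @export
solve_alpha <- function(x, hp, params = ghknn_params()) {
  if (!all(is.finite(hp$Vc)) || !all(is.finite(hp$xc))) {
    stop("non-finite values in hyperplane inputs")
  }
  K <- kernel_matrix(hp$Vc, hp$Vc, params)
  kvec <- drop(kernel_matrix(hp$Vc, rbind(hp$xc), params))
  A <- K + diag(params$lam, nrow(K)) + params$mu * hp$L
  hp$alpha <- unname(drop(solve(A, kvec)))
  hp$K <- K
  hp$kvec <- kvec
  hp
}

#' Squared kernel-space distance from a test point to a local hyperplane
#'
#' `K(xc,xc) + alpha' K alpha - 2 kvec' alpha`, clamped to be non-negative
#' (round-off negatives above -1e-10 are set to 0; anything more negative is a
#' numerical failure).
#'
#' @inheritParams solve_alpha
#' @return A single non-negative distance.
#' @export
hyperplane_distance <- function(x, hp, params = ghknn_params()) {
  if (is.null(hp$alpha)) stop("hyperplane coefficients not solved yet")
  d <- kernel_self(hp$xc, params) +
    drop(crossprod(hp$alpha, hp$K %*% hp$alpha)) -
    2 * sum(hp$kvec * hp$alpha)
  if (d < -1e-10) stop("hyperplane distance is strongly negative (", d,
                       "): numerical failure")
  max(d, 0)
}

#' GHKNN distance from a test point to one class
#'
#' Convenience chain of [local_hyperplane()], [solve_alpha()] and
#' [hyperplane_distance()].
#'
#' @inheritParams local_hyperplane
#' @return A single non-negative distance.
#' @export
ghknn_distance <- function(x, class_rows, params = ghknn_params()) {
  hp <- solve_alpha(x, local_hyperplane(x, class_rows, params), params)
  hyperplane_distance(x, hp, params)
}

#' GHKNN classification of test points
#'
#' Assigns each test row the class whose local hyperplane is nearest
#' (argmin of [hyperplane_distance()] over classes). Ties are broken by the
#' declared label order: the factor levels of `y_train` if it is a factor,
#' otherwise the sorted unique labels.
#'
#' @param X_test numeric matrix of test rows (a single vector is accepted).
#' @param X_train numeric matrix of training rows.
#' @param y_train class labels for `X_train` (any number of classes >= 2).
#' @param params a [ghknn_params()] object.
#' @return A list with `labels` (predicted label per test row) and
#'   `distances` (n_test x n_class matrix of per-class hyperplane distances).
#' @export
ghknn_predict <- function(X_test, X_train, y_train,
                          params = ghknn_params()) {
  X_test <- rbind(X_test)
  X_train <- as.matrix(X_train)
  if (nrow(X_train) != length(y_train)) stop("X_train/y_train length mismatch")
  classes <- if (is.factor(y_train)) levels(y_train) else sort(unique(as.character(y_train)))
  y_train <- as.character(y_train)
  if (length(classes) < 2L) stop("need at least 2 classes in y_train")

  dists <- matrix(NA_real_, nrow(X_test), length(classes),
                  dimnames = list(NULL, classes))
  for (cl in classes) {
    Xc <- X_train[y_train == cl, , drop = FALSE]
    if (nrow(Xc) == 0L) stop("class '", cl, "' has no training rows")
    # one cross-distance matrix per class serves every test point's
    # neighbor search
    D2 <- cross_dist2(X_test, Xc)
    kp <- min(params$k, nrow(Xc))
    for (i in seq_len(nrow(X_test))) {
      idx <- order(D2[i, ])[seq_len(kp)]
      V <- Xc[idx, , drop = FALSE]
      Nbar <- colMeans(V)
      hp <- structure(
        list(V = V, Nbar = Nbar, Vc = sweep(V, 2L, Nbar),
             xc = X_test[i, ] - Nbar,
             L = build_graph_laplacian(V, params$gamma)),
        class = "local_hyperplane")
      hp <- solve_alpha(X_test[i, ], hp, params)
      dists[i, cl] <- hyperplane_distance(X_test[i, ], hp, params)
    }
  }
  pick <- apply(dists, 1L, which.min)   # first minimum = declared-order tie-break
  list(labels = classes[pick], distances = dists)
}

#' Input-space HKNN distance (baseline)
#'
#' Squared Euclidean distance from a test point to the ridge-regularized local
#' hyperplane of its k class-neighbors in the original input space:
#' `||xc - Vc' alpha||^2` with `(lambda I + Vc Vc') alpha = Vc xc` (rows of
#' `Vc` are the centered neighbors). Equals the GHKNN distance with linear
#' kernel and `mu = 0`.
#'
#' @param x test point.
#' @param class_rows training rows of one class.
#' @param k neighborhood size.
#' @param lam ridge weight lambda > 0.
#' @return A single non-negative distance.
#' @export
hknn_distance <- function(x, class_rows, k = 10L, lam = 0.01) {
  class_rows <- rbind(class_rows)
  idx <- select_neighbors(x, class_rows, k)
  V <- class_rows[idx, , drop = FALSE]
  Nbar <- colMeans(V)
  Vc <- sweep(V, 2L, Nbar)
  xc <- x - Nbar
  G <- tcrossprod(Vc)                       # k' x k' Gram
  alpha <- drop(solve(G + diag(lam, nrow(G)), Vc %*% xc))
  sum((xc - drop(crossprod(Vc, alpha)))^2)
}
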