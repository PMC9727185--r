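# SMOTE minority-class oversampling.

#' SMOTE oversampling of a minority-class feature matrix
#'
#' Generates `target_count - nrow(minority)` synthetic rows. Each synthetic
#' row is `x + u * (x_n - x)` for a minority row `x`, one of its `k_neighbors`
#' nearest Euclidean neighbors `x_n` within the minority class (chosen
#' uniformly; distance ties broken by lower row index), and `u` drawn
#' uniformly from (0, 1). Base rows are taken in whole passes over the
#' minority set, with any remainder sampled without replacement.
#'
#' @param minority numeric matrix of minority-class feature rows.
#' @param target_count requested total minority count (>= current count).
#' @param k_neighbors number of nearest neighbors considered (default 5);
#'   must be smaller than `nrow(minority)`.
#' @param seed optional integer seed; the output is fully reproducible from it.
#' @return Matrix of synthetic rows (possibly 0-row), with integer attributes
#'   `base` and `neighbor` (row indices into `minority`) and numeric attribute
#'   `u` recording each row's provenance.
#' @export
smote_oversample <- function(minority, target_count, k_neighbors = 5L,
                             seed = NULL) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (k_neighbors < 1L || k_neighbors >= n) {
    stop("k_neighbors must be in [1, nrow(minority) - 1]; got ", k_neighbors,
         " with ", n, " minority rows")
  }
  if (target_count < n) stop("target_count (", target_count,
                             ") is below the current minority count (", n, ")")
  m <- target_count - n
  empty <- matrix(numeric(0), nrow = 0L, ncol = ncol(minority),
                  dimnames = list(NULL, colnames(minority)))
  if (m == 0L) {
    return(structure(empty, base = integer(0), neighbor = integer(0),
                     u = numeric(0)))
  }
  # k nearest neighbors within the minority class, excluding self;
  # order() is stable, so distance ties resolve to the lower row index.
  D <- as.matrix(stats::dist(minority))
  nn <- t(vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    order(d)[seq_len(k_neighbors)]
  }, integer(k_neighbors)))

  gen <- function() {
    base <- c(rep(seq_len(n), m %/% n),
              if (m %% n > 0L) sample.int(n, m %% n))
    pick <- sample.int(k_neighbors, m, replace = TRUE)
    u <- stats::runif(m)
    list(base = base, pick = pick, u = u)
  }
  draw <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  neighbor <- nn[cbind(draw$base, draw$pick)]
  synth <- minority[draw$base, , drop = FALSE] +
    draw$u * (minority[neighbor, , drop = FALSE] -
                minority[draw$base, , drop = FALSE])
  rownames(synth) <- NULL
  structure(synth, base = draw$base, neighbor = neighbor, u = draw$u)
}

#' Balance a binary dataset by SMOTE oversampling of the minority class
#'
#' The minority class is oversampled to `target` rows (default: the majority
#' count); majority rows are untouched; the combined rows are then shuffled.
#' Original rows appear unchanged in the output.
#'
#' @param X numeric feature matrix.
#' @param y binary label vector, length `nrow(X)`.
#' @param target requested minority count: `"match"` (majority count, the
#'   default) or a positive integer.
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param seed optional integer seed controlling both SMOTE and the shuffle.
#' @return A list with `X` (balanced matrix), `y` (labels), and `synthetic`
#'   (logical; `TRUE` for SMOTE-generated rows).
#' @export
balance_dataset <- function(X, y, target = "match", k_neighbors = 5L,
                            seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y must have matching lengths")
  counts <- table(y)
  if (length(counts) != 2L) {
    stop("balance_dataset requires exactly 2 classes, got ", length(counts))
  }
  minority_label <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  if (identical(target, "match")) target <- as.integer(n_maj)
  target <- as.integer(target)
  if (target < n_min) stop("target (", target,
                           ") is below the minority count (", n_min, ")")

  run <- function() {
    synth <- smote_oversample(X[y == minority_label, , drop = FALSE],
                              target_count = target,
                              k_neighbors = k_neighbors)
    Xb <- rbind(X, synth)
    yb <- c(as.character(y), rep(minority_label, nrow(synth)))
    tag <- c(rep(FALSE, nrow(X)), rep(TRUE, nrow(synth)))
    ord <- sample.int(nrow(Xb))
    list(X = Xb[ord, , drop = FALSE], y = yb[ord], synthetic = tag[ord])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
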