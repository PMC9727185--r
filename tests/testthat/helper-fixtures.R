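# Shared fixtures and independent oracles for the test suite.

# A toy 3-group table whose assignments are easy to hand-check.
toy_table <- function() {
  list(property = "toy",
       groups = list(c("A"), c("R"),
                     setdiff(snareid::AA_ALPHABET, c("A", "R"))))
}

write_temp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

# Random small GHKNN instance: a test point plus a neighbor matrix.
random_instance <- function(d = NULL, kp = NULL) {
  if (is.null(d)) d <- sample(2:10, 1)
  if (is.null(kp)) kp <- sample(2:6, 1)
  list(x = rnorm(d), V = matrix(rnorm(kp * d), kp, d), d = d, kp = kp)
}

# Eq-8-style objective (ridge + graph penalty mu*a'La + kernel reconstruction
# error), written independently of the closed-form solve path.
ghknn_objective <- function(alpha, x, V, params) {
  Nbar <- colMeans(V)
  Vc <- sweep(V, 2, Nbar)
  xc <- x - Nbar
  kfun <- function(a, b) {
    if (params$kernel == "rbf") exp(-params$gamma * sum((a - b)^2))
    else sum(a * b)
  }
  kp <- nrow(Vc)
  K <- matrix(0, kp, kp)
  for (p in seq_len(kp)) for (q in seq_len(kp)) {
    K[p, q] <- kfun(Vc[p, ], Vc[q, ])
  }
  kv <- vapply(seq_len(kp), function(p) kfun(Vc[p, ], xc), numeric(1))
  L <- snareid::build_graph_laplacian(V, params$gamma)
  recon <- kfun(xc, xc) - 2 * sum(kv * alpha) +
    drop(crossprod(alpha, K %*% alpha))
  params$lam * sum(alpha^2) + params$mu * drop(crossprod(alpha, L %*% alpha)) +
    recon
}

# Brute-force confusion tally, one sample at a time.
tally_confusion <- function(y_true, y_pred, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == positive && y_pred[i] == positive) tp <- tp + 1L
    if (y_true[i] != positive && y_pred[i] != positive) tn <- tn + 1L
    if (y_true[i] != positive && y_pred[i] == positive) fp <- fp + 1L
    if (y_true[i] == positive && y_pred[i] != positive) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}
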