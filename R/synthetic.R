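# Seeded synthetic sequence sets and feature clusters with controllable
# class separation; the test-time stand-in for curated SNARE/non-SNARE data.

#' Sample a random amino-acid sequence
#'
#' Residues are drawn i.i.d. from the normalized weight distribution over the
#' 20 standard residues.
#'
#' @param length sequence length (>= 2).
#' @param residue_weights non-negative weights, one per residue of
#'   [AA_ALPHABET] (named or positional); not all zero. Default uniform.
#' @param seed optional integer seed.
#' @return A sequence string.
#' @export
sample_sequence <- function(length, residue_weights = rep(1, 20), seed = NULL) {
  if (length < 2L) stop("length must be >= 2")
  w <- residue_weights
  if (!is.null(names(w))) w <- w[AA_ALPHABET]
  if (length(w) != 20L || any(!is.finite(w)) || any(w < 0) || sum(w) == 0) {
    stop("residue_weights must be 20 non-negative finite weights, not all zero")
  }
  gen <- function() paste0(sample(AA_ALPHABET, length, replace = TRUE,
                                  prob = w / sum(w)), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a labeled synthetic sequence set
#'
#' Emits `n_pos` positive and `n_neg` negative records. Negatives are sampled
#' with uniform residue weights; positives have the weights of
#' `bias_residues` multiplied by `1 + bias_strength`, producing a controllable
#' residue-composition separation in descriptor space. `bias_strength = 0`
#' makes the two populations exchangeable in distribution.
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range inclusive integer range of sequence lengths, uniform;
#'   default `c(50, 400)`.
#' @param bias_residues residues enriched in positives; default the
#'   hydrophobic group of the shipped hydrophobicity table (CLVIMFW).
#' @param bias_strength non-negative multiplier increment on bias-residue
#'   weights (default 0).
#' @param seed optional integer seed; the whole set is reproducible from it.
#' @return A list with `records` (data.frame `id`, `sequence`, `length`) and
#'   `labels` (character, `"pos"`/`"neg"`).
#' @export
generate_labeled_set <- function(n_pos, n_neg, length_range = c(50L, 400L),
                                 bias_residues = NULL, bias_strength = 0,
                                 seed = NULL) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1L] >= 2L, length_range[1L] <= length_range[2L],
            bias_strength >= 0)
  if (is.null(bias_residues)) {
    bias_residues <- default_property_groups()$hydrophobicity$groups[[3L]]
  }
  if (!all(bias_residues %in% AA_ALPHABET)) stop("unknown bias residues")
  w_neg <- stats::setNames(rep(1, 20), AA_ALPHABET)
  w_pos <- w_neg
  w_pos[bias_residues] <- w_pos[bias_residues] * (1 + bias_strength)

  gen <- function() {
    n <- n_pos + n_neg
    lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
    labels <- rep(c("pos", "neg"), c(n_pos, n_neg))
    seqs <- vapply(seq_len(n), function(i) {
      w <- if (labels[i] == "pos") w_pos else w_neg
      paste0(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = w / sum(w)),
             collapse = "")
    }, character(1))
    list(records = data.frame(id = sprintf("synth%05d", seq_len(n)),
                              sequence = seqs, length = lens,
                              stringsAsFactors = FALSE),
         labels = labels)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate two Gaussian feature clusters
#'
#' Two isotropic Gaussian classes of `n_per_class` points in `dim` dimensions
#' with common spread (standard deviation per coordinate). The positive
#' class's center is displaced by `mean_shift` in every coordinate, so
#' per-coordinate mean separation is `mean_shift` (see the methods vignette
#' for why the displacement is per-coordinate). Used to exercise the
#' classifier independently of sequence featurization.
#'
#' @param n_per_class points per class.
#' @param dim dimensionality (>= 1).
#' @param mean_shift per-coordinate displacement of the positive class center.
#' @param spread per-coordinate standard deviation (> 0), default 1.
#' @param seed optional integer seed.
#' @return A list with `X` (2*n_per_class x dim matrix) and `y`
#'   (`"pos"`/`"neg"`).
#' @export
generate_feature_clusters <- function(n_per_class, dim, mean_shift,
                                      spread = 1, seed = NULL) {
  stopifnot(n_per_class >= 1L, dim >= 1L, spread > 0)
  gen <- function() {
    n <- 2L * n_per_class
    X <- matrix(stats::rnorm(n * dim, sd = spread), n, dim)
    X[seq_len(n_per_class), ] <- X[seq_len(n_per_class), ] + mean_shift
    colnames(X) <- paste0("f", seq_len(dim))
    list(X = X, y = rep(c("pos", "neg"), each = n_per_class))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
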