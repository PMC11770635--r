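#' Generalized cross-entropy loss
#'
#' `L_q(p) = (1 - p^q) / q` for the predicted probability `p` of the true
#' class. As `q -> 0` the loss approaches cross-entropy `-log(p)`; at
#' `q = 1` it is the bounded mean-absolute-error-like loss, which is robust
#' to label noise. Zero iff `p = 1`, strictly decreasing in `p`.
#'
#' @param p Predicted probability of the true class, in (0, 1].
#' @param q Exponent in (0, 1].
#' @return Nonnegative loss, vectorized over `p`.
#' @examples
#' gce_loss(0.8, 1)      # 0.2
#' gce_loss(0.8, 1e-4)   # ~ -log(0.8)
#' @export
gce_loss <- function(p, q = 0.7) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  if (length(q) != 1L || q <= 0 || q > 1) {
    stop("q must lie in (0, 1]", call. = FALSE)
  }
  (1 - p^q) / q
}

#' Sample-specific pruning weights for noisy-label training
#'
#' The early (warm-up) epochs train on every sample; afterwards, the
#' `prune_fraction` of samples whose predicted true-class probability is
#' lowest — the putatively mislabeled ones — receive weight 0 and are
#' excluded from the loss, the rest weight 1. Within a round, weights are
#' monotone nondecreasing in the probability.
#'
#' @param p Per-sample predicted probabilities of the labelled class, in
#'   \[0, 1\].
#' @param prune_fraction Fraction in \[0, 1) of samples to down-weight.
#' @param epoch Current epoch (1-based).
#' @param warmup_epochs Number of initial epochs with no pruning.
#' @return Numeric 0/1 weight vector, same length as `p`.
#' @export
sample_weight_update <- function(p, prune_fraction = 0.1, epoch = 1L,
                                 warmup_epochs = 2L) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (prune_fraction < 0 || prune_fraction >= 1) {
    stop("prune_fraction must be in [0, 1)", call. = FALSE)
  }
  n <- length(p)
  w <- rep(1, n)
  if (epoch <= warmup_epochs || prune_fraction == 0 || n == 0L) return(w)
  k <- floor(prune_fraction * n)
  if (k > 0) {
    w[order(p)[seq_len(k)]] <- 0
  }
  w
}
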