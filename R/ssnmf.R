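#' Semisupervised nonnegative matrix factorization of bulk expression
#'
#' Factorizes a nonnegative genes x cases expression matrix as
#' `expression ~ metagenes %*% coefficients` under Frobenius loss using
#' multiplicative updates, with component identity pinned by anchor cases:
#' each metagene is initialized as the mean expression of its subtype's
#' anchors, and anchors' coefficient columns start one-hot on their subtype.
#' Multiplicative updates preserve zeros, so the anchors stay locked to
#' their component for the first `anchor_iters` iterations; the zero
#' supports are then released (set to a tiny positive value) and all
#' coefficients refined freely. After every iteration the metagene columns
#' are rescaled to unit sum (with the inverse applied to the coefficients),
#' which leaves the objective unchanged but removes the diagonal scale
#' indeterminacy that would otherwise distort the proportion estimates.
#' Columns are upper-quartile normalized before fitting; negative input
#' entries are clamped to zero with a warning.
#'
#' @param expression Nonnegative genes x cases matrix with case ids as
#'   column names.
#' @param reference_labels Named character vector mapping anchor case ids to
#'   subtypes; at least one anchor per subtype.
#' @param n_components Number of components; must equal the number of
#'   subtypes (4).
#' @param max_iter Maximum multiplicative-update iterations. Multiplicative
#'   updates converge slowly near the optimum, and proportion accuracy keeps
#'   improving well past visual convergence of the objective, hence the
#'   generous default.
#' @param tol Relative Frobenius-objective change declaring convergence
#'   (checked only after the anchors are released).
#' @param anchor_iters Length of the anchored phase. A short phase suffices
#'   to pin component identity; anchor cases are themselves mixtures, so a
#'   long one-hot phase biases the metagenes.
#' @param seed Integer seed (random initialization of non-anchor
#'   coefficients).
#' @return Object of class `ssnmf`: list with `metagenes` (genes x 4),
#'   `coefficients` (4 x cases), `objective_trace`, `converged`,
#'   `iterations`, `anchors`.
#' @seealso [admixture_proportions()] to turn coefficients into per-case
#'   proportions.
#' @export
fit_ssnmf <- function(expression, reference_labels, n_components = 4L,
                      max_iter = 2000L, tol = 1e-7, anchor_iters = 50L,
                      seed = 1L) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("expression must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(expression)) stop("expression contains NA", call. = FALSE)
  if (n_components != length(SUBTYPES)) {
    stop("n_components must equal the number of subtypes (4)", call. = FALSE)
  }
  n_neg <- sum(expression < 0)
  if (n_neg > 0) {
    warning(sprintf("clamped %d negative entries to 0", n_neg))
    expression[expression < 0] <- 0
  }
  if (is.null(colnames(expression))) {
    colnames(expression) <- sprintf("case%04d", seq_len(ncol(expression)))
  }
  anchors <- reference_labels[names(reference_labels) %in% colnames(expression)]
  missing_sub <- setdiff(SUBTYPES, unique(anchors))
  if (length(anchors) < length(reference_labels)) {
    stop("anchor case ids absent from expression columns", call. = FALSE)
  }
  if (length(missing_sub)) {
    stop("no anchor case for subtype(s): ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  }

  V <- upper_quartile_normalize(expression)
  n_cases <- ncol(V)
  eps <- 1e-10

  with_seed(seed, {
    W <- vapply(SUBTYPES, function(s) {
      rowMeans(V[, names(anchors)[anchors == s], drop = FALSE])
    }, numeric(nrow(V)))
    W <- W + eps
    scale0 <- mean(colSums(V)) / mean(colSums(W))
    H <- matrix(runif(4L * n_cases, 0.5, 1.5) * scale0 / 4, 4L, n_cases,
                dimnames = list(SUBTYPES, colnames(V)))
    anchor_idx <- match(names(anchors), colnames(V))
    for (j in seq_along(anchor_idx)) {
      h <- numeric(4L)
      h[match(anchors[[j]], SUBTYPES)] <- scale0
      H[, anchor_idx[j]] <- h
    }

    trace <- numeric(0)
    obj_prev <- Inf
    released <- FALSE
    release_at <- min(max(1L, anchor_iters), max_iter)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      if (!released && it > release_at) {
        H[H == 0] <- eps * max(H)
        released <- TRUE
      }
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H) + eps))
      csum <- colSums(W)           # objective-invariant diagonal rescale
      W <- sweep(W, 2L, csum, "/")
      H <- H * csum
      obj <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, obj)
      if (released && is.finite(obj_prev) &&
          abs(obj_prev - obj) <= tol * max(obj_prev, eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }

    structure(list(metagenes = W, coefficients = H, objective_trace = trace,
                   converged = converged, iterations = it,
                   anchors = anchors, call = match.call()),
              class = "ssnmf")
  })
}

# Upper-quartile column normalization on the nonnegative linear scale.
upper_quartile_normalize <- function(x) {
  uq <- apply(x, 2L, stats::quantile, probs = 0.75, names = FALSE)
  uq[uq <= 0] <- 1
  sweep(x, 2L, uq / mean(uq), "/")
}

#' Per-case subtype admixture proportions from an ssNMF fit
#'
#' Divides each case's coefficient column by its sum so the four proportions
#' sum to one. A degenerate all-zero column yields the uniform vector
#' (0.25 each) with a warning.
#'
#' @param fit An `ssnmf` object, or a 4 x cases nonnegative coefficient
#'   matrix.
#' @return data.frame of class `admixture_profile` with columns `case_id`,
#'   `pLumA`, `pLumB`, `pHER2`, `pBasal`.
#' @export
admixture_proportions <- function(fit) {
  H <- if (inherits(fit, "ssnmf")) fit$coefficients else fit
  if (!is.matrix(H) || nrow(H) != 4L) {
    stop("fit must be an ssnmf object or a 4 x cases matrix", call. = FALSE)
  }
  if (any(H < 0)) stop("coefficients must be nonnegative", call. = FALSE)
  s <- colSums(H)
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero coefficient column(s); set to uniform 0.25",
                    sum(zero)))
    H[, zero] <- 0.25
    s[zero] <- 1
  }
  P <- sweep(H, 2L, s, "/")
  ids <- colnames(H)
  if (is.null(ids)) ids <- sprintf("case%04d", seq_len(ncol(H)))
  out <- data.frame(case_id = ids, t(P), stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c("case_id", paste0("p", SUBTYPES))
  class(out) <- c("admixture_profile", "data.frame")
  out
}

#' @export
print.ssnmf <- function(x, ...) {
  cat(sprintf("ssNMF fit: %d genes x %d cases, %d components\n",
              nrow(x$metagenes), ncol(x$coefficients), nrow(x$coefficients)))
  cat(sprintf("  %d iterations, %sconverged; final objective %.4g\n",
              x$iterations, if (x$converged) "" else "not ",
              utils::tail(x$objective_trace, 1)))
  cat(sprintf("  anchors: %s\n",
              paste(sprintf("%s=%d", SUBTYPES,
                            as.integer(table(factor(x$anchors, SUBTYPES)))),
                    collapse = " ")))
  invisible(x)
}

#' @export
coef.ssnmf <- function(object, ...) object$coefficients

#' @export
fitted.ssnmf <- function(object, ...) object$metagenes %*% object$coefficients

#' Project new expression columns onto fitted metagenes
#'
#' Holds the metagenes fixed and runs multiplicative coefficient updates on
#' new (upper-quartile normalized) expression columns.
#'
#' @param object An `ssnmf` fit.
#' @param newdata Nonnegative genes x cases matrix with the same gene order
#'   as the training expression.
#' @param max_iter,tol Update budget and convergence tolerance.
#' @param ... Unused.
#' @return 4 x cases coefficient matrix.
#' @export
predict.ssnmf <- function(object, newdata, max_iter = 200L, tol = 1e-8, ...) {
  stopifnot(is.matrix(newdata), nrow(newdata) == nrow(object$metagenes))
  newdata[newdata < 0] <- 0
  V <- upper_quartile_normalize(newdata)
  W <- object$metagenes
  eps <- 1e-10
  H <- matrix(mean(colSums(V)) / (4 * mean(colSums(W))), 4L, ncol(V),
              dimnames = list(SUBTYPES, colnames(V)))
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    obj <- sqrt(sum((V - W %*% H)^2))
    if (abs(obj_prev - obj) <= tol * max(obj_prev, eps)) break
    obj_prev <- obj
  }
  H
}
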