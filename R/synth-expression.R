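#' Generate synthetic subtype metagenes
#'
#' Builds a nonnegative genes x 4 signature matrix, one column per intrinsic
#' subtype in the canonical order (LumA, LumB, HER2, Basal). Each gene carries
#' a shared baseline expression level plus a subtype-specific boost on the
#' genes assigned as markers of that subtype; `separation` scales the boost,
#' so larger values drive the four columns towards orthogonality while
#' `separation = 0` leaves the columns statistically exchangeable.
#'
#' @param n_genes Number of genes (rows); at least 4.
#' @param separation Nonnegative scalar controlling how distinct the subtype
#'   columns are. Marker genes are upweighted by `exp(separation)`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Object of class `signature_matrix`: a nonnegative matrix with
#'   rownames `gene_ids` and colnames the four subtypes, plus attribute
#'   `marker` giving each gene's marker subtype.
#' @examples
#' sig <- generate_metagenes(300, separation = 2, seed = 1)
#' dim(sig)
#' @export
generate_metagenes <- function(n_genes, separation = 2, seed = 1) {
  stopifnot_scalar(n_genes, "n_genes")
  stopifnot_scalar(separation, "separation")
  if (n_genes < 4) stop("n_genes must be at least 4", call. = FALSE)
  if (separation < 0) stop("separation must be nonnegative", call. = FALSE)
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    baseline <- rgamma(n_genes, shape = 2, rate = 1) + 0.1
    marker <- rep_len(seq_len(4L), n_genes)  # each gene marks one subtype
    boost <- matrix(1, n_genes, 4L)
    boost[cbind(seq_len(n_genes), marker)] <- exp(separation)
    jitter <- matrix(exp(rnorm(n_genes * 4L, sd = 0.05)), n_genes, 4L)
    values <- baseline * boost * jitter
    dimnames(values) <- list(sprintf("gene%04d", seq_len(n_genes)), SUBTYPES)
    structure(values, marker = SUBTYPES[marker], class = c("signature_matrix", "matrix", "array"))
  })
}

#' Simulate bulk expression as noisy convex mixtures of subtype metagenes
#'
#' Each case's admixture proportions are drawn from a Dirichlet distribution
#' and its expression column is `signatures %*% proportions` with
#' multiplicative log-normal noise, so values remain strictly nonnegative
#' (the nonnegativity NMF requires). The argmax component gives the case's
#' assigned subtype, the stand-in for a PAM50 call.
#'
#' @param signatures A `signature_matrix` from [generate_metagenes()].
#' @param n_cases Number of cases (columns).
#' @param alpha Dirichlet concentration 4-vector; all entries positive.
#' @param noise_sd Standard deviation (log scale) of the multiplicative
#'   noise; `0` gives the exact noiseless mixture.
#' @param seed Integer seed.
#' @return List with `expression` (genes x cases matrix, case ids as
#'   colnames) and `admixture`, a data.frame of class `true_admixture` with
#'   columns `case_id`, `pLumA`, `pLumB`, `pHER2`, `pBasal`,
#'   `assigned_subtype`.
#' @examples
#' sig <- generate_metagenes(50, seed = 1)
#' sim <- generate_expression(sig, n_cases = 10, seed = 2)
#' colSums(sim$admixture[, c("pLumA", "pLumB", "pHER2", "pBasal")])
#' @export
generate_expression <- function(signatures, n_cases,
                                alpha = c(2.2, 0.6, 0.6, 0.6),
                                noise_sd = 0.2, seed = 1) {
  stopifnot(is.matrix(signatures), ncol(signatures) == 4L)
  stopifnot_scalar(n_cases, "n_cases")
  if (any(alpha <= 0)) stop("alpha entries must be positive", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  n_cases <- as.integer(n_cases)
  with_seed(seed, {
    g <- matrix(rgamma(4L * n_cases, shape = alpha), nrow = 4L)
    props <- sweep(g, 2L, colSums(g), "/")  # Dirichlet(alpha) draws
    clean <- unclass(signatures) %*% props
    if (noise_sd > 0) {
      clean <- clean * exp(matrix(rnorm(length(clean), sd = noise_sd),
                                  nrow = nrow(clean)))
    }
    case_id <- sprintf("case%04d", seq_len(n_cases))
    colnames(clean) <- case_id
    adm <- as.data.frame(t(props))
    names(adm) <- paste0("p", SUBTYPES)
    adm <- cbind(case_id = case_id, adm,
                 assigned_subtype = SUBTYPES[apply(props, 2L, which.max)],
                 stringsAsFactors = FALSE)
    class(adm) <- c("true_admixture", "data.frame")
    list(expression = clean, admixture = adm)
  })
}
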