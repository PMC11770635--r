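#' Rank cases by transcriptomic purity within each assigned subtype
#'
#' Within each assigned (PAM50) subtype, cases are ordered by descending
#' proportion of that subtype in their admixture profile — i.e. by
#' transcriptomic adherence to the assigned class. Ties break by ascending
#' case id, so the ranking is stable under permutations of the input.
#'
#' @param profiles An `admixture_profile` data.frame
#'   ([admixture_proportions()]).
#' @param assigned Named character vector mapping every case id in
#'   `profiles` to its assigned subtype.
#' @return Named list (one entry per subtype present) of data.frames with
#'   columns `case_id`, `purity`, `rank`.
#' @export
purity_rank <- function(profiles, assigned) {
  missing <- setdiff(profiles$case_id, names(assigned))
  if (length(missing)) {
    stop("no assigned subtype for case(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- assigned[profiles$case_id]
  out <- list()
  for (s in intersect(SUBTYPES, unique(sub))) {
    rows <- profiles[sub == s, , drop = FALSE]
    purity <- rows[[paste0("p", s)]]
    ord <- order(-purity, rows$case_id)
    out[[s]] <- data.frame(case_id = rows$case_id[ord],
                           purity = purity[ord],
                           rank = seq_along(ord),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Default split counts (desk scale)
#'
#' The full-scale study design takes the purest LumA and non-LumA cases as a
#' pure pool, randomly partitions that pool into training / validation /
#' initial-test groups, and forms the final test set from the pure LumA cases
#' held out for initial testing plus every more heterogeneous LumA case.
#' These counts scale that design down to the default 200-case synthetic
#' cohort.
#'
#' @param n_pure_luma,n_pure_other Sizes of the pure pools.
#' @param train,validation,initial_test Partition sizes; must sum to
#'   `n_pure_luma + n_pure_other`.
#' @return Named list of counts.
#' @export
split_counts <- function(n_pure_luma = 30L, n_pure_other = 30L,
                         train = 34L, validation = 8L, initial_test = 18L) {
  list(n_pure_luma = as.integer(n_pure_luma),
       n_pure_other = as.integer(n_pure_other),
       train = as.integer(train), validation = as.integer(validation),
       initial_test = as.integer(initial_test))
}

#' Assign cases to training, validation and test splits
#'
#' @param ranked_luma Ranked LumA case ids (vector or a [purity_rank()]
#'   data.frame), purest first.
#' @param ranked_other Ranked non-LumA case ids, purest first.
#' @param counts Split counts, see [split_counts()].
#' @param seed Integer seed for the random partition of the pure pool.
#' @return Object of class `split_assignment`: list with character-vector
#'   elements `train`, `validation`, `initial_test`, `final_test` and a
#'   named integer `purity_rank` over the pure pool. `final_test` overlaps
#'   `initial_test` (the held-out pure LumA cases) but never `train` or
#'   `validation`.
#' @export
make_splits <- function(ranked_luma, ranked_other, counts = split_counts(),
                        seed = 1L) {
  if (is.data.frame(ranked_luma)) ranked_luma <- ranked_luma$case_id
  if (is.data.frame(ranked_other)) ranked_other <- ranked_other$case_id
  n_pool <- counts$n_pure_luma + counts$n_pure_other
  n_parts <- counts$train + counts$validation + counts$initial_test
  if (counts$n_pure_luma > length(ranked_luma) ||
      counts$n_pure_other > length(ranked_other)) {
    stop("pure-pool counts exceed available ranked cases", call. = FALSE)
  }
  if (n_parts != n_pool) {
    stop(sprintf("train+validation+initial_test (%d) must equal the pure pool size (%d)",
                 n_parts, n_pool), call. = FALSE)
  }
  pure_luma <- ranked_luma[seq_len(counts$n_pure_luma)]
  pure_other <- ranked_other[seq_len(counts$n_pure_other)]
  pool <- c(pure_luma, pure_other)
  with_seed(seed, {
    perm <- sample(pool)
    train <- perm[seq_len(counts$train)]
    validation <- perm[counts$train + seq_len(counts$validation)]
    initial_test <- perm[counts$train + counts$validation +
                           seq_len(counts$initial_test)]
    heterogeneous_luma <- setdiff(ranked_luma, pure_luma)
    final_test <- c(intersect(initial_test, pure_luma), heterogeneous_luma)
    structure(list(train = train, validation = validation,
                   initial_test = initial_test, final_test = final_test,
                   purity_rank = stats::setNames(seq_along(pool), pool),
                   counts = counts),
              class = "split_assignment")
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Split assignment\n")
  for (nm in c("train", "validation", "initial_test", "final_test")) {
    cat(sprintf("  %-13s %d cases\n", nm, length(x[[nm]])))
  }
  invisible(x)
}
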