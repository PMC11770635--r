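profile_of <- function(ids, pLumA, assigned = "LumA") {
  pr <- data.frame(case_id = ids, pLumA = pLumA, pLumB = (1 - pLumA) / 3,
                   pHER2 = (1 - pLumA) / 3, pBasal = (1 - pLumA) / 3,
                   stringsAsFactors = FALSE)
  class(pr) <- c("admixture_profile", "data.frame")
  pr
}

test_that("cases are ranked by descending adherence to their subtype", {
  pr <- profile_of(c("case1", "case2", "case3"), c(0.9, 0.7, 0.8))
  assigned <- stats::setNames(rep("LumA", 3), pr$case_id)
  r <- purity_rank(pr, assigned)
  expect_identical(r$LumA$case_id, c("case1", "case3", "case2"))
  expect_identical(r$LumA$rank, 1:3)
})

test_that("purity ties break by ascending case id, whatever the input order", {
  pr <- profile_of(c("caseB", "caseA", "caseC"), c(0.8, 0.8, 0.5))
  assigned <- stats::setNames(rep("LumA", 3), pr$case_id)
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    r <- purity_rank(pr[perm, ], assigned)
    expect_identical(r$LumA$case_id, c("caseA", "caseB", "caseC"))
  }
})

test_that("a missing assignment is a key error", {
  pr <- profile_of(c("a", "b"), c(0.9, 0.8))
  expect_error(purity_rank(pr, c(a = "LumA")), "no assigned subtype")
})

test_that("top-k selection returns exactly k ranked ids", {
  n <- 296
  ids <- sprintf("case%03d", seq_len(n))
  set.seed(3)
  pr <- profile_of(ids, runif(n))
  assigned <- stats::setNames(rep("LumA", n), ids)
  r <- purity_rank(pr, assigned)
  top81 <- r$LumA$case_id[1:81]
  expect_length(unique(top81), 81)
  expect_true(all(r$LumA$purity[1:81] >= r$LumA$purity[82]))
})

test_that("study-scale counts produce exact split sizes and a 230-like final set", {
  luma <- sprintf("L%03d", 1:287)    # 81 pure + 206 heterogeneous
  other <- sprintf("N%03d", 1:120)
  counts <- split_counts(n_pure_luma = 81, n_pure_other = 86,
                         train = 94, validation = 23, initial_test = 50)
  sp <- make_splits(luma, other, counts, seed = 4)
  expect_length(sp$train, 94)
  expect_length(sp$validation, 23)
  expect_length(sp$initial_test, 50)
  held_out_pure_luma <- intersect(sp$initial_test, luma[1:81])
  expect_length(sp$final_test, length(held_out_pure_luma) + 206)
  expect_length(intersect(sp$final_test, sp$train), 0)
  expect_length(intersect(sp$final_test, sp$validation), 0)
})

test_that("splits are deterministic and partition the pure pool", {
  luma <- sprintf("L%02d", 1:40)
  other <- sprintf("N%02d", 1:40)
  counts <- split_counts(n_pure_luma = 20, n_pure_other = 20,
                         train = 24, validation = 6, initial_test = 10)
  a <- make_splits(luma, other, counts, seed = 11)
  b <- make_splits(luma, other, counts, seed = 11)
  expect_identical(a[c("train", "validation", "initial_test", "final_test")],
                   b[c("train", "validation", "initial_test", "final_test")])
  pool <- c(luma[1:20], other[1:20])
  parts <- c(a$train, a$validation, a$initial_test)
  expect_setequal(parts, pool)
  expect_length(parts, 40)  # disjoint and exhaustive
})

test_that("infeasible counts are rejected", {
  expect_error(make_splits(sprintf("L%d", 1:10), sprintf("N%d", 1:10),
                           split_counts(n_pure_luma = 20, n_pure_other = 5,
                                        train = 15, validation = 5,
                                        initial_test = 5)),
               "exceed")
  expect_error(make_splits(sprintf("L%d", 1:10), sprintf("N%d", 1:10),
                           split_counts(n_pure_luma = 5, n_pure_other = 5,
                                        train = 15, validation = 5,
                                        initial_test = 5)),
               "pure pool")
})
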