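#' Pick anchor cases for ssNMF semisupervision
#'
#' For each assigned subtype, selects the `k` cases whose expression
#' correlates best with their subtype's mean expression profile — a
#' label-only purity proxy available before any factorization.
#'
#' @param expression Genes x cases matrix.
#' @param assigned Named character vector of assigned subtypes per case id.
#' @param k Anchors per subtype.
#' @return Named character vector mapping anchor case ids to subtypes.
#' @export
pick_anchors <- function(expression, assigned, k = 4L) {
  assigned <- assigned[colnames(expression)]
  out <- character(0)
  for (s in SUBTYPES) {
    ids <- names(assigned)[assigned == s]
    if (!length(ids)) stop("no cases assigned to subtype ", s, call. = FALSE)
    centroid <- rowMeans(expression[, ids, drop = FALSE])
    r <- apply(expression[, ids, drop = FALSE], 2L, stats::cor, y = centroid)
    sel <- ids[order(-r, ids)][seq_len(min(k, length(ids)))]
    out[sel] <- s
  }
  out
}

# Slide label for training: the case's assigned subtype collapsed to the
# binary LumA / nonLumA scheme.
binary_slide_label <- function(subtype) {
  ifelse(subtype == "LumA", "LumA", "nonLumA")
}

# Extract and featurize one case's patches, streaming (pixels discarded).
case_patch_features <- function(cohort, case_id, patch_size = 512L,
                                coverage_threshold = 0.75,
                                augment_ops = NULL, seed = 1L) {
  sl <- cohort_slide(cohort, case_id)
  ps <- extract_patches(sl, patch_size = patch_size,
                        coverage_threshold = coverage_threshold,
                        slide_id = case_id)
  if (!nrow(ps$manifest)) {
    return(list(features = matrix(numeric(0), 0, 12L), manifest = ps$manifest,
                true_luma_frac = NA_real_))
  }
  tiles <- ps$tiles
  if (!is.null(augment_ops) && any(unlist(augment_ops))) {
    tiles <- lapply(seq_along(tiles), function(i) {
      augment(tiles[[i]], augment_ops, seed = derive_seed(seed, i))
    })
  }
  feats <- t(vapply(tiles, patch_features, numeric(12L)))
  inside <- sl$annotation_mask == 1L
  list(features = feats, manifest = ps$manifest,
       true_luma_frac = mean(sl$subtype_map[inside] == 1L))
}

#' Run the full heterogeneity study on a synthetic cohort
#'
#' Executes every stage end to end: cohort generation; ssNMF admixture
#' estimation with label-derived anchors; purity ranking and splitting;
#' patch extraction, weak slide-level labelling and featurization of the
#' training and validation slides; noise-robust classifier training and
#' calibration-based checkpoint selection; iLumA% scoring of the final
#' test slides; and the clinicomolecular/survival association battery.
#'
#' @param config Cohort configuration ([cohort_config()]).
#' @param counts Split counts ([split_counts()]).
#' @param tconfig Training configuration ([train_config()]).
#' @param patch_size,coverage_threshold Patch extraction parameters.
#' @param anchors_per_subtype Anchors per subtype for ssNMF.
#' @param label_noise Optional fraction of training patch labels flipped
#'   symmetrically (for noise-robustness experiments).
#' @param verbose Print stage progress.
#' @return Object of class `luma_study` with elements `cohort`, `fit`,
#'   `profiles`, `splits`, `model`, `training`, `scores`, `cohort_table`,
#'   `associations`, `survival`, `correlations`.
#' @export
run_study <- function(config = cohort_config(), counts = split_counts(),
                      tconfig = train_config(), patch_size = 512L,
                      coverage_threshold = 0.75, anchors_per_subtype = 4L,
                      label_noise = 0, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("generating cohort")
  cohort <- generate_cohort(config)
  assigned <- stats::setNames(cohort$truth$assigned_subtype,
                              cohort$truth$case_id)

  say("fitting ssNMF")
  anchors <- pick_anchors(cohort$expression, assigned, anchors_per_subtype)
  fit <- fit_ssnmf(cohort$expression, anchors, seed = config$seed)
  profiles <- admixture_proportions(fit)

  say("ranking purity and splitting")
  ranked <- purity_rank(profiles, assigned)
  other <- do.call(rbind, ranked[setdiff(names(ranked), "LumA")])
  other <- other[order(-other$purity, other$case_id), ]
  splits <- make_splits(ranked$LumA, other, counts,
                        seed = derive_seed(config$seed, 7L))

  say("featurizing training/validation patches")
  plum <- stats::setNames(profiles$pLumA, profiles$case_id)
  collect <- function(ids) {
    feats <- list(); labs <- character(0); slide <- character(0)
    for (id in ids) {
      cp <- case_patch_features(cohort, id, patch_size, coverage_threshold,
                                tconfig$augment_ops,
                                seed = derive_seed(config$seed, match(id, cohort$truth$case_id)))
      if (!nrow(cp$features)) next
      feats[[id]] <- cp$features
      labs <- c(labs, rep(binary_slide_label(assigned[[id]]),
                          nrow(cp$features)))
      slide <- c(slide, rep(id, nrow(cp$features)))
    }
    list(features = do.call(rbind, feats), labels = labs, slide_id = slide)
  }
  tr <- collect(splits$train)
  va <- collect(splits$validation)
  if (label_noise > 0) {
    tr$labels <- flip_labels(tr$labels, label_noise,
                             seed = derive_seed(config$seed, 99L))
  }
  validation <- list(features = va$features, labels = va$labels,
                     slide_id = va$slide_id, pLumA = plum)

  say("training classifier")
  training <- train_classifier(tr$features, tr$labels, validation, tconfig)
  model <- select_model(training)

  say("scoring final test slides")
  score_rows <- list()
  truth_frac <- numeric(0)
  for (id in splits$final_test) {
    cp <- case_patch_features(cohort, id, patch_size, coverage_threshold)
    if (!nrow(cp$features)) next
    pr <- classify_patches(model, cp$features)
    score_rows[[id]] <- slide_iluma(pr, slide_id = id)
    truth_frac[id] <- cp$true_luma_frac
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL

  say("association battery")
  tab <- cohort_table(scores, profiles, cohort$clinical)
  truth_cols <- cohort$truth[, c("case_id", paste0("p", SUBTYPES))]
  names(truth_cols)[-1] <- paste0("true_", names(truth_cols)[-1])
  tab <- merge(tab, truth_cols, by = "case_id")
  correlations <- list(
    pearson = correlate(tab$iluma_pct, tab$true_pLumA, "pearson"),
    spearman = correlate(tab$iluma_pct, tab$true_pLumA, "spearman"),
    pearson_ssnmf = correlate(tab$iluma_pct, tab$pLumA, "pearson"))
  associations <- quartile_association(tab)
  surv <- survival_table(tab)

  structure(list(cohort = cohort, fit = fit, profiles = profiles,
                 splits = splits, training = training, model = model,
                 scores = scores, cohort_table = tab,
                 associations = associations, survival = surv,
                 correlations = correlations,
                 true_luma_fraction = truth_frac),
            class = "luma_study")
}

#' Flip a fraction of patch labels symmetrically
#'
#' Utility for label-noise experiments: a random `fraction` of the labels
#' swap class.
#'
#' @param labels Character vector of `"LumA"`/`"nonLumA"` labels.
#' @param fraction Fraction to flip.
#' @param seed Integer seed.
#' @return The label vector with flips applied.
#' @export
flip_labels <- function(labels, fraction, seed = 1L) {
  with_seed(seed, {
    n <- length(labels)
    k <- round(fraction * n)
    idx <- sample.int(n, k)
    labels[idx] <- ifelse(labels[idx] == "LumA", "nonLumA", "LumA")
    labels
  })
}

#' @export
print.luma_study <- function(x, ...) {
  cat("LumA heterogeneity study (synthetic cohort)\n")
  cat(sprintf("  cases: %d; final test slides scored: %d\n",
              x$cohort$config$n_cases, nrow(x$scores)))
  cat(sprintf("  selected checkpoint: epoch %d (val r = %s)\n",
              x$model$epoch, format(x$model$val_correlation, digits = 3)))
  cat(sprintf("  iLumA%% vs true pLumA: Pearson r = %.3f, Spearman rho = %.3f\n",
              x$correlations$pearson$coefficient,
              x$correlations$spearman$coefficient))
  cat(sprintf("  pure calls: %d / %d\n", sum(x$scores$call == "pure"),
              nrow(x$scores)))
  invisible(x)
}

#' @export
summary.luma_study <- function(object, ...) {
  print(object)
  cat("\nFeature-by-quartile associations:\n")
  print(object$associations, digits = 3)
  cat("\nPure vs admixed survival:\n")
  print(object$survival, digits = 3)
  invisible(object)
}
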