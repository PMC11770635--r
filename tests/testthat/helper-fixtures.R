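# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small noiseless mixture with known admixture (fast ssNMF checks).
tiny_mixture <- function() {
  fixture("tiny_mixture", function() {
    sig <- generate_metagenes(300, separation = 2, seed = 1)
    sim <- generate_expression(sig, 40, alpha = c(1, 1, 1, 1),
                               noise_sd = 0, seed = 101)
    assigned <- stats::setNames(sim$admixture$assigned_subtype,
                                sim$admixture$case_id)
    list(sig = sig, sim = sim, assigned = assigned,
         anchors = pick_anchors(sim$expression, assigned, 4))
  })
}

# One small synthetic slide plus its patch set.
tiny_slide <- function() {
  fixture("tiny_slide", function() {
    sl <- generate_slide(c(0.5, 0.3, 0.1, 0.1), 1024, 1024, seed = 7)
    ps <- extract_patches(sl, patch_size = 256, coverage_threshold = 0.75,
                          slide_id = "s1")
    list(slide = sl, patches = ps)
  })
}

# Patch features from slides rendered at known admixture: pure slides give
# zero-label-noise training/validation data; the mixed set exercises the
# iLumA%-vs-pLumA calibration machinery. Used by the training tests.
slide_features <- function(pvec, seed) {
  sl <- generate_slide(pvec, 1024, 1024, seed = seed)
  ps <- extract_patches(sl, patch_size = 512, coverage_threshold = 0.5,
                        slide_id = sprintf("s%04d", seed))
  featurize_patches(ps)
}

patch_training_data <- function() {
  fixture("patch_training_data", function() {
    pure_vec <- function(k) { p <- rep(0, 4); p[k] <- 1; p }
    build <- function(n_luma, n_other, seed0) {
      feats <- list(); labs <- character(0); slide <- character(0)
      for (i in seq_len(n_luma + n_other)) {
        k <- if (i <= n_luma) 1L else 2L + (i %% 3L)  # cycle LumB/HER2/Basal
        f <- slide_features(pure_vec(k), seed0 + i)
        id <- sprintf("s%04d", seed0 + i)
        feats[[id]] <- f
        labs <- c(labs, rep(if (k == 1L) "LumA" else "nonLumA", nrow(f)))
        slide <- c(slide, rep(id, nrow(f)))
      }
      list(features = do.call(rbind, feats), labels = labs, slide_id = slide,
           pLumA = stats::setNames(as.numeric(labs == "LumA")[
             !duplicated(slide)], unique(slide)))
    }
    train <- build(12, 12, 1000)
    val_pure <- build(4, 4, 2000)
    # admixed slides spanning the purity range, remainder on LumB
    pl <- c(0.1, 0.3, 0.45, 0.6, 0.8, 0.95)
    mfeats <- list(); mslide <- character(0)
    for (i in seq_along(pl)) {
      f <- slide_features(c(pl[i], 1 - pl[i], 0, 0), 3000 + i)
      id <- sprintf("s%04d", 3000 + i)
      mfeats[[id]] <- f
      mslide <- c(mslide, rep(id, nrow(f)))
    }
    val_mixed <- list(features = do.call(rbind, mfeats),
                      labels = ifelse(pl[match(mslide, unique(mslide))] > 0.5,
                                      "LumA", "nonLumA"),
                      slide_id = mslide,
                      pLumA = stats::setNames(pl, unique(mslide)))
    list(train = train, val_pure = val_pure, val_mixed = val_mixed)
  })
}
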