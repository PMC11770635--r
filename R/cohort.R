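#' Default synthetic-cohort configuration
#'
#' Desk-scale stand-in for the real study: 300 genes, 200 cases, 1536 px
#' slides of 512 px patches. The Dirichlet concentration gives a cohort that
#' is predominantly LumA-assigned but spans the full purity range, mirroring
#' a LumA test set with heterogeneous admixture.
#'
#' @param ... Named overrides of any default entry.
#' @return Named configuration list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_cases = 200L,
    n_genes = 300L,
    separation = 2,
    alpha = c(2.2, 0.6, 0.6, 0.6),
    noise_sd = 0.2,
    slide_height = 1536L,
    slide_width = 1536L,
    n_regions = 64L,
    mpp = 0.25,
    textures = default_textures(),
    effects = default_effects(),
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg <- utils::modifyList(cfg, over)
  }
  cfg
}

#' Generate a complete synthetic study cohort
#'
#' Builds subtype metagenes, noisy expression mixtures with known admixture,
#' and clinical/survival tables with planted effects, all sharing one set of
#' case ids. Slides are not rendered eagerly (a 200-case image set would be
#' large); [cohort_slide()] regenerates any case's slide deterministically
#' from the cohort seed.
#'
#' @param config Configuration list from [cohort_config()].
#' @return Object of class `luma_cohort`: list with `config`, `signatures`,
#'   `expression`, `truth` (true admixture), `clinical`.
#' @examples
#' co <- generate_cohort(cohort_config(n_cases = 8, n_genes = 40))
#' nrow(co$truth)
#' @export
generate_cohort <- function(config = cohort_config()) {
  sig <- generate_metagenes(config$n_genes, config$separation,
                            seed = derive_seed(config$seed, 1L))
  sim <- generate_expression(sig, config$n_cases, alpha = config$alpha,
                             noise_sd = config$noise_sd,
                             seed = derive_seed(config$seed, 2L))
  clin <- generate_clinical(sim$admixture, config$effects,
                            seed = derive_seed(config$seed, 3L))
  if (!identical(clin$case_id, sim$admixture$case_id)) {
    stop("case ids of clinical table and truth are inconsistent", call. = FALSE)
  }
  structure(list(config = config, signatures = sig,
                 expression = sim$expression, truth = sim$admixture,
                 clinical = clin),
            class = "luma_cohort")
}

#' Regenerate one case's synthetic slide
#'
#' Deterministic given the cohort: the slide seed is derived from the cohort
#' seed and the case index, and the slide's subtype territories follow that
#' case's true admixture.
#'
#' @param cohort A `luma_cohort`.
#' @param case Case id (character) or index (integer).
#' @return A `synthetic_slide`, see [generate_slide()].
#' @export
cohort_slide <- function(cohort, case) {
  idx <- if (is.character(case)) match(case, cohort$truth$case_id) else as.integer(case)
  if (is.na(idx) || idx < 1L || idx > nrow(cohort$truth)) {
    stop("unknown case: ", case, call. = FALSE)
  }
  cfg <- cohort$config
  generate_slide(cohort$truth[idx, ], height = cfg$slide_height,
                 width = cfg$slide_width, texture_params = cfg$textures,
                 seed = derive_seed(cfg$seed, 1000L + idx),
                 n_regions = cfg$n_regions, mpp = cfg$mpp)
}

#' @export
print.luma_cohort <- function(x, ...) {
  cat("Synthetic LumA heterogeneity cohort\n")
  cat(sprintf("  %d cases, %d genes, slides %d x %d px\n",
              x$config$n_cases, x$config$n_genes,
              x$config$slide_height, x$config$slide_width))
  cat("  assigned subtypes:\n")
  print(table(x$truth$assigned_subtype))
  invisible(x)
}

#' Write a cohort to the standard on-disk layout
#'
#' Expression (and metagenes) as genes x cases TSV with a header row of case
#' ids; truth, clinical and mutant-allele fractions as CSV; configuration as
#' YAML; optionally the first `slides` cases' slide rasters as PNG (image,
#' 0/255 annotation mask, label-coded subtype map).
#'
#' @param cohort A `luma_cohort`.
#' @param dir Output directory (created if needed).
#' @param slides Number of leading cases whose slides to render to PNG.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, slides = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_matrix_tsv(unclass(cohort$signatures), file.path(dir, "signatures.tsv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  clin <- cohort$clinical
  utils::write.csv(as.data.frame(unclass(clin)), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  vaf <- attr(clin, "vaf")
  vl <- data.frame(case_id = rep(names(vaf), lengths(vaf)),
                   vaf = unlist(vaf, use.names = FALSE))
  utils::write.csv(vl, file.path(dir, "vaf.csv"), row.names = FALSE)
  yaml::write_yaml(config_for_yaml(cohort$config), file.path(dir, "config.yaml"))
  for (i in seq_len(min(slides, cohort$config$n_cases))) {
    sl <- cohort_slide(cohort, i)
    id <- cohort$truth$case_id[i]
    png::writePNG(sl$image, file.path(dir, sprintf("%s_image.png", id)))
    png::writePNG(sl$annotation_mask + 0, file.path(dir, sprintf("%s_mask.png", id)))
    png::writePNG(sl$subtype_map / 255, file.path(dir, sprintf("%s_subtypes.png", id)))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `luma_cohort` (tables read back; slides regenerable via
#'   [cohort_slide()]).
#' @export
read_cohort <- function(dir) {
  cfg <- config_from_yaml(yaml::read_yaml(file.path(dir, "config.yaml")))
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  sig <- read_matrix_tsv(file.path(dir, "signatures.tsv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  class(truth) <- c("true_admixture", "data.frame")
  clin <- utils::read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  vl <- utils::read.csv(file.path(dir, "vaf.csv"), stringsAsFactors = FALSE)
  vaf <- split(vl$vaf, vl$case_id)[clin$case_id]
  attr(clin, "vaf") <- vaf
  class(clin) <- c("synthetic_clinical", "data.frame")
  structure(list(config = cfg,
                 signatures = structure(sig, class = c("signature_matrix", "matrix", "array")),
                 expression = expr, truth = truth, clinical = clin),
            class = "luma_cohort")
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# YAML cannot hold nested R structures like texture lists verbatim; flatten
# and rebuild the few nested pieces explicitly.
config_for_yaml <- function(cfg) {
  cfg$textures <- lapply(cfg$textures, function(t) lapply(t, as.numeric))
  cfg$effects$binary <- lapply(cfg$effects$binary, as.list)
  cfg
}

config_from_yaml <- function(y) {
  cfg <- cohort_config()
  y$alpha <- as.numeric(y$alpha)
  y$effects$binary <- lapply(y$effects$binary, function(b) {
    c(base = as.numeric(b$base), slope = as.numeric(b$slope))
  })
  utils::modifyList(cfg, y)
}
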