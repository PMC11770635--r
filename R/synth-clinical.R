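#' Default planted clinicomolecular effect configuration
#'
#' Baselines are the prevalences/means for a perfectly pure LumA case
#' (`pLumA = 1`); slopes act on `1 - pLumA`, so admixed cases drift towards
#' the non-LumA phenotype: more HER2 positivity, larger/higher-grade/higher-
#' stage tumors, slightly lower PR positivity, older age. Survival follows an
#' exponential model whose hazard is multiplied by `hazard_ratio` for cases
#' whose LumA proportion falls below `purity_cutoff`, with administrative
#' censoring at `horizon_months`.
#'
#' @return Named list of effect parameters.
#' @export
default_effects <- function() {
  list(
    hazard_ratio = 2,
    purity_cutoff = 0.5,
    base_hazard = 0.0025,     # events per month for pure cases
    horizon_months = 120,     # 10-year administrative censoring
    age_mean = 54.5, age_slope = 5, age_sd = 11,
    binary = list(             # baseline prevalence at pLumA = 1, slope on (1 - pLumA)
      er_pos    = c(base = 0.93, slope =  0.09),
      pr_pos    = c(base = 0.95, slope = -0.17),
      her2_pos  = c(base = 0.13, slope =  0.30),
      node_pos  = c(base = 0.50, slope =  0.06),
      size_gt20 = c(base = 0.38, slope =  0.25),
      stage_gt1 = c(base = 0.60, slope =  0.23),
      grade3    = c(base = 0.07, slope =  0.33)
    ),
    n_mutations = 15,
    # Beta(2.5, 5) allele fractions put the cohort mean MATH score near the
    # 0.35 ratio scale reported for LumA tumors
    vaf_shape1 = 2.5, vaf_shape2 = 5
  )
}

#' Simulate clinical, molecular and survival records with planted effects
#'
#' For each case, binary feature prevalences are monotone (linear, clamped)
#' functions of the true LumA proportion; age shifts linearly with admixture;
#' mutant-allele fractions are Beta draws feeding the MATH score; and
#' survival time is exponential with the hazard multiplied by the configured
#' ratio for cases below the purity cutoff, censored administratively at the
#' horizon.
#'
#' @param admixtures A `true_admixture` data.frame from
#'   [generate_expression()].
#' @param effect_config Effect sizes, see [default_effects()].
#' @param seed Integer seed.
#' @return data.frame of class `synthetic_clinical` with one row per case:
#'   `case_id`, `age`, binary flags, `mutational_load`, `survival_time`
#'   (months), `event`, and attribute `vaf` (named list of per-case
#'   mutant-allele fraction vectors).
#' @export
generate_clinical <- function(admixtures, effect_config = default_effects(),
                              seed = 1) {
  cfg <- utils::modifyList(default_effects(), effect_config)
  if (cfg$hazard_ratio <= 0) stop("hazard ratio must be positive", call. = FALSE)
  if (cfg$horizon_months <= 0) stop("censoring horizon must be positive", call. = FALSE)
  p <- admixtures$pLumA
  n <- length(p)
  with_seed(seed, {
    admix <- 1 - p
    out <- data.frame(case_id = admixtures$case_id,
                      age = rnorm(n, cfg$age_mean + cfg$age_slope * admix,
                                  cfg$age_sd),
                      stringsAsFactors = FALSE)
    for (nm in names(cfg$binary)) {
      pr <- pmin(1, pmax(0, cfg$binary[[nm]]["base"] +
                              cfg$binary[[nm]]["slope"] * admix))
      out[[nm]] <- rbinom(n, 1L, pr)
    }
    m <- cfg$n_mutations
    vaf <- lapply(seq_len(n), function(i) {
      # slight upward shift of the allele-fraction spread with purity
      rbeta(m, cfg$vaf_shape1 + 0.5 * p[i], cfg$vaf_shape2)
    })
    names(vaf) <- out$case_id
    out$mutational_load <- rpois(n, 22)
    hazard <- cfg$base_hazard * ifelse(p < cfg$purity_cutoff,
                                       cfg$hazard_ratio, 1)
    t_raw <- rexp(n, rate = hazard)
    out$event <- as.integer(t_raw <= cfg$horizon_months)
    out$survival_time <- pmin(t_raw, cfg$horizon_months)
    attr(out, "vaf") <- vaf
    class(out) <- c("synthetic_clinical", "data.frame")
    out
  })
}
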