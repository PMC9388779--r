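# Group-wise clinical covariate distributions (mean, SD, truncation range)
# used by the cohort generator. Sex is Bernoulli with the group-specific
# male probability. Values follow the published demographic summaries of a
# 17 responder / 17 non-responder tDCS cohort.
.clinical_params <- list(
  responder = list(
    age = c(30.06, 7.89, 18, 48),
    education_years = c(14.11, 1.71, 5, 24),
    duration_untreated_months = c(12.88, 23.86, 0, 360),
    duration_illness_months = c(105.88, 88.39, 1, 480),
    olanzapine_eq = c(15.68, 8.98, 0, 80),
    pre_saps = c(44.47, 19.66, 0, 170),
    pre_sans = c(38.35, 20.89, 0, 125),
    pre_madrs = c(13.47, 7.01, 0, 60),
    pre_psyrats = c(31.0, 4.74, 7, 44),
    percent_improvement = c(47.7, 17.0, 25, 100),
    p_male = 7 / 17
  ),
  nonresponder = list(
    age = c(32.23, 7.47, 18, 48),
    education_years = c(13.70, 1.67, 5, 24),
    duration_untreated_months = c(9.35, 15.14, 0, 360),
    duration_illness_months = c(106.23, 71.16, 1, 480),
    olanzapine_eq = c(22.70, 16.67, 0, 80),
    pre_saps = c(31.06, 12.36, 0, 170),
    pre_sans = c(16.94, 12.58, 0, 125),
    pre_madrs = c(10.25, 5.67, 0, 60),
    pre_psyrats = c(29.82, 5.84, 7, 44),
    percent_improvement = c(10.4, 8.0, -60, 24.999),
    p_male = 12 / 17
  )
)

# truncated-normal draw by rejection (ranges are wide, acceptance is high)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a clinical table for a synthetic tDCS cohort
#'
#' Covariates are drawn independently from truncated normal distributions
#' with the group means/SDs of the reference cohort; sex is Bernoulli with
#' the group male:female ratio. The post-treatment hallucination score is
#' derived from a drawn percent improvement (responders >= 25, otherwise
#' < 25), so the responder rule applied to the generated pre/post scores
#' recovers the intended label for every subject.
#'
#' @param n_responders,n_nonresponders Subject counts per group (>= 0).
#' @param seed RNG seed.
#' @return A data.frame with one row per subject; columns include
#'   `subject_id`, `responder`, `sex` (1 = male), the baseline covariates,
#'   `pre_psyrats`, `post_psyrats` and `percent_improvement`.
#' @export
make_clinical_table <- function(n_responders, n_nonresponders, seed = 1L) {
  if (n_responders < 0 || n_nonresponders < 0) stopf("counts must be >= 0")
  draw_group <- function(n, pars, responder) {
    if (n == 0) return(NULL)
    cols <- lapply(pars[setdiff(names(pars), "p_male")], function(p)
      rtruncnorm(n, p[1], p[2], p[3], p[4]))
    df <- as.data.frame(cols)
    df$sex <- stats::rbinom(n, 1, pars$p_male)
    df$responder <- responder
    df
  }
  with_seed(seed, {
    df <- rbind(draw_group(n_responders, .clinical_params$responder, TRUE),
                draw_group(n_nonresponders, .clinical_params$nonresponder, FALSE))
    df$post_psyrats <- df$pre_psyrats * (1 - df$percent_improvement / 100)
    df$subject_id <- sprintf("sub-%03d", seq_len(nrow(df)))
    df[, c("subject_id", "responder", "age", "sex", "education_years",
           "duration_untreated_months", "duration_illness_months",
           "olanzapine_eq", "pre_saps", "pre_sans", "pre_madrs",
           "pre_psyrats", "post_psyrats", "percent_improvement")]
  })
}

#' Generate a full synthetic cohort (clinical table + BOLD series)
#'
#' @param n_responders,n_nonresponders Subject counts (>= 1).
#' @param config A [sim_config()].
#' @param atlas Optional pre-built atlas (rebuilt from `config` otherwise).
#' @return A list with `clinical` (data.frame), `bolds` (list of
#'   [bold_series()] in table order) and `atlas`.
#' @export
make_cohort <- function(n_responders, n_nonresponders, config = sim_config(),
                        atlas = NULL) {
  if (n_responders < 1 || n_nonresponders < 1) stopf("counts must be >= 1")
  if (is.null(atlas)) atlas <- make_atlas(config)
  clinical <- make_clinical_table(n_responders, n_nonresponders,
                                  seed = config$seed)
  bolds <- lapply(seq_len(nrow(clinical)), function(i)
    make_subject_bold(atlas, clinical$responder[i], config,
                      subject_seed = derive_seed(config$seed, i)))
  names(bolds) <- clinical$subject_id
  list(clinical = clinical, bolds = bolds, atlas = atlas)
}

#' Pre-training cohort specification
#'
#' Sub-cohort sizes and CGI sampling rules for the disjoint pre-training
#' dataset: healthy controls (HC) and unaffected first-degree relatives
#' (FDR-SZ) always carry CGI 0; schizophrenia (SZ) and obsessive-compulsive
#' disorder (OCD) patients are at least moderately ill, CGI drawn from
#' {4, 5, 6}.
#'
#' @param n_hc,n_fdr,n_sz,n_ocd Sub-cohort sizes (>= 0).
#' @return An object of class `pretrain_cohort_spec`.
#' @export
pretrain_cohort_spec <- function(n_hc = 186L, n_fdr = 62L, n_sz = 44L,
                                 n_ocd = 149L) {
  counts <- c(n_hc = n_hc, n_fdr = n_fdr, n_sz = n_sz, n_ocd = n_ocd)
  if (any(counts < 0)) stopf("all sub-cohort counts must be >= 0")
  structure(as.list(counts), class = "pretrain_cohort_spec")
}

#' Generate the disjoint pre-training cohort
#'
#' Each record carries group, CGI, sex, age and a seed-FC volume derived
#' from a short BOLD series simulated on a reduced grid, with seed-to-region
#' coupling increasing with illness severity (CGI). Labels are *not*
#' assigned here; see [assign_cgi_labels()].
#'
#' @param spec A [pretrain_cohort_spec()].
#' @param config Reduced-grid [sim_config()] for the per-record volumes.
#' @param seed RNG seed.
#' @param with_volumes If `FALSE`, skip volume generation (records only).
#' @return A list with `records` (data.frame: record_id, group, cgi, sex,
#'   age) and `fc_maps` (list of 3D Fisher-Z arrays, or `NULL`).
#' @export
make_pretrain_cohort <- function(spec = pretrain_cohort_spec(),
                                 config = sim_config(grid_dims = c(10, 12, 10),
                                                     voxel_size_mm = 8,
                                                     n_volumes = 40),
                                 seed = 1L, with_volumes = TRUE) {
  stopifnot(inherits(spec, "pretrain_cohort_spec"))
  groups <- rep(c("HC", "FDR_SZ", "SZ", "OCD"),
                times = c(spec$n_hc, spec$n_fdr, spec$n_sz, spec$n_ocd))
  n <- length(groups)
  records <- with_seed(seed, {
    cgi <- ifelse(groups %in% c("HC", "FDR_SZ"), 0L,
                  sample(4:6, n, replace = TRUE))
    data.frame(record_id = sprintf("pre-%03d", seq_len(n)),
               group = groups, cgi = as.integer(cgi),
               sex = stats::rbinom(n, 1, 0.5),
               age = round(rtruncnorm(n, 31, 8, 18, 60), 1),
               stringsAsFactors = FALSE)
  })
  fc_maps <- NULL
  if (with_volumes && n > 0) {
    atlas <- make_atlas(config)
    sphere <- make_sphere_mask(seed_spec(), config$grid_dims,
                               sim_affine(config))
    fc_maps <- lapply(seq_len(n), function(i) {
      rho <- min(0.1 + 0.08 * records$cgi[i], 0.9)
      b <- make_subject_bold(atlas, FALSE, config,
                             subject_seed = derive_seed(seed, i), rho = rho)
      seed_fc_map(b, sphere)$z_values
    })
    names(fc_maps) <- records$record_id
  }
  list(records = records, fc_maps = fc_maps, config = config)
}

#' QC fixture: a 39-subject cohort with planted failures
#'
#' Emulates the quality-control attrition of a 39-subject study: exactly 2
#' subjects are flagged with irrecoverable boundary-registration failure and
#' exactly 3 are generated with motion artifacts dense enough that at least
#' 30\% of their volumes exceed the outlier thresholds; the remaining 34
#' pass both checks by construction (quiet motion, no spikes).
#'
#' @param seed RNG seed.
#' @param config Reduced-grid [sim_config()] used for every subject.
#' @return A list with `clinical`, `bolds`, `registration_ok` (logical
#'   39-vector), `atlas` and `config`.
#' @export
make_qc_fixture_cohort39 <- function(seed = 1L,
                                     config = sim_config(
                                       grid_dims = c(12, 14, 12),
                                       voxel_size_mm = 8,
                                       n_volumes = 100,
                                       seed = seed)) {
  atlas <- make_atlas(config)
  clinical <- make_clinical_table(20, 19, seed = seed)
  n <- nrow(clinical)
  picks <- with_seed(seed, sample(n, 5))
  reg_bad <- picks[1:2]
  censor_bad <- picks[3:5]
  bolds <- lapply(seq_len(n), function(i) {
    b <- make_subject_bold(atlas, clinical$responder[i], config,
                           subject_seed = derive_seed(seed, i))
    if (i %in% censor_bad) {
      # isolated 3 mm x-translation excursions: each censors its own volume
      # and the return volume, pushing the censored fraction past 30%
      planted <- seq(5, config$n_volumes - 5, by = 6)[1:16]
      b$motion[planted, 1] <- b$motion[planted, 1] + 3
    }
    b
  })
  names(bolds) <- clinical$subject_id
  registration_ok <- !(seq_len(n) %in% reg_bad)
  list(clinical = clinical, bolds = bolds,
       registration_ok = registration_ok, atlas = atlas, config = config)
}
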