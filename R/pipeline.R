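#' Per-subject profile table of a cohort
#'
#' @param cohort a \code{\link{generate_cohort}} result (or any list of
#'   subjects with \code{profile} fields).
#' @return data.frame, one row per subject.
#' @export
cohort_profiles <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    p <- s$profile
    data.frame(subject_id = p$subject_id, phenotype = p$phenotype,
               effect_hr = p$stress_effect$hr,
               effect_scr_rate = p$stress_effect$scr_rate,
               effect_st = p$stress_effect$st,
               pss = p$pss, dass_depression = p$dass_depression,
               dass_anxiety = p$dass_anxiety, dass_stress = p$dass_stress,
               psqi = p$psqi, age = p$age, gender = p$gender,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full stress-phenotyping pipeline on a simulated cohort
#'
#' Generates the cohort subject by subject (recordings are discarded after
#' feature extraction to bound memory), assembles the labeled dataset,
#' runs the leave-one-subject-out classification, assigns F1 performance
#' groups, computes dynamic ranges, group comparisons and the state-wise
#' median-difference matrix.
#'
#' @param n_subjects,responsive_fraction,days,seed,config cohort settings,
#'   see \code{\link{generate_cohort}}.
#' @param spec a \code{\link{window_spec}}.
#' @param verbose print progress.
#' @return list of class \code{"phenotype_report"}: \code{profiles},
#'   \code{dataset}, \code{loso}, \code{groups}, \code{dynamic_range},
#'   \code{comparisons}, \code{state_matrix}, \code{population_summary}.
#' @export
run_stress_pipeline <- function(n_subjects = 30, responsive_fraction = 0.5,
                                days = 2, seed = 1L, config = sim_config(),
                                spec = window_spec(), verbose = FALSE) {
  if (n_subjects < 2) stop("n_subjects must be >= 2 (LOSO undefined)")
  if (responsive_fraction < 0 || responsive_fraction > 1)
    stop("responsive_fraction must be in [0, 1]")
  n_resp <- round(responsive_fraction * n_subjects)
  feats <- vector("list", n_subjects)
  ema_list <- list()
  profiles <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    phen <- if (i <= n_resp) "responsive" else "blunted"
    prof <- subject_profile(sprintf("S%03d", i), phen,
                            seed = .derive_seed(seed, i, 1L), config = config)
    subj <- simulate_subject(prof, days = days,
                             seed = .derive_seed(seed, i, 2L), config = config)
    feats[[i]] <- extract_features(subj, spec = spec)
    ema_list[[prof$subject_id]] <- subj$ema
    profiles[[i]] <- subj$profile
    if (verbose) message("subject ", prof$subject_id, ": ",
                         nrow(feats[[i]]), " windows")
    rm(subj)
  }
  features <- do.call(rbind, feats)
  prof_df <- cohort_profiles(lapply(profiles, function(p) list(profile = p)))

  dataset <- assemble_dataset(features, ema_list)
  loso <- loso_train_eval(dataset, seed = seed)
  groups <- data.frame(subject_id = loso$per_subject$subject_id,
                       group = assign_groups(loso$per_subject$f1),
                       stringsAsFactors = FALSE)
  dr <- dynamic_range(dataset$rows, groups, dataset$features)
  comparisons <- compare_groups(groups, prof_df, dataset$rows)
  sm <- state_median_matrix(dataset$rows, dataset$features)
  ps <- population_summary(dataset$rows, dataset$features)
  structure(list(profiles = prof_df, dataset = dataset, loso = loso,
                 groups = groups, dynamic_range = dr,
                 comparisons = comparisons, state_matrix = sm,
                 population_summary = ps, seed = seed),
            class = "phenotype_report")
}
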