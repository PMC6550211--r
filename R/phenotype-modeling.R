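#' Multi-class F1 score
#'
#' Per-class F1 = 2PR/(P+R) (0 when P+R = 0), averaged over the classes
#' present in \code{y_true}: unweighted (macro, the default) or weighted by
#' class support.
#'
#' @param y_true,y_pred character/factor label vectors of equal length.
#' @param average \code{"macro"} or \code{"weighted"}.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(y_true, y_pred, average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!length(y_true)) stop("empty label vectors")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  f1 <- vapply(classes, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  if (average == "macro") mean(f1)
  else sum(f1 * table(factor(y_true, classes))) / length(y_true)
}

#' Majority-class baseline F1
#'
#' F1 obtained by predicting one fixed class (the training-set majority, by
#' default the majority of \code{y_true}) for every sample.
#'
#' @param y_true true labels.
#' @param majority class to predict; defaults to the mode of \code{y_true}.
#' @param average passed to \code{\link{f1_score}}.
#' @return F1 in [0, 1].
#' @export
majority_baseline_f1 <- function(y_true, majority = NULL,
                                 average = c("macro", "weighted")) {
  if (is.null(majority)) {
    tab <- table(as.character(y_true))
    majority <- names(tab)[which.max(tab)]
  }
  f1_score(y_true, rep(majority, length(y_true)), average = match.arg(average))
}

## one-way ANOVA F p-value per feature (closed form, complete obs)
.anova_p <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  tab <- table(g)
  k <- sum(tab > 0)
  n <- length(x)
  if (k < 2 || n <= k) return(NA_real_)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ssb <- sum(tab[tab > 0] * (means[names(tab[tab > 0])] - gm)^2)
  ssw <- sum((x - means[as.character(g)])^2)
  if (ssw <= 0) return(if (ssb > 0) 0 else NA_real_)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' FDR-supervised feature selection
#'
#' Univariate one-way ANOVA F-test of each feature against the class label,
#' followed by Benjamini-Hochberg selection at \code{alpha}: the features in
#' the BH rejection set survive. Applied per training fold only, so no test
#' information leaks into selection. If nothing survives (or every p-value
#' is undefined), all features are returned as a fallback.
#'
#' @param rows training rows.
#' @param features candidate feature names.
#' @param y class labels of the training rows.
#' @param alpha FDR level.
#' @return character vector of selected feature names.
#' @export
fdr_select_features <- function(rows, features, y, alpha = 0.05) {
  p <- vapply(features, function(f) .anova_p(rows[[f]], y), numeric(1))
  ok <- !is.na(p)
  if (!any(ok)) return(features)
  rej <- bh_adjust(p[ok], q = alpha)$reject
  sel <- features[ok][rej]
  if (!length(sel)) features else sel
}

## per-fold median imputation: train rows by their subject's median (global
## fallback), test rows by the train global median
.impute_fold <- function(train, test, features) {
  for (f in features) {
    gmed <- median(train[[f]], na.rm = TRUE)
    if (is.na(gmed)) gmed <- 0
    med <- tapply(train[[f]], train$subject_id, median, na.rm = TRUE)
    na_tr <- is.na(train[[f]])
    if (any(na_tr)) {
      fill <- med[train$subject_id[na_tr]]
      fill[is.na(fill)] <- gmed
      train[[f]][na_tr] <- fill
    }
    test[[f]][is.na(test[[f]])] <- gmed
  }
  list(train = train, test = test)
}

#' Leave-one-subject-out stress classification
#'
#' For each subject, a random forest (100 trees by default, sqrt(p)
#' variables per split, no depth cap) is trained on all other subjects'
#' daytime rows after per-fold
#' FDR-supervised feature selection, and evaluated on the held-out subject.
#' Every subject is tested exactly once; the run is deterministic given
#' \code{seed}. The majority-class baseline predicts the training-set
#' majority state for every test sample.
#'
#' @param dataset a \code{\link{assemble_dataset}} result (or a list with
#'   \code{rows} and \code{features}).
#' @param seed integer RNG seed.
#' @param num_trees number of trees per forest.
#' @param alpha FDR level for per-fold feature selection.
#' @param average F1 averaging, see \code{\link{f1_score}}.
#' @return list of class \code{"loso_result"}: \code{per_subject}
#'   (data.frame \code{subject_id}, \code{f1}, \code{baseline_f1},
#'   \code{n_rows}), \code{confusion} (summed 3x3 matrix), \code{selected}
#'   (per-fold selected features), \code{importance} (mean impurity
#'   importance per feature).
#' @export
loso_train_eval <- function(dataset, seed = 1L, num_trees = 100,
                            alpha = 0.05, average = "macro") {
  rows <- dataset$rows[dataset$rows$state %in% c("S1", "S2", "S3"), ,
                       drop = FALSE]
  features <- dataset$features
  subjects <- unique(rows$subject_id)
  if (length(subjects) < 2) stop("LOSO requires at least two subjects")
  states <- c("S1", "S2", "S3")
  confusion <- matrix(0, 3, 3, dimnames = list(true = states, pred = states))
  selected <- list()
  imp_acc <- setNames(numeric(length(features)), features)
  imp_n <- 0
  res <- data.frame(subject_id = subjects, f1 = NA_real_,
                    baseline_f1 = NA_real_, n_rows = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    train <- rows[rows$subject_id != sid, , drop = FALSE]
    test <- rows[rows$subject_id == sid, , drop = FALSE]
    sel <- fdr_select_features(train, features, train$state, alpha)
    selected[[sid]] <- sel
    imp <- .impute_fold(train, test, sel)
    fold_seed <- .derive_seed(seed, i, 3L)
    fit <- ranger::ranger(
      x = imp$train[, sel, drop = FALSE],
      y = factor(imp$train$state, levels = states),
      num.trees = num_trees,
      mtry = max(1L, floor(sqrt(length(sel)))),
      importance = "impurity",
      seed = fold_seed, num.threads = 1
    )
    pred <- as.character(predict(fit, data = imp$test[, sel, drop = FALSE],
                                 seed = fold_seed,
                                 num.threads = 1)$predictions)
    res$f1[i] <- f1_score(test$state, pred, average = average)
    maj <- names(which.max(table(train$state)))
    res$baseline_f1[i] <- f1_score(test$state, rep(maj, nrow(test)),
                                   average = average)
    res$n_rows[i] <- nrow(test)
    confusion <- confusion + table(factor(test$state, states),
                                   factor(pred, states))
    imp_acc[sel] <- imp_acc[sel] + fit$variable.importance[sel]
    imp_n <- imp_n + 1
  }
  structure(list(per_subject = res, confusion = confusion,
                 selected = selected, importance = imp_acc / imp_n),
            class = "loso_result")
}

#' Assign F1-based performance groups
#'
#' Subjects with F1 below 0.33 (chance level for a balanced 3-class task)
#' form the low-performance group, above 0.66 the high-performance group,
#' and everything in between (boundaries included) the medium group.
#'
#' @param f1 numeric vector of per-subject F1 scores in [0, 1].
#' @return character vector \code{"low"}/\code{"medium"}/\code{"high"}.
#' @export
assign_groups <- function(f1) {
  stopifnot(all(f1 >= 0 & f1 <= 1, na.rm = TRUE))
  ifelse(f1 < 0.33, "low", ifelse(f1 > 0.66, "high", "medium"))
}

#' Per-group physiological dynamic range
#'
#' For each subject and feature, the dynamic range is the mean feature value
#' under high stress (S3) minus under no stress (S1); the group value is the
#' mean over the group's subjects. Subjects lacking S1 or S3 rows for a
#' feature are excluded from that feature's group mean.
#'
#' @param rows labeled (normalized) rows with \code{subject_id} and
#'   \code{state}.
#' @param groups data.frame \code{subject_id}, \code{group}.
#' @param features feature names.
#' @return list with \code{per_subject} (subjects x features matrix) and
#'   \code{per_group} (groups x features matrix).
#' @export
dynamic_range <- function(rows, groups, features = feature_names()) {
  subjects <- groups$subject_id
  per_subject <- matrix(NA_real_, length(subjects), length(features),
                        dimnames = list(subjects, features))
  for (i in seq_along(subjects)) {
    s3 <- rows[rows$subject_id == subjects[i] & rows$state == "S3", ,
               drop = FALSE]
    s1 <- rows[rows$subject_id == subjects[i] & rows$state == "S1", ,
               drop = FALSE]
    if (nrow(s3) == 0 || nrow(s1) == 0) next
    for (f in features)
      per_subject[i, f] <- mean(s3[[f]], na.rm = TRUE) -
        mean(s1[[f]], na.rm = TRUE)
  }
  glev <- unique(groups$group)
  per_group <- matrix(NA_real_, length(glev), length(features),
                      dimnames = list(glev, features))
  for (g in glev) {
    sel <- groups$group == g
    per_group[g, ] <- colMeans(per_subject[sel, , drop = FALSE], na.rm = TRUE)
  }
  list(per_subject = per_subject, per_group = per_group)
}

#' Compare phenotype groups on background characteristics
#'
#' Per questionnaire score: Kruskal-Wallis across all groups plus a Wilcoxon
#' rank-sum test low vs high performance, BH-corrected across the score
#' battery. Gender is compared with a chi-square test; the per-group
#' S1/S2/S3 label shares summarize label imbalance.
#'
#' @param groups data.frame \code{subject_id}, \code{group}.
#' @param profiles data.frame of per-subject background scores
#'   (\code{subject_id}, \code{pss}, \code{dass_depression},
#'   \code{dass_anxiety}, \code{dass_stress}, \code{psqi}, \code{age},
#'   \code{gender}).
#' @param rows labeled rows (for the label-share summary); optional.
#' @param scores score columns to test.
#' @return list with \code{tests} (data.frame per score), \code{gender_p},
#'   \code{label_shares} (group x state proportions or NULL).
#' @export
compare_groups <- function(groups, profiles, rows = NULL,
                           scores = c("pss", "dass_depression",
                                      "dass_anxiety", "dass_stress",
                                      "psqi", "age")) {
  df <- merge(groups, profiles, by = "subject_id")
  present <- unique(df$group)
  if (length(present) < 2) {
    warning("fewer than two nonempty groups; comparisons skipped")
    return(list(tests = NULL, gender_p = NA_real_, label_shares = NULL))
  }
  lh <- df[df$group %in% c("low", "high"), , drop = FALSE]
  tests <- do.call(rbind, lapply(scores, function(sc) {
    kw <- if (length(present) >= 2)
      suppressWarnings(kruskal.test(df[[sc]], factor(df$group))$p.value)
      else NA_real_
    wx <- if (all(c("low", "high") %in% lh$group))
      suppressWarnings(wilcox.test(lh[[sc]][lh$group == "low"],
                                   lh[[sc]][lh$group == "high"])$p.value)
      else NA_real_
    data.frame(score = sc, kruskal_p = kw, wilcox_p = wx,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(tests$wilcox_p)
  tests$wilcox_p_adj <- NA_real_
  if (any(ok)) tests$wilcox_p_adj[ok] <- bh_adjust(tests$wilcox_p[ok])$adjusted
  gender_p <- tryCatch(
    suppressWarnings(chisq.test(table(df$gender, df$group))$p.value),
    error = function(e) NA_real_)
  label_shares <- NULL
  if (!is.null(rows)) {
    day <- rows[rows$state %in% c("S1", "S2", "S3"), , drop = FALSE]
    day <- merge(day[, c("subject_id", "state")], groups, by = "subject_id")
    if (nrow(day))
      label_shares <- prop.table(table(day$group, day$state), margin = 1)
  }
  list(tests = tests, gender_p = gender_p, label_shares = label_shares)
}
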