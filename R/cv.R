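#' Subject-wise k-fold cross-validation plan
#'
#' Subjects are partitioned into `k` folds, balancing per-fold image counts
#' greedily (largest subject first into the lightest fold, ties broken by a
#' seeded shuffle). Every sample of a subject stays in that subject's fold;
#' over the `k` repetitions each fold serves as the test fold exactly once,
#' with the next fold (cyclically) as validation and the rest as training.
#'
#' @param info data.frame with a `subjectId` column (one row per image), or
#'   a [SpectrogramSet-class].
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return a [CVPlan-class].
#' @export
makeCVPlan <- function(info, k = 10, seed = 1L) {
  if (is(info, "SpectrogramSet")) info <- imageInfo(info)
  counts <- table(info$subjectId)
  subjects <- names(counts)
  if (length(subjects) < k)
    stop("fewer subjects (", length(subjects), ") than folds (", k, ")")
  set.seed(seed)
  ord <- sample(seq_along(subjects))
  counts <- counts[ord]
  subjects <- subjects[ord]
  # stratify by class when labels are available, so folds mix classes
  classOf <- if ("classLabel" %in% names(info)) {
    vapply(subjects, function(s)
      info$classLabel[match(s, info$subjectId)], character(1))
  } else rep("all", length(subjects))
  folds <- integer(length(subjects))
  names(folds) <- subjects
  load <- numeric(k)
  for (cl in unique(classOf)) {
    members <- which(classOf == cl)
    members <- members[order(-as.integer(counts[members]))]
    for (i in members) {
      f <- which.min(load)
      folds[i] <- f
      load[f] <- load[f] + counts[i]
    }
  }
  new("CVPlan", folds = folds, k = as.integer(k), seed = as.integer(seed))
}

#' Validate a fold assignment against the subject-wise constraint
#'
#' @param folds named integer vector (fold per subject entry); a subject
#'   appearing under more than one fold raises an error.
#' @param k fold count.
#' @return `TRUE` invisibly if valid.
#' @export
validateFoldAssignment <- function(folds, k) {
  dup <- names(folds)[duplicated(names(folds))]
  bad <- unique(names(folds)[names(folds) %in% dup &
                             ave(folds, names(folds),
                                 FUN = function(v) length(unique(v))) > 1])
  if (length(bad) > 0)
    stop("subject-wise constraint violated: subject(s) ",
         paste(bad, collapse = ", "), " assigned to multiple folds")
  if (!all(folds %in% seq_len(k))) stop("fold indices outside 1..k")
  invisible(TRUE)
}

#' Check a training set for subject leakage
#'
#' @param trainInfo image info data.frame of the assembled training set.
#' @param testSubjects subject ids present in the current test fold.
#' @return `TRUE` invisibly; raises an error when any training image
#'   (including augmented provenance) belongs to a test-fold subject.
#' @export
checkLeakage <- function(trainInfo, testSubjects) {
  leaked <- intersect(na.omit(unique(trainInfo$subjectId)), testSubjects)
  if (length(leaked) > 0)
    stop("subject leakage into training: ", paste(leaked, collapse = ", "))
  invisible(TRUE)
}

#' Subject-wise cross-validation of the classifier
#'
#' For each of the `k` repetitions, fold `r` is the test set, fold
#' `r %% k + 1` the validation set and the rest training. Images in
#' `extraTrain` join the training set only: subject-tagged augmented images
#' follow their source subject (and are dropped when that subject is in the
#' test or validation fold); generator images without a source subject
#' always train. Leakage is checked structurally before every repetition.
#'
#' @param real a [SpectrogramSet-class] of real images.
#' @param extraTrain optional [SpectrogramSet-class] of augmented/generated
#'   images.
#' @param cfg a [cnnConfig()].
#' @param plan a [CVPlan-class] covering the real images' subjects.
#' @param trainer,predictor optional overrides for the model: `trainer(train,
#'   val, cfg)` returning an object, `predictor(fit, images)` returning
#'   labels; defaults train the package CNN.
#' @return list with `perFold` (data.frame of per-repetition metrics) and
#'   `summary` (mean and sd of each metric).
#' @export
runCrossValidation <- function(real, extraTrain = NULL, cfg = cnnConfig(),
                               plan, trainer = NULL, predictor = NULL) {
  info <- imageInfo(real)
  subjects <- unique(info$subjectId)
  missing <- setdiff(subjects, names(plan@folds))
  if (length(missing) > 0)
    stop("plan lacks fold assignments for: ",
         paste(missing, collapse = ", "))
  validateFoldAssignment(plan@folds, plan@k)
  if (plan@k < 3)
    stop("need k >= 3 folds (one test, one validation, >= 1 training)")
  if (is.null(trainer))
    trainer <- function(train, val, cfg) trainCNN(train, val, cfg)$model
  if (is.null(predictor))
    predictor <- function(fit, images) predictCNN(fit, images)$labels

  k <- plan@k
  rows <- list()
  for (r in seq_len(k)) {
    testFold <- r
    valFold <- r %% k + 1L
    foldOf <- plan@folds[info$subjectId]
    testIdx <- which(foldOf == testFold)
    valIdx <- which(foldOf == valFold)
    trainIdx <- which(!foldOf %in% c(testFold, valFold))
    testSubjects <- names(plan@folds)[plan@folds == testFold]
    valSubjects <- names(plan@folds)[plan@folds == valFold]

    trainSet <- subsetImages(real, trainIdx)
    if (!is.null(extraTrain) && nImages(extraTrain) > 0) {
      xi <- imageInfo(extraTrain)
      keep <- is.na(xi$subjectId) |
        !(xi$subjectId %in% c(testSubjects, valSubjects))
      if (any(keep))
        trainSet <- bindSpectrogramSets(trainSet,
                                        subsetImages(extraTrain, keep))
    }
    checkLeakage(imageInfo(trainSet), testSubjects)
    valSet <- subsetImages(real, valIdx)
    testSet <- subsetImages(real, testIdx)
    fit <- trainer(trainSet, valSet, cfg)
    predicted <- predictor(fit, testSet)
    truth <- imageInfo(testSet)$classLabel
    cc <- .countsFromLabels(predicted, truth)
    acc <- (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn)
    # a test fold may contain a single class; its Se or Sp is then a
    # property of the fold, not the classifier -> NA, not an error
    se <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
    sp <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
    rows[[r]] <- data.frame(fold = r, accuracy = acc, sensitivity = se,
                            specificity = sp)
  }
  perFold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity"),
    mean = c(mean(perFold$accuracy),
             mean(perFold$sensitivity, na.rm = TRUE),
             mean(perFold$specificity, na.rm = TRUE)),
    sd = c(sd(perFold$accuracy),
           sd(perFold$sensitivity, na.rm = TRUE),
           sd(perFold$specificity, na.rm = TRUE)))
  list(perFold = perFold, summary = summ)
}
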