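#' Construct decoder settings
#'
#' @param cParam Soft-margin penalty of the linear C-SVM (default 1).
#' @param labelLag Volumes by which training labels lag the cue
#'   (default 2, about 3.24 s of haemodynamic delay).
#' @param labelMode `"all"` (label every localizer volume) or
#'   `"late3"` (keep only the last 3 volumes of each trial).
#' @return An [SvmConfig-class].
#' @export
svmConfig <- function(cParam = 1, labelLag = 2L, labelMode = c("all", "late3")) {
  new("SvmConfig", cParam = cParam, labelLag = as.integer(labelLag),
      labelMode = match.arg(labelMode))
}

#' Label localizer feature vectors for training
#'
#' Volume t is labeled with the trial direction that was cued
#' `labelLag` volumes earlier; volumes whose lagged time falls before
#' the first trial are dropped. With `labelMode = "late3"` only volumes
#' whose lagged position is in the last 3 volumes of its trial are
#' kept.
#'
#' @param schedule A [CueSchedule-class].
#' @param features T x V matrix of per-volume feature vectors covering
#'   the localizer phase.
#' @param config An [SvmConfig-class].
#' @return List with `x` (examples x V matrix), `y` (factor of class
#'   labels), `volumes` (the volume index of each example).
#' @export
buildTrainingSet <- function(schedule, features, config = svmConfig()) {
  stopifnot(is(schedule, "CueSchedule"))
  features <- as.matrix(features)
  states <- scheduleStates(schedule)
  nT <- min(length(states), nrow(features))
  lag <- config@labelLag
  vols <- (lag + 1L):nT
  labels <- states[vols - lag]
  if (config@labelMode == "late3") {
    tr <- schedule@trials
    posInTrial <- integer(length(states))
    for (r in seq_len(nrow(tr))) {
      sel <- tr$start[r]:(tr$start[r] + tr$length[r] - 1L)
      posInTrial[sel] <- seq_along(sel)
    }
    trialLen <- tr$length[1]
    keep <- posInTrial[vols - lag] > trialLen - 3L
    vols <- vols[keep]
    labels <- labels[keep]
  }
  if (!length(vols)) stop("no labeled training volumes", call. = FALSE)
  list(x = features[vols, , drop = FALSE],
       y = factor(labels, levels = DIRECTIONS),
       volumes = vols)
}

#' Train the one-against-one attention decoder
#'
#' Fits one soft-margin linear C-SVM per unordered pair of the four
#' attention classes (six binary problems) and stores each as an
#' explicit linear decision function (weights + bias). Training is
#' deterministic given a fixed example order.
#'
#' @param examples A list as returned by [buildTrainingSet()] (elements
#'   `x`, `y`).
#' @param config An [SvmConfig-class].
#' @return An [AttnClassifier-class].
#' @export
trainClassifier <- function(examples, config = svmConfig()) {
  x <- as.matrix(examples$x)
  y <- factor(examples$y, levels = DIRECTIONS)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("need at least 2 examples of every class; missing: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  combos <- utils::combn(DIRECTIONS, 2)
  pairs <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    sel <- y %in% c(a, b)
    yy <- factor(as.character(y[sel]), levels = c(a, b))
    fit <- e1071::svm(x[sel, , drop = FALSE], yy, scale = FALSE,
                      type = "C-classification", kernel = "linear",
                      cost = config@cParam)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    bias <- -fit$rho
    # libsvm orients the decision function by order of appearance in
    # the training data, not factor levels; fix the orientation so
    # positive values vote for class a by checking the fitted model's
    # own predictions
    dec <- as.numeric(x[sel, , drop = FALSE] %*% w + bias)
    pr <- predict(fit, x[sel, , drop = FALSE])
    agree <- mean((dec > 0) == (pr == a))
    if (agree < 0.5) {
      w <- -w
      bias <- -bias
    }
    list(classA = a, classB = b, weights = w, bias = bias)
  })
  new("AttnClassifier", pairs = pairs, classes = DIRECTIONS,
      featureDim = ncol(x))
}

#' Classify a feature vector by pairwise majority vote
#'
#' Evaluates the six binary decision functions; each casts one vote.
#' The strict-majority class wins; any tie for first place - including
#' ties involving CENTER itself - is classified as CENTER, so the robot
#' never acts on an ambiguous volume.
#'
#' @param model An [AttnClassifier-class].
#' @param featureVector Numeric vector of length `featureDim`.
#' @return One of `"RIGHT"`, `"LEFT"`, `"UP"`, `"CENTER"`.
#' @export
classifyVolume <- function(model, featureVector) {
  stopifnot(is(model, "AttnClassifier"))
  v <- as.numeric(featureVector)
  if (length(v) != model@featureDim) {
    stop(sprintf("feature vector has length %d but the model expects %d",
                 length(v), model@featureDim), call. = FALSE)
  }
  votes <- setNames(integer(length(model@classes)), model@classes)
  for (p in model@pairs) {
    dec <- sum(p$weights * v) + p$bias
    winner <- if (dec > 0) p$classA else p$classB
    votes[winner] <- votes[winner] + 1L
  }
  top <- max(votes)
  winners <- names(votes)[votes == top]
  if (length(winners) == 1L) winners else "CENTER"
}

setMethod("show", "AttnClassifier", function(object) {
  cat(sprintf("AttnClassifier: %d pairwise linear SVMs over %d features, classes %s\n",
              length(object@pairs), object@featureDim,
              paste(object@classes, collapse = "/")))
})

#' Serialize / restore a trained decoder
#'
#' The model is written as a self-describing plain-text table (one row
#' per pair: the two class labels, the bias, then the weights) suitable
#' for session replay.
#'
#' @param model An [AttnClassifier-class].
#' @param path File path.
#' @return `readClassifier` returns the restored
#'   [AttnClassifier-class].
#' @export
writeClassifier <- function(model, path) {
  stopifnot(is(model, "AttnClassifier"))
  rows <- lapply(model@pairs, function(p) {
    data.frame(classA = p$classA, classB = p$classB, bias = p$bias,
               t(p$weights))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  wcols <- setdiff(names(tab), c("classA", "classB", "bias"))
  pairs <- lapply(seq_len(nrow(tab)), function(i) {
    list(classA = tab$classA[i], classB = tab$classB[i],
         weights = as.numeric(tab[i, wcols]), bias = tab$bias[i])
  })
  new("AttnClassifier", pairs = pairs, classes = DIRECTIONS,
      featureDim = length(wcols))
}

#' Leave-one-trial-out localizer accuracy
#'
#' Cross-validates the decoder at trial granularity: for each localizer
#' trial, all volumes whose (lagged) label comes from that trial are
#' held out, the six pairwise SVMs are retrained on the rest, and the
#' held-out volumes are classified.
#'
#' @param schedule A [CueSchedule-class].
#' @param features T x V localizer feature matrix.
#' @param config An [SvmConfig-class].
#' @return Overall accuracy in [0, 1], with per-volume results in
#'   `attr(, "details")`.
#' @export
leaveTrialOutAccuracy <- function(schedule, features, config = svmConfig()) {
  train <- buildTrainingSet(schedule, features, config)
  tr <- schedule@trials
  trialOf <- integer(schedule@nVolumes)
  for (r in seq_len(nrow(tr))) {
    trialOf[tr$start[r]:(tr$start[r] + tr$length[r] - 1L)] <- r
  }
  exTrial <- trialOf[train$volumes - config@labelLag]
  pred <- character(length(train$y))
  for (heldOut in unique(exTrial)) {
    testIdx <- which(exTrial == heldOut)
    model <- trainClassifier(list(x = train$x[-testIdx, , drop = FALSE],
                                  y = train$y[-testIdx]), config)
    for (i in testIdx) pred[i] <- classifyVolume(model, train$x[i, ])
  }
  acc <- mean(pred == as.character(train$y))
  attr(acc, "details") <- data.frame(volume = train$volumes,
                                     truth = as.character(train$y),
                                     predicted = pred)
  acc
}
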