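# GA-wrapped SVM feature selection with leave-one-out cross-validation.
# The SVM itself is e1071's C-classification machine with the radial basis
# kernel at the study's fixed hyperparameters (gamma 0.6, C 19); the GA
# wrapper, LOOCV harness and fold-safe standardization are implemented
# here.

#' SVM classifier specification
#'
#' @param gamma RBF kernel width parameter (> 0; default 0.6).
#' @param cost Misclassification penalty C (> 0; default 19).
#' @param standardize Z-score features inside each training fold before the
#'   kernel (default `TRUE`; raw intensities in the hundreds would make an
#'   RBF with gamma 0.6 degenerate).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(gamma = 0.6, cost = 19, standardize = TRUE) {
  if (gamma <= 0) stop_config("gamma must be > 0")
  if (cost <= 0) stop_config("cost must be > 0")
  structure(list(kernel = "rbf", gamma = gamma, cost = cost,
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Genetic-algorithm parameters for feature-subset search
#'
#' @param population Chromosomes per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Rates in `[0, 1]`.
#' @param subset_min,subset_max Allowed feature-subset sizes.
#' @param fitness `"loocv_accuracy"` (default) or `"youden"` (LOOCV
#'   Youden index).
#' @param seed Optional integer seed.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(population = 50L, generations = 40L,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      subset_min = 2L, subset_max = 5L,
                      fitness = c("loocv_accuracy", "youden"),
                      seed = NULL) {
  fitness <- match.arg(fitness)
  if (population < 2L) stop_config("population must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop_config("rates must be in [0, 1]")
  if (subset_min < 1L || subset_max < subset_min)
    stop_config("invalid subset size range")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 subset_min = as.integer(subset_min),
                 subset_max = as.integer(subset_max),
                 fitness = fitness, seed = seed),
            class = "ga_params")
}

#' @noRd
.standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

#' @noRd
.standardize_apply <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)
}

#' @noRd
.svm_fit <- function(x, y, spec) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = spec$gamma, cost = spec$cost, scale = FALSE)
}

#' Leave-one-out cross-validation of the SVM classifier
#'
#' For each of the n samples: standardize on the remaining n-1, train the
#' SVM on them, and predict the held-out sample. The held-out sample never
#' influences standardization or training. Sensitivity is with respect to
#' the case group.
#'
#' @param x Samples x features numeric matrix (rows named by sample id).
#' @param labels Character vector or factor of `"case"`/`"control"`, one
#'   per row of `x`.
#' @param spec A [classifier_spec()].
#' @return A list of class `model_report`: confusion counts (`tp`, `fn`,
#'   `tn`, `fp`), `sensitivity`, `specificity`, `accuracy`, `youden_j`,
#'   and `predictions` (data frame: `sample_id`, `truth`, `predicted`,
#'   `decision`).
#' @export
loocv <- function(x, labels, spec = classifier_spec()) {
  x <- as.matrix(x)
  y <- factor(as.character(labels), levels = c("control", "case"))
  n <- nrow(x)
  if (n != length(y)) stop_config("labels length != number of samples")
  pred <- character(n); dec <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L)
      stop_config("training fold %d contains a single class", i)
    xtr <- x[-i, , drop = FALSE]
    if (spec$standardize) {
      st <- .standardize_fit(xtr)
      xtr <- .standardize_apply(xtr, st)
      xte <- .standardize_apply(x[i, , drop = FALSE], st)
    } else xte <- x[i, , drop = FALSE]
    fit <- .svm_fit(xtr, droplevels(ytr), spec)
    p <- stats::predict(fit, xte, decision.values = TRUE)
    pred[i] <- as.character(p)
    dv <- attr(p, "decision.values")
    # orient decision value so that positive = case
    dec[i] <- if (grepl("^case", colnames(dv)[1L])) dv[1L] else -dv[1L]
  }
  truth <- as.character(y)
  tp <- sum(pred == "case" & truth == "case")
  fn <- sum(pred == "control" & truth == "case")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "case" & truth == "control")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec_ <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec_,
                 accuracy = (tp + tn) / n,
                 youden_j = sens + spec_ - 1,
                 predictions = data.frame(
                   sample_id = if (!is.null(rownames(x))) rownames(x)
                               else as.character(seq_len(n)),
                   truth = truth, predicted = pred, decision = dec,
                   stringsAsFactors = FALSE)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report: acc %.3f, sens %.3f, spec %.3f, Youden J %.3f (TP %d FN %d TN %d FP %d)>\n",
    x$accuracy, x$sensitivity, x$specificity, x$youden_j,
    x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' @noRd
.clamp_subset <- function(mask, smin, smax) {
  on <- which(mask); off <- which(!mask)
  while (length(on) > smax) {
    drop <- on[sample.int(length(on), 1L)]
    mask[drop] <- FALSE; on <- setdiff(on, drop)
  }
  while (length(on) < smin && length(off)) {
    add <- off[sample.int(length(off), 1L)]
    mask[add] <- TRUE; on <- c(on, add); off <- setdiff(off, add)
  }
  mask
}

# Lexicographic comparison used for GA tie-breaks: higher fitness, then
# smaller subset, then lower summed m/z.
#' @noRd
.ga_better <- function(fit_a, mask_a, fit_b, mask_b, mz) {
  if (abs(fit_a - fit_b) > 1e-12) return(fit_a > fit_b)
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na != nb) return(na < nb)
  sum(mz[mask_a]) < sum(mz[mask_b])
}

#' Genetic-algorithm search for the best feature subset
#'
#' Binary-mask chromosomes constrained to the configured subset-size range;
#' tournament selection (size 2), uniform crossover, per-bit mutation, and
#' one-elite carry-over, so the best fitness trace is non-decreasing.
#' Fitness is the LOOCV accuracy (or LOOCV Youden index) of the SVM on the
#' masked feature set, memoized per subset. Ties prefer smaller subsets,
#' then lower summed m/z.
#'
#' @param x Samples x features matrix.
#' @param labels `"case"`/`"control"` per sample.
#' @param ga A [ga_params()].
#' @param spec A [classifier_spec()].
#' @param feature_mz Optional numeric m/z per feature (defaults to column
#'   names) used for tie-breaking and reporting.
#' @return A list with `subset` (column indices), `mz`, `fitness`, and
#'   `trace` (best fitness per generation).
#' @export
ga_select <- function(x, labels, ga = ga_params(), spec = classifier_spec(),
                      feature_mz = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 1L) stop_config("no candidate features")
  if (is.null(feature_mz))
    feature_mz <- suppressWarnings(as.numeric(colnames(x)))
  if (length(feature_mz) != p || anyNA(feature_mz))
    feature_mz <- seq_len(p)
  smin <- min(ga$subset_min, p); smax <- min(ga$subset_max, p)
  if (smin > p) stop_config("subset size range infeasible for %d features", p)
  if (!is.null(ga$seed)) set.seed(ga$seed)

  memo <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    rep_ <- loocv(x[, mask, drop = FALSE], labels, spec)
    f <- if (ga$fitness == "loocv_accuracy") rep_$accuracy else rep_$youden_j
    memo[[key]] <- f
    f
  }

  if (p == 1L) {
    mask <- rep(TRUE, 1L)
    f <- fitness_of(mask)
    return(list(subset = 1L, mz = feature_mz, fitness = f, trace = f))
  }

  random_mask <- function() {
    k <- sample(smin:smax, 1L)
    m <- rep(FALSE, p); m[sample.int(p, k)] <- TRUE
    m
  }
  pop <- replicate(ga$population, random_mask(), simplify = FALSE)
  fit <- vapply(pop, fitness_of, numeric(1))
  best_i <- 1L
  for (i in seq_along(pop))
    if (.ga_better(fit[i], pop[[i]], fit[best_i], pop[[best_i]], feature_mz))
      best_i <- i
  best_mask <- pop[[best_i]]; best_fit <- fit[best_i]
  trace <- numeric(ga$generations)

  for (g in seq_len(ga$generations)) {
    newpop <- list(best_mask)  # elitism
    while (length(newpop) < ga$population) {
      pick <- function() {
        c2 <- sample.int(ga$population, 2L)
        i <- if (.ga_better(fit[c2[1L]], pop[[c2[1L]]],
                            fit[c2[2L]], pop[[c2[2L]]], feature_mz))
          c2[1L] else c2[2L]
        pop[[i]]
      }
      pa <- pick(); pb <- pick()
      child <- if (stats::runif(1) < ga$crossover_rate) {
        take_a <- stats::runif(p) < 0.5
        ifelse(take_a, pa, pb)
      } else pa
      flip <- stats::runif(p) < ga$mutation_rate
      child <- xor(child, flip)
      child <- .clamp_subset(child, smin, smax)
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, fitness_of, numeric(1))
    for (i in seq_along(pop))
      if (.ga_better(fit[i], pop[[i]], best_fit, best_mask, feature_mz)) {
        best_mask <- pop[[i]]; best_fit <- fit[i]
      }
    trace[g] <- best_fit
  }
  list(subset = which(best_mask), mz = feature_mz[best_mask],
       fitness = best_fit, trace = trace)
}

#' Fit the final SVM on all samples and emit scatter-plot coordinates
#'
#' Trains on the full cohort (no held-out samples) and returns, per sample,
#' the first principal component of the standardized selected-feature
#' submatrix and the SVM decision value — the coordinates of the
#' two-group scatter display.
#'
#' @param x Samples x features matrix (already restricted to the selected
#'   features).
#' @param labels `"case"`/`"control"` per sample.
#' @param spec A [classifier_spec()].
#' @return A list with `svm` (the fitted model), `center`/`scale`
#'   (standardization), and `scatter` (data frame: `sample_id`, `group`,
#'   `pc1`, `decision`).
#' @export
fit_final_model <- function(x, labels, spec = classifier_spec()) {
  x <- as.matrix(x)
  y <- factor(as.character(labels), levels = c("control", "case"))
  if (length(unique(y)) < 2L) stop_config("both classes required")
  st <- if (spec$standardize) .standardize_fit(x)
        else list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- .standardize_apply(x, st)
  fit <- .svm_fit(xs, y, spec)
  p <- stats::predict(fit, xs, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  dec <- if (grepl("^case", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
  pc1 <- if (ncol(xs) > 1L) stats::prcomp(xs, center = FALSE,
                                          scale. = FALSE)$x[, 1L]
         else xs[, 1L]
  list(svm = fit, center = st$center, scale = st$scale,
       scatter = data.frame(
         sample_id = if (!is.null(rownames(x))) rownames(x)
                     else as.character(seq_len(nrow(x))),
         group = as.character(y), pc1 = as.numeric(pc1),
         decision = as.numeric(dec), stringsAsFactors = FALSE))
}

#' Fit the GA + SVM marker-selection model
#'
#' The package's model-fitting entry point: runs the genetic-algorithm
#' feature-subset search (when more than one candidate feature is
#' supplied), assesses the chosen subset by leave-one-out cross-validation,
#' and fits the final SVM on all samples.
#'
#' @param x Samples x features matrix; column names are the feature m/z
#'   values.
#' @param labels `"case"`/`"control"` per sample (character or factor).
#' @param spec A [classifier_spec()].
#' @param ga A [ga_params()].
#' @param seed Optional integer seed (overrides `ga$seed`).
#' @return An object of class `ga_svm` with elements `selected_mz`,
#'   `subset`, `report` (LOOCV `model_report`), `trace`, `final`
#'   (full-data fit with scatter coordinates), `spec`, `ga`, `call`.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(f1 = c(rnorm(6, 3), rnorm(6, -3)), f2 = rnorm(12))
#' colnames(x) <- c("1699", "3038")
#' labs <- rep(c("case", "control"), each = 6)
#' m <- ga_svm(x, labs, ga = ga_params(population = 10, generations = 5,
#'                                     subset_min = 1, subset_max = 2,
#'                                     seed = 1))
#' m
ga_svm <- function(x, labels, spec = classifier_spec(), ga = ga_params(),
                   seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(seed)) ga$seed <- seed
  if (ncol(x) > 1L) {
    sel <- ga_select(x, labels, ga = ga, spec = spec)
  } else {
    rep1 <- loocv(x, labels, spec)
    f <- if (ga$fitness == "loocv_accuracy") rep1$accuracy else rep1$youden_j
    sel <- list(subset = 1L,
                mz = suppressWarnings(as.numeric(colnames(x))), fitness = f,
                trace = f)
  }
  xs <- x[, sel$subset, drop = FALSE]
  report <- loocv(xs, labels, spec)
  final <- fit_final_model(xs, labels, spec)
  structure(list(selected_mz = sel$mz, subset = sel$subset,
                 fitness = sel$fitness, trace = sel$trace,
                 report = report, final = final, spec = spec, ga = ga,
                 feature_names = colnames(x), call = match.call()),
            class = "ga_svm")
}

#' @export
print.ga_svm <- function(x, ...) {
  cat("GA + SVM (RBF) marker-selection model\n")
  cat(sprintf("  selected features (m/z): %s\n",
              paste(format(x$selected_mz), collapse = ", ")))
  cat(sprintf("  LOOCV: accuracy %.3f, sensitivity %.3f, specificity %.3f, Youden J %.3f\n",
              x$report$accuracy, x$report$sensitivity,
              x$report$specificity, x$report$youden_j))
  invisible(x)
}

#' @export
summary.ga_svm <- function(object, ...) {
  structure(list(model = object), class = "summary.ga_svm")
}

#' @export
print.summary.ga_svm <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  SVM: radial kernel, gamma %.3g, C %.3g, standardize %s\n",
              m$spec$gamma, m$spec$cost, m$spec$standardize))
  cat(sprintf("  GA: population %d, generations %d, fitness %s, best %.3f\n",
              m$ga$population, length(m$trace), m$ga$fitness, m$fitness))
  cat(sprintf("  confusion: TP %d FN %d TN %d FP %d\n",
              m$report$tp, m$report$fn, m$report$tn, m$report$fp))
  invisible(x)
}

#' Predict group membership for new samples
#'
#' @param object A fitted `ga_svm`.
#' @param newdata Samples x features matrix with the same columns as the
#'   training matrix (or already restricted to the selected features).
#' @param ... Unused.
#' @return A data frame with `predicted` and `decision` (positive = case).
#' @export
predict.ga_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == length(object$feature_names))
    newdata <- newdata[, object$subset, drop = FALSE]
  else if (ncol(newdata) != length(object$subset))
    stop_config("newdata must have %d (all) or %d (selected) columns",
                length(object$feature_names), length(object$subset))
  xs <- .standardize_apply(newdata,
                           list(center = object$final$center,
                                scale = object$final$scale))
  p <- stats::predict(object$final$svm, xs, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  dec <- if (grepl("^case", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
  data.frame(predicted = as.character(p), decision = as.numeric(dec),
             stringsAsFactors = FALSE)
}

#' Scatter plot of the fitted model
#'
#' First principal component of the selected-feature submatrix against the
#' SVM decision value, one point per sample, coloured by group.
#'
#' @param x A fitted `ga_svm`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ga_svm <- function(x, ...) {
  sc <- x$final$scatter
  col <- ifelse(sc$group == "case", "firebrick", "steelblue")
  graphics::plot(sc$pc1, sc$decision, col = col, pch = 19,
                 xlab = "principal component 1",
                 ylab = "SVM decision value", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::legend("topleft", legend = c("case", "control"),
                   col = c("firebrick", "steelblue"), pch = 19, bty = "n")
  invisible(x)
}
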