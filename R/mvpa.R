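#' Two-class decoding comparison definitions
#'
#' The three laminar decoding comparisons: audiovisual versus auditory blocks
#' pooled over attended modality (`AV_vs_A`, auditory ROIs), audiovisual
#' versus visual pooled over attention (`AV_vs_V`, visual ROIs), and auditory
#' versus visual attention pooled over stimulus modality (`AttA_vs_AttV`).
#' Pooled comparisons stack the block-wise samples (24 vs 24 for the default
#' design) rather than averaging.
#'
#' @param name comparison name.
#' @return a list: `name`, `class1`, `class2` (condition label sets).
#' @export
decoding_comparison <- function(name = c("AV_vs_A", "AV_vs_V",
                                         "AttA_vs_AttV")) {
  name <- match.arg(name)
  switch(name,
    AV_vs_A = list(name = name, class1 = c("AV_AttA", "AV_AttV"),
                   class2 = c("A_AttA", "A_AttV")),
    AV_vs_V = list(name = name, class1 = c("AV_AttA", "AV_AttV"),
                   class2 = c("V_AttA", "V_AttV")),
    AttA_vs_AttV = list(name = name,
                        class1 = c("A_AttA", "V_AttA", "AV_AttA"),
                        class2 = c("A_AttV", "V_AttV", "AV_AttV")))
}

## Train a linear maximum-margin classifier (cost fixed) on a feature-
## centred training set.  The primal weight vector is oriented so that a
## positive margin maps to the first (alphabetically lower) class label,
## independent of libsvm's internal label order.
train_linear_svc <- function(x, y, cost = 1) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  lev <- sort(unique(y))
  fit <- e1071::svm(x = xc, y = factor(y, levels = lev),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  dec <- attr(stats::predict(fit, xc, decision.values = TRUE),
              "decision.values")
  if (!identical(colnames(dec)[1], paste(lev[1], lev[2], sep = "/"))) {
    w <- -w
    rho <- -rho
  }
  list(w = w, rho = rho, levels = lev, train_center = mu)
}

## Decision for centred test patterns: positive margin maps to the first
## (lower) class label; exact ties break toward the lower label index too.
predict_linear_svc <- function(model, x_test_centred) {
  dec <- as.numeric(x_test_centred %*% model$w) - model$rho
  ifelse(dec >= 0, model$levels[1], model$levels[2])
}

#' Per-depth decoding profile with leave-one-run-out cross-validation
#'
#' At each of the six cortical depths, the block-wise vertex patterns of the
#' two classes are classified with a linear support vector classifier
#' (cost = 1).  Features (vertices) are mean-centred within the training set
#' and, separately, within the test set of every fold; folds hold out one
#' run each.
#'
#' @param dataset a `vertex_beta_dataset`.
#' @param roi ROI name.
#' @param comparison a [decoding_comparison()] (or its name).
#' @param cost SVC cost parameter.
#' @return an object of class `decoding_profile`: `accuracy` (6 values in
#'   \[0, 1\]), `comparison`, `folds` (per depth x fold accuracy matrix),
#'   `fold_models` (per-depth list of per-fold weight vectors).
#' @export
decode_per_depth <- function(dataset, roi, comparison, cost = 1) {
  if (is.character(comparison)) comparison <- decoding_comparison(comparison)
  sel_v <- which(dataset$roi == roi)
  if (length(sel_v) == 0) stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  lab <- dataset$labels
  in1 <- lab$condition %in% comparison$class1
  in2 <- lab$condition %in% comparison$class2
  use <- in1 | in2
  cls <- ifelse(in1, "class1", "class2")[use]
  runs <- lab$run[use]
  run_levels <- sort(unique(runs))
  if (length(run_levels) < 2) stop("need at least 2 runs", call. = FALSE)
  for (r in run_levels) {
    if (length(unique(cls[runs == r])) < 2) {
      stop(sprintf("run %d lacks samples of both classes", r), call. = FALSE)
    }
  }
  acc <- matrix(NA_real_, 6, length(run_levels),
                dimnames = list(NULL, paste0("run", run_levels)))
  fold_models <- vector("list", 6)
  for (d in 1:6) {
    X <- t(matrix(dataset$betas[sel_v, d, use, drop = FALSE],
                  nrow = length(sel_v)))
    fold_models[[d]] <- vector("list", length(run_levels))
    for (fi in seq_along(run_levels)) {
      test <- runs == run_levels[fi]
      model <- train_linear_svc(X[!test, , drop = FALSE], cls[!test], cost)
      xt <- X[test, , drop = FALSE]
      xt <- sweep(xt, 2, colMeans(xt))     # test-set centring, independent
      pred <- predict_linear_svc(model, xt)
      acc[d, fi] <- mean(pred == cls[test])
      fold_models[[d]][[fi]] <- model$w
    }
  }
  structure(list(accuracy = rowMeans(acc), comparison = comparison$name,
                 folds = acc, fold_models = fold_models),
            class = "decoding_profile")
}

#' Shape parameters of a decoding-accuracy profile
#'
#' Subtracts chance level (0.5) and applies the laminar shape GLM, so the
#' constant tests the above-chance level and the linear term the depth
#' trend of decoding accuracy.
#'
#' @param profile a [decode_per_depth()] result or a length-6 accuracy
#'   vector.
#' @param chance chance level to subtract.
#' @return a list `(C, L)` as in [fit_laminar_glm()].
#' @export
fit_accuracy_shape <- function(profile, chance = 0.5) {
  acc <- if (inherits(profile, "decoding_profile")) profile$accuracy else profile
  fit_laminar_glm(acc - chance)
}

#' Pattern similarity between condition pairs, per subject
#'
#' Computes, over the vertices of an ROI, the Spearman correlation between
#' the condition-mean activation patterns of each listed pair (patterns
#' averaged across blocks, runs and — by default — depths), Fisher
#' z-transforms the coefficients, averages within each named family, and
#' returns the difference between the first and second family.  The default
#' pairs contrast attention-pair similarity (same stimulus, different
#' attended modality) against stimulus-pair similarity (auditory versus
#' audiovisual under the same attention): a multiplicative attentional gain
#' preserves the pattern (high first family) while a pattern-altering
#' crossmodal field lowers the second.
#'
#' @param dataset a `vertex_beta_dataset`.
#' @param roi ROI name.
#' @param pairs named list of two families, each a list of length-2
#'   condition-label vectors.
#' @param depth `"pooled"` to average patterns over depths, or a depth index
#'   1..6.
#' @return a list: `rho` and `z` per pair, `family_z` means, and `contrast`
#'   (family-1 minus family-2 mean z).
#' @export
pattern_similarity <- function(dataset, roi,
                               pairs = list(
                                 attention = list(c("A_AttV", "A_AttA"),
                                                  c("AV_AttV", "AV_AttA")),
                                 stimulus = list(c("A_AttA", "AV_AttA"),
                                                 c("A_AttV", "AV_AttV"))),
                               depth = "pooled") {
  sel_v <- which(dataset$roi == roi)
  if (length(sel_v) == 0) stop(sprintf("ROI '%s' is empty", roi), call. = FALSE)
  lab <- dataset$labels
  cond_pattern <- function(cond) {
    idx <- which(lab$condition == cond)
    sub <- dataset$betas[sel_v, , idx, drop = FALSE]
    if (identical(depth, "pooled")) {
      apply(sub, 1, mean)
    } else {
      apply(sub[, depth, , drop = FALSE], 1, mean)
    }
  }
  zcap <- atanh(1 - 1e-12)
  fam <- lapply(pairs, function(fam_pairs) {
    vapply(fam_pairs, function(pr) {
      p1 <- cond_pattern(pr[1]); p2 <- cond_pattern(pr[2])
      if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
        stop("constant pattern: Spearman correlation undefined", call. = FALSE)
      }
      stats::cor(p1, p2, method = "spearman")
    }, numeric(1))
  })
  z <- lapply(fam, function(r) pmin(pmax(atanh(pmin(pmax(r, -1 + 1e-12),
                                                    1 - 1e-12)), -zcap), zcap))
  family_z <- vapply(z, mean, numeric(1))
  list(rho = fam, z = z, family_z = family_z,
       contrast = family_z[[1]] - family_z[[2]])
}

#' Exact sign-permutation test on per-subject values
#'
#' Enumerates all `2^n` sign assignments of the subject values and returns
#' the proportion whose (absolute) mean reaches the observed (absolute)
#' mean — an exact test under sign symmetry, with p-value granularity in
#' multiples of `2^(1 - n)` (two-sided) and a minimum of `2^(-n)`.
#'
#' @param values finite per-subject values (n <= 20 for exhaustive
#'   enumeration).
#' @param two_sided compare absolute means (default) or upper tail only.
#' @return the exact permutation p-value.
#' @export
exact_sign_permutation <- function(values, two_sided = TRUE) {
  n <- length(values)
  if (n < 1 || any(!is.finite(values))) {
    stop("values must be finite and non-empty", call. = FALSE)
  }
  if (n > 20) {
    stop("n > 20: exhaustive enumeration infeasible; use a Monte-Carlo test",
         call. = FALSE)
  }
  ## subset sums by doubling: sums over all subsets that are flipped negative
  sums <- 0
  for (v in values) sums <- c(sums, sums + v)
  means <- (sum(values) - 2 * sums) / n
  obs <- mean(values)
  eps <- 1e-12 * max(1, abs(obs))
  if (two_sided) {
    mean(abs(means) >= abs(obs) - eps)
  } else {
    mean(means >= obs - eps)
  }
}
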