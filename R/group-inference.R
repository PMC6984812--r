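#' Assemble the 2 (shape) x 2 (ROI) group table for one cortex family
#'
#' Per subject and ROI, the block-wise contrast shape parameters are reduced
#' to subject-level values (mean over the 12 block-by-run estimates by
#' default, or kept block-wise) and stacked into the long-format table the
#' group model expects.
#'
#' @param datasets list of `vertex_beta_dataset` (one per subject).
#' @param rois named character vector `c(primary = ..., nonprimary = ...)`
#'   giving ROI names in the datasets.
#' @param spec contrast name or [contrast_spec()].
#' @param blockwise keep the 12 block-wise values per subject-cell instead of
#'   averaging.
#' @return a tibble of class `group_table` (subject, roi, shape, value, and
#'   block/run when `blockwise`), with the contrast name as attribute.
#' @export
group_shape_table <- function(datasets, rois, spec, blockwise = FALSE) {
  stopifnot(all(c("primary", "nonprimary") %in% names(rois)))
  rows <- list()
  for (ds in datasets) {
    for (level in c("primary", "nonprimary")) {
      sh <- roi_contrast_shapes(ds, rois[[level]], spec)$shapes
      if (blockwise) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = ds$subject, roi = level,
          shape = rep(c("C", "L"), each = nrow(sh)),
          value = c(sh$C, sh$L),
          block = rep(sh$block, 2), run = rep(sh$run, 2))
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = ds$subject, roi = level, shape = c("C", "L"),
          value = c(mean(sh$C), mean(sh$L)))
      }
    }
  }
  out <- do.call(rbind, rows)
  spec_name <- if (is.character(spec)) spec else spec$name
  structure(out, class = c("group_table", class(out)), contrast = spec_name)
}

check_group_table <- function(tab) {
  needed <- c("subject", "roi", "shape", "value")
  if (!all(needed %in% names(tab))) {
    stop("group table needs columns subject, roi, shape, value", call. = FALSE)
  }
  counts <- base::table(tab$subject, interaction(tab$roi, tab$shape))
  if (ncol(counts) != 4L || length(unique(as.vector(counts))) != 1L ||
      any(counts == 0)) {
    stop("group table must be balanced: every subject x (2 ROI x 2 shape) cell",
         call. = FALSE)
  }
  if (nrow(counts) < 3L) stop("need at least 3 subjects", call. = FALSE)
  invisible(TRUE)
}

#' Fit the 2 (shape) x 2 (ROI) linear mixed model
#'
#' Cell-mean fixed effects for the four shape-by-ROI cells with a random
#' intercept per subject, fitted by REML.  In the balanced design the fixed
#' effects equal the cell means.
#'
#' @param table a [group_shape_table()] (or any balanced long table with
#'   columns subject, roi, shape, value).
#' @return an object of class `shape_lmm`: the `lmerTest` fit, the table,
#'   and the cell-mean estimates.
#' @export
fit_shape_lmm <- function(table) {
  check_group_table(table)
  d <- as.data.frame(table)
  d$shape <- factor(d$shape, levels = c("C", "L"))
  d$roi <- factor(d$roi, levels = c("primary", "nonprimary"))
  d$subject <- factor(d$subject)
  ## degenerate (e.g. zero-variance) tables break the Satterthwaite
  ## machinery; fall back to the plain lme4 fit there
  model <- tryCatch(
    suppressMessages(lmerTest::lmer(value ~ 0 + shape:roi + (1 | subject),
                                    data = d)),
    error = function(e) {
      lme4::lmer(value ~ 0 + shape:roi + (1 | subject), data = d)
    })
  cm <- lme4::fixef(model)
  structure(list(model = model, table = tibble::as_tibble(table),
                 cell_means = cm, contrast = attr(table, "contrast")),
            class = "shape_lmm")
}

## Subject-level reduction: one row per subject with ROI-averaged and
## per-ROI values of each shape (block-wise tables averaged per cell first).
subject_reduction <- function(table) {
  d <- as.data.frame(table)
  agg <- stats::aggregate(value ~ subject + roi + shape, d, mean)
  subjects <- sort(unique(agg$subject))
  get <- function(roi, shape) {
    v <- agg$value[agg$roi == roi & agg$shape == shape]
    v[order(agg$subject[agg$roi == roi & agg$shape == shape])]
  }
  list(subjects = subjects,
       C_primary = get("primary", "C"), C_nonprimary = get("nonprimary", "C"),
       L_primary = get("primary", "L"), L_nonprimary = get("nonprimary", "L"))
}

one_sample_t <- function(v, side) {
  n <- length(v)
  s <- stats::sd(v)
  if (s == 0) {
    t <- if (mean(v) == 0) 0 else sign(mean(v)) * Inf
  } else {
    t <- mean(v) / (s / sqrt(n))
  }
  p <- switch(side,
              less = stats::pt(t, n - 1),
              greater = stats::pt(t, n - 1, lower.tail = FALSE),
              two.sided = 2 * stats::pt(-abs(t), n - 1))
  list(stat = t, df = n - 1, p = p, side = side)
}

#' Step-down testing of the 2 x 2 shape-by-ROI model
#'
#' Stage 1: a two-dimensional test that the constant and the linear
#' parameter, each averaged across the two ROIs, are jointly zero.  Stage 2
#' (only if stage 1 is significant): per-parameter tests, ROI-averaged.
#' Stage 3 (only for parameters significant at stage 2): per-ROI tests.
#' One-sided alternatives encode a-priori directional hypotheses (e.g.
#' negative constants for crossmodal deactivation).
#'
#' The default `"exact"` method uses subject-level reductions — Hotelling's
#' T-squared at stage 1 and one-sample t (or its squared F) at stages 2–3 —
#' which are exactly calibrated for the balanced one-value-per-cell design.
#' `method = "wald"` instead computes Wald F contrasts on the fitted mixed
#' model with Satterthwaite denominator degrees of freedom.
#'
#' @param x a `shape_lmm` fit or a balanced group table.
#' @param sidedness named list/vector giving the alternative for each shape
#'   (`"less"`, `"greater"`, `"two.sided"`); applied at stages 2 and 3.
#' @param alpha gating significance level for every stage.
#' @param method `"exact"` (subject-level reductions) or `"wald"` (mixed-
#'   model contrasts).
#' @return an object of class `stepdown_result`: `stage1` (stat, df, p),
#'   `stage2` (per shape), `stage3` (per shape x ROI), `gating` (stages
#'   run), `alpha`, `method`.
#' @export
stepdown_test <- function(x, sidedness = c(C = "two.sided", L = "two.sided"),
                          alpha = 0.05, method = c("exact", "wald")) {
  method <- match.arg(method)
  table <- if (inherits(x, "shape_lmm")) x$table else x
  check_group_table(table)
  red <- subject_reduction(table)
  n <- length(red$subjects)
  gating <- "stage1"
  if (method == "exact") {
    M <- cbind(C = (red$C_primary + red$C_nonprimary) / 2,
               L = (red$L_primary + red$L_nonprimary) / 2)
    m <- colMeans(M)
    S <- stats::cov(M)
    scale2 <- mean(M^2) + mean(m^2)
    if (!all(is.finite(S)) || abs(det(S)) < 1e-24 * max(scale2, 1e-12)^2) {
      ## degenerate (zero-variance) data: evidence is all-or-nothing
      zero_mean <- sqrt(mean(m^2)) <= 1e-10 * sqrt(max(scale2, 1e-300))
      stage1 <- list(stat = if (zero_mean) 0 else Inf, df1 = 2, df2 = n - 2,
                     p = if (zero_mean) 1 else 0)
    } else {
      T2 <- n * drop(t(m) %*% solve(S, m))
      Fstat <- (n - 2) / (2 * (n - 1)) * T2
      stage1 <- list(stat = Fstat, df1 = 2, df2 = n - 2,
                     p = stats::pf(Fstat, 2, n - 2, lower.tail = FALSE))
    }
  } else {
    fit <- if (inherits(x, "shape_lmm")) x else fit_shape_lmm(table)
    L2 <- contrast_rows(fit$model)
    ct <- lmerTest::contest(fit$model, rbind(L2$C, L2$L), joint = TRUE)
    stage1 <- list(stat = ct[["F value"]], df1 = ct$NumDF, df2 = ct$DenDF,
                   p = ct[["Pr(>F)"]])
  }
  stage2 <- NULL; stage3 <- NULL
  if (is.finite(stage1$p) && stage1$p < alpha) {
    gating <- c(gating, "stage2")
    stage2 <- list()
    for (sh in c("C", "L")) {
      side <- if (!is.null(sidedness[[sh]])) sidedness[[sh]] else "two.sided"
      avg <- (red[[paste0(sh, "_primary")]] + red[[paste0(sh, "_nonprimary")]]) / 2
      if (method == "exact") {
        tt <- one_sample_t(avg, side)
        stage2[[sh]] <- if (side == "two.sided") {
          list(stat = tt$stat^2, df1 = 1, df2 = tt$df, p = tt$p,
               side = side, type = "F")
        } else c(tt, type = "t")
      } else {
        fit <- if (inherits(x, "shape_lmm")) x else fit_shape_lmm(table)
        Lr <- contrast_rows(fit$model)[[sh]]
        ct <- lmerTest::contest(fit$model, Lr, joint = TRUE)
        p <- ct[["Pr(>F)"]]
        stat <- ct[["F value"]]
        if (side != "two.sided") {
          tval <- sign(sum(Lr * lme4::fixef(fit$model))) * sqrt(stat)
          p <- if (side == "less") stats::pt(tval, ct$DenDF) else
            stats::pt(tval, ct$DenDF, lower.tail = FALSE)
          stage2[[sh]] <- list(stat = tval, df = ct$DenDF, p = p, side = side,
                               type = "t")
        } else {
          stage2[[sh]] <- list(stat = stat, df1 = ct$NumDF, df2 = ct$DenDF,
                               p = p, side = side, type = "F")
        }
      }
    }
    sig2 <- names(stage2)[vapply(stage2, function(s) s$p < alpha, logical(1))]
    if (length(sig2) > 0) {
      gating <- c(gating, "stage3")
      stage3 <- list()
      for (sh in sig2) {
        side <- if (!is.null(sidedness[[sh]])) sidedness[[sh]] else "two.sided"
        for (level in c("primary", "nonprimary")) {
          v <- red[[paste0(sh, "_", level)]]
          stage3[[paste(sh, level, sep = "_")]] <- one_sample_t(v, side)
        }
      }
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 gating = gating, alpha = alpha, method = method, n = n),
            class = "stepdown_result")
}

## ROI-averaging contrast rows over the 0 + shape:roi cell-mean coding.
contrast_rows <- function(model) {
  nm <- names(lme4::fixef(model))
  row_for <- function(sh) {
    r <- as.numeric(grepl(paste0("shape", sh), nm)) / 2
    stats::setNames(r, nm)
  }
  list(C = row_for("C"), L = row_for("L"))
}

#' @export
print.stepdown_result <- function(x, ...) {
  cat(sprintf("<stepdown_result> n=%d method=%s\n", x$n, x$method))
  cat(sprintf("  stage 1: F(%g, %g) = %.3f, p = %.4g\n", x$stage1$df1,
              x$stage1$df2, x$stage1$stat, x$stage1$p))
  for (sh in names(x$stage2)) {
    s <- x$stage2[[sh]]
    cat(sprintf("  stage 2 [%s]: stat = %.3f, p = %.4g (%s)\n", sh, s$stat,
                s$p, s$side))
  }
  for (nm in names(x$stage3)) {
    s <- x$stage3[[nm]]
    cat(sprintf("  stage 3 [%s]: t(%d) = %.3f, p = %.4g (%s)\n", nm, s$df,
                s$stat, s$p, s$side))
  }
  invisible(x)
}

#' Tidy a step-down result into a long table
#'
#' @param x a [stepdown_test()] result.
#' @param contrast optional contrast name column.
#' @return a tibble (contrast, stage, term, statistic, df1, df2, p, side).
#' @export
stepdown_table <- function(x, contrast = NA_character_) {
  rows <- list(tibble::tibble(contrast = contrast, stage = 1L, term = "joint",
                              statistic = x$stage1$stat, df1 = x$stage1$df1,
                              df2 = x$stage1$df2, p = x$stage1$p,
                              side = "two.sided"))
  for (sh in names(x$stage2)) {
    s <- x$stage2[[sh]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contrast = contrast, stage = 2L, term = sh, statistic = s$stat,
      df1 = if (!is.null(s$df1)) s$df1 else 1,
      df2 = if (!is.null(s$df2)) s$df2 else s$df, p = s$p, side = s$side)
  }
  for (nm in names(x$stage3)) {
    s <- x$stage3[[nm]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contrast = contrast, stage = 3L, term = nm, statistic = s$stat,
      df1 = 1, df2 = s$df, p = s$p, side = s$side)
  }
  do.call(rbind, rows)
}
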