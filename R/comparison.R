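#' Summarize measurement records per method
#'
#' Produces the per-method mean and SD of a measured variable, both at the
#' lesion level (each lesion's values first averaged over observers and
#' repeats, so every lesion contributes once) and over the raw records.
#' A single-record summary reports SD 0 with `n_flag = TRUE`.
#'
#' @param records measurement data.frame with columns `lesion_id`, `method`,
#'   `observer_id`, `repeat_index` and the requested variables.
#' @param variables character vector of variable columns (default the four
#'   dimensions `A`, `B`, `C`, `D`).
#' @return data.frame with columns `variable`, `method`, `level`
#'   (`"lesion"` or `"raw"`), `mean`, `sd`, `n`, `n_flag`.
#' @export
summarize_measurements <- function(records, variables = c("A", "B", "C", "D")) {
  if (!nrow(records)) stop("no measurement records")
  out <- list()
  for (v in variables) {
    df <- records[!is.na(records[[v]]), ]
    for (m in sort(unique(df$method))) {
      sub <- df[df$method == m, ]
      les <- tapply(sub[[v]], sub$lesion_id, mean)
      for (lev in c("lesion", "raw")) {
        x <- if (lev == "lesion") as.numeric(les) else sub[[v]]
        out[[length(out) + 1L]] <- data.frame(
          variable = v, method = m, level = lev,
          mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
          n = length(x), n_flag = length(x) == 1L)
      }
    }
  }
  do.call(rbind, out)
}

#' Compare levels of a within-lesion factor
#'
#' Reproduces the multilevel method-agreement analysis: measurements of each
#' lesion under every level of a within-lesion factor (`method`, `observer`
#' or `repeat`) are compared with a model containing fixed main effects for
#' the three factors (no interactions) and a lesion-specific random
#' intercept.
#'
#' Lesions missing any level of the requested factor are dropped (the
#' comparison is over lesions measured under both levels), and lesion-level
#' means per level are formed by averaging over the remaining factors. For a
#' two-level factor the reported estimate is the fitted fixed-effect
#' contrast (level 2 minus level 1) from the [lme4::lmer()] model - which in
#' a complete balanced design equals the mean of the per-lesion paired
#' differences - and the p-value comes from the exact paired t-test on the
#' lesion-level means with `n_lesions - 1` degrees of freedom. For the
#' three-level repeat factor a within-lesion repeated-measures ANOVA F-test
#' is used and the estimate is the range of the level means.
#'
#' @param records measurement data.frame (see [summarize_measurements()]).
#' @param variable name of the measured column to compare.
#' @param factor one of `"method"`, `"observer"`, `"repeat"`.
#' @return An object of class `comparison_result`: list with `variable`,
#'   `factor`, `levels`, `means`, `sds` (lesion-level, per level),
#'   `estimate`, `se`, `df`, `p_value`, `n_lesions`.
#' @export
compare_factor <- function(records, variable,
                           factor = c("method", "observer", "repeat")) {
  factor <- match.arg(factor)
  fcol <- switch(factor, method = "method", observer = "observer_id",
                 `repeat` = "repeat_index")
  for (col in c("lesion_id", "method", "observer_id", "repeat_index", variable))
    if (!col %in% names(records)) stop("records lack column ", col)
  df <- records[!is.na(records[[variable]]), , drop = FALSE]
  if (!nrow(df)) stop("variable ", variable, " has no observed values")
  lv <- sort(unique(df[[fcol]]))
  if (length(lv) < 2L)
    stop("factor ", factor, " has fewer than 2 observed levels")

  ## paired restriction: lesions observed under every level
  tab <- table(df$lesion_id, df[[fcol]])
  complete <- rownames(tab)[apply(tab > 0, 1, all)]
  df <- df[as.character(df$lesion_id) %in% complete, , drop = FALSE]
  n <- length(complete)
  if (n < 2L) stop("fewer than 2 lesions measured under all levels")

  ## lesion-level means per level (averaging over the other factors)
  lmeans <- tapply(df[[variable]], list(df$lesion_id, df[[fcol]]), mean)
  lmeans <- lmeans[, as.character(lv), drop = FALSE]
  means <- colMeans(lmeans)
  sds <- apply(lmeans, 2, stats::sd)

  est_lmm <- fit_lmm_contrast(df, variable, fcol, lv)
  if (length(lv) == 2L) {
    diffs <- lmeans[, 2] - lmeans[, 1]
    est_paired <- mean(diffs)
    sd_d <- stats::sd(diffs)
    se <- sd_d / sqrt(n)
    estimate <- if (is.na(est_lmm)) est_paired else est_lmm
    if (sd_d == 0) {
      p <- if (abs(est_paired) < 1e-12) 1 else 0
    } else {
      tstat <- est_paired / se
      p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
    dfree <- n - 1
  } else {
    long <- data.frame(y = as.vector(lmeans),
                       level = factor(rep(colnames(lmeans),
                                          each = nrow(lmeans))),
                       lesion = factor(rep(rownames(lmeans),
                                           ncol(lmeans))))
    if (stats::var(long$y) == 0) {
      p <- 1
    } else {
      fit <- stats::aov(y ~ level + Error(lesion), data = long)
      tabl <- summary(fit)[["Error: Within"]][[1]]
      p <- tabl[["Pr(>F)"]][1]
      if (is.na(p)) p <- 1  # zero residual variance, identical levels
    }
    estimate <- max(means) - min(means)
    se <- NA_real_
    dfree <- (n - 1) * (length(lv) - 1)
  }
  structure(list(variable = variable, factor = factor, levels = lv,
                 means = means, sds = sds, estimate = unname(estimate),
                 se = unname(se), df = dfree, p_value = unname(p),
                 n_lesions = n),
            class = "comparison_result")
}

## fixed-effect contrast (last level minus first) of `fcol` from a mixed
## model with all three within-lesion factors as main effects and a random
## intercept per lesion; NA when the fit is unavailable
fit_lmm_contrast <- function(df, variable, fcol, lv) {
  dat <- data.frame(y = df[[variable]],
                    method = factor(df$method),
                    observer_id = factor(df$observer_id),
                    repeat_index = factor(df$repeat_index),
                    lesion_id = factor(df$lesion_id))
  terms <- c("method", "observer_id", "repeat_index")
  terms <- terms[vapply(terms, function(t) nlevels(dat[[t]]) >= 2L,
                        logical(1))]
  if (!length(terms) || stats::var(dat$y) == 0) return(NA_real_)
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + "),
                               "+ (1 | lesion_id)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(f, data = dat, REML = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  fe <- lme4::fixef(fit)
  nm <- paste0(fcol, lv[length(lv)])
  if (!nm %in% names(fe)) return(NA_real_)
  unname(fe[[nm]])
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison of %s across %s (%s)\n", x$variable, x$factor,
              paste(x$levels, collapse = " vs ")))
  for (i in seq_along(x$levels))
    cat(sprintf("  %s: %.3f +/- %.3f\n", x$levels[i], x$means[i], x$sds[i]))
  cat(sprintf("  estimate %.4f, p = %.4g (n = %d lesions, df = %d)\n",
              x$estimate, x$p_value, x$n_lesions, x$df))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(variable = x$variable, factor = x$factor,
             level_1 = as.character(x$levels[1]),
             level_2 = as.character(x$levels[length(x$levels)]),
             mean_1 = unname(x$means[1]), sd_1 = unname(x$sds[1]),
             mean_2 = unname(x$means[length(x$means)]),
             sd_2 = unname(x$sds[length(x$sds)]),
             estimate = x$estimate, p_value = x$p_value,
             n_lesions = x$n_lesions)
}

#' Inter- and intra-observer variability
#'
#' `level = "inter"` compares the two observers' lesion-level means (a
#' within-lesion observer contrast via [compare_factor()]).
#' `level = "intra"` quantifies repeatability within each observer: the mean
#' within-cell (lesion x method) SD across the three repeats, together with
#' the repeat-factor contrast p-value computed per observer.
#'
#' @inheritParams compare_factor
#' @param level `"inter"` or `"intra"`.
#' @return For `"inter"`, a `comparison_result`. For `"intra"`, a data.frame
#'   with one row per observer: `observer_id`, `sd_within`, `p_repeat`.
#' @export
observer_variability <- function(records, variable,
                                 level = c("inter", "intra")) {
  level <- match.arg(level)
  obs <- sort(unique(records$observer_id))
  if (level == "inter") {
    if (length(obs) < 2L) stop("inter-observer comparison needs 2 observers")
    return(compare_factor(records, variable, "observer"))
  }
  out <- lapply(obs, function(o) {
    sub <- records[records$observer_id == o & !is.na(records[[variable]]), ]
    cell <- interaction(sub$lesion_id, sub$method, drop = TRUE)
    sds <- tapply(sub[[variable]], cell,
                  function(x) if (length(x) > 1L) stats::sd(x) else NA_real_)
    p <- if (length(unique(sub$repeat_index)) >= 2L)
      compare_factor(sub, variable, "repeat")$p_value else NA_real_
    data.frame(observer_id = o, sd_within = mean(sds, na.rm = TRUE),
               p_repeat = p)
  })
  do.call(rbind, out)
}

#' Chi-square test of lesion recognition rates
#'
#' Compares the number of lesions recognized by two methods with a Pearson
#' chi-square test on the 2x2 recognized/missed table. The uncorrected
#' statistic is the default; Yates continuity correction is available behind
#' `correct = TRUE`.
#'
#' @param recognized_a,total_a recognized and total counts for method A.
#' @param recognized_b,total_b recognized and total counts for method B.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic` (chi-square), `p_value`, `df`, `table`
#'   (observed 2x2), `expected`.
#' @export
recognition_test <- function(recognized_a, total_a, recognized_b, total_b,
                             correct = FALSE) {
  counts <- c(recognized_a, total_a, recognized_b, total_b)
  if (any(counts < 0) || recognized_a > total_a || recognized_b > total_b ||
      total_a == 0 || total_b == 0)
    stop("impossible recognition counts")
  tab <- matrix(c(recognized_a, total_a - recognized_a,
                  recognized_b, total_b - recognized_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(method = c("a", "b"),
                                outcome = c("recognized", "missed")))
  if (any(colSums(tab) == 0))  # degenerate table: identical outcomes
    return(list(statistic = 0, p_value = 1, df = 1L, table = tab,
                expected = tab))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), table = tab, expected = ht$expected)
}
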