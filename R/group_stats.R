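# Group-level inferential machinery: subject x condition aggregation,
# repeated-measures ANOVA with Greenhouse-Geisser correction and generalized
# eta-squared, Bonferroni post-hocs, and one-sample bias tests.

#' Aggregate trial-level metrics to subject x condition means
#'
#' One value per subject x posture x stimulus cell (the subject average over
#' trials), the unit of analysis for the repeated-measures tests. An
#' incomplete crossing is an explicit error naming the missing cells.
#'
#' @param metrics data.frame with `subject_id`, `posture`, `stimulus_type`
#'   and one or more numeric metric columns.
#' @param dv name of the metric column to aggregate.
#' @return data.frame `subject_id`, `posture`, `stimulus_type`, `value`.
#' @export
aggregate_metrics <- function(metrics, dv) {
  stopifnot(dv %in% names(metrics))
  agg <- stats::aggregate(metrics[[dv]],
                          by = list(subject_id = metrics$subject_id,
                                    posture = metrics$posture,
                                    stimulus_type = metrics$stimulus_type),
                          FUN = mean)
  names(agg)[4] <- "value"
  full <- expand.grid(subject_id = unique(agg$subject_id),
                      posture = unique(agg$posture),
                      stimulus_type = unique(agg$stimulus_type),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$posture, d$stimulus_type)
  missing <- setdiff(key(full), key(agg))
  if (length(missing))
    stop("aggregate_metrics: incomplete crossing; missing cells: ",
         paste(missing, collapse = "; "))
  agg[order(agg$subject_id, agg$posture, agg$stimulus_type), ]
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' Fully within-subjects ANOVA over one or two factors on subject-level
#' cell means. Sphericity is assessed per multi-df effect with Mauchly's
#' test; when violated (Mauchly p < alpha) the Greenhouse-Geisser epsilon
#' rescales that effect's degrees of freedom and p-value. Both corrected
#' and raw p-values are reported. Effect sizes are generalized eta-squared
#' with all factors treated as manipulated:
#' `SS_effect / (SS_effect + sum of all error SS including the
#' between-subject SS)`.
#'
#' The multivariate fit, Mauchly test, and epsilon come from
#' `car::Anova()`; the sums of squares it returns feed the effect-size
#' computation.
#'
#' @param table subject x condition table from [aggregate_metrics()]
#'   (columns `subject_id`, `value`, plus the factor columns).
#' @param within character vector of within-subject factor names (1 or 2).
#' @param alpha Mauchly significance gate for applying the correction
#'   (default 0.05).
#' @return data.frame, one row per effect: `effect`, `F`, `df1`, `df2`
#'   (corrected when sphericity was violated, hence possibly non-integer),
#'   `p`, `p_uncorrected`, `etaG2`, `epsilon`, `mauchly_p`, `corrected`.
#' @export
rm_anova <- function(table, within = c("posture", "stimulus_type"),
                     alpha = 0.05) {
  stopifnot(all(c("subject_id", "value", within) %in% names(table)),
            length(within) %in% 1:2)
  if (stats::var(table$value) < 1e-24)
    stop("rm_anova: dependent variable has zero variance")
  for (f in within) table[[f]] <- factor(table[[f]])
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 3) stop("rm_anova: need at least 3 subjects")
  idata <- do.call(expand.grid, c(rev(lapply(table[within], levels)),
                                  list(stringsAsFactors = TRUE)))
  names(idata) <- rev(within)
  idata <- idata[, within, drop = FALSE]
  # response matrix: rows = subjects, columns ordered as idata
  ord <- do.call(order, c(list(table$subject_id), table[within]))
  tt <- table[ord, ]
  idata_key <- do.call(paste, idata)
  cell_key <- do.call(paste, tt[within])
  Y <- matrix(NA_real_, length(subjects), nrow(idata))
  for (i in seq_along(subjects)) {
    rows <- tt[tt$subject_id == subjects[i], ]
    Y[i, ] <- rows$value[match(idata_key, do.call(paste, rows[within]))]
  }
  if (anyNA(Y)) stop("rm_anova: incomplete subject x condition crossing")
  mod <- stats::lm(Y ~ 1)
  des <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  an <- car::Anova(mod, idata = idata, idesign = des, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  uni <- s$univariate.tests
  effects <- setdiff(rownames(uni), "(Intercept)")
  ss_sub <- uni["(Intercept)", "Error SS"]
  ss_err_all <- sum(uni[effects, "Error SS"]) + ss_sub
  adj <- s$pval.adjustments
  sph <- s$sphericity.tests
  out <- do.call(rbind, lapply(effects, function(e) {
    ss <- uni[e, "Sum Sq"]
    f_val <- uni[e, "F value"]
    df1 <- uni[e, "num Df"]; df2 <- uni[e, "den Df"]
    p_raw <- uni[e, "Pr(>F)"]
    eps <- 1; mau <- NA_real_
    if (!is.null(adj) && e %in% rownames(adj)) {
      eps <- adj[e, "GG eps"]
      mau <- sph[e, "p-value"]
    }
    correct <- is.finite(mau) && mau < alpha
    data.frame(effect = e, F = f_val,
               df1 = if (correct) df1 * eps else df1,
               df2 = if (correct) df2 * eps else df2,
               p = if (correct) adj[e, "Pr(>F[GG])"] else p_raw,
               p_uncorrected = p_raw,
               etaG2 = ss / (ss + ss_err_all),
               epsilon = eps, mauchly_p = mau, corrected = correct)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise comparisons of factor levels
#'
#' Paired t-tests between every pair of levels on subject means; each p is
#' multiplied by the number of comparisons and capped at 1.
#'
#' @param table subject x condition table (as for [rm_anova()]); values are
#'   first averaged within subject x level of `factor_name`.
#' @param factor_name factor whose levels are compared.
#' @return data.frame `level1`, `level2`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `significant` (at .05).
#' @export
bonferroni_pairwise <- function(table, factor_name = "posture") {
  stopifnot(all(c("subject_id", "value", factor_name) %in% names(table)))
  agg <- stats::aggregate(table$value,
                          by = list(subject_id = table$subject_id,
                                    level = table[[factor_name]]),
                          FUN = mean)
  lv <- unique(as.character(agg$level))
  if (length(lv) < 2) stop("bonferroni_pairwise: need >= 2 levels")
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(k) {
    a <- agg$x[agg$level == pairs[1, k]][order(agg$subject_id[agg$level == pairs[1, k]])]
    b <- agg$x[agg$level == pairs[2, k]][order(agg$subject_id[agg$level == pairs[2, k]])]
    tst <- stats::t.test(a, b, paired = TRUE)
    data.frame(level1 = pairs[1, k], level2 = pairs[2, k],
               t = unname(tst$statistic), df = unname(tst$parameter),
               p_raw = tst$p.value,
               p_bonferroni = min(1, tst$p.value * m))
  }))
  out$significant <- out$p_bonferroni < 0.05
  out
}

#' One-sample t-test with Cohen's d
#'
#' Standard one-sample t against a null mean (default 0, the equator), with
#' `d = mean / sd`, so `d = t / sqrt(n)` exactly. Zero-variance input is
#' flagged rather than producing an infinite statistic.
#'
#' @param x numeric vector (e.g. subject mean latitudes).
#' @param null null-hypothesis mean (default 0).
#' @return list: `bias` (mean of x minus null... the raw mean offset), `t`,
#'   `df`, `p`, `d`, `n`, `zero_variance`.
#' @export
one_sample_bias_test <- function(x, null = 0) {
  n <- length(x)
  if (n < 2) stop("one_sample_bias_test: need n >= 2")
  m <- mean(x) - null
  s <- stats::sd(x)
  if (s < 1e-12)
    return(list(bias = m, t = NA_real_, df = n - 1, p = NA_real_,
                d = NA_real_, n = n, zero_variance = TRUE))
  t_val <- m / (s / sqrt(n))
  list(bias = m, t = t_val, df = n - 1,
       p = 2 * stats::pt(-abs(t_val), n - 1),
       d = m / s, n = n, zero_variance = FALSE)
}
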