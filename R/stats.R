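#' One-way ANOVA for a named contrast
#'
#' Classical fixed-effects between/within decomposition,
#' `F = MS_between / MS_within`, with the p-value from the F distribution
#' (delegated to `stats::oneway.test(var.equal = TRUE)`).
#'
#' Degenerate inputs are resolved explicitly: identical groups with no
#' within-group variance give F = 0, p = 1; zero within-group variance with
#' a real between-group difference gives F = Inf, p = 0 (flagged).
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @param label contrast label carried into the result.
#' @return data.frame of class `anova_result` with `label`, `f`,
#'   `df_between`, `df_within`, `p`, `significant` (at alpha = 0.05) and
#'   `infinite_f`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5
#' @export
one_way_anova <- function(groups, label = "") {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least two values")
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop("non-finite values in ANOVA input")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  means <- tapply(values, g, mean)
  ss_w <- sum((values - means[g])^2)
  ss_b <- sum(tapply(values, g, length) * (means - mean(values))^2)
  if (ss_w == 0) {
    if (ss_b <= .Machine$double.eps * sum(values^2)) {
      f <- 0; p <- 1; inf_f <- FALSE
    } else {
      f <- Inf; p <- 0; inf_f <- TRUE
    }
  } else {
    ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
    f <- unname(ow$statistic); p <- unname(ow$p.value); inf_f <- FALSE
  }
  structure(
    data.frame(label = label, f = f, df_between = df_b, df_within = df_w,
               p = p, significant = is.finite(p) && p < 0.05,
               infinite_f = inf_f, stringsAsFactors = FALSE),
    class = c("anova_result", "data.frame"))
}

# pre/post contrast helper: one ANOVA row per cell, NA-flagged when a cell
# has fewer than two subjects per session
contrast_cell <- function(df, value_col, pre = "pre", post = "post30") {
  a <- df[[value_col]][df$session == pre]
  b <- df[[value_col]][df$session == post]
  if (length(a) < 2 || length(b) < 2)
    return(data.frame(f = NA_real_, df_between = NA_integer_,
                      df_within = NA_integer_, p = NA_real_,
                      significant = NA, insufficient_n = TRUE))
  r <- one_way_anova(list(a, b))
  data.frame(f = r$f, df_between = r$df_between, df_within = r$df_within,
             p = r$p, significant = r$significant, insufficient_n = FALSE)
}

#' Pre/post one-way ANOVA comparison tables
#'
#' Reproduces the study's comparison structure: within each group x
#' condition cell, the pre session is compared against the post session
#' (default post30) by one-way ANOVA, treating subjects as independent
#' observations.
#'
#' Three tables are built: `ecg` (group x condition x {rr_mean, svi, pnn50};
#' 18 rows for 2 groups x 3 conditions x 3 variables), `eeg` (group x
#' condition x channel, one column block per EEG variable — per-epoch
#' features are first averaged to one value per subject x channel x
#' condition x session to avoid pseudo-replication) and `scores`
#' (group x condition subjective workload scores). Stars follow the
#' study's convention (significant at p < 0.05); a Benjamini-Hochberg
#' adjusted p-value column is emitted additionally but does not drive the
#' stars.
#'
#' @param eeg an `eeg_feature_table` (from [extract_features()], rows for
#'   many recordings bound together), or NULL to skip.
#' @param hrv a data.frame of [hrv_pipeline()] rows, or NULL.
#' @param scores a data.frame with subject/group/session/condition/score,
#'   or NULL.
#' @param eeg_variable which EEG column to compare (default "ei"; energies
#'   and rms work too).
#' @param pre,post session labels to contrast.
#' @return list of class `comparison_tables` with elements `ecg`, `eeg`,
#'   `scores` (data.frames or NULL).
#' @export
build_comparison_tables <- function(eeg = NULL, hrv = NULL, scores = NULL,
                                    eeg_variable = "ei",
                                    pre = "pre", post = "post30") {
  conditions <- c("BL", "LWL", "HWL")
  out <- list(ecg = NULL, eeg = NULL, scores = NULL)

  if (!is.null(hrv)) {
    rows <- list()
    for (grp in unique(hrv$group)) for (cond in conditions)
      for (var in c("rr_mean", "svi", "pnn50")) {
        cell <- hrv[hrv$group == grp & hrv$condition == cond &
                      hrv$session %in% c(pre, post), ]
        rows[[length(rows) + 1]] <- cbind(
          data.frame(group = grp, condition = cond, variable = var,
                     stringsAsFactors = FALSE),
          contrast_cell(cell, var, pre, post))
      }
    out$ecg <- do.call(rbind, rows)
    out$ecg$p_bh <- stats::p.adjust(out$ecg$p, method = "BH")
  }

  if (!is.null(eeg)) {
    if (!eeg_variable %in% names(eeg))
      stop("eeg_variable '", eeg_variable, "' not found in feature table")
    agg <- stats::aggregate(
      eeg[[eeg_variable]],
      by = list(subject = eeg$subject, group = eeg$group,
                session = eeg$session, condition = eeg$condition,
                channel = eeg$channel),
      FUN = mean)
    names(agg)[names(agg) == "x"] <- "value"
    rows <- list()
    for (grp in unique(agg$group)) for (cond in conditions)
      for (ch in unique(agg$channel)) {
        cell <- agg[agg$group == grp & agg$condition == cond &
                      agg$channel == ch & agg$session %in% c(pre, post), ]
        rows[[length(rows) + 1]] <- cbind(
          data.frame(group = grp, condition = cond, channel = ch,
                     variable = eeg_variable, stringsAsFactors = FALSE),
          contrast_cell(cell, "value", pre, post))
      }
    out$eeg <- do.call(rbind, rows)
    out$eeg$p_bh <- stats::p.adjust(out$eeg$p, method = "BH")
  }

  if (!is.null(scores)) {
    rows <- list()
    for (grp in unique(scores$group))
      for (cond in intersect(conditions, unique(scores$condition))) {
        cell <- scores[scores$group == grp & scores$condition == cond &
                         scores$session %in% c(pre, post), ]
        rows[[length(rows) + 1]] <- cbind(
          data.frame(group = grp, condition = cond, variable = "score",
                     stringsAsFactors = FALSE),
          contrast_cell(cell, "score", pre, post))
      }
    out$scores <- do.call(rbind, rows)
    out$scores$p_bh <- stats::p.adjust(out$scores$p, method = "BH")
  }
  class(out) <- "comparison_tables"
  out
}

#' @export
print.comparison_tables <- function(x, ...) {
  for (nm in c("ecg", "eeg", "scores")) {
    if (is.null(x[[nm]])) next
    cat("--", toupper(nm), "pre/post one-way ANOVA --\n")
    tb <- x[[nm]]
    tb$star <- ifelse(!is.na(tb$significant) & tb$significant, "*", "")
    print(tb, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
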