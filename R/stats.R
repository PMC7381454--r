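# Study-level statistics: repeated-measures one-way ANOVA with the
# Greenhouse-Geisser sphericity correction and both eta-squared variants,
# plus Bonferroni-corrected paired comparisons with Cohen's d for paired
# data. Implemented directly from the sums-of-squares and covariance
# formulas so every reported quantity is explicit.

#' Build a participants x conditions matrix of mean distances
#'
#' Aggregates per-trial mean predator-prey distances to one cell per
#' (subject, condition): the mean of that subject's trial means.
#'
#' @param trials Data frame with columns `subject`, `condition`, and
#'   `mean_distance` (one row per trial; e.g. `mean_distance` from
#'   [distance_series()]).
#' @param condition_levels Column order of the result (default
#'   `c("P", "S", "R", "U")`: predictable, semi-random, random,
#'   user-generated).
#' @return A `condition_matrix`: numeric matrix, rows = subjects, columns =
#'   conditions.
#' @export
condition_summary <- function(trials,
                              condition_levels = c("P", "S", "R", "U")) {
  stopifnot(all(c("subject", "condition", "mean_distance") %in% names(trials)))
  condition_levels <- intersect(condition_levels, unique(trials$condition))
  if (length(condition_levels) < 2L) {
    stop("need at least 2 conditions", call. = FALSE)
  }
  subjects <- unique(trials$subject)
  m <- matrix(NA_real_, length(subjects), length(condition_levels),
              dimnames = list(as.character(subjects), condition_levels))
  for (s in seq_along(subjects)) for (cnd in condition_levels) {
    v <- trials$mean_distance[trials$subject == subjects[s] &
                                trials$condition == cnd]
    if (length(v) == 0L) {
      stop(sprintf("subject '%s' has no trial in condition '%s'",
                   subjects[s], cnd), call. = FALSE)
    }
    m[s, cnd] <- mean(v)
  }
  class(m) <- c("condition_matrix", class(m))
  m
}

#' Read / write a condition matrix as CSV
#'
#' Rows are subjects (first column `subject`), remaining columns the
#' conditions in order.
#'
#' @param path CSV file path.
#' @return For `read_condition_matrix`, a `condition_matrix`.
#' @export
read_condition_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  class(m) <- c("condition_matrix", class(m))
  m
}

#' @rdname read_condition_matrix
#' @param matrix A `condition_matrix`.
#' @export
write_condition_matrix <- function(matrix, path) {
  subj <- rownames(matrix)
  if (is.null(subj)) subj <- as.character(seq_len(nrow(matrix)))
  df <- data.frame(subject = subj, as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Repeated-measures one-way ANOVA with Greenhouse-Geisser correction
#'
#' Partitions the total sum of squares into subjects, conditions, and error;
#' F is the conditions mean square over the error mean square. The
#' Greenhouse-Geisser epsilon is computed from the double-centered
#' covariance matrix of the conditions and deflates both degrees of
#' freedom before the p-value is taken from the F distribution. Both the
#' classical eta squared (`SS_cond / SS_total`) and the partial variant
#' (`SS_cond / (SS_cond + SS_error)`) are reported.
#'
#' @param matrix Numeric matrix, rows = subjects (n >= 2), columns =
#'   conditions (k >= 2), no missing cells.
#' @return An object of class `rm_anova_result`: list with `F`, `df1`,
#'   `df2` (corrected), `df1_uncorrected`, `df2_uncorrected`, `epsilon_gg`,
#'   `p`, `eta_sq`, `eta_sq_partial`, and the sums of squares.
#' @export
rm_anova <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (anyNA(m)) stop("matrix has missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need n >= 2 subjects and k >= 2 conditions",
                             call. = FALSE)
  gm <- mean(m)
  subj_means <- rowMeans(m)
  cond_means <- colMeans(m)
  ss_total <- sum((m - gm)^2)
  ss_subj <- k * sum((subj_means - gm)^2)
  ss_cond <- n * sum((cond_means - gm)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  if (ss_err <= 0 && ss_cond == 0) {
    stop("undefined F: constant matrix (zero effect and zero error SS)",
         call. = FALSE)
  }
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)

  # Greenhouse-Geisser epsilon from the double-centered covariance matrix
  S <- stats::cov(m)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps <- if (k == 2L) 1 else {
    sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  }
  eps <- min(eps, 1)
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)

  structure(list(F = Fv, df1 = df1 * eps, df2 = df2 * eps,
                 df1_uncorrected = df1, df2_uncorrected = df2,
                 epsilon_gg = eps, p = p,
                 eta_sq = ss_cond / ss_total,
                 eta_sq_partial = ss_cond / (ss_cond + ss_err),
                 ss = c(subjects = ss_subj, conditions = ss_cond,
                        error = ss_err, total = ss_total),
                 n = n, k = k),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf(
    "rm ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g (GG eps = %.3f)\n  eta^2 = %.3f, partial eta^2 = %.3f\n",
    x$df1, x$df2, x$F, x$p, x$epsilon_gg, x$eta_sq, x$eta_sq_partial))
  invisible(x)
}

#' Bonferroni-corrected paired comparisons with Cohen's d
#'
#' Two-sided paired t-tests on the per-subject condition differences. The
#' Bonferroni multiplier is the number of comparisons requested. Cohen's d
#' for paired data is `mean(diff) / sd(diff)`.
#'
#' @param matrix Numeric matrix, rows = subjects, named columns = conditions.
#' @param pairs List of length-2 character vectors naming condition pairs;
#'   default: all pairs of columns.
#' @return Data frame with one row per pair: `a`, `b`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `d`, `undefined` (TRUE when the difference variance is
#'   zero: `t` is infinite and `d` undefined unless the mean is also zero).
#' @export
paired_comparisons <- function(matrix, pairs = NULL) {
  m <- unclass(as.matrix(matrix))
  if (is.null(pairs)) {
    cn <- colnames(m)
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  }
  n <- nrow(m)
  mult <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    if (pr[1] == pr[2]) stop("a pair must name two distinct conditions",
                             call. = FALSE)
    dif <- m[, pr[1]] - m[, pr[2]]
    md <- mean(dif); sdd <- stats::sd(dif)
    if (sdd == 0) {
      tt <- if (md == 0) 0 else sign(md) * Inf
      d <- if (md == 0) 0 else NA_real_
      p <- if (md == 0) 1 else 0
      undef <- md != 0
    } else {
      tt <- md / (sdd / sqrt(n))
      d <- md / sdd
      p <- 2 * stats::pt(-abs(tt), df = n - 1)
      undef <- FALSE
    }
    data.frame(a = pr[1], b = pr[2], t = tt, df = n - 1, p_raw = p,
               p_bonferroni = min(1, mult * p), d = d, undefined = undef)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
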