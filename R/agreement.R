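#' Information-based measure of disagreement (IBMD)
#'
#' Entropy-motivated disagreement score for M observers rating the same
#' quantity. For each of the M(M-1)/2 observer pairs (a, b) the pair term is
#' \deqn{\log_2\!\left(\frac{|x_a - x_b|}{\max(x_a, x_b)} + 1\right),}
#' with the 0/0 pair (both observers report absence) defined as 0, i.e.
#' perfect agreement on absence. The multi-observer IBMD is the mean over all
#' pairs. It equals 0 exactly when all observers agree and grows toward 1 as
#' the relative distance between observers' values increases.
#'
#' @param values numeric vector of length M >= 2 of non-negative observer
#'   values for one cell (one directed character pair, one emotion).
#' @return a single number in \[0, 1\] (up to the log2(2) = 1 pair ceiling).
#' @examples
#' ibmd(rep(7, 11))   # 0: all 11 judges agree
#' ibmd(c(1, 10))     # log2(1.9), about 0.926
#' ibmd(c(2, 2, 4))   # mean of {0, log2(1.5), log2(1.5)}, about 0.390
#' @export
ibmd <- function(values) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 2) stopf("ibmd needs at least 2 observers, got %d", m)
  if (anyNA(values)) stopf("ibmd: NA observer values")
  if (any(values < 0)) stopf("ibmd: observer values must be non-negative")
  pr <- utils::combn(m, 2)
  a <- values[pr[1, ]]
  b <- values[pr[2, ]]
  mean(ibmd_pair_term(a, b))
}

# Vectorized pair term; both-zero pairs are 0 by definition.
ibmd_pair_term <- function(a, b) {
  mx <- pmax(a, b)
  term <- numeric(length(a))
  nz <- mx > 0
  term[nz] <- log2(abs(a[nz] - b[nz]) / mx[nz] + 1)
  term
}

#' Percentile-bootstrap confidence interval for IBMD
#'
#' Resamples the M observers with replacement `n_boot` times, recomputes the
#' multi-observer IBMD on each resample, and returns the percentile interval.
#' Fully deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @inheritParams ibmd
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed, required: every stochastic step in the package
#'   takes an explicit seed so runs are reproducible.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `c(ci_low = , ci_high = )`.
#' @export
ibmd_ci <- function(values, n_boot = 2000, seed, conf = 0.95) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 2) stopf("ibmd_ci needs at least 2 observers, got %d", m)
  if (any(values < 0)) stopf("ibmd_ci: observer values must be non-negative")
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (missing(seed) || is.null(seed)) stopf("ibmd_ci: an explicit seed is required")
  stats <- with_seed(seed, {
    idx <- matrix(sample.int(m, n_boot * m, replace = TRUE), nrow = n_boot)
    ibmd_rows(matrix(values[idx], nrow = n_boot))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stats, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

# IBMD of every row of a matrix (rows = resamples), vectorized over rows.
ibmd_rows <- function(x) {
  m <- ncol(x)
  pr <- utils::combn(m, 2)
  acc <- numeric(nrow(x))
  for (p in seq_len(ncol(pr))) {
    acc <- acc + ibmd_pair_term(x[, pr[1, p]], x[, pr[2, p]])
  }
  acc / ncol(pr)
}

#' Per-cell observer values of a matrix set
#'
#' Pivots a [rater_matrix_set()] into one row per cell (emotion, source,
#' target) with the M raters' final accumulated values as a matrix column
#' block, the unit at which disagreement is scored.
#'
#' @param set a [rater_matrix_set()] with at least 2 raters.
#' @return data.frame with columns `emotion`, `source`, `target` and an
#'   attached numeric matrix attribute `"values"` (cells x raters, columns
#'   named by rater id).
#' @export
cell_observations <- function(set) {
  stopifnot(inherits(set, "rater_matrix_set"))
  if (length(set$raters) < 2) stopf("need at least 2 raters to score disagreement")
  ros <- as.character(set$roster)
  n <- length(ros)
  grid <- expand.grid(source_i = seq_len(n), target_i = seq_len(n))
  out <- list()
  vals <- list()
  for (e in set$emotions) {
    block <- vapply(set$raters,
                    function(r) as.vector(unclass(set$matrices[[r]][[e]])),
                    numeric(n * n))
    # as.vector is column-major: row index = source varies fastest
    out[[e]] <- data.frame(emotion = e,
                           source = ros[grid$source_i],
                           target = ros[grid$target_i],
                           stringsAsFactors = FALSE)
    vals[[e]] <- block[(grid$target_i - 1) * n + grid$source_i, , drop = FALSE]
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  v <- do.call(rbind, vals)
  colnames(v) <- set$raters
  attr(df, "values") <- v
  attr(df, "roster") <- set$roster
  df
}

#' Filter cells by disagreement
#'
#' Scores every cell's IBMD across the M judges with a percentile-bootstrap
#' 95% confidence interval and retains a cell only when the upper CI bound is
#' strictly below `threshold` (default 0.15). All-zero cells (no judge
#' perceived the interaction) score IBMD 0 and are retained, though they
#' yield no edge downstream.
#'
#' @param obs either a [rater_matrix_set()] or the output of
#'   [cell_observations()].
#' @param threshold retention cutoff on the CI upper bound; strictly-below
#'   comparison, so a cell tied at exactly the threshold is dropped.
#' @param n_boot,seed,conf bootstrap settings, see [ibmd_ci()].
#' @return data.frame of class `"cell_agreement"`: one row per cell with
#'   `emotion`, `source`, `target`, `ibmd`, `ci_low`, `ci_high`, `retained`,
#'   plus attributes `threshold`, `n_boot`, `seed`, `values` (the observer
#'   matrix) and `raters`.
#' @export
filter_cells <- function(obs, threshold = 0.15, n_boot = 2000, seed, conf = 0.95) {
  if (inherits(obs, "rater_matrix_set")) obs <- cell_observations(obs)
  if (is.null(attr(obs, "values"))) stopf("obs must carry a 'values' matrix attribute")
  if (threshold <= 0) stopf("threshold must be > 0")
  if (missing(seed) || is.null(seed)) stopf("filter_cells: an explicit seed is required")
  v <- attr(obs, "values")
  m <- ncol(v)
  point <- ibmd_rows(v)
  ci <- matrix(NA_real_, nrow(v), 2)
  for (i in seq_len(nrow(v))) {
    if (all(v[i, ] == v[i, 1])) {
      ci[i, ] <- c(0, 0)  # every resample of a constant vector is constant
    } else {
      ci[i, ] <- ibmd_ci(v[i, ], n_boot = n_boot,
                         seed = derive_seed(seed, i), conf = conf)
    }
  }
  res <- data.frame(obs[, c("emotion", "source", "target")],
                    ibmd = point, ci_low = ci[, 1], ci_high = ci[, 2],
                    retained = ci[, 2] < threshold,
                    stringsAsFactors = FALSE)
  structure(res, threshold = threshold, n_boot = n_boot, seed = seed,
            conf = conf, values = v, raters = colnames(v),
            roster = attr(obs, "roster"),
            class = c("cell_agreement", "data.frame"))
}

#' @export
print.cell_agreement <- function(x, ...) {
  cat(sprintf("Cell agreement: %d cells, %d retained (%.1f%%) at CI upper bound < %.3g\n",
              nrow(x), sum(x$retained), 100 * mean(x$retained),
              attr(x, "threshold")))
  cat(sprintf("  bootstrap: n_boot = %d, seed = %d\n",
              attr(x, "n_boot"), attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more cells\n")
  invisible(x)
}

#' Intraclass correlation for two-way absolute agreement, single measure
#'
#' ICC(A,1) in McGraw-Wong terms: subjects (cells) and raters are both
#' random effects and systematic rater offsets count as disagreement.
#' Computed from the two-way ANOVA mean squares
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n subjects and k raters.
#'
#' @param x numeric matrix, n subjects (rows) x k raters (columns).
#' @return ICC value in \[-1, 1\], or NA (with a warning) when the data have
#'   no between-subject or between-rater variance at all.
#' @export
icc_a1 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stopf("icc_a1 needs >= 2 subjects and >= 2 raters")
  gm <- mean(x)
  if (all(x == gm)) {
    warnf("ICC undefined: zero variance across all cells")
    return(NA_real_)
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - gm)^2)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) {
    warnf("ICC undefined: zero variance across all cells")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Pairwise judge agreement (ICC matrix)
#'
#' For every pair of judges, computes the intraclass correlation over the
#' vector of all cell values — all emotions pooled by default, or per
#' emotion. Complements the per-cell IBMD filter with a judge-level view of
#' which raters diverge.
#'
#' @param set a [rater_matrix_set()] with M >= 2 raters.
#' @param icc_form ICC variant; currently `"ICC(A,1)"` (two-way random,
#'   absolute agreement, single measure), the default and only form.
#' @param per_emotion if TRUE, returns a named list of per-emotion matrices
#'   instead of one pooled matrix.
#' @return symmetric M x M matrix (diagonal 1) of class `"judge_icc"` with
#'   attribute `icc_form`; entries are NA with a warning where a pair has no
#'   variance. With `per_emotion = TRUE`, a named list of such matrices.
#' @export
judge_pair_icc <- function(set, icc_form = "ICC(A,1)", per_emotion = FALSE) {
  stopifnot(inherits(set, "rater_matrix_set"))
  if (!identical(icc_form, "ICC(A,1)")) {
    stopf("unsupported icc_form '%s' (only ICC(A,1) is implemented)", icc_form)
  }
  if (length(set$raters) < 2) stopf("need at least 2 raters")
  if (per_emotion) {
    out <- lapply(set$emotions, function(e) {
      sub <- set
      sub$emotions <- e
      judge_pair_icc(sub, icc_form = icc_form, per_emotion = FALSE)
    })
    names(out) <- set$emotions
    return(out)
  }
  obs <- cell_observations(set)
  v <- attr(obs, "values")
  m <- ncol(v)
  icc <- diag(1, m)
  dimnames(icc) <- list(set$raters, set$raters)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    icc[i, j] <- icc[j, i] <- icc_a1(v[, c(i, j)])
  }
  structure(icc, icc_form = icc_form, class = c("judge_icc", "matrix", "array"))
}

#' @export
print.judge_icc <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise judge agreement, %s (%d judges)\n",
              attr(x, "icc_form"), nrow(x)))
  m <- x
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(round(m, digits))
  invisible(x)
}
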