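#' Fit emotion networks from multi-rater annotations
#'
#' The top-level estimator: takes the M raters' accumulated annotation
#' matrices, filters every cell by inter-observer disagreement (IBMD with a
#' percentile-bootstrap 95% CI, retained when the upper bound is strictly
#' below `threshold`), aggregates retained cells into one weighted directed
#' network per emotion, and computes degree centralities, descriptive
#' statistics, in/out-degree correlations and the pairwise judge ICC matrix.
#'
#' @param set a [rater_matrix_set()] (e.g. from [accumulate_events()], read
#'   from per-rater CSVs, or simulated via [ground_truth()]).
#' @param threshold IBMD CI upper-bound retention cutoff (default 0.15).
#' @param n_boot bootstrap resamples per cell (default 2000).
#' @param seed integer seed for the bootstrap; required.
#' @param aggregator cross-judge edge-weight aggregator, `"mean"` (default),
#'   `"median"` or `"sum"`.
#' @param icc compute the pairwise judge ICC matrix (default TRUE).
#' @param top_k characters kept in the summary ranking tables (default 10).
#' @return an object of class `"emonet"`: a list with components
#'   `agreement` (per-cell [filter_cells()] output), `networks` (named list
#'   of [emotion_network()]), `centrality` (named list of
#'   [degree_indices()] tables), `stats` (per-emotion
#'   [descriptive_stats()] matrices), `correlations` (per-emotion Pearson
#'   and Spearman in/out-degree correlations), `icc` (judge matrix or NULL)
#'   and `config`.
#' @examples
#' gt <- ground_truth(roster = roster(c("A", "B", "C")), emotions = "joy",
#'                    n_raters = 5, noise_sd = 0, annotate_prob = 1,
#'                    repeat_prob = 0, seed = 42)
#' fit <- emonet(simulate(gt), n_boot = 200, seed = 1)
#' summary(fit)
#' @export
emonet <- function(set, threshold = 0.15, n_boot = 2000, seed,
                   aggregator = c("mean", "median", "sum"),
                   icc = TRUE, top_k = 10) {
  stopifnot(inherits(set, "rater_matrix_set"))
  aggregator <- match.arg(aggregator)
  if (missing(seed) || is.null(seed)) stopf("emonet: an explicit seed is required")
  agreement <- filter_cells(set, threshold = threshold, n_boot = n_boot,
                            seed = seed)
  networks <- build_network(agreement, aggregator = aggregator)
  centrality <- lapply(networks, degree_indices)
  stats_ <- lapply(centrality, descriptive_stats)
  correlations <- t(vapply(centrality, function(tab) {
    c(pearson = tryCatch(in_out_correlation(tab, "pearson"),
                         error = function(e) NA_real_),
      spearman = tryCatch(in_out_correlation(tab, "spearman"),
                          error = function(e) NA_real_))
  }, numeric(2)))
  icc_m <- if (icc && length(set$raters) >= 2) judge_pair_icc(set) else NULL
  structure(list(agreement = agreement, networks = networks,
                 centrality = centrality, stats = stats_,
                 correlations = correlations, icc = icc_m,
                 roster = set$roster, raters = set$raters,
                 config = list(threshold = threshold, n_boot = n_boot,
                               seed = as.integer(seed),
                               aggregator = aggregator, top_k = top_k)),
            class = "emonet")
}

#' @export
print.emonet <- function(x, ...) {
  cat("Emotion network fit\n")
  cat(sprintf("  %d raters, %d characters, emotions: %s\n",
              length(x$raters), length(x$roster),
              paste(names(x$networks), collapse = ", ")))
  cat(sprintf("  cells retained: %d / %d (IBMD CI upper bound < %.3g, n_boot %d, seed %d)\n",
              sum(x$agreement$retained), nrow(x$agreement),
              x$config$threshold, x$config$n_boot, x$config$seed))
  for (e in names(x$networks)) {
    cat(sprintf("  %-10s %3d edges, total weight %.4g\n", e,
                nrow(x$networks[[e]]$edges), sum(x$networks[[e]]$edges$weight)))
  }
  invisible(x)
}

#' @export
summary.emonet <- function(object, ...) {
  structure(list(fit = object), class = "summary.emonet")
}

#' @export
print.summary.emonet <- function(x, ...) {
  fit <- x$fit
  print(fit)
  k <- fit$config$top_k
  for (e in names(fit$centrality)) {
    cat(sprintf("\n-- %s --\n", e))
    cat(sprintf("top %d by weighted indegree (received) / outdegree (expressed):\n", k))
    tin <- top_characters(fit$centrality[[e]], "weighted_indegree", k)
    tout <- top_characters(fit$centrality[[e]], "weighted_outdegree", k)
    both <- data.frame(tin, tout, check.names = FALSE)
    print(both, row.names = FALSE)
    cat("descriptive statistics:\n")
    print(round(fit$stats[[e]][, 1:3], 3))
    cat(sprintf("in/out correlation: Pearson %.3f, Spearman %.3f\n",
                fit$correlations[e, "pearson"], fit$correlations[e, "spearman"]))
  }
  if (!is.null(fit$icc)) {
    off <- fit$icc[upper.tri(fit$icc)]
    cat(sprintf("\npairwise judge ICC(A,1): median %.3f, range [%.3f, %.3f]\n",
                stats::median(off, na.rm = TRUE), min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
coef.emonet <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$centrality), function(e) {
    cbind(emotion = e, as.data.frame(object$centrality[[e]]))
  }))
  rownames(out) <- NULL
  out
}

#' Plot the fitted emotion networks
#'
#' One panel per emotion, force-directed layout with a fixed seed. Node area
#' follows weighted indegree (emotion received), node darkness follows
#' weighted outdegree (emotion expressed), edge width follows weight, arrows
#' give direction.
#'
#' @param x an `"emonet"` fit.
#' @param emotions which emotions to draw (default all).
#' @param layout_seed seed for the layout (default the fit's seed).
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.emonet <- function(x, emotions = names(x$networks),
                        layout_seed = x$config$seed, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(emotions)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (e in emotions) {
    net <- x$networks[[e]]
    sty <- styled_attributes(net)
    g <- as_igraph(net)
    idx <- match(igraph::V(g)$name, sty$nodes$character)
    lay <- with_seed(layout_seed, igraph::layout_with_fr(g))
    grey <- grDevices::grey(1 - 0.8 * sty$nodes$darkness[idx])
    igraph::plot.igraph(
      g, layout = lay, main = e,
      vertex.size = 6 + 18 * sty$nodes$size[idx],
      vertex.color = grey, vertex.label.cex = 0.7,
      edge.width = if (nrow(sty$edges)) 0.5 + 3 * sty$edges$thickness else 1,
      edge.arrow.size = 0.3, ...)
  }
  invisible(x)
}
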