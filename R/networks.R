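#' Emotion network
#'
#' A weighted directed graph for one emotion: nodes are the full character
#' roster (isolated characters included — the roster defines the population),
#' edges carry the aggregated perceived-emotion intensity from sender to
#' receiver. Only strictly positive weights are stored; the binary adjacency
#' indicator g is derived as weight > 0.
#'
#' @param emotion emotion label.
#' @param roster a [roster()] (or character vector).
#' @param edges data.frame with columns `source`, `target`, `weight`
#'   (weight > 0, characters in the roster). Zero rows allowed.
#' @return an object of class `"emotion_network"`.
#' @export
emotion_network <- function(emotion, roster, edges) {
  ros <- as_roster(roster)
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    if (!all(c("source", "target", "weight") %in% names(edges))) {
      stopf("edges need columns source, target, weight")
    }
    edges$source <- normalize_labels(edges$source)
    edges$target <- normalize_labels(edges$target)
    bad <- setdiff(unique(c(edges$source, edges$target)), as.character(ros))
    if (length(bad)) stopf("edge endpoint(s) not in roster: %s", paste(bad, collapse = ", "))
    if (any(edges$weight <= 0)) stopf("edge weights must be > 0")
    if (anyDuplicated(paste(edges$source, edges$target, sep = "\r"))) {
      stopf("duplicate edge for a (source, target) pair")
    }
  }
  rownames(edges) <- NULL
  structure(list(emotion = normalize_labels(emotion), roster = ros,
                 edges = edges[, c("source", "target", "weight")]),
            class = "emotion_network")
}

#' @export
print.emotion_network <- function(x, ...) {
  cat(sprintf("Emotion network '%s': %d characters, %d edges, total weight %.4g\n",
              x$emotion, length(x$roster), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Build one weighted directed network per emotion
#'
#' Turns the disagreement-filtered cells into emotion networks. A retained
#' cell with at least one nonzero judge value becomes an edge whose weight is
#' the chosen aggregate of all M judges' values (zeros included); dropped
#' cells contribute no edge regardless of their values.
#'
#' @param agreements a `"cell_agreement"` object from [filter_cells()].
#' @param aggregator how the M judges' values for a retained cell collapse
#'   to one edge weight: `"mean"` (default; stable in the number of judges),
#'   `"median"`, or `"sum"`.
#' @return named list of [emotion_network()] objects, one per emotion.
#' @export
build_network <- function(agreements, aggregator = c("mean", "median", "sum")) {
  stopifnot(inherits(agreements, "cell_agreement"))
  aggregator <- match.arg(aggregator)
  agg_fun <- switch(aggregator, mean = mean, median = stats::median, sum = sum)
  v <- attr(agreements, "values")
  emotions <- unique(agreements$emotion)
  ros <- attr(agreements, "roster")
  if (is.null(ros)) ros <- roster(unique(c(agreements$source, agreements$target)))
  out <- lapply(emotions, function(e) {
    sel <- which(agreements$emotion == e & agreements$retained)
    rows <- sel[rowSums(v[sel, , drop = FALSE]) > 0]
    w <- vapply(rows, function(i) agg_fun(v[i, ]), numeric(1))
    keep <- w > 0
    emotion_network(e, ros,
                    data.frame(source = agreements$source[rows][keep],
                               target = agreements$target[rows][keep],
                               weight = w[keep], stringsAsFactors = FALSE))
  })
  names(out) <- emotions
  out
}

#' Degree centralities of an emotion network
#'
#' For each character i: the unweighted indegree counts the senders j with
#' g_ji = 1, the unweighted outdegree the receivers; the weighted variants
#' sum edge weights along incoming/outgoing edges, measuring how much of the
#' emotion a character receives (weighted indegree) or expresses (weighted
#' outdegree). The weighted degree is their sum. Self-loops count toward
#' both directions.
#'
#' @param net an [emotion_network()].
#' @return data.frame of class `"centrality_table"`: one row per roster
#'   character with columns `character`, `weighted_indegree`,
#'   `weighted_outdegree`, `weighted_degree`, `indegree`, `outdegree`;
#'   attribute `emotion`.
#' @export
degree_indices <- function(net) {
  stopifnot(inherits(net, "emotion_network"))
  ros <- as.character(net$roster)
  win <- wout <- uin <- uout <- stats::setNames(numeric(length(ros)), ros)
  if (nrow(net$edges) > 0) {
    s <- net$edges$source; t <- net$edges$target; w <- net$edges$weight
    for (k in seq_along(w)) {
      wout[s[k]] <- wout[s[k]] + w[k]
      win[t[k]] <- win[t[k]] + w[k]
      uout[s[k]] <- uout[s[k]] + 1
      uin[t[k]] <- uin[t[k]] + 1
    }
  }
  structure(data.frame(character = ros,
                       weighted_indegree = unname(win),
                       weighted_outdegree = unname(wout),
                       weighted_degree = unname(win + wout),
                       indegree = unname(uin),
                       outdegree = unname(uout),
                       stringsAsFactors = FALSE),
            emotion = net$emotion,
            class = c("centrality_table", "data.frame"))
}

#' Descriptive statistics of a centrality table
#'
#' Mean, standard error of the mean, median, standard deviation (n-1
#' denominator) and maximum for each degree index, over all roster
#' characters (isolates included). Because every edge contributes its weight
#' once to an indegree and once to an outdegree, mean weighted indegree
#' always equals mean weighted outdegree, and mean weighted degree is twice
#' either — the structural equilibrium between expressed and received
#' emotion.
#'
#' @param table a `"centrality_table"` from [degree_indices()].
#' @return numeric matrix, rows Mean / SE of Mean / Median / SD / Maximum,
#'   columns the degree indices.
#' @export
descriptive_stats <- function(table) {
  stopifnot(inherits(table, "centrality_table"))
  cols <- c("weighted_indegree", "weighted_outdegree", "weighted_degree",
            "indegree", "outdegree")
  n <- nrow(table)
  if (n == 0) stopf("empty roster: no characters to summarize")
  if (n < 2) warnf("single character: SD undefined, reported as 0")
  out <- sapply(cols, function(cl) {
    x <- table[[cl]]
    sdev <- if (n < 2) 0 else stats::sd(x)
    c(mean = mean(x), se_mean = sdev / sqrt(n), median = stats::median(x),
      sd = sdev, max = max(x))
  })
  rownames(out) <- c("Mean", "Std. Error of Mean", "Median",
                     "Std. Deviation", "Maximum")
  out
}

#' Correlation between weighted in- and outdegree
#'
#' A strong positive correlation indicates an equilibrium between emotion
#' expressed and received by each character.
#'
#' @param table a `"centrality_table"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient, or NA (with a warning) when either
#'   vector has zero variance.
#' @export
in_out_correlation <- function(table, method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "centrality_table"))
  method <- match.arg(method)
  x <- table$weighted_indegree
  y <- table$weighted_outdegree
  if (length(x) < 3) stopf("need at least 3 characters for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("in/out correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Top-k characters per degree index
#'
#' Ranks characters by one index, descending, ties broken by roster order.
#'
#' @param table a `"centrality_table"`.
#' @param by index column to rank by (default `"weighted_indegree"`).
#' @param k how many characters to keep (default 10, truncated to the roster
#'   size).
#' @return data.frame with columns `character` and the chosen index, `k`
#'   rows.
#' @export
top_characters <- function(table, by = "weighted_indegree", k = 10) {
  stopifnot(inherits(table, "centrality_table"))
  if (!by %in% names(table)) stopf("unknown index '%s'", by)
  ord <- order(-table[[by]], seq_len(nrow(table)))
  k <- min(k, nrow(table))
  out <- table[ord[seq_len(k)], c("character", by)]
  rownames(out) <- NULL
  out
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("Centrality table, emotion '%s' (%d characters)\n",
              attr(x, "emotion"), nrow(x)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
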