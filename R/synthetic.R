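#' Example character roster
#'
#' The nineteen character ids used throughout the package examples: the
#' principals of a nonlinear crime film, plus aggregate pseudo-characters
#' ("Others", "Diners", "Drug", "The Gold Watch") which are treated as
#' ordinary roster entries.
#'
#' @return a [roster()] of 19 character labels.
#' @export
example_roster <- function() {
  roster(c("Vincent Vega", "Jules Winnfield", "Butch Coolidge",
           "Marsellus Wallace", "Mia Wallace", "Lance", "Jody", "Fabienne",
           "Pumpkin (Ringo)", "Honey Bunny (Yolanda)", "Brett",
           "The Wolf (Winston)", "Jimmie Dimmick", "Esmarelda Villalobos",
           "Captain Koons", "Diners", "Drug", "The Gold Watch", "Others"))
}

#' Ground truth for synthetic multi-rater annotation data
#'
#' Defines a latent true weighted digraph per emotion plus a rater model, so
#' every stage of the pipeline can be tested against a known answer. Latent
#' weights W are 0 (no interaction) or in the Likert range \[1, 10\]. Each of
#' the M raters independently annotates each true-nonzero cell with
#' probability `annotate_prob`, reporting `clamp(round(W + N(0, noise_sd)),
#' 1, 10)`; with probability `repeat_prob` the report is split into two
#' additive annotation events, exercising the accumulation rule. Raters
#' never annotate true-zero cells (no hallucinated edges).
#'
#' @param roster a [roster()] or character vector; default [example_roster()].
#' @param emotions emotion labels; default anger, fear, joy, sadness.
#' @param n_raters number of judges M (default 11).
#' @param density probability that a directed off-diagonal pair carries a
#'   true interaction, used only when `weights` is NULL (default 0.25).
#' @param noise_sd per-rater Gaussian noise SD on the Likert scale
#'   (default 0.5).
#' @param annotate_prob probability a rater annotates a true-nonzero cell
#'   (default 0.9).
#' @param repeat_prob probability an annotation is entered as two additive
#'   events (default 0.1).
#' @param seed integer seed; all stochastic draws (latent W included) derive
#'   from it.
#' @param weights optional named list (by emotion) of n x n latent weight
#'   matrices with entries 0 or in \[1, 10\]; overrides random generation.
#' @return an object of class `"emonet_truth"`.
#' @export
ground_truth <- function(roster = example_roster(),
                         emotions = default_emotions(),
                         n_raters = 11, density = 0.25, noise_sd = 0.5,
                         annotate_prob = 0.9, repeat_prob = 0.1,
                         seed = 1L, weights = NULL) {
  ros <- as_roster(roster)
  emotions <- normalize_labels(emotions)
  n <- length(ros)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (annotate_prob <= 0 || annotate_prob > 1) stopf("annotate_prob must be in (0, 1]")
  if (repeat_prob < 0 || repeat_prob > 1) stopf("repeat_prob must be in [0, 1]")
  if (n_raters < 1) stopf("need at least 1 rater")
  if (is.null(weights)) {
    weights <- with_seed(derive_seed(seed, 0L), {
      ws <- lapply(emotions, function(e) {
        w <- matrix(0, n, n, dimnames = list(as.character(ros), as.character(ros)))
        off <- which(row(w) != col(w))
        on <- off[stats::runif(length(off)) < density]
        w[on] <- sample(1:10, length(on), replace = TRUE)
        w
      })
      names(ws) <- emotions
      ws
    })
  } else {
    if (!all(emotions %in% names(weights))) stopf("weights must be named by emotion")
    weights <- lapply(weights[emotions], function(w) {
      w <- as.matrix(w)
      if (nrow(w) != n || ncol(w) != n) stopf("weight matrix dimension != roster size")
      if (any(w < 0 | (w > 0 & w < 1) | w > 10)) {
        stopf("latent weights must be 0 or in [1, 10]")
      }
      dimnames(w) <- list(as.character(ros), as.character(ros))
      w
    })
  }
  structure(list(roster = ros, emotions = emotions, weights = weights,
                 n_raters = as.integer(n_raters), density = density,
                 noise_sd = noise_sd, annotate_prob = annotate_prob,
                 repeat_prob = repeat_prob, seed = as.integer(seed)),
            class = "emonet_truth")
}

#' @export
print.emonet_truth <- function(x, ...) {
  nz <- vapply(x$weights, function(w) sum(w > 0), numeric(1))
  cat(sprintf("Synthetic ground truth: %d characters, %d raters, seed %d\n",
              length(x$roster), x$n_raters, x$seed))
  cat(sprintf("  noise_sd %.3g, annotate_prob %.3g, repeat_prob %.3g\n",
              x$noise_sd, x$annotate_prob, x$repeat_prob))
  cat("  true edges:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a multi-rater annotation data set from ground truth
#'
#' Draws annotation events per rater and emotion according to the rater
#' model in [ground_truth()], then accumulates them into matrices — so the
#' generator exercises the same accumulation path as real data. Bit
#' reproducible for a given truth object (the seed lives in the truth).
#'
#' @param object an `"emonet_truth"`.
#' @param nsim number of replicate data sets (default 1).
#' @param seed optional seed overriding the one stored in `object`.
#' @param ... unused.
#' @return a [rater_matrix_set()], or a list of them when `nsim > 1`
#'   (replicates use consecutive derived seeds).
#' @export
simulate.emonet_truth <- function(object, nsim = 1, seed = NULL, ...) {
  base_seed <- if (is.null(seed)) object$seed else as.integer(seed)
  one <- function(rep_i) {
    with_seed(derive_seed(base_seed, rep_i), {
      evs <- list()
      for (r in seq_len(object$n_raters)) {
        rid <- sprintf("rater%02d", r)
        for (e in object$emotions) {
          w <- object$weights[[e]]
          nz <- which(w > 0, arr.ind = TRUE)
          if (nrow(nz) == 0) next
          ann <- stats::runif(nrow(nz)) < object$annotate_prob
          for (k in which(ann)) {
            v <- w[nz[k, 1], nz[k, 2]] + stats::rnorm(1, 0, object$noise_sd)
            v <- min(10, max(1, round(v)))
            vals <- if (v >= 2 && stats::runif(1) < object$repeat_prob) {
              c(floor(v / 2), v - floor(v / 2))  # additive repeat
            } else v
            evs[[length(evs) + 1]] <- data.frame(
              rater_id = rid, emotion = e,
              source = rownames(w)[nz[k, 1]],
              target = colnames(w)[nz[k, 2]],
              value = vals, stringsAsFactors = FALSE)
          }
        }
      }
      events <- if (length(evs)) do.call(rbind, evs) else
        data.frame(rater_id = character(0), emotion = character(0),
                   source = character(0), target = character(0),
                   value = numeric(0))
      accumulate_events(events, object$roster, emotions = object$emotions,
                        raters = sprintf("rater%02d", seq_len(object$n_raters)))
    })
  }
  if (nsim == 1) one(1L) else lapply(seq_len(nsim), one)
}

#' End-to-end parameter recovery experiment
#'
#' Generates data from known ground truth, runs the full pipeline
#' (accumulate, disagreement filter, network build, degree indices) and
#' measures how faithfully the true networks are reconstructed.
#'
#' @param gt an `"emonet_truth"`.
#' @param threshold,n_boot,seed filter settings, see [filter_cells()];
#'   `seed` defaults to the truth's seed.
#' @param aggregator edge-weight aggregator, see [build_network()].
#' @return list with elements `networks` (recovered), `truth_networks`,
#'   `retention_fraction` (share of annotated cells retained), and per
#'   emotion metrics `edge_precision`, `edge_recall`, `degree_spearman`
#'   (rank correlation of true vs recovered weighted degree). Metrics over
#'   an empty truth are trivially perfect, with a warning.
#' @export
recovery_experiment <- function(gt, threshold = 0.15, n_boot = 2000,
                                seed = NULL, aggregator = "mean") {
  stopifnot(inherits(gt, "emonet_truth"))
  if (is.null(seed)) seed <- gt$seed
  set <- simulate(gt, seed = seed)
  agr <- filter_cells(set, threshold = threshold, n_boot = n_boot,
                      seed = derive_seed(seed, 7919L))
  nets <- build_network(agr, aggregator = aggregator)
  truth_nets <- lapply(gt$emotions, function(e) {
    w <- gt$weights[[e]]
    nz <- which(w > 0, arr.ind = TRUE)
    emotion_network(e, gt$roster,
                    data.frame(source = rownames(w)[nz[, 1]],
                               target = colnames(w)[nz[, 2]],
                               weight = w[nz], stringsAsFactors = FALSE))
  })
  names(truth_nets) <- gt$emotions

  v <- attr(agr, "values")
  annotated <- rowSums(v) > 0
  retention <- if (any(annotated)) mean(agr$retained[annotated]) else {
    warnf("empty ground truth: no annotated cells, metrics trivially perfect")
    1
  }
  key <- function(net) paste(net$edges$source, net$edges$target, sep = "\r")
  metrics <- lapply(gt$emotions, function(e) {
    est <- key(nets[[e]]); tru <- key(truth_nets[[e]])
    precision <- if (length(est)) mean(est %in% tru) else 1
    recall <- if (length(tru)) mean(tru %in% est) else 1
    dtru <- degree_indices(truth_nets[[e]])$weighted_degree
    dest <- degree_indices(nets[[e]])$weighted_degree
    rho <- if (stats::sd(dtru) == 0 || stats::sd(dest) == 0) {
      if (all(dtru == dest)) 1 else NA_real_
    } else stats::cor(dtru, dest, method = "spearman")
    c(edge_precision = precision, edge_recall = recall, degree_spearman = rho)
  })
  names(metrics) <- gt$emotions
  list(networks = nets, truth_networks = truth_nets,
       retention_fraction = retention,
       metrics = do.call(rbind, metrics))
}
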