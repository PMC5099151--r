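# Independent oracles used across tests. These deliberately reimplement the
# quantities under test by a different route (explicit loops, base-R aov,
# igraph) so the package code is never checked against itself.

# Brute-force pairwise IBMD: explicit double loop over observer pairs.
ibmd_oracle <- function(v) {
  m <- length(v)
  total <- 0
  npairs <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    npairs <- npairs + 1
    a <- v[i]; b <- v[j]
    if (max(a, b) > 0) total <- total + log2(abs(a - b) / max(a, b) + 1)
  }
  total / npairs
}

# ICC(A,1) via variance components extracted from a base-R two-way aov fit.
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Degree indices via an O(n^2) dense adjacency-matrix scan.
degree_oracle <- function(net) {
  ros <- as.character(net$roster)
  n <- length(ros)
  A <- matrix(0, n, n, dimnames = list(ros, ros))
  if (nrow(net$edges) > 0) {
    for (k in seq_len(nrow(net$edges))) {
      A[net$edges$source[k], net$edges$target[k]] <- net$edges$weight[k]
    }
  }
  data.frame(character = ros,
             weighted_indegree = unname(colSums(A)),
             weighted_outdegree = unname(rowSums(A)),
             weighted_degree = unname(colSums(A) + rowSums(A)),
             indegree = unname(colSums(A > 0)),
             outdegree = unname(rowSums(A > 0)),
             stringsAsFactors = FALSE)
}

# Random weighted digraph on up to n_max nodes (self-loops allowed).
random_network <- function(seed, n_max = 50, p_edge = 0.1) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  ros <- sprintf("c%02d", seq_len(n))
  pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(source = ros[pairs$s[keep]],
                      target = ros[pairs$t[keep]],
                      weight = round(stats::runif(sum(keep), 0.5, 20), 2),
                      stringsAsFactors = FALSE)
  suppressWarnings(emotion_network("test", ros, edges))
}

# Small seeded multi-rater set built through the public generator.
small_set <- function(seed = 7, n_char = 4, emotions = "joy", n_raters = 3,
                      noise_sd = 0, annotate_prob = 1, density = 0.5) {
  gt <- ground_truth(roster = roster(sprintf("ch%02d", seq_len(n_char))),
                     emotions = emotions, n_raters = n_raters,
                     density = density, noise_sd = noise_sd,
                     annotate_prob = annotate_prob, repeat_prob = 0,
                     seed = seed)
  list(gt = gt, set = simulate(gt))
}

demo_dir <- function() system.file("extdata", "demo", package = "emonet")
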