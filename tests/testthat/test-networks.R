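test_that("networks store only positive-weight edges over the fixed roster", {
  ros <- roster(c("A", "B", "C"))
  net <- emotion_network("joy", ros,
                         data.frame(source = "A", target = "B", weight = 2))
  expect_identical(as.character(net$roster), c("A", "B", "C"))
  expect_error(emotion_network("joy", ros,
                               data.frame(source = "A", target = "B", weight = 0)),
               "> 0")
  expect_error(emotion_network("joy", ros,
                               data.frame(source = "A", target = "Zed", weight = 1)),
               "not in roster")
  expect_error(emotion_network("joy", ros,
                               data.frame(source = c("A", "A"),
                                          target = c("B", "B"), weight = c(1, 2))),
               "duplicate")
})

test_that("edge weights equal the chosen aggregate of the judges' values", {
  ros <- roster(c("A", "B", "C"))
  evs <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(rater_id = sprintf("j%d", j), emotion = "joy",
               source = "A", target = "B", value = 6)
  }))
  set <- accumulate_events(evs, ros, emotions = "joy")
  agr <- filter_cells(set, n_boot = 100, seed = 2)
  for (aggr in c("mean", "median", "sum")) {
    net <- build_network(agr, aggregator = aggr)$joy
    expect_equal(nrow(net$edges), 1)
    expect_equal(net$edges$weight, if (aggr == "sum") 18 else 6)
  }
  expect_error(build_network(agr, aggregator = "mode"), "arg")
})

test_that("mean edge weights match an independent per-cell recomputation", {
  s <- small_set(seed = 31, n_char = 5, n_raters = 4, noise_sd = 0.3)$set
  agr <- filter_cells(s, n_boot = 200, seed = 8)
  net <- build_network(agr, aggregator = "mean")$joy
  v <- attr(agr, "values")
  for (k in seq_len(nrow(net$edges))) {
    i <- which(agr$emotion == "joy" & agr$source == net$edges$source[k] &
                 agr$target == net$edges$target[k])
    expect_equal(net$edges$weight[k], mean(v[i, ]))
    expect_true(agr$retained[i])
  }
  # dropped cells contribute no edge
  dropped <- agr[!agr$retained, ]
  if (nrow(dropped) > 0) {
    keys <- paste(net$edges$source, net$edges$target)
    expect_false(any(paste(dropped$source, dropped$target) %in% keys))
  }
})

test_that("degree indices match hand summation and the igraph oracle", {
  ros <- roster(c("A", "B", "C"))
  net <- emotion_network("anger", ros,
                         data.frame(source = c("A", "B", "A"),
                                    target = c("B", "A", "C"),
                                    weight = c(2, 1, 4)))
  tab <- degree_indices(net)
  expect_equal(tab$weighted_outdegree[tab$character == "A"], 6)
  expect_equal(tab$weighted_indegree[tab$character == "C"], 4)
  expect_equal(sum(tab$weighted_indegree), sum(tab$weighted_outdegree))
  expect_equal(sum(tab$weighted_indegree), 7)
  g <- as_igraph(net)
  expect_equal(tab$weighted_indegree,
               unname(igraph::strength(g, mode = "in")[tab$character]))
  expect_equal(tab$weighted_outdegree,
               unname(igraph::strength(g, mode = "out")[tab$character]))
  # empty network: everything zero, roster intact
  tab0 <- degree_indices(emotion_network("joy", ros, data.frame()))
  expect_true(all(tab0[, -1] == 0))
  expect_equal(nrow(tab0), 3)
})

test_that("adding one edge shifts exactly the sender's out and receiver's in", {
  net <- random_network(77, n_max = 12)
  before <- degree_indices(net)
  # add an edge not already present
  ros <- as.character(net$roster)
  present <- paste(net$edges$source, net$edges$target)
  cand <- expand.grid(s = ros, t = ros, stringsAsFactors = FALSE)
  cand <- cand[!paste(cand$s, cand$t) %in% present, ][1, ]
  net2 <- emotion_network(net$emotion, net$roster,
                          rbind(net$edges,
                                data.frame(source = cand$s, target = cand$t,
                                           weight = 3.5)))
  after <- degree_indices(net2)
  d_out <- after$weighted_outdegree - before$weighted_outdegree
  d_in <- after$weighted_indegree - before$weighted_indegree
  expect_equal(sum(d_out != 0), 1)
  expect_equal(d_out[after$character == cand$s], 3.5)
  expect_equal(sum(d_in != 0), 1)
  expect_equal(d_in[after$character == cand$t], 3.5)
})

test_that("self-loops count toward both in- and outdegree", {
  ros <- roster(c("A", "B"))
  net <- emotion_network("sadness", ros,
                         data.frame(source = "A", target = "A", weight = 5))
  tab <- degree_indices(net)
  a <- tab[tab$character == "A", ]
  expect_equal(a$weighted_indegree, 5)
  expect_equal(a$weighted_outdegree, 5)
  expect_equal(a$weighted_degree, 10)
})

test_that("descriptive statistics use the n-1 SD and midpoint median", {
  ros <- roster(sprintf("c%d", 1:4))
  net <- emotion_network("joy", ros,
                         data.frame(source = c("c1", "c1", "c1"),
                                    target = c("c2", "c3", "c4"),
                                    weight = c(2, 3, 4)))
  tab <- degree_indices(net)
  # indegree vector over nodes is (0, 2, 3, 4) -> check against (1,2,3,4)-style hand values
  st <- descriptive_stats(tab)
  x <- tab$weighted_indegree
  expect_equal(st["Mean", "weighted_indegree"], mean(x))
  expect_equal(st["Std. Deviation", "weighted_indegree"],
               sqrt(sum((x - mean(x))^2) / 3), tolerance = 1e-12)
  expect_equal(st["Std. Error of Mean", "weighted_indegree"],
               st["Std. Deviation", "weighted_indegree"] / 2, tolerance = 1e-12)
  expect_equal(st["Median", "weighted_indegree"], 2.5)  # midpoint of 2 and 3
  expect_equal(st["Maximum", "weighted_indegree"], 4)
  # the (1,2,3,4) reference values themselves
  expect_equal(sd(1:4), 1.2909944, tolerance = 1e-6)
  expect_equal(sd(1:4) / 2, 0.6454972, tolerance = 1e-6)
  # structural identities
  expect_equal(st["Mean", "weighted_indegree"], st["Mean", "weighted_outdegree"])
  expect_equal(st["Mean", "weighted_degree"], 2 * st["Mean", "weighted_indegree"])
})

test_that("degenerate stats: single character reports SD 0 with a warning", {
  net <- emotion_network("joy", roster("A"), data.frame())
  tab <- degree_indices(net)
  expect_warning(st <- descriptive_stats(tab), "SD undefined")
  expect_equal(st["Mean", "weighted_degree"], 0)
  expect_equal(st["Std. Deviation", "weighted_degree"], 0)
})

test_that("in/out correlation behaves at the exact and degenerate limits", {
  ros <- roster(c("A", "B", "C"))
  # reciprocal edges give every node identical in and out -> r = 1
  recip <- emotion_network("joy", ros,
                           data.frame(source = c("A", "B", "B", "C"),
                                      target = c("B", "A", "C", "B"),
                                      weight = c(1, 1, 2, 2)))
  tab <- degree_indices(recip)
  expect_equal(tab$weighted_indegree, tab$weighted_outdegree)
  expect_equal(in_out_correlation(tab, "pearson"), 1)
  expect_equal(in_out_correlation(tab, "spearman"), 1)
  # perfect anti-correlation, hand-built table
  anti <- structure(data.frame(character = c("A", "B", "C"),
                               weighted_indegree = c(1, 2, 3),
                               weighted_outdegree = c(3, 2, 1),
                               weighted_degree = 4, indegree = 1, outdegree = 1),
                    emotion = "joy",
                    class = c("centrality_table", "data.frame"))
  expect_equal(in_out_correlation(anti), -1)
  # zero variance -> NA with warning
  flat <- degree_indices(emotion_network("joy", ros, data.frame()))
  expect_warning(r <- in_out_correlation(flat), "zero variance")
  expect_true(is.na(r))
  # seeded network vs the textbook formula
  net <- random_network(13, n_max = 20)
  t2 <- degree_indices(net)
  x <- t2$weighted_indegree; y <- t2$weighted_outdegree
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(in_out_correlation(t2), r_hand, tolerance = 1e-12)
})

test_that("top-k ranking is value-descending with roster-order tie-break", {
  ros <- roster(c("Zed", "A", "B", "C"))
  net <- emotion_network("joy", ros,
                         data.frame(source = c("A", "B", "C"),
                                    target = c("Zed", "Zed", "A"),
                                    weight = c(5, 5, 5)))
  tab <- degree_indices(net)
  top <- top_characters(tab, "weighted_outdegree", k = 3)
  expect_equal(top$character, c("A", "B", "C"))  # tie at 5 -> roster order
  expect_equal(nrow(top_characters(tab, k = 10)), 4)  # k truncated to roster
  expect_error(top_characters(tab, by = "nope"), "unknown index")
})

test_that("unweighted degree equals weighted degree on a unit-weight copy", {
  for (seed in c(5, 6)) {
    net <- random_network(seed, n_max = 25)
    ed <- net$edges
    ed$weight <- rep(1, nrow(ed))
    unit <- emotion_network(net$emotion, net$roster, ed)
    tab <- degree_indices(net)
    tabu <- degree_indices(unit)
    expect_equal(tab$indegree, tabu$weighted_indegree)
    expect_equal(tab$outdegree, tabu$weighted_outdegree)
  }
})
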