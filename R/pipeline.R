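#' Run the full pipeline and write the output bundle
#'
#' Reads a multi-rater annotation data set (a directory of per-rater square
#' matrix CSVs named `<rater>__<emotion>.csv`, or one long-format event CSV
#' plus a roster), fits [emonet()], and writes the analysis bundle:
#' agreement report (JSON), pairwise judge ICC (CSV matrix), per-emotion
#' networks (GraphML/GEXF with visual encodings), ranked centrality tables,
#' descriptive statistics, and in/out correlations. Every file embeds the
#' run configuration (threshold, n_boot, seed, aggregator), and re-running
#' with the same inputs and configuration reproduces every file
#' byte-for-byte.
#'
#' @param input directory of matrix CSVs, or path of a long-format CSV.
#' @param out_dir output directory (created if needed).
#' @param roster roster labels or path to a one-name-per-line text file;
#'   required for long-format input, ignored for matrix directories (the
#'   matrices carry their roster).
#' @param threshold,n_boot,seed,aggregator,top_k see [emonet()].
#' @param emotions restrict/declare the emotion set (default: inferred).
#' @param formats network export formats (subset of graphml/gexf/dot).
#' @return the `"emonet"` fit, invisibly.
#' @export
run_pipeline <- function(input, out_dir, roster = NULL,
                         threshold = 0.15, n_boot = 2000, seed,
                         aggregator = "mean", top_k = 10, emotions = NULL,
                         formats = c("graphml", "gexf")) {
  set <- read_input(input, roster = roster, emotions = emotions)
  fit <- emonet(set, threshold = threshold, n_boot = n_boot, seed = seed,
                aggregator = aggregator, top_k = top_k)
  write_bundle(fit, out_dir, formats = formats)
  invisible(fit)
}

# Resolve either input layout into a rater_matrix_set.
read_input <- function(input, roster = NULL, emotions = NULL) {
  if (dir.exists(input)) {
    files <- sort(list.files(input, pattern = "__.*\\.csv$", full.names = TRUE))
    files <- files[!grepl("ground_truth", files)]
    if (length(files) == 0) stopf("no '<rater>__<emotion>.csv' matrices in %s", input)
    mats <- lapply(files, function(f) {
      parts <- strsplit(sub("\\.csv$", "", basename(f)), "__", fixed = TRUE)[[1]]
      if (length(parts) != 2) stopf("cannot parse rater/emotion from %s", basename(f))
      read_matrix_csv(f, rater_id = parts[1], emotion = parts[2])
    })
    return(rater_matrix_set(mats))
  }
  if (!file.exists(input)) stopf("input not found: %s", input)
  if (is.null(roster)) stopf("long-format input requires a roster")
  ros <- if (length(roster) == 1 && file.exists(roster)) {
    roster(readLines(roster, encoding = "UTF-8"))
  } else as_roster(roster)
  accumulate_events(read_long_csv(input), ros, emotions = emotions)
}

#' Write the per-rater matrices of a set to a directory
#'
#' One canonical CSV per (rater, emotion), named `<rater>__<emotion>.csv` —
#' the directory layout [run_pipeline()] reads back.
#'
#' @param set a [rater_matrix_set()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(set, dir) {
  stopifnot(inherits(set, "rater_matrix_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in set$raters) for (e in set$emotions) {
    write_matrix_csv(set$matrices[[r]][[e]],
                     file.path(dir, sprintf("%s__%s.csv", r, e)))
  }
  invisible(dir)
}

config_header <- function(config) {
  sprintf("# %s", paste(sprintf("%s=%s", names(config),
                                vapply(config, function(v) as.character(v)[1],
                                       character(1))),
                        collapse = " "))
}

write_csv_with_config <- function(df, path, config) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(config_header(config), con, useBytes = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Write the full analysis bundle for a fit.
write_bundle <- function(fit, out_dir, formats = c("graphml", "gexf")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fit$config
  # agreement report
  agr <- as.data.frame(fit$agreement)
  jsonlite::write_json(
    list(metadata = c(cfg, list(conf = attr(fit$agreement, "conf"),
                                icc_form = "ICC(A,1)",
                                raters = as.list(fit$raters))),
         cells = agr),
    file.path(out_dir, "agreement.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # pairwise ICC matrix
  if (!is.null(fit$icc)) {
    m <- fit$icc
    icc_df <- data.frame(rater = rownames(m), as.data.frame(unclass(m)),
                         check.names = FALSE)
    write_csv_with_config(icc_df, file.path(out_dir, "icc.csv"), cfg)
  }
  # networks + centrality per emotion
  for (e in names(fit$networks)) {
    for (fmt in formats) {
      export_styled(fit$networks[[e]],
                    file.path(out_dir, sprintf("network_%s.%s", e, fmt)),
                    format = fmt, config = cfg)
    }
    tab <- as.data.frame(fit$centrality[[e]])
    ord <- order(-tab$weighted_degree, seq_len(nrow(tab)))
    write_csv_with_config(tab[ord, ],
                          file.path(out_dir, sprintf("centrality_%s.csv", e)),
                          cfg)
    write_csv_with_config(
      fit$networks[[e]]$edges,
      file.path(out_dir, sprintf("edges_%s.csv", e)), cfg)
  }
  # descriptive statistics, long layout
  stats_long <- do.call(rbind, lapply(names(fit$stats), function(e) {
    m <- fit$stats[[e]]
    data.frame(emotion = e,
               statistic = rep(rownames(m), times = ncol(m)),
               index = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  write_csv_with_config(stats_long, file.path(out_dir, "stats.csv"), cfg)
  cor_df <- data.frame(emotion = rownames(fit$correlations),
                       as.data.frame(fit$correlations))
  write_csv_with_config(cor_df, file.path(out_dir, "correlations.csv"), cfg)
  invisible(out_dir)
}

#' Write simulated data plus its ground truth
#'
#' Companion to [ground_truth()]/[simulate()]: writes the per-rater matrix
#' CSVs and a `ground_truth.json` sidecar holding the latent weights and
#' generator settings.
#'
#' @param gt an `"emonet_truth"`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(gt, dir) {
  stopifnot(inherits(gt, "emonet_truth"))
  set <- simulate(gt)
  write_matrix_dir(set, dir)
  jsonlite::write_json(
    list(roster = as.character(gt$roster), emotions = gt$emotions,
         n_raters = gt$n_raters, density = gt$density,
         noise_sd = gt$noise_sd, annotate_prob = gt$annotate_prob,
         repeat_prob = gt$repeat_prob, seed = gt$seed,
         weights = lapply(gt$weights, function(w) unclass(w))),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
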