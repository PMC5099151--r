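#' Character roster
#'
#' The roster is the fixed, ordered set of characters being annotated. Its
#' order defines matrix row/column order everywhere in the package; events
#' referencing names outside the roster are rejected rather than silently
#' added, so typos in character names surface as errors.
#'
#' @param names character vector of character labels (e.g. `"Vincent Vega"`,
#'   `"Others"`). Whitespace is trimmed and internal runs collapsed; labels
#'   must be unique and non-empty after normalization.
#' @return a character vector of class `"character_roster"`.
#' @examples
#' roster(c("Vincent Vega", "Butch Coolidge", "Others"))
#' @export
roster <- function(names) {
  nm <- normalize_labels(names)
  if (length(nm) == 0) stopf("roster must contain at least one character")
  if (any(nm == "")) stopf("roster labels must be non-empty")
  if (anyDuplicated(nm)) {
    stopf("duplicate character label(s) after normalization: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(nm, class = "character_roster")
}

#' @export
print.character_roster <- function(x, ...) {
  cat("Character roster (", length(x), " characters):\n", sep = "")
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' Single-rater emotion matrix
#'
#' One judge's accumulated annotation matrix for one emotion. Rows index the
#' sender ("from"), columns the receiver ("to"): cell `[s, t]` holds the sum
#' of all Likert values this rater entered for emotion flowing from character
#' `s` to character `t`. A cell of 0 means the pair was never annotated /
#' no perceived emotional interaction; accumulated values may exceed the
#' per-annotation Likert ceiling of 10.
#'
#' @param mat numeric matrix, square, non-negative, with dimnames equal to
#'   the roster in roster order (or unnamed, in which case roster names are
#'   applied).
#' @param rater_id identifier of the judge.
#' @param emotion emotion label (e.g. `"anger"`).
#' @param roster a [roster()] object (or character vector coerced to one).
#' @return a numeric matrix of class `"rater_matrix"` with attributes
#'   `rater_id` and `emotion`.
#' @export
rater_matrix <- function(mat, rater_id, emotion, roster) {
  roster <- as_roster(roster)
  n <- length(roster)
  mat <- as.matrix(mat)
  if (nrow(mat) != n || ncol(mat) != n) {
    stopf("matrix is %dx%d but roster has %d characters",
          nrow(mat), ncol(mat), n)
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stopf("matrix contains NA cells")
  if (any(mat < 0)) stopf("negative cell values are not allowed")
  if (!is.null(dimnames(mat))) {
    rn <- normalize_labels(rownames(mat))
    cn <- normalize_labels(colnames(mat))
    if (!identical(rn, as.character(roster)) ||
        !identical(cn, as.character(roster))) {
      stopf("matrix dimnames do not match the roster (order included)")
    }
  }
  dimnames(mat) <- list(as.character(roster), as.character(roster))
  if (any(diag(mat) > 0)) {
    warnf("rater '%s', emotion '%s': nonzero diagonal (self-directed emotion) retained",
          rater_id, emotion)
  }
  structure(mat,
            rater_id = as.character(rater_id),
            emotion = normalize_labels(emotion),
            roster = roster,
            class = c("rater_matrix", "matrix", "array"))
}

as_roster <- function(x) {
  if (inherits(x, "character_roster")) x else roster(x)
}

#' @export
print.rater_matrix <- function(x, ...) {
  cat(sprintf("Rater matrix: rater '%s', emotion '%s' (%d characters, %d annotated cells)\n",
              attr(x, "rater_id"), attr(x, "emotion"),
              nrow(x), sum(x > 0)))
  m <- x
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(m, ...)
  invisible(x)
}

#' Read a square annotation matrix from CSV
#'
#' Parses the matrix layout used for annotation: character names repeated in
#' both the first row and the first column, cell `[i, j]` holding the
#' accumulated value from character `i` (sender) to character `j` (receiver).
#' Empty cells mean "never annotated" and map to 0.
#'
#' @param path path to a UTF-8, comma-delimited CSV file.
#' @param rater_id,emotion identifiers attached to the resulting matrix.
#' @return a [rater_matrix()] whose roster order equals the file order.
#' @seealso [write_matrix_csv()] for the canonical writer.
#' @export
read_matrix_csv <- function(path, rater_id, emotion) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stopf("%s: not a square matrix CSV (needs a label column)", path)
  row_labels <- normalize_labels(df[[1]])
  col_labels <- normalize_labels(names(df)[-1])
  if (length(row_labels) != length(col_labels)) {
    stopf("%s: non-square layout (%d rows vs %d columns)",
          path, length(row_labels), length(col_labels))
  }
  if (!identical(row_labels, col_labels)) {
    stopf("%s: row labels do not match column labels", path)
  }
  ros <- roster(row_labels)  # errors on duplicates / empties
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells == ""] <- "0"
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) stopf("%s: non-numeric cell value(s)", path)
  if (any(num < 0)) stopf("%s: negative cell value(s)", path)
  rater_matrix(num, rater_id = rater_id, emotion = emotion, roster = ros)
}

#' Write a square annotation matrix as CSV
#'
#' Canonical dialect: roster order, zeros written as empty cells, integers
#' without decimal point, minimal quoting. Reading a file written by this
#' function and writing it again is byte-identical.
#'
#' @param x a [rater_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  stopifnot(inherits(x, "rater_matrix"))
  ros <- rownames(x)
  quote_csv <- function(s) {
    needs <- grepl('[",\n]', s)
    s[needs] <- paste0('"', gsub('"', '""', s[needs]), '"')
    s
  }
  header <- paste(c("", quote_csv(ros)), collapse = ",")
  rows <- vapply(seq_along(ros), function(i) {
    vals <- fmt_num(x[i, ])
    vals[x[i, ] == 0] <- ""
    paste(c(quote_csv(ros[i]), vals), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Multi-rater, multi-emotion matrix set
#'
#' Container holding one [rater_matrix()] per (rater, emotion) combination,
#' all sharing one roster. This is the unit the agreement filter and network
#' builder consume.
#'
#' @param matrices list of [rater_matrix()] objects covering every
#'   (rater, emotion) combination exactly once, all on the same roster.
#' @return an object of class `"rater_matrix_set"`: a list with elements
#'   `roster`, `raters`, `emotions` and `matrices` (nested list indexed as
#'   `matrices[[rater]][[emotion]]`).
#' @export
rater_matrix_set <- function(matrices) {
  if (length(matrices) == 0) stopf("need at least one rater matrix")
  ros <- attr(matrices[[1]], "roster")
  raters <- unique(vapply(matrices, attr, character(1), "rater_id"))
  emotions <- unique(vapply(matrices, attr, character(1), "emotion"))
  seen <- character(0)
  nested <- stats::setNames(
    lapply(raters, function(r) stats::setNames(vector("list", length(emotions)), emotions)),
    raters)
  for (m in matrices) {
    if (!identical(as.character(attr(m, "roster")), as.character(ros))) {
      stopf("all matrices must share an identical roster")
    }
    key <- paste(attr(m, "rater_id"), attr(m, "emotion"), sep = "\r")
    if (key %in% seen) {
      stopf("duplicate matrix for rater '%s', emotion '%s'",
            attr(m, "rater_id"), attr(m, "emotion"))
    }
    seen <- c(seen, key)
    nested[[attr(m, "rater_id")]][[attr(m, "emotion")]] <- m
  }
  # materialize any missing (rater, emotion) combination as all-zero
  for (r in raters) for (e in emotions) {
    if (is.null(nested[[r]][[e]])) {
      zero <- matrix(0, length(ros), length(ros))
      nested[[r]][[e]] <- rater_matrix(zero, r, e, ros)
    }
  }
  structure(list(roster = ros, raters = raters, emotions = emotions,
                 matrices = nested),
            class = "rater_matrix_set")
}

#' @export
print.rater_matrix_set <- function(x, ...) {
  cat(sprintf("Rater matrix set: %d raters x %d emotions, %d characters\n",
              length(x$raters), length(x$emotions), length(x$roster)))
  cat("  raters:  ", paste(x$raters, collapse = ", "), "\n")
  cat("  emotions:", paste(x$emotions, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one matrix from a set
#' @param set a [rater_matrix_set()].
#' @param rater,emotion identifiers of the matrix wanted.
#' @return the [rater_matrix()].
#' @export
get_matrix <- function(set, rater, emotion) {
  stopifnot(inherits(set, "rater_matrix_set"))
  m <- set$matrices[[as.character(rater)]][[normalize_labels(emotion)]]
  if (is.null(m)) stopf("no matrix for rater '%s', emotion '%s'", rater, emotion)
  m
}

default_emotions <- function() c("anger", "fear", "joy", "sadness")

#' Accumulate annotation events into matrices
#'
#' Applies the within-rater additive rule: every time a rater re-annotates
#' the same directed character pair for the same emotion, the new Likert
#' value is added to the cell, strengthening the link. Cell values therefore
#' equal the sum of that cell's event values, independent of event order.
#'
#' @param events data.frame with columns `rater_id`, `emotion`, `source`,
#'   `target`, `value` (and optionally `order_index`, ignored for sums since
#'   addition is order-invariant). Each `value` must lie in the Likert range
#'   \[1, 10\]; `source`/`target` must be roster members.
#' @param roster a [roster()] (or character vector).
#' @param emotions emotion labels whose matrices must exist even without
#'   events. Defaults to emotions present in `events`, or to
#'   anger/fear/joy/sadness when `events` is empty.
#' @param raters rater ids whose matrices must exist even without events;
#'   defaults to the raters present in `events`.
#' @return a [rater_matrix_set()]; missing (rater, emotion) combinations are
#'   all-zero matrices.
#' @examples
#' ros <- roster(c("Vincent Vega", "Butch Coolidge"))
#' ev <- data.frame(rater_id = "j1", emotion = "fear",
#'                  source = "Vincent Vega", target = "Butch Coolidge",
#'                  value = c(3, 4))
#' set <- accumulate_events(ev, ros)
#' get_matrix(set, "j1", "fear")["Vincent Vega", "Butch Coolidge"]  # 7
#' @export
accumulate_events <- function(events, roster, emotions = NULL, raters = NULL) {
  ros <- as_roster(roster)
  n <- length(ros)
  events <- as.data.frame(events)
  required <- c("rater_id", "emotion", "source", "target", "value")
  if (nrow(events) > 0 && !all(required %in% names(events))) {
    stopf("events must have columns: %s", paste(required, collapse = ", "))
  }
  if (nrow(events) > 0) {
    events$source <- normalize_labels(events$source)
    events$target <- normalize_labels(events$target)
    events$emotion <- normalize_labels(events$emotion)
    events$rater_id <- as.character(events$rater_id)
    bad <- setdiff(unique(c(events$source, events$target)), as.character(ros))
    if (length(bad) > 0) {
      stopf("unknown character(s) not in roster: %s", paste(bad, collapse = ", "))
    }
    if (any(!is.finite(events$value) | events$value < 1 | events$value > 10)) {
      stopf("event values must lie in the Likert range [1, 10]")
    }
  }
  emotions <- if (is.null(emotions)) {
    if (nrow(events) > 0) unique(events$emotion) else default_emotions()
  } else normalize_labels(emotions)
  raters <- if (is.null(raters)) {
    if (nrow(events) > 0) unique(events$rater_id) else "rater1"
  } else as.character(raters)
  if (nrow(events) > 0) {
    emotions <- union(emotions, unique(events$emotion))
    raters <- union(raters, unique(events$rater_id))
  }

  mats <- list()
  for (r in raters) for (e in emotions) {
    m <- matrix(0, n, n, dimnames = list(as.character(ros), as.character(ros)))
    if (nrow(events) > 0) {
      sel <- events$rater_id == r & events$emotion == e
      if (any(sel)) {
        idx <- cbind(match(events$source[sel], as.character(ros)),
                     match(events$target[sel], as.character(ros)))
        sums <- tapply(events$value[sel],
                       paste(idx[, 1], idx[, 2], sep = "\r"), sum)
        pos <- do.call(rbind, lapply(strsplit(names(sums), "\r"), as.integer))
        m[pos] <- as.numeric(sums)
      }
    }
    mats[[length(mats) + 1]] <- rater_matrix(m, r, e, ros)
  }
  rater_matrix_set(mats)
}

#' Export a matrix set to long format
#'
#' Emits one row per nonzero cell with columns `rater_id`, `emotion`,
#' `source`, `target`, `value`, `order_index`. Accumulated cell values above
#' the single-annotation ceiling of 10 are split into several events (full
#' chunks of 10 plus a remainder) so that every emitted event respects the
#' Likert bounds and re-accumulation reproduces the set cell-for-cell.
#' Integer-valued cells round-trip exactly; non-integral values above 10 use
#' a near-equal split, exact to floating-point addition.
#'
#' @param set a [rater_matrix_set()].
#' @return data.frame of annotation events (empty for an all-zero set).
#' @export
to_long_format <- function(set) {
  stopifnot(inherits(set, "rater_matrix_set"))
  out <- list()
  for (r in set$raters) for (e in set$emotions) {
    m <- set$matrices[[r]][[e]]
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    for (k in seq_len(nrow(nz))) {
      v <- m[nz[k, 1], nz[k, 2]]
      chunks <- split_likert(v)
      out[[length(out) + 1]] <- data.frame(
        rater_id = r, emotion = e,
        source = rownames(m)[nz[k, 1]],
        target = colnames(m)[nz[k, 2]],
        value = chunks, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(rater_id = character(0), emotion = character(0),
                      source = character(0), target = character(0),
                      value = numeric(0), order_index = integer(0)))
  }
  res <- do.call(rbind, out)
  res$order_index <- seq_len(nrow(res)) - 1L
  rownames(res) <- NULL
  res
}

# Split an accumulated cell value into Likert-legal [1,10] event values
# summing back to v.
split_likert <- function(v) {
  if (v <= 10) return(v)
  if (v == round(v)) {
    k <- v %/% 10
    r <- v - 10 * k
    if (r == 0) rep(10, k) else c(rep(10, k), r)
  } else {
    k <- ceiling(v / 10)
    base <- v / k
    c(rep(base, k - 1), v - base * (k - 1))
  }
}

#' Read / write long-format annotation CSV
#'
#' Long format is the tidy event stream: columns `rater_id`, `emotion`,
#' `source`, `target`, `value`, `order_index`.
#'
#' @param path CSV file path.
#' @return `read_long_csv`: a data.frame of events.
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("rater_id", "emotion", "source", "target", "value")
  if (!all(required %in% names(df))) {
    stopf("%s: long-format CSV needs columns %s", path,
          paste(required, collapse = ", "))
  }
  df
}

#' @param events data.frame of annotation events.
#' @rdname read_long_csv
#' @export
write_long_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
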