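# Human-readable reporting: the Table-2-shaped accuracy matrix
# ("mean +- sd" in percent, families x classifiers by band), per-subject
# maxima, ranking summaries and grid file round-tripping.

#' Format the aggregate grid as a band-by-band accuracy table
#'
#' @param grid an `evaluation_grid`.
#' @param digits decimals for the percentage strings.
#' @return data.frame with `family`, `classifier` and one "mean ± sd"
#'   percent column per band (sd blank when only one subject).
#' @export
format_grid <- function(grid, digits = 2) {
  agg <- grid$aggregate
  bands <- unique(agg$band)
  fams <- unique(agg$family)
  cls <- unique(agg$classifier)
  out <- expand.grid(classifier = cls, family = fams,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  for (bn in bands) {
    col <- character(nrow(out))
    for (i in seq_len(nrow(out))) {
      r <- agg[agg$family == out$family[i] & agg$band == bn &
                 agg$classifier == out$classifier[i], ]
      col[i] <- if (!nrow(r)) NA_character_
      else if (is.na(r$sd_accuracy))
        sprintf("%.*f", digits, 100 * r$mean_accuracy)
      else sprintf("%.*f ± %.*f", digits, 100 * r$mean_accuracy,
                   digits, 100 * r$sd_accuracy)
    }
    out[[bn]] <- col
  }
  out
}

#' Rank classifiers and bands by aggregate accuracy
#'
#' @param grid an `evaluation_grid`.
#' @return list with `classifier_ranking` and `band_ranking` (data.frames,
#'   best first) and `text` (printable summary lines).
#' @export
summarize_grid <- function(grid) {
  agg <- grid$aggregate
  rank_by <- function(axis) {
    m <- tapply(agg$mean_accuracy, agg[[axis]], mean)
    data.frame(level = names(m), mean_accuracy = as.numeric(m),
               stringsAsFactors = FALSE)[order(-m), ]
  }
  cr <- rank_by("classifier")
  br <- rank_by("band")
  text <- c(
    paste("classifier ranking:",
          paste(sprintf("%s (%.1f%%)", cr$level, 100 * cr$mean_accuracy),
                collapse = " > ")),
    paste("band ranking:",
          paste(sprintf("%s (%.1f%%)", br$level, 100 * br$mean_accuracy),
                collapse = " > ")))
  list(classifier_ranking = cr, band_ranking = br, text = text)
}

#' Write an evaluation grid to disk
#'
#' Writes `<prefix>_table.tsv` (the formatted Table-2-style matrix),
#' `<prefix>_cells.tsv` (per-subject numeric cells) and
#' `<prefix>_folds.tsv` (long format, one row per fold accuracy).
#'
#' @param grid an `evaluation_grid`.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_grid <- function(grid, prefix) {
  p1 <- paste0(prefix, "_table.tsv")
  p2 <- paste0(prefix, "_cells.tsv")
  p3 <- paste0(prefix, "_folds.tsv")
  write.table(format_grid(grid), p1, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  num <- grid$cells[, c("subject_id", "family", "band", "classifier",
                        "mean_accuracy", "sd_accuracy", "n_test",
                        "n_dropped")]
  write.table(num, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- do.call(rbind, lapply(seq_len(nrow(grid$cells)), function(i) {
    fa <- grid$cells$fold_accuracy[[i]]
    data.frame(subject_id = grid$cells$subject_id[i],
               family = grid$cells$family[i], band = grid$cells$band[i],
               classifier = grid$cells$classifier[i],
               fold = seq_along(fa), accuracy = fa,
               stringsAsFactors = FALSE)
  }))
  write.table(folds, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read an evaluation grid written by [write_grid()]
#'
#' Reconstructs the per-subject cells and fold accuracies and recomputes
#' the cross-subject aggregate (confusion matrices are not persisted).
#'
#' @param prefix the path prefix used by [write_grid()].
#' @return an `evaluation_grid`.
#' @export
read_grid <- function(prefix) {
  cells <- read.delim(paste0(prefix, "_cells.tsv"),
                      stringsAsFactors = FALSE)
  folds <- read.delim(paste0(prefix, "_folds.tsv"),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$family, d$band, d$classifier)
  fsplit <- split(folds$accuracy, key(folds))
  cells$fold_accuracy <- I(unname(fsplit[key(cells)]))
  structure(list(cells = cells, aggregate = .aggregate_cells(cells),
                 protocol = NA_character_, n_folds = NA_integer_,
                 seed = NA_integer_, sd_axis = "subjects"),
            class = "evaluation_grid")
}

#' Render a report from a grid (or a written grid prefix)
#'
#' @param grid an `evaluation_grid` or a path prefix readable by
#'   [read_grid()].
#' @return list with `table` (formatted matrix), `best_by_classifier`,
#'   `best_by_family` (per-subject maxima) and `summary` lines; printed to
#'   the console.
#' @export
render_report <- function(grid) {
  if (is.character(grid)) grid <- read_grid(grid)
  tab <- format_grid(grid)
  s <- summarize_grid(grid)
  out <- list(table = tab,
              best_by_classifier = best_per_subject(grid, "classifier"),
              best_by_family = best_per_subject(grid, "family"),
              summary = s$text)
  cat(paste(s$text, collapse = "\n"), "\n")
  invisible(out)
}

#' Plot aggregate accuracy by band and classifier
#'
#' @param grid an `evaluation_grid`.
#' @param family feature family to plot.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_grid_accuracy <- function(grid, family = "DE") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_grid_accuracy requires ggplot2")
  agg <- grid$aggregate[grid$aggregate$family == family, ]
  agg$band <- factor(agg$band, levels = unique(grid$aggregate$band))
  agg$accuracy_pct <- 100 * agg$mean_accuracy
  ggplot2::ggplot(agg, ggplot2::aes(x = band, y = accuracy_pct,
                                    fill = classifier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = paste(family, "decoding accuracy by band")) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("band", "accuracy_pct", "classifier"))
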