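# Gaze / annotation interval files: tab-separated onset, offset, label with
# a header line. Times are seconds from recording start, half-open
# [onset, offset) semantics.

#' Read an interval annotation file
#'
#' Intervals are sorted by onset and overlapping (or touching) intervals
#' with the same label are merged, so the returned set is disjoint within
#' each label.
#'
#' @param path tab-separated file with columns `onset`, `offset`, `label`.
#' @return data.frame with columns `onset`, `offset` (seconds) and `label`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path))
    stop_thetamod(sprintf("file not found: %s", path), "thetamod_io_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("onset", "offset", "label"), names(tab))
  if (length(missing_cols))
    stop_thetamod(paste0("interval file missing column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "thetamod_format_error")
  if (!nrow(tab))
    return(data.frame(onset = numeric(), offset = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  bad <- which(!(tab$onset >= 0 & tab$offset > tab$onset))
  if (length(bad))
    stop_thetamod(sprintf(
      "invalid interval at line %d: onset %g, offset %g (need 0 <= onset < offset)",
      bad[1] + 1L, tab$onset[bad[1]], tab$offset[bad[1]]),
      "thetamod_validation_error")
  merge_intervals(tab[c("onset", "offset", "label")])
}

#' Merge overlapping same-label intervals
#' @param intervals data.frame with `onset`, `offset`, `label`.
#' @return sorted, disjoint-per-label data.frame.
#' @export
merge_intervals <- function(intervals) {
  out <- do.call(rbind, lapply(split(intervals, intervals$label), function(g) {
    g <- g[order(g$onset), , drop = FALSE]
    on <- g$onset[1]; off <- g$offset[1]
    res <- list()
    for (i in seq_len(nrow(g))[-1]) {
      if (g$onset[i] <= off) {
        off <- max(off, g$offset[i])
      } else {
        res[[length(res) + 1]] <- c(on, off)
        on <- g$onset[i]; off <- g$offset[i]
      }
    }
    res[[length(res) + 1]] <- c(on, off)
    m <- do.call(rbind, res)
    data.frame(onset = m[, 1], offset = m[, 2], label = g$label[1],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interval annotation file
#' @param intervals data.frame with `onset`, `offset`, `label`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals[c("onset", "offset", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
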