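## Behavior durations and paired tests ------------------------------------

#' Aggregate frame labels into per-behavior durations
#'
#' @param frame_labels data.frame (frame_index, behavior, label) with one
#'   logical/0-1 label per frame per behavior, or a path to such a CSV.
#' @param fps frames per second (default 30).
#' @param expected_frames session length check (default 18000 = 10 min at
#'   30 fps); a mismatch warns but proceeds.
#' @return data.frame (behavior, seconds).
#' @export
total_time <- function(frame_labels, fps = 30, expected_frames = 18000) {
  if (is.character(frame_labels))
    frame_labels <- read.csv(frame_labels, stringsAsFactors = FALSE)
  nf <- length(unique(frame_labels$frame_index))
  if (!is.null(expected_frames) && nf != expected_frames)
    warnf("session has %d frames, expected %d", nf, expected_frames)
  agg <- tapply(as.logical(frame_labels$label), frame_labels$behavior, sum)
  data.frame(behavior = names(agg), seconds = as.numeric(agg) / fps,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired Wilcoxon tests per behavior
#'
#' Two-tailed exact Wilcoxon signed-rank on the paired ctrl/TBS durations of
#' each behavior.
#'
#' @param behavior_table data.frame (mouse_id, behavior, condition, seconds)
#'   as from [simulate_behavior()].
#' @return data.frame (behavior, n_pairs, W, p, exact).
#' @export
behavior_compare <- function(behavior_table) {
  behaviors <- unique(behavior_table$behavior)
  rows <- lapply(behaviors, function(b) {
    sub <- behavior_table[behavior_table$behavior == b, ]
    wide <- stats::reshape(sub[, c("mouse_id", "condition", "seconds")],
                           idvar = "mouse_id", timevar = "condition",
                           direction = "wide")
    wr <- wilcoxon_exact(wide$seconds.ctrl, wide$seconds.TBS)
    data.frame(behavior = b, n_pairs = wr$n_pairs, W = wr$W, p = wr$p,
               exact = wr$exact, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
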