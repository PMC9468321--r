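# Suture-cycle segmentation. Event detection itself is upstream (vision);
# this module trusts the per-stitch annotations and partitions the timeline.

#' Partition annotated stitches into suture cycles
#'
#' Active suturing time runs from needle entry to complete needle removal;
#' idle time runs from one stitch's pull-out to the next stitch's entry. The
#' last stitch has no idle interval. All intervals are half-open.
#'
#' @param stitches A [stitch_annotations()] table.
#' @return List of `suture_cycle` objects, each with `stitch_index`,
#'   `active = c(start, end)` and `idle = c(start, end)` or `NULL`.
#' @export
partition_cycles <- function(stitches) {
  stitches <- stitch_annotations(stitches)
  n <- nrow(stitches)
  lapply(seq_len(n), function(k) {
    structure(list(
      stitch_index = stitches$stitch_index[k],
      active = c(stitches$t_entry[k], stitches$t_pullout[k]),
      idle = if (k < n) c(stitches$t_pullout[k], stitches$t_entry[k + 1L])
    ), class = "suture_cycle")
  })
}

#' Label the phases of one active suturing time
#'
#' With only the three stored events (entry, needle-tip exit, pull-out
#' complete) the four conceptual phases (entry, driving, exit, pull-out)
#' cannot all be reconstructed, so a three-segment labeling is exposed:
#' entry+driving = \[t_entry, t_exit), exit = \[t_exit, t_thread) when a
#' thread-entry time is annotated or \[t_exit, midpoint(t_exit, t_pullout))
#' otherwise, and pull-out = the remainder. The labels are descriptive
#' metadata only; no metric depends on them.
#'
#' @param cycle A cycle from [partition_cycles()].
#' @param ann The matching single-row annotation.
#' @return data.frame with columns `phase`, `t_start`, `t_end`.
#' @export
label_phases <- function(cycle, ann) {
  if (!inherits(cycle, "suture_cycle"))
    abort_validation("label_phases expects a suture_cycle")
  ann <- as.data.frame(ann)
  if (!"t_thread" %in% names(ann)) ann$t_thread <- NA_real_
  if (nrow(ann) != 1L || ann$stitch_index != cycle$stitch_index ||
      abs(ann$t_entry - cycle$active[1L]) > 1e-9 ||
      abs(ann$t_pullout - cycle$active[2L]) > 1e-9)
    abort_validation("annotation does not match cycle for stitch %d",
                     cycle$stitch_index)
  if (!(ann$t_entry < ann$t_exit && ann$t_exit < ann$t_pullout))
    abort_validation("degenerate annotation for stitch %d", ann$stitch_index)
  exit_end <- if (!is.na(ann$t_thread)) ann$t_thread
              else (ann$t_exit + ann$t_pullout) / 2
  data.frame(phase = c("entry_driving", "exit", "pull_out"),
             t_start = c(ann$t_entry, ann$t_exit, exit_end),
             t_end = c(ann$t_exit, exit_end, ann$t_pullout))
}

#' Cycles of a session
#' @param s A [suture_session()].
#' @return As [partition_cycles()].
#' @export
session_cycles <- function(s) partition_cycles(validate_session(s)$stitches)
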