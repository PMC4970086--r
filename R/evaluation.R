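# Sensitivity/specificity of the accept decision and pre/post-QC accuracy
# tables. Sensitivity is defined on good segments only (fraction accepted)
# and specificity on bad segments only (fraction rejected); tolerable
# segments enter neither metric.

#' Confusion counts of the accept decision per quality category
#'
#' @param labels Quality labels (`good`/`tolerable`/`bad`).
#' @param accepted Logical accept decisions, same length.
#' @return Object of class `confusion_counts` with per-category totals and
#'   accepted counts.
#' @export
confusion_counts <- function(labels, accepted) {
  labels <- factor(as.character(labels), levels = c("good", "tolerable", "bad"))
  if (anyNA(labels)) stop("labels must be good, tolerable or bad")
  accepted <- as.logical(accepted)
  if (length(labels) != length(accepted)) stop("labels and decisions differ in length")
  structure(list(
    n_good = sum(labels == "good"),
    n_tolerable = sum(labels == "tolerable"),
    n_bad = sum(labels == "bad"),
    n_accepted_good = sum(accepted & labels == "good"),
    n_accepted_tolerable = sum(accepted & labels == "tolerable"),
    n_accepted_bad = sum(accepted & labels == "bad")
  ), class = "confusion_counts")
}

#' Sensitivity: proportion of good segments accepted
#'
#' @param c A `confusion_counts` object.
#' @return `n_accepted_good / n_good`.
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$n_good == 0) stop("undefined metric: no good segments")
  c$n_accepted_good / c$n_good
}

#' Specificity: proportion of bad segments rejected
#'
#' @param c A `confusion_counts` object.
#' @return `(n_bad - n_accepted_bad) / n_bad`.
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$n_bad == 0) stop("undefined metric: no bad segments")
  (c$n_bad - c$n_accepted_bad) / c$n_bad
}

#' Pre/post quality-control accuracy table per task and joint
#'
#' For every (phase, joint) cell: segment counts, the count of good segments,
#' mean and SD of RMSD over all segments, the count of accepted segments, and
#' mean and SD of RMSD over accepted segments. The two walking phases are
#' pooled into a single `walk` row.
#'
#' @param segments Data frame with columns `phase`, `joint`, `rmsd`, `label`,
#'   `accepted`.
#' @return Data frame of class `qc_table`, one row per (phase, joint).
#' @export
pre_post_table <- function(segments) {
  req <- c("phase", "joint", "rmsd", "label", "accepted")
  missing <- setdiff(req, names(segments))
  if (length(missing)) stop("schema error: missing columns ", paste(missing, collapse = ", "))
  phase <- as.character(segments$phase)
  phase[phase %in% c("walk1", "walk2")] <- "walk"
  phase_levels <- c("sit", "sit_to_stand", "walk", "turn", "turn_to_sit")
  phase <- factor(phase, levels = unique(c(phase_levels, phase)))
  joint <- factor(as.character(segments$joint),
                  levels = unique(c(names(tug_joints()), as.character(segments$joint))))
  cells <- split(seq_len(nrow(segments)), list(phase = phase, joint = joint), drop = TRUE)
  rows <- lapply(names(cells), function(key) {
    idx <- cells[[key]]
    rmsd <- segments$rmsd[idx]
    acc <- as.logical(segments$accepted[idx])
    data.frame(
      phase = as.character(phase[idx][1L]),
      joint = as.character(joint[idx][1L]),
      n_total = length(idx),
      n_good = sum(segments$label[idx] == "good"),
      rmsd_mean = mean(rmsd),
      rmsd_sd = stats::sd(rmsd),
      n_accepted = sum(acc),
      rmsd_accepted_mean = if (any(acc)) mean(rmsd[acc]) else NA_real_,
      rmsd_accepted_sd = if (sum(acc) > 1) stats::sd(rmsd[acc]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$phase, levels(phase)), match(out$joint, levels(joint))), ]
  rownames(out) <- NULL
  class(out) <- c("qc_table", "data.frame")
  out
}

#' @export
print.qc_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$rmsd_total <- sprintf("%.1f (%.1f)", y$rmsd_mean, y$rmsd_sd)
  y$rmsd_accepted <- ifelse(is.na(y$rmsd_accepted_mean), "-",
                            sprintf("%.1f (%.1f)", y$rmsd_accepted_mean,
                                    ifelse(is.na(y$rmsd_accepted_sd), 0,
                                           y$rmsd_accepted_sd)))
  print(y[, c("phase", "joint", "n_total", "n_good", "rmsd_total",
              "n_accepted", "rmsd_accepted")], row.names = FALSE, ...)
  invisible(x)
}
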