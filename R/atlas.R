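# Aggregation of per-family reconciliation events into a species-tree-wide
# gain/loss atlas: per-branch counts and per-My rates, time-windowed rates
# (events smeared uniformly along their branch), and epoch means over the
# branches alive in an interval.

#' Aggregate reconciliation events into a gain/loss atlas
#'
#' @param recs list of `reconciliation` objects, or a combined event table
#'   (data.frame with columns `type` in gain/loss and `branch_id`)
#' @param tt `timetree` all events refer to
#' @return `event_atlas`: data.frame with branch_id, parent_age, child_age,
#'   duration, gains, losses, gain_rate, loss_rate. Events whose duplication
#'   maps to the species root are collected in attribute `root_events` (the
#'   root subtends no branch and has no duration).
#' @export
aggregate_events <- function(recs, tt) {
  events <- if (is.data.frame(recs)) {
    recs
  } else if (length(recs)) {
    do.call(rbind, c(lapply(recs, `[[`, "events"), list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(events)) events <- data.frame(type = character(0), branch_id = character(0))
  bt <- branch_table(tt)
  known <- c(bt$branch_id, tt$labels[tt$root])
  bad <- setdiff(unique(events$branch_id), known)
  if (length(bad)) stop("event refers to unknown branch id: ", bad[1])
  at_root <- events$branch_id == tt$labels[tt$root]
  root_events <- events[at_root, , drop = FALSE]
  events <- events[!at_root, , drop = FALSE]
  g <- table(factor(events$branch_id[events$type == "gain"], levels = bt$branch_id))
  l <- table(factor(events$branch_id[events$type == "loss"], levels = bt$branch_id))
  atlas <- bt[, c("branch_id", "parent_age", "child_age", "duration")]
  atlas$gains <- as.integer(g)
  atlas$losses <- as.integer(l)
  atlas$gain_rate <- atlas$gains / atlas$duration
  atlas$loss_rate <- atlas$losses / atlas$duration
  structure(atlas, class = c("event_atlas", "data.frame"),
            root_events = root_events)
}

#' Events per My on one branch
#' @param count event count
#' @param duration branch duration, My (> 0)
#' @return rate per My
#' @export
branch_rate <- function(count, duration) {
  if (any(duration <= 0)) stop("duration must be positive")
  count / duration
}

#' Time-windowed gain/loss rates
#'
#' Each branch's events are smeared uniformly over its duration; a window
#' receives `count * overlap / duration` from every overlapping branch and
#' its rate is the received count divided by the window width. Windows that
#' jointly span the whole tree depth conserve total event counts.
#'
#' @param atlas `event_atlas`
#' @param window_edges sorted ages (Mya) delimiting consecutive windows
#' @return data.frame: window_start (older edge), window_end, gain_rate,
#'   loss_rate, gains, losses
#' @export
window_rates <- function(atlas, window_edges) {
  e <- sort(window_edges, decreasing = TRUE)
  if (any(diff(e) == 0)) stop("zero-width window")
  out <- data.frame(window_start = e[-length(e)], window_end = e[-1])
  out$width <- out$window_start - out$window_end
  ov <- function(lo, hi) {
    # overlap of [hi_age, lo_age] windows with each branch interval
    pmax(0, pmin(atlas$parent_age, lo) - pmax(atlas$child_age, hi))
  }
  out$gains <- vapply(seq_len(nrow(out)), function(i) {
    sum(atlas$gains * ov(out$window_start[i], out$window_end[i]) / atlas$duration)
  }, numeric(1))
  out$losses <- vapply(seq_len(nrow(out)), function(i) {
    sum(atlas$losses * ov(out$window_start[i], out$window_end[i]) / atlas$duration)
  }, numeric(1))
  out$gain_rate <- out$gains / out$width
  out$loss_rate <- out$losses / out$width
  out[, c("window_start", "window_end", "width", "gains", "losses",
          "gain_rate", "loss_rate")]
}

#' Mean per-branch rate over branches alive in an epoch
#'
#' Unweighted arithmetic mean of the per-branch rates of every branch whose
#' time interval overlaps the epoch (duration-weighted mean available via
#' `weighted = TRUE`).
#'
#' @param atlas `event_atlas`
#' @param epoch length-2 ages (Mya), older first
#' @param what `"loss"` or `"gain"`
#' @param weighted duration-weight the mean
#' @return mean rate (NA with a warning when no branch is alive)
#' @export
lineage_mean_rate <- function(atlas, epoch, what = c("loss", "gain"),
                              weighted = FALSE) {
  what <- match.arg(what)
  lo <- max(epoch); hi <- min(epoch)
  alive <- atlas$parent_age > hi & atlas$child_age < lo
  if (!any(alive)) {
    warning("no branch alive in epoch [", lo, ", ", hi, "] Mya")
    return(NA_real_)
  }
  r <- if (what == "loss") atlas$loss_rate[alive] else atlas$gain_rate[alive]
  if (weighted) {
    w <- pmin(atlas$parent_age[alive], lo) - pmax(atlas$child_age[alive], hi)
    sum(r * w) / sum(w)
  } else {
    mean(r)
  }
}

#' Epoch series of mean rates (atlas bar-plot statistic)
#'
#' @param atlas `event_atlas`
#' @param width epoch width in My
#' @param root_age oldest age to cover (default: oldest branch in the atlas)
#' @inheritParams lineage_mean_rate
#' @return data.frame epoch_start, epoch_end, mean_rate
#' @export
epoch_series <- function(atlas, width = 5, root_age = NULL,
                         what = c("loss", "gain"), weighted = FALSE) {
  what <- match.arg(what)
  if (is.null(root_age)) root_age <- max(atlas$parent_age)
  starts <- seq(root_age, width, by = -width)
  out <- data.frame(epoch_start = starts, epoch_end = starts - width)
  out$mean_rate <- vapply(seq_len(nrow(out)), function(i) {
    suppressWarnings(lineage_mean_rate(atlas, c(out$epoch_start[i], out$epoch_end[i]),
                                       what, weighted))
  }, numeric(1))
  out
}
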