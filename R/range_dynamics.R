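#' Majority-vote consensus binary map
#'
#' A pixel (row) is suitable when the fraction of models whose suitability
#' strictly exceeds their own cutoff is strictly greater than the consensus
#' fraction.
#'
#' @param preds numeric matrix of suitabilities, one column per model (or a
#'   vector for a single model).
#' @param cutoffs per-model cutoff values (the TSS-maximizing cutoffs from
#'   evaluation).
#' @param consensus required vote fraction (default 0.5, strict).
#' @return integer 0/1 vector, one element per row of `preds`.
#' @export
binarize_consensus <- function(preds, cutoffs, consensus = 0.5) {
  preds <- as.matrix(preds)
  stopifnot(ncol(preds) == length(cutoffs))
  votes <- sweep(preds, 2, cutoffs, `>`)
  as.integer(rowMeans(votes) > consensus)
}

#' Threshold a suitability grid into a binary map
#'
#' @param suitability numeric grid (matrix) or vector.
#' @param cutoff threshold; suitability strictly greater than it maps to 1.
#' @return integer 0/1 object of the same shape (`NA` preserved).
#' @export
binary_from_truth <- function(suitability, cutoff) {
  out <- suitability
  out[] <- as.integer(suitability > cutoff)
  out
}

#' Classify per-pixel range transitions
#'
#' Compares two binary maps on the same grid: pixels unoccupied in both are
#' `never` (0), occupied in both `always` (1), occupied only currently
#' `lost` (2), occupied only in the future `gained` (3).
#'
#' @param current,future 0/1 matrices on the same grid (`NA` = off-mask).
#' @return integer matrix of transition codes with attribute `legend`;
#'   class `transition_map`.
#' @export
classify_transitions <- function(current, future) {
  if (!all(dim(current) == dim(future)))
    stop("grid mismatch between current and future maps")
  if (!identical(which(is.na(current)), which(is.na(future))))
    stop("grid mismatch: masks differ between current and future maps")
  tm <- current
  tm[] <- NA_integer_
  tm[current == 0 & future == 0] <- 0L
  tm[current == 1 & future == 1] <- 1L
  tm[current == 1 & future == 0] <- 2L
  tm[current == 0 & future == 1] <- 3L
  # conservation: the four classes partition the masked-in pixels
  stopifnot(sum(!is.na(tm)) == sum(!is.na(current)))
  structure(tm, legend = c(never = 0L, always = 1L, lost = 2L, gained = 3L),
            class = c("transition_map", class(tm)))
}

#' Pixel counts per transition class
#' @param transitions a `transition_map`.
#' @return named integer vector (never, always, lost, gained).
#' @export
transition_counts <- function(transitions) {
  tab <- tabulate(as.integer(transitions) + 1L, nbins = 4)
  stats::setNames(tab, c("never", "always", "lost", "gained"))
}

#' Range change under dispersal and no-dispersal assumptions
#'
#' From a transition map, computes loss, gain and net range change as
#' percentages of the current range (always + lost pixels).  The full
#' dispersal mode counts every gained pixel.  The no-dispersal mode counts
#' a gained pixel only when its habitat patch in the future binary map
#' (always + gained pixels, connected at `connectivity`) also contains at
#' least one always-occupied pixel, i.e. gains disconnected from currently
#' occupied habitat are precluded.
#'
#' @param transitions a `transition_map` (see [classify_transitions()]).
#' @param connectivity 8 (queen, default) or 4 (rook).
#' @return list of class `range_change` with pixel counts (`n_current`,
#'   `n_lost`, `n_gained`, `n_gained_connected`) and a `stats` data.frame
#'   (mode, loss_pct, gain_pct, net_pct).
#' @export
range_change <- function(transitions, connectivity = 8) {
  cnt <- transition_counts(transitions)
  n_current <- cnt[["always"]] + cnt[["lost"]]
  if (n_current == 0)
    stop("undefined-percentage error: empty current range")
  future <- transitions
  future[] <- NA_integer_
  future[transitions %in% c(0L, 2L)] <- 0L
  future[transitions %in% c(1L, 3L)] <- 1L
  n_gain_conn <- 0L
  if (cnt[["gained"]] > 0) {
    ps <- label_patches(future, connectivity = connectivity)
    lab <- ps$labels
    conn <- unique(lab[transitions == 1L & !is.na(lab)])  # patches holding an 'always'
    n_gain_conn <- sum(transitions == 3L & lab %in% conn, na.rm = TRUE)
  }
  loss <- 100 * cnt[["lost"]] / n_current
  gain_full <- 100 * cnt[["gained"]] / n_current
  gain_nodisp <- 100 * n_gain_conn / n_current
  stats <- data.frame(
    mode = c("dispersal", "no_dispersal"),
    loss_pct = c(loss, loss),
    gain_pct = c(gain_full, gain_nodisp),
    net_pct = c(gain_full - loss, gain_nodisp - loss),
    stringsAsFactors = FALSE)
  structure(list(n_current = n_current, n_lost = cnt[["lost"]],
                 n_gained = cnt[["gained"]],
                 n_gained_connected = n_gain_conn,
                 connectivity = connectivity, stats = stats),
            class = "range_change")
}

#' @export
print.range_change <- function(x, ...) {
  cat("Range change (current range:", x$n_current, "pixels)\n")
  s <- x$stats
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s loss %6.1f%%  gain %6.1f%%  net %+6.1f%%\n",
                s$mode[i], s$loss_pct[i], s$gain_pct[i], s$net_pct[i]))
  invisible(x)
}
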