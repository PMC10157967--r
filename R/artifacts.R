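#' Artifact-rejection criteria
#'
#' Thresholds for the automatic rejection of channels and epochs. An epoch
#' or channel is removed when its peak amplitude lies more than `peak_k`
#' standard deviations above or below the mean peak (two-tailed), or when its
#' variance, mean absolute z-value, or kurtosis exceeds the mean of that
#' metric by more than `dist_k` standard deviations (upper tail only), with
#' means and SDs taken across all (channel, epoch) cells. A dataset is
#' retained only if at least `min_channels` channels and at least
#' `min_epochs` epochs survive (defaults: at least one channel and more than
#' five epochs).
#'
#' @param peak_k SD multiplier for the two-tailed peak criterion (default 5).
#' @param dist_k SD multiplier for the upper-tailed distribution criteria
#'   (default 2.5).
#' @param min_epochs minimum surviving epochs for retention (default 6).
#' @param min_channels minimum surviving channels (default 1).
#' @param kurtosis `"pearson"` (standardized fourth moment, Gaussian = 3) or
#'   `"excess"` (Gaussian = 0); affects reported values, not removals, since
#'   the two differ by a constant shift.
#' @return object of class `"rejection_criteria"`.
#' @export
rejection_criteria <- function(peak_k = 5, dist_k = 2.5, min_epochs = 6,
                               min_channels = 1,
                               kurtosis = c("pearson", "excess")) {
  stopifnot(peak_k > 0, dist_k > 0, min_epochs >= 1, min_channels >= 1)
  structure(list(peak_k = peak_k, dist_k = dist_k,
                 min_epochs = as.integer(min_epochs),
                 min_channels = as.integer(min_channels),
                 kurtosis = match.arg(kurtosis)),
            class = "rejection_criteria")
}

#' Per-(channel, epoch) quality metrics
#'
#' For every channel/epoch cell: `peak` (max absolute amplitude, uV),
#' `variance` (within-epoch sample variance, uV^2), `zvalue` (mean absolute
#' standardized amplitude, standardized against the channel's mean and SD
#' pooled over all epochs), and `kurtosis` (within-epoch standardized fourth
#' moment; Pearson convention by default, so a Gaussian epoch is near 3 and
#' a +/-1 square wave is exactly 1). Zero-variance cells report zvalue and
#' kurtosis of 0 with a warning.
#'
#' @param epochs an `"epoch_set"` from [trim_and_epoch()].
#' @param kurtosis convention, `"pearson"` or `"excess"`.
#' @return data.frame with columns channel, epoch, peak, variance, zvalue,
#'   kurtosis (one row per cell, 1-based indices).
#' @export
compute_epoch_metrics <- function(epochs, kurtosis = c("pearson", "excess")) {
  stopifnot(inherits(epochs, "epoch_set"))
  kurtosis <- match.arg(kurtosis)
  d <- dim(epochs$data)
  n_epochs <- d[1]; n_channels <- d[2]; n_samples <- d[3]
  out <- expand.grid(epoch = seq_len(n_epochs), channel = seq_len(n_channels))
  out <- out[, c("channel", "epoch")]
  out$peak <- out$variance <- out$zvalue <- out$kurtosis <- NA_real_
  warned <- FALSE
  for (ch in seq_len(n_channels)) {
    pooled <- as.vector(epochs$data[, ch, ])
    mu_ch <- mean(pooled)
    sd_ch <- stats::sd(pooled)
    if (sd_ch == 0 && !warned) {
      warning("zero-variance channel: zvalue and kurtosis reported as 0")
      warned <- TRUE
    }
    for (e in seq_len(n_epochs)) {
      x <- epochs$data[e, ch, ]
      i <- which(out$channel == ch & out$epoch == e)
      out$peak[i] <- max(abs(x))
      v <- stats::var(x)
      out$variance[i] <- v
      out$zvalue[i] <- if (sd_ch > 0) mean(abs(x - mu_ch) / sd_ch) else 0
      if (v > 0) {
        m2 <- mean((x - mean(x))^2)
        k <- mean((x - mean(x))^4) / m2^2
        out$kurtosis[i] <- if (kurtosis == "pearson") k else k - 3
      } else {
        if (!warned) {
          warning("zero-variance epoch: kurtosis reported as 0")
          warned <- TRUE
        }
        out$kurtosis[i] <- 0
      }
    }
  }
  out
}

#' Automatic artifact rejection
#'
#' Single-pass statistical thresholding over the metric table of
#' [compute_epoch_metrics()]. Thresholds are computed once from all
#' (channel, epoch) cells: the peak criterion is two-tailed
#' (|peak - mean| > peak_k * SD), the variance / zvalue / kurtosis criteria
#' are upper-tailed (metric > mean + dist_k * SD); all comparisons are
#' strict, so a table with zero spread removes nothing. An epoch is removed
#' if any of its channel cells exceeds any criterion; a channel is removed
#' if its metrics averaged over epochs exceed the same thresholds. The
#' dataset is retained when at least `min_channels` channels and
#' `min_epochs` epochs survive.
#'
#' @param epochs an `"epoch_set"`.
#' @param criteria a [rejection_criteria()].
#' @return object of class `"rejection_report"`: `metrics` (the cell table,
#'   with a logical `removed` column), `removed_epochs`, `removed_channels`
#'   (1-based index vectors), `retained` (logical verdict),
#'   `n_epochs_surviving`, `n_channels_surviving`, `criteria`.
#' @export
autoreject <- function(epochs, criteria = rejection_criteria()) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(criteria, "rejection_criteria"))
  met <- compute_epoch_metrics(epochs, kurtosis = criteria$kurtosis)
  d <- dim(epochs$data)
  n_epochs <- d[1]; n_channels <- d[2]

  cell_exceeds <- function(tab) {
    ex <- abs(tab$peak - mean(met$peak)) > criteria$peak_k * stats::sd(met$peak)
    for (m in c("variance", "zvalue", "kurtosis")) {
      ex <- ex | (tab[[m]] > mean(met[[m]]) + criteria$dist_k * stats::sd(met[[m]]))
    }
    ex & !is.na(ex)
  }

  met$removed <- cell_exceeds(met)
  removed_epochs <- sort(unique(met$epoch[met$removed]))

  ## channel verdicts from per-channel means over epochs, same thresholds
  ch_tab <- do.call(rbind, lapply(seq_len(n_channels), function(ch) {
    rows <- met[met$channel == ch, ]
    data.frame(peak = mean(rows$peak), variance = mean(rows$variance),
               zvalue = mean(rows$zvalue), kurtosis = mean(rows$kurtosis))
  }))
  removed_channels <- which(cell_exceeds(ch_tab))

  n_ch_surv <- n_channels - length(removed_channels)
  n_ep_surv <- n_epochs - length(removed_epochs)
  structure(
    list(metrics = met, removed_epochs = removed_epochs,
         removed_channels = removed_channels,
         n_epochs_surviving = n_ep_surv, n_channels_surviving = n_ch_surv,
         retained = n_ch_surv >= criteria$min_channels &&
           n_ep_surv >= criteria$min_epochs,
         criteria = criteria),
    class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> removed %d epoch(s), %d channel(s); %d epoch(s) survive\n",
              length(x$removed_epochs), length(x$removed_channels),
              x$n_epochs_surviving))
  cat(sprintf("  dataset retained: %s\n", x$retained))
  invisible(x)
}

#' Drop rejected epochs and channels from an epoch set
#'
#' @param epochs an `"epoch_set"`.
#' @param report the matching [autoreject()] report.
#' @return the cleaned `"epoch_set"`.
#' @export
drop_rejected <- function(epochs, report) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(report, "rejection_report"))
  keep_e <- setdiff(seq_len(dim(epochs$data)[1]), report$removed_epochs)
  keep_c <- setdiff(seq_len(dim(epochs$data)[2]), report$removed_channels)
  if (length(keep_e) == 0 || length(keep_c) == 0)
    stop_planeeg("no epochs or channels survive rejection")
  epochs$data <- epochs$data[keep_e, keep_c, , drop = FALSE]
  epochs$channel_labels <- epochs$channel_labels[keep_c]
  epochs
}
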