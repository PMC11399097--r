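#' Difference-scattering series
#'
#' The merged light-minus-dark matrix \eqn{\Delta S(q,t)} together with its
#' grids and provenance (filter threshold, normalization range, merge
#' weights).
#'
#' @param q A [q_grid()] or increasing numeric vector.
#' @param time_us Delay grid, µs.
#' @param delta_S q x t matrix, finite entries.
#' @param n_light_frames Number of light frames that entered the average.
#' @param provenance Free-form list of processing parameters.
#' @return Object of class \code{difference_series}.
#' @export
difference_series <- function(q, time_us, delta_S, n_light_frames,
                              provenance = list()) {
  q <- as_q_grid(q)
  delta_S <- as.matrix(delta_S)
  if (!all(dim(delta_S) == c(length(q$values), length(time_us)))) {
    stop("delta_S must be q x t matching the grids")
  }
  if (any(!is.finite(delta_S))) stop("delta_S must be finite")
  if (n_light_frames <= 0) stop("n_light_frames must be positive")
  structure(list(q = q, time_us = as.numeric(time_us), delta_S = delta_S,
                 n_light_frames = n_light_frames, provenance = provenance),
            class = "difference_series")
}

#' @export
print.difference_series <- function(x, ...) {
  cat(sprintf("difference series: %d q bins x %d delays, %d light frames\n",
              nrow(x$delta_S), ncol(x$delta_S), x$n_light_frames))
  invisible(x)
}

# Pulse-averaged q profile of one train.
train_mean_profile <- function(p) rowMeans(p)

#' Filter unstable trains by profile correlation
#'
#' Computes the Pearson correlation between each train's pulse-averaged
#' q-profile and the run-average profile of trains with the same light/dark
#' flag, and drops trains whose correlation falls below the threshold. The
#' default threshold 0.99995 targets intermittent jet instability: shape
#' changes of the scattering curve, not intensity jitter.
#'
#' @param series A \code{train_series} with at least two trains.
#' @param threshold Correlation threshold; trains with r < threshold are
#'   dropped.
#' @param reference \code{"median"} (default) builds the run reference as
#'   the per-bin median over trains of like flag, so that corrupted trains
#'   cannot drag the reference toward themselves in small runs;
#'   \code{"mean"} uses the plain average.
#' @return List with \code{kept} (a \code{train_series}) and \code{report}
#'   (data frame: train, light, correlation, kept) plus kept/dropped counts.
#' @export
filter_trains <- function(series, threshold = 0.99995,
                          reference = c("median", "mean")) {
  reference <- match.arg(reference)
  n <- length(series$profiles)
  if (n < 2) stop("need at least two trains to filter")
  means <- vapply(series$profiles, train_mean_profile,
                  numeric(length(series$q$values)))
  r <- numeric(n)
  for (flag in unique(series$light_flag)) {
    sel <- series$light_flag == flag
    run_avg <- if (reference == "median") {
      apply(means[, sel, drop = FALSE], 1, median)
    } else {
      rowMeans(means[, sel, drop = FALSE])
    }
    r[sel] <- apply(means[, sel, drop = FALSE], 2, cor, y = run_avg)
  }
  keep <- r >= threshold
  if (!any(keep)) stop("all trains fell below the correlation threshold")
  report <- data.frame(train = seq_len(n), light = series$light_flag,
                       correlation = r, kept = keep)
  kept_truth <- series$truth
  if (!is.null(kept_truth)) {
    kept_truth$corrupt_ids <- intersect(kept_truth$corrupt_ids, which(keep))
  }
  kept <- train_series(series$profiles[keep], series$q, series$time_us,
                       series$light_flag[keep], truth = kept_truth,
                       check_alternating = FALSE)
  list(kept = kept, report = report,
       n_kept = sum(report$kept), n_dropped = sum(!report$kept))
}

#' Normalize a scattering curve by its integrated intensity
#'
#' Divides every point by the sum of the curve over a q window, so the
#' window sum of the output is exactly 1. The analysis default window is the
#' full recorded range 0.08–2.1 Å\eqn{^{-1}}; a high-q display window
#' (1.4–1.6 Å\eqn{^{-1}}) is also common.
#'
#' @param intensity Numeric vector (or \code{radial_profile}).
#' @param q q values matching \code{intensity} (ignored when a profile is
#'   given).
#' @param q_lo,q_hi Normalization window, Å\eqn{^{-1}}.
#' @return Same type as the input, normalized.
#' @export
normalize_profile <- function(intensity, q = NULL, q_lo = 0.08, q_hi = 2.1) {
  if (inherits(intensity, "radial_profile")) {
    prof <- intensity
    out <- normalize_profile(prof$intensity, prof$q$values, q_lo, q_hi)
    return(radial_profile(prof$q, out, prof$counts_per_bin))
  }
  if (is.null(q)) stop("q values required")
  win <- q >= q_lo & q <= q_hi
  if (!any(win)) stop("normalization window contains no q bins")
  s <- sum(intensity[win])
  if (!is.finite(s) || s <= 0) stop("non-positive integrated intensity in window")
  intensity / s
}

#' Light-minus-dark difference scattering
#'
#' Computes \eqn{\Delta S(q,t) = S_{light}(q,t) - S_{dark}(q,t)} from a
#' (filtered) train series. Default strategy \code{"mean"}: average trains
#' within each flag class per pulse index, optionally normalize each delay's
#' curve over the window, then subtract. Strategy \code{"adjacent"}: each
#' adjacent light/dark train pair is subtracted first and the pair
#' differences averaged — this cancels train-level common-mode fluctuations
#' (jet thickness, X-ray intensity) that survive class-mean averaging. An
#' unpaired trailing train is dropped with a message.
#'
#' @param series A \code{train_series} with both light and dark trains.
#' @param pairing \code{"mean"} or \code{"adjacent"}.
#' @param normalize Normalize each delay curve by its window sum before
#'   subtracting (the production ordering: average, normalize, subtract).
#' @param q_lo,q_hi Normalization window.
#' @return A \code{difference_series}.
#' @export
compute_difference <- function(series, pairing = c("mean", "adjacent"),
                               normalize = TRUE, q_lo = 0.08, q_hi = 2.1) {
  pairing <- match.arg(pairing)
  lf <- series$light_flag
  if (!any(lf) || !all(c(TRUE, FALSE) %in% lf)) {
    stop("need at least one light and one dark train")
  }
  nq <- length(series$q$values)
  qv <- series$q$values
  norm_cols <- function(m) {
    if (!normalize) return(m)
    apply(m, 2, normalize_profile, q = qv, q_lo = q_lo, q_hi = q_hi)
  }
  s_dark_mean <- Reduce(`+`, series$profiles[!lf]) / sum(!lf)
  win_sum <- mean(colSums(s_dark_mean[qv >= q_lo & qv <= q_hi, , drop = FALSE]))
  if (pairing == "mean") {
    s_light <- Reduce(`+`, series$profiles[lf]) / sum(lf)
    dS <- norm_cols(s_light) - norm_cols(s_dark_mean)
  } else {
    li <- which(lf); di <- which(!lf)
    npair <- min(length(li), length(di))
    if (length(li) != length(di)) {
      message("unpaired trailing train dropped (", abs(length(li) - length(di)),
              ")")
    }
    diffs <- lapply(seq_len(npair), function(k) {
      norm_cols(series$profiles[[li[k]]]) - norm_cols(series$profiles[[di[k]]])
    })
    dS <- Reduce(`+`, diffs) / npair
  }
  difference_series(series$q, series$time_us, dS,
                    n_light_frames = sum(lf) * length(series$time_us),
                    provenance = list(pairing = pairing,
                                      normalize = normalize,
                                      norm_range = c(q_lo, q_hi),
                                      mean_dark_window_sum = win_sum))
}

#' Merge difference series from two sample concentrations
#'
#' Scales the low-concentration series onto the high one by a least-squares
#' scale and a single scalar offset (systematic detector baseline), then
#' merges with a weighted average where the weights are the numbers of
#' light frames.
#'
#' @param ds_high,ds_low \code{difference_series} on identical q and time
#'   grids.
#' @return Merged \code{difference_series}; scale and offset are stored in
#'   the provenance.
#' @export
merge_concentrations <- function(ds_high, ds_low) {
  if (!isTRUE(all.equal(ds_high$q$values, ds_low$q$values)) ||
      !isTRUE(all.equal(ds_high$time_us, ds_low$time_us))) {
    stop("q and time grids must match to merge")
  }
  x <- as.numeric(ds_low$delta_S)
  y <- as.numeric(ds_high$delta_S)
  fit <- lm.fit(cbind(x, 1), y)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  aligned <- a * ds_low$delta_S + b
  w_h <- ds_high$n_light_frames; w_l <- ds_low$n_light_frames
  merged <- (w_h * ds_high$delta_S + w_l * aligned) / (w_h + w_l)
  difference_series(ds_high$q, ds_high$time_us, merged,
                    n_light_frames = w_h + w_l,
                    provenance = list(scale = unname(a), offset = unname(b),
                                      weights = c(high = w_h, low = w_l)))
}
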