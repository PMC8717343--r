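#' Point sounding set
#'
#' A data.frame-backed container of singlebeam depth records with coordinates
#' (m), acquisition time (s) and depth (m, positive down), plus a provenance
#' log of the QC operations applied. An optional `transect` column groups
#' records; QC operations that respect track structure (block averaging,
#' despiking) operate within transects when it is present.
#'
#' @param records data.frame with at least columns `x`, `y`, `t`, `depth`.
#' @param crs_label coordinate system label.
#' @param provenance character vector of processing-log entries.
#' @return An object of class `sounding_set` (also a data.frame).
#' @export
sounding_set <- function(records, crs_label = "local-metres",
                         provenance = character(0)) {
  req <- c("x", "y", "t", "depth")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (!all(is.finite(records$x)) || !all(is.finite(records$y)))
    stop("non-finite coordinates in sounding records")
  out <- as.data.frame(records)
  rownames(out) <- NULL
  structure(out, crs_label = crs_label, provenance = provenance,
            class = c("sounding_set", "data.frame"))
}

## Re-wrap a data.frame as a sounding_set, appending a provenance entry.
ss_update <- function(records, template, log_entry) {
  sounding_set(records, crs_label = attr(template, "crs_label"),
               provenance = c(attr(template, "provenance"), log_entry))
}

#' @export
print.sounding_set <- function(x, ...) {
  cat(sprintf("<sounding_set> %d records", nrow(x)))
  if ("transect" %in% names(x))
    cat(sprintf(" on %d transects", length(unique(x$transect))))
  ok <- is.finite(x$depth)
  if (any(ok))
    cat(sprintf("; depth %.2f-%.2f m (mean %.2f)",
                min(x$depth[ok]), max(x$depth[ok]), mean(x$depth[ok])))
  cat("\n")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance:", paste(prov, collapse = " -> "), "\n")
  invisible(x)
}

#' Block-average consecutive soundings
#'
#' Replaces each non-overlapping group of `k` consecutive records (within a
#' transect, ordered by time) with a single record holding the group means of
#' x, y, t and depth — the depth-domain analogue of averaging consecutive
#' pings to improve signal-to-noise. A trailing remainder group is kept (as
#' the mean of its members) when it holds at least `k/2` records, otherwise
#' dropped.
#'
#' @param s a [sounding_set].
#' @param k block size (>= 1).
#' @return A block-averaged [sounding_set].
#' @export
block_average <- function(s, k = 10L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("'k' must be >= 1")
  k <- as.integer(k)
  if (k == 1L) return(ss_update(s, s, "block_average(k=1)"))
  tr <- if ("transect" %in% names(s)) s$transect else rep(1L, nrow(s))
  pieces <- lapply(split(seq_len(nrow(s)), tr), function(idx) {
    idx <- idx[order(s$t[idx])]
    n <- length(idx)
    grp <- (seq_len(n) - 1L) %/% k
    keepable <- table(grp)
    last <- max(grp)
    if (keepable[as.character(last)] < k / 2 && last > 0)
      idx <- idx[grp != last]
    grp <- factor((seq_along(idx) - 1L) %/% k)
    grp <- factor(grp, levels = as.character(sort(as.integer(levels(grp)))))
    agg <- function(v) as.numeric(tapply(v[idx], grp, mean))
    data.frame(x = agg(s$x), y = agg(s$y), t = agg(s$t), depth = agg(s$depth),
               transect = tr[idx[1L]])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$t), , drop = FALSE]
  if (!("transect" %in% names(s))) out$transect <- NULL
  ss_update(out, s, sprintf("block_average(k=%d)", k))
}

#' Correct soundings for tide height
#'
#' Subtracts the tide height (linearly interpolated at each sounding time,
#' less the chart-datum offset) from the raw depths, referencing them to the
#' vertical datum. The correction is exactly invertible given the same tide
#' series.
#'
#' @param s a [sounding_set].
#' @param tide a [tide_series] spanning all sounding times.
#' @param invert if TRUE, adds the correction back (restores raw depths).
#' @return A corrected [sounding_set].
#' @export
tide_correct <- function(s, tide, invert = FALSE) {
  ts <- tide$samples
  outside <- s$t < min(ts$t) | s$t > max(ts$t)
  if (any(outside))
    stop(sprintf("sounding time(s) outside tide span, first at record %d (t=%.1f s)",
                 which(outside)[1], s$t[which(outside)[1]]))
  h <- stats::approx(ts$t, ts$height, xout = s$t)$y
  corr <- h - tide$datum_offset
  out <- as.data.frame(s)
  out$depth <- if (invert) out$depth + corr else out$depth - corr
  ss_update(out, s, if (invert) "tide_correct(inverted)" else "tide_correct")
}

#' Remove depth spikes with a running median/MAD filter
#'
#' Removes records whose depth deviates from the running median (window
#' `window`) by more than `threshold_factor` times a running robust noise
#' scale (floored at 0.01 m), together with any non-positive depths. The
#' noise scale is the running median absolute first difference
#' `median(|z[i+1] - z[i]|) / sqrt(2)` over a wider window (five times
#' `window`, at least 25 records): on a smooth seabed the running median
#' equals the centre value over locally monotone stretches, so the MAD of
#' the median residuals degenerates to zero and would reject ordinary noise,
#' whereas the first-difference scale estimates the sounding noise robustly
#' regardless of smooth terrain. A reproducible replacement for manual
#' editing of erroneous soundings. Applied per transect when a `transect`
#' column exists.
#'
#' @param s a [sounding_set].
#' @param window odd window length (>= 3).
#' @param threshold_factor rejection threshold in MAD units.
#' @return A despiked [sounding_set]; the number of removed records is
#'   recorded in the provenance log and in attribute `"n_removed"`.
#' @export
despike <- function(s, window = 5L, threshold_factor = 6) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("'window' must be odd and >= 3")
  tr <- if ("transect" %in% names(s)) s$transect else rep(1L, nrow(s))
  keep <- logical(nrow(s))
  half <- window %/% 2L
  for (idx in split(seq_len(nrow(s)), tr)) {
    idx <- idx[order(s$t[idx])]
    z <- s$depth[idx]
    n <- length(z)
    if (n < window) {
      med <- rep(stats::median(z), n)
    } else {
      med <- stats::runmed(z, window, endrule = "median")
    }
    resid <- abs(z - med)
    dif <- if (n > 1) abs(diff(z)) / sqrt(2) else 0.01
    dif <- c(dif, dif[length(dif)])   # align scale series with records
    mad_half <- max(12L, (5L * window) %/% 2L)
    mad_run <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - mad_half); hi <- min(n, i + mad_half)
      stats::median(dif[lo:hi])
    }, numeric(1))
    mad_run <- pmax(mad_run, 0.01)
    keep[idx] <- resid <= threshold_factor * mad_run & z > 0
  }
  removed <- sum(!keep)
  out <- as.data.frame(s)[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("despike removed every record")
  res <- ss_update(out, s,
                   sprintf("despike(window=%d, factor=%g, removed=%d)",
                           window, threshold_factor, removed))
  attr(res, "n_removed") <- removed
  res
}

#' Summarize a sounding set
#'
#' Reports n, min, max, mean depth and the adjusted Fisher-Pearson skewness
#' coefficient; |skewness| > 1 raises the transformation-advised flag used to
#' decide whether depths need transforming before geostatistical analysis.
#' Constant samples get skewness 0 with a zero-variance flag.
#'
#' @param s a [sounding_set] (or numeric depth vector) with >= 3 records.
#' @return An object of class `sounding_summary` with fields `n`, `min`,
#'   `max`, `mean`, `skewness`, `transformation_advised`, `zero_variance`.
#' @export
summarize_soundings <- function(s) {
  z <- if (is.numeric(s)) s else s$depth
  n <- length(z)
  if (n < 3) stop("skewness undefined for n < 3")
  zero_var <- stats::sd(z) == 0
  skew <- if (zero_var) 0 else e1071::skewness(z, type = 2)
  structure(list(n = n, min = min(z), max = max(z), mean = mean(z),
                 skewness = skew,
                 transformation_advised = is.finite(skew) && abs(skew) > 1,
                 zero_variance = zero_var),
            class = "sounding_summary")
}

#' @export
print.sounding_summary <- function(x, ...) {
  cat(sprintf("n = %d, depth %.2f-%.2f m, mean %.2f m, skewness %.3f%s%s\n",
              x$n, x$min, x$max, x$mean, x$skewness,
              if (x$transformation_advised) " [transformation advised]" else "",
              if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}

#' Read / write sounding CSV files
#'
#' Soundings are exchanged as CSV with columns `x,y,t,depth` (extra columns
#' preserved); tides as CSV with columns `t,height`.
#'
#' @param s a [sounding_set].
#' @param path file path.
#' @return `write_soundings_csv` returns `path` invisibly;
#'   `read_soundings_csv` returns a [sounding_set].
#' @export
write_soundings_csv <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_soundings_csv
#' @param crs_label coordinate label for the read set.
#' @export
read_soundings_csv <- function(path, crs_label = "local-metres") {
  sounding_set(utils::read.csv(path), crs_label = crs_label,
               provenance = sprintf("read(%s)", basename(path)))
}

#' @rdname write_soundings_csv
#' @param tide a [tide_series].
#' @export
write_tide_csv <- function(tide, path) {
  utils::write.csv(tide$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_soundings_csv
#' @param datum_offset chart-datum offset (m) to attach on read.
#' @export
read_tide_csv <- function(path, datum_offset = 0) {
  tide_series(utils::read.csv(path), datum_offset = datum_offset)
}
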