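#' Peak detection configuration
#'
#' Controls the automated replacement for manual peak marking. A grid cell
#' is reported as an analyte peak when it is the strict maximum of its
#' neighborhood, its intensity reaches `min_intensity`, and it lies outside
#' the RIP exclusion band. `min_intensity = NULL` uses an automatic
#' threshold of 5 times a robust noise estimate (median absolute deviation
#' of the whole intensity field, which off-peak cells dominate).
#'
#' The default RIP exclusion halfwidth of 0.04 ms keeps the band below a
#' relative drift time of about 1.008, clear of the lowest library analyte
#' (acetone monomer at 1.012).
#'
#' @param min_intensity absolute intensity threshold (V) or `NULL` for
#'   automatic
#' @param neighborhood numeric length-2: local-maximum window halfwidths
#'   as (drift ms, retention s)
#' @param rip_exclusion_halfwidth_ms halfwidth of the drift band around the
#'   RIP excluded from analyte detection (ms)
#' @param merge_tolerance numeric length-2: consensus clustering tolerances
#'   as (drift ms, retention s)
#' @return an object of class `detection_config`
#' @export
detection_config <- function(min_intensity = NULL,
                             neighborhood = c(drift_ms = 0.02,
                                              retention_s = 2),
                             rip_exclusion_halfwidth_ms = 0.04,
                             merge_tolerance = c(drift_ms = 0.02,
                                                 retention_s = 2)) {
  if (!is.null(min_intensity))
    check_positive(min_intensity = min_intensity)
  check_positive(neighborhood = neighborhood,
                 rip_exclusion_halfwidth_ms = rip_exclusion_halfwidth_ms,
                 merge_tolerance = merge_tolerance)
  stopifnot(length(neighborhood) == 2, length(merge_tolerance) == 2)
  structure(list(min_intensity = min_intensity,
                 neighborhood = unname(neighborhood),
                 rip_exclusion_halfwidth_ms = rip_exclusion_halfwidth_ms,
                 merge_tolerance = unname(merge_tolerance)),
            class = "detection_config")
}

# grey-scale dilation of M by +-wc columns and +-wr rows via iterated
# 3-neighbour maxima; O((wc + wr) * cells)
dilate_max <- function(M, wr, wc) {
  nc <- ncol(M); nr <- nrow(M)
  if (wc > 0) for (k in seq_len(wc)) {
    M <- pmax(M, cbind(M[, -1, drop = FALSE], -Inf),
              cbind(-Inf, M[, -nc, drop = FALSE]))
  }
  if (wr > 0) for (k in seq_len(wr)) {
    M <- pmax(M, rbind(M[-1, , drop = FALSE], -Inf),
              rbind(-Inf, M[-nr, , drop = FALSE]))
  }
  M
}

empty_peak_table <- function() {
  data.frame(retention_time_s = numeric(), drift_time_ms = numeric(),
             relative_drift_time = numeric(), intensity_V = numeric(),
             is_rip = logical())
}

#' Detect peaks on a spectrum
#'
#' Finds every grid cell that is a strict local maximum within the
#' configured neighborhood, at or above the intensity threshold, and
#' outside the RIP exclusion band. The RIP itself is reported once, as the
#' apex of the excluded band, with `is_rip = TRUE`. Plateau ties are broken
#' in favour of the lowest drift time (then lowest retention time). Peaks
#' are sorted by retention then drift time and carry their RIP-relative
#' drift time.
#'
#' @param spectrum an [ims_spectrum()]
#' @param config a [detection_config()]
#' @return data.frame with columns `retention_time_s`, `drift_time_ms`,
#'   `relative_drift_time`, `intensity_V`, `is_rip`; the RIP drift time is
#'   attached as attribute `rip_drift_time_ms`
#' @export
#' @examples
#' sp <- generate_spectrum(peak_spec(73, 1.056), noise_sd = 0, seed = 1)
#' detect_peaks(sp)
detect_peaks <- function(spectrum, config = detection_config()) {
  stopifnot(inherits(spectrum, "ims_spectrum"))
  M <- spectrum$intensity
  if (length(M) == 0) stop("empty spectrum", call. = FALSE)
  dr <- spectrum$drift_axis_ms
  rt <- spectrum$retention_axis_s
  rip <- spectrum$device$rip_drift_time_ms
  dstep <- stats::median(diff(dr))
  rstep <- stats::median(diff(rt))
  wc <- max(0L, floor(config$neighborhood[1] / dstep + 1e-9))
  wr <- max(0L, floor(config$neighborhood[2] / rstep + 1e-9))
  thr <- config$min_intensity %||% max(5 * stats::mad(M), 1e-9)

  D <- dilate_max(M, wr, wc)
  in_band <- abs(dr - rip) <= config$rip_exclusion_halfwidth_ms
  cand <- which(M >= D & M >= thr & M > 0, arr.ind = TRUE)
  cand <- cand[!in_band[cand[, 2]], , drop = FALSE]

  # plateau ties: among equal-valued candidates within one neighborhood,
  # the lowest drift (then lowest retention) cell wins
  if (nrow(cand) > 1) {
    v <- M[cand]
    ord <- order(cand[, 2], cand[, 1])
    cand <- cand[ord, , drop = FALSE]; v <- v[ord]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(cand)) > i &
                       abs(cand[, 2] - cand[i, 2]) <= wc &
                       abs(cand[, 1] - cand[i, 1]) <= wr &
                       v == v[i])
      keep[later] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }

  peaks <- data.frame(retention_time_s = rt[cand[, 1]],
                      drift_time_ms = dr[cand[, 2]],
                      relative_drift_time = dr[cand[, 2]] / rip,
                      intensity_V = M[cand],
                      is_rip = rep(FALSE, nrow(cand)))

  # RIP apex within the excluded band (if a positive ridge exists there)
  if (any(in_band)) {
    B <- M[, in_band, drop = FALSE]
    if (max(B) > max(thr, 0)) {
      ij <- which(B == max(B), arr.ind = TRUE)
      ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE][1, , drop = FALSE]
      cols <- which(in_band)
      peaks <- rbind(peaks,
                     data.frame(retention_time_s = rt[ij[1]],
                                drift_time_ms = dr[cols[ij[2]]],
                                relative_drift_time = dr[cols[ij[2]]] / rip,
                                intensity_V = max(B), is_rip = TRUE))
    }
  }
  peaks <- peaks[order(peaks$retention_time_s, peaks$drift_time_ms), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "rip_drift_time_ms") <- rip
  peaks
}

#' Consensus peak table across replicate measurements
#'
#' Pools the peak lists of replicate spectra and clusters them by
#' single linkage: two peaks are linked when both their drift and
#' retention differences are within `merge_tolerance`. RIP and analyte
#' peaks never merge. Each consensus peak carries mean coordinates, mean
#' intensity over the replicates in which it occurred, its occurrence
#' count, and the full per-replicate intensity series (`NA` where absent),
#' for replicate-stability analysis. The result is invariant under
#' permutation of the replicate lists.
#'
#' @param replicate_peak_lists list of peak tables from [detect_peaks()]
#' @param config a [detection_config()]
#' @return data.frame with columns `retention_time_s`, `drift_time_ms`,
#'   `relative_drift_time`, `intensity_V` (mean), `is_rip`, `occurrence`,
#'   `n_replicates`, and list-column `intensity_series`
#' @export
consensus_peaks <- function(replicate_peak_lists,
                            config = detection_config()) {
  if (!is.list(replicate_peak_lists) || length(replicate_peak_lists) < 1)
    stop("need at least one replicate peak list", call. = FALSE)
  n_rep <- length(replicate_peak_lists)
  rip <- attr(replicate_peak_lists[[1]], "rip_drift_time_ms") %||% 4.889
  pooled <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    p <- replicate_peak_lists[[i]]
    if (is.null(p) || nrow(p) == 0) return(NULL)
    cbind(p[, c("retention_time_s", "drift_time_ms", "intensity_V",
                "is_rip")], .rep = i)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- cbind(empty_peak_table(),
                 data.frame(occurrence = integer(),
                            n_replicates = integer()))
    out$intensity_series <- list()
    return(out)
  }
  n <- nrow(pooled)
  tol_d <- config$merge_tolerance[1]
  tol_r <- config$merge_tolerance[2]
  # union-find over pooled peaks
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    linked <- which(abs(pooled$drift_time_ms[-seq_len(i)] -
                          pooled$drift_time_ms[i]) <= tol_d &
                    abs(pooled$retention_time_s[-seq_len(i)] -
                          pooled$retention_time_s[i]) <= tol_r &
                    pooled$is_rip[-seq_len(i)] == pooled$is_rip[i]) + i
    for (j in linked) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  rows <- lapply(groups, function(idx) {
    g <- pooled[idx, , drop = FALSE]
    series <- rep(NA_real_, n_rep)
    for (r in unique(g$.rep))
      series[r] <- mean(g$intensity_V[g$.rep == r])
    data.frame(retention_time_s = mean(g$retention_time_s),
               drift_time_ms = mean(g$drift_time_ms),
               relative_drift_time = mean(g$drift_time_ms) / rip,
               intensity_V = mean(series, na.rm = TRUE),
               is_rip = g$is_rip[1],
               occurrence = length(unique(g$.rep)),
               n_replicates = n_rep,
               intensity_series = I(list(series)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$retention_time_s, out$drift_time_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rip_drift_time_ms") <- rip
  out
}

#' Write a peak table to CSV
#'
#' Flat CSV of the detection (or consensus) output; the list-column of
#' per-replicate intensities is dropped.
#'
#' @param peaks a peak table from [detect_peaks()] or [consensus_peaks()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_peak_table <- function(peaks, path) {
  cols <- intersect(c("retention_time_s", "drift_time_ms",
                      "relative_drift_time", "intensity_V", "is_rip",
                      "occurrence"), names(peaks))
  data.table::fwrite(peaks[, cols, drop = FALSE], path)
  invisible(path)
}
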