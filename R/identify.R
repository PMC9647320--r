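#' Identification matching configuration
#'
#' Tolerances for cross-checking detected peak coordinates against the
#' reference library. The defaults (3 s retention, 0.01 relative drift)
#' are about half the smallest coordinate gaps between named library
#' entries, so the packaged named library is collision-free under them.
#' `distance_scale` sets the units of the tie-breaking distance; by
#' default it equals the tolerances.
#'
#' @param tol_retention_s retention-time tolerance (s)
#' @param tol_relative_drift relative-drift-time tolerance
#' @param distance_scale numeric length-2 (seconds, dimensionless) scaling
#'   the Euclidean matching distance; `NULL` uses the tolerances
#' @return an object of class `match_config`
#' @export
match_config <- function(tol_retention_s = 3, tol_relative_drift = 0.01,
                         distance_scale = NULL) {
  check_positive(tol_retention_s = tol_retention_s,
                 tol_relative_drift = tol_relative_drift)
  if (is.null(distance_scale))
    distance_scale <- c(tol_retention_s, tol_relative_drift)
  check_positive(distance_scale = distance_scale)
  stopifnot(length(distance_scale) == 2)
  structure(list(tol_retention_s = tol_retention_s,
                 tol_relative_drift = tol_relative_drift,
                 distance_scale = unname(distance_scale)),
            class = "match_config")
}

# greedy one-to-one assignment of peaks to library entries by ascending
# scaled distance; pairs must be within both tolerances
greedy_assign <- function(peaks, entries, config) {
  np <- nrow(peaks); ne <- nrow(entries)
  if (np == 0 || ne == 0)
    return(data.frame(peak = integer(), entry = integer(),
                      distance = numeric()))
  d_rt <- abs(outer(peaks$retention_time_s, entries$retention_time_s, "-"))
  d_rd <- abs(outer(peaks$relative_drift_time,
                    entries$relative_drift_time, "-"))
  ok <- d_rt <= config$tol_retention_s & d_rd <= config$tol_relative_drift
  dist <- sqrt((d_rt / config$distance_scale[1])^2 +
               (d_rd / config$distance_scale[2])^2)
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(peak = integer(), entry = integer(),
                      distance = numeric()))
  cand <- data.frame(peak = cand[, 1], entry = cand[, 2],
                     distance = dist[cand])
  cand <- cand[order(cand$distance, cand$peak, cand$entry), , drop = FALSE]
  used_p <- logical(np); used_e <- logical(ne)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$peak[i]; e <- cand$entry[i]
    if (!used_p[p] && !used_e[e]) {
      keep[i] <- TRUE; used_p[p] <- TRUE; used_e[e] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Identify detected peaks against the reference library
#'
#' Each non-RIP peak is matched to the named library entry lying within
#' both tolerances that minimises the scaled Euclidean distance
#' `sqrt((dRT/s1)^2 + (dRDT/s2)^2)`. Assignment is greedy one-to-one by
#' ascending distance, so each library entry is claimed by at most one
#' peak (a monomer and a dimer are distinct entries and can never collapse
#' onto one peak, and a spurious neighbour cannot steal an entry from the
#' peak that sits on it). Peaks with no admissible entry are returned with
#' status `not_identified`. Unidentified ("N.I.") library rows are never
#' matched against.
#'
#' @param peaks a peak table from [detect_peaks()] or [consensus_peaks()]
#' @param library a [reference_library()]; its named subset must be
#'   collision-free under the tolerances (else an error lists the
#'   colliding entries)
#' @param config a [match_config()]
#' @return data.frame: the non-RIP peak columns plus `status`
#'   (`"identified"`/`"not_identified"`), `group_id`, `compound_name`,
#'   `form`, `cas_number`, `distance`
#' @export
match_peaks <- function(peaks, library, config = match_config()) {
  stopifnot(inherits(library, "reference_library"))
  entries <- named_entries(library)
  check_library_unique(entries, config$tol_retention_s,
                       config$tol_relative_drift)
  peaks <- peaks[!peaks$is_rip, , drop = FALSE]
  out <- peaks
  n <- nrow(peaks)
  out$status <- rep("not_identified", n)
  out$group_id <- rep(NA_integer_, n)
  out$compound_name <- rep(NA_character_, n)
  out$form <- rep(NA_character_, n)
  out$cas_number <- rep(NA_character_, n)
  out$distance <- rep(NA_real_, n)
  asn <- greedy_assign(peaks, entries, config)
  if (nrow(asn)) {
    out$status[asn$peak] <- "identified"
    out$group_id[asn$peak] <- entries$group_id[asn$entry]
    out$compound_name[asn$peak] <- entries$compound_name[asn$entry]
    out$form[asn$peak] <- entries$form[asn$entry]
    out$cas_number[asn$peak] <- entries$cas_number[asn$entry]
    out$distance[asn$peak] <- asn$distance
  }
  rownames(out) <- NULL
  out
}

#' Assign library group ids to peaks (full library)
#'
#' Profiling needs a compound-group coordinate for every peak, including
#' the unidentified ones, so this helper runs the same greedy one-to-one
#' assignment as [match_peaks()] but against the full library (N.I. rows
#' included) and without the uniqueness precondition; residual ambiguity is
#' resolved by distance. Peaks with no entry within tolerance get `NA`.
#'
#' @inheritParams match_peaks
#' @return `peaks` (non-RIP rows) with `group_id`, `form`,
#'   `compound_name`, `distance` columns appended
#' @export
assign_groups <- function(peaks, library, config = match_config()) {
  stopifnot(inherits(library, "reference_library"))
  peaks <- peaks[!peaks$is_rip, , drop = FALSE]
  out <- peaks
  n <- nrow(peaks)
  out$group_id <- rep(NA_integer_, n)
  out$form <- rep(NA_character_, n)
  out$compound_name <- rep(NA_character_, n)
  out$distance <- rep(NA_real_, n)
  asn <- greedy_assign(peaks, library, config)
  if (nrow(asn)) {
    out$group_id[asn$peak] <- library$group_id[asn$entry]
    out$form[asn$peak] <- library$form[asn$entry]
    out$compound_name[asn$peak] <- library$compound_name[asn$entry]
    out$distance[asn$peak] <- asn$distance
  }
  rownames(out) <- NULL
  out
}

#' Summarise an identification run
#'
#' @param idents output of [match_peaks()]
#' @return list with `n_detected` (non-RIP peaks), `n_identified`,
#'   `n_distinct_compounds` (distinct names among identified peaks), and
#'   `per_compound`, a named list mapping compound name to the character
#'   vector of forms found
#' @export
#' @examples
#' \donttest{
#' sp <- generate_spectrum(library_peak_specs(default_library()),
#'                         noise_sd = 0, seed = 1)
#' s <- summarize_identifications(
#'   match_peaks(detect_peaks(sp), default_library()))
#' c(s$n_detected, s$n_identified, s$n_distinct_compounds)  # 31 23 13
#' }
summarize_identifications <- function(idents) {
  iden <- idents[idents$status == "identified", , drop = FALSE]
  per <- lapply(split(iden$form, iden$compound_name), unname)
  list(n_detected = nrow(idents),
       n_identified = nrow(iden),
       n_distinct_compounds = length(unique(iden$compound_name)),
       per_compound = per)
}

#' Write an identification table to CSV
#'
#' @param idents output of [match_peaks()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_identifications <- function(idents, path) {
  cols <- intersect(c("retention_time_s", "drift_time_ms",
                      "relative_drift_time", "intensity_V", "occurrence",
                      "status", "group_id", "compound_name", "form",
                      "cas_number", "distance"), names(idents))
  data.table::fwrite(idents[, cols, drop = FALSE], path)
  invisible(path)
}
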