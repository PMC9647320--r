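#' Mean intensity per compound group and form
#'
#' Averages consensus intensities per (group, form) for one location. The
#' consensus intensity is already the arithmetic mean over the replicates
#' in which the peak occurred; should several consensus peaks map to the
#' same (group, form), their occurrence-weighted mean is taken.
#'
#' @param consensus a consensus table from [consensus_peaks()] annotated
#'   with `group_id` and `form` columns (see [assign_groups()])
#' @return data.frame with columns `group_id`, `form`,
#'   `mean_intensity_V`, `occurrence`
#' @export
mean_group_intensity <- function(consensus) {
  stopifnot(all(c("group_id", "form", "intensity_V") %in% names(consensus)))
  x <- consensus[!is.na(consensus$group_id) &
                   !(consensus$is_rip %||% FALSE), , drop = FALSE]
  if (nrow(x) == 0)
    return(data.frame(group_id = integer(), form = character(),
                      mean_intensity_V = numeric(),
                      occurrence = integer()))
  occ <- if ("occurrence" %in% names(x)) x$occurrence else rep(1L, nrow(x))
  key <- interaction(x$group_id, x$form, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(x)), key), function(idx) {
    data.frame(group_id = x$group_id[idx[1]], form = x$form[idx[1]],
               mean_intensity_V = sum(x$intensity_V[idx] * occ[idx]) /
                 sum(occ[idx]),
               occurrence = as.integer(max(occ[idx])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_id, out$form), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Outdoor-normalized relative-intensity score
#'
#' The fold ratio is `indoor / outdoor`. The display score is zero-centred
#' and signed: `fold - 1` for enrichment, `-(1/fold - 1)` for depletion,
#' so a compound at outdoor level scores 0, a compound 4x more intense
#' scores 3, and a compound 4x less intense scores -3. The score is odd
#' under `fold -> 1/fold`. Folds are reported alongside so a plain-ratio
#' reading remains available.
#'
#' @param indoor_mean_V mean intensity at the studied location (V)
#' @param outdoor_mean_V mean intensity in outdoor air (V)
#' @return list with numeric vectors `fold` and `score`
#' @export
#' @examples
#' relative_score(8, 2)  # fold 4, score 3
relative_score <- function(indoor_mean_V, outdoor_mean_V) {
  check_positive(indoor_mean_V = indoor_mean_V,
                 outdoor_mean_V = outdoor_mean_V)
  fold <- indoor_mean_V / outdoor_mean_V
  score <- ifelse(fold >= 1, fold - 1, -(1 / fold - 1))
  list(fold = fold, score = score)
}

#' Aggregate per-form scores to compound groups
#'
#' The relative intensities of the monomer, dimer and trimer of an analyte
#' are added: group score is the sum of its form scores. The group fold is
#' the intensity-weighted ratio `sum(indoor) / sum(outdoor)` when the
#' means are available, else the mean of the form folds (exact whenever
#' all forms share one fold).
#'
#' @param per_form data.frame with columns `group_id`, `form`, `score`,
#'   and either (`indoor_mean_V`, `outdoor_mean_V`) or `fold`
#' @return data.frame with columns `group_id`, `fold`, `score`,
#'   `censored` (any form censored, if a `censored` column is present)
#' @export
#' @examples
#' aggregate_forms(data.frame(group_id = 1, form = c("monomer", "dimer"),
#'                            fold = c(2.2, 1.8), score = c(1.2, 0.8)))
aggregate_forms <- function(per_form) {
  stopifnot(all(c("group_id", "score") %in% names(per_form)))
  rows <- lapply(split(per_form, per_form$group_id), function(g) {
    fold <- if (all(c("indoor_mean_V", "outdoor_mean_V") %in% names(g)))
      sum(g$indoor_mean_V) / sum(g$outdoor_mean_V)
    else mean(g$fold)
    data.frame(group_id = g$group_id[1], fold = fold,
               score = sum(g$score),
               censored = if ("censored" %in% names(g)) any(g$censored)
                          else FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-location relative-intensity profiles
#'
#' Builds the outdoor-normalized profile of every indoor location: per
#' compound group, the fold ratio of its mean intensity (forms pooled as
#' in [aggregate_forms()]) against the outdoor baseline, and the
#' zero-centred score. Groups not detected at a location score 0 (fold 1).
#' Groups detected indoors but absent from the outdoor baseline are
#' normalized against `outdoor_floor` and flagged `censored`, since a
#' ratio to zero is undefined.
#'
#' @param location_tables named list: location name -> consensus table
#'   from [consensus_peaks()]
#' @param library a [reference_library()]
#' @param outdoor_name name of the baseline location (must be present)
#' @param config a [match_config()] used to assign groups
#' @param outdoor_floor intensity floor (V) substituted for an outdoor
#'   mean when a group is undetected outdoors
#' @return data.frame of class `location_profiles` with columns
#'   `location`, `group_id`, `compound_name`, `fold`, `score`, `censored`;
#'   one row per indoor location and library group, in group order
#' @export
build_profiles <- function(location_tables, library,
                           outdoor_name = "outdoor",
                           config = match_config(),
                           outdoor_floor = 1e-3) {
  stopifnot(inherits(library, "reference_library"),
            is.list(location_tables))
  if (!outdoor_name %in% names(location_tables))
    stop(sprintf("outdoor location '%s' missing from location_tables",
                 outdoor_name), call. = FALSE)
  check_positive(outdoor_floor = outdoor_floor)
  groups <- sort(unique(library$group_id))
  gname <- vapply(groups, function(g) {
    nm <- unique(library$compound_name[library$group_id == g])
    nm[1]
  }, character(1))
  means <- lapply(location_tables, function(tab)
    mean_group_intensity(assign_groups(tab, library, config)))
  outdoor <- means[[outdoor_name]]
  indoor_names <- setdiff(names(location_tables), outdoor_name)
  rows <- list()
  for (loc in indoor_names) {
    m <- means[[loc]]
    per_form <- NULL
    for (i in seq_len(nrow(m))) {
      o <- outdoor$mean_intensity_V[outdoor$group_id == m$group_id[i] &
                                      outdoor$form == m$form[i]]
      censored <- length(o) == 0
      o <- if (censored) outdoor_floor else o
      rs <- relative_score(m$mean_intensity_V[i], o)
      per_form <- rbind(per_form,
                        data.frame(group_id = m$group_id[i],
                                   form = m$form[i],
                                   indoor_mean_V = m$mean_intensity_V[i],
                                   outdoor_mean_V = o,
                                   fold = rs$fold, score = rs$score,
                                   censored = censored))
    }
    agg <- if (is.null(per_form))
      data.frame(group_id = integer(), fold = numeric(),
                 score = numeric(), censored = logical())
    else aggregate_forms(per_form)
    full <- data.frame(location = loc, group_id = groups,
                       compound_name = gname, fold = 1, score = 0,
                       censored = FALSE, stringsAsFactors = FALSE)
    hit <- match(agg$group_id, full$group_id)
    full$fold[hit] <- agg$fold
    full$score[hit] <- agg$score
    full$censored[hit] <- agg$censored
    rows[[loc]] <- full
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("location_profiles", "data.frame")
  out
}

#' Replicate stability report
#'
#' Quantifies measurement stability per location: for every (location,
#' compound group, form) the per-replicate intensity series from the
#' consensus table, its mean, and its coefficient of variation (sample
#' standard deviation over mean, computed over the replicates in which the
#' peak occurred). Locations are ranked by their median CV; ties are
#' broken by location name order. Requires at least two replicates.
#'
#' @param location_tables named list: location -> consensus table from
#'   [consensus_peaks()]
#' @param library a [reference_library()]
#' @param config a [match_config()]
#' @return an object of class `stability_report`: list with `per_series`
#'   (data.frame `location`, `group_id`, `form`, `n`, `mean_V`, `cv`, and
#'   list-column `series`), `location_ranking` (data.frame `location`,
#'   `median_cv`, `rank`), `most_stable`, `least_stable`
#' @export
stability_report <- function(location_tables, library,
                             config = match_config()) {
  stopifnot(is.list(location_tables), length(location_tables) >= 1)
  rows <- list()
  for (loc in names(location_tables)) {
    tab <- location_tables[[loc]]
    if (!"intensity_series" %in% names(tab) ||
        (nrow(tab) > 0 && tab$n_replicates[1] < 2))
      stop("stability_report needs consensus tables with >= 2 replicates",
           call. = FALSE)
    ann <- assign_groups(tab, library, config)
    ann <- ann[!is.na(ann$group_id), , drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      s <- ann$intensity_series[[i]]
      v <- s[!is.na(s)]
      rows[[length(rows) + 1L]] <-
        data.frame(location = loc, group_id = ann$group_id[i],
                   form = ann$form[i], n = length(v), mean_V = mean(v),
                   cv = if (length(v) >= 2) stats::sd(v) / mean(v) else NA_real_,
                   series = I(list(s)), stringsAsFactors = FALSE)
    }
  }
  per_series <- if (length(rows)) do.call(rbind, rows) else
    data.frame(location = character(), group_id = integer(),
               form = character(), n = integer(), mean_V = numeric(),
               cv = numeric())
  med <- vapply(names(location_tables), function(loc) {
    cvs <- per_series$cv[per_series$location == loc]
    if (length(cvs)) stats::median(cvs, na.rm = TRUE) else NA_real_
  }, numeric(1))
  ord <- order(med, names(location_tables))  # ties: location name order
  ranking <- data.frame(location = names(location_tables)[ord],
                        median_cv = unname(med[ord]),
                        rank = seq_along(med), stringsAsFactors = FALSE)
  structure(list(per_series = per_series, location_ranking = ranking,
                 most_stable = ranking$location[1],
                 least_stable = ranking$location[nrow(ranking)]),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Replicate stability report\n")
  cat(sprintf("  most stable:  %s\n  least stable: %s\n",
              x$most_stable, x$least_stable))
  print(x$location_ranking, row.names = FALSE)
  invisible(x)
}

#' Write location profiles to CSV
#'
#' @param profiles output of [build_profiles()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_profiles <- function(profiles, path) {
  data.table::fwrite(as.data.frame(profiles), path)
  invisible(path)
}
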