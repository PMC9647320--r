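#' Reference library of VOC signatures
#'
#' The identification database: one row per product-ion signal (monomer,
#' dimer or trimer of a compound group), holding the GC retention time in
#' seconds and the RIP-relative drift time. Unidentified signals carry the
#' sentinel name `"N.I."` and an empty CAS number. The packaged library
#' (see [default_library()]) holds the 31 signals observed across a
#' 16-location air-sampling campaign: 20 compound groups, 23 named entries
#' covering 13 distinct compounds, and 8 unidentified entries.
#'
#' Relative drift times of analytes must lie strictly between 1.0 (the RIP
#' itself) and 1.4; the packaged values span 1.012-1.333.
#'
#' `cas_annotation` flags transcription caveats; the packaged library marks
#' the propanoic acid CAS number, printed identically to propanal's, as
#' `"printed_as_is"`.
#'
#' @param entries data.frame with columns `group_id`, `compound_name`,
#'   `cas_number`, `form`, `retention_time_s`, `relative_drift_time` and
#'   optionally `cas_annotation`
#' @return an object of class `reference_library` (a data.frame)
#' @export
reference_library <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("group_id", "compound_name", "cas_number", "form",
            "retention_time_s", "relative_drift_time")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("missing library columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"cas_annotation" %in% names(entries)) entries$cas_annotation <- ""
  entries$cas_number[is.na(entries$cas_number)] <- ""
  entries$cas_annotation[is.na(entries$cas_annotation)] <- ""
  entries$group_id <- as.integer(entries$group_id)
  if (any(is.na(entries$group_id)) ||
      any(entries$group_id < 1L | entries$group_id > 20L))
    stop("group_id must be an integer in [1, 20]", call. = FALSE)
  if (!all(entries$form %in% c("monomer", "dimer", "trimer")))
    stop("form must be one of monomer, dimer, trimer", call. = FALSE)
  check_positive(retention_time_s = entries$retention_time_s)
  rdt <- entries$relative_drift_time
  if (any(!is.finite(rdt)) || any(rdt <= 1.0 | rdt >= 1.4))
    stop("relative_drift_time must lie in (1.0, 1.4) for analytes",
         call. = FALSE)
  structure(entries[, c(need, "cas_annotation")],
            class = c("reference_library", "data.frame"))
}

#' Read a reference library from TSV
#'
#' Tab-delimited UTF-8 with a header row; columns as in
#' [reference_library()]; `"N.I."` marks unidentified entries.
#'
#' @param path TSV file path
#' @return a [reference_library()]
#' @export
read_reference_library <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, fill = TRUE,
                          colClasses = list(character = c("compound_name",
                                                          "cas_number",
                                                          "form")),
                          showProgress = FALSE)
  reference_library(as.data.frame(dt))
}

#' The packaged reference library
#'
#' @return the 31-entry [reference_library()] shipped with the package
#' @export
#' @examples
#' lib <- default_library()
#' library_summary(lib)
default_library <- function() {
  read_reference_library(system.file("extdata", "reference_library.tsv",
                                     package = "airims", mustWork = TRUE))
}

#' Named (identifiable) subset of a library
#'
#' Drops the `"N.I."` sentinel rows; this subset is what peak
#' identification matches against.
#'
#' @param library a [reference_library()]
#' @return a [reference_library()] with only named entries
#' @export
named_entries <- function(library) {
  stopifnot(inherits(library, "reference_library"))
  reference_library(library[library$compound_name != .NI, , drop = FALSE])
}

#' Library head counts
#'
#' @param library a [reference_library()]
#' @return list with `n_entries`, `n_groups`, `n_named`,
#'   `n_distinct_compounds`, `n_unidentified`
#' @export
library_summary <- function(library) {
  stopifnot(inherits(library, "reference_library"))
  named <- library$compound_name != .NI
  list(n_entries = nrow(library),
       n_groups = length(unique(library$group_id)),
       n_named = sum(named),
       n_distinct_compounds = length(unique(library$compound_name[named])),
       n_unidentified = sum(!named))
}

#' Find colliding library entries
#'
#' Two entries collide when their retention times and relative drift times
#' are simultaneously within the matching tolerances: a peak sitting on one
#' entry could then equally claim the other, violating the principle that
#' no two analytes share both coordinates.
#'
#' @param library a [reference_library()]
#' @param tol_retention_s retention-time tolerance (s)
#' @param tol_relative_drift relative-drift-time tolerance
#' @return data.frame of colliding index pairs (possibly empty) with the
#'   offending coordinate differences
#' @export
library_collisions <- function(library, tol_retention_s = 3,
                               tol_relative_drift = 0.01) {
  stopifnot(inherits(library, "reference_library"))
  check_positive(tol_retention_s = tol_retention_s,
                 tol_relative_drift = tol_relative_drift)
  n <- nrow(library)
  out <- list()
  if (n >= 2) {
    idx <- utils::combn(n, 2)
    drt <- abs(library$retention_time_s[idx[1, ]] -
               library$retention_time_s[idx[2, ]])
    drd <- abs(library$relative_drift_time[idx[1, ]] -
               library$relative_drift_time[idx[2, ]])
    hit <- drt <= tol_retention_s & drd <= tol_relative_drift
    if (any(hit))
      out <- data.frame(i = idx[1, hit], j = idx[2, hit],
                        delta_retention_s = drt[hit],
                        delta_relative_drift = drd[hit])
  }
  if (!length(out))
    out <- data.frame(i = integer(), j = integer(),
                      delta_retention_s = numeric(),
                      delta_relative_drift = numeric())
  out
}

#' Assert that a library is collision-free under given tolerances
#'
#' @inheritParams library_collisions
#' @return `TRUE` invisibly, or an error listing the colliding entries
#' @export
check_library_unique <- function(library, tol_retention_s = 3,
                                 tol_relative_drift = 0.01) {
  coll <- library_collisions(library, tol_retention_s, tol_relative_drift)
  if (nrow(coll)) {
    desc <- apply(coll, 1, function(r) {
      i <- as.integer(r[["i"]]); j <- as.integer(r[["j"]])
      sprintf("[%s %s (%g s, %.3f)] ~ [%s %s (%g s, %.3f)]",
              library$compound_name[i], library$form[i],
              library$retention_time_s[i], library$relative_drift_time[i],
              library$compound_name[j], library$form[j],
              library$retention_time_s[j], library$relative_drift_time[j])
    })
    stop("library entries collide under the matching tolerances:\n  ",
         paste(desc, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reconstruct absolute drift times for library entries
#'
#' Library drift coordinates are RIP-relative; the absolute drift time on a
#' given device is `relative_drift_time * rip_drift_time`.
#'
#' @param library a [reference_library()]
#' @param device a [device_config()]
#' @return numeric vector of drift times (ms), one per entry
#' @export
library_drift_times <- function(library, device = device_config()) {
  stopifnot(inherits(library, "reference_library"))
  library$relative_drift_time * device$rip_drift_time_ms
}
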