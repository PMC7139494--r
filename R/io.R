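## Delimited-text readers and writers: behavioural action streams,
## connectivity matrices (square or long format), network-spec and
## prior configuration files, and persisted posterior samples.

#' Write BART sessions to CSV
#'
#' One row per observed action, columns `subject_id, trial, occasion,
#' action, burst` (the burst flag is the trial's outcome repeated on
#' each of its rows).
#'
#' @param sessions list of [bart_session()] objects.
#' @param path output file.
#' @export
write_behaviour <- function(sessions, path) {
  rows <- lapply(sessions, function(ses) {
    do.call(rbind, lapply(ses$trials, function(tr) {
      data.frame(subject_id = ses$subject_id, trial = tr$k,
                 occasion = seq_along(tr$actions), action = tr$actions,
                 burst = as.integer(tr$burst))
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(subject_id = character(0), trial = integer(0),
                     occasion = integer(0), action = integer(0),
                     burst = integer(0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read BART sessions from CSV
#'
#' Reads the format written by [write_behaviour()], groups rows into
#' sessions, and validates every session invariant (consecutive trials,
#' consecutive occasions, a cash only as the final action, all-pump
#' burst trials).
#'
#' @param path CSV file with header
#'   `subject_id, trial, occasion, action, burst`.
#' @return list of [bart_session()] objects, in order of first
#'   appearance.
#' @export
read_behaviour <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("no such file:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "occasion", "action", "burst")
  if (!all(need %in% names(df)))
    stop_invalid(paste("behaviour file must have columns:",
                       paste(need, collapse = ", ")))
  if (!nrow(df)) return(list())
  bad <- which(!df$action %in% c(0L, 1L) | !df$burst %in% c(0L, 1L) |
                 is.na(df$trial) | is.na(df$occasion))
  if (length(bad))
    stop_invalid(sprintf("malformed row(s) at line(s): %s",
                         paste(head(bad + 1L, 5L), collapse = ", ")))
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    ks <- sort(unique(sub$trial))
    if (!identical(as.integer(ks), seq_along(ks)))
      stop_invalid(sprintf("subject %s: trial indices must be 1..K consecutive", id))
    trials <- lapply(ks, function(k) {
      tr <- sub[sub$trial == k, , drop = FALSE]
      tr <- tr[order(tr$occasion), , drop = FALSE]
      if (!identical(as.integer(tr$occasion), seq_len(nrow(tr))))
        stop_invalid(sprintf("subject %s trial %d: occasions must be 1..J consecutive",
                             id, k))
      a <- as.integer(tr$action)
      cash <- which(a == 0L)
      if (length(cash) && any(cash != length(a)))
        stop_invalid(sprintf("subject %s trial %d: actions after the cash", id, k))
      if (length(unique(tr$burst)) != 1L)
        stop_invalid(sprintf("subject %s trial %d: inconsistent burst flag", id, k))
      list(actions = a, burst = tr$burst[1] == 1L)
    })
    bart_session(id, trials)
  })
}

#' Write connectivity matrices to CSV
#'
#' Square format: one file per subject (`<subject_id>_connectivity.csv`
#' under `dir`) with ROI labels as header row and first column.
#'
#' @param connectivity named list of [connectivity_matrix()] objects.
#' @param dir output directory (created if missing).
#' @return the written file paths, invisibly.
#' @export
write_connectivity <- function(connectivity, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(connectivity), function(id) {
    p <- file.path(dir, paste0(id, "_connectivity.csv"))
    write.csv(as.data.frame(unclass(connectivity[[id]])), p, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}

parse_square_connectivity <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  connectivity_matrix(as.matrix(df))
}

parse_long_connectivity <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "roi_i", "roi_j", "fa")
  if (!all(need %in% names(df)))
    stop_invalid(paste("long connectivity file must have columns:",
                       paste(need, collapse = ", ")))
  labs <- roi_labels()
  out <- lapply(split(df, df$subject_id), function(sub) {
    M <- matrix(0, 12L, 12L, dimnames = list(labs, labs))
    for (r in seq_len(nrow(sub))) {
      i <- sub$roi_i[r]; j <- sub$roi_j[r]
      if (!i %in% labs || !j %in% labs)
        stop_invalid(sprintf("unknown ROI label '%s' or '%s'", i, j))
      M[i, j] <- M[j, i] <- sub$fa[r]
    }
    connectivity_matrix(M)
  })
  out[unique(df$subject_id)]
}

#' Read connectivity matrices
#'
#' Accepts either a directory of per-subject square 12x12 CSV matrices
#' (files named `<subject_id>_connectivity.csv`), a single square
#' matrix file, or a single long-format file with columns
#' `subject_id, roi_i, roi_j, fa`.  Near-symmetric input (discrepancy
#' `<= 1e-9`) is symmetrised; anything larger is rejected.
#'
#' @param path file or directory.
#' @param subject_id label used when `path` is a single square matrix.
#' @return named list of [connectivity_matrix()] objects.
#' @export
read_connectivity <- function(path, subject_id = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "_connectivity\\.csv$",
                        full.names = TRUE)
    if (!length(files)) stop_invalid(paste("no connectivity files in", path))
    out <- lapply(files, parse_square_connectivity)
    names(out) <- sub("_connectivity\\.csv$", "", basename(files))
    return(out)
  }
  if (!file.exists(path)) stop_invalid(paste("no such file:", path))
  header <- names(read.csv(path, nrows = 1L))
  if ("roi_i" %in% header) return(parse_long_connectivity(path))
  out <- list(parse_square_connectivity(path))
  names(out) <- subject_id %||% sub("(_connectivity)?\\.csv$", "", basename(path))
  out
}

#' Read or write network specifications
#'
#' JSON mapping of network name to a list of ROI-label pairs.
#'
#' @param path JSON file.
#' @return list of [network_spec()] objects.
#' @export
read_network_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(names(cfg), function(nm) network_spec(nm, cfg[[nm]]))
}

#' @rdname read_network_spec
#' @param networks list of [network_spec()] objects.
#' @export
write_network_spec <- function(networks, path) {
  cfg <- setNames(lapply(networks, function(nw) unname(nw$pairs)),
                  vapply(networks, `[[`, character(1), "name"))
  jsonlite::write_json(cfg, path, pretty = TRUE)
  invisible(path)
}

#' Persist posterior samples as delimited text
#'
#' Writes the draws as one CSV (columns `chain`, `iteration`, then one
#' column per scalar parameter) plus a JSON sidecar with the full
#' sampling configuration, so a run can be reproduced exactly.
#'
#' @param fit a [bjm_fit()].
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_samples <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- lapply(seq_along(fit$draws), function(ch)
    data.frame(chain = ch, iteration = seq_len(nrow(fit$draws[[ch]])),
               fit$draws[[ch]], check.names = FALSE))
  csv <- file.path(dir, "samples.csv")
  write.csv(do.call(rbind, tabs), csv, row.names = FALSE, quote = FALSE)
  meta <- fit$meta
  meta$priors <- unclass(meta$priors)
  meta$subject_ids <- fit$subject_ids
  js <- file.path(dir, "samples_meta.json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(samples = csv, meta = js))
}

#' Read prior overrides from a JSON config file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path JSON file with any of the [bjm_priors()] fields.
#' @return a `bjm_priors` object.
#' @export
read_priors <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(bjm_priors))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_invalid(paste("unknown prior keys:", paste(bad, collapse = ", ")))
  do.call(bjm_priors, cfg)
}
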