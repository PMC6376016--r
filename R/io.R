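# Serialisation helpers. All floating-point values are written with 17
# significant digits so that round-trips are exact for doubles.
fmt17 <- function(x) {
  if (is.double(x)) trimws(formatC(x, digits = 17, format = "g"))
  else as.character(x)
}

write_tidy_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) out[[j]] <- fmt17(out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a time course to CSV with a metadata sidecar
#'
#' The CSV has a `time_s` column followed by one column per species;
#' a JSON sidecar (`<path>.meta.json`) records the value domain
#' (concentration or count), the compartment volume, the event count
#' for stochastic runs, and the package version. Floats carry 17
#' significant digits, so [read_timecourse_csv()] reproduces the
#' object exactly.
#'
#' @param tc A `pho_timecourse`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "pho_timecourse"))
  df <- cbind(time_s = tc$times, as.data.frame(tc$values))
  write_tidy_csv(df, path)
  meta <- list(domain = tc$domain, volume_um3 = tc$volume_um3,
               package_version = as.character(utils::packageVersion("phoregulon")))
  if (!is.null(attr(tc, "n_events"))) meta$n_events <- attr(tc, "n_events")
  if (!is.null(attr(tc, "seed"))) meta$seed <- attr(tc, "seed")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a time course written by [write_timecourse_csv()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read when
#'   present (defaults: concentration domain, 1 um^3).
#' @return A `pho_timecourse`.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s: ", path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  tc <- new_timecourse(df$time_s,
                       as.matrix(df[, -1, drop = FALSE]),
                       domain = meta$domain %||% "concentration",
                       volume_um3 = meta$volume_um3 %||% 1)
  if (!is.null(meta$n_events)) attr(tc, "n_events") <- meta$n_events
  tc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an observed dataset to CSV
#'
#' Columns `time_s`, `phoA` and, when present, `phoB`.
#'
#' @param dataset A `pho_dataset`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "pho_dataset"))
  write_tidy_csv(as.data.frame(dataset), path)
}

#' Read an observed dataset from CSV
#'
#' Expects a header `time_s,phoA[,phoB]`. Malformed lines (wrong field
#' count or non-numeric fields) abort with the offending line number.
#'
#' @param path CSV path.
#' @return A `pho_dataset`.
#' @export
read_dataset_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("dataset CSV needs a header and data: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("time_s", "phoA")) ||
      !(length(header) == 2 ||
        (length(header) == 3 && header[3] == "phoB"))) {
    stop("expected header 'time_s,phoA[,phoB]' in ", path)
  }
  n_fields <- length(header)
  rows <- matrix(NA_real_, length(lines) - 1, n_fields)
  for (i in seq.int(2, length(lines))) {
    if (!nzchar(trimws(lines[i]))) stop("empty line ", i, " in ", path)
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != n_fields) {
      stop("line ", i, " of ", path, ": expected ", n_fields,
           " fields, found ", length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("line ", i, " of ", path, ": non-numeric field '",
           fields[which(is.na(vals))[1]], "'")
    }
    rows[i - 1, ] <- vals
  }
  observed_dataset(rows[, 1], rows[, 2],
                   phoB = if (n_fields == 3) rows[, 3])
}

fit_to_list <- function(fit) {
  list(best_par = as.list(fit$best_par),
       best_rates = as.list(rate_values(fit$best_rates)),
       residual_norm = fit$residual_norm,
       scale_factors = as.list(fit$scale_factors),
       n_starts = nrow(fit$starts),
       n_converged = sum(fit$starts$converged),
       seed = fit$fitspec$seed)
}

#' Serialise a calibration result to JSON
#'
#' Accepts a single `pho_fit` or a `pho_two_step`; writes best
#' parameters, full rate set, residual norm, scale factors and
#' multi-start bookkeeping with full double precision.
#'
#' @param fit A `pho_fit` or `pho_two_step`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "pho_two_step")) {
    list(step1 = fit_to_list(fit$step1), step2 = fit_to_list(fit$step2),
         time_to_peak_shift_s = fit$time_to_peak_shift_s)
  } else if (inherits(fit, "pho_fit")) {
    list(step1 = fit_to_list(fit))
  } else {
    stop("fit must be a pho_fit or pho_two_step")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
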