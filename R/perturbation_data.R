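#' Perturbation time-course datasets
#'
#' A `perturbation_data` object holds time-resolved measurements of signaling
#' activities under combinations of stimuli (ligands, clamped to a constant
#' level per experiment) and inhibitors (recorded as binary applied/not-applied
#' flags; the numeric inhibition strength is a modelling parameter applied
#' later). It is the in-memory form of a MIDAS file.
#'
#' @param measurements Tibble with columns `experiment`, `time`, `signal`,
#'   `value`. `value` may be `NA` (missing measurement). Times must be
#'   non-negative; within an experiment each (time, signal) pair is unique.
#' @param treatments Tibble with columns `experiment`, `type` (`"stimulus"` or
#'   `"inhibitor"`), `name`, `level`. Stimulus levels are arbitrary
#'   non-negative numbers (typically 0/1 or 0/0.5/1); inhibitor levels are
#'   0/1 applied flags.
#' @param signals Optional character vector fixing the signal ordering;
#'   defaults to order of first appearance in `measurements`.
#'
#' @return An object of class `perturbation_data`: a list with elements
#'   `measurements`, `treatments`, `signals`, `stimuli`, `inhibitors`,
#'   `normalization` (named maxima after [normalize_dataset()], else `NULL`).
#' @export
perturbation_data <- function(measurements, treatments, signals = NULL) {
  measurements <- as_tibble(measurements)
  treatments <- as_tibble(treatments)
  if (nrow(treatments) == 0) {
    treatments <- tibble(experiment = character(), type = character(),
                         name = character(), level = numeric())
  }
  req <- c("experiment", "time", "signal", "value")
  if (!all(req %in% names(measurements))) {
    abort(paste0("measurements must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(treatments) > 0 &&
      !all(c("experiment", "type", "name", "level") %in% names(treatments))) {
    abort("treatments must have columns: experiment, type, name, level")
  }
  if (any(measurements$time < 0, na.rm = TRUE)) abort("times must be non-negative")
  bad <- treatments$type == "inhibitor" &
    (treatments$level < 0 | treatments$level > 1)
  if (any(bad)) abort("inhibitor levels must lie in [0, 1]")
  if (is.null(signals)) signals <- unique(measurements$signal)
  if (!all(measurements$signal %in% signals)) {
    abort("measurements reference signals absent from the signal set")
  }
  dup <- measurements |>
    dplyr::count(.data$experiment, .data$time, .data$signal) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("duplicate (experiment, time, signal) measurement")
  structure(
    list(
      measurements = dplyr::arrange(measurements, .data$experiment, .data$time,
                                    match(.data$signal, signals)),
      treatments = treatments,
      signals = signals,
      stimuli = as.character(unique(treatments$name[treatments$type == "stimulus"])),
      inhibitors = as.character(unique(treatments$name[treatments$type == "inhibitor"])),
      normalization = NULL
    ),
    class = "perturbation_data"
  )
}

#' @export
print.perturbation_data <- function(x, ...) {
  cat("<perturbation_data>\n")
  cat("  experiments:", n_experiments(x), "\n")
  cat("  signals:    ", length(x$signals), paste0("(", toString(head(x$signals, 8)),
      if (length(x$signals) > 8) ", ...)" else ")"), "\n")
  cat("  stimuli:    ", toString(x$stimuli), "\n")
  cat("  inhibitors: ", toString(x$inhibitors), "\n")
  cat("  normalized: ", !is.null(x$normalization), "\n")
  invisible(x)
}

#' @rdname perturbation_data
#' @param x A `perturbation_data` object.
#' @export
n_experiments <- function(x) length(experiment_ids(x))

#' @rdname perturbation_data
#' @export
experiment_ids <- function(x) unique(x$measurements$experiment)

#' Extract one experiment's treatments, times and measurement matrix
#'
#' @param x A `perturbation_data` object.
#' @param id Experiment identifier.
#' @return A list with `stimuli` (named levels), `inhibitors` (named 0/1
#'   flags), `times` (sorted), and `values` (matrix time x signal, `NA` where
#'   a signal was not measured at a time).
#' @export
get_experiment <- function(x, id) {
  if (!id %in% experiment_ids(x)) abort(paste0("unknown experiment: ", id))
  tr <- dplyr::filter(x$treatments, .data$experiment == id)
  mm <- dplyr::filter(x$measurements, .data$experiment == id)
  times <- sort(unique(mm$time))
  vals <- matrix(NA_real_, length(times), length(x$signals),
                 dimnames = list(NULL, x$signals))
  vals[cbind(match(mm$time, times), match(mm$signal, x$signals))] <- mm$value
  list(
    stimuli = setNames(tr$level[tr$type == "stimulus"], tr$name[tr$type == "stimulus"]),
    inhibitors = setNames(tr$level[tr$type == "inhibitor"], tr$name[tr$type == "inhibitor"]),
    times = times,
    values = vals
  )
}

#' Read a MIDAS-format perturbation dataset
#'
#' MIDAS is a CSV layout for perturbation experiments: `TR:<name>` columns are
#' treatments (a trailing `i`, as in `TR:RAFi`, marks an inhibitor), `DA:ALL`
#' or `DA:<signal>` columns give acquisition times, and `DV:<signal>` columns
#' give measured values. Rows sharing one treatment combination form one
#' experiment. Inhibitor columns are read as binary applied flags; the numeric
#' inhibition strength is supplied later, at modelling time.
#'
#' @param path Path to a MIDAS CSV file.
#' @return A [perturbation_data] object with one experiment per distinct
#'   treatment combination.
#' @export
read_midas <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- names(df)
  tr_cols <- grep("^TR:", cols, value = TRUE)
  da_cols <- grep("^DA:", cols, value = TRUE)
  dv_cols <- grep("^DV:", cols, value = TRUE)
  if (length(dv_cols) == 0) abort("MIDAS format error: no DV: columns")
  if (length(da_cols) == 0) {
    abort(paste0("MIDAS format error: no DA: column for DV columns ",
                 toString(dv_cols)))
  }
  for (cc in c(tr_cols, da_cols, dv_cols)) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(!is.na(df[[cc]]) & is.na(suppressWarnings(as.numeric(df[[cc]]))))
      abort(paste0("MIDAS parse error: non-numeric value in column ", cc,
                   if (length(bad)) paste0(", row ", bad[1]) else ""))
    }
  }
  signals <- sub("^DV:", "", dv_cols)
  is_inh <- grepl("i$", sub("^TR:", "", tr_cols))
  tr_names <- sub("^TR:", "", tr_cols)
  tr_names[is_inh] <- sub("i$", "", tr_names[is_inh])

  # experiment id = treatment signature
  tr_mat <- as.matrix(df[tr_cols])
  tr_mat[is.na(tr_mat)] <- 0
  sig <- apply(tr_mat, 1, function(r) {
    on <- which(r != 0)
    if (length(on) == 0) "control" else
      paste(paste0(tr_names[on], ifelse(is_inh[on], "i", ""), "=",
                   format(r[on], trim = TRUE)), collapse = "|")
  })
  exp_ids <- unique(sig)

  meas <- purrr::map_dfr(seq_along(dv_cols), function(j) {
    signame <- signals[j]
    da <- if (paste0("DA:", signame) %in% da_cols) {
      df[[paste0("DA:", signame)]]
    } else if ("DA:ALL" %in% da_cols) {
      df[["DA:ALL"]]
    } else {
      abort(paste0("MIDAS format error: no DA column for signal ", signame))
    }
    tibble(experiment = sig, time = as.numeric(da), signal = signame,
           value = as.numeric(df[[dv_cols[j]]]))
  })
  meas <- dplyr::filter(meas, !is.na(.data$time))

  treat <- purrr::map_dfr(which(!duplicated(sig)), function(r) {
    if (length(tr_cols) == 0) return(tibble())
    tibble(
      experiment = sig[r],
      type = ifelse(is_inh, "inhibitor", "stimulus"),
      name = tr_names,
      level = as.numeric(tr_mat[r, ])
    )
  })
  pd <- perturbation_data(meas, treat, signals = signals)
  # keep experiment ordering as in the file
  pd$measurements <- dplyr::arrange(pd$measurements,
                                    match(.data$experiment, exp_ids), .data$time)
  pd
}

#' Write a perturbation dataset as a MIDAS CSV file
#'
#' Emits columns in the order `TR:`, `DA:ALL`, `DV:`; each row is one
#' (experiment, time) pair with every signal's value (`NA` where missing), so
#' re-reading the file reproduces the dataset.
#'
#' @param x A [perturbation_data] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_midas <- function(x, path) {
  stopifnot(inherits(x, "perturbation_data"))
  tr_names <- c(x$stimuli, paste0(x$inhibitors, "i"))
  header <- c(paste0("TR:", tr_names), "DA:ALL", paste0("DV:", x$signals))
  rows <- list()
  for (id in experiment_ids(x)) {
    ex <- get_experiment(x, id)
    lev <- c(ex$stimuli[x$stimuli], ex$inhibitors[x$inhibitors])
    lev[is.na(lev)] <- 0
    for (ti in seq_along(ex$times)) {
      rows[[length(rows) + 1L]] <-
        c(unname(lev), ex$times[ti], unname(ex$values[ti, x$signals]))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (nrow(out) == 0) out <- as.data.frame(matrix(numeric(), 0, length(header)))
  names(out) <- header
  tryCatch(readr::write_csv(out, path, na = ""),
           error = function(e) abort(paste0("cannot write MIDAS file: ",
                                            conditionMessage(e))))
  invisible(path)
}

#' Normalize measurements by per-signal maxima
#'
#' Divides every value of each signal by the maximum value of that signal
#' across all experiments and time points, so that simulated states in
#' \eqn{[0,1]} are comparable with the data. The maxima are stored in the
#' returned object's `normalization` field; pass them via `maxima` to scale a
#' held-out dataset by the *training* maxima.
#'
#' @param x A [perturbation_data] object.
#' @param maxima Optional named numeric vector of per-signal maxima (from a
#'   training set). Defaults to the maxima of `x` itself.
#' @return A normalized [perturbation_data]; signals whose maximum is 0 (or
#'   all missing) are left unscaled with a warning.
#' @export
normalize_dataset <- function(x, maxima = NULL) {
  stopifnot(inherits(x, "perturbation_data"))
  if (is.null(maxima)) {
    maxima <- x$measurements |>
      dplyr::group_by(.data$signal) |>
      dplyr::summarise(m = if (all(is.na(.data$value))) NA_real_ else
        max(.data$value, na.rm = TRUE), .groups = "drop")
    maxima <- setNames(maxima$m, maxima$signal)[x$signals]
  }
  if (all(is.na(maxima))) abort("no finite values to normalize by")
  scal <- maxima
  degenerate <- is.na(scal) | scal == 0
  if (any(degenerate)) {
    warn(paste0("signals left unscaled (zero or missing maximum): ",
                toString(names(scal)[degenerate])))
    scal[degenerate] <- 1
  }
  x$measurements$value <- x$measurements$value /
    unname(scal[x$measurements$signal])
  x$normalization <- maxima
  x
}

#' Tidy measurements table of a perturbation dataset
#'
#' @param x A [perturbation_data] object.
#' @param ... Unused.
#' @return The long measurements tibble (`experiment`, `time`, `signal`,
#'   `value`).
#' @export
tidy.perturbation_data <- function(x, ...) x$measurements

#' @export
glance.perturbation_data <- function(x, ...) {
  tibble(
    n_experiments = n_experiments(x),
    n_signals = length(x$signals),
    n_stimuli = length(x$stimuli),
    n_inhibitors = length(x$inhibitors),
    n_points = sum(!is.na(x$measurements$value)),
    normalized = !is.null(x$normalization)
  )
}

#' Compare two perturbation datasets for equality
#'
#' Experiments are matched by their treatment combination (the MIDAS notion
#' of experiment identity), so datasets whose experiments merely carry
#' different labels still compare equal.
#'
#' @param a,b `perturbation_data` objects.
#' @param tol Numeric tolerance for values, times and treatment levels.
#' @return `TRUE` or `FALSE`.
#' @export
datasets_equal <- function(a, b, tol = 1e-9) {
  signature_map <- function(p) {
    ids <- experiment_ids(p)
    sig <- vapply(ids, function(id) {
      tr <- dplyr::filter(p$treatments, .data$experiment == id,
                          .data$level != 0) |>
        dplyr::arrange(.data$type, .data$name)
      paste(tr$type, tr$name, signif(tr$level, 9), collapse = ";")
    }, character(1))
    if (anyDuplicated(sig)) sig <- ids  # fall back to labels
    setNames(sig, ids)
  }
  key <- function(p) {
    mp <- signature_map(p)
    m <- p$measurements
    m$experiment <- unname(mp[m$experiment])
    dplyr::arrange(m, .data$experiment, .data$signal, .data$time)
  }
  ma <- key(a); mb <- key(b)
  if (!identical(ma$experiment, mb$experiment)) return(FALSE)
  if (nrow(ma) != nrow(mb)) return(FALSE)
  if (!identical(ma$signal, mb$signal)) return(FALSE)
  if (max(abs(ma$time - mb$time)) > tol) return(FALSE)
  va <- ma$value; vb <- mb$value
  if (!identical(is.na(va), is.na(vb))) return(FALSE)
  if (any(abs(va - vb) > tol, na.rm = TRUE)) return(FALSE)
  tkey <- function(p) {
    mp <- signature_map(p)
    p$treatments |>
      dplyr::filter(.data$level != 0) |>
      dplyr::mutate(experiment = unname(mp[.data$experiment])) |>
      dplyr::arrange(.data$experiment, .data$type, .data$name)
  }
  ta <- tkey(a); tb <- tkey(b)
  nrow(ta) == nrow(tb) && identical(ta$name, tb$name) &&
    all(abs(ta$level - tb$level) <= tol)
}
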