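#' Perturbation dataset
#'
#' The central data container: replicated, multi-condition time-series (or
#' steady-state) measurements of `n` molecules together with the perturbation
#' signals that were applied in each condition. Measurements enter as a long
#' tibble with one row per observed value; perturbation signals as a second
#' long tibble defined for every (condition, time) pair.
#'
#' Each (condition, replicate) pair forms one measurement *block* (one time
#' series, or a single steady-state vector). Time grids may be irregular but
#' must be strictly increasing within a block; in steady-state mode every
#' block holds exactly one time point and time-interval lengths are never
#' used.
#'
#' @param values Tibble/data frame with columns `condition`, `replicate`,
#'   `time`, `molecule`, `value`. Missing measurements may be encoded as `NA`
#'   values or simply omitted rows.
#' @param signals Tibble with columns `condition`, `time`, `perturbation`,
#'   `value`, or `NULL` for purely observational data. Signals are typically
#'   0/1 but may be quantitative.
#' @param mode `"timeseries"` or `"steadystate"`.
#' @param molecules,perturbations Optional character vectors fixing node
#'   order; defaults to order of first appearance.
#' @return An object of class `pert_dataset`.
#' @export
pert_dataset <- function(values, signals = NULL,
                         mode = c("timeseries", "steadystate"),
                         molecules = NULL, perturbations = NULL) {
  mode <- match.arg(mode)
  values <- tibble::as_tibble(values)
  req <- c("condition", "replicate", "time", "molecule", "value")
  if (!all(req %in% names(values))) {
    abort(sprintf("`values` must have columns %s.", paste(req, collapse = ", ")))
  }
  molecules <- molecules %||% unique(as.character(values$molecule))
  if (!is.null(signals)) {
    signals <- tibble::as_tibble(signals)
    perturbations <- perturbations %||% unique(as.character(signals$perturbation))
  } else {
    perturbations <- perturbations %||% character(0)
  }
  if (length(intersect(molecules, perturbations))) {
    abort("Molecule and perturbation names must be disjoint.")
  }

  keys <- dplyr::distinct(values, .data$condition, .data$replicate)
  blocks <- purrr::pmap(keys, function(condition, replicate) {
    sub <- values[values$condition == condition & values$replicate == replicate, ]
    times <- sort(unique(sub$time))
    if (mode == "steadystate" && length(times) != 1L) {
      abort(sprintf(
        "Steady-state block (condition %s, replicate %s) must have exactly one time point, found %d.",
        condition, replicate, length(times)))
    }
    if (any(diff(times) <= 0)) {
      abort(sprintf("Time grid not strictly increasing in condition %s, replicate %s.",
                    condition, replicate))
    }
    y <- matrix(NA_real_, length(times), length(molecules),
                dimnames = list(NULL, molecules))
    y[cbind(match(sub$time, times), match(as.character(sub$molecule), molecules))] <-
      sub$value
    x <- matrix(0, length(times), length(perturbations),
                dimnames = list(NULL, perturbations))
    if (!is.null(signals) && length(perturbations)) {
      sc <- signals[signals$condition == condition, ]
      for (tt in seq_along(times)) {
        row <- sc[sc$time == times[tt], ]
        if (nrow(row) < length(perturbations)) {
          missing_p <- setdiff(perturbations, as.character(row$perturbation))
          if (length(missing_p)) {
            abort(sprintf(
              "Perturbation signal for %s undefined at condition %s, time %g.",
              paste(missing_p, collapse = ", "), condition, times[tt]))
          }
        }
        x[tt, as.character(row$perturbation)] <- row$value
      }
    }
    list(condition = condition, replicate = replicate, times = times, y = y, x = x)
  })

  structure(
    list(molecules = molecules, perturbations = perturbations,
         mode = mode, blocks = blocks),
    class = "pert_dataset")
}

n_molecules <- function(dataset) length(dataset$molecules)
n_perturbations <- function(dataset) length(dataset$perturbations)

#' @export
print.pert_dataset <- function(x, ...) {
  cat(sprintf("<pert_dataset: %s>\n", x$mode))
  cat(sprintf("  %d molecules, %d perturbation nodes, %d blocks\n",
              n_molecules(x), n_perturbations(x), length(x$blocks)))
  tp <- unique(vapply(x$blocks, function(b) length(b$times), integer(1)))
  cat(sprintf("  time points per block: %s\n", paste(tp, collapse = ", ")))
  invisible(x)
}

#' Measurements as a long tibble
#'
#' @param x A [pert_dataset].
#' @param ... Unused.
#' @return Tibble with columns condition, replicate, time, molecule, value.
#' @method as_tibble pert_dataset
#' @export
as_tibble.pert_dataset <- function(x, ...) {
  purrr::map_dfr(x$blocks, function(b) {
    tidyr::expand_grid(time_idx = seq_along(b$times), molecule = x$molecules) |>
      dplyr::mutate(condition = b$condition, replicate = b$replicate,
                    time = b$times[.data$time_idx],
                    value = b$y[cbind(.data$time_idx, match(.data$molecule, x$molecules))]) |>
      dplyr::select("condition", "replicate", "time", "molecule", "value")
  })
}

#' Perturbation signals as a long tibble
#'
#' @param dataset A [pert_dataset].
#' @return Tibble with columns condition, time, perturbation, value (zero rows
#'   for observational data).
#' @export
perturbation_signals <- function(dataset) {
  if (!n_perturbations(dataset)) {
    return(tibble::tibble(condition = character(0), time = numeric(0),
                          perturbation = character(0), value = numeric(0)))
  }
  seen <- character(0)
  purrr::map_dfr(dataset$blocks, function(b) {
    key <- as.character(b$condition)
    if (key %in% seen) return(NULL)
    seen <<- c(seen, key)
    tidyr::expand_grid(time_idx = seq_along(b$times),
                       perturbation = dataset$perturbations) |>
      dplyr::mutate(condition = b$condition, time = b$times[.data$time_idx],
                    value = b$x[cbind(.data$time_idx,
                                      match(.data$perturbation, dataset$perturbations))]) |>
      dplyr::select("condition", "time", "perturbation", "value")
  })
}

# z matrix (T x (n+m)) of molecule values followed by perturbation signals
block_z <- function(block) cbind(block$y, block$x)

#' Perturbation scheme
#'
#' Describes how perturbation signals act: which molecules each perturbation
#' node targets (or `NULL` when targets are unknown, in which case every
#' molecule is a candidate target), whether signals are constant or
#' time-dependent, and their onset/offset times.
#'
#' Edges *into* perturbation nodes are never representable.
#'
#' @param target_map Named list mapping perturbation name to a character
#'   vector of target molecules, or `NULL` when targets are unknown.
#' @param type `"constant"` or `"onoff"`.
#' @param onset,offset Activity window in real time units (used by the
#'   simulator for `"onoff"` signals).
#' @export
pert_scheme <- function(target_map = NULL, type = c("constant", "onoff"),
                        onset = 0, offset = Inf) {
  type <- match.arg(type)
  structure(list(target_map = target_map, type = type,
                 onset = onset, offset = offset),
            class = "pert_scheme")
}
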