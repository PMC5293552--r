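# DREAM4-style tab-separated dialect: a header row ("Time" then molecule
# names), measurement blocks separated by blank lines, one block per
# (condition, replicate) series. A sidecar file in the same layout carries
# perturbation signals; an optional design table maps block number to
# condition and replicate ids.

parse_blocks <- function(lines, what, path) {
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) abort(sprintf("%s: file `%s` is empty.", what, path))
  header <- strsplit(lines[nonblank[1]], "\t", fixed = TRUE)[[1]]
  if (header[1] != "Time") {
    abort(sprintf("%s: line %d of `%s` must start a header row with `Time`.",
                  what, nonblank[1], path))
  }
  cols <- header[-1]
  if (anyDuplicated(cols)) {
    abort(sprintf("%s: duplicated column names (%s) in `%s`.",
                  what, paste(cols[duplicated(cols)], collapse = ", "), path))
  }
  blocks <- list(); cur_t <- c(); cur_v <- list()
  flush <- function() {
    if (length(cur_t)) {
      blocks[[length(blocks) + 1L]] <<-
        list(times = cur_t, values = do.call(rbind, cur_v))
    }
    cur_t <<- c(); cur_v <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (trimws(line) == "") { flush(); next }
    tok <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (identical(tok, header)) { flush(); next }  # repeated header
    if (length(tok) != length(header)) {
      abort(sprintf("%s: ragged row at line %d of `%s` (%d fields, expected %d).",
                    what, ln, path, length(tok), length(header)))
    }
    tval <- suppressWarnings(as.numeric(tok[1]))
    if (is.na(tval)) {
      abort(sprintf("%s: unparsable time value at line %d of `%s`.", what, ln, path))
    }
    if (length(cur_t) && tval <= cur_t[length(cur_t)]) {
      abort(sprintf("%s: non-increasing time at line %d of `%s`.", what, ln, path))
    }
    cur_t <- c(cur_t, tval)
    vals <- suppressWarnings(as.numeric(tok[-1]))
    cur_v[[length(cur_v) + 1L]] <- vals
  }
  flush()
  list(columns = cols, blocks = blocks)
}

#' Read a DREAM4-style time-series file
#'
#' @param path Measurement file: tab-separated, header `Time` plus one
#'   column per molecule, blank-line-separated blocks (one per condition /
#'   replicate series).
#' @param perturbations_path Optional sidecar in the same layout whose
#'   columns are perturbation signals, blocks aligned with the data blocks.
#' @param design_path Optional tab-separated table with columns `block`,
#'   `condition`, `replicate` mapping block number to ids; by default block
#'   k becomes condition `ck`, replicate 1.
#' @param mode `"timeseries"` or `"steadystate"` (single-row blocks).
#' @return A [pert_dataset].
#' @export
read_timeseries <- function(path, perturbations_path = NULL, design_path = NULL,
                            mode = "timeseries") {
  parsed <- parse_blocks(readLines(path), "data", path)
  nb <- length(parsed$blocks)
  design <- if (!is.null(design_path)) {
    d <- utils::read.delim(design_path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("block", "condition", "replicate") %in% names(d))) {
      abort("Design file needs columns block, condition, replicate.")
    }
    d[match(seq_len(nb), d$block), ]
  } else {
    data.frame(block = seq_len(nb), condition = sprintf("c%d", seq_len(nb)),
               replicate = 1L)
  }
  pert <- NULL
  if (!is.null(perturbations_path)) {
    pert <- parse_blocks(readLines(perturbations_path), "perturbations",
                         perturbations_path)
    if (length(pert$blocks) != nb) {
      abort(sprintf("Perturbation sidecar has %d blocks, data file has %d.",
                    length(pert$blocks), nb))
    }
  }
  mols <- parsed$columns
  perts <- if (!is.null(pert)) pert$columns else character(0)
  blocks <- purrr::map(seq_len(nb), function(k) {
    b <- parsed$blocks[[k]]
    y <- b$values; colnames(y) <- mols
    x <- if (!is.null(pert)) {
      xb <- pert$blocks[[k]]
      if (!isTRUE(all.equal(xb$times, b$times))) {
        abort(sprintf("Perturbation block %d has a different time grid than the data.", k))
      }
      xv <- xb$values; colnames(xv) <- perts
      xv
    } else matrix(numeric(0), nrow(y), 0)
    list(condition = design$condition[k], replicate = design$replicate[k],
         times = b$times, y = y, x = x)
  })
  ds <- structure(list(molecules = mols, perturbations = perts,
                       mode = mode, blocks = blocks),
                  class = "pert_dataset")
  if (mode == "steadystate") {
    bad <- which(vapply(ds$blocks, function(b) length(b$times) != 1L, logical(1)))
    if (length(bad)) {
      abort(sprintf("Steady-state mode: block(s) %s have more than one time point.",
                    paste(bad, collapse = ", ")))
    }
  }
  ds
}

#' Write a dataset in the DREAM4-style dialect
#'
#' Decimals are written with 6 significant digits; output is byte-for-byte
#' deterministic for a given dataset.
#'
#' @param dataset A [pert_dataset].
#' @param path Measurement file path.
#' @param perturbations_path,design_path Optional sidecar paths.
#' @export
write_timeseries <- function(dataset, path, perturbations_path = NULL,
                             design_path = NULL) {
  header <- paste(c("Time", dataset$molecules), collapse = "\t")
  out <- c()
  for (b in dataset$blocks) {
    rows <- vapply(seq_along(b$times), function(tt) {
      paste(c(fmt_num(b$times[tt]), fmt_num(b$y[tt, ])), collapse = "\t")
    }, character(1))
    out <- c(out, header, rows, "")
  }
  writeLines(out[-length(out)], path)
  if (!is.null(perturbations_path) && n_perturbations(dataset) > 0) {
    ph <- paste(c("Time", dataset$perturbations), collapse = "\t")
    pout <- c()
    for (b in dataset$blocks) {
      rows <- vapply(seq_along(b$times), function(tt) {
        paste(c(fmt_num(b$times[tt]), fmt_num(b$x[tt, ])), collapse = "\t")
      }, character(1))
      pout <- c(pout, ph, rows, "")
    }
    writeLines(pout[-length(pout)], perturbations_path)
  }
  if (!is.null(design_path)) {
    d <- purrr::imap_chr(dataset$blocks, function(b, k) {
      paste(k, b$condition, b$replicate, sep = "\t")
    })
    writeLines(c("block\tcondition\treplicate", d), design_path)
  }
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Tab-separated lines `source target label` with label 0 or 1; pairs
#' absent from the file default to 0.
#'
#' @param path File path.
#' @param molecules Optional molecule universe (defaults to all names seen
#'   in the file).
#' @param target_map Optional perturbation target map to attach.
#' @return A gold standard object.
#' @export
read_gold_standard <- function(path, molecules = NULL, target_map = NULL) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  edges <- tibble::tibble(source = character(0), target = character(0))
  seen <- new.env(parent = emptyenv())
  for (ln in seq_along(lines)) {
    tok <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(tok) != 3) {
      abort(sprintf("Gold standard line %d: expected `source<TAB>target<TAB>label`.", ln))
    }
    if (!tok[3] %in% c("0", "1")) {
      abort(sprintf("Gold standard line %d: label must be 0 or 1, got `%s`.", ln, tok[3]))
    }
    key <- paste(tok[1], tok[2])
    prev <- get0(key, envir = seen)
    if (!is.null(prev) && prev != tok[3]) {
      abort(sprintf("Contradictory labels for edge %s -> %s.", tok[1], tok[2]))
    }
    assign(key, tok[3], envir = seen)
    if (tok[3] == "1" && is.null(prev)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(source = tok[1], target = tok[2]))
    }
  }
  names_seen <- unique(unlist(lapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1:2])))
  molecules <- molecules %||% names_seen
  structure(list(edges = edges, molecules = molecules, target_map = target_map),
            class = "gold_standard")
}

#' @rdname read_gold_standard
#' @param gold A gold standard object.
#' @export
write_gold_standard <- function(gold, path) {
  writeLines(sprintf("%s\t%s\t1", gold$edges$source, gold$edges$target), path)
  invisible(path)
}

#' Read prior-knowledge edges onto a default prior
#'
#' Lines `source target rho` with rho in (0, 1]; the prior matrix starts at
#' its defaults and listed edges are overwritten. Entries for forbidden
#' edges are rejected with a warning.
#'
#' @param path File path (may be empty).
#' @param prior A default [spike_slab_prior] to overwrite.
#' @export
read_prior <- function(path, prior) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines)) return(prior)
  tok <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(tok) != 3)
  if (length(bad)) {
    abort(sprintf("Prior line %d: expected `source<TAB>target<TAB>rho`.", bad[1]))
  }
  edges <- tibble::tibble(source = vapply(tok, `[`, "", 1),
                          target = vapply(tok, `[`, "", 2),
                          rho = as.numeric(vapply(tok, `[`, "", 3)))
  if (any(is.na(edges$rho) | edges$rho <= 0 | edges$rho > 1)) {
    abort("Prior confidences must lie in (0, 1].")
  }
  set_prior_edges(prior, edges)
}

#' Write a ranked edge list
#'
#' Tab-separated `source target confidence`, sorted by descending
#' confidence with lexicographic (source, target) tie-break; deterministic
#' byte-for-byte for given scores.
#'
#' @param scores A `network_fit`, or a tibble with columns `source`,
#'   `target`, `score`.
#' @param path Output path.
#' @param include_perturbation_edges When `scores` is a fit: write
#'   perturbation-to-molecule edges too?
#' @export
write_edge_list <- function(scores, path, include_perturbation_edges = TRUE) {
  if (inherits(scores, "network_fit")) {
    scores <- ranking_from_fit(scores, include_perturbation_edges)
  }
  scores <- scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$source, .data$target)
  writeLines(sprintf("%s\t%s\t%s", scores$source, scores$target,
                     fmt_num(scores$score)), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  tok <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(source = vapply(tok, `[`, "", 1),
                 target = vapply(tok, `[`, "", 2),
                 score = as.numeric(vapply(tok, `[`, "", 3)))
}
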