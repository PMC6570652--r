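#' @useDynLib engramtrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov rnorm rpois runif sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

VALID_LABELS <- c("A", "B", "C", "D", "E", "F")
VALID_STAGES <- c("awake", "NREM", "REM")

#' Cell registry
#'
#' The shared registry every session matrix references: one row per extracted
#' cell, with its id, snapshot-frame centroid and (optionally) an
#' engram/non-engram flag.
#'
#' @param cell_id character vector of unique cell ids.
#' @param x,y numeric centroids in snapshot pixel coordinates (non-negative).
#' @param engram_flag logical vector or `NA` (unset).
#' @return A `cell_registry` object (data.frame subclass).
#' @export
cell_registry <- function(cell_id, x = NA_real_, y = NA_real_,
                          engram_flag = NA) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) {
    stop("duplicate cell_id in registry: ",
         paste(unique(cell_id[duplicated(cell_id)]), collapse = ", "))
  }
  n <- length(cell_id)
  reg <- data.frame(
    cell_id = cell_id,
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    engram_flag = rep_len(as.logical(engram_flag), n),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(reg$x) & (reg$x < 0 | reg$y < 0)
  if (any(bad)) stop("negative centroid coordinates for: ",
                     paste(reg$cell_id[bad], collapse = ", "))
  class(reg) <- c("cell_registry", "data.frame")
  reg
}

#' Trace matrix
#'
#' A cells x frames matrix of fluorescence values, tagged with whether it has
#' been baseline-normalized (delta F / F) already.
#'
#' @param values numeric matrix, cells in rows, frames in columns; rownames are
#'   cell ids.
#' @param normalized logical; `TRUE` when values are delta F / F.
#' @return A `trace_matrix` object.
#' @export
trace_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) && !all(is.finite(values))) {
    stop("trace matrix contains non-finite entries")
  }
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d frames, %s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "dF/F" else "raw F"))
  invisible(x)
}

#' Session set
#'
#' Ordered collection of per-session trace matrices over one shared cell
#' registry, with a session label (A-F), a stage (awake/NREM/REM) and a common
#' frame rate.
#'
#' @param sessions named list; each element is a list with fields `label`,
#'   `stage`, `frame_rate_hz`, `traces` (a [trace_matrix()]).
#' @param registry a [cell_registry()].
#' @return A `session_set` object.
#' @export
session_set <- function(sessions, registry) {
  stopifnot(inherits(registry, "cell_registry"))
  labels <- vapply(sessions, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate session label: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  if (!all(labels %in% VALID_LABELS)) {
    stop("session labels must be among ", paste(VALID_LABELS, collapse = ","))
  }
  stages <- vapply(sessions, `[[`, "", "stage")
  if (!all(stages %in% VALID_STAGES)) {
    stop("session stage must be one of ", paste(VALID_STAGES, collapse = ","))
  }
  rates <- vapply(sessions, `[[`, 0, "frame_rate_hz")
  if (any(rates <= 0)) stop("frame_rate_hz must be positive")
  if (length(unique(rates)) > 1) stop("frame_rate_hz must be identical across sessions")
  n_cells <- nrow(registry)
  for (s in sessions) {
    tm <- s$traces
    if (!inherits(tm, "trace_matrix")) stop("each session needs a trace_matrix")
    if (nrow(tm$values) != n_cells ||
        !identical(rownames(tm$values), registry$cell_id)) {
      stop("cell set mismatch: session ", s$label,
           " does not match the registry cell ids/order")
    }
  }
  names(sessions) <- labels
  ord <- order(match(labels, VALID_LABELS))
  structure(list(sessions = sessions[ord], registry = registry),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set> %d cells, %d sessions [%s]\n",
              nrow(x$registry), length(x$sessions),
              paste(names(x$sessions), collapse = " ")))
  invisible(x)
}

#' @rdname session_set
#' @param x a `session_set`.
#' @param label session label to extract.
#' @export
get_session <- function(x, label) {
  stopifnot(inherits(x, "session_set"))
  if (!label %in% names(x$sessions)) stop("missing session ", label)
  x$sessions[[label]]
}

#' Write a session set to disk
#'
#' One comma-delimited text file per session (frames in rows, header
#' `frame,<cell_id>,...`), plus a JSON manifest tying files, labels, stages,
#' frame rate and the registry together. [load_session_set()] inverts it.
#'
#' @param s a [session_set()].
#' @param out_dir output directory (created if absent).
#' @return Path to the written manifest JSON, invisibly usable downstream.
#' @export
write_session_set <- function(s, out_dir) {
  stopifnot(inherits(s, "session_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable output path: ", out_dir)
  entries <- lapply(s$sessions, function(sess) {
    file <- paste0("session_", sess$label, ".csv")
    m <- t(sess$traces$values)                    # frames x cells on disk
    # 17 significant digits so the write/load round trip is value-exact
    df <- data.frame(frame = seq_len(nrow(m)) - 1L, check.names = FALSE)
    for (j in seq_len(ncol(m))) {
      df[[colnames(m)[j]]] <- formatC(m[, j], digits = 17, format = "g")
    }
    write.csv(df, file.path(out_dir, file), row.names = FALSE, quote = FALSE)
    list(label = sess$label, stage = sess$stage, file = file,
         frame_rate_hz = sess$frame_rate_hz,
         normalized = sess$traces$normalized)
  })
  manifest <- list(
    sessions = unname(entries),
    registry = list(cells = lapply(seq_len(nrow(s$registry)), function(i) {
      list(id = s$registry$cell_id[i], x = s$registry$x[i], y = s$registry$y[i])
    }))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  manifest_path
}

#' Load a session set from a manifest
#'
#' @param manifest_path path to a manifest JSON written by
#'   [write_session_set()] (or hand-authored in the same schema).
#' @return A [session_set()].
#' @export
load_session_set <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("missing file: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  cells <- manifest$registry$cells
  registry <- cell_registry(
    cell_id = vapply(cells, function(c) as.character(c$id), ""),
    x = vapply(cells, function(c) if (is.null(c$x)) NA_real_ else as.numeric(c$x), 0),
    y = vapply(cells, function(c) if (is.null(c$y)) NA_real_ else as.numeric(c$y), 0)
  )
  sessions <- lapply(manifest$sessions, function(e) {
    path <- file.path(base, e$file)
    if (!file.exists(path)) stop("missing file: ", path)
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    ids <- setdiff(colnames(df), "frame")
    if (!setequal(ids, registry$cell_id)) {
      stop("cell set mismatch: session ", e$label,
           " file does not carry the registry's cells")
    }
    m <- suppressWarnings(
      t(vapply(registry$cell_id,
               function(id) as.numeric(df[[id]]), numeric(nrow(df))))
    )
    if (nrow(df) == 0) m <- matrix(0, length(registry$cell_id), 0)
    if (length(m) && !all(is.finite(m))) {
      stop("non-numeric cell value in session ", e$label)
    }
    dimnames(m) <- list(registry$cell_id, NULL)
    list(label = e$label, stage = e$stage,
         frame_rate_hz = as.numeric(e$frame_rate_hz),
         traces = trace_matrix(m, normalized = isTRUE(e$normalized)))
  })
  session_set(sessions, registry)
}

#' Baseline-normalize traces (delta F over F)
#'
#' Per-cell dF/F: row i becomes (F_i(t) - F0_i)/F0_i with F0_i the session
#' baseline of that cell. The session-mean baseline is the 1-D analogue of the
#' mean-image baseline used on movies; a percentile baseline is available.
#'
#' @param raw a [trace_matrix()] of raw fluorescence.
#' @param baseline `"mean"` (default) or `"percentile"`.
#' @param prob percentile used when `baseline = "percentile"`.
#' @return A normalized [trace_matrix()].
#' @export
deltaf_over_f <- function(raw, baseline = c("mean", "percentile"), prob = 0.2) {
  stopifnot(inherits(raw, "trace_matrix"))
  baseline <- match.arg(baseline)
  v <- raw$values
  f0 <- switch(baseline,
               mean = rowMeans(v),
               percentile = apply(v, 1, stats::quantile, probs = prob, names = FALSE))
  bad <- f0 <= 0
  if (any(bad)) {
    stop("non-positive baseline F0 for cell(s): ",
         paste(rownames(v)[bad], collapse = ", "))
  }
  trace_matrix(sweep(sweep(v, 1, f0, "-"), 1, f0, "/"), normalized = TRUE)
}

#' Read / write engram labels
#'
#' Labels files are JSON maps `cell_id -> "engram" | "non_engram"`.
#'
#' @param path file path.
#' @return `read_labels`: named character vector of labels.
#' @export
read_labels <- function(path) {
  x <- jsonlite::read_json(path)
  out <- vapply(x, as.character, "")
  if (!all(out %in% c("engram", "non_engram"))) {
    stop("labels must be 'engram' or 'non_engram'")
  }
  out
}

#' @rdname read_labels
#' @param labels named character vector (`"engram"`/`"non_engram"`).
#' @export
write_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  jsonlite::write_json(as.list(labels), path, auto_unbox = TRUE)
  invisible(path)
}

# Split a session's traces into the two label groups (cells x frames each).
group_traces <- function(sess, registry, labels) {
  ids <- registry$cell_id
  lab <- labels[ids]
  if (anyNA(lab)) stop("labels missing for some registry cells")
  v <- sess$traces$values
  list(engram = v[lab == "engram", , drop = FALSE],
       non_engram = v[lab == "non_engram", , drop = FALSE])
}
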