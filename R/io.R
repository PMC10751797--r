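# Plain-text interchange formats.  Every stage output is an ordinary CSV,
# JSON, or one-string-per-line text file so that third-party metrics and
# discretizers can be slotted into the workflow.

#' Write pathways to a JSON record file
#'
#' One record per pathway: `id`, `symbols` (list of ints), `weight`,
#' `iteration` of arrival (when known), and `frames` (the event duration).
#'
#' @param pathways List of `pathway` objects.
#' @param path Output file.
#' @export
write_pathways_json <- function(pathways, path) {
  records <- lapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    list(id = if (!is.na(p$id)) p$id else i,
         symbols = as.integer(p$symbols),
         weight = p$weight,
         iteration = if (!is.null(p$origin$iteration)) p$origin$iteration
                     else NA,
         frames = p$event_duration_frames,
         start_frame = p$start_frame, end_frame = p$end_frame)
  })
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read pathways from a JSON record file
#'
#' @param path File written by [write_pathways_json()].
#' @return List of `pathway` objects.
#' @export
read_pathways_json <- function(path) {
  records <- jsonlite::read_json(path)
  lapply(records, function(r) {
    pathway(unlist(r$symbols),
            weight = if (is.null(r$weight)) 1 else r$weight,
            start_frame = if (is.null(r$start_frame)) NA else r$start_frame,
            end_frame = if (is.null(r$end_frame)) NA else r$end_frame,
            event_duration_frames = r$frames,
            origin = if (!is.null(r$iteration))
              list(kind = "we", iteration = r$iteration) else list(),
            id = r$id)
  })
}

#' Write pathway strings as plain text, one display string per line
#'
#' @inheritParams write_pathways_json
#' @export
write_pathway_strings <- function(pathways, path) {
  writeLines(vapply(pathways, function(p) encode_symbols(as_symbols(p)), ""),
             path)
  invisible(path)
}

#' Read plain-text pathway strings
#'
#' @param path One display-alphabet string per line.
#' @return List of `path_string` objects.
#' @export
read_pathway_strings <- function(path) {
  lapply(readLines(path), path_string)
}

#' Write the pathway manifest CSV (id, weight, duration, origin)
#'
#' @inheritParams write_pathways_json
#' @export
write_pathway_manifest <- function(pathways, path) {
  df <- do.call(rbind, lapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    data.frame(id = if (!is.na(p$id)) p$id else i, weight = p$weight,
               duration_frames = p$event_duration_frames,
               origin_kind = if (!is.null(p$origin$kind)) p$origin$kind else NA,
               origin_iteration = if (!is.null(p$origin$iteration))
                 p$origin$iteration else NA,
               origin_seg_id = if (!is.null(p$origin$seg_id))
                 p$origin$seg_id else NA)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a distance matrix as CSV
#'
#' @param d Square numeric matrix.
#' @param path CSV file (plain numeric grid with a header row of ids).
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  dimnames(m) <- list(colnames(m), colnames(m))
  m
}

#' Write / read per-frame state labels as a one-column CSV
#'
#' @param labels Integer label vector.
#' @param path CSV file with a single `label` column, one row per frame.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(data.frame(label = as.integer(labels)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  as.integer(utils::read.csv(path)$label)
}

#' Write / read a trajectory tree as CSV
#'
#' Columns: `iteration`, `seg_id`, `parent_id`, `weight`, then `f1..fT`
#' per-frame labels for that iteration.
#'
#' @param tree A [trajectory_tree()].
#' @param path CSV file.
#' @export
write_tree_csv <- function(tree, path) {
  lab <- as.data.frame(tree$labels)
  names(lab) <- paste0("f", seq_len(ncol(lab)))
  utils::write.csv(cbind(tree$segments, lab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(path) {
  df <- utils::read.csv(path)
  fcols <- grep("^f[0-9]+$", names(df))
  trajectory_tree(df[, c("iteration", "seg_id", "parent_id", "weight")],
                  as.matrix(df[, fcols, drop = FALSE]),
                  tau_frames = length(fcols))
}

#' Write the linkage merge table as CSV
#'
#' @param tree A `linkage_tree`.
#' @param path CSV file with columns `a`, `b`, `height`, `size`.
#' @export
write_linkage_csv <- function(tree, path) {
  utils::write.csv(tree$merges, path, row.names = FALSE)
  invisible(path)
}

#' Write a class report as JSON plus CSV companions
#'
#' Writes `<stem>.json` (classes, probabilities, cut, durations),
#' `<stem>_edges.csv` (directed network edge list) and
#' `<stem>_classes.csv` (per-pathway class labels).
#'
#' @param report A `class_report`.
#' @param stem Output path stem (no extension).
#' @export
write_class_report <- function(report, stem) {
  jsonlite::write_json(
    list(n_classes = report$n_classes, cut_height = report$cut_height,
         class_prob = as.list(report$class_prob),
         class_of = report$class_of,
         durations = report$durations),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(report$edges), paste0(stem, "_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(pathway = seq_along(report$class_of),
                              class = report$class_of),
                   paste0(stem, "_classes.csv"), row.names = FALSE)
  invisible(stem)
}
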