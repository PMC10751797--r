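# End-to-end pipeline: synthesize -> discretize -> extract -> match, with
# every stage resumable from the previous stage's files and a persistent
# JSON run report capturing counts, warnings and the chosen cut.

.default_config <- list(
  mode = "cmd", stride = 1L, exclude_length = 0L, condense = 2L,
  metric = "gestalt", seed = 1L, output_dir = ".",
  cut_height = NULL, n_classes = NULL, stages = c("extract", "match"))

#' Load a pipeline configuration
#'
#' Configuration is a JSON key-value file (or an R list) with the documented
#' fields: `mode` (`"cmd"` or `"we"`), `labels_file` or `tree_file`,
#' `source`, `target`, `stride`, `exclude_length`, `condense`, `metric`
#' (`"gestalt"`, `"gestalt-uncorrected"`), `cut_height`/`n_classes`
#' (optional), `seed`, `output_dir`, `stages`.
#'
#' @param config Path to a JSON file or a named list.
#' @return Validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(.default_config, config)
  if (cfg$stride < 1) stop("validation error: stride must be >= 1")
  if (cfg$exclude_length < 0)
    stop("validation error: exclude_length must be >= 0")
  if (cfg$condense < 0) stop("validation error: condense must be >= 0")
  for (f in c("labels_file", "tree_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("validation error: ", f, " does not exist: ", cfg[[f]])
  }
  cfg
}

#' Run the discretize/extract/match pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `output_dir` so later stages (or a rerun with, say, a different
#' condense level) can resume from files: `pathways.json`,
#' `pathway_strings.txt`, `pathways.csv`, `distance_matrix.csv`,
#' `linkage.csv`, `classes.json`/`classes_edges.csv`, and `report.json`.
#'
#' @param config A config list or JSON path, see [load_config()].
#' @return The final `class_report` (invisibly, when the match stage ran),
#'   with the run report attached as attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  report <- list(config = cfg[setdiff(names(cfg), "stages")],
                 stages = list())

  out <- function(name) file.path(cfg$output_dir, name)
  paths <- NULL

  if ("extract" %in% cfg$stages) {
    paths <- note(
      if (identical(cfg$mode, "we")) {
        tree <- read_tree_csv(cfg$tree_file)
        extract_we(tree, cfg$source, cfg$target, stride = cfg$stride,
                   exclude_length = cfg$exclude_length)
      } else {
        labels <- read_labels_csv(cfg$labels_file)
        extract_cmd(labels, cfg$source, cfg$target, stride = cfg$stride,
                    exclude_length = cfg$exclude_length)
      })
    write_pathways_json(paths, out("pathways.json"))
    write_pathway_strings(paths, out("pathway_strings.txt"))
    write_pathway_manifest(paths, out("pathways.csv"))
    short <- sum(vapply(paths, function(p) p$event_duration_frames, 0L) < 10)
    report$stages$extract <- list(n_pathways = length(paths),
                                  n_short = short,
                                  frac_short = if (length(paths)) short / length(paths) else 0)
  }

  result <- NULL
  if ("match" %in% cfg$stages) {
    if (is.null(paths)) paths <- read_pathways_json(out("pathways.json"))
    if (length(paths) < 2) stop("match stage: need at least two pathways")
    corrected <- !identical(cfg$metric, "gestalt-uncorrected")
    result <- note(class_report(
      paths, corrected = corrected,
      condense_level = if (cfg$condense >= 1) cfg$condense else NULL,
      cut_height = cfg$cut_height, n_classes = cfg$n_classes))
    write_distance_csv(result$distance_matrix, out("distance_matrix.csv"))
    write_linkage_csv(result$linkage, out("linkage.csv"))
    write_class_report(result, out("classes"))
    report$stages$match <- list(
      n_classes = result$n_classes, cut_height = result$cut_height,
      class_prob = as.list(result$class_prob))
  }

  report$warnings <- warnings_seen
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  if (!is.null(result)) attr(result, "report") <- report
  invisible(if (is.null(result)) report else result)
}
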