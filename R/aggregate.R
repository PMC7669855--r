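# Cross-subject aggregation: counts and fractions of significant
# classifications over time and over category divisions.

#' Percentage of significant classifications over time
#'
#' Per interval, `100 * significant cells / (subjects x tasks)` over a task
#' subset of a significance matrix; the time course summarizing how often
#' each interval decodes category information across the group.
#'
#' @param sig a [significance_matrix()].
#' @param tasks task ids to include (default all tasks in `sig`).
#' @return data frame with `interval_start` (ms) and `percent`.
#' @export
significant_fraction_timecourse <- function(sig, tasks = NULL) {
  ids <- sig$tasks$id
  tasks <- tasks %||% ids
  missing <- setdiff(tasks, ids)
  if (length(missing) > 0) {
    stopf("task(s) not present in the matrix: %s",
          paste(missing, collapse = ", "))
  }
  ti <- match(tasks, ids)
  sub <- sig$significant[, ti, , drop = FALSE]
  denom <- dim(sub)[1] * dim(sub)[2]
  data.frame(
    interval_start = sig$interval_start,
    percent = 100 * apply(sub, 3, sum) / denom
  )
}

#' Define a task division
#'
#' Maps tasks to named groups (each task to at most one group) plus a
#' reference group, for descriptive fraction summaries.
#'
#' @param name division name.
#' @param groups named list of task-id vectors.
#' @param reference task ids of the reference group (object vs scrambled).
#' @return a `division_spec`.
#' @export
division_spec <- function(name, groups, reference) {
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stopf("division '%s': a task maps to more than one group", name)
  }
  if (length(reference) < 1) stopf("reference group must be defined")
  for (g in names(groups)) {
    if (length(groups[[g]]) < 1) stopf("group '%s' is empty", g)
  }
  structure(list(name = name, groups = groups, reference = reference),
            class = "division_spec")
}

#' Standard divisions of the scrambled-versus-other tasks
#'
#' Three descriptive groupings of the seven scrambled-vs-other tasks, each
#' with object-vs-scrambled as the reference: by species (dogs / humans vs
#' scrambled), by expression (happy / neutral / aggressive vs scrambled),
#' and by the combined species x expression categories.
#'
#' @return a `division_spec`.
#' @export
division_species <- function() {
  division_spec("species",
                list(dogs = c("AD_vs_S", "ND_vs_S", "HD_vs_S"),
                     humans = c("AH_vs_S", "NH_vs_S", "HH_vs_S")),
                reference = "OB_vs_S")
}

#' @rdname division_species
#' @export
division_expression <- function() {
  division_spec("expression",
                list(happy = c("HD_vs_S", "HH_vs_S"),
                     neutral = c("ND_vs_S", "NH_vs_S"),
                     aggressive = c("AD_vs_S", "AH_vs_S")),
                reference = "OB_vs_S")
}

#' @rdname division_species
#' @export
division_combined <- function() {
  ids <- paste(face_categories(), "S", sep = "_vs_")
  groups <- as.list(ids)
  names(groups) <- face_categories()
  division_spec("combined", groups, reference = "OB_vs_S")
}

#' Fractions of significant classifications per division group
#'
#' Per group (and for the reference), `100 * significant cells / total
#' cells` across subjects, tasks of the group, and intervals.
#'
#' @param sig a [significance_matrix()].
#' @param division a [division_spec()].
#' @return data frame with `division`, `group`, `n_tasks`, `n_cells`,
#'   `n_significant` and `percent`.
#' @export
division_fractions <- function(sig, division) {
  ids <- sig$tasks$id
  groups <- c(division$groups, list(reference = division$reference))
  rows <- lapply(names(groups), function(g) {
    tasks <- groups[[g]]
    missing <- setdiff(tasks, ids)
    if (length(missing) > 0) {
      stopf("group '%s': task(s) not in the matrix: %s", g,
            paste(missing, collapse = ", "))
    }
    sub <- sig$significant[, match(tasks, ids), , drop = FALSE]
    data.frame(division = division$name, group = g,
               n_tasks = length(tasks), n_cells = length(sub),
               n_significant = sum(sub),
               percent = 100 * sum(sub) / length(sub))
  })
  do.call(rbind, rows)
}
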