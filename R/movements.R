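#' The movement condition set
#'
#' A `movement_set` holds the condition labels of a motor task together with
#' an ethological category for each movement: `"precision-prehensile"`,
#' `"power-prehensile"` or `"nonprehensile"`. The default is the 26
#' naturalistic hand movements used throughout the package (pinches, grips,
#' single- and multi-digit flexions, thumb movements), with pinch-type and
#' thumb-opposition movements classed as precision prehensile, whole-hand
#' grips as power prehensile, and unopposed digit movements as nonprehensile.
#'
#' @param labels character vector of unique condition names.
#' @param categories named character vector mapping every label to one of the
#'   three ethological categories.
#' @return an object of class `movement_set` with elements `labels` and
#'   `categories`.
#' @examples
#' ms <- movement_set()
#' length(ms$labels)   # 26
#' table(ms$categories)
#' @export
movement_set <- function(labels = NULL, categories = NULL) {
  if (is.null(labels)) {
    def <- default_movements()
    labels <- def$labels
    categories <- categories %||% def$categories
  }
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("movement labels must be unique")
  if (is.null(categories)) stop("categories must be supplied for custom labels")
  if (!all(labels %in% names(categories))) {
    missing <- setdiff(labels, names(categories))
    stop("movements without a category: ", paste(missing, collapse = ", "))
  }
  categories <- categories[labels]
  valid <- c("precision-prehensile", "power-prehensile", "nonprehensile")
  bad <- setdiff(unique(categories), valid)
  if (length(bad)) stop("unknown ethological category: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, categories = categories),
            class = "movement_set")
}

default_movements <- function() {
  precision <- c(
    "pinch thumb-little", "pinch thumb-index", "pinch thumb-middle",
    "pinch thumb-ring", "thumb-index roll", "twiddle thumb-index")
  power <- c("cylinder grip", "hook grip", "spherical grip",
             "squeeze thumb-fingers")
  nonpreh <- c(
    "abduct fingers", "index flexion 45", "index flexion 90",
    "index-middle flexion 90", "little flexion 45", "little flexion 90",
    "middle flexion 45", "middle flexion 90", "middle-ring flexion 90",
    "ring flexion 45", "ring flexion 90", "ring-little flexion 90",
    "rock fingers", "abduct thumb", "extend thumb", "flex thumb")
  labels <- c(precision, power, nonpreh)
  categories <- c(rep("precision-prehensile", length(precision)),
                  rep("power-prehensile", length(power)),
                  rep("nonprehensile", length(nonpreh)))
  names(categories) <- labels
  list(labels = labels, categories = categories)
}

#' @export
print.movement_set <- function(x, ...) {
  cat(sprintf("<movement_set> %d movements\n", length(x$labels)))
  print(table(x$categories))
  invisible(x)
}

#' Motor-task timing and trial-count arithmetic
#'
#' The motor task is organized as runs of condition blocks; each block is a
#' cue sequence followed by repeated movement trials. `task_protocol()`
#' returns the component durations for one session type; `block_duration()`
#' and `run_duration()` recompute block and run lengths from those
#' components. In the fMRI protocol a block is 3 s instruction + 3 s video +
#' 1 s instruction + 5 trials of (1.6 s movement + 0.4 s rest) = 17 s; in the
#' MEG protocol 2 s fixation + 3 s video + 1 s instruction + 5 trials of
#' (1.6 + 0.8) s = 18 s; in the behavioral protocol 3 s video + 1 s
#' preparation + 8 trials of (1.6 + 0.8) s = 23.2 s, giving a 26-block run of
#' 603.2 s (10 min 3.2 s).
#'
#' @param session one of `"fmri"`, `"meg"`, `"behavioral"`.
#' @param n_conditions number of movement blocks per run.
#' @param n_rest_blocks rest blocks per run (fMRI only; rest blocks have the
#'   same duration as movement blocks).
#' @return `task_protocol()`: a list of component durations in seconds;
#'   `block_duration()`, `run_duration()`: a duration in seconds.
#' @examples
#' block_duration("fmri")        # 17
#' block_duration("meg")         # 18
#' run_duration("behavioral")    # 603.2
#' @export
task_protocol <- function(session = c("fmri", "meg", "behavioral")) {
  session <- match.arg(session)
  switch(session,
    fmri = list(cue_s = c(instruction = 3, video = 3, instruction2 = 1),
                n_trials = 5L, movement_s = 1.6, rest_s = 0.4),
    meg = list(cue_s = c(fixation = 2, video = 3, instruction = 1),
               n_trials = 5L, movement_s = 1.6, rest_s = 0.8),
    behavioral = list(cue_s = c(video = 3, preparation = 1),
                      n_trials = 8L, movement_s = 1.6, rest_s = 0.8))
}

#' @rdname task_protocol
#' @export
block_duration <- function(session = c("fmri", "meg", "behavioral")) {
  p <- task_protocol(session)
  sum(p$cue_s) + p$n_trials * (p$movement_s + p$rest_s)
}

#' @rdname task_protocol
#' @export
run_duration <- function(session = c("fmri", "meg", "behavioral"),
                         n_conditions = 26L, n_rest_blocks = 0L) {
  session <- match.arg(session)
  if (session != "fmri" && n_rest_blocks > 0L) {
    stop("rest blocks are part of the fMRI protocol only")
  }
  (n_conditions + n_rest_blocks) * block_duration(session)
}

#' Trial bookkeeping for the MEG protocol
#'
#' Concatenating all runs of a session pair gives `n_runs * trials_per_block`
#' repeats of each movement (10 runs x 5 trials = 50 by default); trials with
#' artifacts may be rejected up to a cap, so the guaranteed minimum per
#' movement is `total - max_rejected` (40 by default).
#'
#' @param n_runs task runs contributing trials.
#' @param trials_per_block movement trials per block.
#' @param max_rejected maximum number of trials rejected per movement.
#' @return an integer count.
#' @examples
#' trials_per_condition()          # 50
#' min_trials_after_rejection()    # 40
#' @export
trials_per_condition <- function(n_runs = 10L, trials_per_block = 5L) {
  as.integer(n_runs) * as.integer(trials_per_block)
}

#' @rdname trials_per_condition
#' @export
min_trials_after_rejection <- function(n_runs = 10L, trials_per_block = 5L,
                                       max_rejected = 10L) {
  total <- trials_per_condition(n_runs, trials_per_block)
  if (max_rejected >= total) stop("rejection cap leaves no trials")
  total - as.integer(max_rejected)
}
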