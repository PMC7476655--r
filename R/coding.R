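# Scene-coding schema: 14 categorical classifiers describing one captured
# snapshot (task context, lighting, visual and practical requirements), a
# 48-item task vocabulary with a bespoke escape category, and inter-rater
# percent agreement.

#' The 14-classifier scene-coding schema
#'
#' One classifier per scene characteristic, each with its closed category
#' set: task duration, location, familiarity, light type, brightness,
#' object distance, focus plane, periphery, visual scanning, hands,
#' walking, coping-strategy use, ability to complete alone and time of day.
#'
#' @return A named list of classifier specs, each a list with `name` and
#'   `categories` (ordered character vector).
#' @export
default_scene_schema <- function() {
  specs <- list(
    duration = c("ad hoc", "short", "medium", "long"),
    location = c("indoors", "outdoors"),
    familiarity = c("home", "public", "work", "school"),
    light_type = c("artificial", "natural", "mixed", "backlit", "other"),
    brightness = c("low", "medium", "bright"),
    object_distance = c("within reach", "short", "medium", "long"),
    focus_plane = c("single", "multiple"),
    periphery = c("none", "side", "bottom", "both"),
    scanning = c("yes", "no"),
    hands = c("none", "1 hand", "2 hands"),
    walking = c("yes", "no"),
    coping_used = c("yes", "no"),
    able_alone = c("yes", "no"),
    time_of_day = c("6-12", "12-18", "18-24", "0-6")
  )
  lapply(setNames(names(specs), names(specs)), function(nm)
    list(name = nm, categories = specs[[nm]]))
}

check_schema <- function(schema) {
  nms <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(nms) > 0L)
    vd_stop("classifier names must be unique", "visdemand_validation_error")
  for (sp in schema)
    if (length(sp$categories) < 2L)
      vd_stop(sprintf("classifier '%s' needs at least 2 categories", sp$name),
              "visdemand_validation_error")
  invisible(schema)
}

#' Write / read a scene-coding schema as JSON
#'
#' The shipped schema round-trips unchanged, so site-specific category sets
#' can be versioned alongside the data.
#'
#' @param schema A schema as returned by [default_scene_schema()].
#' @param path JSON path.
#' @return `write_scene_schema`: `path` invisibly; `read_scene_schema`: the
#'   schema.
#' @export
write_scene_schema <- function(schema, path) {
  check_schema(schema)
  jsonlite::write_json(unname(schema), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_schema
#' @export
read_scene_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- lapply(raw, function(sp)
    list(name = sp$name,
         categories = vapply(sp$categories, as.character, character(1))))
  names(schema) <- vapply(schema, `[[`, character(1), "name")
  check_schema(schema)
}

#' Validate scene codes against a schema
#'
#' `codes` holds one snapshot per row: a `snapshot_id` column plus one
#' column per classifier. Every classifier of the schema must be present
#' and every value must be a member of its category set.
#'
#' @param codes A data.frame of scene codes.
#' @param schema A schema as returned by [default_scene_schema()].
#' @return `codes`, unchanged, if valid; otherwise a validation or
#'   completeness error naming the classifier (and offending value).
#' @export
validate_scene_code <- function(codes, schema = default_scene_schema()) {
  stopifnot(is.data.frame(codes))
  check_schema(schema)
  nms <- vapply(schema, `[[`, character(1), "name")
  missing_cls <- setdiff(nms, names(codes))
  if (length(missing_cls) > 0L)
    vd_stop(sprintf("scene code is missing classifier(s): %s",
                    paste(missing_cls, collapse = ", ")),
            "visdemand_completeness_error")
  for (sp in schema) {
    vals <- codes[[sp$name]]
    bad <- !is.na(vals) & !vals %in% sp$categories
    if (any(is.na(vals)))
      vd_stop(sprintf("classifier '%s' has missing values", sp$name),
              "visdemand_completeness_error")
    if (any(bad))
      vd_stop(sprintf("classifier '%s' has out-of-vocabulary value '%s'",
                      sp$name, vals[bad][1]), "visdemand_validation_error")
  }
  codes
}

#' Bin a clock time into the schema's time-of-day category
#'
#' Half-open, lower-inclusive bins: \[6,12) -> "6-12", \[12,18) -> "12-18",
#' \[18,24) -> "18-24", \[0,6) -> "0-6".
#'
#' @param time Clock time as `"HH:MM"` / `"HH:MM:SS"` text or numeric hours
#'   on \[0, 24).
#' @return Category label(s).
#' @export
bin_time_of_day <- function(time) {
  if (is.character(time)) {
    parts <- strsplit(time, ":", fixed = TRUE)
    hours <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p))) NA_real_
      else sum(p * c(1, 1 / 60, 1 / 3600)[seq_along(p)])
    }, numeric(1))
  } else {
    hours <- as.numeric(time)
  }
  if (any(is.na(hours)) || any(hours < 0) || any(hours >= 24))
    vd_stop("time must be a valid 24-h clock time", "visdemand_validation_error")
  ifelse(hours >= 6 & hours < 12, "6-12",
         ifelse(hours >= 12 & hours < 18, "12-18",
                ifelse(hours >= 18, "18-24", "0-6")))
}

#' Simplify a six-point difficulty rating to the binary ability code
#'
#' The six-point narrative difficulty scale had poor inter-rater
#' repeatability, so it collapses to whether the task could be completed
#' alone: only "unable" (could not be completed at all, or only with help
#' from others) maps to `unable_alone`; the five other levels map to
#' `able_alone`.
#'
#' @param rating One of "very easy", "easy", "average", "difficult",
#'   "very difficult", "unable" (case-insensitive).
#' @return `"able_alone"` or `"unable_alone"`.
#' @export
simplify_difficulty <- function(rating) {
  levels6 <- c("very easy", "easy", "average", "difficult",
               "very difficult", "unable")
  r <- tolower(trimws(rating))
  bad <- !r %in% levels6
  if (any(bad))
    vd_stop(sprintf("unknown difficulty rating '%s'", rating[bad][1]),
            "visdemand_validation_error")
  ifelse(r == "unable", "unable_alone", "able_alone")
}

norm_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' The shipped task vocabulary
#'
#' The 48-item visual functioning questionnaire (VA LV VFQ-48) task list as
#' adapted to captured everyday activities, plus the bespoke labels
#' observed for activities outside the questionnaire. Twelve questionnaire
#' items were adapted without their exact adapted wording being published;
#' the shipped wording for those items is provisional (flagged `adapted`),
#' and the file is editable so a site can substitute its own.
#'
#' @param path Optional path to a vocabulary JSON file; defaults to the
#'   copy shipped with the package.
#' @return A data.frame with columns `task_label`, `is_bespoke`, `adapted`.
#' @export
default_task_vocabulary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "task_vocabulary.json",
                        package = "visdemand", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("task_label", "is_bespoke", "adapted") %in% names(raw)))
  df <- data.frame(task_label = raw$task_label, is_bespoke = raw$is_bespoke,
                   adapted = raw$adapted, stringsAsFactors = FALSE)
  for (extra in c("snapshot_pct", "participant_pct"))
    if (!is.null(raw[[extra]])) df[[extra]] <- raw[[extra]]
  df
}

#' Map a curated task label to the vocabulary
#'
#' Exact match after case folding and whitespace normalization against the
#' 48 questionnaire items; anything else is flagged bespoke.
#'
#' @param label Task label text (non-empty).
#' @param vocabulary A vocabulary data.frame, see
#'   [default_task_vocabulary()].
#' @return A list with `task_label` (the vocabulary's canonical wording for
#'   matches, the input label otherwise) and `is_bespoke`.
#' @export
map_task <- function(label, vocabulary = default_task_vocabulary()) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label)))
    vd_stop("task label must be non-empty", "visdemand_validation_error")
  vfq <- vocabulary[!vocabulary$is_bespoke, ]
  hit <- match(norm_label(label), norm_label(vfq$task_label))
  if (is.na(hit)) {
    list(task_label = trimws(label), is_bespoke = TRUE)
  } else {
    list(task_label = vfq$task_label[hit], is_bespoke = FALSE)
  }
}

#' One narrated subtask mapped to the task vocabulary
#'
#' @param participant_id,snapshot_id Identifiers.
#' @param narrative Narrated activity text (may be empty).
#' @param task_label Curated task label; mapped via [map_task()].
#' @param able_alone Could the participant complete the task alone?
#' @param coping_used Was a sight aid or other coping strategy used?
#' @param vocabulary See [default_task_vocabulary()].
#' @return A one-row data.frame (a task record).
#' @export
task_record <- function(participant_id, snapshot_id, task_label,
                        narrative = "", able_alone = TRUE,
                        coping_used = FALSE,
                        vocabulary = default_task_vocabulary()) {
  m <- map_task(task_label, vocabulary)
  data.frame(participant_id = as.character(participant_id),
             snapshot_id = as.character(snapshot_id),
             narrative = as.character(narrative),
             task_label = m$task_label, is_bespoke = m$is_bespoke,
             able_alone = isTRUE(able_alone),
             coping_used = isTRUE(coping_used),
             stringsAsFactors = FALSE)
}

#' Inter-rater percent agreement per classifier
#'
#' Raw (chance-uncorrected) proportion of items on which two independent
#' coders assigned the same category, per classifier, as a percentage.
#' Symmetric in its arguments. Chance-corrected agreement is available via
#' [cohen_kappa()].
#'
#' @param codes_a,codes_b Scene-code data.frames (one row per snapshot,
#'   `snapshot_id` column plus classifier columns) covering the same
#'   snapshots.
#' @param classifiers Classifier columns to compare; defaults to the
#'   columns shared by both tables (minus `snapshot_id`).
#' @return An object of class `agreement_report`: a data.frame with
#'   columns `classifier`, `matches`, `agreement_pct`, and attribute
#'   `n_items`.
#' @export
percent_agreement <- function(codes_a, codes_b, classifiers = NULL) {
  stopifnot(is.data.frame(codes_a), is.data.frame(codes_b))
  if (nrow(codes_a) != nrow(codes_b))
    vd_stop("coder tables differ in length", "visdemand_pairing_error")
  if ("snapshot_id" %in% names(codes_a) && "snapshot_id" %in% names(codes_b)) {
    ord <- match(codes_a$snapshot_id, codes_b$snapshot_id)
    if (any(is.na(ord)))
      vd_stop("coder tables cover different snapshot_ids",
              "visdemand_pairing_error")
    codes_b <- codes_b[ord, , drop = FALSE]
  }
  if (is.null(classifiers))
    classifiers <- setdiff(intersect(names(codes_a), names(codes_b)),
                           "snapshot_id")
  if (length(classifiers) == 0L)
    vd_stop("no shared classifier columns to compare",
            "visdemand_pairing_error")
  n <- nrow(codes_a)
  matches <- vapply(classifiers, function(cl)
    sum(codes_a[[cl]] == codes_b[[cl]]), integer(1))
  out <- data.frame(classifier = classifiers, matches = unname(matches),
                    agreement_pct = unname(100 * matches / n),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, n_items = n, class = c("agreement_report", "data.frame"))
}

#' Cohen's kappa per classifier (optional chance-corrected extra)
#'
#' @inheritParams percent_agreement
#' @return A data.frame with columns `classifier` and `kappa` (`NA` when
#'   the expected agreement is 1, i.e. both coders constant).
#' @export
cohen_kappa <- function(codes_a, codes_b, classifiers = NULL) {
  rep_ <- percent_agreement(codes_a, codes_b, classifiers)
  n <- attr(rep_, "n_items")
  kap <- vapply(rep_$classifier, function(cl) {
    a <- codes_a[[cl]]; b <- codes_b[[cl]]
    cats <- union(a, b)
    pa <- sum(a == b) / n
    pe <- sum(vapply(cats, function(k)
      mean(a == k) * mean(b == k), numeric(1)))
    if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
    (pa - pe) / (1 - pe)
  }, numeric(1))
  data.frame(classifier = rep_$classifier, kappa = unname(kap),
             stringsAsFactors = FALSE)
}
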