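# Summary outputs: dual task rankings, per-classifier scene distributions,
# metric distribution summaries and narrative word frequencies.

#' Dual task ranking
#'
#' Ranks tasks two ways. Snapshot frequency counts every occurrence: a
#' participant recording the same task three times contributes three counts
#' there. Participant prevalence counts each participant at most once per
#' task: the same participant contributes one count there. Ties are broken
#' alphabetically so output is deterministic.
#'
#' @param records Data.frame of task records with at least
#'   `participant_id` and `task_label` columns (see [task_record()]).
#' @return An object of class `ranking_table`: a data.frame with columns
#'   `task_label`, `snapshot_count`, `snapshot_pct`, `rank_snapshot`,
#'   `participant_count`, `participant_pct`, `rank_participant`, sorted by
#'   `rank_snapshot`. Attributes `n_records` and `n_participants` record
#'   the denominators.
#' @export
rank_tasks <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- data.frame(task_label = character(0), snapshot_count = integer(0),
                      snapshot_pct = numeric(0), rank_snapshot = integer(0),
                      participant_count = integer(0),
                      participant_pct = numeric(0),
                      rank_participant = integer(0))
    return(structure(out, n_records = 0L, n_participants = 0L,
                     class = c("ranking_table", "data.frame")))
  }
  stopifnot(all(c("participant_id", "task_label") %in% names(records)))
  n_rec <- nrow(records)
  n_part <- length(unique(records$participant_id))
  snap <- table(records$task_label)
  uniq <- unique(records[c("participant_id", "task_label")])
  part <- table(uniq$task_label)
  labels <- sort(names(snap))  # alphabetical base order = tie-break order
  sc <- as.integer(snap[labels])
  pc <- as.integer(part[labels])
  ord_snap <- order(-sc, labels)
  ord_part <- order(-pc, labels)
  out <- data.frame(task_label = labels, snapshot_count = sc,
                    snapshot_pct = 100 * sc / n_rec,
                    rank_snapshot = NA_integer_,
                    participant_count = pc,
                    participant_pct = 100 * pc / n_part,
                    rank_participant = NA_integer_,
                    stringsAsFactors = FALSE)
  out$rank_snapshot[ord_snap] <- seq_along(labels)
  out$rank_participant[ord_part] <- seq_along(labels)
  out <- out[ord_snap, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_records = n_rec, n_participants = n_part,
            class = c("ranking_table", "data.frame"))
}

#' Per-classifier category distributions
#'
#' For each classifier of the schema, the share of snapshots per category
#' as a percentage of all snapshots (each row of a classifier sums to 100
#' up to rounding).
#'
#' @param codes Validated scene-code data.frame (see
#'   [validate_scene_code()]).
#' @param schema Schema defining classifier order and category order.
#' @return A data.frame with columns `classifier`, `category`, `count`,
#'   `pct`, categories in schema order including zero-count ones.
#' @export
distribution_by_classifier <- function(codes, schema = default_scene_schema()) {
  codes <- validate_scene_code(codes, schema)
  n <- nrow(codes)
  rows <- lapply(schema, function(sp) {
    counts <- vapply(sp$categories, function(k) sum(codes[[sp$name]] == k),
                     integer(1))
    data.frame(classifier = sp$name, category = sp$categories,
               count = unname(counts), pct = unname(100 * counts / n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize metric distributions across images
#'
#' Per metric: mean, sample SD (n-1 denominator; reported as 0 with a
#' degenerate-n warning for a single image), min, max, and a normalized
#' histogram whose bar heights are proportions of images (0-1 scale).
#'
#' @param metrics Data.frame with one row per image and one numeric column
#'   per metric (e.g. the output of [batch_scene_metrics()]), or a list of
#'   `scene_metrics` objects.
#' @param breaks Histogram break specification passed to [graphics::hist()]
#'   semantics via `hist(..., plot = FALSE)`.
#' @return A list keyed by metric name, each with `mean`, `sd`, `min`,
#'   `max`, `n` and `histogram` (data.frame `mid`, `lower`, `upper`,
#'   `proportion`; proportions sum to 1).
#' @export
summarize_metric_distributions <- function(metrics, breaks = "Sturges") {
  if (!is.data.frame(metrics)) {
    if (length(metrics) == 0L)
      vd_stop("no metrics to summarize", "visdemand_empty_input_error")
    metrics <- do.call(rbind, lapply(metrics, function(m)
      as.data.frame(unclass(m))))
  }
  if (nrow(metrics) == 0L)
    vd_stop("no metrics to summarize", "visdemand_empty_input_error")
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  if (nrow(num) == 1L)
    warning("single observation: SDs are degenerate and reported as 0",
            call. = FALSE)
  lapply(num, function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0,
         min = min(x), max = max(x), n = length(x),
         histogram = data.frame(
           mid = h$mids,
           lower = head(h$breaks, -1L), upper = tail(h$breaks, -1L),
           proportion = h$counts / sum(h$counts)))
  })
}

#' Narrative word frequencies
#'
#' Case-folded tokenization on non-alphanumeric boundaries, optional
#' stemming via a supplied token map (e.g. `"reading" -> "read"`), stop
#' words removed, counts and percentages relative to the retained tokens.
#'
#' @param narratives Character vector of narrative texts.
#' @param stem_map Named character vector mapping token -> stem, or `NULL`.
#'   The shipped default map is available via
#'   `default_stem_map()`.
#' @param stopwords Character vector of stop words to drop; the shipped
#'   editable list via `default_stopwords()`. Use `character(0)` to keep
#'   everything.
#' @return A data.frame with columns `word`, `count`, `pct`, sorted by
#'   descending count then alphabetically. Attribute `n_tokens` records the
#'   retained-token denominator.
#' @export
word_frequency <- function(narratives, stem_map = default_stem_map(),
                           stopwords = default_stopwords()) {
  toks <- unlist(strsplit(tolower(narratives), "[^a-z0-9]+"))
  toks <- toks[nzchar(toks)]
  if (!is.null(stem_map) && length(stem_map) > 0L) {
    hit <- match(toks, names(stem_map))
    toks[!is.na(hit)] <- unname(stem_map[hit[!is.na(hit)]])
  }
  toks <- toks[!toks %in% stopwords]
  if (length(toks) == 0L) {
    out <- data.frame(word = character(0), count = integer(0),
                      pct = numeric(0))
    return(structure(out, n_tokens = 0L))
  }
  tab <- table(toks)
  words <- sort(names(tab))
  counts <- as.integer(tab[words])
  ord <- order(-counts, words)
  out <- data.frame(word = words[ord], count = counts[ord],
                    pct = 100 * counts[ord] / length(toks),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_tokens = length(toks))
}

#' @rdname word_frequency
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "visdemand",
                      mustWork = TRUE)
  readLines(path, warn = FALSE)
}

#' @rdname word_frequency
#' @export
default_stem_map <- function() {
  path <- system.file("extdata", "stem_map.json", package = "visdemand",
                      mustWork = TRUE)
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Render a percentage the way the summary tables print it
#'
#' Whole percent at or above 1%, one decimal below 1% (so small shares are
#' not rounded to zero). Machine outputs keep full precision; this is for
#' rendered tables only.
#'
#' @param pct Numeric percentages.
#' @return Character vector like `"8%"`, `"0.5%"`.
#' @export
format_table_pct <- function(pct) {
  ifelse(pct >= 1 | pct == 0,
         sprintf("%d%%", as.integer(round(pct))),
         sprintf("%.1f%%", pct))
}

#' Aggregate a study's tables into one report
#'
#' File-level driver: reads a task-record CSV, a scene-code CSV and a
#' metrics CSV (as produced by [batch_scene_metrics()]), computes the task
#' ranking, classifier distributions, metric summaries and word
#' frequencies, and optionally writes them as CSVs plus a single JSON
#' report.
#'
#' @param task_csv CSV with `participant_id`, `task_label` and optionally
#'   `narrative` columns.
#' @param scene_csv CSV of scene codes (snapshot rows, classifier columns).
#' @param metrics_csv CSV of per-image metrics; `NULL` to skip.
#' @param out_dir Output directory for `ranking.csv`, `distribution.csv`,
#'   `word_frequency.csv` and `report.json`; `NULL` to skip writing.
#' @param schema Scene-coding schema.
#' @return List with `ranking`, `distribution`, `metric_summary`,
#'   `word_frequency`.
#' @export
aggregate_report_files <- function(task_csv, scene_csv, metrics_csv = NULL,
                                   out_dir = NULL,
                                   schema = default_scene_schema()) {
  records <- read.csv(task_csv, stringsAsFactors = FALSE)
  codes <- read.csv(scene_csv, stringsAsFactors = FALSE)
  ranking <- rank_tasks(records)
  distribution <- distribution_by_classifier(codes, schema)
  metric_summary <- NULL
  if (!is.null(metrics_csv)) {
    mt <- read.csv(metrics_csv, stringsAsFactors = FALSE)
    metric_summary <- summarize_metric_distributions(
      mt[setdiff(names(mt), "file")])
  }
  wf <- if ("narrative" %in% names(records))
    word_frequency(records$narrative) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(ranking), file.path(out_dir, "ranking.csv"),
              row.names = FALSE)
    write.csv(distribution, file.path(out_dir, "distribution.csv"),
              row.names = FALSE)
    if (!is.null(wf))
      write.csv(as.data.frame(wf), file.path(out_dir, "word_frequency.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(ranking = as.data.frame(ranking),
           n_records = attr(ranking, "n_records"),
           n_participants = attr(ranking, "n_participants"),
           distribution = distribution,
           metric_summary = metric_summary,
           word_frequency = if (is.null(wf)) NULL else as.data.frame(wf),
           word_denominator = if (is.null(wf)) NULL else attr(wf, "n_tokens")),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(ranking = ranking, distribution = distribution,
       metric_summary = metric_summary, word_frequency = wf)
}
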