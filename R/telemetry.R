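#' File notifier
#'
#' Default pluggable notifier: writes each notification as a small text file
#' under `sync_dir/notifications/` (an external synchroniser and mail relay
#' are deliberately outside the instrument).
#'
#' @param sync_dir synchronised output directory.
#' @return `function(subject, body)`.
#' @export
file_notifier <- function(sync_dir) {
  counter <- 0L
  function(subject, body = "") {
    counter <<- counter + 1L
    dir <- file.path(sync_dir, "notifications")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE,
                                     showWarnings = FALSE)
    path <- file.path(dir, sprintf("%04d-%s.txt", counter,
                                   gsub("[^a-z0-9_]+", "-", tolower(subject))))
    writeLines(c(subject, body), path)
    invisible(path)
  }
}

#' Create an action log
#'
#' Append-only JSONL action log under the synchronised directory
#' (`actions-YYYY-MM.jsonl`, one file per calendar month). Telemetry must
#' never take the instrument down: if the directory is unwritable, records
#' are buffered in memory and flushed on the next successful write.
#'
#' @param sync_dir synchronised output directory.
#' @param notifier `function(subject, body)`; defaults to [file_notifier()].
#' @return an environment of class `telemetry_log`.
#' @export
telemetry_log <- function(sync_dir, notifier = file_notifier(sync_dir)) {
  log <- new.env(parent = emptyenv())
  log$sync_dir <- sync_dir
  log$notifier <- notifier
  log$buffer <- character(0)
  log$n_records <- 0L
  class(log) <- "telemetry_log"
  log
}

#' @export
print.telemetry_log <- function(x, ...) {
  cat(sprintf("<telemetry_log at %s, %d records, %d buffered>\n",
              x$sync_dir, x$n_records, length(x$buffer)))
  invisible(x)
}

format_t <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")

log_file_for <- function(log, t)
  file.path(log$sync_dir, sprintf("actions-%s.jsonl", format(t, "%Y-%m", tz = "UTC")))

write_lines_safe <- function(log, lines, t) {
  path <- log_file_for(log, t)
  ok <- tryCatch({
    if (!dir.exists(log$sync_dir)) dir.create(log$sync_dir, recursive = TRUE)
    con <- file(path, open = "a")
    on.exit(close(con))
    writeLines(lines, con)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  ok
}

#' Log a user/system action
#'
#' Every action triggered by a user, plus session starts, shutdowns and mode
#' changes, is logged — exceptions alone would say nothing about how the
#' instrument is used.
#'
#' @param log a [telemetry_log()].
#' @param kind record kind: `"button:<name>"`, `"stack_acquired"`,
#'   `"session_start"`, `"session_shutdown"`, `"error"`, `"mode_change"`.
#' @param detail free-text detail.
#' @param t POSIXct timestamp.
#' @param notify also dispatch a notification (used for start/shutdown).
#' @return the log, invisibly.
#' @export
log_action <- function(log, kind, detail = "", t = Sys.time(),
                       notify = FALSE) {
  line <- jsonlite::toJSON(list(t = format_t(t), kind = kind, detail = detail),
                           auto_unbox = TRUE)
  pending <- c(log$buffer, as.character(line))
  if (write_lines_safe(log, pending, t)) {
    log$buffer <- character(0)
  } else {
    log$buffer <- pending
  }
  log$n_records <- log$n_records + 1L
  if (notify) {
    tryCatch(suppressWarnings(log$notifier(kind, detail)),
             error = function(e) {
      # the notifier failing is itself only worth a log line
      log_action(log, "error", detail = sprintf("notifier failed: %s",
                                                conditionMessage(e)), t = t)
    })
  }
  invisible(log)
}

#' Log an exception and notify the administrator
#'
#' @param log a [telemetry_log()].
#' @param error a condition object.
#' @param t POSIXct timestamp.
#' @return the log, invisibly.
#' @export
log_exception <- function(log, error, t = Sys.time()) {
  detail <- conditionMessage(error)
  if (!is.null(error$device))
    detail <- sprintf("%s (device=%s, phase=%s)", detail, error$device,
                      error$phase)
  log_action(log, "error", detail = detail, t = t, notify = TRUE)
}

#' Aggregate the action log into daily usage statistics
#'
#' One row per calendar day present in the log: how often each of the seven
#' buttons was pressed, how many stacks were acquired, and the cumulative
#' stack count since the first record (the number shown "since the opening
#' of the exhibition"). Malformed lines are skipped and counted in the
#' `diagnostics` attribute.
#'
#' @param log a [telemetry_log()], a directory containing
#'   `actions-*.jsonl`, or a single JSONL file path.
#' @return data frame with columns `date`, the seven button names, `stacks`,
#'   `cumulative_stacks`; attribute `diagnostics` holds
#'   `list(malformed = <count>)`.
#' @export
aggregate_daily <- function(log) {
  dir <- if (inherits(log, "telemetry_log")) log$sync_dir else log
  files <- if (length(dir) == 1L && dir.exists(dir))
    sort(list.files(dir, pattern = "^actions-.*\\.jsonl$", full.names = TRUE))
  else dir
  files <- files[file.exists(files)]
  lines <- unlist(lapply(files, readLines, warn = FALSE), use.names = FALSE)
  lines <- lines[nzchar(lines)]
  malformed <- 0L
  recs <- lapply(lines, function(l) {
    r <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(r) || is.null(r$t) || is.null(r$kind)) {
      malformed <<- malformed + 1L
      NULL
    } else r
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  empty <- data.frame(date = as.Date(character(0)))
  for (b in BUTTONS) empty[[b]] <- integer(0)
  empty$stacks <- integer(0); empty$cumulative_stacks <- integer(0)
  if (!length(recs)) {
    attr(empty, "diagnostics") <- list(malformed = malformed)
    return(empty)
  }
  dates <- as.Date(vapply(recs, function(r) substr(r$t, 1, 10), ""))
  kinds <- vapply(recs, function(r) r$kind, "")
  days <- sort(unique(dates))
  out <- data.frame(date = days)
  for (b in BUTTONS)
    out[[b]] <- vapply(days, function(d)
      sum(dates == d & kinds == paste0("button:", b)), integer(1))
  out$stacks <- vapply(days, function(d)
    sum(dates == d & kinds == "stack_acquired"), integer(1))
  out$cumulative_stacks <- cumsum(out$stacks)
  attr(out, "diagnostics") <- list(malformed = malformed)
  out
}

#' Archive a rendering, one per day
#'
#' Stores the rendering under `archive/YYYY-MM-DD.png`, replacing any file
#' already archived for that date (last writer wins, matching "most
#' recently acquired"), and unconditionally refreshes `latest.png`. Storage
#' failures are logged by the caller and never fatal.
#'
#' @param store_dir archive root (typically `sync_dir`).
#' @param view a [spim_view].
#' @param t POSIXct acquisition time.
#' @param retention archived renderings kept per calendar day.
#' @return invisibly, the archived file path (or `NA` on failure).
#' @export
archive_rendering <- function(store_dir, view, t, retention = 1L) {
  tryCatch(suppressWarnings({
    arch <- file.path(store_dir, "archive")
    if (!dir.exists(arch)) dir.create(arch, recursive = TRUE,
                                      showWarnings = FALSE)
    day <- format(t, "%Y-%m-%d", tz = "UTC")
    existing <- sort(list.files(arch, pattern = paste0("^", day),
                                full.names = TRUE))
    path <- if (retention == 1L) {
      file.path(arch, paste0(day, ".png"))
    } else {
      slot <- length(existing) %% retention
      file.path(arch, sprintf("%s-%02d.png", day, slot))
    }
    write_view_png(view, path)
    write_view_png(view, file.path(store_dir, "latest.png"))
    invisible(path)
  }), error = function(e) invisible(NA_character_))
}

#' Export the website statistics table
#'
#' The small CSV the website polls at a fixed interval: one header line,
#' then one row per day (newest last) with the seven button counts, the
#' daily stack count and the cumulative stack count. Byte-stable for
#' identical input — no embedded timestamps.
#'
#' @param stats data frame from [aggregate_daily()].
#' @param path output CSV path (e.g. `file.path(sync_dir, "stats.csv")`).
#' @return `path`, invisibly.
#' @export
export_stats_table <- function(stats, path) {
  cols <- c("date", BUTTONS, "stacks", "cumulative_stacks")
  df <- stats[, cols, drop = FALSE]
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
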