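# Run reporting: every user-visible event is printed to the console and
# appended, identically and in the same order, to a per-run log file
# `logs/<bucket>.S3_integrity_log.<YYYY.MM.DD-HH.MM.SS>.txt`. A new file is
# created for every run; earlier logs are never touched.

#' Open a run log
#'
#' Creates the log folder if it is missing and opens a fresh, timestamped
#' log file for this run. The file name embeds the bucket name and the wall
#' clock at run start (local time, `YYYY.MM.DD-HH.MM.SS`), so two runs in
#' the same second against different buckets still get distinct files.
#'
#' @param bucket_name Bucket under verification (becomes the filename stem).
#' @param log_dir Folder for log files; created when absent.
#' @param now Clock value used in the filename; injectable for
#'   deterministic tests. Defaults to the current time.
#' @return An object of class `s3fixity_run_log` with field `path`.
#' @export
open_run_log <- function(bucket_name, log_dir = "logs", now = Sys.time()) {
  if (!dir.exists(log_dir)) {
    ok <- dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(log_dir)) {
      stop(sprintf("cannot create log folder %s.", sQuote(log_dir)),
           call. = FALSE)
    }
  }
  stamp <- format(now, "%Y.%m.%d-%H.%M.%S")
  path <- file.path(log_dir,
                    sprintf("%s.S3_integrity_log.%s.txt", bucket_name, stamp))
  ok <- tryCatch({ file.create(path, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot create log file %s.", sQuote(path)), call. = FALSE)
  }
  structure(list(path = path, bucket_name = bucket_name),
            class = "s3fixity_run_log")
}

#' Emit a run event to console and log file
#'
#' Writes one line per event to standard output and appends the identical
#' line to the run's log file. Checksum mismatches use the exact template
#' `ERROR: local and remote ETag numbers for the file '<name>' do not
#' match.`; files absent from the bucket and skipped entries are prefixed
#' `WARNING:` (the run continues past both); successful checks state that
#' the file's integrity is proven.
#'
#' @param event A list with a `type` field (one of `"verified"`,
#'   `"mismatch"`, `"missing_remote"`, `"skip"`, `"info"`, `"summary"`) plus
#'   the fields that type needs (`key`, `local_etag`, `remote_etag`,
#'   `counts`, `text`, ...).
#' @param run_log An open [open_run_log()] object, or `NULL` to print to the
#'   console only.
#' @return The rendered line, invisibly.
#' @export
emit <- function(event, run_log = NULL) {
  line <- render_event(event)
  cat(line, "\n", sep = "")
  if (!is.null(run_log)) {
    stopifnot(inherits(run_log, "s3fixity_run_log"))
    ok <- tryCatch({
      cat(line, "\n", sep = "", file = run_log$path, append = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("cannot write to log file %s.", sQuote(run_log$path)),
           call. = FALSE)
    }
  }
  invisible(line)
}

render_event <- function(event) {
  switch(
    event$type,
    mismatch = sprintf(
      "ERROR: local and remote ETag numbers for the file '%s' do not match.",
      event$key),
    missing_remote = sprintf(
      "WARNING: the file '%s' does not exist within the remote S3 bucket. Continuing.",
      event$key),
    skip = sprintf("WARNING: skipping '%s': %s", event$key, event$reason),
    verified = sprintf(
      "OK: the integrity of the file '%s' is proven (ETag %s).",
      event$key, format(event$local_etag)),
    info = event$text,
    summary = sprintf(
      "Integrity check finished for bucket '%s': %d file(s) checked; %d verified, %d not found in the bucket, %d ETag mismatch(es).%s",
      event$bucket_name,
      sum(event$counts),
      event$counts[["VERIFIED"]],
      event$counts[["MISSING_REMOTE"]],
      event$counts[["ETAG_MISMATCH"]],
      if (isTRUE(event$remote_only > 0)) {
        sprintf(" Note: %d remote object(s) have no local counterpart.",
                event$remote_only)
      } else ""
    ),
    stop(sprintf("unknown event type %s.", sQuote(event$type)),
         call. = FALSE)
  )
}
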