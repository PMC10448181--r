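# The verifier walks the local tree, maps each regular file to its bucket
# key (the "/"-separated path relative to the root, which is exactly the key
# `aws s3 sync local_folder/ s3://bucket/` assigns), recomputes the local
# ETag, and compares it with the bucket metadata. A file missing from the
# bucket or failing the comparison produces a warning or error verdict and
# the run continues; only broken preconditions abort.

VERIFICATION_STATUSES <- c("VERIFIED", "MISSING_REMOTE", "ETAG_MISMATCH")

#' Discover the local files to verify
#'
#' Recursively walks `root` and returns the relative key of every regular
#' file, using `/` separators and deterministic byte-wise lexicographic
#' order. Symbolic links and other non-regular entries are skipped with a
#' warning. Hidden files are included: a sync-style upload transfers them.
#'
#' @param root An existing, readable directory.
#' @return Character vector of relative keys (possibly empty).
#' @export
discover_local_files <- function(root) {
  if (!is.character(root) || length(root) != 1 || !file.exists(root)) {
    stop(sprintf("local folder %s does not exist.", sQuote(root)),
         call. = FALSE)
  }
  if (!dir.exists(root)) {
    stop(sprintf("%s is not a directory.", sQuote(root)), call. = FALSE)
  }
  if (file.access(root, mode = 4) != 0) {
    stop(sprintf("permission denied reading folder %s.", sQuote(root)),
         call. = FALSE)
  }
  keys <- list.files(root, recursive = TRUE, all.files = TRUE,
                     no.. = TRUE, include.dirs = FALSE, full.names = FALSE)
  keep <- vapply(keys, function(k) {
    full <- file.path(root, k)
    if (nzchar(Sys.readlink(full))) {
      warning(sprintf("skipping symbolic link %s.", sQuote(k)),
              call. = FALSE)
      return(FALSE)
    }
    isTRUE(!file.info(full, extra_cols = FALSE)$isdir)
  }, logical(1))
  sort(keys[keep], method = "radix")
}

new_file_report <- function(relative_key, status, local_etag = NULL,
                            remote_etag = NULL, size_bytes = NA_real_) {
  stopifnot(status %in% VERIFICATION_STATUSES)
  structure(
    list(relative_key = relative_key, status = status,
         local_etag = local_etag, remote_etag = remote_etag,
         size_bytes = size_bytes),
    class = "s3_file_report"
  )
}

#' @export
print.s3_file_report <- function(x, ...) {
  cat(sprintf("<s3_file_report> %s  %s\n", x$status, x$relative_key))
  invisible(x)
}

#' Verify one local file against the bucket manifest
#'
#' If the file's relative key is absent from the manifest the verdict is
#' `MISSING_REMOTE` and no checksum is computed. Otherwise the local ETag is
#' recomputed under `policy` and compared structurally with the remote one:
#' equal digests and part counts give `VERIFIED`, anything else
#' `ETAG_MISMATCH`. In particular a large file whose remote tag lacks a part
#' suffix (e.g. a console upload) is a mismatch; no re-chunking fallback is
#' attempted.
#'
#' @param root Local root directory.
#' @param relative_key File path relative to `root`, `/`-separated.
#' @param manifest An `s3_bucket_manifest`.
#' @param policy A [chunking_policy()].
#' @return An `s3_file_report`.
#' @export
verify_file <- function(root, relative_key, manifest,
                        policy = chunking_policy()) {
  stopifnot(inherits(manifest, "s3_bucket_manifest"))
  remote <- manifest$objects[[relative_key]]
  path <- file.path(root, relative_key)
  size <- as.numeric(file.info(path, extra_cols = FALSE)$size)
  if (is.null(remote)) {
    return(new_file_report(relative_key, "MISSING_REMOTE",
                           size_bytes = size))
  }
  local <- compute_etag_for_file(path, policy)
  status <- if (etags_equal(local$etag, remote$etag)) "VERIFIED"
            else "ETAG_MISMATCH"
  new_file_report(relative_key, status, local_etag = local$etag,
                  remote_etag = remote$etag, size_bytes = local$size_bytes)
}

#' Verify a local tree against a bucket manifest
#'
#' Runs [verify_file()] over every discovered file in deterministic order,
#' emitting one reporter event per file and a final summary. Warnings
#' (missing remote objects) and errors (ETag mismatches, unreadable files)
#' never abort the run; every remaining file is still checked.
#'
#' @param root Local root directory.
#' @param manifest An `s3_bucket_manifest`.
#' @param policy A [chunking_policy()].
#' @param run_log An [open_run_log()] object mirroring events to a file, or
#'   `NULL` for console-only output.
#' @param quiet If `TRUE`, suppress all event output (counts and reports are
#'   still produced).
#' @return An `s3_run_report`: bucket name, per-status `counts` (which
#'   always sum to the number of discovered files), the ordered list of
#'   per-file `reports`, the number of `remote_only` objects, and the log
#'   file path (or `NA`).
#' @export
verify_tree <- function(root, manifest, policy = chunking_policy(),
                        run_log = NULL, quiet = FALSE) {
  stopifnot(inherits(manifest, "s3_bucket_manifest"))
  say <- function(event) {
    if (!quiet) emit(event, run_log) else invisible(NULL)
  }
  keys <- discover_local_files(root)
  bucket <- if (is.na(manifest$bucket_name)) "<unnamed>"
            else manifest$bucket_name
  say(list(type = "info",
           text = sprintf("Checking %d local file(s) under '%s' against bucket '%s' (%d remote object(s)).",
                          length(keys), root, bucket,
                          length(manifest$objects))))

  counts <- stats::setNames(integer(length(VERIFICATION_STATUSES)),
                            VERIFICATION_STATUSES)
  reports <- vector("list", length(keys))
  errors <- 0L
  for (i in seq_along(keys)) {
    key <- keys[[i]]
    report <- tryCatch(
      verify_file(root, key, manifest, policy),
      error = function(e) {
        say(list(type = "skip", key = key, reason = conditionMessage(e)))
        NULL
      }
    )
    if (is.null(report)) {
      errors <- errors + 1L
      next
    }
    reports[[i]] <- report
    counts[[report$status]] <- counts[[report$status]] + 1L
    say(switch(
      report$status,
      VERIFIED = list(type = "verified", key = key,
                      local_etag = report$local_etag),
      MISSING_REMOTE = list(type = "missing_remote", key = key),
      ETAG_MISMATCH = list(type = "mismatch", key = key)
    ))
  }
  reports <- reports[!vapply(reports, is.null, logical(1))]
  remote_only <- length(setdiff(names(manifest$objects), keys))
  say(list(type = "summary", bucket_name = bucket, counts = counts,
           remote_only = remote_only))
  structure(
    list(bucket_name = bucket, counts = counts, reports = reports,
         remote_only = remote_only, read_errors = errors,
         log_file_path = if (is.null(run_log)) NA_character_
                         else run_log$path),
    class = "s3_run_report"
  )
}

#' @export
print.s3_run_report <- function(x, ...) {
  cat(sprintf(
    "<s3_run_report> bucket %s: %d checked; %d verified, %d missing remote, %d mismatched\n",
    sQuote(x$bucket_name), sum(x$counts), x$counts[["VERIFIED"]],
    x$counts[["MISSING_REMOTE"]], x$counts[["ETAG_MISMATCH"]]))
  invisible(x)
}

#' Exit code implied by a run report
#'
#' `0` when every file verified, `1` when any file was missing from the
#' bucket or mismatched (or could not be read), `2` is reserved for fatal
#' errors that prevent a run entirely.
#'
#' @param report An `s3_run_report`.
#' @return An integer exit code.
#' @export
run_exit_code <- function(report) {
  stopifnot(inherits(report, "s3_run_report"))
  findings <- report$counts[["MISSING_REMOTE"]] +
    report$counts[["ETAG_MISMATCH"]] + report$read_errors
  if (findings > 0) 1L else 0L
}
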