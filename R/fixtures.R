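# Synthetic test data: deterministic file trees whose sizes straddle the
# multipart threshold, plus a matching bucket manifest whose ETags come
# from an independent checksum oracle. The oracle deliberately shares no
# code with the streaming engine in etag-core.R: it reads each file whole,
# slices it in memory, and hashes every piece with base R's tools::md5sum()
# on temporary files. Agreement between the two code paths is the core
# correctness evidence for the package.

#' Declarative fixture specification
#'
#' Describes a synthetic file tree: relative keys with exact sizes, a seed,
#' and the chunking policy the tree is meant to exercise. The same
#' `(entries, seed)` pair always regenerates byte-identical trees. The
#' default policy uses a 1 KiB threshold and chunk so multipart behaviour is
#' exercised on kilobyte-sized files.
#'
#' @param entries Named numeric vector: `c("a.txt" = 5, "sub/b.bam" = 3000)`
#'   maps relative keys to sizes in bytes (sizes >= 0, keys unique).
#' @param seed Integer seed for the content generator.
#' @param policy The [chunking_policy()] the fixture targets.
#' @return An object of class `s3_fixture_spec`.
#' @export
fixture_spec <- function(entries, seed = 1L,
                         policy = chunking_policy(1024, 1024)) {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("`entries` must be a named vector mapping relative keys to sizes.",
         call. = FALSE)
  }
  if (anyDuplicated(names(entries))) {
    stop("fixture keys must be unique.", call. = FALSE)
  }
  sizes <- as.numeric(entries)
  if (any(!is.finite(sizes) | sizes < 0 | sizes != trunc(sizes))) {
    stop("fixture sizes must be non-negative integers (bytes).",
         call. = FALSE)
  }
  structure(
    list(entries = stats::setNames(sizes, names(entries)),
         seed = as.integer(seed), policy = policy),
    class = "s3_fixture_spec"
  )
}

# Deterministic per-file seed: mixes the spec seed with a key hash so each
# file's bytes depend on (seed, key) only, kept within the 32-bit range.
key_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- 0
  for (code in codes) h <- (h * 131 + code) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

random_bytes <- function(n, seed) {
  if (n == 0) return(raw(0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  as.raw(sample.int(256L, n, replace = TRUE) - 1L)
}

#' Generate a synthetic file tree
#'
#' Materializes a [fixture_spec()] under `root`: each entry becomes a file
#' of exactly the requested size filled with pseudo-random bytes derived
#' from `(spec$seed, key)`. Intermediate directories are created as needed;
#' clobbering an existing file is an error.
#'
#' @param spec An `s3_fixture_spec`.
#' @param root Writable directory (created if absent).
#' @return Character vector of created paths, invisibly.
#' @export
generate_tree <- function(spec, root) {
  stopifnot(inherits(spec, "s3_fixture_spec"))
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  created <- character(0)
  for (key in names(spec$entries)) {
    path <- file.path(root, key)
    if (file.exists(path)) {
      stop(sprintf("refusing to overwrite existing file %s.", sQuote(path)),
           call. = FALSE)
    }
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeBin(random_bytes(spec$entries[[key]], key_seed(spec$seed, key)),
             path)
    created <- c(created, path)
  }
  invisible(created)
}

# --- independent checksum oracle (no code shared with etag-core.R) --------

hex_to_raw <- function(hex) {
  n <- nchar(hex)
  as.raw(strtoi(substring(hex, seq(1, n, 2), seq(2, n, 2)), base = 16L))
}

md5sum_of_bytes <- function(bytes) {
  tmp <- tempfile("oracle-")
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  unname(tools::md5sum(tmp))
}

oracle_etag_string <- function(path, policy) {
  size <- file.info(path, extra_cols = FALSE)$size
  if (size < policy$threshold_bytes) {
    return(unname(tools::md5sum(path)))
  }
  content <- readBin(path, "raw", n = size)
  chunk <- policy$chunk_size_bytes
  n_parts <- max(1L, as.integer(ceiling(length(content) / chunk)))
  digest_blob <- raw(0)
  for (i in seq_len(n_parts)) {
    lo <- (i - 1) * chunk + 1
    hi <- min(length(content), i * chunk)
    piece <- if (lo > length(content)) raw(0) else content[lo:hi]
    digest_blob <- c(digest_blob, hex_to_raw(md5sum_of_bytes(piece)))
  }
  paste0(md5sum_of_bytes(digest_blob), "-", n_parts)
}

#' Oracle bucket manifest for a generated tree
#'
#' Emulates the server side of an upload: computes the expected ETag of
#' every file in the tree with an independent checksum implementation
#' (whole-file read, in-memory slicing, base R `tools::md5sum()`) and writes
#' a `list-objects` JSON document — quoted ETag strings, `Size`, and a
#' fixed `LastModified` — that is the ground truth the verification engine
#' must match.
#'
#' @param root Directory holding the generated tree.
#' @param spec The `s3_fixture_spec` used to generate it.
#' @param bucket_name Bucket name to label the manifest with.
#' @return The manifest JSON document as a single string.
#' @export
oracle_manifest <- function(root, spec, bucket_name = "fixture-bucket") {
  stopifnot(inherits(spec, "s3_fixture_spec"))
  keys <- sort(names(spec$entries), method = "radix")
  contents <- lapply(keys, function(key) {
    path <- file.path(root, key)
    if (!file.exists(path)) {
      stop(sprintf("fixture file %s is missing; generate the tree first.",
                   sQuote(path)), call. = FALSE)
    }
    list(
      Key = key,
      LastModified = "2023-07-31T22:59:01.000Z",
      ETag = paste0('"', oracle_etag_string(path, spec$policy), '"'),
      Size = file.info(path, extra_cols = FALSE)$size,
      StorageClass = "STANDARD"
    )
  })
  as.character(jsonlite::toJSON(list(Contents = contents),
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

#' Corrupt a fixture file
#'
#' Applies exactly one reproducible mutation to a generated file, emulating
#' the kinds of damage an integrity check must catch: a single flipped
#' byte, truncation to a shorter (possibly empty) prefix, or appended
#' trailing bytes (which can push a file across a chunk boundary).
#'
#' @param root Directory holding the tree.
#' @param relative_key File to mutate, relative to `root`.
#' @param mode One of `"flip-byte"`, `"truncate"`, `"append"`.
#' @param seed Integer seed making the mutation reproducible.
#' @param n_bytes For `"append"`, how many bytes to add (default 1); for
#'   `"truncate"`, the resulting size (default: a random proper prefix).
#' @return A list describing the mutation (`mode`, `offset`, `old`, `new`,
#'   `old_size`, `new_size`), invisibly.
#' @export
corrupt_file <- function(root, relative_key,
                         mode = c("flip-byte", "truncate", "append"),
                         seed = 1L, n_bytes = NULL) {
  mode <- match.arg(mode)
  path <- file.path(root, relative_key)
  if (!file.exists(path)) {
    stop(sprintf("cannot corrupt %s: file does not exist.", sQuote(path)),
         call. = FALSE)
  }
  size <- file.info(path, extra_cols = FALSE)$size
  content <- readBin(path, "raw", n = size)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  desc <- switch(
    mode,
    "flip-byte" = {
      if (size == 0) {
        stop("cannot flip a byte in an empty file.", call. = FALSE)
      }
      offset <- sample.int(size, 1L)
      old_byte <- content[offset]
      # xor with a random non-zero mask guarantees the byte changes
      new_byte <- as.raw(bitwXor(as.integer(old_byte),
                                 sample.int(255L, 1L)))
      content[offset] <- new_byte
      writeBin(content, path)
      list(mode = mode, offset = offset, old = old_byte, new = new_byte,
           old_size = size, new_size = size)
    },
    "truncate" = {
      new_size <- if (!is.null(n_bytes)) as.integer(n_bytes)
                  else sample.int(max(size, 1L), 1L) - 1L
      if (new_size >= size) {
        stop("truncation must shorten the file.", call. = FALSE)
      }
      writeBin(content[seq_len(new_size)], path)
      list(mode = mode, offset = new_size, old = NULL, new = NULL,
           old_size = size, new_size = new_size)
    },
    "append" = {
      n <- if (is.null(n_bytes)) 1L else as.integer(n_bytes)
      extra <- as.raw(sample.int(256L, n, replace = TRUE) - 1L)
      writeBin(c(content, extra), path)
      list(mode = mode, offset = size, old = NULL, new = extra,
           old_size = size, new_size = size + n)
    }
  )
  invisible(desc)
}
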