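# Shared test helpers: small policies so multipart behaviour is exercised
# on kilobyte files, and one-call construction of tree + oracle manifest.

kb_policy <- function(bytes = 1024) chunking_policy(bytes, bytes)

# Generate a tree and its oracle manifest in a fresh temp dir; returns
# root, spec, manifest (parsed) and manifest_json.
make_fixture <- function(entries, seed = 1L, policy = kb_policy(),
                         bucket = "fixture-bucket") {
  root <- tempfile("tree-")
  spec <- fixture_spec(entries, seed = seed, policy = policy)
  generate_tree(spec, root)
  json <- oracle_manifest(root, spec, bucket)
  list(root = root, spec = spec,
       manifest = parse_list_objects(json, bucket),
       manifest_json = json)
}

# A random fixture spec whose sizes straddle the threshold: a mix of empty,
# tiny, boundary (chunk +/- 1) and multi-chunk files.
random_entries <- function(n_files, chunk = 1024) {
  pool <- c(0, 1, 5, chunk - 1, chunk, chunk + 1,
            2 * chunk, 2 * chunk + 3, 3 * chunk)
  sizes <- sample(pool, n_files, replace = TRUE)
  keys <- sprintf("dir%d/file_%03d.bin", seq_len(n_files) %% 3, seq_len(n_files))
  stats::setNames(sizes, keys)
}

# Entry list in the mock-backend dialect for a parsed manifest.
manifest_entries <- function(manifest) {
  lapply(unname(manifest$objects), function(obj) {
    list(Key = obj$key, ETag = paste0('"', format(obj$etag), '"'),
         Size = obj$size_bytes)
  })
}
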