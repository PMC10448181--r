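# Tree walking, per-file verdicts, and aggregate run semantics.

test_that("discover_local_files walks recursively in deterministic order", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "sub"))
  file.create(file.path(root, "a.txt"))
  file.create(file.path(root, "sub", "b.bam"))
  file.create(file.path(root, ".hidden"))
  expect_identical(discover_local_files(root),
                   c(".hidden", "a.txt", "sub/b.bam"))

  empty <- withr::local_tempdir()
  expect_identical(discover_local_files(empty), character(0))

  expect_error(discover_local_files(file.path(root, "a.txt")),
               "not a directory")
  expect_error(discover_local_files(file.path(root, "ghost")),
               "does not exist")
})

test_that("symbolic links are skipped with a warning", {
  skip_on_os("windows")
  root <- withr::local_tempdir()
  writeLines("x", file.path(root, "real.txt"))
  ok <- file.symlink(file.path(root, "real.txt"), file.path(root, "link.txt"))
  skip_if_not(isTRUE(ok), "filesystem does not support symlinks")
  expect_warning(keys <- discover_local_files(root), "symbolic link")
  expect_identical(keys, "real.txt")
})

test_that("verify_file assigns the three verdicts correctly", {
  fx <- make_fixture(c("ok.bin" = 2000, "gone.bin" = 50), seed = 4)

  rep_ok <- verify_file(fx$root, "ok.bin", fx$manifest, fx$spec$policy)
  expect_identical(rep_ok$status, "VERIFIED")
  expect_true(etags_equal(rep_ok$local_etag, rep_ok$remote_etag))

  # drop one manifest entry -> MISSING_REMOTE, no remote etag recorded
  pruned <- fx$manifest
  pruned$objects[["gone.bin"]] <- NULL
  rep_missing <- verify_file(fx$root, "gone.bin", pruned, fx$spec$policy)
  expect_identical(rep_missing$status, "MISSING_REMOTE")
  expect_null(rep_missing$remote_etag)

  # modify the file after manifest creation -> ETAG_MISMATCH
  corrupt_file(fx$root, "ok.bin", "flip-byte", seed = 99)
  rep_bad <- verify_file(fx$root, "ok.bin", fx$manifest, fx$spec$policy)
  expect_identical(rep_bad$status, "ETAG_MISMATCH")
})

test_that("a multipart-sized file with a suffix-less remote tag mismatches", {
  # emulates a console upload: remote ETag is the plain MD5 even though the
  # file is over the threshold; no adaptive fallback is attempted
  fx <- make_fixture(c("big.bin" = 3000), seed = 6)
  plain <- fx$manifest
  path <- file.path(fx$root, "big.bin")
  plain$objects[["big.bin"]]$etag <- etag(md5_hex(path))
  rep <- verify_file(fx$root, "big.bin", plain, fx$spec$policy)
  expect_identical(rep$status, "ETAG_MISMATCH")
})

test_that("verify_tree counts partition the discovered files", {
  set.seed(77)
  for (i in 1:5) {
    fx <- make_fixture(random_entries(sample(5:12, 1)), seed = i)
    rep <- verify_tree(fx$root, fx$manifest, fx$spec$policy, quiet = TRUE)
    expect_identical(sum(rep$counts),
                     length(discover_local_files(fx$root)))
    expect_identical(rep$counts[["VERIFIED"]], sum(rep$counts))
  }
})

test_that("missing manifest entries warn but never stop the run", {
  fx <- make_fixture(c("a" = 100, "b" = 1500, "c" = 2048, "d" = 5), seed = 8)
  pruned <- fx$manifest
  pruned$objects[["b"]] <- NULL
  pruned$objects[["d"]] <- NULL
  rep <- verify_tree(fx$root, pruned, fx$spec$policy, quiet = TRUE)
  expect_identical(rep$counts[["MISSING_REMOTE"]], 2L)
  expect_identical(rep$counts[["VERIFIED"]], 2L)   # the rest still checked
  expect_identical(sum(rep$counts), 4L)
})

test_that("single-byte corruption flips exactly one verdict", {
  fx <- make_fixture(c("a" = 1025, "b" = 2048, "c" = 300), seed = 10)
  corrupt_file(fx$root, "b", "flip-byte", seed = 1)
  rep <- verify_tree(fx$root, fx$manifest, fx$spec$policy, quiet = TRUE)
  expect_identical(rep$counts[["ETAG_MISMATCH"]], 1L)
  expect_identical(rep$counts[["VERIFIED"]], 2L)
  bad <- Filter(function(r) r$status == "ETAG_MISMATCH", rep$reports)
  expect_identical(bad[[1]]$relative_key, "b")
})

test_that("verifying a downloaded copy matches verifying the original", {
  fx <- make_fixture(c("x/a.fastq" = 1500, "y/b.vcf" = 77), seed = 12)
  copy_root <- withr::local_tempdir()
  for (key in discover_local_files(fx$root)) {
    dir.create(file.path(copy_root, dirname(key)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(fx$root, key), file.path(copy_root, key))
  }
  rep_orig <- verify_tree(fx$root, fx$manifest, fx$spec$policy, quiet = TRUE)
  rep_copy <- verify_tree(copy_root, fx$manifest, fx$spec$policy,
                          quiet = TRUE)
  expect_identical(rep_orig$counts, rep_copy$counts)
  expect_identical(
    vapply(rep_orig$reports, function(r) r$status, character(1)),
    vapply(rep_copy$reports, function(r) r$status, character(1)))
})

test_that("remote-only objects are counted as informational only", {
  fx <- make_fixture(c("present" = 100), seed = 13)
  extra <- fx$manifest
  extra$objects[["remote-only.bin"]] <-
    s3fixity:::new_remote_object("remote-only.bin",
                                 etag("d41d8cd98f00b204e9800998ecf8427e"))
  rep <- verify_tree(fx$root, extra, fx$spec$policy, quiet = TRUE)
  expect_identical(sum(rep$counts), 1L)   # local files only
  expect_identical(rep$remote_only, 1L)
  expect_identical(run_exit_code(rep), 0L)
})
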