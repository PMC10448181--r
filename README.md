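# s3fixity

Fixity verification for datasets stored on Amazon-S3-compatible object
storage, for anyone who moves large biomedical data (FASTQ, BAM, VCF,
imaging stacks, ...) in and out of buckets and needs proof that every byte
arrived intact. Network faults during a transfer can silently corrupt
files; `s3fixity` proves (or disproves) end-to-end integrity after the
fact, file by file, without re-uploading anything and without touching the
network more than once.

## How it works

S3 tags every object with an **ETag**. For a simple upload the tag is the
MD5 of the object's bytes. For a multipart upload — which the AWS CLI
transfer commands trigger automatically once a file reaches the
`multipart_threshold` of 8 MB, splitting it into `multipart_chunksize`
(8 MB) parts — the tag is a *digest of digests*:

```
ETag = MD5( md5(part 1) || md5(part 2) || ... || md5(part N) ) - N
```

where each `md5(part i)` is the raw 16-byte digest of one part and `-N`
records the part count. `s3fixity` recomputes this tag locally for every
file under a root directory (plain MD5 below the threshold,
digest-of-digests at or above it, streamed in constant memory), fetches
the bucket's metadata with **one logical `list-objects` query**, and
compares local against remote:

* key present, tags equal → **VERIFIED** — the file's integrity is proven;
* key absent from the bucket → **MISSING_REMOTE** — warning, run continues;
* tags differ → **ETAG_MISMATCH** — error line, run continues.

Every message is printed and mirrored to
`logs/<bucket>.S3_integrity_log.<YYYY.MM.DD-HH.MM.SS>.txt`. The exit code
is 0 (all verified), 1 (any missing/mismatched file), or 2 (fatal: bad
arguments, unreadable folder, access denied — checked up front and the run
stops).

This covers objects uploaded with `aws s3 cp/sync/mv` at default transfer
settings, stored plaintext or SSE-S3. SSE-C and SSE-KMS objects carry
non-MD5 ETags and cannot be verified this way.

## Worked example

The package ships a synthetic-fixture generator whose manifest ETags come
from an independent checksum oracle, so the whole workflow runs offline:

```r
library(s3fixity)

spec <- fixture_spec(
  c("readme.txt" = 300, "assay/counts.mtx" = 2100, "assay/meta.csv" = 1024),
  seed = 7, policy = chunking_policy(1024, 1024))   # 1 KiB parts for the demo
generate_tree(spec, "nucCyt")
writeLines(oracle_manifest("nucCyt", spec, "nuccyt"), "manifest.json")

main(c("-l", "nucCyt", "-b", "nuccyt",
       "--manifest", "manifest.json", "--chunk-size", "1024"))
```

prints (and logs) the following — note the `-3` part suffix on the
2,100-byte file (three 1 KiB parts), the `-1` on the file exactly at the
threshold, and the bare MD5 on the 300-byte file:

```
Checking 3 local file(s) under 'nucCyt' against bucket 'nuccyt' (3 remote object(s)).
OK: the integrity of the file 'assay/counts.mtx' is proven (ETag cf833f6f0093b1d63d1ecd469ce4b674-3).
OK: the integrity of the file 'assay/meta.csv' is proven (ETag 9b6d5e0de1784c9e2ea36c8761f46c2e-1).
OK: the integrity of the file 'readme.txt' is proven (ETag 84177b8e12caee0db7e25bf1dabaea6c).
Integrity check finished for bucket 'nuccyt': 3 file(s) checked; 3 verified, 0 not found in the bucket, 0 ETag mismatch(es).
```

and returns exit code 0. Flip a single byte —
`corrupt_file("nucCyt", "readme.txt", "flip-byte", seed = 1)` — and the
same run returns exit code 1 with:

```
ERROR: local and remote ETag numbers for the file 'readme.txt' do not match.
Integrity check finished for bucket 'nuccyt': 3 file(s) checked; 2 verified, 0 not found in the bucket, 1 ETag mismatch(es).
```

From a shell, the installed script offers the same interface:

```sh
aws-s3-integrity-check -l /data/nucCyt -b nuccyt -p my_aws_profile
aws-s3-integrity-check -l /data/nucCyt -b nuccyt --manifest manifest.json   # offline
```

Live mode needs the `aws` CLI and credentials; offline mode (`--manifest`,
a saved `list-objects` JSON document) needs neither.

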