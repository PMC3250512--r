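# compare two report bundles file-by-file, ignoring the manifest (the only
# file carrying a timestamp)
bundle_files <- function(dir) {
  f <- list.files(dir, recursive = TRUE)
  sort(f[f != "manifest.json"])
}

expect_bundles_identical <- function(d1, d2) {
  f1 <- bundle_files(d1); f2 <- bundle_files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
}

write_inputs <- function(meta, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  community <- file.path(dir, "community.csv")
  coords <- file.path(dir, "coords.csv")
  write_presence_absence(meta$matrix, community)
  write.table(meta$sites, coords, sep = ",", quote = FALSE, row.names = FALSE)
  list(community = community, coords = coords)
}
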