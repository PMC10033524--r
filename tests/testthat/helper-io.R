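# Read just the sizes field from an NRRD header (independent of read_nrrd).
read_nrrd_header_sizes <- function(path) {
  lines <- suppressWarnings(readLines(path, n = 10, warn = FALSE,
                                      skipNul = TRUE))
  sz <- grep("^sizes:", lines, value = TRUE, useBytes = TRUE)[1]
  as.integer(strsplit(sub("^sizes:\\s*", "", sz), "\\s+")[[1]])
}
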