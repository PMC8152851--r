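#' Write a result or trial table as TSV with a commented header
#'
#' Tables are written as plain tab-separated text preceded by `# key: value`
#' comment lines carrying units, seeds and config provenance, so files are
#' self-describing and round-trip through [read_gloss_tsv()].
#'
#' @param x data frame.
#' @param path output path.
#' @param meta named list of scalar metadata written as header comments.
#' @return `path`, invisibly.
#' @export
write_gloss_tsv <- function(x, path, meta = list()) {
  gp_check(is.data.frame(x), "x must be a data frame")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_gloss_tsv()]
#'
#' @param path input path.
#' @return data frame with header metadata in attribute `meta`.
#' @export
read_gloss_tsv <- function(path) {
  gp_check(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^# ([^:]+): (.*)$", lines[h]))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- read.table(text = lines[setdiff(seq_along(lines), hdr)],
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  structure(df, meta = meta)
}

#' Write a ground-truth manifest as JSON
#'
#' Every synthetic dataset carries its latent parameters and seeds; writing
#' them beside the trial tables lets downstream validation compare
#' estimates against truth without reverse-engineering it.
#'
#' @param manifest list (e.g. the `manifest` attribute of a simulated
#'   table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- rapply(manifest, function(f)
    if (is.function(f)) paste(deparse(f), collapse = " ") else f,
    how = "replace")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
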