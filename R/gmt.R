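# GMT gene-set files: one set per line, tab-separated
# (name, description, member genes...).

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return Named list of unique gene-identifier vectors; descriptions kept
#'   in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    .stopf("malformed GMT line(s): %s",
           paste(utils::head(which(bad), 5), collapse = ", "))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) .stopf("duplicate set names in %s", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of gene-identifier vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("all sets must be named")
  if (any(lengths(sets) == 0L)) .stopf("empty gene sets are not allowed")
  desc <- attr(sets, "descriptions") %||% descriptions
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
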