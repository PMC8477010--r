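#' Assemble a gene-by-sample count matrix with its sample sheet
#'
#' The central input container of the package: a nonnegative integer matrix
#' of gene-level read counts (genes in rows, samples in columns) together
#' with a sample sheet assigning every sample to one cell of the 2x2
#' genotype-by-treatment design (WT/KO crossed with Veh/Mem).
#'
#' @param counts Integer matrix, genes x samples, with gene identifiers as
#'   row names and sample identifiers as column names.
#' @param sample_sheet Data frame with columns `sample_id`, `genotype`
#'   (one of `"WT"`, `"KO"`) and `treatment` (one of `"Veh"`, `"Mem"`),
#'   one row per column of `counts`, in any order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (the matrix, columns ordered as in the sample sheet) and
#'   `samples` (the sample sheet with an added `group` column,
#'   `"<genotype>.<treatment>"`).
#' @examples
#' cm <- count_matrix(
#'   matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
#'   data.frame(sample_id = paste0("s", 1:4),
#'              genotype = c("WT", "WT", "KO", "KO"),
#'              treatment = c("Veh", "Mem", "Veh", "Mem")))
#' @export
count_matrix <- function(counts, sample_sheet) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicated gene identifiers in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    .stopf("counts must be nonnegative integers")
  req <- c("sample_id", "genotype", "treatment")
  if (!all(req %in% names(sample_sheet)))
    .stopf("sample sheet must have columns: %s", paste(req, collapse = ", "))
  sample_sheet <- as.data.frame(sample_sheet, stringsAsFactors = FALSE)
  if (!setequal(sample_sheet$sample_id, colnames(counts)) ||
      nrow(sample_sheet) != ncol(counts))
    .stopf("sample sheet ids must match count matrix columns one-to-one")
  if (!all(sample_sheet$genotype %in% c("WT", "KO")))
    .stopf("genotype must be 'WT' or 'KO'")
  if (!all(sample_sheet$treatment %in% c("Veh", "Mem")))
    .stopf("treatment must be 'Veh' or 'Mem'")
  counts <- counts[, sample_sheet$sample_id, drop = FALSE]
  sample_sheet$group <- paste(sample_sheet$genotype, sample_sheet$treatment,
                              sep = ".")
  structure(list(counts = counts, samples = sample_sheet),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$samples$group))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' The six pairwise contrasts of the 2x2 study design
#'
#' Returns the comparison plan used throughout: all six pairwise contrasts
#' among the four (genotype, treatment) cells, under their conventional
#' names. The first-named group is always the numerator of the fold
#' change, e.g. `Veh-K/W` is KO.Veh over WT.Veh.
#'
#' @return Named list of contrasts; each element is a list with `name`,
#'   `numerator` and `denominator` (group labels `"<genotype>.<treatment>"`).
#' @export
study_contrasts <- function() {
  mk <- function(name, num, den)
    list(name = name, numerator = num, denominator = den)
  list(
    "Veh-K/W"   = mk("Veh-K/W",   "KO.Veh", "WT.Veh"),
    "Mem-K/W"   = mk("Mem-K/W",   "KO.Mem", "WT.Mem"),
    "KO-M/V"    = mk("KO-M/V",    "KO.Mem", "KO.Veh"),
    "WT-M/V"    = mk("WT-M/V",    "WT.Mem", "WT.Veh"),
    "K-M/W-V"   = mk("K-M/W-V",   "KO.Mem", "WT.Veh"),
    "WT-M/KO-V" = mk("WT-M/KO-V", "WT.Mem", "KO.Veh"))
}

# Resolve a contrast given by name or structure; validate against a sheet.
#' @keywords internal
resolve_contrast <- function(contrast, samples) {
  if (is.character(contrast)) {
    plan <- study_contrasts()
    if (!contrast %in% names(plan))
      .stopf("unknown contrast '%s'; known: %s", contrast,
             paste(names(plan), collapse = ", "))
    contrast <- plan[[contrast]]
  }
  stopifnot(all(c("name", "numerator", "denominator") %in% names(contrast)))
  num <- samples$sample_id[samples$group %in% contrast$numerator]
  den <- samples$sample_id[samples$group %in% contrast$denominator]
  if (length(num) == 0L || length(den) == 0L)
    .stopf("contrast '%s': empty numerator or denominator group",
           contrast$name)
  if (length(intersect(num, den)))
    .stopf("contrast '%s': numerator and denominator overlap", contrast$name)
  list(name = contrast$name, numerator = num, denominator = den)
}

#' Read a count matrix and sample sheet from tab-separated files
#'
#' The counts file is genes x samples with a header row of sample ids and
#' gene ids in the first column; the sample sheet is tab-separated with
#' columns sample_id, genotype, treatment.
#'
#' @param counts_file,samples_file Paths to the two TSV files.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_file, samples_file) {
  tab <- .read_tsv(counts_file)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  count_matrix(counts, .read_tsv(samples_file))
}

#' Write a count matrix and sample sheet to tab-separated files
#'
#' @param cm A [count_matrix()].
#' @param counts_file,samples_file Output paths.
#' @export
write_count_matrix <- function(cm, counts_file, samples_file) {
  stopifnot(inherits(cm, "count_matrix"))
  .write_tsv(data.frame(gene_id = rownames(cm$counts), cm$counts,
                        check.names = FALSE), counts_file)
  .write_tsv(cm$samples[, c("sample_id", "genotype", "treatment")],
             samples_file)
  invisible(cm)
}
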