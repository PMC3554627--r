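# Readers and writers for p-value matrices, correlation matrices,
# phenotype tables and PLINK-style association output.

#' Read an n x m p-value matrix
#'
#' Tab-separated file with variant identifiers in the first column and
#' one column per phenotype. Validates that every non-missing entry lies
#' in `(0, 1]` and that variant identifiers are unique.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @param na_token token encoding missing values.
#' @return numeric matrix, variants in rows (rownames = variant ids).
#' @export
read_pvalue_matrix <- function(path, delim = "\t", na_token = "NA") {
  d <- utils::read.table(path, header = TRUE, sep = delim, na.strings = na_token,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("expected a variant-id column plus at least one phenotype column")
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) stop("duplicate variant ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  P <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(P)) stop("non-numeric p-value entries in ", path)
  bad <- which(!is.na(P) & (P <= 0 | P > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("p-values outside (0, 1] at row ", bad[1, 1], " ('", ids[bad[1, 1]],
         "'), column '", colnames(P)[bad[1, 2]], "'")
  rownames(P) <- ids
  P
}

#' Write a p-value matrix
#'
#' @param P numeric matrix with variant rownames.
#' @param path output path.
#' @inheritParams read_pvalue_matrix
#' @export
write_pvalue_matrix <- function(P, path, delim = "\t") {
  d <- data.frame(variant_id = rownames(P), P, check.names = FALSE)
  utils::write.table(format(d, digits = 12, scientific = NA, trim = TRUE),
                     path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square correlation matrix
#'
#' Whitespace/tab-delimited numeric matrix, optional header row and
#' leading name column. Validates symmetry and a unit diagonal to 1e-6.
#'
#' @inheritParams read_pvalue_matrix
#' @export
read_correlation_matrix <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1)), "[ \t]+")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  d <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.numeric(d[[1]])) {
    rn <- as.character(d[[1]])
    d <- d[, -1, drop = FALSE]
    rownames(d) <- rn
  }
  R <- as.matrix(d)
  if (nrow(R) != ncol(R)) stop("correlation matrix in ", path, " is not square")
  if (max(abs(R - t(R))) > 1e-6) stop("correlation matrix is not symmetric (tolerance 1e-6)")
  if (max(abs(diag(R) - 1)) > 1e-6) stop("correlation matrix diagonal differs from 1")
  R
}

#' Write a correlation matrix
#'
#' @param R square matrix.
#' @param path output path.
#' @export
write_correlation_matrix <- function(R, path) {
  utils::write.table(format(as.data.frame(R), digits = 12, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(R)))
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with a header of phenotype names, one row per subject. Measurement
#' levels may be given explicitly or are inferred per column (<= 2
#' distinct observed values: dichotomous; <= 6: ordinal; else
#' continuous).
#'
#' @inheritParams read_pvalue_matrix
#' @param levels optional per-column measurement levels.
#' @export
read_phenotype_table <- function(path, levels = NULL, delim = "\t", na_token = "NA") {
  d <- utils::read.table(path, header = TRUE, sep = delim, na.strings = na_token,
                         check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(d)
  if (!is.numeric(x)) stop("non-numeric phenotype entries in ", path)
  phenotype_table(x, levels = levels)
}

#' Write a phenotype table
#'
#' @param table a [phenotype_table()].
#' @param path output path.
#' @inheritParams read_pvalue_matrix
#' @export
write_phenotype_table <- function(table, path, delim = "\t", na_token = "NA") {
  utils::write.table(as.matrix(table), path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = na_token)
  invisible(path)
}

#' Read per-phenotype PLINK-style association output into a p-value matrix
#'
#' Each file is whitespace-delimited association output for one phenotype
#' with (at least) a variant-identifier column and a p-value column.
#' Variants are inner-joined on the identifier across files, preserving
#' the first file's order; dropped variants are reported via a warning.
#'
#' @param paths one file per phenotype.
#' @param snp_col,p_col column names of the variant id and p-value.
#' @param phenotype_names names for the resulting columns (defaults to
#'   the file base names).
#' @return numeric matrix, variants in rows.
#' @export
read_plink_assoc_set <- function(paths, snp_col = "SNP", p_col = "P",
                                 phenotype_names = NULL) {
  if (is.null(phenotype_names))
    phenotype_names <- sub("\\.[^.]*$", "", basename(paths))
  tabs <- lapply(paths, function(f) {
    d <- utils::read.table(f, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (!snp_col %in% names(d)) stop("file ", f, " has no '", snp_col, "' column")
    if (!p_col %in% names(d)) stop("file ", f, " has no '", p_col, "' column")
    d[, c(snp_col, p_col)]
  })
  ids <- tabs[[1]][[snp_col]]
  for (t in tabs[-1]) ids <- ids[ids %in% t[[snp_col]]]
  if (length(ids) == 0) stop("no variants shared by all association files")
  n_dropped <- length(unique(unlist(lapply(tabs, function(t) t[[snp_col]])))) - length(ids)
  if (n_dropped > 0)
    warning(n_dropped, " variant(s) not present in every file were dropped")
  P <- vapply(tabs, function(t) t[[p_col]][match(ids, t[[snp_col]])],
              numeric(length(ids)))
  P <- matrix(P, ncol = length(tabs),
              dimnames = list(ids, phenotype_names))
  bad <- which(!is.na(P) & (P <= 0 | P > 1), arr.ind = TRUE)
  if (nrow(bad)) stop("p-value outside (0, 1] for variant '", ids[bad[1, 1]], "'")
  P
}

#' Write a per-variant combined-result table
#'
#' Output of [combine_matrix()] as TSV at full precision (12 significant
#' digits), deterministic column order.
#'
#' @param results data frame from [combine_matrix()].
#' @param path output path.
#' @export
write_combined_results <- function(results, path) {
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  out[num] <- lapply(results[num], function(x) format(x, digits = 12, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
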