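#' Expression matrix container
#'
#' A light container for one dataset's probe-by-sample matrix of log2
#' expression intensities, as deposited in GEO-style series matrices. Values
#' are assumed to be already normalised and log2-transformed; no
#' preprocessing is performed here.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   rownames (probe IDs) and colnames (sample IDs).
#' @param dataset_id Character label for the dataset (e.g. `"FH1"`).
#' @param cell_type Character label for the profiled cell type (e.g.
#'   `"monocyte"`, `"t_cell"`, `"wbc"`, `"macrophage"`).
#'
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   `dataset_id` and `cell_type` attributes.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("S1", "S2")))
#' x <- expr_matrix(m, "demo", "monocyte")
#' dim(x)
expr_matrix <- function(values, dataset_id, cell_type) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid)) {
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(pid)) {
    stop("duplicated probe IDs: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-finite value at probe '%s', sample '%s'",
                 pid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  structure(values,
            dataset_id = as.character(dataset_id),
            cell_type = as.character(cell_type),
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s (%s): %d probes x %d samples\n",
              attr(x, "dataset_id"), attr(x, "cell_type"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An object to test or subset.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  expr_matrix(out, attr(x, "dataset_id"), attr(x, "cell_type"))
}

probe_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

#' Read and write tab-delimited expression matrices
#'
#' The file dialect is a plain UTF-8 TSV in the spirit of a GEO series
#' matrix: a header row of sample IDs, first column of probe IDs, numeric
#' body (scientific notation accepted). Row and column order is preserved.
#'
#' @param path Path to a tab-delimited file.
#' @inheritParams expr_matrix
#' @return `read_expr_matrix()` returns a validated [expr_matrix];
#'   `write_expr_matrix()` invisibly returns `path`.
#' @export
read_expr_matrix <- function(path, dataset_id, cell_type) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs probe column plus >= 1 sample", call. = FALSE)
  pid <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(pid, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row %d (probe '%s'), column '%s'",
                 bad[1], pid[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  expr_matrix(vals, dataset_id, cell_type)
}

#' @rdname read_expr_matrix
#' @param digits Significant digits written; the round-trip is exact to this
#'   text precision.
#' @export
write_expr_matrix <- function(x, path, digits = 10) {
  stopifnot(is_expr_matrix(x))
  df <- data.frame(probe_id = probe_ids(x),
                   signif(unclass(x), digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

subclass_levels <- function() c("homozygous_FH", "heterozygous_FH", "atherosclerosis", "control")

validate_metadata <- function(meta) {
  need <- c("sample_id", "risk_class", "subclass")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad_sub <- setdiff(unique(meta$subclass), subclass_levels())
  if (length(bad_sub)) stop("unknown subclass token(s): ", paste(bad_sub, collapse = ", "), call. = FALSE)
  bad_rc <- setdiff(unique(meta$risk_class), c("high", "low"))
  if (length(bad_rc)) stop("unknown risk_class token(s): ", paste(bad_rc, collapse = ", "), call. = FALSE)
  expected <- ifelse(meta$subclass == "control", "low", "high")
  conflict <- meta$risk_class != expected
  if (any(conflict)) {
    stop("risk_class/subclass conflict for sample(s): ",
         paste(meta$sample_id[conflict], collapse = ", "),
         " (control implies low risk; FH/atherosclerosis imply high)", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata", call. = FALSE)
  tibble::as_tibble(meta[c("sample_id", "risk_class", "subclass")])
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `risk_class` (`high`/`low`) and
#' `subclass` (`homozygous_FH`, `heterozygous_FH`, `atherosclerosis`,
#' `control`). Controls must be low risk and every disease subclass high
#' risk; inconsistent rows are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three validated columns.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character")
  validate_metadata(meta)
}

#' Read a probe function-annotation table
#'
#' TSV with columns `probe_id`, `gene_symbol`, `category` — the static
#' stand-in for a pathway-analysis triage of biomarkers (one category per
#' probe).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("probe_id", "gene_symbol", "category")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$probe_id)) stop("duplicated probe_id in annotation table", call. = FALSE)
  tibble::as_tibble(ann[need])
}

#' Restrict two expression matrices to their common probes
#'
#' Different array platforms share only part of their probe sets (HG-U133A
#' is a subset of HG-U133 Plus 2.0), so cross-dataset modelling starts from
#' the probe intersection. Both matrices are returned restricted to the
#' shared probes in the same, lexicographic, order; samples are untouched.
#'
#' @param a,b [expr_matrix] objects.
#' @return A list with elements `a` and `b`.
#' @export
intersect_probes <- function(a, b) {
  stopifnot(is_expr_matrix(a), is_expr_matrix(b))
  common <- sort(intersect(probe_ids(a), probe_ids(b)))
  if (!length(common)) stop("no probes shared between the two matrices", call. = FALSE)
  list(a = a[common, ], b = b[common, ])
}
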