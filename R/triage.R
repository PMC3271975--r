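#' Biomarker panels
#'
#' An ordered, duplicate-free list of probe IDs with provenance: `universal`
#' panels come straight from discovery + functional triage on the training
#' set; `coxen` panels are the concordance-filtered subsets tailored to one
#' test cell type.
#'
#' @param probe_ids Character vector of probe IDs (order is meaningful).
#' @param source `"universal"` or `"coxen"`.
#' @param training_dataset_id Dataset the panel was derived on.
#' @param description Free-text provenance note.
#' @return A `biomarker_panel` object.
#' @export
biomarker_panel <- function(probe_ids, source = c("universal", "coxen"),
                            training_dataset_id = NA_character_,
                            description = "") {
  source <- match.arg(source)
  probe_ids <- as.character(probe_ids)
  if (!length(probe_ids)) stop("a biomarker panel must be non-empty", call. = FALSE)
  if (anyDuplicated(probe_ids)) stop("duplicated probes in panel", call. = FALSE)
  structure(list(probe_ids = probe_ids, source = source,
                 training_dataset_id = training_dataset_id,
                 description = description),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d probes (%s, trained on %s)\n",
              length(x$probe_ids), x$source, x$training_dataset_id))
  invisible(x)
}

#' @export
length.biomarker_panel <- function(x) length(x$probe_ids)

#' Triage discovered biomarkers by annotated function
#'
#' Stage 2: restrict the q-value-flagged discovery hits to probes whose
#' annotated function category belongs to the allowed, atherosclerosis
#' relevant vocabulary — the reproducible stand-in for a proprietary pathway
#' analysis triage. Ascending-p order is preserved; unannotated probes are
#' dropped with a message.
#'
#' @param records Discovery tibble from [discover_biomarkers()] (only
#'   `flagged` rows are considered).
#' @param annotations Annotation tibble (`probe_id`, `gene_symbol`,
#'   `category`).
#' @param allowed_categories Character set of retained categories; defaults
#'   to [atherosclerosis_categories()].
#' @param training_dataset_id Provenance label for the resulting panel.
#' @return A [biomarker_panel()] with `source = "universal"`.
#' @export
filter_by_function <- function(records, annotations,
                               allowed_categories = atherosclerosis_categories(),
                               training_dataset_id = NA_character_) {
  if (!length(allowed_categories)) {
    stop("allowed_categories must be non-empty", call. = FALSE)
  }
  flagged <- dplyr::filter(records, .data$flagged)
  if (!nrow(flagged)) stop("no flagged biomarkers to triage", call. = FALSE)
  ann <- annotations[match(flagged$probe_id, annotations$probe_id), ]
  unannotated <- is.na(ann$category)
  if (any(unannotated)) {
    message(sum(unannotated), " flagged probe(s) lack annotation and were dropped")
  }
  keep <- !unannotated & ann$category %in% allowed_categories
  if (!any(keep)) {
    stop("functional triage removed every biomarker; review allowed_categories",
         call. = FALSE)
  }
  biomarker_panel(flagged$probe_id[keep], source = "universal",
                  training_dataset_id = training_dataset_id,
                  description = sprintf("discovery + function triage (%d of %d flagged kept)",
                                        sum(keep), nrow(flagged)))
}
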