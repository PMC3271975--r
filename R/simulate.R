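#' Configure a synthetic multi-cell-type cohort
#'
#' Describes the generative world the test suite runs in: a case-control
#' familial-hypercholesterolemia (FH) style cohort profiled across several
#' leukocyte cell types. Expression for probe g in sample s of one cell type
#' follows
#' \deqn{x_{gs} = \mu_g + \sum_k \lambda_{gk} f_{ks} + \delta_g z_s + \epsilon_{gs}}
#' with baseline \eqn{\mu_g}, latent co-expression factors \eqn{f_{ks}} (scores
#' drawn fresh per cell type), loadings \eqn{\lambda_{gk}} shared across cell
#' types for concordant probes and redrawn independently for discordant ones,
#' log2 risk effect \eqn{\delta_g} (scaled by `homozygous_multiplier` for
#' homozygous-FH samples), risk indicator \eqn{z_s}, and Gaussian noise.
#'
#' The default design copies the study shapes this generator emulates:
#' a 23-sample monocyte training set (3 homozygous FH + 7 heterozygous FH +
#' 13 controls), a T-cell set from the same subjects, an independent 5+5
#' whole-white-blood-cell set, and a 14+14 macrophage set. Default log2
#' effect magnitudes span \eqn{[\log_2 1.1, \log_2 1.9]}, the published
#' fold-change range of the training biomarkers.
#'
#' @param n_probes Number of probes (default 2000; desk-scale stand-in for a
#'   full array).
#' @param n_de Number of truly differential probes.
#' @param cohort_design Named list: one element per cell type, each a data
#'   frame with columns `subclass` and `n`, plus an optional
#'   `same_subjects_as` naming another cell type whose sample IDs it reuses.
#' @param log2_effect_range Length-2 interval of |log2 effect| sizes.
#' @param homozygous_multiplier Scale factor on effects for homozygous-FH
#'   samples (default 1.8; homozygous disease is clinically more severe, only
#'   the ordering matters here).
#' @param concordant_fraction Fraction of DE probes whose factor loadings are
#'   shared across cell types.
#' @param n_latent Number of latent co-expression factors.
#' @param loading_sd Standard deviation of factor loadings (log2 units).
#' @param noise_sd Residual standard deviation (log2 units).
#' @param out_of_vocab_fraction Fraction of DE probes annotated with a
#'   category outside the atherosclerosis vocabulary, to exercise triage.
#' @param seed Integer seed; the cohort is a pure function of the config.
#'
#' @return A `cohort_config` list.
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
cohort_config <- function(n_probes = 2000,
                          n_de = 100,
                          cohort_design = default_cohort_design(),
                          log2_effect_range = c(log2(1.1), log2(1.9)),
                          homozygous_multiplier = 1.8,
                          concordant_fraction = 0.5,
                          n_latent = 3,
                          loading_sd = 0.08,
                          noise_sd = 0.18,
                          out_of_vocab_fraction = 0.2,
                          seed = 1L) {
  if (n_de > n_probes) stop("n_de must not exceed n_probes", call. = FALSE)
  if (concordant_fraction < 0 || concordant_fraction > 1) {
    stop("concordant_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  stopifnot(length(log2_effect_range) == 2, diff(log2_effect_range) >= 0)
  structure(list(n_probes = as.integer(n_probes), n_de = as.integer(n_de),
                 cohort_design = cohort_design,
                 log2_effect_range = log2_effect_range,
                 homozygous_multiplier = homozygous_multiplier,
                 concordant_fraction = concordant_fraction,
                 n_latent = as.integer(n_latent),
                 loading_sd = loading_sd, noise_sd = noise_sd,
                 out_of_vocab_fraction = out_of_vocab_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_design <- function() {
  fh <- data.frame(subclass = c("homozygous_FH", "heterozygous_FH", "control"),
                   n = c(3L, 7L, 13L))
  list(
    monocyte   = list(dataset_id = "FH1", design = fh),
    t_cell     = list(dataset_id = "FH2", design = fh, same_subjects_as = "monocyte"),
    wbc        = list(dataset_id = "FH3",
                      design = data.frame(subclass = c("heterozygous_FH", "control"),
                                          n = c(5L, 5L))),
    macrophage = list(dataset_id = "ATHERO1",
                      design = data.frame(subclass = c("atherosclerosis", "control"),
                                          n = c(14L, 14L)))
  )
}

#' The atherosclerosis-relevant function vocabulary
#'
#' The controlled vocabulary of biomarker function categories retained at the
#' triage stage — inflammation, lipid/other metabolism and haematological
#' development categories as used for the published 56-probe panel.
#'
#' @return Character vector of category names.
#' @export
atherosclerosis_categories <- function() {
  c("Inflammatory Response", "Inflammatory Disease", "Immunological Disease",
    "Lipid Metabolism", "Other Metabolic Processes", "Carbohydrate Metabolism",
    "Hematological System Development and Function")
}

#' Generate a synthetic multi-cell-type cohort
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `expression` (named list of
#'   [expr_matrix], one per cell type), `metadata` (tibble), `annotations`
#'   (tibble) and `truth` (list: `de_probes`, `concordant_probes`,
#'   `log2_effects` named vector).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_probes
  probes <- sprintf("p%04d", seq_len(np))
  mu <- stats::rnorm(np, mean = 8, sd = 1.5)

  de_idx <- if (config$n_de > 0) sort(sample.int(np, config$n_de)) else integer(0)
  n_conc <- round(config$concordant_fraction * length(de_idx))
  conc_idx <- if (n_conc > 0) sort(sample(de_idx, n_conc)) else integer(0)
  effects <- numeric(np)
  if (length(de_idx)) {
    mag <- stats::runif(length(de_idx), config$log2_effect_range[1],
                        config$log2_effect_range[2])
    effects[de_idx] <- mag * sample(c(-1, 1), length(de_idx), replace = TRUE)
  }

  # loadings: one shared draw, redrawn per cell type for discordant DE probes
  shared_lambda <- matrix(stats::rnorm(np * config$n_latent, sd = config$loading_sd),
                          np, config$n_latent)

  meta_list <- list()
  expr <- list()
  for (ct in names(config$cohort_design)) {
    spec_ct <- config$cohort_design[[ct]]
    des <- spec_ct$design
    if (!is.null(spec_ct$same_subjects_as)) {
      ref <- meta_list[[spec_ct$same_subjects_as]]
      if (is.null(ref)) stop("same_subjects_as refers to a later cell type", call. = FALSE)
      meta_ct <- ref
    } else {
      sid <- sprintf("%s_S%02d", spec_ct$dataset_id, seq_len(sum(des$n)))
      meta_ct <- tibble::tibble(
        sample_id = sid,
        subclass = rep(des$subclass, des$n),
        risk_class = ifelse(rep(des$subclass, des$n) == "control", "low", "high")
      )
      meta_list[[ct]] <- meta_ct
    }
    ns <- nrow(meta_ct)
    lambda <- shared_lambda
    eff_ct <- effects
    if (length(de_idx)) {
      disc <- setdiff(de_idx, conc_idx)
      if (length(disc) && ct != names(config$cohort_design)[1]) {
        # discordant probes: both their co-expression loadings and their risk
        # effect are cell-type-specific; only concordant probes transfer
        lambda[disc, ] <- stats::rnorm(length(disc) * config$n_latent,
                                       sd = config$loading_sd)
        mag_d <- stats::runif(length(disc), config$log2_effect_range[1],
                              config$log2_effect_range[2])
        eff_ct[disc] <- mag_d * sample(c(-1, 1), length(disc), replace = TRUE)
      }
    }
    f <- matrix(stats::rnorm(config$n_latent * ns), config$n_latent, ns)
    z <- as.numeric(meta_ct$risk_class == "high")
    z[meta_ct$subclass == "homozygous_FH"] <- config$homozygous_multiplier
    vals <- mu + lambda %*% f + outer(eff_ct, z) +
      matrix(stats::rnorm(np * ns, sd = config$noise_sd), np, ns)
    dimnames(vals) <- list(probes, meta_ct$sample_id)
    expr[[ct]] <- expr_matrix(vals, spec_ct$dataset_id, ct)
  }

  metadata <- validate_metadata(dplyr::distinct(dplyr::bind_rows(meta_list)))

  vocab <- atherosclerosis_categories()
  category <- sample(c(vocab, "Neuronal Signaling"), np, replace = TRUE)
  if (length(de_idx)) {
    n_oov <- round(config$out_of_vocab_fraction * length(de_idx))
    in_vocab <- sample(vocab, length(de_idx), replace = TRUE)
    category[de_idx] <- in_vocab
    if (n_oov > 0) category[sample(de_idx, n_oov)] <- "Neuronal Signaling"
  }
  annotations <- tibble::tibble(probe_id = probes,
                                gene_symbol = toupper(probes),
                                category = category)

  truth <- list(de_probes = probes[de_idx],
                concordant_probes = probes[conc_idx],
                log2_effects = stats::setNames(effects[de_idx], probes[de_idx]))
  structure(list(expression = expr, metadata = metadata,
                 annotations = annotations, truth = truth, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d probes, %d DE (%d concordant), cell types: %s\n",
              x$config$n_probes, length(x$truth$de_probes),
              length(x$truth$concordant_probes),
              paste(names(x$expression), collapse = ", ")))
  invisible(x)
}

#' Write or read a cohort as plain-text files
#'
#' Materialises one expression TSV per cell type plus `metadata.tsv`,
#' `annotations.tsv` and `truth.json` — the same dialects the readers in this
#' package consume, so generate/write/read round-trips to text precision.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` invisibly returns the vector of files written;
#'   `read_cohort()` returns a list like [simulate_cohort()]'s (with `truth`
#'   if `truth.json` is present).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ct in names(cohort$expression)) {
    f <- file.path(dir, paste0("expression_", ct, ".tsv"))
    write_expr_matrix(cohort$expression[[ct]], f)
    files <- c(files, f)
  }
  fm <- file.path(dir, "metadata.tsv")
  utils::write.table(cohort$metadata, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "annotations.tsv")
  utils::write.table(cohort$annotations, fa, sep = "\t", quote = FALSE, row.names = FALSE)
  ft <- file.path(dir, "truth.json")
  jsonlite::write_json(list(de_probes = cohort$truth$de_probes,
                            concordant_probes = cohort$truth$concordant_probes,
                            log2_effects = as.list(cohort$truth$log2_effects)),
                       ft, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, fm, fa, ft))
}

#' @rdname write_cohort
#' @param cell_types Named character vector `cell_type = dataset_id` to load;
#'   defaults to every `expression_*.tsv` found (dataset_id read from file
#'   name).
#' @export
read_cohort <- function(dir, cell_types = NULL) {
  files <- list.files(dir, pattern = "^expression_.*\\.tsv$", full.names = TRUE)
  cts <- sub("^expression_(.*)\\.tsv$", "\\1", basename(files))
  expr <- stats::setNames(vector("list", length(files)), cts)
  for (i in seq_along(files)) {
    id <- if (!is.null(cell_types) && cts[i] %in% names(cell_types)) {
      cell_types[[cts[i]]]
    } else cts[i]
    expr[[cts[i]]] <- read_expr_matrix(files[i], dataset_id = id, cell_type = cts[i])
  }
  out <- list(expression = expr,
              metadata = read_sample_metadata(file.path(dir, "metadata.tsv")),
              annotations = read_annotations(file.path(dir, "annotations.tsv")))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    out$truth <- list(de_probes = as.character(tr$de_probes),
                      concordant_probes = as.character(tr$concordant_probes),
                      log2_effects = unlist(tr$log2_effects))
  }
  out
}
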