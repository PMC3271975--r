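#' Standardize expression within each gene
#'
#' Centres and scales every probe row to mean 0, sample standard deviation 1
#' (divisor n - 1) across the samples of the set. Each dataset is
#' standardized within itself — never with another set's statistics — to
#' absorb platform and batch shifts between independently generated sets.
#' Constant rows become all-zero with a warning.
#'
#' @param x An [expr_matrix] with >= 2 samples.
#' @return The standardized [expr_matrix].
#' @export
standardize_within_genes <- function(x) {
  stopifnot(is_expr_matrix(x))
  if (ncol(x) < 2) stop("standardization needs at least 2 samples", call. = FALSE)
  v <- unclass(x)
  m <- rowMeans(v)
  s <- sqrt(rowSums((v - m)^2) / (ncol(v) - 1))
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant probe row(s) set to zero", call. = FALSE)
    s[const] <- 1
  }
  expr_matrix((v - m) / s, attr(x, "dataset_id"), attr(x, "cell_type"))
}

#' Top-3 principal components of a standardized biomarker panel
#'
#' PCA with samples as observations and panel probes as variables, on
#' already gene-standardized data (so this is correlation-matrix PCA). The
#' number of components is fixed at 3; if they carry 70% or less of the
#' total variance a warning is emitted but the fit proceeds. Loading signs
#' are fixed so each component's largest-magnitude loading is positive,
#' making repeated fits bit-identical.
#'
#' @param std_matrix A standardized [expr_matrix] (see
#'   [standardize_within_genes()]).
#' @param panel Optional [biomarker_panel()] restricting the probes; default
#'   uses every row.
#' @return A `pca_model`: `panel_probe_ids`, `loadings` (probes x 3),
#'   `explained_variance_fraction` (length 3), `n_components = 3`.
#' @export
fit_pca <- function(std_matrix, panel = NULL) {
  stopifnot(is_expr_matrix(std_matrix))
  probes <- if (is.null(panel)) probe_ids(std_matrix)
            else if (inherits(panel, "biomarker_panel")) panel$probe_ids
            else as.character(panel)
  missing_p <- setdiff(probes, probe_ids(std_matrix))
  if (length(missing_p)) {
    stop("panel probe(s) absent: ", paste(missing_p, collapse = ", "), call. = FALSE)
  }
  if (length(probes) < 3) stop("panel must contain at least 3 probes", call. = FALSE)
  if (ncol(std_matrix) < 4) stop("need at least 4 samples for a 3-component PCA", call. = FALSE)
  obs <- t(unclass(std_matrix)[probes, , drop = FALSE])   # samples x probes
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  k <- 3L
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) load[, j] <- -load[, j]
  }
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  evf3 <- evf[seq_len(k)]
  if (sum(evf3) <= 0.70) {
    warning(sprintf("top 3 components carry only %.1f%% of variance (<= 70%%)",
                    100 * sum(evf3)), call. = FALSE)
  }
  structure(list(panel_probe_ids = probes, loadings = load,
                 explained_variance_fraction = evf3, n_components = k),
            class = "pca_model")
}

# project a standardized matrix onto PCA loadings -> samples x 3 scores
pca_scores <- function(pca, std_matrix) {
  obs <- t(unclass(std_matrix)[pca$panel_probe_ids, , drop = FALSE])
  obs %*% pca$loadings
}

#' Gaussian linear discriminant analysis in component space
#'
#' Two-class LDA with a pooled within-class covariance and equal priors
#' (misclassification in either direction weighted equally). The fitted
#' object yields posterior probabilities of the high-risk class via the
#' Gaussian Bayes rule. A numerically singular pooled covariance is
#' ridge-regularized (epsilon = 1e-6 * trace/dim) with a warning.
#'
#' @param pc_scores Numeric matrix, samples x components (rownames = sample
#'   IDs).
#' @param labels Character/factor vector of `"high"`/`"low"` per sample.
#' @param priors Length-2 numeric (low, high) summing to 1; default equal.
#' @return An `lda_model`: `class_labels = c("low", "high")`, `class_means`,
#'   `pooled_covariance`, `priors`.
#' @export
fit_lda <- function(pc_scores, labels, priors = c(0.5, 0.5)) {
  pc_scores <- as.matrix(pc_scores)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(pc_scores))
  if (!all(labels %in% c("low", "high"))) stop("labels must be 'low'/'high'", call. = FALSE)
  if (min(table(labels)) < 2 || length(unique(labels)) < 2) {
    stop("both classes need at least 2 samples", call. = FALSE)
  }
  stopifnot(length(priors) == 2, abs(sum(priors) - 1) < 1e-8)
  d <- ncol(pc_scores)
  mu <- list(low = colMeans(pc_scores[labels == "low", , drop = FALSE]),
             high = colMeans(pc_scores[labels == "high", , drop = FALSE]))
  sw <- matrix(0, d, d)
  for (cl in c("low", "high")) {
    xc <- sweep(pc_scores[labels == cl, , drop = FALSE], 2, mu[[cl]])
    sw <- sw + crossprod(xc)
  }
  sigma <- sw / (nrow(pc_scores) - 2)
  if (rcond_sym(sigma) < 1e-12) {
    eps <- 1e-6 * sum(diag(sigma)) / d
    if (eps == 0) eps <- 1e-6
    warning(sprintf("singular pooled covariance; ridge epsilon %.3g added", eps),
            call. = FALSE)
    sigma <- sigma + diag(eps, d)
  }
  structure(list(class_labels = c("low", "high"), class_means = mu,
                 pooled_covariance = sigma,
                 priors = stats::setNames(priors, c("low", "high"))),
            class = "lda_model")
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' @rdname fit_lda
#' @param object A fitted `lda_model`.
#' @param newdata Numeric matrix of component scores, samples x components.
#' @param ... Unused.
#' @return `predict()` returns a tibble `sample_id`, `posterior_high`.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  si <- solve(object$pooled_covariance)
  disc <- function(mu, prior) {
    # linear discriminant: x' Si mu - mu' Si mu / 2 + log prior
    drop(newdata %*% si %*% mu) - drop(t(mu) %*% si %*% mu) / 2 + log(prior)
  }
  dh <- disc(object$class_means$high, object$priors["high"])
  dl <- disc(object$class_means$low, object$priors["low"])
  post <- stats::plogis(dh - dl)
  tibble::tibble(sample_id = rownames(newdata) %||% as.character(seq_len(nrow(newdata))),
                 posterior_high = unname(post))
}

#' Train the atherogenic-risk predictor
#'
#' The full stage-3 model: standardize the training set within genes,
#' restrict to the biomarker panel, take the top-3 principal components, and
#' fit an equal-prior Gaussian LDA on the component scores. The resulting
#' posterior probability of the high-risk class is the continuous risk score
#' in `[0, 1]`.
#'
#' @param train An [expr_matrix] (raw, un-standardized).
#' @param metadata Sample metadata tibble covering the training samples.
#' @param panel A [biomarker_panel()].
#' @param priors LDA priors (low, high); default equal.
#' @return A `risk_predictor` with elements `pca`, `lda`, `panel`,
#'   `training_dataset_id` and the training scores.
#' @export
train_risk_predictor <- function(train, metadata, panel, priors = c(0.5, 0.5)) {
  stopifnot(is_expr_matrix(train), inherits(panel, "biomarker_panel"))
  metadata <- validate_metadata(as.data.frame(metadata))
  std <- standardize_within_genes(train)
  pca <- fit_pca(std, panel)
  scores <- pca_scores(pca, std)
  labels <- metadata$risk_class[match(rownames(scores), metadata$sample_id)]
  if (anyNA(labels)) stop("metadata missing training sample(s)", call. = FALSE)
  lda <- fit_lda(scores, labels, priors = priors)
  fit <- structure(list(pca = pca, lda = lda, panel = panel,
                        training_dataset_id = attr(train, "dataset_id"),
                        cell_type = attr(train, "cell_type")),
                   class = "risk_predictor")
  fit$training_scores <- predict(fit, train)
  fit
}

#' @export
print.risk_predictor <- function(x, ...) {
  cat(sprintf("<risk_predictor> %d-probe %s panel (trained on %s, %s), 3 PCs + LDA\n",
              length(x$panel), x$panel$source, x$training_dataset_id, x$cell_type))
  cat(sprintf("  top-3 explained variance: %.1f%%\n",
              100 * sum(x$pca$explained_variance_fraction)))
  invisible(x)
}

#' Predict posterior risk scores for a new dataset
#'
#' The test set is standardized within its own genes (its provenance differs
#' from training, so training statistics never transfer), projected on the
#' training PCA loadings, and scored by the trained LDA posterior.
#'
#' @param object A `risk_predictor`.
#' @param newdata An [expr_matrix] containing every panel probe.
#' @param ... Unused.
#' @return A tibble `sample_id`, `posterior_high`.
#' @export
predict.risk_predictor <- function(object, newdata, ...) {
  stopifnot(is_expr_matrix(newdata))
  missing_p <- setdiff(object$pca$panel_probe_ids, probe_ids(newdata))
  if (length(missing_p)) {
    stop("test matrix missing panel probe(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  std <- standardize_within_genes(newdata)
  predict(object$lda, pca_scores(object$pca, std))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted risk predictor
#'
#' One row per panel probe and principal component, giving the loading
#' (weight) of that probe on that component.
#'
#' @param x A `risk_predictor`.
#' @param ... Unused.
#' @return A tibble `probe_id`, `component`, `loading`.
#' @method tidy risk_predictor
#' @export
tidy.risk_predictor <- function(x, ...) {
  ld <- x$pca$loadings
  tibble::tibble(
    probe_id = rep(x$pca$panel_probe_ids, times = ncol(ld)),
    component = rep(paste0("PC", seq_len(ncol(ld))), each = nrow(ld)),
    loading = as.vector(ld)
  )
}

#' @rdname tidy.risk_predictor
#' @return `glance()` returns a one-row tibble summarising the fit: panel
#'   size and source, training set, per-component and cumulative explained
#'   variance.
#' @method glance risk_predictor
#' @export
glance.risk_predictor <- function(x, ...) {
  evf <- x$pca$explained_variance_fraction
  tibble::tibble(
    n_probes = length(x$panel),
    panel_source = x$panel$source,
    training_dataset_id = x$training_dataset_id,
    pc1_var = evf[1], pc2_var = evf[2], pc3_var = evf[3],
    cum_var_top3 = sum(evf),
    prior_high = unname(x$lda$priors["high"])
  )
}

#' Serialize or restore a risk predictor as JSON
#'
#' Stores the panel, PCA loadings, explained-variance fractions, LDA class
#' means, pooled covariance, priors and training provenance, so a saved
#' model reproduces its posteriors exactly (to JSON numeric precision).
#'
#' @param object A `risk_predictor`.
#' @param path JSON file path.
#' @return `write_predictor()` invisibly returns `path`; `read_predictor()`
#'   returns the `risk_predictor`.
#' @export
write_predictor <- function(object, path) {
  stopifnot(inherits(object, "risk_predictor"))
  obj <- list(
    panel = list(probe_ids = object$panel$probe_ids, source = object$panel$source,
                 training_dataset_id = object$panel$training_dataset_id,
                 description = object$panel$description),
    pca = list(panel_probe_ids = object$pca$panel_probe_ids,
               loadings = object$pca$loadings,
               explained_variance_fraction = object$pca$explained_variance_fraction,
               n_components = object$pca$n_components),
    lda = list(class_labels = object$lda$class_labels,
               class_means = object$lda$class_means,
               pooled_covariance = object$lda$pooled_covariance,
               priors = as.list(object$lda$priors)),
    provenance = list(training_dataset_id = object$training_dataset_id,
                      cell_type = object$cell_type)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pca <- structure(list(
    panel_probe_ids = as.character(obj$pca$panel_probe_ids),
    loadings = matrix(unlist(obj$pca$loadings), ncol = obj$pca$n_components,
                      dimnames = list(obj$pca$panel_probe_ids,
                                      paste0("PC", seq_len(obj$pca$n_components)))),
    explained_variance_fraction = as.numeric(obj$pca$explained_variance_fraction),
    n_components = as.integer(obj$pca$n_components)), class = "pca_model")
  lda <- structure(list(
    class_labels = as.character(obj$lda$class_labels),
    class_means = list(low = as.numeric(obj$lda$class_means$low),
                       high = as.numeric(obj$lda$class_means$high)),
    pooled_covariance = matrix(unlist(obj$lda$pooled_covariance),
                               nrow = obj$pca$n_components),
    priors = c(low = obj$lda$priors$low, high = obj$lda$priors$high)),
    class = "lda_model")
  panel <- biomarker_panel(obj$panel$probe_ids, source = obj$panel$source,
                           training_dataset_id = obj$panel$training_dataset_id,
                           description = obj$panel$description %||% "")
  structure(list(pca = pca, lda = lda, panel = panel,
                 training_dataset_id = obj$provenance$training_dataset_id,
                 cell_type = obj$provenance$cell_type),
            class = "risk_predictor")
}
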