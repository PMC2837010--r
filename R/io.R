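# Plain-text readers and writers for every interchange format the pipeline
# touches: probe-level matrices, sample sheets, expression matrices,
# cohorts (expression + survival), ground-truth records and run manifests.

#' Write / read a probe-level matrix as TSV
#'
#' The matrix file has columns `probeset_id`, `probe_index`, then one
#' column per array; the sample sheet (`<path>.samples.tsv`) has columns
#' `array_id`, `condition`, `temperature`, `replicate`.
#'
#' @param x A `probe_matrix`.
#' @param path TSV file path.
#' @return `read_probe_matrix()`: a `probe_matrix`.
#' @export
write_probe_matrix <- function(x, path) {
  tab <- cbind(x$probes, as.data.frame(x$intensities, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- utils::read.delim(paste0(path, ".samples.tsv"),
                               colClasses = c(temperature = "character"),
                               stringsAsFactors = FALSE)
  probes <- tab[, c("probeset_id", "probe_index")]
  m <- as.matrix(tab[, samples$array_id, drop = FALSE])
  rownames(m) <- paste0(probes$probeset_id, "_p", probes$probe_index)
  structure(list(intensities = m, probes = probes, samples = samples),
            class = "probe_matrix")
}

#' Write / read an expression matrix as TSV
#'
#' First column `feature_id`, then one column per sample; the sample sheet
#' travels in `<path>.samples.tsv` when metadata are present.
#'
#' @param x An `expr_matrix`.
#' @param path TSV file path.
#' @return `read_expr_matrix()`: an `expr_matrix`.
#' @export
write_expr_matrix <- function(x, path) {
  tab <- data.frame(feature_id = rownames(x$values),
                    as.data.frame(x$values, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$samples)) {
    utils::write.table(x$samples, paste0(path, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$feature_id
  samples <- NULL
  sp <- paste0(path, ".samples.tsv")
  if (file.exists(sp)) {
    samples <- utils::read.delim(sp, stringsAsFactors = FALSE)
  }
  structure(list(values = m, samples = samples), class = "expr_matrix")
}

#' Write / read a tumor cohort (expression + survival TSVs)
#'
#' @param cohort A `tumor_cohort`.
#' @param dir Output directory; writes `expression.tsv` (gene x tumor,
#'   `feature_id` first column) and `survival.tsv` (`tumor_id`, `time`,
#'   `event`, `endpoint`, `time_unit`).
#' @return `read_tumor_cohort()`: a `tumor_cohort`.
#' @export
write_tumor_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  etab <- data.frame(feature_id = rownames(cohort$expression),
                     as.data.frame(cohort$expression, check.names = FALSE),
                     check.names = FALSE)
  utils::write.table(etab, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stab <- cbind(cohort$survival, endpoint = cohort$endpoint,
                time_unit = cohort$time_unit)
  utils::write.table(stab, file.path(dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_tumor_cohort
#' @export
read_tumor_cohort <- function(dir) {
  etab <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(etab[, -1, drop = FALSE])
  rownames(expr) <- etab$feature_id
  stab <- utils::read.delim(file.path(dir, "survival.tsv"),
                            stringsAsFactors = FALSE)
  structure(list(expression = expr,
                 survival = stab[, c("tumor_id", "time", "event")],
                 time_unit = if ("time_unit" %in% names(stab))
                   stab$time_unit[1] else "years",
                 endpoint = if ("endpoint" %in% names(stab))
                   stab$endpoint[1] else "disease-free"),
            class = "tumor_cohort")
}

#' Write a ground-truth record as JSON
#'
#' @param truth A `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the bundled 42-gene aggressive tumor signature
#'
#' The v-Src aggressive tumor gene signature: the intersection of
#' poor-prognosis-cluster candidate genes across two independent breast
#' carcinoma training cohorts, shipped as a GMT fixture.
#'
#' @return Character vector of 42 unique human gene symbols.
#' @export
load_aggressive_signature <- function() {
  path <- system.file("extdata", "aggressive_signature.gmt",
                      package = "srcsig", mustWork = TRUE)
  read_gmt(path)[["aggressive_tumor_signature"]]
}

#' Assemble a run manifest
#'
#' A manifest records everything needed to reproduce a pipeline run: the
#' configuration snapshot, the seeds, MD5 digests of every output file, and
#' per-stage summaries. Deterministic stages re-run with the manifest's
#' config and seed reproduce identical digests.
#'
#' @param config Configuration object(s) used for the run.
#' @param seeds Named list/vector of seeds.
#' @param files Character vector of output file paths to digest.
#' @param summaries Named list of per-stage summaries.
#' @return List of class `run_manifest`.
#' @export
build_manifest <- function(config, seeds, files = character(),
                           summaries = list()) {
  digests <- if (length(files)) {
    d <- tools::md5sum(files)
    data.frame(file = names(d), md5 = unname(d), stringsAsFactors = FALSE)
  } else {
    data.frame(file = character(), md5 = character())
  }
  structure(list(config = config, seeds = seeds, file_digests = digests,
                 summaries = summaries,
                 version = as.character(utils::packageVersion("srcsig"))),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (srcsig %s): %d output file(s), %d stage summaries\n",
              x$version, nrow(x$file_digests), length(x$summaries)))
  invisible(x)
}
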