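#' Construct a directed gene set
#'
#' A gene set is a named collection of gene (or probe-set) identifiers, each
#' carrying a regulation direction (`"up"` or `"down"`) and optionally a
#' linear fold change. Gene sets are the currency of the discovery stage:
#' transformation-regulated (TR) lists, temperature-sensitive (ts) lists and
#' their set-algebra combinations are all `gene_set` objects.
#'
#' @param name Set name (e.g. `"TR"`, `"CSR"`).
#' @param gene_id Character vector of unique member identifiers.
#' @param direction Character vector, one of `"up"`/`"down"` per member.
#' @param fold_change Optional numeric vector of linear fold changes
#'   (>= 1 by convention; the direction label carries the sign).
#' @param provenance Free-text label recording which comparison(s) produced
#'   the set.
#' @return An object of class `gene_set`: a list with elements `name`,
#'   `members` (a data.frame with columns `gene_id`, `direction` and, when
#'   supplied, `fold_change`) and `provenance`.
#' @examples
#' gs <- gene_set("demo", c("G1", "G2"), c("up", "down"))
#' gs$members
#' @export
gene_set <- function(name, gene_id, direction, fold_change = NULL,
                     provenance = "") {
  gene_id <- as.character(gene_id)
  direction <- as.character(direction)
  if (length(direction) == 1L) direction <- rep(direction, length(gene_id))
  if (length(gene_id) != length(direction)) {
    stopf("gene_set '%s': %d ids but %d directions",
          name, length(gene_id), length(direction))
  }
  if (anyDuplicated(gene_id)) {
    stopf("gene_set '%s': duplicated member ids (e.g. %s)", name,
          gene_id[duplicated(gene_id)][1L])
  }
  if (length(gene_id) && !all(direction %in% c("up", "down"))) {
    stopf("gene_set '%s': directions must be 'up' or 'down'", name)
  }
  members <- data.frame(gene_id = gene_id, direction = direction,
                        stringsAsFactors = FALSE)
  if (!is.null(fold_change)) {
    stopifnot(length(fold_change) == length(gene_id))
    members$fold_change <- as.numeric(fold_change)
  }
  structure(list(name = name, members = members, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  tab <- table(factor(x$members$direction, levels = c("up", "down")))
  cat(sprintf("gene_set '%s': %d members (%d up, %d down)\n",
              x$name, nrow(x$members), tab[["up"]], tab[["down"]]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$members)

#' Gene-set accessors
#'
#' `set_ids()` returns a gene set's member identifiers;
#' `up_down_counts()` its up/down breakdown.
#'
#' @param x A `gene_set`.
#' @return `set_ids()`: character vector; `up_down_counts()`: named integer
#'   vector with elements `up` and `down`.
#' @export
set_ids <- function(x) x$members$gene_id

#' @rdname set_ids
#' @export
up_down_counts <- function(x) {
  tab <- table(factor(x$members$direction, levels = c("up", "down")))
  c(up = unname(tab[["up"]]), down = unname(tab[["down"]]))
}

#' Read and write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line,
#' fields `name`, `description`, then member identifiers. Directions are not
#' part of GMT; [write_gene_sets_gmt()] therefore also writes a TSV sidecar
#' (`<path>.members.tsv`) with per-member direction and provenance, and
#' [read_gmt()] returns plain (direction-free) membership lists.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("malformed GMT line: %s", substr(l, 1, 50))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out
}

#' @rdname read_gmt
#' @param sets A list of `gene_set` objects (or a single one).
#' @export
write_gene_sets_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$provenance, s$members$gene_id), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  side <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set = s$name, gene_id = s$members$gene_id,
               direction = s$members$direction,
               fold_change = if (is.null(s$members$fold_change)) NA_real_
                             else s$members$fold_change,
               provenance = s$provenance, stringsAsFactors = FALSE)
  }))
  utils::write.table(side, paste0(path, ".members.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
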