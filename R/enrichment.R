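#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB member genes`.
#' Duplicate members within a set are de-duplicated with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; set descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated fields",
           call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", fields[1], "' de-duplicated")
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
    descriptions[fields[1]] <- fields[2]
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in GMT", call. = FALSE)
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||%
      stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' Offline stand-in for web-based annotation: for each gene set, the upper
#' tail P(X >= overlap) of the hypergeometric distribution with the tested
#' universe as population, the set's universe overlap as successes and the
#' module as the draw, Bonferroni-corrected over the number of tested sets.
#'
#' @param module_genes Genes of the module under test (must lie in
#'   `universe`).
#' @param universe Background gene ids (typically all genes in the merged
#'   expression matrix).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); each set is
#'   intersected with the universe before testing.
#' @return Tibble sorted by ascending p: `set`, `overlap`, `module_size`,
#'   `set_size`, `universe_size`, `p`, `bonferroni_p`.
#' @export
overrepresentation <- function(module_genes, universe, sets) {
  module_genes <- unique(module_genes)
  universe <- unique(universe)
  outside <- setdiff(module_genes, universe)
  if (length(outside) > 0) {
    stop("module genes outside universe: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  n_tests <- length(sets)
  rows <- purrr::imap_dfr(sets, function(members, nm) {
    s <- intersect(members, universe)
    ov <- length(intersect(s, module_genes))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(module_genes), lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = ov,
                   module_size = length(module_genes),
                   set_size = length(s), universe_size = length(universe),
                   p = p, bonferroni_p = min(1, p * n_tests))
  })
  dplyr::arrange(rows, .data$p, .data$set)
}
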