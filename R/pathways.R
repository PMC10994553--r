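# Pathway collections (GMT) and the pathway-hierarchy relation graph.
#
# A pathway collection is a tibble with one row per pathway:
#   pathway_id    unique identifier (e.g. "R-HSA-71384")
#   pathway_name  free-text description
#   members       list-column of molecule identifier character vectors
# Molecule identifiers are opaque strings; a pathway may mix identifier
# namespaces (ChEBI metabolites, UniProt proteins, ENSEMBL genes), which is
# what makes a collection "multi-omics".

#' Read a pathway collection from a GMT file
#'
#' Parses the Broad-style GMT dialect: UTF-8, tab-separated, no header; each
#' line is `id<TAB>description<TAB>member1<TAB>member2...`. Trailing empty
#' fields are ignored and duplicate members within a line are dropped.
#'
#' @param path Path to a GMT file.
#' @param source_tag Optional label recording where the collection came from
#'   (stored as the `"source_tag"` attribute). Defaults to the file name.
#' @return A tibble with columns `pathway_id`, `pathway_name` and the
#'   list-column `members`, in file order.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("R-HSA-1\tCarnitine metabolism\tCHEBI:17126\tP43155", f)
#' read_gmt(f)
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) {
    rlang::abort(paste0("GMT file not found: ", path))
  }
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    out <- tibble::tibble(pathway_id = character(), pathway_name = character(),
                          members = list())
    attr(out, "source_tag") <- source_tag
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    # drop trailing empty fields only
    while (length(f) > 0 && !nzchar(f[length(f)])) f <- f[-length(f)]
    f
  })
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    rlang::abort(paste0("Malformed GMT line ", line_no[bad[1]],
                        ": fewer than 3 tab-separated fields."))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicate pathway id in GMT file: ",
                        paste(unique(dup), collapse = ", ")))
  }
  out <- tibble::tibble(
    pathway_id = ids,
    pathway_name = vapply(fields, `[[`, character(1), 2),
    members = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  attr(out, "source_tag") <- source_tag
  out
}

#' Write a pathway collection to a GMT file
#'
#' @param collection A pathway collection tibble as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  check_collection(collection)
  lines <- mapply(function(id, name, members) {
    paste(c(id, name, members), collapse = "\t")
  }, collection$pathway_id, collection$pathway_name, collection$members)
  readr::write_lines(as.character(lines), path)
  invisible(path)
}

check_collection <- function(collection) {
  req <- c("pathway_id", "pathway_name", "members")
  if (!all(req %in% names(collection))) {
    rlang::abort(
      "A pathway collection needs columns pathway_id, pathway_name, members.")
  }
  if (anyDuplicated(collection$pathway_id)) {
    rlang::abort("Pathway ids must be unique within a collection.")
  }
  invisible(collection)
}

#' Merge pathway collections into one multi-omics collection
#'
#' Pathways sharing an id across collections (e.g. the metabolite and protein
#' views of the same Reactome pathway) are unioned over their members, giving
#' a single multi-omics pathway definition. Ids present in only one input are
#' kept unchanged. Pathway order follows first appearance.
#'
#' @param ... Pathway collection tibbles, or a single list of them.
#' @return A merged pathway collection tibble.
#' @export
merge_multiomics <- function(...) {
  colls <- list(...)
  if (length(colls) == 1 && is.list(colls[[1]]) && !is.data.frame(colls[[1]])) {
    colls <- colls[[1]]
  }
  if (length(colls) == 0) rlang::abort("Need at least one collection.")
  lapply(colls, check_collection)
  all <- dplyr::bind_rows(colls)
  merged <- all |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      pathway_name = dplyr::first(.data$pathway_name),
      members = list(unique(unlist(.data$members))),
      .ord = min(.data$.ord),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
  merged
}

#' Filter a pathway collection by dataset coverage
#'
#' Coverage is the number of a pathway's member molecules actually observed
#' in a dataset. Members are intersected with `observed` and pathways with
#' fewer than `min_coverage` observed members are dropped. The default of 2
#' is a deliberately liberal threshold: a pathway submatrix needs at least
#' two molecule profiles before a principal-component activity score is
#' meaningful. Simulation target pathways typically require 3.
#'
#' @param collection A pathway collection tibble.
#' @param observed Character vector of molecule identifiers measured in the
#'   dataset (e.g. `colnames` of the abundance blocks).
#' @param min_coverage Minimum number of observed members to retain a
#'   pathway (default 2).
#' @return The filtered collection with members restricted to `observed` and
#'   an added `coverage` column.
#' @export
filter_coverage <- function(collection, observed, min_coverage = 2) {
  check_collection(collection)
  if (length(observed) == 0) {
    rlang::abort("`observed` must contain at least one molecule identifier.")
  }
  if (min_coverage < 1) rlang::abort("`min_coverage` must be >= 1.")
  observed <- unique(as.character(observed))
  out <- collection
  out$members <- lapply(out$members, function(m) m[m %in% observed])
  out$coverage <- vapply(out$members, length, integer(1))
  out[out$coverage >= min_coverage, , drop = FALSE]
}

#' Read a pathway parent-child hierarchy
#'
#' Reads a two-column tab-separated edge list (parent id, child id), the
#' format used for Reactome's pathway-relation file. The edge set must form
#' a directed acyclic graph.
#'
#' @param path Path to the relation file.
#' @return A tibble with columns `parent` and `child`.
#' @export
read_hierarchy <- function(path) {
  edges <- readr::read_tsv(path, col_names = c("parent", "child"),
                           col_types = "cc", progress = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    rlang::abort("Pathway hierarchy contains a cycle; it must be a DAG.")
  }
  edges
}

#' Restrict a hierarchy to a set of pathway ids
#'
#' Keeps only edges whose parent and child both belong to `ids` (the induced
#' subgraph), e.g. the ids of a coverage-filtered collection.
#'
#' @param hierarchy Edge tibble from [read_hierarchy()].
#' @param ids Character vector of pathway ids to keep.
#' @return The induced edge tibble.
#' @export
hierarchy_subset <- function(hierarchy, ids) {
  hierarchy[hierarchy$parent %in% ids & hierarchy$child %in% ids, ,
            drop = FALSE]
}
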