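#' Hierarchical classification of taxa
#'
#' A classification maps every taxon identifier to an ordered lineage of
#' nested group names, outermost group (the family) first — the shape of
#' the Ethnologue's grouping of ISO 639-3 languages into families and
#' subfamilies.  Within one analysis every lineage must start with the same
#' family, and a group name must have a single, consistent parent group
#' wherever it appears (no reticulate classification).
#'
#' @param taxa character vector of unique taxon identifiers.
#' @param lineages list of character vectors, one per taxon, each non-empty
#'   and ordered outermost-first.
#' @return an object of class `"classification"`: a list with elements
#'   `taxon` and `lineage`.
#' @seealso [read_classification()], [classification_to_tree()],
#'   [graft_missing()]
#' @export
classification <- function(taxa, lineages) {
  taxa <- as.character(taxa)
  if (length(taxa) == 0L) stop("classification is empty")
  if (length(taxa) != length(lineages))
    stop("'taxa' and 'lineages' lengths differ")
  if (anyDuplicated(taxa))
    stop("duplicate taxon id(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  lineages <- lapply(lineages, as.character)
  empty <- vapply(lineages, function(l) length(l) == 0L || any(!nzchar(l)),
                  logical(1))
  if (any(empty))
    stop("empty lineage for taxon: ", paste(taxa[empty], collapse = ", "))
  fams <- vapply(lineages, `[`, "", 1L)
  if (length(unique(fams)) > 1L)
    stop("all lineages must start with the same family; found: ",
         paste(unique(fams), collapse = ", "))
  # consistent parentage: a group name determines its parent group
  parent_of <- character(0)
  for (l in lineages) {
    if (length(l) < 2L) next
    for (d in 2:length(l)) {
      g <- l[d]; p <- l[d - 1L]
      if (g %in% names(parent_of)) {
        if (parent_of[[g]] != p)
          stop("inconsistent parentage for group '", g, "': both '",
               parent_of[[g]], "' and '", p, "'")
      } else parent_of[[g]] <- p
    }
  }
  if (fams[1L] %in% names(parent_of))
    stop("family name '", fams[1L], "' also appears as a nested group")
  structure(list(taxon = taxa, lineage = lineages), class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("Classification of", length(x$taxon), "taxa under family '",
      x$lineage[[1L]][1L], "'\n", sep = "")
  depth <- vapply(x$lineage, length, 0L)
  cat("lineage depth:", min(depth), "to", max(depth), "\n")
  invisible(x)
}

#' Read a classification table
#'
#' Expects a delimited file with two columns: taxon identifier and lineage
#' path (e.g. `Swedish,Germanic/North`).  Taxon labels join to tree tip
#' labels by exact string match, no normalization.
#'
#' @param file path to the table (UTF-8).
#' @param sep column separator, default `","`.
#' @param path_sep separator between nested group names inside the lineage
#'   path, default `"/"`.
#' @param header does the file carry a header row?  Default `TRUE`.
#' @return a `"classification"` object.
#' @export
read_classification <- function(file, sep = ",", path_sep = "/",
                                header = TRUE) {
  df <- utils::read.csv(file, sep = sep, header = header,
                        stringsAsFactors = FALSE, comment.char = "#",
                        fileEncoding = "UTF-8", colClasses = "character")
  if (ncol(df) < 2L) stop("classification table needs two columns")
  lineages <- strsplit(df[[2L]], path_sep, fixed = TRUE)
  classification(df[[1L]], lineages)
}

#' Write a classification table
#'
#' @param x a `"classification"` object.
#' @param file output path.
#' @param path_sep lineage-path separator.
#' @return `file`, invisibly.
#' @export
write_classification <- function(x, file, path_sep = "/") {
  stopifnot(inherits(x, "classification"))
  df <- data.frame(taxon = x$taxon,
                   lineage = vapply(x$lineage, paste, "", collapse = path_sep),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Convert a classification into a (branch-length-free) tree
#'
#' Builds the rooted tree implied by the nested groups: internal nodes are
#' the classification groups (labeled by group name), tips are the taxa,
#' and no edge carries a length.  Groups that do not resolve order come out
#' as polytomies.  Nodes with a single child (a group containing exactly
#' one subgroup or taxon) are kept, since they are meaningful levels of the
#' classification.
#'
#' @param x a `"classification"` object.
#' @return a `"phylo"` object with `NULL` `edge.length` and group names as
#'   `node.label`.
#' @export
classification_to_tree <- function(x) {
  stopifnot(inherits(x, "classification"))
  n <- length(x$taxon)
  # groups in order of first appearance; family is first, parents precede
  # children because lineages list outermost groups first
  groups <- character(0)
  for (l in x$lineage) groups <- c(groups, setdiff(l, groups))
  g_index <- stats::setNames(seq_along(groups) + n, groups)
  parent_edges <- NULL
  seen <- character(0)
  for (l in x$lineage) {
    if (length(l) >= 2L) {
      for (d in 2:length(l)) {
        if (!(l[d] %in% seen)) {
          parent_edges <- rbind(parent_edges,
                                c(g_index[[l[d - 1L]]], g_index[[l[d]]]))
          seen <- c(seen, l[d])
        }
      }
    }
  }
  tip_edges <- cbind(vapply(x$lineage, function(l) g_index[[l[length(l)]]], 0L),
                     seq_len(n))
  edge <- rbind(parent_edges, tip_edges)
  storage.mode(edge) <- "integer"
  tr <- list(edge = edge, tip.label = x$taxon, Nnode = length(groups),
             node.label = groups)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# taxonomy structure used by grafting: per-group member lists and the
# group parent map, without building a phylo
.classification_index <- function(x) {
  groups <- character(0)
  for (l in x$lineage) groups <- c(groups, setdiff(l, groups))
  parent <- stats::setNames(rep(NA_character_, length(groups)), groups)
  members <- stats::setNames(vector("list", length(groups)), groups)
  children_groups <- stats::setNames(vector("list", length(groups)), groups)
  direct_taxa <- stats::setNames(vector("list", length(groups)), groups)
  for (i in seq_along(x$taxon)) {
    l <- x$lineage[[i]]
    for (d in seq_along(l)) {
      members[[l[d]]] <- c(members[[l[d]]], x$taxon[i])
      if (d >= 2L && is.na(parent[[l[d]]])) parent[[l[d]]] <- l[d - 1L]
    }
    direct_taxa[[l[length(l)]]] <- c(direct_taxa[[l[length(l)]]], x$taxon[i])
  }
  for (g in groups) {
    p <- parent[[g]]
    if (!is.na(p) && !(g %in% children_groups[[p]]))
      children_groups[[p]] <- c(children_groups[[p]], g)
  }
  list(groups = groups, family = x$lineage[[1L]][1L], parent = parent,
       members = members, children_groups = children_groups,
       direct_taxa = direct_taxa)
}
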