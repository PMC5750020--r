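#' Graft taxa missing from a backbone tree using a classification
#'
#' Inserts every taxon of `x` that is absent from `backbone` into the
#' backbone at the position implied by the classification, producing a tree
#' whose tip set equals the taxon set of `x`.  This corrects the
#' descendant-tip counts used by fair-proportion ED without fabricating
#' distinctiveness for the grafted taxa:
#'
#' * Missing taxa are handled as *maximal missing units*: a classification
#'   group none of whose members are on the backbone is imported whole (as a
#'   [classification_to_tree()] subtree); a lone missing taxon whose group
#'   has backbone members is imported alone.
#' * Each unit attaches at the crown of the innermost enclosing group that
#'   has at least one backbone member — the MRCA of that group's backbone
#'   members — as a new child.
#' * If that MRCA is a single tip, a new internal node is inserted at the
#'   parent end of the tip's pendant edge (zero length to the original
#'   parent; the tip keeps its full pendant length) and the unit attaches
#'   there, so the tip's exclusive pendant contribution is preserved.
#' * Every newly created edge has length 0; backbone branch lengths are
#'   never altered.  The backbone's total branch length is therefore
#'   preserved exactly, and no backbone tip's ED can increase.
#' * When a group's backbone members are not monophyletic on the backbone, a
#'   warning is recorded and the MRCA is used anyway.
#'
#' @param backbone a `"phylo"` tree with measured branch lengths; every tip
#'   must appear in `x`.
#' @param x a `"classification"` covering all backbone tips, possibly with
#'   additional (missing) taxa.
#' @return a list of class `"graft_result"` with elements `tree` (the
#'   enlarged `"phylo"`), `report` (one data-frame row per grafted taxon:
#'   `taxon`, `unit_group`, `attachment_group`, `attachment`,
#'   `monophyletic`) and `warnings` (character vector).
#' @examples
#' bb <- parse_newick("((English:4,German:1):1,(Icelandic:1,Norwegian:5):2);")
#' cl <- classification(
#'   c("English", "German", "Dutch", "Icelandic", "Norwegian", "Swedish"),
#'   list(c("Germanic", "West"), c("Germanic", "West", "Continental"),
#'        c("Germanic", "West", "Continental"), c("Germanic", "North"),
#'        c("Germanic", "North"), c("Germanic", "North")))
#' g <- graft_missing(bb, cl)
#' g$tree$tip.label
#' @export
graft_missing <- function(backbone, x) {
  stopifnot(inherits(backbone, "phylo"), inherits(x, "classification"))
  btips <- backbone$tip.label
  not_classified <- setdiff(btips, x$taxon)
  if (length(not_classified) > 0L)
    stop("backbone tip(s) absent from the classification: ",
         paste(utils::head(not_classified, 5L), collapse = ", "))
  missing <- setdiff(x$taxon, btips)
  empty_report <- data.frame(taxon = character(0), unit_group = character(0),
                             attachment_group = character(0),
                             attachment = character(0),
                             monophyletic = logical(0),
                             stringsAsFactors = FALSE)
  if (length(missing) == 0L)
    return(structure(list(tree = backbone, report = empty_report,
                          warnings = character(0)),
                     class = "graft_result"))

  idx <- .classification_index(x)
  present <- vapply(idx$members, function(m) any(m %in% btips), logical(1))
  names(present) <- idx$groups
  if (!present[[idx$family]])
    stop("no backbone member anywhere in the classification")

  # maximal missing units, in deterministic (classification) order
  units <- list()
  for (g in idx$groups) {
    p <- idx$parent[[g]]
    if (!present[[g]] && !is.na(p) && present[[p]])
      units[[length(units) + 1L]] <- list(type = "group", id = g,
                                          attach_group = p)
  }
  for (i in seq_along(x$taxon)) {
    t <- x$taxon[i]
    if (!(t %in% missing)) next
    g <- x$lineage[[i]][length(x$lineage[[i]])]
    if (present[[g]])
      units[[length(units) + 1L]] <- list(type = "taxon", id = t,
                                          attach_group = g)
  }

  A <- .as_adjacency(backbone)
  anchors <- integer(0)           # tip node -> inserted junction node
  attach_cache <- list()          # attach_group -> list(node, monophyletic)
  warnings <- character(0)
  rows <- list()

  for (u in units) {
    G <- u$attach_group
    if (is.null(attach_cache[[G]])) {
      members <- intersect(idx$members[[G]], btips)
      if (length(members) == 1L) {
        tipv <- match(members, A$label[seq_along(btips)])
        key <- as.character(tipv)
        if (is.na(anchors[key])) {
          ins <- .adj_insert_above_tip(A, tipv)
          A <- ins$A
          anchors[key] <- ins$node
        }
        attach_cache[[G]] <- list(node = anchors[[key]], monophyletic = TRUE,
                                  label = members)
      } else {
        nodes <- match(members, A$label[seq_along(btips)])
        m <- .adj_mrca(A, nodes)
        below <- intersect(A$label[.adj_tips_below(A, m)], btips)
        mono <- setequal(below, members)
        if (!mono)
          warnings <- c(warnings, paste0(
            "group '", G, "' is not monophyletic on the backbone; ",
            "attached at the MRCA of its members"))
        lab <- if (nzchar(A$label[m])) A$label[m] else paste0("mrca(", G, ")")
        attach_cache[[G]] <- list(node = m, monophyletic = mono, label = lab)
      }
    }
    at <- attach_cache[[G]]
    if (u$type == "taxon") {
      A <- .adj_add_child(A, at$node, label = u$id, len = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = u$id, unit_group = NA_character_, attachment_group = G,
        attachment = at$label, monophyletic = at$monophyletic,
        stringsAsFactors = FALSE)
    } else {
      res <- .adj_add_group_subtree(A, at$node, u$id, idx)
      A <- res$A
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = res$taxa, unit_group = u$id, attachment_group = G,
        attachment = at$label, monophyletic = at$monophyletic,
        stringsAsFactors = FALSE)
    }
  }

  tree <- .adjacency_to_phylo(A)
  tree <- ape::collapse.singles(tree)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  stopifnot(setequal(tree$tip.label, x$taxon))
  structure(list(tree = tree, report = report, warnings = warnings),
            class = "graft_result")
}

#' @export
print.graft_result <- function(x, ...) {
  cat("Grafted", nrow(x$report), "taxa;",
      length(x$tree$tip.label), "tips in the grafted tree\n")
  if (length(x$warnings) > 0L)
    cat(length(x$warnings), "warning(s), e.g.:", x$warnings[1L], "\n")
  invisible(x)
}

#' Write a graft report as CSV
#'
#' @param x a `"graft_result"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_graft_report <- function(x, file) {
  stopifnot(inherits(x, "graft_result"))
  utils::write.csv(x$report, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

## ---- internal adjacency representation ------------------------------------
## parent/children/label/len vectors indexed by node id; node ids of the
## original tree never change, so attachment points stay valid across grafts.

.as_adjacency <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  parent <- rep(NA_integer_, N)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  len <- rep(NA_real_, N)
  if (!is.null(tree$edge.length)) len[tree$edge[, 2L]] <- tree$edge.length
  label <- character(N)
  label[seq_len(n)] <- tree$tip.label
  if (!is.null(tree$node.label)) label[n + seq_len(tree$Nnode)] <- tree$node.label
  list(parent = parent, children = .children_list(tree), label = label,
       len = len, root = n + 1L, n_original_tips = n)
}

.adj_add_child <- function(A, v, label, len = 0) {
  w <- length(A$parent) + 1L
  A$parent[w] <- v
  A$children[[w]] <- integer(0)
  A$label[w] <- label
  A$len[w] <- len
  A$children[[v]] <- c(A$children[[v]], w)
  A
}

# insert a junction node X between tip v and its parent: parent->X edge gets
# length 0, X->v keeps the tip's full pendant length
.adj_insert_above_tip <- function(A, v) {
  p <- A$parent[v]
  w <- length(A$parent) + 1L
  A$parent[w] <- p
  A$children[[w]] <- v
  A$label[w] <- ""
  A$len[w] <- 0
  A$children[[p]][A$children[[p]] == v] <- w
  A$parent[v] <- w
  list(A = A, node = w)
}

# graft the whole classification subtree rooted at group g (all lengths 0)
.adj_add_group_subtree <- function(A, at, g, idx) {
  taxa <- character(0)
  rec <- function(A, parent_node, grp) {
    A <- .adj_add_child(A, parent_node, label = grp, len = 0)
    gnode <- length(A$parent)
    for (t in idx$direct_taxa[[grp]])
      A <- .adj_add_child(A, gnode, label = t, len = 0)
    taxa <<- c(taxa, idx$direct_taxa[[grp]])
    for (sub in idx$children_groups[[grp]])
      A <- rec(A, gnode, sub)
    A
  }
  A <- rec(A, at, g)
  list(A = A, taxa = taxa)
}

.adj_mrca <- function(A, nodes) {
  path1 <- nodes[1L]
  v <- nodes[1L]
  while (!is.na(A$parent[v])) { v <- A$parent[v]; path1 <- c(path1, v) }
  cut <- 1L
  for (v in nodes[-1L]) {
    w <- v
    repeat {
      pos <- match(w, path1)
      if (!is.na(pos)) { cut <- max(cut, pos); break }
      w <- A$parent[w]
    }
  }
  path1[cut]
}

.adj_tips_below <- function(A, v) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0L) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- A$children[[u]]
    if (length(kids) == 0L) out <- c(out, u)
    else stack <- c(stack, kids)
  }
  out
}

.adjacency_to_phylo <- function(A) {
  # preorder walk; tips and internal nodes renumbered in encounter order
  N <- length(A$parent)
  is_tip <- lengths(A$children) == 0L
  order_nodes <- integer(0)
  stack <- A$root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_nodes <- c(order_nodes, v)
    kids <- A$children[[v]]
    if (length(kids) > 0L) stack <- c(stack, rev(kids))
  }
  tips <- order_nodes[is_tip[order_nodes]]
  internals <- order_nodes[!is_tip[order_nodes]]
  n <- length(tips)
  map <- integer(N)
  map[tips] <- seq_len(n)
  map[internals] <- n + seq_along(internals)
  edge <- matrix(0L, N - 1L, 2L)
  elen <- numeric(N - 1L)
  i <- 0L
  for (v in order_nodes) {
    if (is.na(A$parent[v])) next
    i <- i + 1L
    edge[i, ] <- c(map[A$parent[v]], map[v])
    elen[i] <- A$len[v]
  }
  node_label <- A$label[internals]
  tr <- list(edge = edge, tip.label = A$label[tips],
             Nnode = length(internals), edge.length = elen)
  if (any(nzchar(node_label))) tr$node.label <- node_label
  if (all(is.na(elen))) tr$edge.length <- NULL
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}
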