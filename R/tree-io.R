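#' Parse a Newick string into a rooted tree
#'
#' Reads a rooted, possibly polytomous tree from Newick text.  Unquoted and
#' single-quoted labels are accepted, branch lengths may be absent on any
#' edge (stored as `NA`), internal-node labels are kept, and unifurcations
#' (internal nodes with exactly one child) are collapsed by summing the two
#' incident edge lengths.  An absent length summed with anything stays
#' absent: lengths are never invented.
#'
#' A root edge length, if written, is retained in `$root.edge` but is
#' excluded from [total_branch_length()] and all ED computation, since the
#' root has no ancestral lineage to apportion.
#'
#' @param text a single character string of well-formed Newick, ending in
#'   `";"`.
#' @return an object of class `"phylo"`.  Trees in which every edge lacks a
#'   length have no `edge.length` element; partially lengthed trees carry
#'   `NA` for the absent edges.
#' @seealso [write_newick()], [read_newick()]
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' total_branch_length(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string of Newick")
  .newick_lex_check(text)
  # read.tree mishandles quoted labels holding metacharacters, so quoted
  # labels are swapped for safe placeholders and restored after parsing
  q <- .mask_quoted_labels(trimws(text))
  if (!grepl("(", q$text, fixed = TRUE)) {
    tr <- .parse_single_tip(q$text)
    tr$tip.label <- .restore_labels(tr$tip.label, q$values)
    return(tr)
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = q$text)),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr))
    stop("Newick parse error: input could not be read as a tree")
  tr$tip.label <- .restore_labels(tr$tip.label, q$values)
  if (!is.null(tr$node.label)) {
    tr$node.label <- .restore_labels(tr$node.label, q$values)
    if (all(tr$node.label == "")) tr$node.label <- NULL
  }
  if (!is.null(tr$edge.length)) {
    tr$edge.length[is.nan(tr$edge.length)] <- NA_real_
    if (all(is.na(tr$edge.length))) tr$edge.length <- NULL
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE))
    stop("negative edge length(s) are not allowed")
  tr <- ape::collapse.singles(tr)
  tr
}

#' Read a Newick tree from a file
#'
#' @param file path to a file whose first non-empty line holds a Newick
#'   string.
#' @return a `"phylo"` object, as from [parse_newick()].
#' @export
read_newick <- function(file) {
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("no Newick string found in ", file)
  parse_newick(paste(lines, collapse = ""))
}

# structural lexing with character offsets, so malformed input fails with a
# location instead of whatever read.tree happens to do
.newick_lex_check <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L; in_quote <- FALSE; semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") in_quote <- FALSE
      next
    }
    if (ch == "'") in_quote <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character offset ", i)
    } else if (ch == ";") { semi <- i; break }
  }
  if (in_quote)
    stop("Newick parse error: unterminated quoted label at character offset ",
         length(chars))
  if (is.na(semi))
    stop("Newick parse error: missing terminating ';' at character offset ",
         length(chars))
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character offset ",
         semi)
  invisible(TRUE)
}

# "A;" or "A:3;" — below what read.tree can represent, built by hand
.parse_single_tip <- function(txt) {
  body <- sub(";\\s*$", "", txt)
  if (!nzchar(body)) stop("Newick parse error: empty tree")
  if (grepl(":", body)) {
    lab <- sub(":.*$", "", body)
    len <- suppressWarnings(as.numeric(sub("^[^:]*:", "", body)))
    if (is.na(len)) stop("Newick parse error: bad branch length in '", body, "'")
    if (len < 0) stop("negative edge length(s) are not allowed")
  } else {
    lab <- body
    len <- NA_real_
  }
  tr <- list(edge = matrix(c(2L, 1L), 1L, 2L),
             tip.label = trimws(lab),
             Nnode = 1L)
  if (!is.na(len)) tr$edge.length <- len
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# swap every single-quoted label for a metacharacter-free placeholder;
# '' inside quotes unescapes to a literal quote
.mask_quoted_labels <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  prefix <- "QLBL"
  while (grepl(prefix, text, fixed = TRUE))
    prefix <- paste0(prefix, "Q")
  out <- character(0); values <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    if (chars[i] != "'") { out <- c(out, chars[i]); i <- i + 1L; next }
    j <- i + 1L; lab <- character(0)
    repeat {
      if (chars[j] != "'") { lab <- c(lab, chars[j]); j <- j + 1L; next }
      if (j + 1L <= n && chars[j + 1L] == "'") {  # escaped quote
        lab <- c(lab, "'"); j <- j + 2L; next
      }
      break
    }
    values <- c(values, paste(lab, collapse = ""))
    out <- c(out, sprintf("%s%06d", prefix, length(values)))
    i <- j + 1L
  }
  list(text = paste(out, collapse = ""),
       values = stats::setNames(values,
                                sprintf("%s%06d", prefix, seq_along(values))))
}

.restore_labels <- function(x, values) {
  hit <- !is.na(match(x, names(values)))
  x[hit] <- values[x[hit]]
  x
}

#' Write a tree as a Newick string
#'
#' Emits labels (single-quoting any label containing Newick metacharacters)
#' and branch lengths at full double precision; edges with absent (`NA`)
#' lengths get no length token at all.  `write_newick(parse_newick(s))`
#' reparses to an identical tree.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- .children_list(tree)
  el <- tree$edge.length
  len_of <- rep(NA_real_, n + nnode)
  if (!is.null(el)) len_of[tree$edge[, 2]] <- el
  node_lab <- character(n + nnode)
  node_lab[seq_len(n)] <- tree$tip.label
  if (!is.null(tree$node.label)) node_lab[n + seq_len(nnode)] <- tree$node.label
  rec <- function(v) {
    lab <- .quote_label(node_lab[v])
    sub <- if (length(kids[[v]]) == 0L) lab
           else paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","),
                       ")", lab)
    if (!is.na(len_of[v])) sub <- paste0(sub, ":", .format_blen(len_of[v]))
    sub
  }
  root <- n + 1L
  s <- if (n == 1L && length(kids[[root]]) == 1L) rec(1L) else rec(root)
  if (!is.null(tree$root.edge) && !is.na(tree$root.edge))
    s <- paste0(s, ":", .format_blen(tree$root.edge))
  s <- paste0(s, ";")
  if (!is.null(file)) {
    writeLines(s, file, useBytes = FALSE)
    return(invisible(s))
  }
  s
}

.quote_label <- function(lab) {
  if (!nzchar(lab)) return(lab)
  if (grepl("[][(){}:;,'\t ]", lab))
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  else lab
}

# shortest decimal form that round-trips the double exactly
.format_blen <- function(x) {
  s <- sprintf("%.15g", x)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}

# children of every node, in edge-matrix (plotting) order
.children_list <- function(tree) {
  n <- length(tree$tip.label)
  kids <- vector("list", n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

.parent_vec <- function(tree) {
  par <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}
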