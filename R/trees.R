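# Phylogeny handling.  Trees are ape "phylo" objects; the foreground
# branch of a branch-site scan is identified by the label of the node the
# branch leads to (a tip label or an internal node label) and stored in
# attr(tree, "foreground").  In newick files the foreground branch carries
# the "#1" suffix token used by codon-model software.

FG_MARK <- "__FG__"

#' Tag the foreground branch of a phylogeny
#'
#' @param tree an \code{ape} \code{phylo} object with branch lengths.
#' @param node label of the tip or internal node the foreground branch
#'   leads to.
#' @return The tree with the foreground attribute set.
#' @export
set_foreground <- function(tree, node) {
  labs <- c(tree$tip.label, tree$node.label)
  if (!(node %in% labs)) {
    stop("unknown-branch: no node labelled '", node, "'", call. = FALSE)
  }
  attr(tree, "foreground") <- node
  tree
}

#' @rdname set_foreground
#' @export
get_foreground <- function(tree) attr(tree, "foreground")

# Resolve a node label to its node id.
node_id <- function(tree, label) {
  nt <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) {
    stop("unknown-branch: no node labelled '", label, "'", call. = FALSE)
  }
  nt + j
}

# Postorder edge representation consumed by the likelihood core.
# Returns list(edge, lengths, fg_edge (0 if none), tip_labels).
tree_postorder <- function(tree, foreground = NULL) {
  if (is.null(tree$edge.length)) {
    stop("invalid-tree: tree has no branch lengths", call. = FALSE)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  fg <- foreground %||% get_foreground(tree)
  fg_edge <- 0L
  if (!is.null(fg)) {
    child <- node_id(tree, fg)
    fg_edge <- which(po$edge[, 2] == child)
    if (length(fg_edge) != 1L) {
      stop("unknown-branch: foreground node is not below any branch",
           call. = FALSE)
    }
  }
  list(edge = po$edge, lengths = po$edge.length, fg_edge = as.integer(fg_edge),
       tips = po$tip.label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a newick tree with an optional foreground tag
#'
#' Parses a newick string or file.  A single \code{#1} token after a tip
#' or internal node (the labelling convention of codon-model software)
#' marks the branch above that node as the foreground branch.
#'
#' @param x path to a newick file, or a newick string.
#' @return A \code{phylo} object; the foreground attribute is set if a
#'   \code{#1} tag was present.
#' @examples
#' tr <- read_newick("((A:0.1 #1,B:0.1):0.05,C:0.2);")
#' get_foreground(tr)
#' @export
read_newick <- function(x) {
  txt <- if (file.exists(x) && !grepl("\\(", x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  n_tags <- length(gregexpr("#1", txt, fixed = TRUE)[[1]])
  if (attr(gregexpr("#1", txt, fixed = TRUE)[[1]], "match.length")[1] == -1) {
    n_tags <- 0L
  }
  if (n_tags > 1L) {
    stop("invalid-tree: more than one '#1' foreground tag", call. = FALSE)
  }
  if (n_tags == 1L) {
    txt <- mark_foreground_token(txt)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) stop("invalid-tree: unparsable newick", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("invalid-tree: missing branch lengths", call. = FALSE)
  }
  fg <- NULL
  hit_tip <- grep(FG_MARK, tree$tip.label, fixed = TRUE)
  if (length(hit_tip)) {
    tree$tip.label[hit_tip] <- sub(FG_MARK, "", tree$tip.label[hit_tip],
                                   fixed = TRUE)
    fg <- tree$tip.label[hit_tip]
  }
  if (!is.null(tree$node.label)) {
    hit_node <- grep(FG_MARK, tree$node.label, fixed = TRUE)
    if (length(hit_node)) {
      tree$node.label[hit_node] <- sub(FG_MARK, "", tree$node.label[hit_node],
                                       fixed = TRUE)
      lab <- tree$node.label[hit_node]
      if (lab == "") {
        # unlabelled internal node: give it a label so it stays addressable
        tree$node.label[hit_node] <- "fgnode"
        lab <- "fgnode"
      }
      fg <- lab
    }
  }
  if (!is.null(fg)) tree <- set_foreground(tree, fg)
  tree
}

# Move a "#1" token into the label of the node it follows, so the standard
# newick parser can carry it through as part of the label.
mark_foreground_token <- function(txt) {
  pos <- regexpr("#1", txt, fixed = TRUE)[1]
  i <- pos - 1L
  while (i >= 1L && substr(txt, i, i) == " ") i <- i - 1L
  if (i < 1L) stop("invalid-tree: dangling '#1' tag", call. = FALSE)
  ch <- substr(txt, i, i)
  insert_at <- i + 1L  # default: directly after a label or ')'
  if (grepl("[0-9.eE+-]", ch)) {
    # the tag may follow a branch length; walk back over the number and
    # look for its ':' (labels can end in digits, so ':' decides)
    j <- i
    while (j >= 1L && grepl("[0-9.eE+-]", substr(txt, j, j))) j <- j - 1L
    if (j >= 1L && substr(txt, j, j) == ":") {
      insert_at <- j  # insert marker just before the ':'
    }
  }
  body <- paste0(substr(txt, 1L, insert_at - 1L), FG_MARK,
                 substr(txt, insert_at, pos - 1L),
                 substr(txt, pos + 2L, nchar(txt)))
  # drop the whitespace left where the tag sat
  gsub(paste0(FG_MARK, " +"), FG_MARK, body)
}

#' Write a tree to newick, tagging the foreground branch
#'
#' @param tree a \code{phylo} object, optionally with a foreground
#'   attribute (see \code{\link{set_foreground}}).
#' @param path output file; if \code{NULL} the newick string is returned.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  fg <- get_foreground(tree)
  if (!is.null(fg)) {
    i <- match(fg, tree$tip.label)
    if (!is.na(i)) {
      tree$tip.label[i] <- paste0(tree$tip.label[i], "#1")
    } else {
      j <- match(fg, tree$node.label)
      tree$node.label[j] <- paste0(tree$node.label[j], "#1")
    }
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
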