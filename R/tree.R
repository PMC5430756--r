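#' Read and write rooted Newick trees
#'
#' Thin wrappers over ape's Newick reader/writer that enforce the contract
#' used throughout this package: a rooted tree with uniquely named tips and
#' non-negative branch lengths in millions of years.
#'
#' @param text a Newick string, or `path` a file path (give exactly one).
#' @param path file path.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  stopifnot(xor(is.null(text), is.null(path)))
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse error", call. = FALSE)
  validate_tree(tr)
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_tree(tree)
  if (is.null(path)) ape::write.tree(tree) else ape::write.tree(tree, file = path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-12))
    stop("negative branch lengths", call. = FALSE)
  tree
}

#' Tip character states for heterogametic systems
#'
#' Builds the tip -> state map over `{XY, ZW, OTHER, UNKNOWN}` under one of
#' two coding schemes. Under `two_state` only XY and ZW are observable
#' states and `OTHER` (the unexplained Armadillidium assimile all-male
#' system) is remapped to `UNKNOWN`; under `three_state` `OTHER` is a
#' third observable state with its own transitions.
#'
#' @param states named character vector, names are species/tip labels,
#'   values in `XY`, `ZW`, `OTHER`, `UNKNOWN`.
#' @param scheme `"two_state"` or `"three_state"`.
#' @return named character vector with attributes `scheme` and `levels`
#'   (the observable states), class `"sd_states"`.
#' @export
character_states <- function(states, scheme = c("two_state", "three_state")) {
  scheme <- match.arg(scheme)
  if (is.null(names(states)) || any(names(states) == ""))
    stop("states must be named by tip label", call. = FALSE)
  bad <- !states %in% c("XY", "ZW", "OTHER", "UNKNOWN")
  if (any(bad))
    stop("invalid states: ", paste(unique(states[bad]), collapse = ", "),
         call. = FALSE)
  if (scheme == "two_state") states[states == "OTHER"] <- "UNKNOWN"
  structure(states, scheme = scheme,
            levels = if (scheme == "two_state") c("XY", "ZW")
                     else c("XY", "ZW", "OTHER"),
            class = "sd_states")
}

#' @export
print.sd_states <- function(x, ...) {
  cat("Heterogamety states (", attr(x, "scheme"), "): ", sep = "")
  print(table(factor(unclass(x), levels = c(attr(x, "levels"), "UNKNOWN"))))
  invisible(x)
}

#' Read a tip-state TSV (`species  state`)
#'
#' @param path TSV with header `species` and `state`.
#' @inheritParams character_states
#' @export
read_states <- function(path, scheme = "two_state") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "state") %in% names(df)))
  character_states(stats::setNames(toupper(df$state), df$species), scheme)
}

# align a state vector to a tree's tips; absent tips become UNKNOWN with a
# warning, extra entries are dropped
align_states <- function(tree, states) {
  lv <- attr(states, "levels"); sc <- attr(states, "scheme")
  out <- stats::setNames(unclass(states)[tree$tip.label], tree$tip.label)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " tip(s) absent from the state table, ",
            "treated as UNKNOWN", call. = FALSE)
    out[is.na(out)] <- "UNKNOWN"
  }
  structure(out, scheme = sc, levels = lv, class = "sd_states")
}

#' Drop outgroup taxa before ancestral-state analyses
#'
#' Reconstructions of heterogamety evolution are run on the ingroup only;
#' the outgroups used to root the tree are removed first.
#'
#' @param tree a `phylo`.
#' @param outgroups tip labels to drop.
#' @export
prune_outgroups <- function(tree,
                            outgroups = c("Talitrus_saltator",
                                          "Cherax_quadricarinatus")) {
  keep <- setdiff(tree$tip.label, outgroups)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::drop.tip(tree, setdiff(tree$tip.label, keep))
}

# children list, postorder node sequence and per-node stem length for a
# phylo tree (every non-root node occurs once as a child in the edge
# matrix, so the postorder-sorted child column is a node postorder)
tree_traversal <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- stats::reorder(tree, "postorder")
  kids <- vector("list", n_node)
  elen <- rep(NA_real_, n_node)  # branch length above each node
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    kids[[p]] <- c(kids[[p]], ch)
    elen[ch] <- if (is.null(po$edge.length)) 1 else po$edge.length[i]
  }
  root <- n_tip + 1L
  list(children = kids, postorder = c(po$edge[, 2], root), root = root,
       n_tip = n_tip, edge_len = elen)
}
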