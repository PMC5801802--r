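## branch names: every branch is named by its child node (tip label or
## internal node label; unlabeled internal nodes get "node<k>")
tree_branch_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  node_lab <- tree$node.label
  if (is.null(node_lab) || length(node_lab) != n_node) {
    node_lab <- rep(NA_character_, n_node)
  }
  blank <- is.na(node_lab) | node_lab == ""
  node_lab[blank] <- paste0("node", which(blank) + n_tip)
  c(tree$tip.label, node_lab)
}

validate_species_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree leaf names are not unique", call. = FALSE)
  }
  tree
}

subtree_leaves <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) {
    return(tree$tip.label[node])
  }
  tree$tip.label[
    unlist(ape::prop.part(tree)[[node - n_tip]], use.names = FALSE)
  ]
}

#' Place inactivation events on a species tree under a Dollo model
#'
#' Under Dollo parsimony a functional gene is inactivated at most once and
#' never regained, so an event shared by a set of species maps to the stem
#' branch of their most recent common ancestor. An event whose species set
#' does not equal the full leaf set of that subtree is flagged as
#' inconsistent (homoplasy: the placement implies descendants without the
#' event); it is reported under the MRCA, never re-split.
#'
#' @param events A `shared_events` tibble (see [collect_events()]) and/or
#'   single-species mutations: any tibble with `gene`, `kind`, and either
#'   a `species_set` list-column or a `species` column.
#' @param tree A rooted `phylo` tree whose tips include every event
#'   species. Branches are named by their child node; unlabeled internal
#'   nodes are named `node<k>`.
#' @return A tibble of class `placed_events`: one row per event with
#'   `branch` (child-node label of the stem branch), `node` (ape node
#'   id), `consistent` and `note`.
#' @export
place_events <- function(events, tree) {
  tree <- validate_species_tree(tree)
  labels <- tree_branch_labels(tree)
  n_tip <- length(tree$tip.label)
  events <- as_tibble(events)
  if (!"species_set" %in% names(events)) {
    events$species_set <- as.list(events$species)
  }
  if (!"event_id" %in% names(events)) {
    events$event_id <- seq_len(nrow(events))
  }
  rows <- purrr::pmap_dfr(
    list(events$event_id, events$gene, events$kind, events$species_set),
    function(id, gene, kind, sset) {
      sset <- unique(unlist(sset))
      missing <- setdiff(sset, tree$tip.label)
      if (length(missing) > 0L) {
        stop(
          "species not in tree: ", paste(missing, collapse = ", "),
          call. = FALSE
        )
      }
      node <- if (length(sset) == 1L) {
        match(sset, tree$tip.label)
      } else {
        ape::getMRCA(tree, sset)
      }
      leaves <- subtree_leaves(tree, node)
      consistent <- setequal(leaves, sset)
      tibble(
        event_id = id,
        gene = gene,
        kind = kind,
        n_species = length(sset),
        branch = labels[node],
        node = node,
        consistent = consistent,
        note = if (consistent) {
          ""
        } else {
          paste0(
            "homoplasy: subtree also contains ",
            paste(setdiff(leaves, sset), collapse = ",")
          )
        }
      )
    }
  )
  if (nrow(rows) == 0L) {
    rows <- tibble(
      event_id = integer(), gene = character(), kind = character(),
      n_species = integer(), branch = character(), node = integer(),
      consistent = logical(), note = character()
    )
  }
  class(rows) <- c("placed_events", class(rows))
  rows
}

#' Decorate a species tree with placed gene-loss events
#'
#' Appends the gene names of the events placed on each branch to the
#' label of the branch's child node (`label|loss:geneA,geneB`);
#' inconsistent events carry a `*` homoplasy marker. Returns the
#' annotated tree plus the branch table.
#'
#' @param placements A `placed_events` tibble.
#' @param tree The `phylo` tree the events were placed on.
#' @param newick_path,table_path Optional output paths (Newick / TSV).
#' @return List with `tree` (annotated `phylo`), `newick` (string) and
#'   `table` (tibble: branch, gene, kind, consistent).
#' @export
decorate_tree <- function(placements, tree, newick_path = NULL,
                          table_path = NULL) {
  tree <- validate_species_tree(tree)
  labels <- tree_branch_labels(tree)
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label)) {
    tree$node.label <- labels[(n_tip + 1L):length(labels)]
  }
  ann <- tree
  tab <- as_tibble(placements)[, c("branch", "gene", "kind", "consistent")]
  if (nrow(tab) > 0L) {
    per_branch <- tab |>
      dplyr::group_by(.data$branch) |>
      dplyr::summarise(
        ## Newick-safe separators: ape replaces ":" and "," in labels
        tag = paste0(
          "loss=",
          paste(
            paste0(.data$gene, ifelse(.data$consistent, "", "*")),
            collapse = "+"
          )
        ),
        .groups = "drop"
      )
    for (i in seq_len(nrow(per_branch))) {
      node <- match(per_branch$branch[i], labels)
      new_lab <- paste0(labels[node], "|", per_branch$tag[i])
      if (node <= n_tip) {
        ann$tip.label[node] <- new_lab
      } else {
        ann$node.label[node - n_tip] <- new_lab
      }
    }
  }
  newick <- ape::write.tree(ann)
  if (!is.null(newick_path)) writeLines(newick, newick_path)
  if (!is.null(table_path)) readr::write_tsv(tab, table_path, progress = FALSE)
  list(tree = ann, newick = newick, table = tab)
}
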