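## Readers and writers for the standard formats: Newick strain trees,
## Roary-style presence/absence matrices (Rtab and gene_presence_absence.csv),
## and TSV trait/annotation/result tables.

#' Read a rooted strain tree from a Newick file
#'
#' Parses a Newick tree with branch lengths in substitutions per site.
#' Polytomies (including a basal polytomy) are preserved. Every non-root
#' branch must carry a non-negative length; internal nodes without labels
#' are assigned stable labels (`N<node number>`) so that branches can be
#' referred to by their child-node label throughout the package.
#'
#' @param path path to a Newick file (single tree), or a Newick string
#'   when `text = TRUE`
#' @param text logical; interpret `path` as a literal Newick string
#' @return an [ape::read.tree()] `"phylo"` object with unique tip labels,
#'   complete non-negative branch lengths and non-empty node labels
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
#' @export
read_newick <- function(path, text = FALSE) {
  string <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(string)
  tree <- tryCatch(
    ape::read.tree(text = string),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found", call. = FALSE)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree", call. = FALSE)
  validate_strain_tree(tree)
}

## Cheap syntactic pre-scan so malformed input is reported with a character
## offset (ape's parser does not expose positions).
check_newick_syntax <- function(string) {
  chars <- strsplit(string, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error at character ", i, ": unbalanced ')'", call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error at character ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  if (!grepl(";\\s*$", string))
    stop("Newick parse error at character ", length(chars),
         ": missing terminal ';'", call. = FALSE)
  invisible(TRUE)
}

#' Validate a strain tree
#'
#' Checks the contract shared by all downstream stages: unique leaf labels,
#' a single root, and a finite non-negative branch length on every edge.
#' Missing internal-node labels are filled in as `N<node number>`.
#'
#' @param tree a `"phylo"` object
#' @return the (possibly relabelled) tree, invisibly usable in pipelines
#' @export
validate_strain_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  n_edges <- nrow(tree$edge)
  if (is.null(tree$edge.length) || length(tree$edge.length) != n_edges ||
      anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("missing branch length on one or more edges", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  ## exactly one root: one node that never appears as a child
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, tree$edge[, 2])
  if (length(roots) != 1) stop("tree must have exactly one root", call. = FALSE)
  label_internal_nodes(tree)
}

label_internal_nodes <- function(tree) {
  n_int <- tree$Nnode
  ids <- ape::Ntip(tree) + seq_len(n_int)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0("N", ids[empty])
  if (anyDuplicated(c(tree$tip.label, lab)))
    lab <- paste0("N", ids)   # fall back to guaranteed-unique scheme
  tree$node.label <- lab
  tree
}

## Branch identifiers: the label of the child node of each edge, in
## tree$edge order.
branch_ids <- function(tree) {
  labels <- c(tree$tip.label, tree$node.label)
  labels[tree$edge[, 2]]
}

#' Read a gene-family presence/absence matrix
#'
#' Supports the two Roary output dialects: `rtab` (tab-separated, first
#' column the family id, one column per genome, cells 0/1) and `roary_csv`
#' (`gene_presence_absence.csv`: 14 metadata columns followed by one column
#' per genome; presence is a non-empty cell).
#'
#' @param path input file
#' @param dialect `"rtab"` or `"roary_csv"`
#' @return a list with `matrix` (integer 0/1, genomes x families) and
#'   `singleton` (named logical: family present in exactly one genome)
#' @export
read_presence_matrix <- function(path, dialect = c("rtab", "roary_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "rtab") {
    raw <- read.delim(path, check.names = FALSE, colClasses = "character")
    fam <- raw[[1]]
    if (anyDuplicated(fam))
      stop("duplicated family id: ",
           paste(unique(fam[duplicated(fam)]), collapse = ", "), call. = FALSE)
    cells <- as.matrix(raw[, -1, drop = FALSE])
    if (!all(cells %in% c("0", "1")))
      stop("non-binary cell in Rtab matrix", call. = FALSE)
    mat <- matrix(as.integer(cells), nrow = nrow(cells),
                  dimnames = list(fam, colnames(cells)))
  } else {
    raw <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 15)
      stop("roary_csv requires 14 metadata columns plus >=1 genome column",
           call. = FALSE)
    fam <- raw[[1]]
    if (anyDuplicated(fam))
      stop("duplicated family id: ",
           paste(unique(fam[duplicated(fam)]), collapse = ", "), call. = FALSE)
    cells <- as.matrix(raw[, 15:ncol(raw), drop = FALSE])
    mat <- matrix(as.integer(nzchar(cells) & !is.na(cells)), nrow = nrow(cells),
                  dimnames = list(fam, colnames(cells)))
  }
  mat <- t(mat)  # genomes x families
  list(matrix = mat, singleton = colSums(mat) == 1L)
}

#' Read a per-genome defense-system presence table
#'
#' TSV with a `genome` column followed by one 0/1 column per defense system.
#' Column names must be drawn from the seven tracked systems
#' (`r paste(DEFENSE_SYSTEMS, collapse = ", ")`).
#'
#' @param path input TSV
#' @return integer 0/1 matrix, genomes x systems
#' @export
read_trait_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE)
  if (colnames(raw)[1] != "genome")
    stop("trait table must start with a 'genome' column", call. = FALSE)
  systems <- colnames(raw)[-1]
  bad <- setdiff(systems, DEFENSE_SYSTEMS)
  if (length(bad))
    stop("unknown defense system(s): ", paste(bad, collapse = ", "),
         "; accepted names: ", paste(DEFENSE_SYSTEMS, collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!all(vals %in% c(0L, 1L))) stop("trait values must be 0/1", call. = FALSE)
  storage.mode(vals) <- "integer"
  rownames(vals) <- as.character(raw$genome)
  vals
}

#' Read a gene-family annotation table
#'
#' TSV with columns `family_id`, `mge_class`, `cog_category`,
#' `defense_system`, `mge_resident`, `singleton`.
#'
#' @param path input TSV
#' @return data.frame, one row per family
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("family_id", "mge_class", "cog_category", "defense_system",
              "mge_resident", "singleton")
  missing <- setdiff(needed, colnames(ann))
  if (length(missing))
    stop("annotation missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$family_id)) stop("duplicated family_id", call. = FALSE)
  bad <- setdiff(unique(ann$mge_class), MGE_CLASSES)
  if (length(bad))
    stop("unknown mge_class: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$defense_system), c(DEFENSE_SYSTEMS, "none"))
  if (length(bad))
    stop("unknown defense_system: ", paste(bad, collapse = ", "),
         "; accepted names: ", paste(c(DEFENSE_SYSTEMS, "none"), collapse = ", "),
         call. = FALSE)
  ann$mge_resident <- as.logical(ann$mge_resident)
  ann$singleton <- as.logical(ann$singleton)
  ann[needed]
}

#' Write a result table as TSV
#'
#' All package outputs are TSV with a fixed column order; floating-point
#' columns are serialized at 10 significant digits.
#'
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(x, path) {
  out <- as.data.frame(x)
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) "NA" else format(v, digits = 10, trim = TRUE), "")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param traits trait matrix as returned by [read_trait_table()]
#' @export
write_trait_table <- function(traits, path) {
  df <- data.frame(genome = rownames(traits), as.data.frame(traits),
                   check.names = FALSE)
  write_table(df, path)
}

#' @rdname write_table
#' @param ann annotation data.frame as returned by [read_annotation()]
#' @export
write_annotation <- function(ann, path) {
  out <- ann
  out$mge_resident <- ifelse(ann$mge_resident, "TRUE", "FALSE")
  out$singleton <- ifelse(ann$singleton, "TRUE", "FALSE")
  write_table(out, path)
}

#' @rdname write_table
#' @param mat presence matrix (genomes x families)
#' @export
write_rtab <- function(mat, path) {
  df <- data.frame(Gene = colnames(mat), t(mat), check.names = FALSE)
  write_table(df, path)
}

#' Pair a presence matrix (or trait table) with a strain tree
#'
#' Genome/leaf matching is by exact string equality; any mismatch is a hard
#' error. Rows are reordered to the tree's tip order.
#'
#' @param tree strain tree
#' @param mat matrix with genome row names
#' @return `mat` with rows in `tree$tip.label` order
#' @export
match_tree_data <- function(tree, mat) {
  if (is.null(rownames(mat))) stop("matrix has no genome row names", call. = FALSE)
  extra <- setdiff(rownames(mat), tree$tip.label)
  miss <- setdiff(tree$tip.label, rownames(mat))
  if (length(extra) || length(miss))
    stop("genome set does not match tree leaves",
         if (length(miss)) paste0("; absent from matrix: ",
                                  paste(utils::head(miss, 5), collapse = ", ")),
         if (length(extra)) paste0("; absent from tree: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  mat[tree$tip.label, , drop = FALSE]
}
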