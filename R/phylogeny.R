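# Distance-based phylogeny: Poisson-corrected amino-acid distances,
# neighbor-joining with deterministic tie-breaking, column-bootstrap
# support, and clade-based group assignment against reference exemplars.

aln_to_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    stop("alignment rows must have unique names", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("alignment rows must all have the same length", call. = FALSE)
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Poisson-corrected amino-acid distance matrix
#'
#' For each pair of aligned sequences, the proportion of differing
#' comparable sites p is corrected for multiple substitutions as
#' d = -ln(1 - p), the Poisson-model distance for amino-acid data.
#'
#' @param alignment Named character vector of equal-length gapped
#'   amino-acid strings (gap character `-`), or an `AAStringSet`.
#' @param gap_policy `"complete"` (default; columns containing any gap are
#'   removed before all comparisons) or `"pairwise"` (each pair uses the
#'   columns where neither member is gapped).
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
poisson_distance <- function(alignment, gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  m <- aln_to_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (gap_policy == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no gap-free columns under complete deletion",
                         call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  taxa <- rownames(m)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- m[i, ] != "-" & m[j, ] != "-"
    nc <- sum(comp)
    if (nc == 0L)
      stop("no comparable columns for pair ", taxa[i], "/", taxa[j],
           call. = FALSE)
    p <- sum(m[i, comp] != m[j, comp]) / nc
    if (p >= 1)
      stop("Poisson distance undefined (p >= 1) for pair ",
           taxa[i], "/", taxa[j], call. = FALSE)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

check_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric", call. = FALSE)
  d
}

fmt_len <- function(x) sprintf("%.15g", max(x, 0))

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' rate-corrected criterion Q(i,j) = (m-2) d(i,j) - r(i) - r(j) is joined,
#' with two-point branch-length estimates. Ties in Q are broken by the
#' lowest (row, column) index pair, so results are platform-deterministic.
#' Negative branch estimates are clamped to zero with the deficit
#' transferred to the sibling branch. On additive input the returned
#' tree's path lengths reproduce the input distances.
#'
#' @param dm Symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
nj_tree <- function(dm) {
  d <- check_distance_matrix(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa", call. = FALSE)
  # each active node carries its newick subtree string
  labs <- rownames(d)
  sub <- as.list(labs)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(1L, 2L); bq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (Q[i, j] < bq) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    newsub <- paste0("(", sub[[i]], ":", fmt_len(li), ",",
                     sub[[j]], ":", fmt_len(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    sub <- c(sub[keep], list(newsub))
    d <- d2
  }
  # final three nodes: closed-form three-point branch lengths
  x1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  x2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  x3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", sub[[1]], ":", fmt_len(x1), ",",
                sub[[2]], ":", fmt_len(x2), ",",
                sub[[3]], ":", fmt_len(x3), ");")
  ape::read.tree(text = nwk)
}

#' Internal bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves into two sets; the split is
#' reported canonically as the sorted side that does not contain the
#' alphabetically first taxon.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split strings
#'   (taxa joined by `|`); empty for trees with fewer than 4 tips.
#' @export
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character())
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)        # clades of the (arbitrary) rooting
  labs <- attr(parts, "labels")
  out <- character()
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal bipartition of the full-data tree
#' with the percentage of replicates containing it.
#'
#' @inheritParams poisson_distance
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixed seed gives identical support values.
#' @return A list with `tree` (the full-data `phylo`, node labels carrying
#'   integer support) and `support` (data frame of canonical splits and
#'   their percentages).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = NULL,
                              gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(replicates >= 1L)
  m <- aln_to_matrix(alignment)
  if (nrow(m) < 4L)
    warning("fewer than 4 taxa: no internal bipartitions to support")
  full <- nj_tree(poisson_distance(stats::setNames(apply(m, 1, paste,
                  collapse = ""), rownames(m)), gap_policy))
  splits <- tree_splits(full)
  counts <- stats::setNames(numeric(length(splits)), splits)
  if (!is.null(seed)) set.seed(seed)
  failed <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rows <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                  collapse = ""), rownames(m))
    rep_splits <- tryCatch(
      tree_splits(nj_tree(poisson_distance(rows, gap_policy))),
      error = function(e) { NULL })
    if (is.null(rep_splits)) { failed <- failed + 1L; next }
    hit <- splits %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  if (failed > 0L)
    warning(failed, " replicate(s) had undefined distances and count as ",
            "non-supporting")
  support <- data.frame(split = splits,
                        support = 100 * unname(counts) / replicates,
                        stringsAsFactors = FALSE)
  full <- annotate_support(full, support)
  list(tree = full, support = support)
}

# write integer support values into the node labels of `tree`
annotate_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  labels <- rep("", nn)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(tree$tip.label)[1]
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    hit <- match(key, support$split)
    if (!is.na(hit)) labels[k] <- as.character(round(support$support[hit]))
  }
  tree$node.label <- labels
  tree
}

tip_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # edges in postorder so children are filled before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Assign subfamily/section labels by clade membership
#'
#' Roots the tree at an outgroup and labels each unlabeled taxon with the
#' group of the smallest rooted clade that contains it together with
#' reference exemplars of exactly one group. Taxa whose smallest
#' reference-containing clade spans two groups are reported as
#' `"ambiguous"` rather than guessed.
#'
#' @param tree A `phylo` tree containing the outgroup.
#' @param references Named character vector: names are reference taxon ids,
#'   values their group labels (e.g. `"PT"`, `"YSL"`, or section labels).
#' @param outgroup Taxon id used to root the tree (labeling only; the
#'   unrooted tree is unchanged).
#' @return Data frame with columns `taxon` and `group` covering every tip
#'   except the outgroup; reference taxa keep their given group.
#' @export
assign_clades <- function(tree, references, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup ", outgroup, " not in tree", call. = FALSE)
  if (!length(references)) stop("need at least one reference", call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  desc <- tip_descendants(rooted)
  parent <- integer(ntip + rooted$Nnode)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  ref_ids <- names(references)
  out <- data.frame(taxon = setdiff(rooted$tip.label, outgroup),
                    group = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    tx <- out$taxon[k]
    if (tx %in% ref_ids) { out$group[k] <- references[[tx]]; next }
    node <- match(tx, rooted$tip.label)
    repeat {
      node <- parent[node]
      if (node == 0L) { out$group[k] <- "ambiguous"; break }
      tips_here <- rooted$tip.label[desc[[node]]]
      refs_here <- intersect(tips_here, ref_ids)
      if (length(refs_here)) {
        groups <- unique(references[refs_here])
        out$group[k] <- if (length(groups) == 1L) groups else "ambiguous"
        break
      }
    }
  }
  out
}
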