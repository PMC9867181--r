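# Barcode phylogenetics: uncorrected p-distances, neighbor-joining,
# nonparametric bootstrap.

#' Uncorrected p-distance between two aligned sequences
#'
#' The p-distance is the proportion of differing sites among comparable
#' sites. A site is comparable iff both characters are unambiguous bases
#' (`A`, `C`, `G`, `T`); gaps and IUPAC ambiguity codes are treated as
#' missing data and never count as matches or mismatches.
#'
#' @param a,b Aligned residue strings of equal length.
#' @param deletion `"pairwise"` or `"complete"`. For a single pair the two
#'   modes coincide (complete deletion over a two-sequence set drops
#'   exactly the sites pairwise deletion skips); the distinction matters in
#'   [distance_matrix()], where complete deletion drops columns globally.
#' @return List with `distance` (in `[0, 1]`) and `n_comparable` (sites
#'   compared). Zero comparable sites is an error: the distance is
#'   undefined, not zero.
#' @examples
#' p_distance("ACGT", "ACGA")        # 0.25 over 4 sites
#' p_distance("AC-TN", "ACGTA")      # pairwise deletion: 3 comparable sites
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (nchar(a) != nchar(b)) {
    stop("p_distance requires equal-length sequences (", nchar(a), " vs ", nchar(b), ")")
  }
  ca <- chars(a)
  cb <- chars(b)
  comparable <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(comparable)
  if (n == 0L) stop("no comparable sites: p-distance undefined")
  list(distance = sum(ca[comparable] != cb[comparable]) / n, n_comparable = n)
}

#' Pairwise p-distance matrix for a labeled alignment
#'
#' @param aln A `labeled_alignment` from [as_alignment()] or
#'   [simulate_panel()].
#' @param deletion `"pairwise"` (default; each pair uses the sites where
#'   both members are unambiguous) or `"complete"` (columns containing a gap
#'   or ambiguity in *any* record are dropped globally first).
#' @return A `dist_matrix`: list with `labels`, `d` (symmetric p-distance
#'   matrix, zero diagonal) and `n_comparable` (integer matrix of sites
#'   compared per pair).
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "labeled_alignment"))
  n <- length(aln$id)
  if (n < 2L) stop("distance matrix needs at least 2 records")
  m <- aln_matrix(aln)
  if (deletion == "complete") {
    keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  plain <- m %in% c("A", "C", "G", "T")
  dim(plain) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  nc <- matrix(ncol(m), n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comparable <- plain[i, ] & plain[j, ]
      cnt <- sum(comparable)
      if (cnt == 0L) {
        stop("no comparable sites between '", aln$id[i], "' and '", aln$id[j], "'")
      }
      d[i, j] <- d[j, i] <- sum(m[i, comparable] != m[j, comparable]) / cnt
      nc[i, j] <- nc[j, i] <- cnt
    }
  }
  structure(
    list(labels = aln$id, d = d, n_comparable = nc, deletion = deletion),
    class = "dist_matrix"
  )
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("p-distance matrix (", x$deletion, " deletion), ",
      length(x$labels), " taxa\n", sep = "")
  print(round(x$d, 4L))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration with the Studier–Keppler Q-criterion. Ties in Q
#' are broken by the lexicographically smallest index pair, so results are
#' reproducible. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister edge, preserving the joined pair's
#' total path length. On an additive matrix the leaf-to-leaf path lengths
#' reproduce the input distances exactly (within round-off).
#'
#' @param dm A `dist_matrix` from [distance_matrix()], or a square symmetric
#'   numeric matrix with dimnames.
#' @return An unrooted [ape::phylo] tree (basal trifurcation).
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  stopifnot(!is.null(labels), isTRUE(all.equal(D, t(D))))

  # Node bookkeeping: tips are 1..n; internals are appended. `children`
  # maps an internal node to its (child, branch length) pairs.
  next_node <- n + 1L
  children <- list()
  active <- seq_len(n)       # node ids of current rows of D
  Dw <- D

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (length(active) > 3L) {
    r <- length(active)
    rs <- rowSums(Dw)
    Q <- (r - 2) * Dw - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # lexicographically smallest (i, j) among minima, row-major upper triangle
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < qmin - 1e-12) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    dij <- Dw[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    lens <- clamp_pair(li, lj)
    children[[as.character(next_node)]] <- list(
      list(node = active[i], length = lens[1L]),
      list(node = active[j], length = lens[2L])
    )
    newd <- (Dw[i, ] + Dw[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    active <- c(active[keep], next_node)
    rownames(Dw) <- colnames(Dw) <- NULL
    next_node <- next_node + 1L
  }

  # Final three nodes join at the basal trifurcation (closed form).
  d12 <- Dw[1L, 2L]; d13 <- Dw[1L, 3L]; d23 <- Dw[2L, 3L]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  children[[as.character(next_node)]] <- list(
    list(node = active[1L], length = max(l1, 0)),
    list(node = active[2L], length = max(l2, 0)),
    list(node = active[3L], length = max(l3, 0))
  )
  root <- next_node

  # Convert to an ape phylo in cladewise order.
  n_internal <- length(children)
  edge <- NULL
  edge_len <- NULL
  new_id <- integer(root)        # my id -> ape id
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n + 1L
  assign_ids <- function(node) {
    new_id[node] <<- counter
    counter <<- counter + 1L
    for (ch in children[[as.character(node)]]) {
      if (ch$node > n) assign_ids(ch$node)
    }
  }
  assign_ids(root)
  emit <- function(node) {
    for (ch in children[[as.character(node)]]) {
      edge <<- rbind(edge, c(new_id[node], new_id[ch$node]))
      edge_len <<- c(edge_len, ch$length)
      if (ch$node > n) emit(ch$node)
    }
  }
  emit(root)

  phy <- structure(
    list(
      edge = edge,
      edge.length = as.numeric(edge_len),
      tip.label = labels,
      Nnode = n_internal
    ),
    class = "phylo", order = "cladewise"
  )
  phy
}

# Canonical keys for the non-trivial leaf bipartitions of an unrooted tree.
# Each internal edge splits the leaves in two; the key is the sorted side
# NOT containing the alphabetically first label, pasted with "|".
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  all_labels <- sort(phy$tip.label)
  anchor <- all_labels[1L]
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  clade_tips <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade_tips), use.names = FALSE)
  }
  keys <- character(0)
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2L]
    if (child <= ntip) next               # leaf edge: trivial split
    side <- clade_tips(child)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(phy$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  keys
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `replicates` times; a
#' neighbor-joining tree is built from each resampled alignment, and the
#' support of each internal edge of the original-data tree is the
#' percentage of replicate trees containing the same leaf bipartition.
#' Replicates in which some pair has no comparable sites are skipped with a
#' warning but still count in the denominator. Fully deterministic for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param aln A `labeled_alignment`.
#' @param replicates Number of bootstrap replicates (>= 1); barcode studies
#'   conventionally use 1000.
#' @param seed Integer seed; per-replicate streams are derived from it by
#'   fixed arithmetic.
#' @param deletion Deletion mode passed to [distance_matrix()].
#' @return The original-data NJ tree ([ape::phylo]) with integer percent
#'   supports in `node.label` (empty at the basal node).
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (replicates < 1L) stop("replicates must be >= 1")
  base_tree <- nj_tree(distance_matrix(aln, deletion))
  keys <- tree_bipartitions(base_tree)
  hits <- setNames(numeric(length(keys)), keys)
  skipped <- 0L
  ncol <- aln$n_columns
  for (r in seq_len(replicates)) {
    idx <- with_seed(derive_seed(seed, r), sample.int(ncol, ncol, replace = TRUE))
    rep_aln <- aln
    rep_aln$residues <- vapply(
      strsplit(aln$residues, "", fixed = TRUE),
      function(ch) paste(ch[idx], collapse = ""), character(1L)
    )
    rep_tree <- tryCatch(
      nj_tree(distance_matrix(rep_aln, deletion)),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) {
      skipped <- skipped + 1L
      next
    }
    seen <- tree_bipartitions(rep_tree)
    hit <- keys %in% seen
    hits[hit] <- hits[hit] + 1
  }
  if (skipped > 0L) {
    warning(skipped, " replicate(s) skipped: undefined pairwise distance")
  }
  support <- setNames(as.integer(round(100 * hits / replicates)), names(hits))

  # Map supports back onto internal nodes of the base tree.
  ntip <- length(base_tree$tip.label)
  node.label <- rep("", base_tree$Nnode)
  kids <- split(base_tree$edge[, 2L], base_tree$edge[, 1L])
  anchor <- sort(base_tree$tip.label)[1L]
  clade_tips <- function(node) {
    if (node <= ntip) return(base_tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade_tips), use.names = FALSE)
  }
  for (k in seq_len(nrow(base_tree$edge))) {
    child <- base_tree$edge[k, 2L]
    if (child <= ntip) next
    side <- clade_tips(child)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(base_tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    node.label[child - ntip] <- as.character(support[[key]])
  }
  base_tree$node.label <- node.label
  attr(base_tree, "bootstrap") <- list(
    replicates = replicates, seed = seed, skipped = skipped,
    support = support
  )
  base_tree
}
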