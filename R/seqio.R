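#' Read DNA sequences from a FASTA file
#'
#' Parses (possibly line-wrapped) FASTA via Biostrings, then applies the
#' toolkit's ingest rules: residues are uppercased, `U` is converted to `T`,
#' the record id is the first whitespace-separated token of the header (the
#' remainder is kept as `desc`), and every character must be an IUPAC DNA
#' code or gap.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `desc`, `species`, `role`,
#'   `residues`. `species`/`role` are `"unknown"` until labels are attached
#'   with [as_alignment()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
#' @seealso [write_fasta()], [as_alignment()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("empty FASTA header id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1L])
  desc <- sub("^\\S+\\s*", "", headers)
  residues <- normalize_residues(as.character(set))
  for (i in seq_along(ids)) {
    if (!nzchar(residues[i])) stop("empty sequence for record '", ids[i], "'")
    validate_residues(residues[i], id = ids[i])
  }
  data.frame(
    id = ids, desc = desc,
    species = "unknown", role = "unknown",
    residues = unname(residues),
    stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id` and `residues` (as returned by
#'   [read_fasta()]), or a `labeled_alignment`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "labeled_alignment")) records <- as.data.frame(records)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

ROLE_LEVELS <- c("target", "non_target", "unknown")

#' Read a sample sheet mapping record ids to species and roles
#'
#' The sheet is a TSV with header columns `id`, `species`, `role`. Roles are
#' matched case-insensitively against `target`, `non_target` (also accepted
#' spelled `non-target` or `nontarget`) and `unknown`.
#'
#' @param path Path to the TSV sample sheet.
#' @return Data frame with columns `id`, `species`, `role`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "species", "role")
  missing <- setdiff(need, names(sheet))
  if (length(missing)) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  sheet <- sheet[, need]
  dup <- sheet$id[duplicated(sheet$id)]
  if (length(dup)) stop("sample sheet repeats id ", dup[1L])
  role <- gsub("-", "_", tolower(trimws(sheet$role)))
  role[role == "nontarget"] <- "non_target"
  bad <- which(!role %in% ROLE_LEVELS)
  if (length(bad)) {
    stop(
      "unknown role '", sheet$role[bad[1L]], "' for id '", sheet$id[bad[1L]],
      "'; allowed roles: ", paste(ROLE_LEVELS, collapse = ", ")
    )
  }
  sheet$role <- role
  sheet
}

#' Build a labeled alignment from records and a label mapping
#'
#' Attaches species and role labels to sequence records and enforces the
#' alignment invariants: at least two records, all of identical length, every
#' record labeled.
#'
#' @param records Data frame with columns `id`, `residues` ([read_fasta()]).
#' @param labels Data frame with columns `id`, `species`, `role`
#'   ([read_sample_sheet()]).
#' @return A `labeled_alignment`: list with `id`, `species`, `role`,
#'   `residues` (parallel vectors) and `n_columns`.
#' @export
as_alignment <- function(records, labels) {
  missing <- setdiff(records$id, labels$id)
  if (length(missing)) {
    stop("unlabeled record(s): ", paste(missing, collapse = ", "))
  }
  lens <- nchar(records$residues)
  if (length(unique(lens)) > 1L) {
    stop(
      "records have unequal lengths: ",
      paste(sprintf("%s=%d", records$id, lens), collapse = ", ")
    )
  }
  if (nrow(records) < 2L) stop("an alignment needs at least 2 records")
  idx <- match(records$id, labels$id)
  aln <- structure(
    list(
      id = records$id,
      species = labels$species[idx],
      role = labels$role[idx],
      residues = records$residues,
      n_columns = lens[1L]
    ),
    class = "labeled_alignment"
  )
  aln
}

#' @export
as.data.frame.labeled_alignment <- function(x, ...) {
  data.frame(
    id = x$id, desc = "", species = x$species, role = x$role,
    residues = x$residues, stringsAsFactors = FALSE
  )
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(
    "labeled_alignment: ", length(x$id), " records x ", x$n_columns,
    " columns (", sum(x$role == "target"), " target, ",
    sum(x$role == "non_target"), " non-target)\n",
    sep = ""
  )
  invisible(x)
}

# Character matrix view (records x columns) of an alignment.
aln_matrix <- function(aln) {
  m <- matrix(
    unlist(strsplit(aln$residues, "", fixed = TRUE), use.names = FALSE),
    nrow = length(aln$id), ncol = aln$n_columns, byrow = TRUE
  )
  rownames(m) <- aln$id
  m
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are written with six decimals; integer bootstrap supports
#' (the tree's `node.label`) become internal node labels, the encoding with
#' the widest parser support. The output re-parses with [ape::read.tree()].
#'
#' @param tree An [ape::phylo] object (e.g. from [nj_tree()] or
#'   [bootstrap_support()]).
#' @param path Optional file to write to.
#' @return The Newick string (invisibly if `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (is.null(tree$node.label)) return("")
    l <- tree$node.label[node - ntip]
    if (is.na(l) || !nzchar(as.character(l))) "" else as.character(l)
  }
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(lab(node))
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2L]
      len <- if (is.null(tree$edge.length)) "" else {
        sprintf(":%.6f", tree$edge.length[r])
      }
      paste0(build(child), len)
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  txt <- paste0(build(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a distance matrix as square TSV
#'
#' Values are printed with two decimals (the display precision of barcode
#' distance reports); the diagonal is `0.00`.
#'
#' @param dm A `dist_matrix` from [distance_matrix()], or any square numeric
#'   matrix with dimnames.
#' @param path Optional output file.
#' @return The TSV text as a character vector of lines (invisibly if `path`
#'   is given).
#' @export
write_matrix_tsv <- function(dm, path = NULL) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else dm
  labels <- rownames(d)
  lines <- c(
    paste(c("", labels), collapse = "\t"),
    vapply(seq_along(labels), function(i) {
      paste(c(labels[i], sprintf("%.2f", d[i, ])), collapse = "\t")
    }, character(1L))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
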