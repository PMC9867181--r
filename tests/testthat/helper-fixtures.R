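# Shared fixtures and independent oracles. Everything is generated in code;
# no binary data.

ASMF <- known_primers()[["ASMF"]]   # CCTTCTACTTTTATCTTTACCTGTT (25 nt)
ASMR <- known_primers()[["ASMR"]]   # ATTGTAGCAGAGGTAAAG (18 nt)

# Independent per-site p-distance counter (the brute-force oracle).
oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  plain <- c("A", "C", "G", "T")
  n <- 0L; mism <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% plain && cb[i] %in% plain) {
      n <- n + 1L
      if (ca[i] != cb[i]) mism <- mism + 1L
    }
  }
  list(distance = if (n > 0L) mism / n else NA_real_, n_comparable = n)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Quick labeled alignment straight from residue strings.
make_alignment <- function(residues, species, role, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(residues))
  structure(
    list(id = ids, species = species, role = role, residues = residues,
         n_columns = nchar(residues[1])),
    class = "labeled_alignment"
  )
}

# A template carrying the ASMF site, `gap` spacer bases, then the reverse
# binding site for ASMR: the constructed 543 bp amplicon fixture
# (25 + 500 + 18) when pad = 0, gap = 500.
amplicon_fixture <- function(gap = 500L, pad_left = 0L, pad_right = 0L,
                             seed = 42L) {
  set.seed(seed)
  paste0(
    random_dna(pad_left), ASMF, random_dna(gap), revcomp(ASMR),
    random_dna(pad_right)
  )
}

# Package-internal bipartition canonicalizer, reachable from the installed
# namespace.
tree_bipartitions_for_test <- function(phy) sscoi:::tree_bipartitions(phy)

# Canonical bipartition keys of an ape tree, independent of the package's
# tree_bipartitions (uses ape::prop.part on the unrooted topology).
ape_bipartitions <- function(phy) {
  labels <- phy$tip.label
  anchor <- sort(labels)[1]
  pp <- ape::prop.part(phy)
  keys <- character(0)
  for (part in pp) {
    side <- labels[part]
    if (length(side) < 2 || length(side) > length(labels) - 2) next
    if (anchor %in% side) side <- setdiff(labels, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# Synthetic specificity panel mirroring a published gel layout: 4 target
# templates with planted ASMF/ASMR sites, 12 non-target templates without.
fig6_analog_panel <- function(seed = 11L) {
  set.seed(seed)
  n_t <- 4L; n_nt <- 12L
  base_len <- 658L
  target <- lapply(seq_len(n_t), function(i) {
    s <- random_dna(base_len)
    s <- plant_binding_sites(s, ASMF, ASMR, fwd_pos = 60L, rev_pos = 585L)
    s
  })
  nontarget_species <- rep(c("Lymantria xylina", "Lymantria monacha",
                             "Lymantria apicebrunnea"), each = 4L)
  nontarget <- replicate(n_nt, random_dna(base_len))
  data.frame(
    id = c(sprintf("ASM_%d", seq_len(n_t)), sprintf("NT_%d", seq_len(n_nt))),
    species = c(rep("Lymantria dispar asiatica", n_t), nontarget_species),
    role = c(rep("target", n_t), rep("non_target", n_nt)),
    residues = c(unlist(target), nontarget),
    stringsAsFactors = FALSE
  )
}

# Alignment with a planted diagnostic block: targets identical everywhere;
# each non-target species differs from the target consensus at `n_diff`
# fixed columns inside [block_start, block_start + block_len) and matches
# elsewhere inside the block; outside the block everything is identical
# across roles (so the block is the only diagnostic signal).
planted_block_alignment <- function(n_columns = 120L, block_start = 40L,
                                    block_len = 30L, n_diff = 5L,
                                    n_target = 4L, species = c("sp1", "sp2"),
                                    per_species = 2L, seed = 5L) {
  set.seed(seed)
  backbone <- strsplit(random_dna(n_columns), "")[[1]]
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  target_seq <- paste(backbone, collapse = "")
  seqs <- rep(target_seq, n_target)
  sp <- rep("target sp", n_target)
  role <- rep("target", n_target)
  diff_cols <- block_start + seq_len(n_diff) * 5L   # spread inside block
  stopifnot(max(diff_cols) <= block_start + block_len)
  for (s in species) {
    mutated <- backbone
    for (j in diff_cols) mutated[j] <- flip(backbone[j])
    for (i in seq_len(per_species)) {
      seqs <- c(seqs, paste(mutated, collapse = ""))
      sp <- c(sp, s)
      role <- c(role, "non_target")
    }
  }
  list(
    alignment = make_alignment(seqs, sp, role),
    block = c(start = block_start, end = block_start + block_len),
    diff_cols = diff_cols
  )
}

# Brute-force diagnostic-window oracle: enumerate every window of length
# >= min_len over eligible, sufficiently conserved columns and return the
# union as maximal merged intervals (matrix with start/end 0-based
# half-open), recomputing everything from the alignment itself.
oracle_windows <- function(aln, min_len, min_within, min_disc) {
  m <- matrix(unlist(strsplit(aln$residues, "")), nrow = length(aln$id),
              byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  is_t <- aln$role == "target"
  cons <- apply(m[is_t, , drop = FALSE], 2, function(col) {
    col <- col[col %in% bases]
    if (!length(col)) return(NA)
    names(sort(table(factor(col, levels = bases)), decreasing = TRUE))[1]
  })
  eligible <- apply(m[is_t, , drop = FALSE], 2, function(col) all(col %in% bases))
  within <- sapply(seq_len(ncol(m)), function(j) {
    if (!eligible[j]) return(0)
    mean(m[is_t, j] == cons[j])
  })
  spp <- unique(aln$species[aln$role == "non_target"])
  disc <- sapply(seq_len(ncol(m)), function(j) {
    if (is.na(cons[j])) return(rep(FALSE, length(spp)))
    sapply(spp, function(s) {
      col <- m[aln$role == "non_target" & aln$species == s, j]
      col <- col[col %in% bases]
      if (!length(col)) return(FALSE)
      cs <- names(sort(table(factor(col, levels = bases)), decreasing = TRUE))[1]
      cs != cons[j]
    })
  })
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = length(spp))
  ok <- eligible & within >= min_within
  covered <- rep(FALSE, ncol(m))
  for (i in seq_len(ncol(m))) {
    for (j in i:ncol(m)) {
      if (j - i + 1 < min_len) next
      if (!all(ok[i:j])) next
      if (min(rowSums(disc[, i:j, drop = FALSE])) < min_disc) next
      covered[i:j] <- TRUE
    }
  }
  if (!any(covered)) return(matrix(numeric(0), ncol = 2))
  r <- rle(covered)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  cbind(start = s[r$values] - 1, end = e[r$values])
}
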