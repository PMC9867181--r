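# Scan an alignment for regions conserved within the target taxon but
# divergent from every non-target species: the selection step behind
# species-diagnostic primer placement.

#' Per-column conservation/divergence profile
#'
#' For every alignment column, computes the target consensus (most frequent
#' unambiguous base among target records; ties broken alphabetically
#' A < C < G < T), the within-target conservation (share of target records
#' carrying the consensus base), and the divergence of the *nearest*
#' non-target species (the minimum, over non-target species, of the share of
#' that species' records differing from the target consensus). A column is
#' `eligible` for primer placement iff no target record carries a gap or
#' ambiguity code there. Ineligible columns report conservation 0.
#'
#' Non-target records with a gap/ambiguity at a column are excluded from
#' that column's divergence denominator; a species with no unambiguous base
#' at a column is treated as non-discriminating there (conservative).
#'
#' @param aln A `labeled_alignment` with at least one `target` and one
#'   `non_target` record.
#' @return A `site_profile`: list with `n_columns`, `within_conservation`,
#'   `min_nontarget_divergence`, `eligible`, `target_consensus`,
#'   `nontarget_species` and the per-species logical `discriminating`
#'   matrix (species x columns: consensus differs from target consensus).
#' @export
site_profile <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  is_t <- aln$role == "target"
  is_n <- aln$role == "non_target"
  if (!any(is_t)) stop("site_profile needs at least one target record")
  if (!any(is_n)) stop("site_profile needs at least one non_target record")
  m <- aln_matrix(aln)
  nc <- aln$n_columns
  bases <- c("A", "C", "G", "T")

  consensus_of <- function(rows) {
    # per column: most frequent unambiguous base, alphabetical tie-break;
    # NA when the column has no unambiguous base in these rows
    apply(m[rows, , drop = FALSE], 2L, function(col) {
      col <- col[col %in% bases]
      if (!length(col)) return(NA_character_)
      tab <- table(factor(col, levels = bases))
      bases[which.max(tab)]          # which.max takes the first (A<C<G<T) tie
    })
  }

  target_consensus <- consensus_of(which(is_t))
  eligible <- apply(m[is_t, , drop = FALSE], 2L, function(col) all(col %in% bases))
  n_t <- sum(is_t)
  within <- vapply(seq_len(nc), function(j) {
    if (!eligible[j] || is.na(target_consensus[j])) return(0)
    sum(m[is_t, j] == target_consensus[j]) / n_t
  }, numeric(1L))

  nontarget_species <- sort(unique(aln$species[is_n]))
  div <- matrix(0, length(nontarget_species), nc,
                dimnames = list(nontarget_species, NULL))
  disc <- matrix(FALSE, length(nontarget_species), nc,
                 dimnames = list(nontarget_species, NULL))
  for (s in nontarget_species) {
    rows <- which(is_n & aln$species == s)
    cons_s <- consensus_of(rows)
    for (j in seq_len(nc)) {
      if (is.na(target_consensus[j])) next
      col <- m[rows, j]
      col <- col[col %in% bases]
      if (length(col)) div[s, j] <- sum(col != target_consensus[j]) / length(col)
      disc[s, j] <- !is.na(cons_s[j]) && cons_s[j] != target_consensus[j]
    }
  }
  min_div <- if (nrow(div)) apply(div, 2L, min) else rep(0, nc)

  structure(
    list(
      n_columns = nc,
      within_conservation = within,
      min_nontarget_divergence = min_div,
      eligible = eligible,
      target_consensus = target_consensus,
      nontarget_species = nontarget_species,
      discriminating = disc
    ),
    class = "site_profile"
  )
}

#' @export
print.site_profile <- function(x, ...) {
  cat("site_profile: ", x$n_columns, " columns, ",
      sum(x$eligible), " eligible; ", length(x$nontarget_species),
      " non-target species\n", sep = "")
  invisible(x)
}

#' Locate diagnostic windows in a site profile
#'
#' Within every maximal run of eligible columns whose within-target
#' conservation meets `min_within`, all sub-windows of length >= `min_len`
#' whose worst-case species discrimination meets `min_disc_sites` are found
#' and merged into maximal windows. The discrimination of a window is the
#' minimum, over non-target species, of the number of window columns where
#' that species' consensus differs from the target consensus — a diagnostic
#' region must separate the target from its *closest* relative, not just on
#' average.
#'
#' @param profile A `site_profile`.
#' @param min_len Minimum window length in columns (>= 15, the shortest
#'   plausible primer footprint; default 18).
#' @param min_within Minimum within-target conservation per column
#'   (default 0.95).
#' @param min_disc_sites Minimum discriminating sites against every
#'   non-target species (default 2).
#' @return Data frame (class `diagnostic_windows`) with 0-based half-open
#'   `start`/`end`, `length`, `mean_within_conservation`,
#'   `min_discriminating_sites` and `score` (= mean conservation x
#'   discriminating sites), sorted by score descending. May be empty.
#' @export
find_diagnostic_windows <- function(profile, min_len = 18L, min_within = 0.95,
                                    min_disc_sites = 2L) {
  stopifnot(inherits(profile, "site_profile"))
  if (min_len < 15L) stop("min_len must be >= 15 (shortest plausible primer)")
  if (min_within < 0 || min_within > 1) stop("min_within must be in [0, 1]")
  if (min_disc_sites < 0L) stop("min_disc_sites must be >= 0")

  ok <- profile$eligible & profile$within_conservation >= min_within
  disc <- profile$discriminating
  empty <- data.frame(
    start = integer(0), end = integer(0), length = integer(0),
    mean_within_conservation = numeric(0),
    min_discriminating_sites = integer(0), score = numeric(0)
  )
  if (!any(ok)) return(structure(empty, class = c("diagnostic_windows", "data.frame")))

  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  covered <- logical(profile$n_columns)    # union of qualifying sub-windows

  for (k in which(runs$values)) {
    a <- starts[k]; b <- ends[k]
    if (b - a + 1L < min_len) next
    # cumulative discriminating counts per species over [a, b]
    seg <- disc[, a:b, drop = FALSE]
    cum <- cbind(0, t(apply(seg, 1L, cumsum)))     # species x (len+1)
    len_run <- b - a + 1L
    for (i in seq_len(len_run - min_len + 1L)) {
      for (j in (i + min_len - 1L):len_run) {
        worst <- min(cum[, j + 1L] - cum[, i])
        if (worst >= min_disc_sites) covered[(a + i - 1L):(a + j - 1L)] <- TRUE
      }
    }
  }
  if (!any(covered)) return(structure(empty, class = c("diagnostic_windows", "data.frame")))

  cruns <- rle(covered)
  cends <- cumsum(cruns$lengths)
  cstarts <- cends - cruns$lengths + 1L
  out <- do.call(rbind, lapply(which(cruns$values), function(k) {
    a <- cstarts[k]; b <- cends[k]
    worst <- min(rowSums(disc[, a:b, drop = FALSE]))
    mw <- mean(profile$within_conservation[a:b])
    data.frame(
      start = a - 1L, end = b, length = b - a + 1L,
      mean_within_conservation = mw,
      min_discriminating_sites = as.integer(worst),
      score = mw * worst
    )
  }))
  out <- out[order(-out$score, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("diagnostic_windows", "data.frame"))
}

#' Write a diagnostic-window report TSV
#'
#' Human-readable report with 1-based inclusive coordinates (internal
#' coordinates are 0-based half-open).
#'
#' @param windows A `diagnostic_windows` data frame.
#' @param path Optional output file.
#' @return The TSV lines (invisibly if `path` is given).
#' @export
write_window_report <- function(windows, path = NULL) {
  rep <- data.frame(
    start = windows$start + 1L, end = windows$end,
    length = windows$length,
    mean_within_conservation = sprintf("%.4f", windows$mean_within_conservation),
    min_discriminating_sites = windows$min_discriminating_sites,
    score = sprintf("%.4f", windows$score)
  )
  lines <- c(
    paste(names(rep), collapse = "\t"),
    if (nrow(rep)) apply(rep, 1L, paste, collapse = "\t")
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
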