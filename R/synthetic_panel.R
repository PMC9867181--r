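# Simulator for labeled COI-like barcode panels with controlled divergence
# and optional planted primer binding sites. The generated world mirrors a
# diagnostic-assay study design: a target clade of near-identical
# populations and a handful of congeneric species at barcode-scale
# divergence (p ~ 0.06-0.08).

#' Specification for a synthetic barcode panel
#'
#' Defaults state the emulated world: a 658 bp barcode fragment (the
#' canonical COI barcode length), 14 target populations (one per geographic
#' region in the emulated survey), five congeneric non-target species with
#' three sequences each, near-zero within-species divergence (p = 0.005)
#' and between-species divergence drawn uniformly from [0.06, 0.08].
#'
#' @param seed Integer seed; the whole panel is a deterministic function of
#'   these parameters.
#' @param fragment_length Fragment length in bp (>= 100).
#' @param n_target Number of target sequences.
#' @param target_species Species label for target records.
#' @param nontarget_species Named integer vector: sequences per non-target
#'   species.
#' @param within_target_p Per-site substitution probability within a
#'   species (applies to targets and non-targets alike).
#' @param between_species_p Length-2 interval for per-site target-vs-species
#'   divergence.
#' @param planted_sites Optional `list(fwd = , rev = , fwd_pos = ,
#'   rev_pos = )`: primers to splice into every *target* sequence (0-based
#'   positions; `rev_pos` is where the reverse complement of `rev` goes).
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(seed = 1L,
                       fragment_length = 658L,
                       n_target = 14L,
                       target_species = "Lymantria dispar asiatica",
                       nontarget_species = c(
                         "Lymantria xylina" = 3L,
                         "Lymantria monacha" = 3L,
                         "Lymantria apicebrunnea" = 3L,
                         "Lymantria umbrosa" = 3L,
                         "Lymantria fumida" = 3L
                       ),
                       within_target_p = 0.005,
                       between_species_p = c(0.06, 0.08),
                       planted_sites = NULL) {
  stopifnot(
    fragment_length >= 100L, n_target >= 1L,
    within_target_p >= 0, within_target_p < 1,
    length(between_species_p) == 2L,
    between_species_p[1L] <= between_species_p[2L],
    all(between_species_p >= 0), all(between_species_p < 1)
  )
  if (!is.null(planted_sites)) {
    stopifnot(all(c("fwd", "rev", "fwd_pos", "rev_pos") %in% names(planted_sites)))
  }
  structure(
    list(
      seed = as.integer(seed), fragment_length = as.integer(fragment_length),
      n_target = as.integer(n_target), target_species = target_species,
      nontarget_species = nontarget_species,
      within_target_p = within_target_p,
      between_species_p = between_species_p,
      planted_sites = planted_sites
    ),
    class = "panel_spec"
  )
}

#' Mutate a sequence under a uniform substitution model
#'
#' Each site is independently substituted with probability `p` to a
#' uniformly chosen *different* base (Jukes–Cantor-like, no indels).
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param sequence Unambiguous DNA string.
#' @param p Per-site substitution probability in `[0, 1)`; `p = 1` is also
#'   accepted and forces substitution at every site.
#' @param seed Integer seed.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, p, seed) {
  if (!is_unambiguous_dna(sequence)) stop("sequence must be unambiguous DNA")
  stopifnot(p >= 0, p <= 1)
  ch <- chars(sequence)
  with_seed(seed, {
    hit <- stats::runif(length(ch)) < p
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1L))
    }
  })
  paste(ch, collapse = "")
}

#' Splice primer binding sites into a sequence
#'
#' The forward primer replaces the bases at `fwd_pos`; the reverse
#' complement of the reverse primer replaces the bases at `rev_pos`
#' (0-based). Length is preserved; the two sites must not overlap and the
#' reverse site must lie downstream of the forward site.
#'
#' @param sequence DNA string.
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param fwd_pos,rev_pos 0-based start positions on the sequence.
#' @return The edited sequence. Idempotent on repeated planting.
#' @export
plant_binding_sites <- function(sequence, fwd, rev, fwd_pos, rev_pos) {
  n <- nchar(sequence)
  fl <- nchar(fwd); rl <- nchar(rev)
  if (rev_pos < fwd_pos + fl) {
    stop("binding sites overlap or are out of order: reverse site must start ",
         "at or after position ", fwd_pos + fl)
  }
  if (rev_pos + rl > n) {
    stop("sequence too short: reverse site needs positions up to ",
         rev_pos + rl, " but length is ", n)
  }
  substr(sequence, fwd_pos + 1L, fwd_pos + fl) <- fwd
  substr(sequence, rev_pos + 1L, rev_pos + rl) <- revcomp(rev)
  sequence
}

#' Simulate a labeled barcode panel
#'
#' One ancestral sequence is drawn uniformly; it serves as the target
#' species consensus. Each non-target species' consensus is derived by
#' mutating the ancestor at a rate drawn from `between_species_p`.
#' Individual sequences mutate away from their species consensus at
#' `within_target_p`. When `planted_sites` is given, the sites are spliced
#' into every target sequence (after mutation, so the sites are exact).
#'
#' @param spec A [panel_spec()].
#' @return List with `alignment` (a `labeled_alignment`) and `truth`
#'   (seed, per-species generating rates, realized consensus-vs-ancestor
#'   distances, planted site coordinates and expected product size).
#' @export
simulate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  L <- spec$fragment_length
  ancestor <- with_seed(derive_seed(spec$seed, 0L),
                        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = ""))
  stream <- 1L
  next_seed <- function() {
    s <- derive_seed(spec$seed, stream)
    stream <<- stream + 1L
    s
  }

  ids <- character(0); species <- character(0); role <- character(0)
  seqs <- character(0)

  for (i in seq_len(spec$n_target)) {
    s <- mutate_sequence(ancestor, spec$within_target_p, next_seed())
    if (!is.null(spec$planted_sites)) {
      ps <- spec$planted_sites
      s <- plant_binding_sites(s, ps$fwd, ps$rev, ps$fwd_pos, ps$rev_pos)
    }
    ids <- c(ids, sprintf("ASM_%02d", i))
    species <- c(species, spec$target_species)
    role <- c(role, "target")
    seqs <- c(seqs, s)
  }

  rates <- numeric(0)
  realized <- numeric(0)
  for (sp in names(spec$nontarget_species)) {
    rate <- with_seed(next_seed(),
                      stats::runif(1L, spec$between_species_p[1L],
                                   spec$between_species_p[2L]))
    consensus <- mutate_sequence(ancestor, rate, next_seed())
    rates[sp] <- rate
    realized[sp] <- p_distance(ancestor, consensus)$distance
    tag <- toupper(substr(gsub("^\\S+\\s+", "", sp), 1L, 3L))
    for (i in seq_len(spec$nontarget_species[[sp]])) {
      s <- mutate_sequence(consensus, spec$within_target_p, next_seed())
      ids <- c(ids, sprintf("%s_%02d", tag, i))
      species <- c(species, sp)
      role <- c(role, "non_target")
      seqs <- c(seqs, s)
    }
  }

  ids <- make.unique(ids, sep = "_")   # guards exotic species-name clashes
  aln <- structure(
    list(id = ids, species = species, role = role, residues = seqs,
         n_columns = L),
    class = "labeled_alignment"
  )
  truth <- list(
    seed = spec$seed,
    ancestor = ancestor,
    species_rates = rates,
    realized_consensus_distance = realized,
    planted_sites = spec$planted_sites,
    expected_product_size = if (!is.null(spec$planted_sites)) {
      spec$planted_sites$rev_pos + nchar(spec$planted_sites$rev) -
        spec$planted_sites$fwd_pos
    } else NA_integer_
  )
  list(alignment = aln, truth = truth)
}

#' Write a simulated panel to FASTA + sample sheet + truth file
#'
#' @param panel Result of [simulate_panel()].
#' @param out_prefix Path prefix; writes `<prefix>.fa`, `<prefix>.tsv` and
#'   `<prefix>.truth.json`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_panel <- function(panel, out_prefix) {
  aln <- panel$alignment
  fa <- paste0(out_prefix, ".fa")
  sheet <- paste0(out_prefix, ".tsv")
  truth <- paste0(out_prefix, ".truth.json")
  write_fasta(as.data.frame(aln), fa)
  utils::write.table(
    data.frame(id = aln$id, species = aln$species, role = aln$role),
    sheet, sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(panel$truth[setdiff(names(panel$truth), "ancestor")],
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, sheet = sheet, truth = truth))
}
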