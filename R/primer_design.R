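# Primer candidate enumeration, pairing and melting-temperature estimation.

#' GC content of an unambiguous DNA sequence
#'
#' @param sequence Unambiguous DNA string (A/C/G/T only).
#' @return Fraction of G+C in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (!is_unambiguous_dna(sequence)) {
    stop("GC content undefined for ambiguous/gapped sequence")
  }
  ch <- chars(sequence)
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Wallace-rule melting temperature
#'
#' The classic 2(A+T) + 4(G+C) rule. Only calibrated for short oligos
#' (<= 14 nt); for longer primers it is reported as an advisory figure and
#' nearest-neighbor Tm ([tm_nearest_neighbor()]) should be preferred.
#'
#' @param sequence Unambiguous DNA string.
#' @return Tm in degrees Celsius.
#' @export
tm_wallace <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (!is_unambiguous_dna(sequence)) {
    stop("Wallace Tm undefined for ambiguous/gapped sequence")
  }
  ch <- chars(sequence)
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

# Unified nearest-neighbor parameters (SantaLucia 1998, PNAS 95:1460):
# dH in kcal/mol, dS in cal/(mol K), 1 M NaCl reference.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Tm from unified dinucleotide enthalpy/entropy sums with terminal
#' initiation terms, a symmetry correction for self-complementary oligos,
#' and a monovalent-salt entropy correction
#' (dS + 0.368 (N-1) ln\[Na+\]). Tm = 1000 dH / (dS + R ln(C_T/x)) - 273.15
#' with R = 1.987 cal/(mol K), x = 4 for non-self-complementary duplexes.
#'
#' @param sequence Unambiguous DNA string, length >= 8.
#' @param na_mM Monovalent cation concentration in mM (default 50, a common
#'   PCR buffer value).
#' @param primer_nM Primer concentration in nM (default 500).
#' @return Tm in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(sequence, na_mM = 50, primer_nM = 500) {
  if (!is_unambiguous_dna(sequence)) {
    stop("nearest-neighbor Tm undefined for ambiguous/gapped sequence")
  }
  n <- nchar(sequence)
  if (n < 8L) stop("nearest-neighbor Tm requires length >= 8")
  ch <- chars(sequence)
  steps <- paste0(ch[-n], ch[-1L])
  dH <- sum(NN_DH[steps]) + NN_INIT_DH[[ch[1L]]] + NN_INIT_DH[[ch[n]]]
  dS <- sum(NN_DS[steps]) + NN_INIT_DS[[ch[1L]]] + NN_INIT_DS[[ch[n]]]
  selfcomp <- identical(sequence, revcomp(sequence))
  x <- 4
  if (selfcomp) {
    dS <- dS - 1.4
    x <- 1
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- primer_nM * 1e-9
  1000 * dH / (dS + 1.987 * log(ct / x)) - 273.15
}

#' Primer design constraints
#'
#' Defaults are chosen so that typical diagnostic COI primers — including
#' 18–25 nt oligos with moderate AT richness — are admissible: length
#' 18–25, GC 0.30–0.60, Wallace Tm 45–70 °C, homopolymer runs shorter than
#' 5, and no 3'-terminal self-complementarity of 4 bp or more.
#'
#' @param min_len,max_len Primer length bounds (nt).
#' @param gc_min,gc_max GC-fraction bounds.
#' @param tm_min,tm_max Tm bounds in °C, applied to `tm_metric`.
#' @param tm_metric `"wallace"` or `"nn"`.
#' @param max_homopolymer Longest allowed single-base run.
#' @param selfcomp_3p Minimum 3'-terminal self-complementary stretch that
#'   disqualifies a candidate (bp).
#' @param na_mM,primer_nM Conditions for [tm_nearest_neighbor()].
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 25L,
                               gc_min = 0.30, gc_max = 0.60,
                               tm_min = 45, tm_max = 70,
                               tm_metric = c("wallace", "nn"),
                               max_homopolymer = 4L, selfcomp_3p = 4L,
                               na_mM = 50, primer_nM = 500) {
  tm_metric <- match.arg(tm_metric)
  stopifnot(min_len >= 1L, min_len <= max_len, gc_min <= gc_max, tm_min <= tm_max)
  structure(
    list(
      min_len = as.integer(min_len), max_len = as.integer(max_len),
      gc_min = gc_min, gc_max = gc_max,
      tm_min = tm_min, tm_max = tm_max, tm_metric = tm_metric,
      max_homopolymer = as.integer(max_homopolymer),
      selfcomp_3p = as.integer(selfcomp_3p),
      na_mM = na_mM, primer_nM = primer_nM
    ),
    class = "primer_constraints"
  )
}

max_homopolymer_run <- function(sequence) {
  max(rle(chars(sequence))$lengths)
}

# TRUE iff the reverse complement of the 3'-terminal `k` bases occurs in the
# primer: the 3' end can then anneal to (another copy of) the primer.
has_3prime_selfcomp <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(FALSE)
  suffix <- substr(sequence, n - k + 1L, n)
  grepl(revcomp(suffix), sequence, fixed = TRUE)
}

primer_metrics <- function(sequence, constraints) {
  list(
    gc = gc_content(sequence),
    tm_wallace = tm_wallace(sequence),
    tm_nn = if (nchar(sequence) >= 8L) {
      tm_nearest_neighbor(sequence, constraints$na_mM, constraints$primer_nM)
    } else NA_real_,
    homopolymer = max_homopolymer_run(sequence) > constraints$max_homopolymer,
    self_complementary_3prime = has_3prime_selfcomp(sequence, constraints$selfcomp_3p)
  )
}

passes_constraints <- function(sequence, constraints) {
  len <- nchar(sequence)
  if (len < constraints$min_len || len > constraints$max_len) return(FALSE)
  m <- primer_metrics(sequence, constraints)
  tm <- if (constraints$tm_metric == "wallace") m$tm_wallace else m$tm_nn
  !m$homopolymer && !m$self_complementary_3prime &&
    m$gc >= constraints$gc_min && m$gc <= constraints$gc_max &&
    tm >= constraints$tm_min && tm <= constraints$tm_max
}

#' Enumerate primer candidates within a diagnostic window
#'
#' Candidates are drawn from the *target consensus* (one primer pool serves
#' every target population), on both strands, and must satisfy every
#' constraint: length, GC, Tm, homopolymer run, 3'-terminal
#' self-complementarity. Minus-strand candidates store the reverse
#' complement of the reference slice, i.e. the primer as synthesized.
#'
#' @param aln A `labeled_alignment` (target records define the consensus).
#' @param window One row of a `diagnostic_windows` data frame (or any list
#'   with 0-based half-open `start`/`end`).
#' @param constraints A [primer_constraints()] object.
#' @return Data frame (class `primer_candidates`): `sequence`, `strand`,
#'   0-based half-open `start`/`end` on the alignment, `gc`, `tm_wallace`,
#'   `tm_nn`.
#' @export
enumerate_candidates <- function(aln, window, constraints = primer_constraints()) {
  stopifnot(inherits(aln, "labeled_alignment"))
  w_start <- as.integer(window$start)
  w_end <- as.integer(window$end)
  if (w_start < 0L || w_end > aln$n_columns || w_start >= w_end) {
    stop("window [", w_start, ", ", w_end, ") invalid for a ", aln$n_columns,
         "-column alignment")
  }
  is_t <- aln$role == "target"
  if (!any(is_t)) stop("no target records to take a consensus from")
  m <- aln_matrix(aln)[is_t, (w_start + 1L):w_end, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  cons <- apply(m, 2L, function(col) {
    col <- col[col %in% bases]
    if (!length(col)) return(NA_character_)
    tab <- table(factor(col, levels = bases))
    bases[which.max(tab)]
  })
  if (anyNA(cons)) {
    stop("window contains columns with no unambiguous target base")
  }
  cs <- paste(cons, collapse = "")
  wlen <- nchar(cs)

  rows <- list()
  for (len in constraints$min_len:constraints$max_len) {
    if (len > wlen) break
    for (off in 0L:(wlen - len)) {
      sub <- substr(cs, off + 1L, off + len)
      for (strand in c("plus", "minus")) {
        primer <- if (strand == "plus") sub else revcomp(sub)
        if (!passes_constraints(primer, constraints)) next
        met <- primer_metrics(primer, constraints)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = primer, strand = strand,
          start = w_start + off, end = w_start + off + len,
          gc = met$gc, tm_wallace = met$tm_wallace, tm_nn = met$tm_nn,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sequence = character(0), strand = character(0),
    start = integer(0), end = integer(0),
    gc = numeric(0), tm_wallace = numeric(0), tm_nn = numeric(0)
  )
  rownames(out) <- NULL
  structure(out, class = c("primer_candidates", "data.frame"),
            constraints = constraints)
}

#' Pair forward and reverse primer candidates
#'
#' All cross pairs of a plus-strand forward and a minus-strand reverse
#' candidate with the forward binding site upstream of the reverse binding
#' site, product size (reverse binding end minus forward start, in bp)
#' within `product_range`, and nearest-neighbor Tm difference at most
#' `max_tm_diff` are returned, sorted by Tm difference then product size.
#'
#' @param forwards,reverses `primer_candidates` data frames on the same
#'   reference coordinates.
#' @param product_range Length-2 numeric, allowed product size in bp.
#' @param max_tm_diff Maximum |Tm(forward) - Tm(reverse)| in °C.
#' @return Data frame (class `primer_pairs`) with forward/reverse columns
#'   (prefixed `fwd_`/`rev_`), `product_size` and `tm_difference`.
#' @export
pair_candidates <- function(forwards, reverses, product_range = c(100, 2000),
                            max_tm_diff = 10) {
  fw <- forwards[forwards$strand == "plus", , drop = FALSE]
  rv <- reverses[reverses$strand == "minus", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(fw))) {
    for (j in seq_len(nrow(rv))) {
      if (fw$end[i] > rv$start[j]) next
      product <- rv$end[j] - fw$start[i]
      if (product < product_range[1L] || product > product_range[2L]) next
      tmd <- abs(fw$tm_nn[i] - rv$tm_nn[j])
      if (is.na(tmd) || tmd > max_tm_diff) next
      rows[[length(rows) + 1L]] <- data.frame(
        fwd_sequence = fw$sequence[i], fwd_start = fw$start[i],
        fwd_end = fw$end[i], fwd_gc = fw$gc[i],
        fwd_tm_wallace = fw$tm_wallace[i], fwd_tm_nn = fw$tm_nn[i],
        rev_sequence = rv$sequence[j], rev_start = rv$start[j],
        rev_end = rv$end[j], rev_gc = rv$gc[j],
        rev_tm_wallace = rv$tm_wallace[j], rev_tm_nn = rv$tm_nn[j],
        product_size = product, tm_difference = tmd,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    fwd_sequence = character(0), fwd_start = integer(0), fwd_end = integer(0),
    fwd_gc = numeric(0), fwd_tm_wallace = numeric(0), fwd_tm_nn = numeric(0),
    rev_sequence = character(0), rev_start = integer(0), rev_end = integer(0),
    rev_gc = numeric(0), rev_tm_wallace = numeric(0), rev_tm_nn = numeric(0),
    product_size = numeric(0), tm_difference = numeric(0)
  )
  out <- out[order(out$tm_difference, out$product_size), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("primer_pairs", "data.frame"))
}

#' Recommended annealing-temperature interval for a primer pair
#'
#' The default rule is the bench heuristic "Ta = Tm_min - 5 °C", widened
#' upward by 3 °C: the interval `[min(Tm) - below, min(Tm) + above]`. With
#' the Wallace Tms of a typical diagnostic pair this brackets empirically
#' workable annealing ranges.
#'
#' @param pair One row of a `primer_pairs` data frame, or a list with
#'   `fwd_tm_wallace`/`rev_tm_wallace` (or `_nn`) entries.
#' @param below,above Offsets in °C (defaults 5 and 3).
#' @param tm_metric `"wallace"` (default) or `"nn"`.
#' @return Numeric length-2: `c(low, high)` in °C.
#' @export
annealing_recommendation <- function(pair, below = 5, above = 3,
                                     tm_metric = c("wallace", "nn")) {
  tm_metric <- match.arg(tm_metric)
  cols <- paste0(c("fwd_tm_", "rev_tm_"), tm_metric)
  tms <- c(pair[[cols[1L]]], pair[[cols[2L]]])
  if (anyNA(tms)) stop("pair is missing ", tm_metric, " Tm values")
  lo <- min(tms)
  c(lo - below, lo + above)
}

#' Write a primer pair report TSV (1-based inclusive coordinates)
#'
#' @param pairs A `primer_pairs` data frame.
#' @param path Optional output file.
#' @return TSV lines (invisibly if `path` is given).
#' @export
write_pair_report <- function(pairs, path = NULL) {
  rep <- data.frame(
    fwd_sequence = pairs$fwd_sequence,
    fwd_start = pairs$fwd_start + 1L, fwd_end = pairs$fwd_end,
    fwd_gc_pct = sprintf("%.1f", 100 * pairs$fwd_gc),
    fwd_tm_wallace = sprintf("%.1f", pairs$fwd_tm_wallace),
    fwd_tm_nn = sprintf("%.1f", pairs$fwd_tm_nn),
    rev_sequence = pairs$rev_sequence,
    rev_start = pairs$rev_start + 1L, rev_end = pairs$rev_end,
    rev_gc_pct = sprintf("%.1f", 100 * pairs$rev_gc),
    rev_tm_wallace = sprintf("%.1f", pairs$rev_tm_wallace),
    rev_tm_nn = sprintf("%.1f", pairs$rev_tm_nn),
    product_size = pairs$product_size,
    tm_difference = sprintf("%.2f", pairs$tm_difference)
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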