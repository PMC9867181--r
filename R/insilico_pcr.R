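# Degenerate-aware in-silico PCR: binding-site search with a 3'-clamp
# mismatch rule, amplicon prediction, specificity/mixture panels and a
# virtual gel. Detection here is boolean and sequence-determined;
# concentration and cycle kinetics (wet-lab detection limits) are outside
# the model.

# match_matrix[p, t]: template base t is accepted by primer base p iff the
# template base set is a subset of the primer base set. For unambiguous
# template bases this reduces to plain IUPAC intersection; a degenerate
# template base only matches when all of its readings do.
build_match_matrix <- function() {
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (p in codes) {
    for (t in codes) {
      m[p, t] <- all(IUPAC_SETS[[t]] %in% IUPAC_SETS[[p]])
    }
  }
  m
}
.match_cache <- new.env(parent = emptyenv())
primer_template_match <- function() {
  if (is.null(.match_cache$m)) .match_cache$m <- build_match_matrix()
  .match_cache$m
}

#' Do two IUPAC codes denote intersecting base sets?
#'
#' Pure intersection semantics: `N` matches everything, `W` matches `A` or
#' `T`, and so on. Symmetric in its arguments.
#'
#' @param primer_base,template_base Single IUPAC DNA codes (no gaps).
#' @return Logical scalar.
#' @examples
#' iupac_match("W", "A")  # TRUE
#' iupac_match("Y", "G")  # FALSE
#' @export
iupac_match <- function(primer_base, template_base) {
  for (b in c(primer_base, template_base)) {
    if (b == "-") stop("gap character has no base set")
    if (!b %in% names(IUPAC_SETS)) stop("non-IUPAC character '", b, "'")
  }
  length(intersect(IUPAC_SETS[[primer_base]], IUPAC_SETS[[template_base]])) > 0L
}

#' Binding model configuration
#'
#' Standard in-silico PCR practice: up to 2 mismatches overall, none in the
#' 3'-terminal 3-base clamp (where mismatches abolish extension), products
#' up to 3000 bp.
#'
#' @param max_mismatches Maximum total primer/template mismatches.
#' @param clamp_len Length of the 3'-terminal clamp window (nt).
#' @param max_clamp_mismatches Maximum mismatches allowed inside the clamp.
#' @param max_product Maximum predicted product size (bp).
#' @return A `binding_config` list.
#' @export
binding_config <- function(max_mismatches = 2L, clamp_len = 3L,
                           max_clamp_mismatches = 0L, max_product = 3000L) {
  stopifnot(max_mismatches >= 0L, clamp_len >= 0L,
            max_clamp_mismatches >= 0L, max_product >= 1L)
  structure(
    list(
      max_mismatches = as.integer(max_mismatches),
      clamp_len = as.integer(clamp_len),
      max_clamp_mismatches = as.integer(max_clamp_mismatches),
      max_product = as.integer(max_product)
    ),
    class = "binding_config"
  )
}

# Core scan of one primer against one strand of a template (both as
# character vectors over IUPAC, template gap-free). Returns 0-based starts,
# mismatch counts and clamp mismatch counts.
scan_strand <- function(tch, pch, max_mismatches, clamp_len, max_clamp_mismatches) {
  k <- length(pch)
  L <- length(tch)
  if (k > L) {
    return(data.frame(start = integer(0), mismatches = integer(0),
                      clamp_mismatches = integer(0)))
  }
  clamp_idx <- if (clamp_len > 0L) (k - min(clamp_len, k) + 1L):k else integer(0)
  match_tab <- primer_template_match()
  n_off <- L - k + 1L
  mm <- integer(n_off)
  cmm <- integer(n_off)
  # accumulate mismatch counts one primer position at a time (vectorized
  # over all template offsets)
  for (j in seq_len(k)) {
    miss <- !match_tab[pch[j], tch[j:(j + n_off - 1L)]]
    mm <- mm + miss
    if (j %in% clamp_idx) cmm <- cmm + miss
  }
  keep <- which(mm <= max_mismatches & cmm <= max_clamp_mismatches)
  data.frame(start = keep - 1L, mismatches = mm[keep],
             clamp_mismatches = cmm[keep])
}

#' Find primer binding sites on a template
#'
#' The template is taken unaligned (gaps are stripped before scanning). A
#' plus-strand site is a position where the primer, read 5'->3', matches
#' the template with at most `max_mismatches` mismatches overall and at
#' most `max_clamp_mismatches` within the `clamp_len` 3'-terminal bases.
#' Minus-strand sites are found by scanning the reverse complement of the
#' template and mapping coordinates back to the plus strand. Degenerate
#' primer bases match by IUPAC set intersection; a degenerate template base
#' matches only if every base it could denote is covered by the primer
#' base.
#'
#' @param template Template residues (string) or a record with `$residues`.
#' @param primer Primer sequence, 5'->3' IUPAC (degenerate codes allowed).
#' @param config A [binding_config()].
#' @return Data frame (class `binding_sites`) with 0-based half-open
#'   `start`/`end` on the plus strand, `strand`, `mismatches`,
#'   `clamp_mismatches`. A primer longer than the template yields an empty
#'   frame, not an error.
#' @export
find_binding_sites <- function(template, primer, config = binding_config()) {
  if (is.list(template)) template <- template$residues
  template <- gsub("-", "", normalize_residues(template), fixed = TRUE)
  primer <- normalize_residues(primer)
  validate_residues(template)
  validate_residues(primer)
  if (grepl("-", primer, fixed = TRUE)) stop("primer must be gap-free")
  tch <- chars(template)
  pch <- chars(primer)
  L <- length(tch)
  k <- length(pch)

  plus <- scan_strand(tch, pch, config$max_mismatches, config$clamp_len,
                      config$max_clamp_mismatches)
  rch <- chars(revcomp(template))
  minus <- scan_strand(rch, pch, config$max_mismatches, config$clamp_len,
                       config$max_clamp_mismatches)
  out <- rbind(
    if (nrow(plus)) data.frame(
      start = plus$start, end = plus$start + k, strand = "plus",
      mismatches = plus$mismatches, clamp_mismatches = plus$clamp_mismatches
    ),
    if (nrow(minus)) data.frame(
      start = L - minus$start - k, end = L - minus$start, strand = "minus",
      mismatches = minus$mismatches, clamp_mismatches = minus$clamp_mismatches
    )
  )
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      clamp_mismatches = integer(0))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("binding_sites", "data.frame"))
}

# Accept a primer pair as one row of a primer_pairs frame or as a plain
# list/vector with fwd/rev sequences.
pair_sequences <- function(pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L)
    c(fwd = pair$fwd_sequence[1L], rev = pair$rev_sequence[1L])
  } else if (!is.null(pair$fwd_sequence)) {
    c(fwd = pair$fwd_sequence, rev = pair$rev_sequence)
  } else if (!is.null(pair$fwd)) {
    c(fwd = pair$fwd, rev = pair$rev)
  } else if (length(pair) == 2L) {
    c(fwd = pair[[1L]], rev = pair[[2L]])
  } else {
    stop("cannot interpret primer pair")
  }
}

#' Predict amplicons for a primer pair on one template
#'
#' All binding-site combinations in amplifiable orientation with product
#' size at most `config$max_product` are returned. In the canonical
#' orientation (`fwd_plus`) the forward primer binds the plus strand
#' upstream of the reverse primer's minus-strand site and the product size
#' is the reverse binding end minus the forward start, in bp. Because PCR
#' is indifferent to which strand a template is reported on, the flipped
#' orientation (`fwd_minus`: forward on the minus strand downstream of the
#' reverse primer's plus-strand site) is also detected, which makes the
#' predicted product-size multiset invariant under reverse-complementing
#' the template.
#'
#' @param template Residues string or a record (row) with `$id`/`$residues`.
#' @param pair A primer pair: one `primer_pairs` row, or
#'   `list(fwd = , rev = )` of 5'->3' sequences.
#' @param config A [binding_config()].
#' @return Data frame (class `amplicon_predictions`): `template_id`,
#'   forward/reverse site columns, `product_size`; sorted by product size.
#' @export
predict_amplicons <- function(template, pair, config = binding_config()) {
  id <- if (is.list(template) && !is.null(template$id)) {
    template$id[1L]
  } else "template"
  res <- if (is.list(template)) template$residues[1L] else template
  p <- pair_sequences(pair)
  fsites <- find_binding_sites(res, p[["fwd"]], config)
  rsites <- find_binding_sites(res, p[["rev"]], config)
  rows <- list()
  emit <- function(f, r, product, orientation) {
    rows[[length(rows) + 1L]] <<- data.frame(
      template_id = id,
      fwd_start = f$start, fwd_end = f$end, fwd_mismatches = f$mismatches,
      rev_start = r$start, rev_end = r$end, rev_mismatches = r$mismatches,
      product_size = product, orientation = orientation,
      stringsAsFactors = FALSE
    )
  }
  # canonical orientation: forward on plus strand, reverse on minus
  fp <- fsites[fsites$strand == "plus", , drop = FALSE]
  rm_ <- rsites[rsites$strand == "minus", , drop = FALSE]
  for (i in seq_len(nrow(fp))) {
    for (j in seq_len(nrow(rm_))) {
      if (fp$start[i] >= rm_$end[j]) next
      product <- rm_$end[j] - fp$start[i]
      if (product <= config$max_product) {
        emit(fp[i, ], rm_[j, ], product, "fwd_plus")
      }
    }
  }
  # flipped orientation (template supplied reverse-complemented): forward
  # binds the minus strand, reverse the plus strand
  fm <- fsites[fsites$strand == "minus", , drop = FALSE]
  rp <- rsites[rsites$strand == "plus", , drop = FALSE]
  for (i in seq_len(nrow(fm))) {
    for (j in seq_len(nrow(rp))) {
      if (rp$start[j] >= fm$end[i]) next
      product <- fm$end[i] - rp$start[j]
      if (product <= config$max_product) {
        emit(fm[i, ], rp[j, ], product, "fwd_minus")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    template_id = character(0), fwd_start = integer(0), fwd_end = integer(0),
    fwd_mismatches = integer(0), rev_start = integer(0), rev_end = integer(0),
    rev_mismatches = integer(0), product_size = integer(0),
    orientation = character(0)
  )
  out <- out[order(out$product_size), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("amplicon_predictions", "data.frame"))
}

#' Run a specificity panel: one gel lane per template plus a control
#'
#' The computational analog of a specificity gel: each template gets a
#' lane whose bands are the predicted product sizes (top of gel first), and
#' a final no-template control lane is always reported undetected. Lane
#' order follows the input.
#'
#' @param templates Data frame with columns `id`, `species`, `role`,
#'   `residues` (unaligned; gaps are stripped), or a `labeled_alignment`.
#' @param pair Primer pair (see [predict_amplicons()]).
#' @param config A [binding_config()].
#' @return Data frame (class `gel_lanes`): `lane_label`, `species`, `role`,
#'   `detected`, and list-column `band_sizes` (bp, descending).
#' @export
specificity_panel <- function(templates, pair, config = binding_config()) {
  if (inherits(templates, "labeled_alignment")) {
    templates <- as.data.frame(templates)
  }
  if (nrow(templates) == 0L) stop("empty template panel")
  lanes <- lapply(seq_len(nrow(templates)), function(i) {
    amp <- predict_amplicons(templates[i, ], pair, config)
    sizes <- sort(unique(amp$product_size), decreasing = TRUE)
    list(
      lane_label = templates$id[i],
      species = templates$species[i],
      role = templates$role[i],
      detected = length(sizes) > 0L,
      band_sizes = sizes
    )
  })
  out <- data.frame(
    lane_label = c(vapply(lanes, `[[`, character(1L), "lane_label"), "control"),
    species = c(vapply(lanes, `[[`, character(1L), "species"), "none"),
    role = c(vapply(lanes, `[[`, character(1L), "role"), "control"),
    detected = c(vapply(lanes, `[[`, logical(1L), "detected"), FALSE),
    stringsAsFactors = FALSE
  )
  out$band_sizes <- c(lapply(lanes, `[[`, "band_sizes"), list(integer(0)))
  structure(out, class = c("gel_lanes", "data.frame"))
}

#' Mixture panel: target/background template ratios
#'
#' In-silico semantics: binding is sequence-determined, not
#' concentration-determined, so a mixture is detected iff at least one
#' target template copy is present *and* the pair amplifies some target
#' template. Wet-lab detection limits at extreme dilutions are
#' concentration effects outside this model; the returned table carries
#' that annotation in its `"note"` attribute.
#'
#' @param target_templates,background_templates Template data frames
#'   (columns `id`, `residues`; `species`/`role` optional).
#' @param ratios Character vector like `c("1:0", "1:10")` or list of
#'   numeric pairs `(target_copies, background_copies)`.
#' @param pair Primer pair.
#' @param config A [binding_config()].
#' @return Data frame with `ratio`, `target_copies`, `background_copies`,
#'   `detected`.
#' @export
mixture_panel <- function(target_templates, background_templates, ratios,
                          pair, config = binding_config()) {
  parse_ratio <- function(x) {
    if (is.character(x)) as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]]) else as.numeric(x)
  }
  parsed <- lapply(ratios, parse_ratio)
  if (any(vapply(parsed, function(p) length(p) != 2L || any(p < 0), logical(1L)))) {
    stop("each ratio must be two non-negative copy numbers, e.g. '1:100'")
  }
  target_amplifies <- nrow(target_templates) > 0L && any(vapply(
    seq_len(nrow(target_templates)),
    function(i) nrow(predict_amplicons(target_templates[i, ], pair, config)) > 0L,
    logical(1L)
  ))
  out <- data.frame(
    ratio = vapply(parsed, function(p) paste(p, collapse = ":"), character(1L)),
    target_copies = vapply(parsed, `[`, numeric(1L), 1L),
    background_copies = vapply(parsed, `[`, numeric(1L), 2L),
    stringsAsFactors = FALSE
  )
  out$detected <- out$target_copies > 0 & target_amplifies
  attr(out, "note") <- paste(
    "In-silico detection is sequence-determined; wet-lab detection limits",
    "at high dilution are concentration effects outside this model."
  )
  out
}

#' DL2000 ladder sizes (bp, top of gel first)
#' @return Integer vector `c(2000, 1000, 750, 500, 250, 100)`.
#' @export
dl2000_ladder <- function() c(2000L, 1000L, 750L, 500L, 250L, 100L)

#' Render a virtual gel as fixed-width text
#'
#' The ladder lane comes first; each sample band is drawn on its own size
#' row, which places it between the bracketing ladder rungs. A band larger
#' than the top rung is placed above it with a warning.
#'
#' @param lanes A `gel_lanes` data frame from [specificity_panel()].
#' @param ladder Strictly descending rung sizes (default [dl2000_ladder()]).
#' @return Character vector of text lines (class `virtual_gel`).
#' @export
virtual_gel <- function(lanes, ladder = dl2000_ladder()) {
  if (any(diff(ladder) >= 0)) stop("ladder must be strictly descending")
  band_sizes <- unique(unlist(lanes$band_sizes))
  if (length(band_sizes) && max(band_sizes) > ladder[1L]) {
    warning("band of ", max(band_sizes), " bp above the top ladder rung (",
            ladder[1L], " bp)")
  }
  levels <- sort(unique(c(ladder, band_sizes)), decreasing = TRUE)
  lane_names <- lanes$lane_label
  width <- pmax(nchar(lane_names), 4L)
  header <- paste(
    c(sprintf("%7s", "bp"), sprintf("%4s", "M"),
      sprintf(paste0("%", width, "s"), lane_names)),
    collapse = " "
  )
  rows <- vapply(levels, function(sz) {
    rung <- if (sz %in% ladder) "====" else "    "
    cells <- vapply(seq_len(nrow(lanes)), function(i) {
      mark <- if (sz %in% lanes$band_sizes[[i]]) strrep("=", 4L) else ""
      formatC(mark, width = width[i], flag = "-")
    }, character(1L))
    paste(c(sprintf("%7d", sz), rung, cells), collapse = " ")
  }, character(1L))
  structure(c(header, rows), class = "virtual_gel")
}

#' @export
print.virtual_gel <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Write a gel lane report TSV
#'
#' One row per lane: label, species, role, detected, comma-separated band
#' sizes, and the ladder interval bracketing each band.
#'
#' @param lanes A `gel_lanes` data frame.
#' @param path Optional output file.
#' @param ladder Rung sizes for bracketing (default DL2000).
#' @return TSV lines (invisibly if `path` is given).
#' @export
write_lane_report <- function(lanes, path = NULL, ladder = dl2000_ladder()) {
  bracket <- function(sz) {
    if (sz > ladder[1L]) return(paste0(">", ladder[1L]))
    below <- ladder[ladder <= sz]
    above <- ladder[ladder >= sz]
    paste0(if (length(below)) max(below) else paste0("<", min(ladder)),
           "-", min(above))
  }
  lines <- c(
    "lane_label\tspecies\trole\tdetected\tband_sizes\tbrackets",
    vapply(seq_len(nrow(lanes)), function(i) {
      sizes <- lanes$band_sizes[[i]]
      paste(
        lanes$lane_label[i], lanes$species[i], lanes$role[i],
        lanes$detected[i],
        if (length(sizes)) paste(sizes, collapse = ",") else "",
        if (length(sizes)) paste(vapply(sizes, bracket, character(1L)),
                                 collapse = ",") else "",
        sep = "\t"
      )
    }, character(1L))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
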