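# IUPAC nucleotide machinery shared across modules.

# Base sets for every IUPAC code; gap ("-") deliberately absent.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- c(names(IUPAC_SETS), "-")

# Complement map over the full IUPAC alphabet (gap maps to gap).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Reverse complement of an IUPAC DNA string
#'
#' Degenerate codes are complemented set-wise (e.g. `R` -> `Y`); gaps are
#' preserved.
#'
#' @param x Character scalar over the IUPAC DNA alphabet.
#' @return Character scalar, the reverse complement.
#' @examples
#' revcomp("AATTGGWGGWTTYGGAAAYTG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- chars(x)
  bad <- which(!ch %in% names(IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop("non-IUPAC character '", ch[bad[1L]], "' at position ", bad[1L])
  }
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Uppercase, U -> T. Does not validate.
normalize_residues <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Validate residues against the IUPAC alphabet (+ gap); error names the
# first offending character and its 1-based position.
validate_residues <- function(x, id = NULL) {
  ch <- chars(x)
  bad <- which(!ch %in% IUPAC_ALPHABET)
  if (length(bad)) {
    where <- if (is.null(id)) "" else paste0(" in record '", id, "'")
    stop("non-IUPAC character '", ch[bad[1L]], "' at position ", bad[1L], where)
  }
  invisible(x)
}

is_unambiguous_dna <- function(x) {
  all(chars(x) %in% c("A", "C", "G", "T"))
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored on exit, so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483647
}
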