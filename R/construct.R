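AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AA_THREE <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
  P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr"
)

#' Define an annotated membrane-protein construct
#'
#' Builds a validated construct object from a one-letter amino-acid sequence,
#' a residue-numbering offset into the full-length protein, and named domain
#' spans. The construct is the anchor for every downstream per-residue table:
#' chemical-shift-perturbation results and simulated peak lists are labelled
#' with construct positions and mapped back to full-length numbering through
#' it.
#'
#' @param sequence One-letter amino-acid sequence as a single string.
#'   Whitespace is tolerated and stripped.
#' @param first_full_number Full-length residue number of construct position 1.
#'   Construct position `i` maps to `first_full_number + i - 1`.
#' @param domain_spans Named list of `c(start, end)` integer pairs
#'   (1-based, inclusive, construct coordinates). Recognised names:
#'   `ecto`, `tm`, `cyto` (topology tier) and `c1`, `v`, `c2` (cytoplasmic
#'   subregions). Spans must lie within the sequence and must not overlap
#'   within a tier.
#' @return An object of class `nmr_construct`.
#' @examples
#' cons <- sdc4_construct()
#' cons
#' count_residue(cons, "N")
#' @export
make_construct <- function(sequence, first_full_number = 1L, domain_spans = list()) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single string")
  }
  seq_clean <- gsub("[[:space:]]", "", sequence)
  if (!nzchar(seq_clean)) abort("empty sequence")
  residues <- strsplit(toupper(seq_clean), "")[[1]]
  bad <- which(!(residues %in% AA_CODES))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid amino-acid code '%s' at position %d",
      residues[bad[1]], bad[1]
    ))
  }
  n <- length(residues)
  if (!is_scalar_number(first_full_number) || first_full_number != round(first_full_number)) {
    abort("`first_full_number` must be a single integer")
  }
  first_full_number <- as.integer(first_full_number)

  spans <- validate_spans(domain_spans, n)

  structure(
    list(
      sequence = paste(residues, collapse = ""),
      residues = residues,
      first_full_number = first_full_number,
      domain_spans = spans
    ),
    class = "nmr_construct"
  )
}

validate_spans <- function(domain_spans, n) {
  if (length(domain_spans) == 0) return(list())
  known <- c("ecto", "tm", "cyto", "c1", "v", "c2")
  nm <- names(domain_spans)
  if (is.null(nm) || any(!nzchar(nm))) abort("domain spans must be named")
  unknown <- setdiff(nm, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown domain span name(s): %s", paste(unknown, collapse = ", ")))
  }
  spans <- lapply(domain_spans, function(s) {
    s <- as.integer(s)
    if (length(s) != 2L || anyNA(s) || s[1] > s[2]) {
      abort("each domain span must be c(start, end) with start <= end")
    }
    if (s[1] < 1L || s[2] > n) abort("domain span outside [1, sequence length]")
    s
  })
  names(spans) <- nm
  for (tier in list(c("ecto", "tm", "cyto"), c("c1", "v", "c2"))) {
    present <- intersect(tier, nm)
    if (length(present) > 1) {
      occupied <- integer(0)
      for (d in present) {
        idx <- spans[[d]][1]:spans[[d]][2]
        if (length(intersect(occupied, idx)) > 0) {
          abort(sprintf("domain spans overlap within a tier (at '%s')", d))
        }
        occupied <- c(occupied, idx)
      }
    }
  }
  spans
}

#' The syndecan-4 Syd4-eTC construct
#'
#' Convenience constructor for the 57-residue syndecan-4 construct studied by
#' this package: a four-residue ectodomain stub, the 25-residue transmembrane
#' helix (which carries the GXXXG dimerisation motif), and the full
#' cytoplasmic domain with its C1, V and C2 subregions.
#'
#' The default numbering offset (`first_full_number = 142`) places the unique
#' cytoplasmic serine at full-length position 179, the PKC-regulatory
#' phosphorylation site of syndecan-4. Note that syndecan-4 numbering
#' conventions in the literature differ by one residue (the V-domain tyrosine
#' at construct position 47 is variously numbered 187 or 188); the offset is
#' a parameter so either convention can be selected.
#'
#' @param first_full_number Numbering offset; see [make_construct()].
#' @param domain_spans Domain annotation; the default covers
#'   ecto 1-4, TM 5-29, cyto 30-57 with C1 30-39, V 40-52, C2 53-57.
#' @return An `nmr_construct` object of length 57.
#' @export
sdc4_construct <- function(first_full_number = 142L,
                           domain_spans = list(
                             ecto = c(1, 4), tm = c(5, 29), cyto = c(30, 57),
                             c1 = c(30, 39), v = c(40, 52), c2 = c(53, 57)
                           )) {
  make_construct(
    "ERTEV LAALI VGGVV GILFA VFLIL LLVYR IKKKD EGSYD LGKKP IYKKA PTNEF YA",
    first_full_number = first_full_number,
    domain_spans = domain_spans
  )
}

#' @export
print.nmr_construct <- function(x, ...) {
  cat(sprintf(
    "<nmr_construct> %d residues, full-length numbering %d-%d\n",
    length(x$residues), x$first_full_number,
    x$first_full_number + length(x$residues) - 1L
  ))
  cat(" ", x$sequence, "\n")
  if (length(x$domain_spans) > 0) {
    for (nm in names(x$domain_spans)) {
      s <- x$domain_spans[[nm]]
      cat(sprintf("  %-5s %d-%d\n", nm, s[1], s[2]))
    }
  }
  invisible(x)
}

#' @export
length.nmr_construct <- function(x) length(x$residues)

#' Per-residue table for a construct
#'
#' @param x An `nmr_construct`.
#' @param ... Unused.
#' @return A tibble with one row per construct position: `residue`
#'   (construct index), `aa`, `full_number`, `label` (e.g. `"Ser179"`), and
#'   a logical column per annotated domain.
#' @export
tidy.nmr_construct <- function(x, ...) {
  n <- length(x$residues)
  out <- tibble(
    residue = seq_len(n),
    aa = x$residues,
    full_number = x$first_full_number + seq_len(n) - 1L,
    label = paste0(AA_THREE[x$residues], x$first_full_number + seq_len(n) - 1L)
  )
  for (nm in names(x$domain_spans)) {
    s <- x$domain_spans[[nm]]
    out[[nm]] <- out$residue >= s[1] & out$residue <= s[2]
  }
  out
}

#' Count occurrences of an amino acid in a construct
#'
#' @param construct An `nmr_construct`.
#' @param aa Single one-letter amino-acid code.
#' @return Integer count.
#' @export
count_residue <- function(construct, aa) {
  check_construct(construct)
  if (!is.character(aa) || length(aa) != 1L || !(toupper(aa) %in% AA_CODES)) {
    abort(sprintf("`aa` must be a single valid one-letter code, got '%s'", as.character(aa)[1]))
  }
  sum(construct$residues == toupper(aa))
}

#' Map a construct position to full-length numbering
#'
#' @param construct An `nmr_construct`.
#' @param construct_index Position(s) within the construct (1-based).
#' @return A tibble with `residue`, `aa`, `full_number` and `label`
#'   (three-letter code + full-length number, e.g. `"Ser179"`).
#' @export
map_residue <- function(construct, construct_index) {
  check_construct(construct)
  n <- length(construct$residues)
  idx <- as.integer(construct_index)
  if (length(idx) == 0 || anyNA(idx) || any(idx < 1L | idx > n)) {
    abort(sprintf("construct index out of range [1, %d]", n))
  }
  aa <- construct$residues[idx]
  full <- construct$first_full_number + idx - 1L
  tibble(
    residue = idx, aa = aa, full_number = full,
    label = paste0(AA_THREE[aa], full)
  )
}

#' Find GXXXG motifs
#'
#' Scans for the glycine-zipper motif G-x-x-x-G that mediates transmembrane
#' helix dimerisation. All matches are reported, including overlapping ones,
#' ordered by start position.
#'
#' @param construct An `nmr_construct`.
#' @return A tibble with columns `start`, `end` (1-based inclusive construct
#'   positions) and `motif` (the matched 5-mer); zero rows when no motif is
#'   present.
#' @export
find_gxxxg <- function(construct) {
  check_construct(construct)
  v <- construct$residues
  n <- length(v)
  starts <- integer(0)
  if (n >= 5) {
    for (i in seq_len(n - 4L)) {
      if (v[i] == "G" && v[i + 4L] == "G") starts <- c(starts, i)
    }
  }
  tibble(
    start = starts,
    end = starts + 4L,
    motif = vapply(starts, function(i) paste(v[i:(i + 4L)], collapse = ""), character(1))
  )
}

#' Read a construct from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @inheritParams make_construct
#' @return An `nmr_construct`.
#' @export
read_construct_fasta <- function(path, first_full_number = 1L, domain_spans = list()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) != 1L || headers[1] != 1L) {
    abort("FASTA file must contain exactly one record")
  }
  make_construct(
    paste(lines[-1], collapse = ""),
    first_full_number = first_full_number,
    domain_spans = domain_spans
  )
}

check_construct <- function(x) {
  if (!inherits(x, "nmr_construct")) abort("expected an `nmr_construct` object")
  invisible(x)
}

# construct positions that carry a backbone amide H-N pair:
# everything except position 1 (no preceding carbonyl in the construct)
# and prolines (no amide proton)
amide_positions <- function(construct) {
  check_construct(construct)
  idx <- seq_along(construct$residues)
  idx[idx != 1L & construct$residues != "P"]
}
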